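eu <- geneticCode("euplotes")

# hand-build a transcript with one planted event so classifyEvent can be
# tested without the generator: reference codons, with the first `model`
# bases of the stop codon re-inserted at a codon boundary
plantOne <- function(context, model, nCodons = 120L, site = 60L,
                     seed = 71) {
    set.seed(seed)
    tab <- codonTable(eu)
    sense <- names(tab)[tab != "*"]
    codons <- sample(sense, nCodons, replace = TRUE)
    up <- substr(context, 1L, 3L)
    stopC <- substr(context, 4L, 6L)
    codons[site - 1L] <- up
    suf <- substr(stopC, model + 1L, 3L)
    cands <- sense[startsWith(sense, suf)]
    codons[site] <- cands[1L]
    ref <- paste0(unname(tab[codons]), collapse = "")
    tx <- paste0(paste0(codons[seq_len(site - 1L)], collapse = ""),
                 substr(stopC, 1L, model),
                 paste0(codons[site:nCodons], collapse = ""), "TAA")
    list(tx = tx, ref = ref, stopPos = 3L * (site - 1L))
}

test_that("single-base excision classifies a +1 event with its context", {
    p <- plantOne("AAATAA", 1L)
    ev <- classifyEvent(p$tx, p$stopPos, p$ref, eu)
    expect_identical(ev$model, 1L)
    expect_identical(ev$excised, "T")
    expect_identical(ev$slippery, "AAATAA")
    expect_identical(ev$stopCodon, "TAA")
    expect_identical(ev$position, p$stopPos)
})

test_that("two-base excision classifies a +2 event (TGTTAG context)", {
    p <- plantOne("TGTTAG", 2L)
    ev <- classifyEvent(p$tx, p$stopPos, p$ref, eu)
    expect_identical(ev$model, 2L)
    expect_identical(ev$excised, "TA")
    expect_identical(ev$slippery, "TGTTAG")
})

test_that("a stop followed by unrelated sequence classifies as none", {
    set.seed(72)
    pre <- randomCds(60L)
    tx <- paste0(pre, "TAA", randomDna(240L))
    ref <- translateDNA(pre, eu)
    expect_null(classifyEvent(tx, 180L, ref, eu))
})

test_that("classifying a non-stop position is a precondition error", {
    p <- plantOne("AAATAA", 1L)
    expect_error(classifyEvent(p$tx, p$stopPos + 3L, p$ref, eu),
                 "not a stop codon")
})

test_that("candidate pairs require two frames on the same reference", {
    h <- function(q, s, f, qs, ss) data.frame(
        query_id = q, subject_id = s, pct_identity = 100,
        aln_length = 50L, mismatches = 0L, gap_opens = 0L,
        q_start = qs, q_end = qs + 149L, s_start = ss, s_end = ss + 49L,
        evalue = 1e-30, bitscore = 100, frame = f,
        stringsAsFactors = FALSE)
    twoFrames <- rbind(h("t1", "r1", 1L, 1L, 1L),
                       h("t1", "r1", 2L, 200L, 121L))
    expect_identical(findCandidates(twoFrames)$transcript_id, "t1")
    sameFrame <- rbind(h("t2", "r1", 1L, 1L, 1L),
                       h("t2", "r1", 1L, 200L, 121L))
    expect_identical(nrow(findCandidates(sameFrame)), 0L)
    twoRefs <- rbind(h("t3", "r1", 1L, 1L, 1L),
                     h("t3", "r2", 2L, 200L, 121L))
    expect_identical(nrow(findCandidates(twoRefs)), 0L)
    noFrame <- transform(twoFrames, frame = 0L)
    expect_error(findCandidates(noFrame), "frame")
})

test_that("a three-stop +1 pattern yields three ordered +1 events", {
    spec <- synthSpec(seed = 73, prfPlan = list(
        list(contexts = c("AAATAA", "AAATAG", "AAATAA"),
             models = c(1L, 1L, 1L))))
    p <- synthPrfSet(spec)
    genes <- detectPrf(p$transcripts, p$references, p$hits, eu)
    expect_length(genes, 1L)
    expect_identical(nEvents(genes[[1L]]), 3L)
    ev <- prfEvents(genes[[1L]])
    expect_identical(ev$model, c(1L, 1L, 1L))
    expect_identical(ev$slippery, c("AAATAA", "AAATAG", "AAATAA"))
    expect_false(is.unsorted(ev$position, strictly = TRUE))
    expect_identical(ev$position, p$truth$position)
})

test_that("clean transcripts produce no candidates and no events", {
    spec <- synthSpec(seed = 74, prfPlan = list(NULL, NULL, NULL))
    p <- synthPrfSet(spec)
    expect_identical(nrow(p$truth), 0L)
    expect_length(detectPrf(p$transcripts, p$references, p$hits, eu), 0L)
})

test_that("planted events are recovered exactly, in any input order", {
    spec <- synthSpec(seed = 75, nTranscripts = 30L)
    p <- synthPrfSet(spec)
    genes <- detectPrf(p$transcripts, p$references, p$hits, eu)
    found <- do.call(rbind, lapply(genes, function(g)
        cbind(transcript = g@transcriptId, prfEvents(g))))
    key <- function(df) paste(df$transcript, df$position, df$model)
    expect_setequal(key(found),
                    paste(p$truth$transcript, p$truth$position,
                          p$truth$model))
    expect_identical(found$slippery,
                     p$truth$slippery[order(p$truth$transcript,
                                            p$truth$position)])
    # permuting transcript order leaves the detected gene set unchanged
    perm <- rev(seq_along(p$transcripts))
    genes2 <- detectPrf(p$transcripts[perm], p$references, p$hits, eu)
    expect_setequal(vapply(genes2, function(g) g@transcriptId, ""),
                    vapply(genes, function(g) g@transcriptId, ""))
})

test_that("deleting one or two bases shifts downstream frames as claimed", {
    set.seed(76)
    cds <- randomCds(80L)
    for (k in 1:2) {
        pos <- 120L
        edited <- paste0(substr(cds, 1L, pos),
                         substr(cds, pos + k + 1L, nchar(cds)))
        aaE <- translateDNA(edited, eu)
        # downstream of the cut, translation equals the (k+1)-frame read
        down <- translateDNA(substr(cds, pos + k + 1L, nchar(cds)), eu)
        expect_identical(substr(aaE, pos / 3 + 1L, nchar(aaE)), down)
    }
})

test_that("applying detected excisions yields one ORF matching the reference", {
    spec <- synthSpec(seed = 77, prfPlan = list(
        list(contexts = c("TGTTAG", "AAATAA"), models = c(2L, 1L))))
    p <- synthPrfSet(spec)
    genes <- detectPrf(p$transcripts, p$references, p$hits, eu)
    expect_length(genes, 1L)
    tx <- as.character(p$transcripts[[1L]])
    for (i in rev(seq_len(nEvents(genes[[1L]])))) {
        ev <- prfEvents(genes[[1L]])[i, ]
        tx <- paste0(substr(tx, 1L, ev$position),
                     substr(tx, ev$position + ev$model + 1L, nchar(tx)))
    }
    aa <- translateDNA(tx, eu)
    expect_identical(aa, paste0(as.character(p$references[[1L]]), "*"))
})

test_that("the event cap truncates detection and flags the gene", {
    spec <- synthSpec(seed = 78, prfPlan = list(
        list(contexts = c("AAATAA", "AAATAA", "AAATAA"),
             models = c(1L, 1L, 1L))))
    p <- synthPrfSet(spec)
    genes <- detectPrf(p$transcripts, p$references, p$hits, eu,
                       maxEvents = 2L)
    expect_identical(nEvents(genes[[1L]]), 2L)
    expect_true(genes[[1L]]@truncated)
})

test_that("strict AAATAR mode rejects non-canonical contexts", {
    spec <- synthSpec(seed = 79, prfPlan = list(
        list(contexts = "TGTTAG", models = 2L),
        list(contexts = "AAATAA", models = 1L)))
    p <- synthPrfSet(spec)
    strict <- detectPrf(p$transcripts, p$references, p$hits, eu,
                        requireAaatar = TRUE)
    expect_length(strict, 1L)
    expect_identical(strict[[1L]]@transcriptId, "trans0002")
    loose <- detectPrf(p$transcripts, p$references, p$hits, eu)
    expect_length(loose, 2L)
})

test_that("the report table round-trips the gene list", {
    spec <- synthSpec(seed = 80, nTranscripts = 10L)
    p <- synthPrfSet(spec)
    genes <- detectPrf(p$transcripts, p$references, p$hits, eu)
    rep <- prfReport(genes)
    expect_identical(rep$n_events,
                     vapply(genes, nEvents, 1L))
    back <- parsePrfReport(rep)
    core <- c("position", "stopCodon", "slippery", "model", "excised")
    for (i in seq_along(genes)) {
        expect_identical(back[[i]]@transcriptId, genes[[i]]@transcriptId)
        ev1 <- prfEvents(genes[[i]])[, core]
        ev2 <- prfEvents(back[[i]])[, core]
        rownames(ev1) <- rownames(ev2) <- NULL
        expect_identical(ev1, ev2)
    }
    expect_identical(nrow(prfReport(list())), 0L)
})
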
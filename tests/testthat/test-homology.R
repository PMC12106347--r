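eu <- geneticCode("euplotes")

test_that("a self-hit has full identity, coverage and a tiny E-value", {
    set.seed(81)
    q <- randomProtein(120L)
    h <- searchProtein(c(q1 = q), c(s1 = q))
    expect_identical(nrow(h), 1L)
    expect_equal(h$pct_identity, 100)
    expect_identical(c(h$q_start, h$q_end), c(1L, 120L))
    expect_identical(c(h$s_start, h$s_end), c(1L, 120L))
    expect_lt(h$evalue, 1e-50)
})

test_that("shuffled decoys are not hit at E <= 1e-5", {
    set.seed(82)
    q <- randomProtein(80L)
    letters <- strsplit(q, "")[[1L]]
    decoys <- vapply(1:50, function(i)
        paste0(sample(letters), collapse = ""), "")
    names(decoys) <- paste0("decoy", 1:50)
    h <- searchProtein(c(q1 = q), decoys)
    expect_identical(nrow(h), 0L)
})

test_that("alignment scores equal the brute-force Gotoh oracle", {
    data("BLOSUM62", package = "Biostrings", envir = environment())
    set.seed(83)
    for (i in 1:12) {
        a <- randomProtein(sample(15:50, 1L))
        b <- randomProtein(sample(15:50, 1L))
        if (i %% 3 == 0)  # give some pairs real shared signal
            b <- paste0(substr(a, 3L, 28L), b)
        aln <- Biostrings::pairwiseAlignment(
            a, b, type = "local", substitutionMatrix = "BLOSUM62",
            gapOpening = 11, gapExtension = 1)
        expect_equal(Biostrings::score(aln),
                     swOracleScore(a, b, BLOSUM62, 11, 1))
    }
})

test_that("E-values decrease monotonically in bitscore", {
    set.seed(84)
    q <- randomProtein(150L)
    subs <- c(full = q, part = substr(q, 1L, 60L),
              less = substr(q, 1L, 35L))
    h <- searchProtein(c(q1 = q), subs, evalueMax = 1)
    h <- h[order(h$bitscore), ]
    expect_false(is.unsorted(rev(h$evalue)))
})

test_that("translated search recovers the coding frame", {
    set.seed(85)
    tab <- codonTable(eu)
    prot <- randomProtein(60L)
    cods <- vapply(strsplit(prot, "")[[1L]], function(a)
        names(tab)[tab == a][1L], "")
    tx <- paste0("GA", paste0(cods, collapse = ""), "T")  # frame +3
    h <- searchTranslated(c(t1 = tx), c(ref = prot), eu)
    expect_identical(nrow(h), 1L)
    expect_identical(h$frame, 3L)
    expect_equal(h$pct_identity, 100)
    # random DNA finds nothing
    h0 <- searchTranslated(c(t2 = randomDna(300L)), c(ref = prot), eu)
    expect_identical(nrow(h0), 0L)
})

test_that("a frameshifted transcript produces hits in two frames", {
    spec <- synthSpec(seed = 86, refLenAa = 120L, prfPlan = list(
        list(contexts = "AAATAA", models = 1L)))
    p <- synthPrfSet(spec)
    h <- searchTranslated(p$transcripts, p$references, eu)
    expect_gte(nrow(h), 2L)
    expect_setequal(unique(h$frame), c(1L, 2L))
    expect_identical(nrow(findCandidates(h)), 1L)
})

test_that("family assignment follows the best-hit tie-break chain", {
    set.seed(87)
    exA <- randomProtein(90L)
    exB <- randomProtein(90L)
    exemplars <- Biostrings::AAStringSet(c(famA_ex = exA, famB_ex = exB))
    fam <- c(famA_ex = "A", famB_ex = "B")
    # protein closer to exemplar A (one mismatch vs twelve)
    mutate <- function(s, k) {
        v <- strsplit(s, "")[[1L]]
        idx <- sample(length(v), k)
        v[idx] <- sample(setdiff(c(LETTERS[1:20]), "X"), k, replace = TRUE)
        paste0(v, collapse = "")
    }
    prots <- Biostrings::AAStringSet(c(p1 = mutate(exA, 1L),
                                       p2 = mutate(exB, 2L),
                                       p3 = randomProtein(80L)))
    cat1 <- assignFamilies(list(sp1 = prots), exemplars, fam)
    m <- familyMembers(cat1)
    expect_identical(m$family[m$gene == "p1"], "A")
    expect_identical(m$family[m$gene == "p2"], "B")
    expect_identical(cat1@unassigned$gene, "p3")
})

test_that("a planted multi-species catalog is perfectly recovered", {
    set.seed(88)
    nFam <- 5L
    exemplars <- Biostrings::AAStringSet(
        setNames(vapply(seq_len(nFam), function(i) randomProtein(100L), ""),
                 paste0("fam", seq_len(nFam), "_ex")))
    fam <- setNames(paste0("F", seq_len(nFam)), names(exemplars))
    species <- paste0("sp", 1:4)
    truth <- list()
    prots <- lapply(species, function(sp) {
        picks <- sample(nFam, 3L)
        seqs <- vapply(picks, function(i)
            as.character(exemplars[[i]]), "")
        names(seqs) <- paste0(sp, "_g", seq_along(picks))
        truth[[sp]] <<- setNames(paste0("F", picks), names(seqs))
        Biostrings::AAStringSet(seqs)
    })
    names(prots) <- species
    cat2 <- assignFamilies(prots, exemplars, fam)
    m <- familyMembers(cat2)
    for (sp in species)
        expect_identical(setNames(m$family[m$species == sp],
                                  m$gene[m$species == sp]), truth[[sp]])
})

test_that("the Venn partition is disjoint, exhaustive and correct", {
    members <- rbind(
        expand.grid(family = c("a", "b"), species = paste0("sp", 1:4),
                    stringsAsFactors = FALSE),
        data.frame(family = paste0("u", 1:4), species = paste0("sp", 1:4),
                   stringsAsFactors = FALSE))
    members$gene <- paste0(members$family, "_", members$species)
    cat3 <- familyCatalog(members, species = paste0("sp", 1:4))
    vp <- vennPartition(cat3)
    expect_identical(sum(vp$count), 6L)  # partition property
    expect_identical(vp$count[vp$region == "sp1+sp2+sp3+sp4"], 2L)
    for (i in 1:4)
        expect_identical(vp$count[vp$region == paste0("sp", i)], 1L)
    expect_identical(conservedCore(cat3), c("a", "b"))
    core <- conservedCore(cat3, level = "gene")
    expect_identical(nrow(core), 8L)
    # single-species catalogue: one region only
    cat4 <- familyCatalog(members[members$species == "sp1", ])
    vp4 <- vennPartition(cat4)
    expect_identical(vp4$count, 3L)
})
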
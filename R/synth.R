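#' Slippery-context repertoire observed in validated Euplotes PRF genes
#'
#' 6-nt contexts (3 nt upstream + the stop codon) and their frameshift
#' model as observed across validated +1/+2 PRF genes; AAATAA/+1 dominates.
#' Used as the sampling repertoire of [synthPrfSet()].
#'
#' @format data.frame with columns \code{context}, \code{model}.
#' @export
prfContextRepertoire <- function() {
    data.frame(
        context = c("AAATAA", "AAATAG", "AATTAA", "TTCTAA", "TATTAA",
                    "AAGTAA", "TGATAG", "GGATAA", "ATATAG", "CGATAA",
                    "AGTTAA", "TGTTAG", "TTTTAG", "ATATAA"),
        model = c(1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 1L, 2L, 2L, 2L),
        stringsAsFactors = FALSE)
}

# amino-acid background close to the BLOSUM62 (Robinson-Robinson) mix
AA_BACKGROUND <- c(A = 0.078, R = 0.051, N = 0.045, D = 0.054, C = 0.019,
                   Q = 0.043, E = 0.063, G = 0.074, H = 0.022, I = 0.051,
                   L = 0.090, K = 0.057, M = 0.022, F = 0.039, P = 0.052,
                   S = 0.071, T = 0.058, W = 0.013, Y = 0.032, V = 0.066)

#' Specification for the synthetic-data generators
#'
#' Bundles every tunable of the seeded generators. The defaults emulate the
#' study conditions of the source system: telomere-capped single-gene
#' nanochromosomes, stop usage ~77% TAA / 23% TAG, ~79% intron-free genes,
#' ~30% of transcripts carrying +1/+2 PRF events with contexts drawn from
#' the observed repertoire, a protein-interaction network with planted
#' hubs over an Erdos-Renyi background, 0.3-s-sampled swimming tracks, and
#' Cq tables with set true ddCq values.
#'
#' @param seed integer; fully determines all generator output.
#' @param nContigs number of nanochromosome contigs (one gene each).
#' @param nTranscripts number of PRF-set transcripts.
#' @param code genetic-code name (see [geneticCode()]).
#' @param stopMix named probabilities of stop-codon usage.
#' @param intronMix named probabilities of intron counts (names "0","1",...).
#' @param prfFraction fraction of transcripts carrying PRF events.
#' @param prfPlan optional explicit plan: list of entries
#'   \code{list(contexts=, models=)}, one per PRF transcript (overrides
#'   \code{prfFraction}).
#' @param refLenAa reference protein length (residues).
#' @param hubPlan list: \code{nNodes}, \code{nHubs}, \code{nModules},
#'   \code{moduleSize}, \code{pModule}, \code{pBackground},
#'   \code{hubModules}, \code{pHubAttach}.
#' @param trackPlan list of track entries \code{list(shape=, speed=,
#'   radius=, jitter=, nPoints=)}; \code{dt} fixed at 0.3 s.
#' @param qpcrPlan named numeric vector of true ddCq per gene.
#' @param qpcrNoiseSd replicate Cq noise (cycles).
#' @param qpcrReplicates replicates per sample/gene well.
#' @return list of class \code{"SynthSpec"}.
#' @export
synthSpec <- function(seed = 1L,
                      nContigs = 40L,
                      nTranscripts = 200L,
                      code = "euplotes",
                      stopMix = c(TAA = 0.77, TAG = 0.23),
                      intronMix = c("0" = 0.79, "1" = 0.134, "2" = 0.04,
                                    "3" = 0.024, "4" = 0.012),
                      prfFraction = 0.3,
                      prfPlan = NULL,
                      refLenAa = 400L,
                      hubPlan = list(nNodes = 300L, nHubs = 10L,
                                     nModules = 12L, moduleSize = 20L,
                                     pModule = 0.3, pBackground = 0.02,
                                     hubModules = 8L, pHubAttach = 0.6),
                      trackPlan = list(
                          list(shape = "line", speed = 100, jitter = 0,
                               nPoints = 40L),
                          list(shape = "circle", radius = 50, speed = 80,
                               jitter = 0.5, nPoints = 60L)),
                      qpcrPlan = c(CKAP5 = -1, ADCY3 = -2, IFT88 = 1,
                                   BBS4 = 2, DYNLRB2 = 0),
                      qpcrNoiseSd = 0.05,
                      qpcrReplicates = 3L) {
    stopifnot(abs(sum(stopMix) - 1) < 1e-9, abs(sum(intronMix) - 1) < 1e-9,
              prfFraction >= 0, prfFraction <= 1)
    structure(list(seed = as.integer(seed), nContigs = nContigs,
                   nTranscripts = nTranscripts, code = code,
                   stopMix = stopMix, intronMix = intronMix,
                   prfFraction = prfFraction, prfPlan = prfPlan,
                   refLenAa = refLenAa, hubPlan = hubPlan,
                   trackPlan = trackPlan, qpcrPlan = qpcrPlan,
                   qpcrNoiseSd = qpcrNoiseSd,
                   qpcrReplicates = qpcrReplicates),
              class = "SynthSpec")
}

senseCodons <- function(code) {
    tab <- codonTable(code)
    names(tab)[tab != "*"]
}

# sample a random CDS (no stop codons) of n codons under the code
randomCodons <- function(n, code) {
    tab <- codonTable(code)
    aa <- sample(names(AA_BACKGROUND), n, replace = TRUE,
                 prob = AA_BACKGROUND)
    vapply(aa, function(a) {
        cands <- names(tab)[tab == a]
        cands[sample.int(length(cands), 1L)]
    }, "", USE.NAMES = FALSE)
}

#' Generate a synthetic macronuclear genome
#'
#' Telomere-capped single-gene nanochromosome contigs: each contig carries
#' C4A4 telomeric repeats at the 5' end (G4T4 at 3'), short subtelomeric
#' spacers, and one gene whose intron count is drawn from
#' \code{spec$intronMix} and whose stop codon is drawn from
#' \code{spec$stopMix}. Introns are short GT..AG elements. Gene models are
#' returned as a GFF3-style \code{GRanges} and every planted feature is
#' recorded in the truth table.
#'
#' @param spec a [synthSpec()].
#' @return list: \code{contigs} (\code{DNAStringSet}), \code{models}
#'   (\code{GRanges} with gene/mRNA/exon features), \code{truth}
#'   (data.frame \code{contig}, \code{transcript}, \code{n_introns},
#'   \code{stop_codon}, \code{cds_len}).
#' @export
synthGenome <- function(spec) {
    code <- geneticCode(spec$code)
    withSeed(spec$seed + 11L, {
        telo5 <- strrep("CCCCAAAA", 4L)
        telo3 <- strrep("TTTTGGGG", 4L)
        contigs <- character(spec$nContigs)
        feats <- list()
        truth <- list()
        for (i in seq_len(spec$nContigs)) {
            cid <- sprintf("contig%03d", i)
            tid <- sprintf("gene%03d.t1", i)
            nIntrons <- as.integer(sample(names(spec$intronMix), 1L,
                                          prob = spec$intronMix))
            nCod <- sample(100:300, 1L)
            cds <- paste0(randomCodons(nCod, code), collapse = "")
            stopC <- sample(names(spec$stopMix), 1L, prob = spec$stopMix)
            coding <- paste0(cds, stopC)
            # split coding region into exons at codon-boundary cut points
            cuts <- if (nIntrons > 0L)
                sort(sample(seq(3L, nchar(coding) - 3L, by = 3L),
                            nIntrons)) else integer(0)
            bounds <- c(0L, cuts, nchar(coding))
            exons <- substring(coding, head(bounds, -1L) + 1L,
                               bounds[-1L])
            introns <- replicate(nIntrons, paste0(
                "GT", paste0(sample(c("A", "C", "G", "T"), 24L,
                                    replace = TRUE), collapse = ""), "AG"))
            utr5 <- paste0(sample(c("A", "T"), 15L, replace = TRUE),
                           collapse = "")
            utr3 <- paste0(sample(c("A", "T"), 15L, replace = TRUE),
                           collapse = "")
            body <- exons[1L]
            exStart <- nchar(telo5) + nchar(utr5) + 1L
            exRanges <- matrix(0L, nIntrons + 1L, 2L)
            exRanges[1L, ] <- c(exStart, exStart + nchar(exons[1L]) - 1L)
            for (k in seq_len(nIntrons)) {
                body <- paste0(body, introns[k], exons[k + 1L])
                st <- exRanges[k, 2L] + nchar(introns[k]) + 1L
                exRanges[k + 1L, ] <- c(st, st + nchar(exons[k + 1L]) - 1L)
            }
            contigs[i] <- paste0(telo5, utr5, body, utr3, telo3)
            gStart <- exRanges[1L, 1L]
            gEnd <- exRanges[nIntrons + 1L, 2L]
            feats[[length(feats) + 1L]] <- data.frame(
                seqnames = cid, start = gStart, end = gEnd,
                type = c("gene", "mRNA"),
                ID = c(sub("\\.t1$", "", tid), tid),
                Parent = c(NA, sub("\\.t1$", "", tid)),
                stringsAsFactors = FALSE)
            feats[[length(feats) + 1L]] <- data.frame(
                seqnames = cid, start = exRanges[, 1L],
                end = exRanges[, 2L], type = "exon",
                ID = paste0(tid, ".exon", seq_len(nIntrons + 1L)),
                Parent = tid, stringsAsFactors = FALSE)
            truth[[length(truth) + 1L]] <- data.frame(
                contig = cid, transcript = tid, n_introns = nIntrons,
                stop_codon = stopC, cds_len = nchar(cds),
                stringsAsFactors = FALSE)
        }
        fdf <- do.call(rbind, feats)
        gr <- GenomicRanges::GRanges(
            seqnames = fdf$seqnames,
            ranges = IRanges::IRanges(fdf$start, fdf$end),
            strand = "+", type = fdf$type, ID = fdf$ID,
            Parent = fdf$Parent)
        names(contigs) <- sprintf("contig%03d", seq_len(spec$nContigs))
        list(contigs = DNAStringSet(contigs), models = gr,
             truth = do.call(rbind, truth))
    })
}

#' Generate transcripts with planted programmed frameshifts
#'
#' Builds, for each planned transcript, a random reference protein and a
#' transcript carrying its coding sequence interrupted at chosen codon
#' boundaries by re-inserting the first one (+1) or two (+2) bases of a
#' stop codon into a stop-forming slippery context -- the exact inverse of
#' the excision the detector performs, guaranteeing a consistent ground
#' truth. The codon upstream of each insertion is set to the context's
#' first 3 nt and the codon after it to a sense codon beginning with the
#' remainder of the stop codon. Also emits the translated-search hit table
#' the upstream alignment stage would produce (one hit per reading-frame
#' segment) and a truth table of every planted event.
#'
#' @param spec a [synthSpec()]; \code{spec$prfPlan} may give explicit
#'   per-transcript contexts/models, otherwise \code{prfFraction} of
#'   \code{nTranscripts} transcripts receive 1-3 events sampled from
#'   [prfContextRepertoire()].
#' @return list: \code{transcripts} (\code{DNAStringSet}),
#'   \code{references} (\code{AAStringSet}), \code{hits} (data.frame),
#'   \code{truth} (data.frame \code{transcript}, \code{reference},
#'   \code{event}, \code{position}, \code{slippery}, \code{model}).
#' @export
synthPrfSet <- function(spec) {
    code <- geneticCode(spec$code)
    rep0 <- prfContextRepertoire()
    withSeed(spec$seed + 23L, {
        plan <- spec$prfPlan
        if (is.null(plan)) {
            nPrf <- round(spec$prfFraction * spec$nTranscripts)
            plan <- vector("list", spec$nTranscripts)
            prfIdx <- if (nPrf > 0)
                sort(sample.int(spec$nTranscripts, nPrf)) else integer(0)
            w <- ifelse(rep0$context == "AAATAA", 12, 1)
            for (i in prfIdx) {
                nEv <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
                rows <- sample.int(nrow(rep0), nEv, replace = TRUE,
                                   prob = w)
                plan[[i]] <- list(contexts = rep0$context[rows],
                                  models = rep0$model[rows])
            }
        }
        nT <- length(plan)
        transcripts <- character(nT)
        refs <- character(nT)
        truth <- list()
        hits <- list()
        for (i in seq_len(nT)) {
            tid <- sprintf("trans%04d", i)
            rid <- sprintf("ref%04d", i)
            built <- buildPrfTranscript(plan[[i]], spec$refLenAa, code)
            transcripts[i] <- built$transcript
            refs[i] <- built$reference
            if (nrow(built$truth)) {
                tr <- built$truth
                tr$transcript <- tid
                tr$reference <- rid
                truth[[length(truth) + 1L]] <- tr
            }
            h <- built$hits
            h$query_id <- tid
            h$subject_id <- rid
            hits[[length(hits) + 1L]] <- h
        }
        names(transcripts) <- sprintf("trans%04d", seq_len(nT))
        names(refs) <- sprintf("ref%04d", seq_len(nT))
        truthDf <- if (length(truth)) do.call(rbind, truth) else
            data.frame(event = integer(), position = integer(),
                       slippery = character(), model = integer(),
                       transcript = character(), reference = character(),
                       stringsAsFactors = FALSE)
        rownames(truthDf) <- NULL
        hitsDf <- do.call(rbind, hits)
        rownames(hitsDf) <- NULL
        list(transcripts = DNAStringSet(transcripts),
             references = AAStringSet(refs),
             hits = hitsDf,
             truth = truthDf[, c("transcript", "reference", "event",
                                 "position", "slippery", "model")])
    })
}

# one transcript + reference per plan entry (NULL entry = clean transcript)
buildPrfTranscript <- function(entry, refLenAa, code) {
    tab <- codonTable(code)
    codons <- randomCodons(refLenAa, code)
    nEv <- if (is.null(entry)) 0L else length(entry$contexts)
    sites <- integer(0)
    if (nEv > 0L) {
        # insertion sites at codon boundaries, >= 40 codons apart and away
        # from both ends so every extension is long enough to validate
        lo <- 40L
        hi <- refLenAa - 40L
        stopifnot(hi - lo >= 40L * (nEv - 1L) + 1L)
        repeat {
            sites <- sort(sample(lo:hi, nEv))
            if (nEv == 1L || min(diff(sites)) >= 40L) break
        }
        for (k in seq_len(nEv)) {
            ctx <- entry$contexts[k]
            model <- entry$models[k]
            up <- substr(ctx, 1L, 3L)
            stopC <- substr(ctx, 4L, 6L)
            stopifnot(stopC %in% stopCodons(code), tab[up] != "*",
                      model %in% 1:2)
            pre <- substr(stopC, 1L, model)       # re-inserted bases
            suf <- substr(stopC, model + 1L, 3L)  # start of the next codon
            codons[sites[k] - 1L] <- up
            cands <- names(tab)[startsWith(names(tab), suf) & tab != "*"]
            codons[sites[k]] <- cands[sample.int(length(cands), 1L)]
        }
    }
    reference <- paste0(unname(tab[codons]), collapse = "")
    parts <- character(0)
    len <- 0L
    truth <- list()
    prev <- 1L
    for (k in seq_len(nEv)) {
        seg <- paste0(codons[prev:(sites[k] - 1L)], collapse = "")
        parts <- c(parts, seg)
        len <- len + nchar(seg)
        ins <- substr(entry$contexts[k], 4L, 3L + entry$models[k])
        truth[[k]] <- data.frame(event = k, position = len,
                                 slippery = entry$contexts[k],
                                 model = entry$models[k],
                                 stringsAsFactors = FALSE)
        parts <- c(parts, ins)
        len <- len + nchar(ins)
        prev <- sites[k]
    }
    seg <- paste0(codons[prev:length(codons)], collapse = "")
    termStop <- "TAA"
    transcript <- paste0(paste0(c(parts, seg), collapse = ""), termStop)
    # translated-search hits, one per frame segment
    bounds <- c(0L, vapply(truth, function(t) t$position, 0L),
                nchar(transcript) - 3L)
    refBounds <- c(0L, sites - 1L, refLenAa)
    hseg <- lapply(seq_len(nEv + 1L), function(k) {
        shift <- if (k == 1L) 0L else
            sum(vapply(truth[seq_len(k - 1L)], function(t) t$model, 0L))
        qs <- bounds[k] + (if (k == 1L) 1L else
            vapply(truth[k - 1L], function(t) t$model, 0L) + 1L)
        data.frame(query_id = "", subject_id = "",
                   pct_identity = 100, aln_length = refBounds[k + 1L] -
                       refBounds[k],
                   mismatches = 0L, gap_opens = 0L,
                   q_start = qs, q_end = bounds[k + 1L],
                   s_start = refBounds[k] + 1L, s_end = refBounds[k + 1L],
                   evalue = 1e-60, bitscore = 500 - k,
                   frame = (shift %% 3L) + 1L, stringsAsFactors = FALSE)
    })
    list(transcript = transcript, reference = reference,
         truth = if (nEv) do.call(rbind, truth) else
             data.frame(event = integer(), position = integer(),
                        slippery = character(), model = integer(),
                        stringsAsFactors = FALSE),
         hits = do.call(rbind, hseg))
}

#' Generate a protein-interaction network with planted hubs
#'
#' Module nodes form dense Erdos-Renyi blocks over a sparse global
#' background; each planted hub attaches to a random subset of nodes in
#' several distinct modules, making it central under degree-, path- and
#' neighborhood-based scores alike.
#'
#' @param spec a [synthSpec()]; see \code{hubPlan}.
#' @return list: \code{graph} (igraph), \code{hubs} (character ids).
#' @export
synthPpi <- function(spec) {
    p <- spec$hubPlan
    withSeed(spec$seed + 37L, {
        nModuleNodes <- p$nModules * p$moduleSize
        nFiller <- p$nNodes - p$nHubs - nModuleNodes
        stopifnot(nFiller >= 0L)
        hubs <- sprintf("HUB%02d", seq_len(p$nHubs))
        modNodes <- unlist(lapply(seq_len(p$nModules), function(m)
            sprintf("M%02d_%02d", m, seq_len(p$moduleSize))))
        filler <- if (nFiller) sprintf("BG%03d", seq_len(nFiller))
            else character(0)
        nodes <- c(hubs, modNodes, filler)
        edges <- list()
        for (m in seq_len(p$nModules)) {
            mem <- sprintf("M%02d_%02d", m, seq_len(p$moduleSize))
            prs <- utils::combn(mem, 2L)
            keep <- stats::runif(ncol(prs)) < p$pModule
            if (any(keep)) edges[[length(edges) + 1L]] <-
                t(prs[, keep, drop = FALSE])
        }
        bg <- c(modNodes, filler)
        prs <- utils::combn(bg, 2L)
        # background pairs within a module were already sampled; sampling
        # them again only merges by simplify(), slightly raising density
        keep <- stats::runif(ncol(prs)) < p$pBackground
        if (any(keep)) edges[[length(edges) + 1L]] <-
            t(prs[, keep, drop = FALSE])
        for (h in hubs) {
            mods <- sample.int(p$nModules, p$hubModules)
            for (m in mods) {
                mem <- sprintf("M%02d_%02d", m, seq_len(p$moduleSize))
                att <- mem[stats::runif(p$moduleSize) < p$pHubAttach]
                if (length(att)) edges[[length(edges) + 1L]] <-
                    cbind(h, att)
            }
        }
        el <- do.call(rbind, edges)
        g <- igraph::graph_from_edgelist(el, directed = FALSE)
        g <- igraph::add_vertices(
            g, length(setdiff(nodes, igraph::V(g)$name)),
            name = setdiff(nodes, igraph::V(g)$name))
        g <- igraph::simplify(g)
        list(graph = g, hubs = hubs)
    })
}

#' Generate synthetic swimming tracks
#'
#' Straight-line and circular centroid tracks sampled every 0.3 s with
#' Gaussian positional jitter, emulating motility recordings of swimming
#' cells (circular trajectories with a set radius model the spiralling
#' phenotype of cilia-compromised cells).
#'
#' @param spec a [synthSpec()]; see \code{trackPlan}.
#' @return list: \code{tracks} (data.frame \code{track}, \code{t},
#'   \code{x}, \code{y}), \code{truth} (data.frame \code{track},
#'   \code{shape}, \code{speed}, \code{radius}, \code{jitter}).
#' @export
synthTracks <- function(spec) {
    dt <- 0.3
    withSeed(spec$seed + 53L, {
        rows <- list()
        truth <- list()
        for (i in seq_along(spec$trackPlan)) {
            pl <- spec$trackPlan[[i]]
            id <- sprintf("track%02d", i)
            tt <- (seq_len(pl$nPoints) - 1L) * dt
            if (pl$shape == "line") {
                th <- stats::runif(1, 0, 2 * pi)
                x <- pl$speed * tt * cos(th)
                y <- pl$speed * tt * sin(th)
                r <- NA_real_
            } else {
                r <- pl$radius
                om <- pl$speed / r
                ph <- stats::runif(1, 0, 2 * pi)
                x <- r * cos(om * tt + ph)
                y <- r * sin(om * tt + ph)
            }
            if (pl$jitter > 0) {
                x <- x + stats::rnorm(length(x), 0, pl$jitter)
                y <- y + stats::rnorm(length(y), 0, pl$jitter)
            }
            rows[[i]] <- data.frame(track = id, t = tt, x = x, y = y,
                                    stringsAsFactors = FALSE)
            truth[[i]] <- data.frame(track = id, shape = pl$shape,
                                     speed = pl$speed, radius = r,
                                     jitter = pl$jitter,
                                     stringsAsFactors = FALSE)
        }
        list(tracks = do.call(rbind, rows), truth = do.call(rbind, truth))
    })
}

#' Generate a synthetic qPCR Cq table
#'
#' Cq values for a reference gene and target genes across a control and a
#' target sample, with replicate noise; per target gene the planted true
#' ddCq (\code{spec$qpcrPlan}) separates the two samples.
#'
#' @param spec a [synthSpec()].
#' @param controlSample,targetSample sample ids.
#' @param referenceGene reference gene id.
#' @return list: \code{cq} (data.frame \code{sample}, \code{gene},
#'   \code{cq}), \code{truth} (named ddCq vector).
#' @export
synthQpcr <- function(spec, controlSample = "G0", targetSample = "DIV",
                      referenceGene = "GAPDH") {
    withSeed(spec$seed + 71L, {
        reps <- spec$qpcrReplicates
        sd <- spec$qpcrNoiseSd
        rows <- list()
        add <- function(s, g, mu) {
            rows[[length(rows) + 1L]] <<- data.frame(
                sample = s, gene = g, cq = mu + stats::rnorm(reps, 0, sd),
                stringsAsFactors = FALSE)
        }
        refCq <- 18
        add(controlSample, referenceGene, refCq)
        add(targetSample, referenceGene, refCq)
        for (g in names(spec$qpcrPlan)) {
            dcqControl <- stats::runif(1, 2, 6)
            add(controlSample, g, refCq + dcqControl)
            add(targetSample, g, refCq + dcqControl + spec$qpcrPlan[[g]])
        }
        list(cq = do.call(rbind, rows), truth = spec$qpcrPlan)
    })
}
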
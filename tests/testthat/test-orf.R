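eu <- geneticCode("euplotes")

test_that("a single planted ORF is found with its stop codon", {
    tx <- paste0("ATG", strrep("GCT", 40L), "TAA")
    o <- findOrfs(c(t1 = tx), eu, minAa = 30L)
    # frames 2/3 read the repeat as stop-free 3'-truncated runs
    expect_true(all(is.na(o$stop_codon[o$frame != 1L])))
    o <- o[o$frame == 1L, ]
    expect_identical(nrow(o), 1L)
    expect_identical(o$stop_codon, "TAA")
    expect_identical(nchar(o$protein), 41L)
    expect_identical(o$start, 0L)
    expect_identical(o$end, 123L)
    expect_identical((o$end - o$start) %% 3L, 0L)
})

test_that("stop-dense sequence yields no in-frame ORF above the floor", {
    tx <- strrep("TAATAG", 60L)
    o <- findOrfs(c(t1 = tx), eu, minAa = 30L)
    expect_identical(nrow(o[o$frame == 1L, ]), 0L)
})

test_that("TGA is read through as cysteine, not a break", {
    tx <- paste0(strrep("GCT", 20L), "TGA", strrep("GCT", 20L), "TAA")
    o <- findOrfs(c(t1 = tx), eu, minAa = 30L)
    o <- o[o$frame == 1L, ]
    expect_identical(nrow(o), 1L)
    expect_identical(o$protein, paste0(strrep("A", 20L), "C",
                                       strrep("A", 20L)))
    # under the standard code the same transcript splits at TGA
    oStd <- findOrfs(c(t1 = tx), geneticCode("standard"), minAa = 30L)
    expect_identical(nrow(oStd[oStd$frame == 1L, ]), 0L)
})

test_that("ATG-anchored mode trims to the first methionine", {
    tx <- paste0(strrep("GCT", 10L), "ATG", strrep("GCT", 35L), "TAA")
    stopToStop <- findOrfs(c(t1 = tx), eu, minAa = 30L)
    anchored <- findOrfs(c(t1 = tx), eu, minAa = 30L, atgAnchored = TRUE)
    f1 <- function(x) x[x$frame == 1L, ]
    expect_identical(nchar(f1(stopToStop)$protein), 46L)
    expect_identical(nchar(f1(anchored)$protein), 36L)
    expect_true(startsWith(f1(anchored)$protein, "M"))
})

test_that("a stop between concatenated transcripts prevents junction ORFs", {
    set.seed(61)
    a <- paste0(randomCds(40L), "TAA")
    b <- paste0(randomCds(40L), "TAA")
    sep <- findOrfs(c(t = paste0(a, b)), eu, minAa = 30L)
    sep1 <- sep[sep$frame == 1L, ]
    expect_identical(nrow(sep1), 2L)
    expect_identical(sep1$start, c(0L, 123L))
    expect_identical(sep1$end, c(120L, 243L))
})

test_that("trailing sequence after the last stop does not change ORFs", {
    set.seed(62)
    core <- paste0(randomCds(50L), "TAA")
    o1 <- findOrfs(c(t = core), eu, minAa = 30L)
    o2 <- findOrfs(c(t = paste0(core, "TTTT")), eu, minAa = 30L)
    f1 <- function(x) {
        x <- x[x$frame == 1L, ]
        rownames(x) <- NULL
        x
    }
    expect_identical(f1(o1), f1(o2))
})

test_that("intron histograms report exact proportions", {
    ms <- data.frame(transcript = paste0("t", 1:10),
                     n_exons = c(rep(1L, 8L), 2L, 2L),
                     n_introns = c(rep(0L, 8L), 1L, 1L))
    expect_equal(intronHistogram(ms), c("0" = 0.8, "1" = 0.2))
    expect_equal(intronHistogram(ms[1:8, ]), c("0" = 1.0))
    expect_equal(sum(intronHistogram(ms)), 1)
    expect_error(intronHistogram(ms[0, ]), "no gene models")
})

test_that("stop usage counts proportions and rejects empty input", {
    o <- data.frame(stop_codon = c("TAA", "TAA", "TAA", "TAG"))
    expect_equal(stopUsage(o), c(TAA = 0.75, TAG = 0.25))
    expect_equal(stopUsage(data.frame(stop_codon = rep("TAA", 5L))),
                 c(TAA = 1.0))
    expect_error(stopUsage(data.frame(stop_codon = character())),
                 "no stop codons")
})

test_that("synthetic genome structure is recovered within binomial CI", {
    spec <- synthSpec(seed = 63, nContigs = 150L)
    g <- synthGenome(spec)
    hist <- intronHistogram(geneModelSummary(g$models))
    p0 <- spec$intronMix[["0"]]
    ciHalf <- 3 * sqrt(p0 * (1 - p0) / 150)
    expect_lt(abs(hist[["0"]] - p0), ciHalf)
    stopProp <- table(g$truth$stop_codon) / nrow(g$truth)
    pTaa <- spec$stopMix[["TAA"]]
    expect_lt(abs(stopProp[["TAA"]] - pTaa),
              3 * sqrt(pTaa * (1 - pTaa) / 150))
    # structure summary combines the three proportion sets
    ss <- structureStats(geneModelSummary(g$models),
                         data.frame(stop_codon = g$truth$stop_codon),
                         prfTranscripts = character(), nGenes = 150L)
    expect_equal(sum(ss$intron_histogram), 1, tolerance = 1e-9)
    expect_equal(sum(ss$stop_usage), 1, tolerance = 1e-9)
    expect_identical(ss$prf_fraction, 0)
})
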
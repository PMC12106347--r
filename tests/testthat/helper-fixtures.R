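# shared fixture builders (everything generated in code)

randomDna <- function(n) {
    paste0(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

randomProtein <- function(n) {
    paste0(sample(setdiff(LETTERS, c("B", "J", "O", "U", "X", "Z")), n,
                  replace = TRUE), collapse = "")
}

# a coding sequence of n sense codons under the code (no in-frame stops)
randomCds <- function(n, code = geneticCode("euplotes")) {
    tab <- codonTable(code)
    sense <- names(tab)[tab != "*"]
    paste0(sample(sense, n, replace = TRUE), collapse = "")
}

# the 12-contig toy set for the filtering rules: designed lengths and hits
toyContigSet <- function() {
    set.seed(404)
    lens <- c(big1 = 2000L, big2 = 1500L, big3 = 800L, big4 = 600L,
              mid_redundant1 = 300L, mid_redundant2 = 450L,
              mid_kept_lowid = 300L, mid_kept_lowcov = 300L,
              mid_kept_nohit = 250L, tiny1 = 90L, tiny2 = 50L,
              tiny_withhit = 80L)
    seqs <- vapply(lens, randomDna, "")
    contigs <- Biostrings::DNAStringSet(seqs)
    names(contigs) <- names(lens)
    hit <- function(q, s, pid, qlen, covPct) {
        alen <- as.integer(round(covPct / 100 * qlen))
        data.frame(query_id = q, subject_id = s, pct_identity = pid,
                   aln_length = alen, mismatches = 0L, gap_opens = 0L,
                   q_start = 1L, q_end = alen, s_start = 1L, s_end = alen,
                   evalue = 1e-30, bitscore = 100, frame = 0L,
                   stringsAsFactors = FALSE)
    }
    hits <- rbind(
        hit("mid_redundant1", "big1", 95, 300L, 85),   # removed: both pass
        hit("mid_redundant2", "big2", 90, 450L, 80),   # removed: boundary
        hit("mid_kept_lowid", "big1", 89.9, 300L, 95), # kept: identity fails
        hit("mid_kept_lowcov", "big2", 99, 300L, 79),  # kept: coverage fails
        hit("tiny_withhit", "big3", 99, 80L, 99),      # hard minimum wins
        hit("big3", "big1", 99, 800L, 95))             # long query: kept
    list(contigs = contigs, hits = hits,
         expectRemoved = c(mid_redundant1 = "redundant",
                           mid_redundant2 = "redundant",
                           tiny1 = "below_hard_minimum",
                           tiny2 = "below_hard_minimum",
                           tiny_withhit = "below_hard_minimum"))
}
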
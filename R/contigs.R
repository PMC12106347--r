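#' Flag telomere-capped nanochromosome contigs
#'
#' Macronuclear chromosomes of hypotrich ciliates are gene-sized
#' "nanochromosomes" capped by short telomeric repeats; in \emph{Euplotes}
#' the repeat is C4A4 at the 5' end (G4T4, its reverse complement, at the
#' 3' end). A terminal window at each contig end is scanned for at least
#' \code{minUnits} tandem copies of the unit (5') or of its reverse
#' complement (3'), and boolean flags are recorded in \code{mcols()}.
#'
#' @param contigs a \code{DNAStringSet}.
#' @param repeatUnit the 5' telomeric repeat unit (default \code{"CCCCAAAA"}).
#' @param minUnits minimum tandem copies required.
#' @param window terminal window length scanned at each end.
#' @return \code{contigs} with logical metadata columns \code{telomere5p}
#'   and \code{telomere3p}.
#' @export
detectTelomeres <- function(contigs, repeatUnit = "CCCCAAAA", minUnits = 2L,
                            window = 60L) {
    stopifnot(nchar(repeatUnit) > 0L)
    repeatUnit <- toupper(repeatUnit)
    rcUnit <- as.character(reverseComplement(DNAString(repeatUnit)))
    pat5 <- paste0("(", repeatUnit, "){", minUnits, ",}")
    pat3 <- paste0("(", rcUnit, "){", minUnits, ",}")
    seqs <- as.character(contigs)
    n <- nchar(seqs)
    head5 <- substr(seqs, 1L, pmin(window, n))
    tail3 <- substr(seqs, pmax(1L, n - window + 1L), n)
    mcols(contigs)$telomere5p <- grepl(pat5, head5)
    mcols(contigs)$telomere3p <- grepl(pat3, tail3)
    contigs
}

#' Filter redundant and undersized assembly contigs
#'
#' Implements the assembly clean-up applied to macronuclear genome contigs:
#' contigs shorter than \code{hardMinLen} are always removed; contigs shorter
#' than \code{minLen} are removed when they align to a contig of at least
#' \code{minLen} with percent identity >= \code{minIdentity} and query
#' coverage >= \code{minCoverage} (redundant fragments of longer contigs).
#' Coverage is computed on the query: aligned query length / query length
#' x 100.
#'
#' @param contigs a \code{DNAStringSet}.
#' @param hits data.frame of contig-vs-contig alignments in the tabular hit
#'   format of [readHitsTabular()]; queries are the short contigs.
#' @param minLen length below which a contig is a removal candidate (bp).
#' @param minIdentity minimum percent identity of a disqualifying hit.
#' @param minCoverage minimum percent query coverage of a disqualifying hit.
#' @param hardMinLen absolute minimum contig length (bp).
#' @return list with elements \code{kept} (a \code{DNAStringSet}) and
#'   \code{removed} (data.frame \code{id}, \code{length}, \code{reason}),
#'   where \code{reason} is \code{"below_hard_minimum"} or
#'   \code{"redundant"}.
#' @export
filterContigs <- function(contigs, hits = emptyHits(), minLen = 500L,
                          minIdentity = 90, minCoverage = 80,
                          hardMinLen = 100L) {
    ids <- names(contigs)
    if (is.null(ids) || anyDuplicated(ids))
        stop("contigs must carry unique names")
    len <- setNames(Biostrings::width(contigs), ids)
    if (nrow(hits)) {
        unknown <- setdiff(unique(c(hits$query_id, hits$subject_id)), ids)
        if (length(unknown))
            stop("hit references unknown contig id: ", unknown[1L])
    }
    reason <- setNames(rep(NA_character_, length(ids)), ids)
    reason[len < hardMinLen] <- "below_hard_minimum"
    if (nrow(hits)) {
        cov <- (abs(hits$q_end - hits$q_start) + 1L) /
            len[hits$query_id] * 100
        disq <- hits$pct_identity >= minIdentity & cov >= minCoverage &
            len[hits$subject_id] >= minLen &
            len[hits$query_id] < minLen
        redundant <- unique(hits$query_id[disq])
        sel <- is.na(reason[redundant])
        reason[redundant[sel]] <- "redundant"
    }
    removed <- !is.na(reason)
    list(kept = contigs[!removed],
         removed = data.frame(id = ids[removed],
                              length = unname(len[removed]),
                              reason = unname(reason[removed]),
                              row.names = NULL, stringsAsFactors = FALSE))
}
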
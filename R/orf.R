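#' Find open reading frames under a variant genetic code
#'
#' ORFs are defined stop-to-stop: in each forward frame every maximal run of
#' non-stop codons that begins at the transcript 5' boundary (in frame) or
#' immediately after a stop, and ends at a stop or the 3' boundary, is
#' reported when it encodes at least \code{minAa} residues. Under the
#' Euplotes code TGA encodes cysteine and never terminates an ORF.
#' \code{atgAnchored = TRUE} instead starts each ORF at the first ATG of the
#' run. \code{bothStrands = TRUE} additionally scans the reverse complement
#' (reported with \code{strand == "-"}, coordinates on the
#' reverse-complemented sequence).
#'
#' @param transcripts a \code{DNAStringSet} (or single character string).
#' @param code a [GeneticCode-class].
#' @param minAa minimum protein length in residues.
#' @param atgAnchored start ORFs at the first ATG rather than stop-to-stop.
#' @param bothStrands also scan the reverse complement.
#' @return data.frame with columns \code{transcript_id}, \code{strand},
#'   \code{frame} (1..3), \code{start}, \code{end} (0-based half-open
#'   nucleotide coordinates of the coding run, stop codon excluded),
#'   \code{stop_codon} ("TAA"/"TAG"/"TGA" or NA for 3'-truncated ORFs) and
#'   \code{protein}; ordered by transcript then start.
#' @export
findOrfs <- function(transcripts, code = geneticCode("euplotes"),
                     minAa = 30L, atgAnchored = FALSE, bothStrands = FALSE) {
    if (is.character(transcripts)) {
        nm <- names(transcripts)
        if (is.null(nm)) nm <- paste0("seq", seq_along(transcripts))
        transcripts <- DNAStringSet(setNames(toupper(transcripts), nm))
    }
    res <- lapply(seq_along(transcripts), function(i) {
        id <- names(transcripts)[i]
        seq <- as.character(transcripts[[i]])
        out <- scanStrand(id, seq, code, minAa, atgAnchored, "+")
        if (bothStrands) {
            rc <- as.character(reverseComplement(transcripts[[i]]))
            out <- rbind(out, scanStrand(id, rc, code, minAa, atgAnchored,
                                         "-"))
        }
        out
    })
    out <- do.call(rbind, res)
    out <- out[order(match(out$transcript_id, names(transcripts)),
                     out$start), , drop = FALSE]
    rownames(out) <- NULL
    out
}

scanStrand <- function(id, seq, code, minAa, atgAnchored, strand) {
    rows <- list()
    for (frame in 1:3) {
        aa <- translateDNA(seq, code, frame)
        if (nchar(aa) == 0L) next
        # runs of non-stop residues delimited by '*'
        segs <- strsplit(aa, "*", fixed = TRUE)[[1L]]
        if (length(segs) == 0L) segs <- ""
        pos <- 1L                       # 1-based codon index of segment start
        for (k in seq_along(segs)) {
            seg <- segs[k]
            segStart <- pos
            pos <- pos + nchar(seg) + 1L
            prot <- seg
            startCodon <- segStart
            if (atgAnchored && nchar(prot)) {
                mAt <- regexpr("M", prot, fixed = TRUE)
                if (mAt < 0L) next
                startCodon <- segStart + (mAt - 1L)
                prot <- substr(prot, mAt, nchar(prot))
            }
            if (nchar(prot) < minAa) next
            start0 <- (frame - 1L) + 3L * (startCodon - 1L)
            end0 <- start0 + 3L * nchar(prot)
            # a stop codon exists iff the residue after the run is '*'
            stopIdx <- segStart + nchar(seg)
            stopC <- if (stopIdx <= nchar(aa) &&
                         substr(aa, stopIdx, stopIdx) == "*")
                substr(seq, end0 + 1L, end0 + 3L) else NA_character_
            rows[[length(rows) + 1L]] <-
                data.frame(transcript_id = id, strand = strand,
                           frame = frame, start = start0, end = end0,
                           stop_codon = stopC, protein = prot,
                           stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(transcript_id = character(), strand = character(),
                          frame = integer(), start = integer(),
                          end = integer(), stop_codon = character(),
                          protein = character(), stringsAsFactors = FALSE))
    do.call(rbind, rows)
}

#' Intron-count histogram over gene models
#'
#' Proportion of genes with 0, 1, 2, ... introns, computed from exon counts
#' of supplied gene models (an explicit \code{subset} of transcripts may
#' restrict the computation, e.g. to cilia-associated genes only).
#'
#' @param models data.frame from [geneModelSummary()] (columns
#'   \code{transcript}, \code{n_introns}) or a GFF3 \code{GRanges}.
#' @param subset optional character vector of transcript ids to keep.
#' @return named numeric vector: proportion per intron count; sums to 1.
#' @export
intronHistogram <- function(models, subset = NULL) {
    if (!is.data.frame(models)) models <- geneModelSummary(models)
    if (!is.null(subset)) models <- models[models$transcript %in% subset, ]
    if (nrow(models) == 0L) stop("no gene models to summarise")
    tab <- table(models$n_introns)
    prop <- as.numeric(tab) / sum(tab)
    names(prop) <- names(tab)
    prop
}

#' Stop-codon usage over a set of ORFs
#'
#' @param orfs data.frame from [findOrfs()]; 3'-truncated ORFs (no stop)
#'   are excluded.
#' @return named numeric vector of proportions per stop codon; sums to 1.
#' @export
stopUsage <- function(orfs) {
    stops <- orfs$stop_codon[!is.na(orfs$stop_codon)]
    if (length(stops) == 0L) stop("no stop codons observed")
    tab <- table(stops)
    prop <- as.numeric(tab) / sum(tab)
    names(prop) <- names(tab)
    prop
}

#' Gene-structure statistics: introns, stop usage, PRF fraction
#'
#' Combines the intron-count histogram, the stop-codon usage and the
#' fraction of genes undergoing programmed ribosomal frameshifting into one
#' summary of gene-structure composition.
#'
#' @param models gene models (see [intronHistogram()]).
#' @param orfs ORF table (see [stopUsage()]).
#' @param prfTranscripts character vector of transcript ids with detected
#'   PRF events.
#' @param nGenes total number of genes the PRF fraction is computed over.
#' @param subset optional transcript subset for the intron histogram.
#' @return list with \code{intron_histogram}, \code{stop_usage},
#'   \code{prf_fraction}; each proportion set sums to 1.
#' @export
structureStats <- function(models, orfs, prfTranscripts, nGenes,
                           subset = NULL) {
    stopifnot(nGenes >= 1L)
    list(intron_histogram = intronHistogram(models, subset),
         stop_usage = stopUsage(orfs),
         prf_fraction = length(unique(prfTranscripts)) / nGenes)
}
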
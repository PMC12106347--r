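#' @importFrom Biostrings readDNAStringSet readAAStringSet writeXStringSet
#'   DNAStringSet AAStringSet reverseComplement DNAString
#' @importFrom utils read.delim write.table
NULL

BLAST6_COLS <- c("query_id", "subject_id", "pct_identity", "aln_length",
                 "mismatches", "gap_opens", "q_start", "q_end",
                 "s_start", "s_end", "evalue", "bitscore")

#' Read and write FASTA files
#'
#' Thin wrappers around Biostrings readers that normalise sequences to
#' uppercase and validate the file shape. \code{readFasta} reads DNA by
#' default; use \code{type = "AA"} for protein FASTA.
#'
#' @param path file path.
#' @param type \code{"DNA"} or \code{"AA"}.
#' @return an uppercased \code{DNAStringSet} / \code{AAStringSet}.
#' @export
readFasta <- function(path, type = c("DNA", "AA")) {
    type <- match.arg(type)
    if (!file.exists(path)) stop("no such file: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L)
        stop("malformed FASTA (empty file) at line 1: ", path)
    if (!startsWith(first, ">"))
        stop("malformed FASTA header at line 1: ", path)
    x <- if (type == "DNA") readDNAStringSet(path) else readAAStringSet(path)
    # keep only the first whitespace-delimited token of each header
    names(x) <- sub("\\s.*$", "", names(x))
    if (type == "DNA") DNAStringSet(toupper(x)) else AAStringSet(toupper(x))
}

#' @rdname readFasta
#' @param records named character vector or XStringSet.
#' @param width line-wrap width.
#' @export
writeFasta <- function(records, path, width = 70L) {
    if (is.character(records)) {
        stopifnot(!is.null(names(records)))
        records <- Biostrings::BStringSet(records)
    }
    writeXStringSet(records, path, width = width)
    invisible(path)
}

#' Read a BLAST-style tabular hit file (outfmt 6)
#'
#' Standard 12-column tab-separated hit table; an optional 13th column holds
#' the query reading frame of a translated search (-3..-1, +1..+3; 0 for
#' protein-protein hits). Lines starting with \code{#} are ignored.
#'
#' @param path file path.
#' @return data.frame with columns \code{query_id, subject_id, pct_identity,
#'   aln_length, mismatches, gap_opens, q_start, q_end, s_start, s_end,
#'   evalue, bitscore, frame}. Coordinates are 1-based inclusive.
#' @export
readHitsTabular <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    keep <- !grepl("^\\s*(#|$)", lines)
    idx <- which(keep)
    if (length(idx) == 0L) return(emptyHits())
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(!(nf %in% c(12L, 13L)))
    if (length(bad))
        stop("hit table format error at line ", idx[bad[1L]],
             ": expected 12 or 13 tab-separated columns, got ", nf[bad[1L]])
    m <- do.call(rbind, lapply(parts, function(p) p[1:12]))
    hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                       stringsAsFactors = FALSE)
    for (j in 3:12) hits[[BLAST6_COLS[j]]] <- as.numeric(m[, j])
    for (j in c("aln_length", "mismatches", "gap_opens",
                "q_start", "q_end", "s_start", "s_end"))
        hits[[j]] <- as.integer(hits[[j]])
    hits$frame <- ifelse(nf == 13L,
                         as.integer(vapply(parts, function(p)
                             if (length(p) == 13L) p[13L] else "0", "")), 0L)
    validateHits(hits)
    hits
}

#' @rdname readHitsTabular
#' @param hits a hits data.frame as returned by [readHitsTabular()] or
#'   [searchProtein()].
#' @export
writeHitsTabular <- function(hits, path) {
    cols <- c(BLAST6_COLS, if ("frame" %in% names(hits)) "frame")
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", paste(cols, collapse = "\t")), con)
    write.table(hits[, cols, drop = FALSE], con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

emptyHits <- function() {
    h <- data.frame(query_id = character(), subject_id = character(),
                    pct_identity = numeric(), aln_length = integer(),
                    mismatches = integer(), gap_opens = integer(),
                    q_start = integer(), q_end = integer(),
                    s_start = integer(), s_end = integer(),
                    evalue = numeric(), bitscore = numeric(),
                    frame = integer(), stringsAsFactors = FALSE)
    h
}

validateHits <- function(hits) {
    stopifnot(all(hits$evalue >= 0),
              all(hits$pct_identity >= 0 & hits$pct_identity <= 100))
    invisible(hits)
}

#' Read gene models from GFF3
#'
#' Imports a GFF3 file (via rtracklayer) and summarises exon structure per
#' mRNA. Intron count is exon count minus one.
#'
#' @param path GFF3 file.
#' @return the imported \code{GRanges}.
#' @export
readGff3 <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    rtracklayer::import(path, format = "gff3")
}

#' @rdname readGff3
#' @param gr a \code{GRanges} of gene/mRNA/exon features (GFF3 import).
#' @return for \code{geneModelSummary}: data.frame with columns
#'   \code{transcript}, \code{n_exons}, \code{n_introns}.
#' @export
geneModelSummary <- function(gr) {
    ex <- gr[tolower(as.character(gr$type)) == "exon"]
    if (length(ex) == 0L)
        return(data.frame(transcript = character(), n_exons = integer(),
                          n_introns = integer()))
    parent <- vapply(ex$Parent, function(p) as.character(p)[1L], "")
    tab <- table(parent)
    data.frame(transcript = names(tab),
               n_exons = as.integer(tab),
               n_introns = as.integer(tab) - 1L,
               row.names = NULL, stringsAsFactors = FALSE)
}

#' Read an undirected edge list as an igraph network
#'
#' Tab-separated \code{nodeA<TAB>nodeB[<TAB>weight]} lines; comment lines
#' start with \code{#}. Self-loops are dropped and duplicate undirected
#' edges deduplicated.
#'
#' @param path file path.
#' @return a simple undirected \code{igraph} graph.
#' @export
readEdgeList <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    lines <- readLines(path)
    idx <- which(!grepl("^\\s*(#|$)", lines))
    if (length(idx) == 0L) stop("edge list is empty: ", path)
    parts <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(!(nf %in% c(2L, 3L)))
    if (length(bad))
        stop("edge list format error at line ", idx[bad[1L]],
             ": expected 2 or 3 columns, got ", nf[bad[1L]])
    el <- do.call(rbind, lapply(parts, function(p) p[1:2]))
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    if (any(nf == 3L)) {
        w <- vapply(parts, function(p)
            if (length(p) == 3L) as.numeric(p[3L]) else 1, 1)
        igraph::E(g)$weight <- w
    }
    igraph::simplify(g, edge.attr.comb = "first")
}

#' @rdname readEdgeList
#' @param g an igraph graph.
#' @export
writeEdgeList <- function(g, path) {
    el <- igraph::as_edgelist(g)
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines("# nodeA\tnodeB", con)
    write.table(el, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}

#' Read simple TSV tables (qPCR Cq tables, centroid tracks)
#'
#' Tab-separated with a header line; a leading \code{#} on the header is
#' tolerated and stripped.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readTsv <- function(path) {
    if (!file.exists(path)) stop("no such file: ", path)
    first <- readLines(path, n = 1L)
    if (length(first) == 0L) stop("empty table: ", path)
    if (startsWith(first, "#")) {
        cols <- strsplit(sub("^#\\s*", "", first), "\t", fixed = TRUE)[[1L]]
        df <- tryCatch(read.delim(path, header = FALSE, skip = 1L,
                                  stringsAsFactors = FALSE),
                       error = function(e) data.frame())
        if (nrow(df) == 0L)
            df <- as.data.frame(setNames(rep(list(character(0)),
                                             length(cols)), cols))
        else names(df) <- cols
        df
    } else {
        read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   check.names = FALSE)
    }
}

#' @rdname readTsv
#' @param df data.frame to write.
#' @export
writeTsv <- function(df, path) {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    writeLines(paste0("# ", paste(names(df), collapse = "\t")), con)
    write.table(df, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
    invisible(path)
}
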
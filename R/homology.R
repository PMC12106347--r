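#' @importFrom Biostrings pairwiseAlignment score nmatch nmismatch nindel
#'   pattern subject
NULL

# Karlin-Altschul parameters for BLOSUM62 with gap open 11 / extend 1
# (the standard gapped estimates); effective-length corrections are not
# applied, the raw query length x database length product is used.
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Protein similarity search (Smith-Waterman with E-values)
#'
#' All-vs-all local alignment of query proteins against a subject database:
#' Smith-Waterman alignments under a substitution matrix with affine gaps,
#' scored into bits via Karlin-Altschul statistics
#' (\eqn{S' = (\lambda S - \ln K)/\ln 2}) and an expectation value
#' \eqn{E = m n 2^{-S'}} with m the query length and n the total database
#' length. Hits are filtered at \code{evalueMax}; one best hit is kept per
#' query/subject pair.
#'
#' @param queries,subjects \code{AAStringSet} (or named character vectors).
#' @param substitutionMatrix matrix name or matrix (default BLOSUM62).
#' @param gapOpen,gapExtend affine gap penalties (positive costs).
#' @param evalueMax E-value cutoff.
#' @return hits data.frame in the layout of [readHitsTabular()]
#'   (1-based inclusive coordinates, \code{frame} = 0).
#' @export
searchProtein <- function(queries, subjects,
                          substitutionMatrix = "BLOSUM62",
                          gapOpen = 11, gapExtend = 1, evalueMax = 1e-5) {
    queries <- asAASet(queries, "q")
    subjects <- asAASet(subjects, "s")
    if (length(queries) == 0L || length(subjects) == 0L) return(emptyHits())
    dbLen <- sum(Biostrings::width(subjects))
    rows <- list()
    for (qi in seq_along(queries)) for (si in seq_along(subjects)) {
        aln <- pairwiseAlignment(queries[[qi]], subjects[[si]],
                                 type = "local",
                                 substitutionMatrix = substitutionMatrix,
                                 gapOpening = gapOpen,
                                 gapExtension = gapExtend)
        s <- score(aln)
        if (s <= 0) next
        bits <- (KA_LAMBDA * s - log(KA_K)) / log(2)
        ev <- Biostrings::width(queries)[qi] * dbLen * 2^(-bits)
        if (ev > evalueMax) next
        alnLen <- Biostrings::nchar(aln)
        ind <- nindel(aln)
        gapOpens <- sum(ind@insertion[, "Length"], ind@deletion[, "Length"])
        rows[[length(rows) + 1L]] <- data.frame(
            query_id = names(queries)[qi], subject_id = names(subjects)[si],
            pct_identity = round(100 * nmatch(aln) / alnLen, 2),
            aln_length = alnLen,
            mismatches = nmismatch(aln),
            gap_opens = gapOpens,
            q_start = Biostrings::start(pattern(aln)),
            q_end = Biostrings::end(pattern(aln)),
            s_start = Biostrings::start(subject(aln)),
            s_end = Biostrings::end(subject(aln)),
            evalue = ev, bitscore = round(bits, 1), frame = 0L,
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L) return(emptyHits())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

asAASet <- function(x, prefix) {
    if (is.character(x)) {
        if (is.null(names(x))) names(x) <- paste0(prefix, seq_along(x))
        x <- AAStringSet(toupper(x))
    }
    x
}

#' Translated similarity search (BLASTX-style)
#'
#' Translates each transcript in all three forward frames (six with
#' \code{bothStrands}) under the given genetic code and runs
#' [searchProtein()] on the translations. Query coordinates are reported in
#' transcript nucleotides and the reading frame is recorded per hit
#' (negative frames index the reverse complement).
#'
#' @param transcripts \code{DNAStringSet}.
#' @param subjects \code{AAStringSet} of reference proteins.
#' @param code a [GeneticCode-class].
#' @inheritParams searchProtein
#' @param bothStrands also search the reverse complement.
#' @return hits data.frame with nucleotide query coordinates and
#'   \code{frame} set.
#' @export
searchTranslated <- function(transcripts, subjects,
                             code = geneticCode("euplotes"),
                             substitutionMatrix = "BLOSUM62",
                             gapOpen = 11, gapExtend = 1,
                             evalueMax = 1e-5, bothStrands = FALSE) {
    if (is.character(transcripts)) {
        if (is.null(names(transcripts)))
            names(transcripts) <- paste0("t", seq_along(transcripts))
        transcripts <- DNAStringSet(toupper(transcripts))
    }
    strands <- if (bothStrands) c(1L, -1L) else 1L
    rows <- list()
    for (sgn in strands) for (f in 1:3) {
        tr <- vapply(seq_along(transcripts), function(i) {
            s <- transcripts[[i]]
            if (sgn < 0L) s <- reverseComplement(s)
            translateDNA(s, code, f)
        }, "")
        names(tr) <- names(transcripts)
        keep <- nchar(tr) > 0L
        if (!any(keep)) next
        h <- searchProtein(tr[keep], subjects, substitutionMatrix,
                           gapOpen, gapExtend, evalueMax)
        if (nrow(h) == 0L) next
        # amino-acid -> nucleotide query coordinates in the frame
        h$q_end <- (f - 1L) + 3L * h$q_end
        h$q_start <- (f - 1L) + 3L * (h$q_start - 1L) + 1L
        h$frame <- sgn * f
        rows[[length(rows) + 1L]] <- h
    }
    if (length(rows) == 0L) return(emptyHits())
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Assign proteins to gene families by best exemplar hit
#'
#' Each protein joins the family of its best-scoring family exemplar
#' (curated query sequences standing for the families), with ties broken by
#' higher bitscore, then lower E-value, then lexicographic exemplar id.
#' Proteins with no hit at \code{evalueMax} are listed as unassigned.
#'
#' @param proteinsBySpecies named list: species id -> \code{AAStringSet}.
#' @param exemplars \code{AAStringSet} of family exemplar proteins.
#' @param exemplarFamily named character vector mapping exemplar id ->
#'   family name.
#' @param evalueMax E-value cutoff.
#' @param hits optional precomputed hit table (proteins vs exemplars, e.g.
#'   an imported tabular file) bypassing the internal search.
#' @return a [FamilyCatalog-class].
#' @export
assignFamilies <- function(proteinsBySpecies, exemplars, exemplarFamily,
                           evalueMax = 1e-5, hits = NULL) {
    stopifnot(is.list(proteinsBySpecies), !is.null(names(proteinsBySpecies)),
              all(names(exemplars) %in% names(exemplarFamily)))
    members <- list()
    unassigned <- list()
    for (sp in names(proteinsBySpecies)) {
        prots <- proteinsBySpecies[[sp]]
        h <- if (is.null(hits))
            searchProtein(prots, exemplars, evalueMax = evalueMax)
        else hits[hits$query_id %in% names(prots) &
                  hits$evalue <= evalueMax, , drop = FALSE]
        for (p in names(prots)) {
            hp <- h[h$query_id == p, , drop = FALSE]
            if (nrow(hp) == 0L) {
                unassigned[[length(unassigned) + 1L]] <-
                    data.frame(species = sp, gene = p,
                               stringsAsFactors = FALSE)
                next
            }
            hp <- hp[order(-hp$bitscore, hp$evalue, hp$subject_id), ,
                     drop = FALSE]
            members[[length(members) + 1L]] <-
                data.frame(family = unname(exemplarFamily[hp$subject_id[1L]]),
                           species = sp, gene = p, stringsAsFactors = FALSE)
        }
    }
    bindOrEmpty <- function(lst, cols) {
        if (length(lst)) do.call(rbind, lst)
        else as.data.frame(setNames(rep(list(character(0)), length(cols)),
                                    cols))
    }
    new("FamilyCatalog",
        species = names(proteinsBySpecies),
        members = bindOrEmpty(members, c("family", "species", "gene")),
        unassigned = bindOrEmpty(unassigned, c("species", "gene")))
}

#' @rdname FamilyCatalog-class
#' @export
setMethod("familyMembers", "FamilyCatalog", function(x) x@members)

setMethod("show", "FamilyCatalog", function(object) {
    cat("FamilyCatalog:", length(unique(object@members$family)),
        "families across", length(object@species), "species;",
        nrow(object@members), "genes assigned,",
        nrow(object@unassigned), "unassigned\n")
})

#' Construct a FamilyCatalog from a long-format membership table
#'
#' @param members data.frame with columns \code{family}, \code{species},
#'   \code{gene}.
#' @param species optional species universe (default: those observed).
#' @return a [FamilyCatalog-class].
#' @export
familyCatalog <- function(members, species = unique(members$species)) {
    new("FamilyCatalog", species = species, members = members,
        unassigned = data.frame(species = character(), gene = character(),
                                stringsAsFactors = FALSE))
}

#' Cross-species conservation partition (Venn regions)
#'
#' Partitions the distinct gene families of a catalogue by the exact set of
#' species each family occurs in: one count per non-empty species subset
#' (the regions of a Venn diagram). The counts over all regions sum to the
#' number of distinct families.
#'
#' @param catalog a [FamilyCatalog-class].
#' @return data.frame with columns \code{region} ("+"-joined species ids,
#'   in catalogue species order) and \code{count}.
#' @export
vennPartition <- function(catalog) {
    m <- unique(catalog@members[, c("family", "species")])
    sp <- catalog@species
    pattern <- vapply(split(m$species, m$family), function(s)
        paste(sp[sp %in% s], collapse = "+"), "")
    regions <- unlist(lapply(seq_along(sp), function(k)
        utils::combn(sp, k, paste, collapse = "+")))
    counts <- table(factor(pattern, levels = regions))
    data.frame(region = regions, count = as.integer(counts),
               row.names = NULL, stringsAsFactors = FALSE)
}

#' @rdname vennPartition
#' @param level \code{"family"}: family names present in every species;
#'   \code{"gene"}: the member genes of those core families.
#' @return for \code{conservedCore}: character vector of family names, or a
#'   data.frame of genes when \code{level = "gene"}.
#' @export
conservedCore <- function(catalog, level = c("family", "gene")) {
    level <- match.arg(level)
    m <- unique(catalog@members[, c("family", "species")])
    nsp <- vapply(split(m$species, m$family),
                  function(s) length(unique(s)), 1L)
    core <- names(nsp)[nsp == length(catalog@species)]
    if (level == "family") return(core)
    catalog@members[catalog@members$family %in% core, , drop = FALSE]
}
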
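#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
NULL

DNA_CODONS <- as.vector(outer(outer(c("T", "C", "A", "G"), c("T", "C", "A", "G"),
                                    paste0), c("T", "C", "A", "G"), paste0))

#' GeneticCode: a codon translation table with stop-codon reassignments
#'
#' Ciliate macronuclear genomes use variant nuclear genetic codes. In
#' \emph{Euplotes} the canonical stop UGA is read as cysteine, leaving TAA and
#' TAG as the only stops; in \emph{Oxytricha}/\emph{Stylonychia} UAA and UAG
#' are read as glutamine and UGA is the only stop. A \code{GeneticCode} holds
#' the full 64-codon table (DNA alphabet, stops rendered \code{"*"}) together
#' with the reassignments relative to the standard code.
#'
#' @slot name single string naming the code.
#' @slot table named character vector of length 64 mapping each DNA codon to
#'   an amino-acid letter or \code{"*"}.
#' @slot reassignments data.frame with columns \code{codon} and \code{aa};
#'   every reassigned codon is a stop under the standard code.
#'
#' @seealso [geneticCode()], [translateDNA()]
#' @export
setClass("GeneticCode",
         representation(name = "character",
                        table = "character",
                        reassignments = "data.frame"))

setValidity("GeneticCode", function(object) {
    msg <- character()
    if (length(object@name) != 1L)
        msg <- c(msg, "'name' must be a single string")
    if (length(object@table) != 64L ||
        !setequal(names(object@table), DNA_CODONS))
        msg <- c(msg, "'table' must map exactly the 64 DNA codons")
    std <- Biostrings::getGeneticCode("1")
    re <- object@reassignments
    if (nrow(re) > 0L) {
        if (!all(c("codon", "aa") %in% names(re)))
            msg <- c(msg, "'reassignments' needs columns codon, aa")
        else if (!all(std[re$codon] == "*"))
            msg <- c(msg, "reassigned codons must be stops in the standard code")
    }
    if (length(msg)) msg else TRUE
})

#' PRFGene: a transcript with detected programmed ribosomal frameshifts
#'
#' One gene whose transcript carries one or more +1/+2 programmed ribosomal
#' frameshift (PRF) events, each modelled as an internal TAA/TAG stop codon
#' whose first one or two bases ("T" or "TA") must be excised to restore the
#' reading frame of the C-terminal extension.
#'
#' @slot transcriptId transcript identifier.
#' @slot referenceId identifier of the homologous reference protein the
#'   C-terminal extension was validated against.
#' @slot events data.frame with one row per event, columns \code{position}
#'   (0-based index of the stop codon start on the transcript),
#'   \code{stopCodon} ("TAA"/"TAG"), \code{slippery} (6-nt context: 3 nt
#'   upstream plus the stop codon), \code{model} (integer 1 or 2) and
#'   \code{excised} ("T"/"TA"), ordered by strictly increasing position.
#' @slot localization free-text annotation carried from input (not computed).
#' @slot truncated TRUE when detection stopped at the event cap before
#'   reaching the reference C-terminus.
#'
#' @export
setClass("PRFGene",
         representation(transcriptId = "character",
                        referenceId = "character",
                        events = "data.frame",
                        localization = "character",
                        truncated = "logical"))

setValidity("PRFGene", function(object) {
    ev <- object@events
    need <- c("position", "stopCodon", "slippery", "model", "excised")
    if (!all(need %in% names(ev)))
        return(paste("'events' needs columns", paste(need, collapse = ", ")))
    if (nrow(ev) > 0L) {
        if (is.unsorted(ev$position, strictly = TRUE))
            return("event positions must be strictly increasing")
        if (!all(substr(ev$slippery, 4L, 6L) == ev$stopCodon))
            return("slippery context must end with the stop codon")
        if (!all((ev$model == 1L) == (ev$excised == "T")))
            return("model +1 must excise 'T', model +2 must excise 'TA'")
    }
    TRUE
})

#' FamilyCatalog: per-species gene-family membership
#'
#' Long-format catalogue assigning genes of several species to named gene
#' families, the structure underlying cross-species Venn partitioning of
#' family conservation.
#'
#' @slot species character vector of species identifiers.
#' @slot members data.frame with columns \code{family}, \code{species},
#'   \code{gene}; a gene id appears in at most one family per species.
#' @slot unassigned data.frame with columns \code{species}, \code{gene} for
#'   proteins that hit no family exemplar.
#'
#' @export
setClass("FamilyCatalog",
         representation(species = "character",
                        members = "data.frame",
                        unassigned = "data.frame"))

setValidity("FamilyCatalog", function(object) {
    m <- object@members
    if (!all(c("family", "species", "gene") %in% names(m)))
        return("'members' needs columns family, species, gene")
    if (nrow(m) > 0L) {
        if (!all(m$species %in% object@species))
            return("member species not listed in 'species'")
        if (anyDuplicated(m[, c("species", "gene")]))
            return("a gene may belong to at most one family per species")
    }
    TRUE
})

#' CentralityTable: twelve topological centrality scores with ranks
#'
#' Node-by-method matrix of the twelve CytoHubba-style topological scores
#' (Degree, MNC, DMNC, MCC, EPC, BottleNeck, EcCentricity, Closeness,
#' Radiality, Betweenness, Stress, ClusteringCoefficient) plus the per-method
#' rank vectors (descending score, ties shared at the minimum rank).
#'
#' @slot scores numeric matrix, nodes x 12 methods.
#' @slot ranks integer matrix of the same shape; per column a min-rank
#'   ("1224") ranking of the scores.
#' @slot config list with \code{dmncEpsilon}, \code{epcReps}, \code{seed}.
#'
#' @export
setClass("CentralityTable",
         representation(scores = "matrix",
                        ranks = "matrix",
                        config = "list"))

CENTRALITY_METHODS <- c("Degree", "MNC", "DMNC", "MCC", "EPC", "BottleNeck",
                        "EcCentricity", "Closeness", "Radiality",
                        "Betweenness", "Stress", "ClusteringCoefficient")

setValidity("CentralityTable", function(object) {
    if (!identical(colnames(object@scores), CENTRALITY_METHODS))
        return("score columns must be the 12 centrality methods")
    if (!identical(dim(object@scores), dim(object@ranks)))
        return("scores and ranks must have identical shape")
    for (j in seq_len(ncol(object@ranks))) {
        r <- object@ranks[, j]
        if (!identical(as.integer(sort(unique(r))),
                       as.integer(sort(unique(rank(-object@scores[, j],
                                                   ties.method = "min"))))))
            return("ranks must be min-ranks of descending scores")
    }
    TRUE
})

#' HubSet: consensus hub genes from multi-method centrality ranking
#'
#' Nodes ranked within the top \code{k} by at least \code{m} of the twelve
#' centrality methods. \code{support} records, for every node, the number of
#' methods placing it in the top \code{k}.
#'
#' @slot hubs character vector of hub node ids.
#' @slot support named integer vector, one entry per node.
#' @slot k,m the top-k depth and the minimum method support.
#'
#' @export
setClass("HubSet",
         representation(hubs = "character",
                        support = "integer",
                        k = "integer",
                        m = "integer"))

setValidity("HubSet", function(object) {
    inhub <- names(object@support) %in% object@hubs
    if (!identical(inhub, unname(object@support >= object@m)))
        return("hubs must be exactly the nodes with support >= m")
    TRUE
})
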
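#' @rdname GeneticCode-class
#' @param x a \code{GeneticCode}.
#' @export
setGeneric("codonTable", function(x) standardGeneric("codonTable"))

#' @rdname GeneticCode-class
#' @export
setGeneric("stopCodons", function(x) standardGeneric("stopCodons"))

#' @rdname PRFGene-class
#' @param x object.
#' @export
setGeneric("prfEvents", function(x) standardGeneric("prfEvents"))

#' @rdname PRFGene-class
#' @export
setGeneric("nEvents", function(x) standardGeneric("nEvents"))

#' @rdname FamilyCatalog-class
#' @export
setGeneric("familyMembers", function(x) standardGeneric("familyMembers"))

#' @rdname CentralityTable-class
#' @export
setGeneric("centralityScores", function(x) standardGeneric("centralityScores"))

#' @rdname CentralityTable-class
#' @export
setGeneric("centralityRanks", function(x) standardGeneric("centralityRanks"))

#' @rdname HubSet-class
#' @export
setGeneric("hubGenes", function(x) standardGeneric("hubGenes"))

#' @rdname HubSet-class
#' @export
setGeneric("hubSupport", function(x) standardGeneric("hubSupport"))
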
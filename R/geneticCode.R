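#' Built-in and custom genetic codes
#'
#' Construct a [GeneticCode-class]. Built-ins:
#' \describe{
#'   \item{\code{"standard"}}{the standard nuclear code (stops TAA, TAG, TGA).}
#'   \item{\code{"euplotes"}}{\emph{Euplotes}-type code: TGA reassigned to
#'     cysteine, stops TAA and TAG (the Euplotid nuclear code).}
#'   \item{\code{"oxytricha"}, \code{"stylonychia"}}{TAA and TAG reassigned to
#'     glutamine, TGA the only stop (the ciliate nuclear code).}
#' }
#' Custom codes are built by overriding standard-code stop codons.
#'
#' @param name one of the built-in names above, or any label when
#'   \code{reassign} is given.
#' @param reassign optional named character vector of overrides, e.g.
#'   \code{c(TGA = "C")}; only standard-code stops may be reassigned.
#' @return a \code{GeneticCode}.
#' @examples
#' eu <- geneticCode("euplotes")
#' codonTable(eu)[["TGA"]]   # "C"
#' stopCodons(eu)            # "TAA" "TAG"
#' @export
geneticCode <- function(name = c("euplotes", "oxytricha", "stylonychia",
                                 "standard"),
                        reassign = NULL) {
    if (is.null(reassign)) {
        name <- match.arg(name)
        id <- switch(name, euplotes = "10",
                     oxytricha = "6", stylonychia = "6", standard = "1")
        tab <- as.character(Biostrings::getGeneticCode(id))
        names(tab) <- names(Biostrings::getGeneticCode(id))
        std <- Biostrings::getGeneticCode("1")
        changed <- names(tab)[tab != as.character(std)]
        re <- data.frame(codon = changed, aa = unname(tab[changed]),
                         stringsAsFactors = FALSE)
    } else {
        stopifnot(is.character(reassign), !is.null(names(reassign)))
        std <- Biostrings::getGeneticCode("1")
        if (!all(std[names(reassign)] == "*"))
            stop("only standard-code stop codons may be reassigned")
        tab <- as.character(std)
        names(tab) <- names(std)
        tab[names(reassign)] <- reassign
        re <- data.frame(codon = names(reassign), aa = unname(reassign),
                         stringsAsFactors = FALSE)
    }
    new("GeneticCode", name = name, table = tab, reassignments = re)
}

#' @rdname GeneticCode-class
#' @export
setMethod("codonTable", "GeneticCode", function(x) x@table)

#' @rdname GeneticCode-class
#' @export
setMethod("stopCodons", "GeneticCode",
          function(x) names(x@table)[x@table == "*"])

setMethod("show", "GeneticCode", function(object) {
    cat("GeneticCode:", object@name, "\n")
    cat("  stops:", paste(stopCodons(object), collapse = ", "), "\n")
    if (nrow(object@reassignments))
        cat("  reassigned:",
            paste(object@reassignments$codon, "->",
                  object@reassignments$aa, collapse = ", "), "\n")
})

#' Translate DNA in a fixed frame under a variant genetic code
#'
#' Translates the forward strand starting at frame offset 1, 2 or 3.
#' Trailing partial codons are ignored; stops are rendered \code{"*"}; any
#' codon containing an ambiguity letter (N etc.) translates to \code{"X"}
#' and can never act as a stop.
#'
#' @param seq a DNA string (character) or [Biostrings::DNAString].
#' @param code a [GeneticCode-class]; default the Euplotes code.
#' @param frame 1, 2 or 3 (+1 starts at the first base).
#' @return single amino-acid string of length
#'   \code{floor((nchar(seq) - frame + 1) / 3)}.
#' @examples
#' translateDNA("ATGTGATAA", geneticCode("euplotes"))  # "MC*"
#' @export
translateDNA <- function(seq, code = geneticCode("euplotes"), frame = 1L) {
    stopifnot(frame %in% 1:3)
    seq <- toupper(as.character(seq))
    n <- nchar(seq) - (frame - 1L)
    if (n < 3L) return("")
    ncod <- n %/% 3L
    sub <- substr(seq, frame, frame - 1L + 3L * ncod)
    codons <- substring(sub, seq(1L, by = 3L, length.out = ncod),
                        seq(3L, by = 3L, length.out = ncod))
    aa <- unname(code@table[codons])
    aa[is.na(aa)] <- "X"
    paste0(aa, collapse = "")
}
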
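#' Candidate frameshift genes from translated-search hits
#'
#' A transcript is a programmed-frameshift candidate when it aligns to the
#' same reference protein in two or more different reading frames, with the
#' downstream (more 3') hit covering a more C-terminal region of the
#' reference than the upstream hit.
#'
#' @param hits data.frame of translated-search hits ([searchTranslated()]
#'   or an imported tabular file) with the \code{frame} column set.
#' @return data.frame with columns \code{transcript_id},
#'   \code{reference_id}, one row per candidate pair.
#' @export
findCandidates <- function(hits) {
    if (nrow(hits) == 0L)
        return(data.frame(transcript_id = character(),
                          reference_id = character(),
                          stringsAsFactors = FALSE))
    if (!("frame" %in% names(hits)) || any(hits$frame == 0L))
        stop("candidate search needs translated hits with frame information")
    key <- paste0(hits$query_id, "\r", hits$subject_id)
    out <- lapply(split(seq_len(nrow(hits)), key), function(ix) {
        h <- hits[ix, , drop = FALSE]
        if (length(unique(h$frame)) < 2L) return(NULL)
        h <- h[order(h$q_start), , drop = FALSE]
        for (a in seq_len(nrow(h) - 1L)) for (b in (a + 1L):nrow(h)) {
            if (h$frame[a] != h$frame[b] &&
                h$q_start[a] <= h$q_start[b] &&
                h$s_start[a] < h$s_start[b])
                return(data.frame(transcript_id = h$query_id[1L],
                                  reference_id = h$subject_id[1L],
                                  stringsAsFactors = FALSE))
        }
        NULL
    })
    out <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
    if (is.null(out))
        return(data.frame(transcript_id = character(),
                          reference_id = character(),
                          stringsAsFactors = FALSE))
    rownames(out) <- NULL
    out[order(out$transcript_id, out$reference_id), , drop = FALSE]
}

#' Classify a single stop-codon frameshift event
#'
#' At an in-frame internal stop (TAA or TAG) the two candidate excisions are
#' tried: removing the first base ("T", a +1 frameshift) or the first two
#' bases ("TA", +2). Each edited transcript is re-translated in the original
#' frame; an excision is accepted when the translation downstream of the
#' original stop matches the reference protein with at least
#' \code{minExtensionAa} identical residues contiguous with the stop (the
#' C-terminal extension criterion; the run is scored rather than total
#' matches so that a wrong excision re-synchronising at a later frameshift
#' site cannot win). When both excisions extend, the longer contiguous
#' extension wins; ties resolve to +1, the dominant model. The recorded
#' slippery context is the 3 nt upstream of the stop plus the stop codon.
#'
#' @param transcript DNA string (character or \code{DNAString}).
#' @param stopPos 0-based position of the stop codon start.
#' @param referenceProtein amino-acid string the extension is validated
#'   against.
#' @param code a [GeneticCode-class].
#' @param minExtensionAa minimum identical residues downstream of the stop.
#' @param frame reading frame of the interrupted ORF (1..3); default derived
#'   from \code{stopPos}.
#' @return one-row data.frame (\code{position}, \code{stopCodon},
#'   \code{slippery}, \code{model}, \code{excised}, \code{extensionAa}) or
#'   \code{NULL} when neither excision yields an extension.
#' @export
classifyEvent <- function(transcript, stopPos, referenceProtein,
                          code = geneticCode("euplotes"),
                          minExtensionAa = 10L, frame = NULL) {
    seq <- toupper(as.character(transcript))
    ref <- toupper(as.character(referenceProtein))
    if (is.null(frame)) frame <- (stopPos %% 3L) + 1L
    codon <- substr(seq, stopPos + 1L, stopPos + 3L)
    if (!(codon %in% stopCodons(code)))
        stop("position ", stopPos, " is not a stop codon under code '",
             code@name, "' (found '", codon, "')")
    nPre <- (stopPos - (frame - 1L)) %/% 3L   # residues upstream of the stop
    best <- NULL
    for (excised in c("T", "TA")) {
        m <- nchar(excised)
        edited <- paste0(substr(seq, 1L, stopPos),
                         substr(seq, stopPos + m + 1L, nchar(seq)))
        aa <- translateDNA(edited, code, frame)
        if (nchar(aa) <= nPre) next
        down <- substr(aa, nPre + 1L, nchar(aa))
        stopAt <- as.integer(regexpr("*", down, fixed = TRUE))
        if (stopAt > 0L) down <- substr(down, 1L, stopAt - 1L)
        refDown <- substr(ref, nPre + 1L, nchar(ref))
        L <- min(nchar(down), nchar(refDown))
        if (L == 0L) next
        # score the identity run contiguous with the excised stop: a wrong
        # excision can re-synchronise with the reference further downstream
        # (at the next frameshift site), so total matches would mislead
        eq <- strsplit(substr(down, 1L, L), "")[[1L]] ==
            strsplit(substr(refDown, 1L, L), "")[[1L]]
        nMatch <- if (all(eq)) L else which(!eq)[1L] - 1L
        if (nMatch >= minExtensionAa &&
            (is.null(best) || nMatch > best$extensionAa)) {
            best <- data.frame(position = as.integer(stopPos),
                               stopCodon = codon,
                               slippery = substr(seq, max(1L, stopPos - 2L),
                                                 stopPos + 3L),
                               model = m, excised = excised,
                               extensionAa = nMatch,
                               stringsAsFactors = FALSE)
        }
    }
    best
}

#' Detect programmed ribosomal frameshift genes
#'
#' For each candidate transcript/reference pair (from translated-search
#' hits), iteratively locates the terminal stop of the current reading
#' frame, classifies it with [classifyEvent()], applies the winning excision
#' to a working copy, and repeats until the reference C-terminus is reached,
#' no further event is found, or \code{maxEvents} events have accumulated
#' (the gene is then flagged truncated). Event positions refer to the
#' original, unedited transcript.
#'
#' @param transcripts \code{DNAStringSet} of candidate transcripts.
#' @param referenceProteins \code{AAStringSet} of reference proteins.
#' @param hits translated-search hit table with frames (see
#'   [findCandidates()]).
#' @param code a [GeneticCode-class].
#' @param maxEvents cap on events per gene.
#' @param minExtensionAa see [classifyEvent()].
#' @param requireAaatar strict mode: only accept events whose slippery
#'   context matches 5'-AAA-TAR-3'. Off by default; the recorded contexts in
#'   validated PRF genes are far more diverse than AAATAR.
#' @param annotations optional data.frame (\code{transcript_id},
#'   \code{localization}) carried through to the report.
#' @return list of [PRFGene-class] objects (genes with >= 1 event).
#' @export
detectPrf <- function(transcripts, referenceProteins, hits,
                      code = geneticCode("euplotes"), maxEvents = 5L,
                      minExtensionAa = 10L, requireAaatar = FALSE,
                      annotations = NULL) {
    cand <- findCandidates(hits)
    stops <- stopCodons(code)
    genes <- list()
    for (i in seq_len(nrow(cand))) {
        tid <- cand$transcript_id[i]
        rid <- cand$reference_id[i]
        if (!(tid %in% names(transcripts)) ||
            !(rid %in% names(referenceProteins)))
            stop("candidate references unknown sequence: ", tid, "/", rid)
        seq <- as.character(transcripts[[tid]])
        ref <- as.character(referenceProteins[[rid]])
        h <- hits[hits$query_id == tid & hits$subject_id == rid, ,
                  drop = FALSE]
        frame <- h$frame[which.min(h$q_start)]
        if (frame < 1L) next                    # forward frames only
        working <- seq
        offset <- 0L                            # bases excised so far
        events <- list()
        truncated <- FALSE
        repeat {
            aa <- translateDNA(working, code, frame)
            stopAt <- as.integer(regexpr("*", aa, fixed = TRUE))
            if (stopAt < 0L) break              # ran off the 3' end
            if (stopAt - 1L >= nchar(ref)) break  # C-terminus reached
            stopPos <- (frame - 1L) + 3L * (stopAt - 1L)
            if (length(events) >= maxEvents) {
                truncated <- TRUE
                break
            }
            ev <- classifyEvent(working, stopPos, ref, code,
                                minExtensionAa, frame)
            if (is.null(ev)) break
            if (requireAaatar && !grepl("^AAATA[AG]$", ev$slippery)) break
            ev$position <- ev$position + offset
            events[[length(events) + 1L]] <- ev
            working <- paste0(substr(working, 1L, stopPos),
                              substr(working, stopPos + ev$model + 1L,
                                     nchar(working)))
            offset <- offset + ev$model
        }
        if (length(events)) {
            evd <- do.call(rbind, events)
            loc <- ""
            if (!is.null(annotations)) {
                j <- match(tid, annotations$transcript_id)
                if (!is.na(j)) loc <- annotations$localization[j]
            }
            genes[[length(genes) + 1L]] <-
                new("PRFGene", transcriptId = tid, referenceId = rid,
                    events = evd, localization = loc, truncated = truncated)
        }
    }
    genes
}

#' @rdname PRFGene-class
#' @export
setMethod("prfEvents", "PRFGene", function(x) x@events)

#' @rdname PRFGene-class
#' @export
setMethod("nEvents", "PRFGene", function(x) nrow(x@events))

setMethod("show", "PRFGene", function(object) {
    cat("PRFGene:", object@transcriptId, "->", object@referenceId, "\n")
    cat("  events:", nEvents(object),
        paste0("(", paste(paste0("+", object@events$model, "@",
                                 object@events$position),
                          collapse = ", "), ")"),
        if (object@truncated) "[truncated]" else "", "\n")
})

#' Tabulate detected PRF genes
#'
#' One row per gene in the style of a frameshift overview table: slippery
#' contexts and models are "/"-joined across events; positions (original
#' transcript coordinates) are carried so the table round-trips.
#'
#' @param genes list of [PRFGene-class].
#' @return data.frame with columns \code{transcript}, \code{protein},
#'   \code{slippery}, \code{model}, \code{n_events}, \code{positions},
#'   \code{localization}.
#' @export
prfReport <- function(genes) {
    if (length(genes) == 0L)
        return(data.frame(transcript = character(), protein = character(),
                          slippery = character(), model = character(),
                          n_events = integer(), positions = character(),
                          localization = character(),
                          stringsAsFactors = FALSE))
    do.call(rbind, lapply(genes, function(g) {
        ev <- g@events
        data.frame(transcript = g@transcriptId, protein = g@referenceId,
                   slippery = paste(ev$slippery, collapse = "/"),
                   model = paste(paste0("+", ev$model), collapse = "/"),
                   n_events = nrow(ev),
                   positions = paste(ev$position, collapse = "/"),
                   localization = g@localization,
                   stringsAsFactors = FALSE)
    }))
}

#' @rdname prfReport
#' @param report data.frame produced by \code{prfReport}.
#' @return for \code{parsePrfReport}: the list of [PRFGene-class] objects.
#' @export
parsePrfReport <- function(report) {
    lapply(seq_len(nrow(report)), function(i) {
        sl <- strsplit(report$slippery[i], "/", fixed = TRUE)[[1L]]
        mo <- as.integer(sub("^\\+", "",
                             strsplit(report$model[i], "/",
                                      fixed = TRUE)[[1L]]))
        po <- as.integer(strsplit(report$positions[i], "/",
                                  fixed = TRUE)[[1L]])
        new("PRFGene", transcriptId = report$transcript[i],
            referenceId = report$protein[i],
            events = data.frame(position = po,
                                stopCodon = substr(sl, 4L, 6L),
                                slippery = sl, model = mo,
                                excised = ifelse(mo == 1L, "T", "TA"),
                                stringsAsFactors = FALSE),
            localization = report$localization[i], truncated = FALSE)
    })
}
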
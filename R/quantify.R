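#' qPCR relative quantification by the 2^-ddCq method
#'
#' Computes, for one target gene, the relative expression fold change
#' between a target and a control sample, normalised to a reference
#' (housekeeping) gene: dCq = Cq(target gene) - Cq(reference gene),
#' ddCq = dCq(target sample) - dCq(control sample), fold change =
#' 2^-ddCq. Replicate Cq values are combined by arithmetic mean; any
#' replicate with Cq >= 30 is excluded as invalid before averaging. Per
#' sample, replicate-level dCq values (replicate Cq minus the sample's mean
#' reference Cq) feed a Welch two-sample t-test and the ddCq standard
#' error.
#'
#' @param cq data.frame with columns \code{sample}, \code{gene}, \code{cq}
#'   (one row per replicate well).
#' @param gene target gene id.
#' @param reference reference (housekeeping) gene id.
#' @param targetSample,controlSample sample ids.
#' @param maxCq validity cutoff; replicates at or above it are dropped.
#' @return one-row data.frame: \code{gene}, \code{dcq_target},
#'   \code{dcq_control}, \code{ddcq}, \code{fc}, \code{log2fc}, \code{sem},
#'   \code{p}, \code{n_excluded}.
#' @export
foldChange <- function(cq, gene, reference, targetSample, controlSample,
                       maxCq = 30) {
    stopifnot(all(c("sample", "gene", "cq") %in% names(cq)))
    valid <- cq$cq < maxCq
    nExcluded <- sum(!valid)
    if (nExcluded)
        message(nExcluded, " replicate(s) excluded (Cq >= ", maxCq, ")")
    cq <- cq[valid, , drop = FALSE]
    pick <- function(s, g) cq$cq[cq$sample == s & cq$gene == g]
    tt <- pick(targetSample, gene); tr <- pick(targetSample, reference)
    ct <- pick(controlSample, gene); cr <- pick(controlSample, reference)
    if (!length(tt) || !length(tr) || !length(ct) || !length(cr)) {
        warning("gene '", gene, "' skipped: no valid replicates in some ",
                "sample/gene cell")
        return(NULL)
    }
    dcqT <- mean(tt) - mean(tr)
    dcqC <- mean(ct) - mean(cr)
    ddcq <- dcqT - dcqC
    # replicate-level dCq against the sample's mean reference Cq
    repT <- tt - mean(tr)
    repC <- ct - mean(cr)
    sem <- if (length(repT) >= 2L && length(repC) >= 2L)
        sqrt(stats::var(repT) / length(repT) +
             stats::var(repC) / length(repC)) else NA_real_
    p <- if (length(repT) >= 2L && length(repC) >= 2L)
        welchP(repT, repC) else NA_real_
    data.frame(gene = gene, dcq_target = dcqT, dcq_control = dcqC,
               ddcq = ddcq, fc = 2^(-ddcq), log2fc = -ddcq,
               sem = sem, p = p, n_excluded = nExcluded,
               stringsAsFactors = FALSE)
}

#' @rdname foldChange
#' @param genes target genes to quantify (default: all non-reference genes
#'   in the table).
#' @return for \code{foldChangeTable}: a data.frame with one row per gene.
#' @export
foldChangeTable <- function(cq, reference, targetSample, controlSample,
                            genes = setdiff(unique(cq$gene), reference),
                            maxCq = 30) {
    rows <- lapply(genes, function(g)
        foldChange(cq, g, reference, targetSample, controlSample, maxCq))
    do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

welchP <- function(a, b) {
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
        return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(a, b, var.equal = FALSE)$p.value
}

#' Two-group significance (Welch t-test)
#'
#' @param groupA,groupB numeric vectors (each of length >= 2).
#' @param alpha significance level (default 0.01).
#' @return list with \code{p} and logical \code{significant}.
#' @export
significanceTest <- function(groupA, groupB, alpha = 0.01) {
    if (length(groupA) < 2L || length(groupB) < 2L)
        stop("need at least 2 observations per group")
    p <- welchP(groupA, groupB)
    list(p = p, significant = p < alpha)
}

#' Swimming-track kinematics
#'
#' Metrics over a timestamped centroid track (t in seconds, x/y in
#' micrometres, nominally sampled every 0.3 s): \code{trackSpeed} computes
#' consecutive-frame displacement speeds (optionally after a centred
#' moving-average smoothing of the coordinates), \code{trackStraightness}
#' the ratio of net displacement to path length, and \code{circleFit} an
#' algebraic least-squares circle (Kasa fit).
#'
#' @param track data.frame with columns \code{t}, \code{x}, \code{y};
#'   \code{t} strictly increasing.
#' @param smooth odd moving-average window in frames (1 = no smoothing).
#' @return \code{trackSpeed}: list with \code{mean_speed} (um/s) and
#'   \code{speeds} (per step). \code{trackStraightness}: scalar in [0, 1],
#'   NA for a stationary track. \code{circleFit}: list with \code{xc},
#'   \code{yc}, \code{radius} (um; Inf for degenerate collinear input) and
#'   \code{rmse} of the radial residuals.
#' @export
trackSpeed <- function(track, smooth = 1L) {
    checkTrack(track, 2L)
    x <- track$x; y <- track$y
    if (smooth > 1L) {
        k <- rep(1 / smooth, smooth)
        pad <- (smooth - 1L) %/% 2L
        x <- stats::filter(c(rep(x[1L], pad), x, rep(x[length(x)], pad)), k)
        x <- as.numeric(x[!is.na(x)])
        y <- stats::filter(c(rep(y[1L], pad), y, rep(y[length(y)], pad)), k)
        y <- as.numeric(y[!is.na(y)])
    }
    step <- sqrt(diff(x)^2 + diff(y)^2)
    speeds <- step / diff(track$t)
    list(mean_speed = mean(speeds), speeds = speeds)
}

#' @rdname trackSpeed
#' @export
trackStraightness <- function(track) {
    checkTrack(track, 2L)
    path <- sum(sqrt(diff(track$x)^2 + diff(track$y)^2))
    if (path == 0) return(NA_real_)
    net <- sqrt((track$x[nrow(track)] - track$x[1L])^2 +
                (track$y[nrow(track)] - track$y[1L])^2)
    net / path
}

#' @rdname trackSpeed
#' @export
circleFit <- function(track) {
    checkTrack(track, 3L)
    x <- track$x; y <- track$y
    A <- cbind(2 * x, 2 * y, 1)
    b <- x^2 + y^2
    qrA <- qr(A)
    if (qrA$rank < 3L)
        return(list(xc = NA_real_, yc = NA_real_, radius = Inf,
                    rmse = NA_real_))
    sol <- qr.coef(qrA, b)
    r2 <- sol[3L] + sol[1L]^2 + sol[2L]^2
    if (!is.finite(r2) || r2 <= 0)
        return(list(xc = NA_real_, yc = NA_real_, radius = Inf,
                    rmse = NA_real_))
    r <- sqrt(r2)
    resid <- sqrt((x - sol[1L])^2 + (y - sol[2L])^2) - r
    list(xc = unname(sol[1L]), yc = unname(sol[2L]), radius = unname(r),
         rmse = sqrt(mean(resid^2)))
}

checkTrack <- function(track, minPoints) {
    stopifnot(all(c("t", "x", "y") %in% names(track)))
    if (nrow(track) < minPoints)
        stop("track needs at least ", minPoints, " points")
    if (is.unsorted(track$t, strictly = TRUE))
        stop("track times must be strictly increasing")
    invisible(track)
}
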
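#' @import igraph
#' @importFrom utils head modifyList
#' @importFrom stats setNames runif rnorm
NULL

# evaluate expr under a fixed RNG seed without disturbing the caller's
# random-number stream
withSeed <- function(seed, expr) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
            else if (exists(".Random.seed", envir = globalenv(),
                            inherits = FALSE))
                rm(".Random.seed", envir = globalenv()))
    set.seed(seed)
    eval.parent(substitute(expr))
}

#' Twelve topological centrality scores
#'
#' Computes, for every node of a simple undirected network, the twelve
#' topological scores popularised by the CytoHubba Cytoscape plugin:
#' Degree, MNC (maximum neighborhood component size), DMNC (density of the
#' maximum neighborhood component, edges / size^epsilon), MCC (maximal
#' clique centrality: sum of (|C|-1)! over maximal cliques containing the
#' node), EPC (edge percolation component: mean size of the node's component
#' when every edge survives independently with probability 0.5, Monte Carlo
#' over \code{epcReps} replicates), BottleNeck (see below),
#' EcCentricity (component diameter minus the node's
#' eccentricity, so larger is more central), Closeness (harmonic: sum of
#' reciprocal distances), Radiality (sum of (diameter + 1 - d) / (n - 1)
#' within the component), Betweenness (pair-fraction of shortest paths
#' through the node), Stress (count of shortest paths through the node) and
#' ClusteringCoefficient. Distance-based scores are computed per connected
#' component. BottleNeck counts, per source node s, whether the node is an
#' unavoidable waypoint -- on every shortest path from s -- for more than a
#' quarter of s's component, a formulation that is invariant under node
#' relabeling.
#'
#' @param g a simple undirected \code{igraph} graph (named vertices).
#' @param config list: \code{dmncEpsilon} (default 1.7), \code{epcReps}
#'   (Monte Carlo replicates, default 1000), \code{seed} (EPC seed).
#' @return a [CentralityTable-class].
#' @export
centralities <- function(g, config = list()) {
    cfg <- utils::modifyList(list(dmncEpsilon = 1.7, epcReps = 1000L,
                                  seed = 1L), config)
    if (vcount(g) == 0L) stop("empty graph")
    if (is_directed(g)) stop("graph must be undirected")
    if (!is_simple(g)) stop("graph must be simple (no loops/multi-edges)")
    if (is.null(V(g)$name)) V(g)$name <- paste0("n", seq_len(vcount(g)))
    nodes <- V(g)$name
    n <- vcount(g)
    D <- distances(g, algorithm = "unweighted")
    comp <- components(g)
    sigma <- shortestPathCounts(g, D)
    bs <- betweennessStress(D, sigma)

    deg <- degree(g)
    cc <- transitivity(g, type = "local", isolates = "zero")
    cc[!is.finite(cc)] <- 0

    ecc <- rep(0, n); rad <- rep(0, n); eccScore <- rep(0, n)
    for (ci in seq_len(comp$no)) {
        idx <- which(comp$membership == ci)
        if (length(idx) == 1L) next
        Dc <- D[idx, idx, drop = FALSE]
        e <- apply(Dc, 1L, max)
        diam <- max(e)
        eccScore[idx] <- diam - e
        rad[idx] <- rowSums(diam + 1 - Dc) / (length(idx) - 1)
        # the d(v,v)=0 diagonal contributes (diam+1) per row; drop it
        rad[idx] <- rad[idx] - (diam + 1) / (length(idx) - 1)
    }
    Hinv <- 1 / D
    diag(Hinv) <- 0
    Hinv[!is.finite(Hinv)] <- 0
    closeness <- rowSums(Hinv)

    mcc <- rep(0, n)
    if (ecount(g) > 0L) {
        for (cl in max_cliques(g, min = 2L)) {
            w <- factorial(length(cl) - 1L)
            mcc[as.integer(cl)] <- mcc[as.integer(cl)] + w
        }
    }

    mnc <- rep(0, n); dmnc <- rep(0, n)
    for (v in seq_len(n)) {
        nb <- as.integer(neighbors(g, v))
        if (length(nb) == 0L) next
        sub <- induced_subgraph(g, nb)
        sc <- components(sub)
        sizes <- sc$csize
        mx <- max(sizes)
        mnc[v] <- mx
        if (mx > 1L) {
            # among largest components, take the densest
            cand <- which(sizes == mx)
            edgesIn <- vapply(cand, function(k)
                gsize(induced_subgraph(sub, which(sc$membership == k))), 1)
            dmnc[v] <- max(edgesIn) / mx^cfg$dmncEpsilon
        }
    }

    bn <- bottleneck(D, sigma, comp)
    epc <- withSeed(cfg$seed, epcScore(g, cfg$epcReps))

    scores <- cbind(Degree = deg, MNC = mnc, DMNC = dmnc, MCC = mcc,
                    EPC = epc, BottleNeck = bn, EcCentricity = eccScore,
                    Closeness = closeness, Radiality = rad,
                    Betweenness = bs$betweenness, Stress = bs$stress,
                    ClusteringCoefficient = cc)
    rownames(scores) <- nodes
    ranks <- apply(-scores, 2L, rank, ties.method = "min")
    storage.mode(ranks) <- "integer"
    rownames(ranks) <- nodes
    new("CentralityTable", scores = scores, ranks = ranks, config = cfg)
}

# sigma[s, v]: number of distinct shortest s->v paths (BFS level sums)
shortestPathCounts <- function(g, D) {
    n <- nrow(D)
    M <- as.matrix(as_adjacency_matrix(g, type = "both"))
    sigma <- matrix(0, n, n, dimnames = dimnames(D))
    for (s in seq_len(n)) {
        d <- D[s, ]
        sig <- numeric(n)
        sig[s] <- 1
        lev <- 1
        maxd <- max(d[is.finite(d)])
        while (lev <= maxd) {
            prev <- sig * (d == lev - 1)
            atLev <- d == lev
            if (!any(atLev)) break
            sig[atLev] <- (M %*% prev)[atLev]
            lev <- lev + 1
        }
        sigma[s, ] <- sig
    }
    sigma
}

betweennessStress <- function(D, sigma) {
    n <- nrow(D)
    btw <- numeric(n)
    str <- numeric(n)
    ut <- upper.tri(D)
    for (v in seq_len(n)) {
        on <- outer(D[, v], D[v, ], "+") == D & is.finite(D)
        on[v, ] <- FALSE
        on[, v] <- FALSE
        P <- outer(sigma[, v], sigma[v, ])
        sel <- on & ut
        str[v] <- sum(P[sel])
        btw[v] <- sum((P / pmax(sigma, 1))[sel])
    }
    list(betweenness = btw, stress = str)
}

# BottleNeck: for each source s, a node v != s scores +1 when it is an
# unavoidable waypoint (lies on every shortest path from s, including the
# trivial path to itself) for more than a quarter of s's component. This
# dominator form is invariant under node relabeling, unlike tie-broken
# BFS trees.
bottleneck <- function(D, sigma, comp) {
    n <- nrow(D)
    bn <- numeric(n)
    for (s in seq_len(n)) {
        idx <- which(comp$membership == comp$membership[s])
        csize <- length(idx)
        if (csize == 1L) next
        Dst <- matrix(D[s, ], n, n, byrow = TRUE)      # [v, t] = d(s, t)
        distOK <- (D[s, ] + D) == Dst                  # d(s,v)+d(v,t)=d(s,t)
        sigEq <- (sigma[s, ] * sigma) == matrix(sigma[s, ], n, n,
                                                byrow = TRUE)
        ok <- distOK & sigEq
        ok[, s] <- FALSE
        ok[!is.finite(Dst)] <- FALSE
        cnt <- rowSums(ok)
        scored <- idx[idx != s & cnt[idx] > csize / 4]
        bn[scored] <- bn[scored] + 1
    }
    bn
}

epcScore <- function(g, reps) {
    n <- vcount(g)
    m <- ecount(g)
    acc <- numeric(n)
    for (r in seq_len(reps)) {
        keep <- which(stats::runif(m) < 0.5)
        sg <- subgraph_from_edges(g, keep, delete.vertices = FALSE)
        cs <- components(sg)
        acc <- acc + cs$csize[cs$membership]
    }
    acc / reps
}

#' @rdname CentralityTable-class
#' @export
setMethod("centralityScores", "CentralityTable", function(x) x@scores)

#' @rdname CentralityTable-class
#' @export
setMethod("centralityRanks", "CentralityTable", function(x) x@ranks)

setMethod("show", "CentralityTable", function(object) {
    cat("CentralityTable:", nrow(object@scores), "nodes x",
        ncol(object@scores), "methods (EPC reps =", object@config$epcReps,
        ", seed =", object@config$seed, ")\n")
})

#' Consensus hub genes across centrality methods
#'
#' A node is a hub when it ranks within the top \code{k} under at least
#' \code{m} of the twelve centrality methods. Rank ties share the minimum
#' rank, so the top-k boundary is inclusive of ties.
#'
#' @param table a [CentralityTable-class].
#' @param k top-rank depth (clamped to the node count).
#' @param m minimum number of supporting methods.
#' @return a [HubSet-class].
#' @export
consensusHubs <- function(table, k = 50L, m = 6L) {
    ranks <- table@ranks
    k <- min(as.integer(k), nrow(ranks))
    support <- rowSums(ranks <= k)
    storage.mode(support) <- "integer"
    new("HubSet", hubs = rownames(ranks)[support >= m],
        support = support, k = k, m = as.integer(m))
}

#' @rdname HubSet-class
#' @export
setMethod("hubGenes", "HubSet", function(x) x@hubs)

#' @rdname HubSet-class
#' @export
setMethod("hubSupport", "HubSet", function(x) x@support)

setMethod("show", "HubSet", function(object) {
    cat("HubSet:", length(object@hubs), "hubs (top", object@k,
        "in >=", object@m, "of 12 methods)\n")
    if (length(object@hubs))
        cat(" ", paste(object@hubs, collapse = ", "), "\n")
})
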
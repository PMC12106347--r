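# Independent brute-force oracles used across the suite. These share no
# code with the package implementation: alignment scores come from a plain
# Gotoh dynamic program, path statistics from exhaustive simple-path
# enumeration, cliques from subset enumeration, and EPC from exact
# enumeration of all edge-survival patterns.

# --- Smith-Waterman (affine gaps, Gotoh) ------------------------------
# gap of length k costs gapOpen + k * gapExt (matching pairwiseAlignment)
swOracleScore <- function(a, b, mat, gapOpen = 11, gapExt = 1) {
    a <- strsplit(a, "")[[1]]
    b <- strsplit(b, "")[[1]]
    n <- length(a); m <- length(b)
    H <- matrix(0, n + 1, m + 1)
    E <- matrix(-Inf, n + 1, m + 1)   # gap in a (move along b)
    F <- matrix(-Inf, n + 1, m + 1)   # gap in b
    best <- 0
    for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
        E[i, j] <- max(H[i, j - 1] - gapOpen - gapExt, E[i, j - 1] - gapExt)
        F[i, j] <- max(H[i - 1, j] - gapOpen - gapExt, F[i - 1, j] - gapExt)
        H[i, j] <- max(0, H[i - 1, j - 1] + mat[a[i - 1], b[j - 1]],
                       E[i, j], F[i, j])
        best <- max(best, H[i, j])
    }
    best
}

# --- graph oracles on an adjacency matrix -----------------------------
floydDistances <- function(A) {
    n <- nrow(A)
    D <- ifelse(A > 0, 1, Inf)
    diag(D) <- 0
    for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
        if (D[i, k] + D[k, j] < D[i, j]) D[i, j] <- D[i, k] + D[k, j]
    D
}

# all simple paths s -> t of exactly the geodesic length
enumGeodesics <- function(A, s, t, D) {
    if (!is.finite(D[s, t]) || s == t) return(list())
    res <- list()
    walk <- function(path) {
        v <- path[length(path)]
        if (v == t) {
            if (length(path) - 1 == D[s, t])
                res[[length(res) + 1]] <<- path
            return()
        }
        if (length(path) - 1 >= D[s, t]) return()
        for (w in which(A[v, ] > 0))
            if (!(w %in% path)) walk(c(path, w))
    }
    walk(s)
    res
}

# the twelve scores by brute force; epcReps = 0 computes EPC exactly by
# enumerating every edge-survival pattern (requires few edges)
bruteCentralities <- function(A, dmncEps = 1.7, bnFrac = 4) {
    n <- nrow(A)
    D <- floydDistances(A)
    deg <- rowSums(A > 0)
    btw <- numeric(n); str <- numeric(n)
    for (s in 1:(n - 1)) for (t in (s + 1):n) {
        paths <- enumGeodesics(A, s, t, D)
        if (!length(paths)) next
        sigma <- length(paths)
        for (v in seq_len(n)) {
            if (v == s || v == t) next
            thru <- sum(vapply(paths, function(p)
                v %in% p[-c(1, length(p))], TRUE))
            btw[v] <- btw[v] + thru / sigma
            str[v] <- str[v] + thru
        }
    }
    Hd <- 1 / D; diag(Hd) <- 0; Hd[!is.finite(Hd)] <- 0
    clo <- rowSums(Hd)
    membership <- componentsOracle(A)
    ecc <- numeric(n); rad <- numeric(n)
    for (ci in unique(membership)) {
        idx <- which(membership == ci)
        if (length(idx) == 1) next
        Dc <- D[idx, idx, drop = FALSE]
        e <- apply(Dc, 1, max)
        diam <- max(e)
        ecc[idx] <- diam - e
        rad[idx] <- (rowSums(diam + 1 - Dc) - (diam + 1)) /
            (length(idx) - 1)
    }
    # maximal cliques by subset enumeration
    mcc <- numeric(n)
    subsets <- lapply(seq_len(2^n - 1), function(mask)
        which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0))
    isClique <- vapply(subsets, function(ss) {
        if (length(ss) < 2) return(FALSE)
        all(A[ss, ss][upper.tri(diag(length(ss)))] > 0)
    }, TRUE)
    for (i in which(isClique)) {
        ss <- subsets[[i]]
        maximal <- !any(vapply(setdiff(seq_len(n), ss), function(w)
            all(A[w, ss] > 0), TRUE))
        if (maximal) mcc[ss] <- mcc[ss] + factorial(length(ss) - 1)
    }
    # MNC / DMNC from neighbor-induced subgraphs
    mnc <- numeric(n); dmnc <- numeric(n)
    for (v in seq_len(n)) {
        nb <- which(A[v, ] > 0)
        if (!length(nb)) next
        sub <- A[nb, nb, drop = FALSE]
        mem <- componentsOracle(sub)
        sizes <- table(mem)
        mx <- max(sizes)
        mnc[v] <- mx
        if (mx > 1) {
            cand <- names(sizes)[sizes == mx]
            edgesIn <- vapply(cand, function(k) {
                ii <- which(mem == as.integer(k))
                sum(sub[ii, ii, drop = FALSE]) / 2
            }, 1)
            dmnc[v] <- max(edgesIn) / mx^dmncEps
        }
    }
    # BottleNeck: v scores per source s when it sits on every geodesic
    # from s to more than comp/4 targets (checked by path enumeration)
    bn <- numeric(n)
    for (s in seq_len(n)) {
        idx <- which(membership == membership[s])
        if (length(idx) == 1) next
        for (v in idx) {
            if (v == s) next
            cnt <- 0
            for (t in idx) {
                if (t == s) next
                if (t == v) { cnt <- cnt + 1; next }
                paths <- enumGeodesics(A, s, t, D)
                if (length(paths) &&
                    all(vapply(paths, function(p) v %in% p, TRUE)))
                    cnt <- cnt + 1
            }
            if (cnt > length(idx) / bnFrac) bn[v] <- bn[v] + 1
        }
    }
    cc <- vapply(seq_len(n), function(v) {
        nb <- which(A[v, ] > 0)
        if (length(nb) < 2) return(0)
        tri <- sum(A[nb, nb]) / 2
        2 * tri / (length(nb) * (length(nb) - 1))
    }, 1)
    list(Degree = deg, MNC = mnc, DMNC = dmnc, MCC = mcc,
         BottleNeck = bn, EcCentricity = ecc, Closeness = clo,
         Radiality = rad, Betweenness = btw, Stress = str,
         ClusteringCoefficient = cc)
}

componentsOracle <- function(A) {
    n <- nrow(A)
    mem <- rep(0L, n)
    cur <- 0L
    for (s in seq_len(n)) {
        if (mem[s]) next
        cur <- cur + 1L
        stack <- s
        while (length(stack)) {
            v <- stack[1]; stack <- stack[-1]
            if (mem[v]) next
            mem[v] <- cur
            stack <- c(stack, which(A[v, ] > 0 & mem == 0L))
        }
    }
    mem
}

# exact EPC: expected component size of each node when every edge
# survives independently with p = 0.5 (enumerates all 2^|E| patterns)
epcExact <- function(A) {
    n <- nrow(A)
    el <- which(upper.tri(A) & A > 0, arr.ind = TRUE)
    m <- nrow(el)
    stopifnot(m <= 14)
    bits <- 2^(seq_len(m) - 1)
    acc <- numeric(n)
    for (mask in 0:(2^m - 1)) {
        parent <- seq_len(n)
        find <- function(x) {
            while (parent[x] != x) x <- parent[x]
            x
        }
        for (e in which(bitwAnd(mask, bits) > 0)) {
            ra <- find(el[e, 1]); rb <- find(el[e, 2])
            if (ra != rb) parent[rb] <- ra
        }
        roots <- vapply(seq_len(n), find, 1L)
        acc <- acc + tabulate(roots, n)[roots]
    }
    acc / 2^m
}

# random simple graph as adjacency matrix + matching named igraph
randomGraphPair <- function(n, p) {
    A <- matrix(0, n, n)
    for (i in 1:(n - 1)) for (j in (i + 1):n)
        if (stats::runif(1) < p) A[i, j] <- A[j, i] <- 1
    nodes <- paste0("v", seq_len(n))
    dimnames(A) <- list(nodes, nodes)
    g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
    list(A = A, g = g)
}
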
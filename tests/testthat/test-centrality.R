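namedGraph <- function(...) {
    g <- igraph::make_graph(..., directed = FALSE)
    igraph::V(g)$name <- letters[seq_len(igraph::vcount(g))]
    g
}

quickCfg <- list(epcReps = 50L, seed = 1L)

test_that("textbook values hold on elementary graphs", {
    star <- igraph::make_star(5L, mode = "undirected")
    igraph::V(star)$name <- letters[1:5]
    s <- centralityScores(centralities(star, quickCfg))
    expect_identical(unname(s["a", "Degree"]), 4)
    expect_identical(unname(s["a", "MNC"]), 1)   # leaves are disconnected

    tri <- igraph::make_full_graph(3L)
    igraph::V(tri)$name <- letters[1:3]
    sTri <- centralityScores(centralities(tri, quickCfg))
    expect_identical(unname(sTri[, "MCC"]), rep(2, 3L))  # (3-1)! = 2
    expect_identical(unname(sTri[, "ClusteringCoefficient"]), rep(1, 3L))

    path <- namedGraph(edges = c("a", "b", "b", "c"))
    sP <- centralityScores(centralities(path, quickCfg))
    expect_identical(unname(sP["b", "Betweenness"]), 1)
    expect_identical(unname(sP["b", "Stress"]), 1)
    expect_identical(unname(sP["a", "Betweenness"]), 0)
    expect_identical(unname(sP["b", "EcCentricity"]), 1)  # diam 2, ecc 1
})

test_that("deterministic scores match igraph on random graphs", {
    set.seed(91)
    for (i in 1:15) {
        n <- sample(10:30, 1L)
        gp <- randomGraphPair(n, stats::runif(1, 0.1, 0.3))
        s <- centralityScores(centralities(gp$g, quickCfg))
        expect_equal(unname(s[, "Degree"]),
                     unname(igraph::degree(gp$g)))
        expect_equal(unname(s[, "Betweenness"]),
                     unname(igraph::betweenness(gp$g)))
        expect_equal(unname(s[, "Closeness"]),
                     unname(igraph::harmonic_centrality(gp$g)))
        cc <- unname(igraph::transitivity(gp$g, type = "local"))
        cc[!is.finite(cc)] <- 0
        expect_equal(unname(s[, "ClusteringCoefficient"]), cc)
        # stress against all-geodesic enumeration via igraph
        stress <- numeric(n)
        for (st in seq_len(n)) {
            asp <- igraph::all_shortest_paths(gp$g, st)$vpaths
            for (p in asp) {
                p <- as.integer(p)
                if (length(p) > 2L && p[1L] < p[length(p)]) {
                    mid <- p[-c(1L, length(p))]
                    stress[mid] <- stress[mid] + 1
                }
            }
        }
        expect_equal(unname(s[, "Stress"]), stress)
    }
})

test_that("all twelve scores are invariant under node relabeling", {
    set.seed(92)
    gp <- randomGraphPair(12L, 0.25)
    tab1 <- centralityScores(centralities(gp$g, list(epcReps = 400L,
                                                     seed = 5L)))
    perm <- sample(12L)
    g2 <- igraph::permute(gp$g, perm)
    tab2 <- centralityScores(centralities(g2, list(epcReps = 400L,
                                                   seed = 5L)))
    tab2 <- tab2[rownames(tab1), ]
    det <- setdiff(colnames(tab1), "EPC")
    expect_equal(tab1[, det], tab2[, det])
    # EPC is Monte Carlo: agreement within sampling error
    expect_equal(tab1[, "EPC"], tab2[, "EPC"], tolerance = 0.2)
})

test_that("EPC is seed-reproducible and converges as reps^(-1/2)", {
    set.seed(93)
    gp <- randomGraphPair(15L, 0.2)
    a <- centralityScores(centralities(gp$g, list(epcReps = 200L,
                                                  seed = 42L)))[, "EPC"]
    b <- centralityScores(centralities(gp$g, list(epcReps = 200L,
                                                  seed = 42L)))[, "EPC"]
    expect_identical(a, b)
    # error vs exact enumeration shrinks roughly like reps^(-1/2)
    gp2 <- randomGraphPair(6L, 0.3)
    exact <- epcExact(gp2$A)
    errFor <- function(reps, seed) {
        e <- centralityScores(centralities(
            gp2$g, list(epcReps = reps, seed = seed)))[, "EPC"]
        sqrt(mean((e - exact)^2))
    }
    coarse <- mean(vapply(1:5, function(s) errFor(40L, s), 1))
    fine <- mean(vapply(1:5, function(s) errFor(4000L, s), 1))
    expect_lt(fine, coarse / 3)   # expect ~10x at 100x the reps
})

test_that("disconnected graphs score per component; empty graphs error", {
    g <- namedGraph(edges = c("a", "b", "b", "c", "d", "e"))
    s <- centralityScores(centralities(g, quickCfg))
    expect_identical(unname(s["d", "Closeness"]), 1)
    expect_identical(unname(s["b", "EcCentricity"]), 1)
    expect_identical(unname(s["d", "EcCentricity"]), 0)
    expect_true(all(is.finite(s)))
    expect_error(centralities(igraph::make_empty_graph(0,
                                                       directed = FALSE)),
                 "empty")
})
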
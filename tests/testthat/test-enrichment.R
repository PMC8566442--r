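test_that("hypergeometric upper tails match exhaustive enumeration on small universes", {
    for (N in 5:12) for (K in 1:(N - 1)) for (n in 1:(N - 1)) {
        for (k in 0:min(K, n)) {
            expect_equal(hypergeomUpperTail(k, K, n, N),
                         oracleHypergeom(k, K, n, N),
                         tolerance = 1e-12)
        }
    }
    # worked value: P[X >= 3], K = 4, n = 5, N = 10 is 66/252
    expect_equal(hypergeomUpperTail(3, 4, 5, 10), 66 / 252,
                 tolerance = 1e-15)
    expect_error(hypergeomUpperTail(5, 4, 5, 10), "argument error")
    expect_error(hypergeomUpperTail(1, 11, 5, 10), "argument error")
})

test_that("FDR adjustment reproduces the step-up definition", {
    set.seed(51)
    p <- runif(40)^2
    expect_equal(fdrAdjust(p), oracleBH(p), tolerance = 1e-12)
    expect_true(all(fdrAdjust(p) >= p))
    expect_error(fdrAdjust(c(0.5, 0)), "argument error")
    expect_error(fdrAdjust(c(0.5, 1.2)), "argument error")
})

test_that("the family-wise fixed cutoff is the largest rejected raw p-value", {
    p <- c(1e-6, 2e-5, 3e-4, 0.02, 0.3, 0.7)
    cut <- fdrCutoff(p, alpha = 0.05)
    q <- oracleBH(p)
    expect_equal(cut, max(p[q <= 0.05]))
    expect_identical(fdrCutoff(c(0.5, 0.8), alpha = 0.01), 0)
})

test_that("a planted enriched term gets the smallest p-value and is flagged", {
    planted <- list(big_term = sprintf("gene%03d", 1:30))
    u <- generateAnnotationUniverse(500, 25, planted = planted, seed = 6)
    query <- c(sprintf("gene%03d", 1:15), sprintf("gene%03d", 301:305))
    res <- enrich(query, u)
    expect_identical(res$term[1], "big_term")
    expect_equal(res$p[1], hypergeomUpperTail(15, 30, 20, 500),
                 tolerance = 1e-12)
    expect_true(res$significant[1])
    expect_true(all(diff(res$p) >= 0))
    expect_identical(res$q, unname(fdrAdjust(res$p)))
})

test_that("queries outside the universe are dropped with a warning", {
    u <- generateAnnotationUniverse(50, 5, seed = 7)
    expect_warning(res <- enrich(c(u@universe[1:5], "alien_gene"), u),
                   "outside the universe")
    expect_true(all(res$n == 5))
    expect_identical(nrow(enrich(character(0), u)), 0L)
})

test_that("null queries are calibrated: false-positive rate stays near nominal", {
    u <- generateAnnotationUniverse(500, 30, seed = 11)
    set.seed(12)
    frac <- replicate(300, {
        q <- sample(u@universe, 20)
        mean(enrich(q, u, allTerms = TRUE)$p < 0.05)
    })
    f <- mean(frac)
    expect_lte(f, 0.05 + 3 * sqrt(f * (1 - f) / 300))
})

test_that("GMT round trips preserve terms and agree with a reference parser", {
    u <- generateAnnotationUniverse(80, 6, seed = 8)
    path <- tempfile(fileext = ".gmt")
    writeGMT(u, path)
    back <- readGMT(path, universe = u@universe)
    expect_identical(back@terms, u@terms)
    expect_identical(back@termNames, u@termNames)
    expect_identical(back@universe, u@universe)
    # cross-check the parser against fgsea's GMT reader
    ref <- fgsea::gmtPathways(path)
    expect_identical(ref[names(u@terms)], u@terms)
    # default universe is the union of annotated genes
    expect_identical(sort(readGMT(path)@universe),
                     sort(unique(unlist(u@terms))))
})
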
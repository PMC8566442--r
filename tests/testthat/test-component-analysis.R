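test_that("percentile thresholding matches sort-based counting", {
    set.seed(41)
    v <- rnorm(1500)
    tm <- thresholdMap(v)
    # oracle: count strictly outside the type-7 quantiles computed by hand
    s <- sort(v)
    q <- function(p) {
        h <- (length(s) - 1) * p
        lo <- floor(h)
        s[lo + 1] + (h - lo) * (s[lo + 2] - s[lo + 1])
    }
    expect_equal(tm@lowCut, q(0.01), tolerance = 1e-12)
    expect_equal(tm@highCut, q(0.99), tolerance = 1e-12)
    expect_identical(tm@negativeVoxels, which(v < tm@lowCut))
    expect_identical(tm@positiveVoxels, which(v > tm@highCut))
    # negative and positive sets are disjoint and hold ~1% each
    expect_length(intersect(tm@negativeVoxels, tm@positiveVoxels), 0)
    expect_lte(abs(length(tm@negativeVoxels) + length(tm@positiveVoxels) -
                   0.02 * 1500), 2)
})

test_that("constant maps threshold to empty sets with a warning", {
    expect_warning(tm <- thresholdMap(rep(1, 200)), "constant")
    expect_length(tm@negativeVoxels, 0)
    expect_length(tm@positiveVoxels, 0)
    expect_warning(thresholdMap(rnorm(50)), "fewer than 100")
})

test_that("components of interest require contribution from every modality", {
    fit <- fixtureUniqueFit()
    ds <- fixtureUniqueDataset()
    coi <- selectComponentsOfInterest(fit)
    # the component matching the planted modality-unique source is excluded
    sc <- matchedRecoveryScore(spatialMaps(fit), ds$truth@H)
    uniqueEst <- sc$matching$estimated[sc$matching$reference == 2]
    expect_false(uniqueEst %in% coi)
    expect_length(coi, 4L)
    # its relative contribution concentrates in the loaded modality
    rel <- explainedVariance(fit, relative = TRUE)
    expect_gt(rel[uniqueEst, 1], 0.99)
    # a floor of zero keeps every component
    expect_identical(selectComponentsOfInterest(fit, floor = 0), 1:5)
})

test_that("dominance labels reflect per-modality reconstruction energy", {
    fit <- fixtureFit()
    i <- 1L
    tm <- thresholdMap(spatialMaps(fit)[i, ], componentId = i)
    dom <- dominanceLabels(fit, i, tm)
    expect_identical(dom@voxels,
                     sort(c(tm@negativeVoxels, tm@positiveVoxels)))
    # oracle: energies from the factor matrices directly
    e1 <- sum(fit@X[[1]][, i]^2) * fit@W[[1]][i]^2
    e2 <- sum(fit@X[[2]][, i]^2) * fit@W[[2]][i]^2
    expected <- if (e1 > 2 * e2) "gene_dominated"
                else if (e2 > 2 * e1) "projection_dominated"
                else "shared"
    expect_true(all(dom@labels == expected))
    # labelling is invariant to jointly rescaling both modalities
    fit2 <- fit
    fit2@W <- lapply(fit@W, function(w) 3 * w)
    dom2 <- dominanceLabels(fit2, i, tm)
    expect_identical(dom@labels, dom2@labels)
})

test_that("cross-correlation tables match the direct Pearson formulas", {
    set.seed(43)
    A <- matrix(rnorm(3 * 200), 3)
    B <- matrix(rnorm(2 * 200), 2)
    ct <- crossCorrelate(A, B)
    for (i in 1:3) for (j in 1:2) {
        o <- oraclePearson(A[i, ], B[j, ])
        expect_equal(ct@rho[i, j], unname(o["rho"]), tolerance = 1e-12)
        expect_equal(ct@p[i, j], unname(o["p"]), tolerance = 1e-12)
    }
    expect_identical(ct@significant, !is.na(ct@p) & ct@p < 0.004)
    # a vector correlated with itself plus noise is flagged
    x <- rnorm(200)
    ct2 <- crossCorrelate(x, x + rnorm(200, sd = 0.1))
    expect_true(ct2@significant[1, 1])
    # zero-variance rows give missing entries, not errors
    ct3 <- crossCorrelate(rep(1, 50), rnorm(50))
    expect_true(is.na(ct3@rho[1, 1]))
    expect_false(ct3@significant[1, 1])
    expect_error(crossCorrelate(A, B[, 1:100]), "shape error")
})

test_that("region summaries count supra-threshold voxels per parcel", {
    ds <- fixtureDataset()
    fit <- fixtureFit()
    tm <- thresholdMap(spatialMaps(fit)[1, ], componentId = 1L)
    rs <- regionSummary(tm, ds$annotation, ds$mask)
    expect_true(all(rs$nSelected >= 1))
    expect_identical(sum(rs$nSelected),
                     length(tm@negativeVoxels) + length(tm@positiveVoxels))
    # oracle recount for the first listed region
    region <- ds$annotation@regionId[ds$mask@coords]
    sel <- c(tm@negativeVoxels, tm@positiveVoxels)
    r1 <- rs$region[1]
    expect_identical(rs$nSelected[1], sum(region[sel] == r1))
    expect_identical(rs$regionVoxels[1], sum(region == r1))
    expect_equal(rs$pctOfRegion[1],
                 100 * rs$nSelected[1] / rs$regionVoxels[1])
    # empty selections give an empty frame
    emptyTm <- suppressWarnings(thresholdMap(rep(0, nVoxels(ds$mask))))
    expect_identical(nrow(regionSummary(emptyTm, ds$annotation, ds$mask)),
                     0L)
})

test_that("recovery matching is invariant to permutation and sign flips", {
    set.seed(44)
    ref <- matrix(rnorm(4 * 300), 4)
    est <- ref[c(3, 1, 4, 2), ] * c(-1, 1, -1, 1)
    sc <- matchedRecoveryScore(est, ref)
    expect_equal(sc$meanAbsRho, 1, tolerance = 1e-12)
    expect_identical(sc$matching$estimated[sc$matching$reference == 3], 1L)
    # rectangular matching: more estimates than references is allowed
    sc2 <- matchedRecoveryScore(rbind(est, rnorm(300)), ref)
    expect_identical(nrow(sc2$matching), 4L)
    expect_equal(sc2$meanAbsRho, 1, tolerance = 1e-12)
    expect_error(matchedRecoveryScore(est[, 1:10], ref), "shape error")
})
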
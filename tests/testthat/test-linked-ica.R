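test_that("single-modality noiseless rank-1 data are recovered exactly", {
    set.seed(8)
    N <- 400
    h <- numeric(N)
    h[sample(N, 40)] <- abs(rnorm(40))
    h <- h / sqrt(sum(h^2))
    x <- rnorm(30)
    Y <- x %o% h
    fit <- fitLinkedICA(list(Y), linkedICAConfig(L = 1, seed = 1))
    expect_true(fit@converged)
    expect_gt(abs(cor(spatialMaps(fit)[1, ], h)), 1 - 1e-6)
    rec <- reconstruct(fit, 1, originalUnits = TRUE)
    expect_lt(mse(Y, rec), 1e-10)
})

test_that("fitted spatial maps have unit norm and positive skewness", {
    fit <- fixtureFit()
    H <- spatialMaps(fit)
    expect_equal(unname(sqrt(rowSums(H^2))), rep(1, 5), tolerance = 1e-9)
    Hc <- H - rowMeans(H)
    skew <- rowMeans(Hc^3) / rowMeans(Hc^2)^1.5
    expect_true(all(skew > 0))
})

test_that("modality weights are non-negative and components are sorted by explained variance", {
    fit <- fixtureFit()
    expect_true(all(modalityWeights(fit)[[1]] >= 0))
    expect_true(all(modalityWeights(fit)[[2]] >= 0))
    ev <- rowSums(explainedVariance(fit))
    expect_true(all(diff(ev) <= 1e-12))
    rel <- explainedVariance(fit, relative = TRUE)
    expect_equal(unname(rowSums(rel)), rep(1, 5), tolerance = 1e-9)
})

test_that("the full reconstruction approaches the data at high SNR", {
    fit <- fixtureFit()
    mods <- fixtureModalities()
    for (k in 1:2) {
        Y <- matrixValues(mods[[k]])
        Yz <- (Y - rowMeans(Y)) / apply(Y, 1, sd)
        r2 <- rSquared(Yz, reconstruct(fit, k))
        expect_gt(r2, 0.85)   # SNR 10 => about 10/11 of variance is signal
    }
    # component subsetting: empty set gives the zero reconstruction
    expect_identical(unname(reconstruct(fit, 1, components = integer(0))),
                     matrix(0, 60, ncol(fit@H)))
    expect_error(reconstruct(fit, 1, components = 99), "index error")
    expect_error(reconstruct(fit, 3), "index error")
})

test_that("original-units reconstruction undoes the row standardization", {
    fit <- fixtureFit()
    mods <- fixtureModalities()
    Y <- matrixValues(mods[[1]])
    recZ <- reconstruct(fit, 1)
    recO <- reconstruct(fit, 1, originalUnits = TRUE)
    expect_equal(unname(recO),
                 unname(recZ * fit@rowScale[[1]] + fit@rowCenter[[1]]),
                 tolerance = 1e-12)
    expect_gt(rSquared(Y, recO), 0.85)
})

test_that("random initialization still ascends and recovers most sources", {
    # the posterior is multi-modal, so a random start may trade one source
    # for a local optimum; it must still be a valid monotone VB run and
    # recover the bulk of the planted structure (SVD is the recommended
    # deterministic start)
    mods <- fixtureModalities()
    ds <- fixtureDataset()
    fitR <- fitLinkedICA(mods, linkedICAConfig(L = 5, seed = 4,
                                               init = "random"))
    fe <- freeEnergyTrace(fitR)
    expect_true(all(diff(fe) >= -1e-8 * abs(fe[-1])))
    sc <- matchedRecoveryScore(spatialMaps(fitR), ds$truth@H)
    expect_gte(sum(sc$matching$absRho >= 0.95), 4L)
    expect_gt(sc$meanAbsRho, 0.9)
})

test_that("degenerate inputs are rejected with informative errors", {
    mods <- fixtureModalities()
    expect_error(fitLinkedICA(mods, linkedICAConfig(L = 40, seed = 1)),
                 "model-order|L")
    Y <- matrixValues(mods[[1]])
    Ybad <- Y; Ybad[3, ] <- 2
    expect_error(fitLinkedICA(list(Ybad), linkedICAConfig(L = 2)),
                 "zero-variance")
    Ynan <- Y; Ynan[1, 1] <- NA
    expect_error(fitLinkedICA(list(Ynan), linkedICAConfig(L = 2)),
                 "non-finite")
    Yshort <- Y[, 1:100]
    expect_error(fitLinkedICA(list(Y, Yshort), linkedICAConfig(L = 2)),
                 "voxel|shared|shape")
    expect_error(linkedICAConfig(L = 0), "L")
    expect_error(linkedICAConfig(L = 2, relTol = -1), "relTol")
})

test_that("the fit is deterministic given data and configuration", {
    mods <- fixtureModalities()
    cfg <- linkedICAConfig(L = 3, maxIter = 40, seed = 9)
    f1 <- fitLinkedICA(mods, cfg)
    f2 <- fitLinkedICA(mods, cfg)
    expect_identical(spatialMaps(f1), spatialMaps(f2))
    expect_identical(freeEnergyTrace(f1), freeEnergyTrace(f2))
})

test_that("an iteration-starved run reports non-convergence honestly", {
    mods <- fixtureModalities()
    fit <- fitLinkedICA(mods, linkedICAConfig(L = 5, maxIter = 5, seed = 2))
    expect_false(fit@converged)
    expect_length(freeEnergyTrace(fit), 5L)
})

test_that("held-out rows project onto the basis with near-floor residuals", {
    ds <- fixtureDataset()
    mods <- fixtureModalities()
    hold <- 1:10
    tr <- subsetFeatures(mods[[1]], featureIds(mods[[1]])[-hold])
    fit <- fitLinkedICA(list(tr, mods[[2]]), linkedICAConfig(L = 5, seed = 2))
    Yh <- matrixValues(mods[[1]])[hold, , drop = FALSE]
    pred <- predictUnseenFeatures(fit, Yh, k = 1)
    expect_identical(dim(pred$coefficients), c(10L, 5L))
    expect_identical(dim(pred$reconstruction), dim(Yh))
    # z-scored rows have unit variance, so mse well below 1 means most
    # variance is explained
    expect_true(all(pred$mse < 0.5))
    expect_error(predictUnseenFeatures(fit, Yh[, 1:10]), "shape error")
})

test_that("gene perturbation propagates into the projection modality", {
    fit <- fixtureFit()
    genes <- featureIds(fixtureModalities()[[1]])[1:5]
    d0 <- perturbGenes(fit, genes, scale = 1)      # no change
    expect_equal(max(abs(d0)), 0, tolerance = 1e-9)
    dKO <- perturbGenes(fit, genes, scale = 0)     # knock-out
    expect_identical(dim(dKO), c(30L, ncol(fit@H)))
    expect_gt(max(abs(dKO)), 0)
    # linearity: the predicted change scales with the coefficient change
    dHalf <- perturbGenes(fit, genes, scale = 0.5)
    expect_equal(dKO, 2 * dHalf, tolerance = 1e-8)
    expect_error(perturbGenes(fit, "no_such_gene"), "key error")
})
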
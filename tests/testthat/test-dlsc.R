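test_that("an unpenalized full-rank dictionary reconstructs noiseless low-rank data", {
    set.seed(21)
    H <- matrix(rnorm(4 * 300), 4)
    C0 <- matrix(rnorm(25 * 4), 25)
    Y <- C0 %*% H
    d <- fitDLSCExclusive(Y, nAtoms = 4, penalty = 0, seed = 1)
    rec <- d@codes %*% d@atoms
    Yz <- voxlica:::.zscoreRows(Y)
    expect_gte(rSquared(Yz, rec), 0.999)
})

test_that("the objective trace is non-increasing and atoms stay unit-norm", {
    mods <- fixtureModalities()
    for (d in list(fitDLSCExclusive(mods[[1]], nAtoms = 5, seed = 3),
                   fitDLSCExclusive(mods[[2]], nAtoms = 5, seed = 3),
                   fitDLSCConcat(mods, nAtoms = 5, seed = 3))) {
        obj <- d@objective
        expect_true(all(diff(obj) <= 1e-8 * abs(obj[-1]) + 1e-12))
        expect_equal(unname(sqrt(rowSums(d@atoms^2))), rep(1, 5),
                     tolerance = 1e-9)
    }
})

test_that("positive penalties produce exact zeros in the codes", {
    mods <- fixtureModalities()
    d <- fitDLSCExclusive(mods[[1]], nAtoms = 5, seed = 3)
    expect_gt(mean(d@codes == 0), 0)
    expect_gt(d@penalty, 0)
    expect_error(fitDLSCExclusive(mods[[1]], nAtoms = 5, penalty = -1),
                 "argument error")
    expect_error(fitDLSCExclusive(mods[[1]], nAtoms = 500), "model-order")
})

test_that("the lasso coding step matches an exact reference solver", {
    set.seed(31)
    A <- matrix(rnorm(4 * 120), 4)
    A <- A / sqrt(rowSums(A^2))
    Y <- matrix(rnorm(6 * 120), 6)
    lam <- 0.7
    C <- voxlica:::.lassoCodes(Y %*% t(A), tcrossprod(A), lam,
                               matrix(0, 6, 4))
    # glmnet solves (1/(2n))||y - Xb||^2 + lambda ||b||_1
    n <- ncol(Y)
    for (r in 1:6) {
        g <- glmnet::glmnet(t(A), Y[r, ], alpha = 1, lambda = lam / n,
                            intercept = FALSE, standardize = FALSE,
                            thresh = 1e-14)
        expect_equal(unname(C[r, ]), unname(as.numeric(g$beta)),
                     tolerance = 1e-6)
    }
})

test_that("concat on one modality reduces to the exclusive fit", {
    mods <- fixtureModalities()
    a <- fitDLSCExclusive(mods[[1]], nAtoms = 3, seed = 5)
    b <- fitDLSCConcat(list(mods[[1]]), nAtoms = 3, seed = 5)
    expect_equal(a@atoms, b@atoms, tolerance = 1e-12)
    expect_equal(a@codes, b@codes, tolerance = 1e-12)
})

test_that("concat feature splits partition the stacked rows", {
    mods <- fixtureModalities()
    d <- fitDLSCConcat(mods, nAtoms = 5, seed = 3)
    expect_identical(unname(unlist(d@featureSplit)), 1:90)
    expect_identical(lengths(d@featureSplit),
                     c(gene_expression = 60L, projection_density = 30L))
    short <- matrixValues(mods[[2]])[, 1:100]
    expect_error(fitDLSCConcat(list(mods[[1]], short), nAtoms = 3),
                 "shape error")
})

test_that("a shared planted source is carried by one atom with code energy in both modalities", {
    ds <- fixtureDataset()
    mods <- fixtureModalities()
    d <- fitDLSCConcat(mods, nAtoms = 5, seed = 3, penaltyFactor = 0.03)
    cm <- abs(cor(t(ds$truth@H), t(d@atoms)))
    best <- apply(cm, 1, which.max)
    shared <- which.max(apply(cm, 1, max))   # best-recovered planted source
    atom <- best[shared]
    for (k in 1:2) {
        en <- sum(d@codes[d@featureSplit[[k]], atom]^2)
        expect_gt(en, 0)
    }
})

test_that("dictionary fits are deterministic given the seed", {
    mods <- fixtureModalities()
    a <- fitDLSCExclusive(mods[[2]], nAtoms = 4, seed = 7)
    b <- fitDLSCExclusive(mods[[2]], nAtoms = 4, seed = 7)
    expect_identical(a@atoms, b@atoms)
    expect_identical(a@codes, b@codes)
})
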
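test_that("generated datasets satisfy the planted-model identities", {
    ds <- fixtureDataset()
    spec <- syntheticSpec()

    expect_length(ds$volumes, 2L)
    expect_named(ds$volumes, c("gene_expression", "projection_density"))
    expect_identical(dim(ds$mask@grid), c(12L, 10L, 10L))
    expect_equal(sum(ds$mask@grid), round(0.8 * 12 * 10 * 10))

    # H rows unit-norm and sparse at the requested level
    H <- ds$truth@H
    expect_equal(unname(sqrt(rowSums(H^2))), rep(1, 5), tolerance = 1e-12)
    # ties at the cut value may keep a couple of extra voxels
    active <- rowSums(H != 0)
    keep <- ceiling(0.1 * sum(ds$mask@grid))
    expect_true(all(active >= keep & active <= keep + 3))

    # planted sources are pairwise near-uncorrelated (identifiability)
    cm <- abs(cor(t(H)))
    expect_true(max(cm[upper.tri(cm)]) <= 0.15 + 1e-12)

    # weights inside the stated log-uniform support
    for (k in 1:2)
        expect_true(all(ds$truth@W[[k]] >= 0.5 & ds$truth@W[[k]] <= 2))
})

test_that("noise-free data reproduce Y = X diag(W) H exactly", {
    spec <- syntheticSpec(snr = Inf, missingFraction = 0, seed = 3)
    ds <- generateLinkedDataset(spec)
    for (k in 1:2) {
        Y <- matrixValues(flattenVolume(ds$volumes[[k]], ds$mask))
        S <- ds$truth@X[[k]] %*% (ds$truth@W[[k]] * ds$truth@H)
        expect_equal(unname(Y), unname(S), tolerance = 1e-12)
    }
    expect_identical(ds$truth@noiseSd, c(0, 0))
})

test_that("empirical noise variance matches the requested SNR", {
    ds <- fixtureDataset()
    for (k in 1:2) {
        expect_equal(ds$truth@noiseVar[k],
                     ds$truth@signalVar[k] / 10,
                     tolerance = 0.15)
    }
})

test_that("the stated fraction of in-mask modality-1 entries is missing", {
    ds <- fixtureDataset()
    Y1 <- matrixValues(flattenVolume(ds$volumes[[1]], ds$mask))
    expect_equal(mean(Y1 == -1), 0.008, tolerance = 0.25)
    # modality 2 has no missing entries
    Y2 <- matrixValues(flattenVolume(ds$volumes[[2]], ds$mask))
    expect_identical(sum(Y2 == -1), 0L)
})

test_that("generation is reproducible and seed-sensitive", {
    a <- generateLinkedDataset(syntheticSpec(seed = 5))
    b <- generateLinkedDataset(syntheticSpec(seed = 5))
    c <- generateLinkedDataset(syntheticSpec(seed = 6))
    expect_identical(a$truth@H, b$truth@H)
    expect_identical(a$volumes[[1]]@data, b$volumes[[1]]@data)
    expect_false(identical(a$truth@H, c$truth@H))
})

test_that("modality-unique components carry zero weight as planted", {
    ds <- fixtureUniqueDataset()
    expect_identical(ds$truth@W[[2]][2], 0)
    expect_true(all(ds$truth@W[[2]][-2] > 0))
})

test_that("the parcellation covers the mask with the requested regions", {
    ds <- fixtureDataset()
    region <- ds$annotation@regionId[ds$mask@coords]
    expect_true(all(region >= 1L))
    expect_identical(sort(unique(region)), 1:6)
    # out-of-mask voxels are unlabelled
    expect_true(all(ds$annotation@regionId[!ds$mask@grid] == 0L))
})

test_that("model-order and sparsity misconfigurations are rejected", {
    expect_error(generateLinkedDataset(syntheticSpec(L = 40, R = c(60, 30))),
                 "model-order")
    expect_error(
        generateLinkedDataset(syntheticSpec(gridDims = c(6, 5, 5),
                                            sourceSparsity = 0.001)),
        "sourceSparsity")
    expect_error(syntheticSpec(missingFraction = 1.5), "missingFraction")
})

test_that("annotation universes contain the planted terms verbatim", {
    pl <- list(axon_guidance = sprintf("gene%03d", 1:12))
    u <- generateAnnotationUniverse(100, 8, planted = pl, seed = 4)
    expect_identical(u@terms$axon_guidance, pl$axon_guidance)
    expect_length(u@terms, 8L)
    expect_true(all(unlist(u@terms) %in% u@universe))
    sizes <- lengths(u@terms[names(u@terms) != "axon_guidance"])
    expect_true(all(sizes >= 5 & sizes <= 20))
    expect_error(
        generateAnnotationUniverse(10, 3, planted = list(t = "missing_gene")),
        "outside the universe")
})
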
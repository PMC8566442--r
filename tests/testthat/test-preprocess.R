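test_that("downsampling matches the trilinear oracle on background-free volumes", {
    set.seed(10)
    dims <- c(8L, 6L, 4L)
    arr <- array(runif(2 * prod(dims), 1, 5), c(2L, dims))
    vol <- new("VolumeStack", data = arr,
               featureIds = c("a", "b"), backgroundValue = -1,
               axisOrder = c("P-A", "I-S", "R-L"), voxelSizeUm = 100)
    down <- downsampleVolume(vol, 2L)
    expect_identical(dim(down@data), c(2L, 4L, 3L, 2L))
    expect_identical(down@voxelSizeUm, 200)
    for (r in 1:2) for (i in 1:4) for (j in 1:3) for (k in 1:2)
        expect_equal(down@data[r, i, j, k],
                     oracleTrilinear(arr[r, , , ], 2, i, j, k),
                     tolerance = 1e-12)
})

test_that("downsampling excludes background support and keeps all-background cells at the sentinel", {
    dims <- c(4L, 4L, 4L)
    arr <- array(-1, c(1L, dims))
    arr[1, 1:2, 1:2, 1:2] <- 7          # one constant octant, rest background
    vol <- new("VolumeStack", data = arr, featureIds = "a",
               backgroundValue = -1, axisOrder = c("P-A", "I-S", "R-L"),
               voxelSizeUm = 100)
    down <- downsampleVolume(vol, 2L)
    # the value 7 must survive unchanged: background corners carry no weight
    expect_equal(down@data[1, 1, 1, 1], 7)
    # a coarse cell fully inside the background stays at the sentinel
    expect_equal(down@data[1, 2, 2, 2], -1)
    # oracle agreement on every coarse cell, including the mask border
    for (i in 1:2) for (j in 1:2) for (k in 1:2)
        expect_equal(down@data[1, i, j, k],
                     oracleTrilinear(arr[1, , , ], 2, i, j, k),
                     tolerance = 1e-12)
})

test_that("factor 1 is the identity and odd dims give ceiling-sized output", {
    ds <- fixtureDataset()
    vol <- ds$volumes[[2]]
    expect_identical(downsampleVolume(vol, 1L), vol)
    down <- downsampleVolume(vol, 3L)
    expect_identical(dim(down@data)[2:4], c(4L, 4L, 4L))
    expect_error(downsampleVolume(vol, 0), "argument error")
    expect_error(downsampleVolume(vol, 2.5), "argument error")
})

test_that("the recovered mask equals the generator's mask exactly", {
    ds <- fixtureDataset()
    m <- buildMask(ds$volumes[[2]])
    expect_identical(m@grid, ds$mask@grid)
    expect_identical(m@coords, ds$mask@coords)
})

test_that("mask voxel coordinates follow row-major order (last axis fastest)", {
    grid <- array(TRUE, c(2L, 2L, 2L))
    coords <- voxlica:::.rowMajorCoords(grid)
    expect_identical(coords[, 3], rep(c(1L, 2L), 4))      # z fastest
    expect_identical(coords[, 1], rep(c(1L, 2L), each = 4))  # x slowest
})

test_that("an all-background stack raises an empty-mask error", {
    arr <- array(-1, c(1L, 3L, 3L, 3L))
    vol <- new("VolumeStack", data = arr, featureIds = "a",
               backgroundValue = -1, axisOrder = c("P-A", "I-S", "R-L"),
               voxelSizeUm = 100)
    expect_error(buildMask(vol), "empty-mask")
})

test_that("flatten and unflatten round-trip in-mask values exactly", {
    ds <- fixtureDataset()
    mat <- flattenVolume(ds$volumes[[1]], ds$mask)
    arr <- unflattenMatrix(matrixValues(mat), ds$mask)
    expect_equal(arr, ds$volumes[[1]]@data, tolerance = 0)
    # vector input returns a 3D volume
    v3 <- unflattenMatrix(matrixValues(mat)[1, ], ds$mask)
    expect_identical(dim(v3), dim(ds$mask@grid))
    expect_error(flattenVolume(downsampleVolume(ds$volumes[[1]], 2L),
                               ds$mask),
                 "shape error")
})

test_that("imputation replaces sentinels by region means and is idempotent", {
    ds <- fixtureDataset()
    mat <- flattenVolume(ds$volumes[[1]], ds$mask)
    region <- ds$annotation@regionId[ds$mask@coords]
    imp <- imputeMissing(mat, ds$annotation)
    vals <- matrixValues(mat)
    out <- matrixValues(imp)
    expect_false(any(out == -1))
    # untouched where observed
    expect_identical(out[vals != -1], vals[vals != -1])
    # spot-check the region-mean formula on the first missing entry
    miss <- which(vals == -1, arr.ind = TRUE)
    r <- miss[1, 1]; j <- miss[1, 2]
    ok <- vals[r, ] != -1 & region == region[j]
    expect_equal(unname(out[r, j]), mean(vals[r, ok]), tolerance = 1e-12)
    # idempotent
    expect_identical(matrixValues(imputeMissing(imp, ds$annotation)), out)
})

test_that("imputation falls back to the global mean when a region is empty", {
    grid <- array(TRUE, c(4L, 1L, 1L))
    mask <- new("VoxelMask", grid = grid,
                coords = voxlica:::.rowMajorCoords(grid))
    vals <- matrix(c(-1, -1, 3, 5), 1)   # region 1 entirely missing
    mat <- new("ModalityMatrix", values = vals, featureIds = "g1",
               modalityName = "m", mask = mask)
    regionId <- array(c(1L, 1L, 2L, 2L), c(4L, 1L, 1L))
    annot <- new("AnnotationVolume", regionId = regionId,
                 regionNames = c("1" = "a", "2" = "b"))
    expect_warning(imp <- imputeMissing(mat, annot), "fallback")
    expect_equal(matrixValues(imp)[1, 1:2], c(4, 4))
})

test_that("feature subsetting preserves order and flags unknown ids", {
    ds <- fixtureDataset()
    mat <- flattenVolume(ds$volumes[[2]], ds$mask)
    grp <- c("inj005", "inj001", "inj020")
    sub <- subsetFeatures(mat, grp)
    expect_identical(featureIds(sub), grp)
    expect_identical(nrow(matrixValues(sub)), 3L)
    expect_identical(matrixValues(sub)[2, ], matrixValues(mat)[1, ])
    expect_error(subsetFeatures(mat, c("inj001", "nonexistent")),
                 "key error.*nonexistent")
})
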
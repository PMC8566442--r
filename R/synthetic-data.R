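# Synthetic voxel-linked datasets with planted ground truth.
#
# The generator emulates the statistical structure of volumetric
# expression-energy and projection-density data registered to a common grid:
# a brain-like mask with background sentinel -1, L shared sparse spatial
# sources mixing into every modality through modality-specific coefficients
# and non-negative weights, i.i.d. Gaussian noise per modality, a small
# fraction of missing (-1) entries inside the mask of modality 1, a toy
# parcellation, and a toy gene-annotation universe with planted enriched
# terms. Everything downstream is testable against the emitted ground truth.

#' Construct a synthetic dataset specification
#'
#' @param gridDims integer(3) grid dimensions.
#' @param maskFill fraction of the grid inside the brain-like mask.
#' @param L number of shared spatial sources.
#' @param R integer vector of per-modality feature counts.
#' @param snr per-modality signal-to-noise ratio (total signal variance over
#'   noise variance); recycled across modalities; \code{Inf} = noise-free.
#' @param sourceSparsity fraction of in-mask voxels active per source.
#' @param missingFraction fraction of in-mask modality-1 entries replaced by
#'   the background sentinel (default 0.008, i.e. 0.8\% as observed for
#'   unmeasured expression values in the real atlas data).
#' @param nRegions number of toy parcellation regions.
#' @param seed integer RNG seed.
#' @param uniqueComponents optional integer matrix with columns
#'   \code{component}, \code{modality}; listed weights are zeroed, planting
#'   modality-unique sources.
#' @return a validated \linkS4class{SyntheticSpec}.
#' @examples
#' syntheticSpec(gridDims = c(8, 6, 6), L = 2, R = c(20, 10))
#' @export
syntheticSpec <- function(gridDims = c(12L, 10L, 10L), maskFill = 0.8,
                          L = 5L, R = c(60L, 30L), snr = 10,
                          sourceSparsity = 0.1, missingFraction = 0.008,
                          nRegions = 6L, seed = 1L,
                          uniqueComponents = NULL) {
    if (is.null(uniqueComponents)) {
        uniqueComponents <- matrix(integer(0), ncol = 2,
                                   dimnames = list(NULL,
                                                   c("component", "modality")))
    } else {
        uniqueComponents <- as.matrix(uniqueComponents)
        storage.mode(uniqueComponents) <- "integer"
        colnames(uniqueComponents) <- c("component", "modality")
    }
    new("SyntheticSpec", gridDims = as.integer(gridDims),
        maskFill = maskFill, L = as.integer(L), R = as.integer(R),
        snr = rep_len(as.numeric(snr), length(R)),
        sourceSparsity = sourceSparsity, missingFraction = missingFraction,
        nRegions = as.integer(nRegions), seed = as.integer(seed),
        uniqueComponents = uniqueComponents)
}

# Row-major (last axis fastest) coordinate list of the TRUE cells of a grid.
.rowMajorCoords <- function(grid) {
    d <- dim(grid)
    idx <- which(grid, arr.ind = TRUE)
    colnames(idx) <- NULL
    idx <- idx[order(idx[, 1L], idx[, 2L], idx[, 3L]), , drop = FALSE]
    storage.mode(idx) <- "integer"
    idx
}

# Brain-like mask: smallest values of a perturbed ellipsoidal distance field,
# which gives a single roughly convex blob covering exactly the target count.
.makeBrainMask <- function(dims, fill) {
    cx <- (dims + 1) / 2
    ax <- expand.grid(x = seq_len(dims[1]), y = seq_len(dims[2]),
                      z = seq_len(dims[3]))
    d <- ((ax$x - cx[1]) / (dims[1] / 2))^2 +
         ((ax$y - cx[2]) / (dims[2] / 2))^2 +
         ((ax$z - cx[3]) / (dims[3] / 2))^2
    ph <- runif(3, 0, 2 * pi)
    d <- d + 0.15 * (sin(2 * pi * ax$x / dims[1] + ph[1]) +
                     sin(2 * pi * ax$y / dims[2] + ph[2]) +
                     sin(2 * pi * ax$z / dims[3] + ph[3]))
    m <- round(fill * prod(dims))
    grid <- array(FALSE, dims)
    grid[order(d)[seq_len(m)]] <- TRUE
    grid
}

# One sparse super-Gaussian spatial source: a sum of 1-3 positive Gaussian
# blobs evaluated at the in-mask voxels, hard-thresholded to its top
# `sparsity` fraction of voxels and unit-normalised. ICA-style recovery
# needs exactly this kind of non-Gaussian, spatially contiguous structure.
.makeSource <- function(coords, dims, sparsity) {
    n <- nrow(coords)
    v <- numeric(n)
    nb <- sample(1:3, 1L)
    for (b in seq_len(nb)) {
        ctr <- coords[sample.int(n, 1L), ]
        sdv <- runif(3, 0.08, 0.2) * dims
        amp <- runif(1, 0.5, 1.5)
        v <- v + amp * exp(-0.5 * ((coords[, 1] - ctr[1])^2 / sdv[1]^2 +
                                   (coords[, 2] - ctr[2])^2 / sdv[2]^2 +
                                   (coords[, 3] - ctr[3])^2 / sdv[3]^2))
    }
    keep <- ceiling(sparsity * n)
    cut <- sort(v, decreasing = TRUE)[keep]
    v[v < cut] <- 0
    v / sqrt(sum(v^2))
}

# Toy parcellation of the in-mask voxels into spatially compact regions.
.makeParcellation <- function(coords, dims, nRegions) {
    km <- kmeans(coords, centers = nRegions, nstart = 1L, iter.max = 100L)
    regionId <- array(0L, dims)
    regionId[coords] <- as.integer(km$cluster)
    new("AnnotationVolume", regionId = regionId,
        regionNames = setNames(paste0("region_", seq_len(nRegions)),
                               as.character(seq_len(nRegions))))
}

.volumize <- function(values, coords, dims, background = -1) {
    R <- nrow(values)
    arr <- array(background, c(R, dims))
    lin <- (coords[, 3] - 1) * dims[1] * dims[2] +
           (coords[, 2] - 1) * dims[1] + coords[, 1]
    for (r in seq_len(R)) {
        slab <- array(background, dims)
        slab[lin] <- values[r, ]
        arr[r, , , ] <- slab
    }
    arr
}

#' Generate a voxel-linked multimodal dataset with planted ground truth
#'
#' Emits one \linkS4class{VolumeStack} per modality built exactly as
#' Y^k = X^k diag(W^k) H + E^k over the in-mask voxels, plus the shared
#' \linkS4class{VoxelMask}, a toy \linkS4class{AnnotationVolume} and the
#' \linkS4class{GroundTruth}. Sources are kept pairwise near-uncorrelated
#' so the planted factorization is identifiable. Feature coefficients are
#' standard normal,
#' weights are log-uniform in [0.5, 2] (zeroed for planted modality-unique
#' components), and the per-modality noise standard deviation is set from the
#' requested signal-to-noise ratio. A stated fraction of in-mask modality-1
#' entries is replaced by the background sentinel. The call is fully
#' reproducible given the seed in the spec.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a list with elements \code{volumes} (list of VolumeStack),
#'   \code{mask}, \code{annotation} and \code{truth}.
#' @examples
#' ds <- generateLinkedDataset(syntheticSpec(gridDims = c(8, 6, 6), L = 2,
#'                                           R = c(20, 10), seed = 3))
#' ds$mask
#' @export
generateLinkedDataset <- function(spec) {
    validObject(spec)
    if (spec@L > min(spec@R))
        stop("model-order error: L must not exceed the smallest feature count")
    set.seed(spec@seed)
    dims <- spec@gridDims
    grid <- .makeBrainMask(dims, spec@maskFill)
    coords <- .rowMajorCoords(grid)
    mask <- new("VoxelMask", grid = grid, coords = coords)
    N <- nrow(coords)
    L <- spec@L
    if (ceiling(spec@sourceSparsity * N) < 2L)
        stop("configuration error: sourceSparsity leaves fewer than 2 active voxels")

    # Planted sources must be identifiable: heavily overlapping blobs give
    # mutually correlated sources no factorization method could separate, so
    # each source is rejection-sampled against the accepted ones until the
    # largest pairwise |correlation| is small (best candidate kept if the
    # cap is not reached within the retry budget).
    H <- matrix(0, L, N)
    for (i in seq_len(L)) {
        best <- NULL
        bestC <- Inf
        for (try in seq_len(200L)) {
            cand <- .makeSource(coords, dims, spec@sourceSparsity)
            cmax <- if (i == 1L) 0 else
                max(abs(cor(cand, t(H[seq_len(i - 1L), , drop = FALSE]))))
            if (cmax < bestC) {
                best <- cand
                bestC <- cmax
            }
            if (cmax <= 0.15) break
        }
        H[i, ] <- best
    }

    K <- length(spec@R)
    X <- W <- vector("list", K)
    noiseSd <- signalVar <- noiseVar <- numeric(K)
    volumes <- vector("list", K)
    modNames <- c("gene_expression", "projection_density",
                  paste0("modality_", seq_len(max(0, K - 2)) + 2L))[seq_len(K)]
    prefixes <- c("gene", "inj", paste0("m", seq_len(max(0, K - 2)) + 2L,
                                        "f"))[seq_len(K)]
    for (k in seq_len(K)) {
        Rk <- spec@R[k]
        X[[k]] <- matrix(rnorm(Rk * L), Rk, L)
        W[[k]] <- exp(runif(L, log(0.5), log(2)))
        uq <- spec@uniqueComponents
        if (nrow(uq) > 0) {
            zero <- uq[uq[, "modality"] == k, "component"]
            W[[k]][zero] <- 0
        }
        S <- X[[k]] %*% (W[[k]] * H)
        sv <- mean(S^2) - mean(S)^2
        noiseSd[k] <- if (is.infinite(spec@snr[k])) 0 else
            sqrt(sv / spec@snr[k])
        E <- matrix(rnorm(Rk * N, sd = noiseSd[k]), Rk, N)
        Y <- S + E
        signalVar[k] <- sv
        noiseVar[k] <- mean(E^2) - mean(E)^2
        if (k == 1L && spec@missingFraction > 0) {
            nMiss <- round(spec@missingFraction * Rk * N)
            Y[sample.int(Rk * N, nMiss)] <- -1
        }
        volumes[[k]] <- new("VolumeStack",
                            data = .volumize(Y, coords, dims),
                            featureIds = sprintf("%s%03d", prefixes[k],
                                                 seq_len(Rk)),
                            backgroundValue = -1,
                            axisOrder = c("P-A", "I-S", "R-L"),
                            voxelSizeUm = 200)
    }
    names(volumes) <- modNames
    annotation <- .makeParcellation(coords, dims, spec@nRegions)
    truth <- new("GroundTruth", H = H, X = X, W = W, noiseSd = noiseSd,
                 signalVar = signalVar, noiseVar = noiseVar,
                 seed = spec@seed)
    list(volumes = volumes, mask = mask, annotation = annotation,
         truth = truth)
}

#' Generate a toy gene-annotation universe with planted enriched terms
#'
#' Builds a flat term-to-gene-set mapping over a gene universe. Planted
#' terms contain exactly the stated gene subsets; the remaining terms are
#' random subsets with sizes drawn uniformly from \code{sizeRange}.
#'
#' @param nGenes number of genes in the universe (ignored if \code{universe}
#'   is given).
#' @param nTerms total number of terms including the planted ones.
#' @param planted named list of character gene-id vectors.
#' @param sizeRange integer(2) inclusive size range of the random terms.
#' @param seed integer RNG seed.
#' @param universe optional explicit character vector of gene ids.
#' @return an \linkS4class{AnnotationMap}.
#' @examples
#' u <- generateAnnotationUniverse(50, 10, seed = 2)
#' u
#' @export
generateAnnotationUniverse <- function(nGenes, nTerms, planted = list(),
                                       sizeRange = c(5L, 20L), seed = 1L,
                                       universe = NULL) {
    if (is.null(universe))
        universe <- sprintf("gene%03d", seq_len(nGenes))
    for (nm in names(planted)) {
        if (!all(planted[[nm]] %in% universe))
            stop("configuration error: planted term '", nm,
                 "' annotates genes outside the universe")
    }
    if (length(planted) > nTerms)
        stop("configuration error: more planted terms than nTerms")
    set.seed(seed)
    nRandom <- nTerms - length(planted)
    terms <- planted
    if (nRandom > 0) {
        sizes <- sample(seq(sizeRange[1], min(sizeRange[2], length(universe))),
                        nRandom, replace = TRUE)
        rterms <- lapply(sizes, function(s) sample(universe, s))
        names(rterms) <- sprintf("random_term_%03d", seq_len(nRandom))
        terms <- c(terms, rterms)
    }
    new("AnnotationMap", terms = terms, universe = universe,
        termNames = setNames(paste("term", names(terms)), names(terms)))
}
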
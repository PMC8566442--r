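#' @import methods
#' @importFrom stats quantile rnorm runif sd var cor kmeans setNames phyper
#'   p.adjust pt dnorm median
#' @importFrom utils head tail read.delim write.table
NULL

#' Voxel mask with row-major flattening map
#'
#' A boolean 3D grid together with the ordered list of in-mask voxel
#' coordinates. The ordering is row-major over the grid axes: the voxel index
#' increases fastest along the last (third) axis, so that flattened matrices
#' built from the same mask are voxel-aligned across modalities.
#'
#' @slot grid logical 3D array; \code{TRUE} marks in-mask voxels.
#' @slot coords integer matrix with one row per in-mask voxel giving its
#'   (x, y, z) grid coordinates (1-based), in row-major order.
#' @exportClass VoxelMask
setClass("VoxelMask", representation(grid = "array", coords = "matrix"))

setValidity("VoxelMask", function(object) {
    if (!is.logical(object@grid) || length(dim(object@grid)) != 3L)
        return("grid must be a logical 3D array")
    if (ncol(object@coords) != 3L)
        return("coords must have 3 columns")
    if (nrow(object@coords) != sum(object@grid))
        return("coords must enumerate exactly the TRUE cells of grid")
    ord <- order(object@coords[, 1L], object@coords[, 2L], object@coords[, 3L])
    if (!identical(ord, seq_len(nrow(object@coords))))
        return("coords must be in row-major order (last axis fastest)")
    TRUE
})

#' 4D stack of feature volumes
#'
#' The raw volumetric form of one modality: one 3D intensity volume per
#' feature (gene or injection), on a common grid, with a background sentinel
#' value marking out-of-brain voxels.
#'
#' @slot data numeric 4D array of dimension (features, nx, ny, nz).
#' @slot featureIds character vector of feature labels.
#' @slot backgroundValue numeric sentinel for background voxels (default -1).
#' @slot axisOrder character(3) axis labels; the convention used for the
#'   Allen volumes is Posterior-Anterior, Inferior-Superior, Right-Left.
#' @slot voxelSizeUm numeric voxel edge length in micrometres.
#' @exportClass VolumeStack
setClass("VolumeStack", representation(
    data = "array", featureIds = "character", backgroundValue = "numeric",
    axisOrder = "character", voxelSizeUm = "numeric"))

setValidity("VolumeStack", function(object) {
    d <- dim(object@data)
    if (length(d) != 4L) return("data must be a 4D array (features, x, y, z)")
    if (d[1L] < 1L) return("at least one feature is required")
    if (length(object@featureIds) != d[1L])
        return("featureIds length must equal the number of features")
    if (anyDuplicated(object@featureIds)) return("featureIds must be unique")
    if (length(object@backgroundValue) != 1L)
        return("backgroundValue must be a single value")
    TRUE
})

#' Feature-by-voxel matrix of one modality
#'
#' The 2D, mask-flattened form of a \linkS4class{VolumeStack}: one row per
#' feature, one column per in-mask voxel, with columns ordered by the
#' row-major flattening map of the associated \linkS4class{VoxelMask}.
#'
#' @slot values numeric matrix (features x voxels).
#' @slot featureIds character feature labels (rownames of \code{values}).
#' @slot modalityName single string naming the modality.
#' @slot mask the shared \linkS4class{VoxelMask}.
#' @exportClass ModalityMatrix
setClass("ModalityMatrix", representation(
    values = "matrix", featureIds = "character", modalityName = "character",
    mask = "VoxelMask"))

setValidity("ModalityMatrix", function(object) {
    if (nrow(object@values) != length(object@featureIds))
        return("featureIds length must match the number of rows")
    if (ncol(object@values) != nrow(object@mask@coords))
        return("number of columns must equal the mask voxel count")
    if (length(object@modalityName) != 1L)
        return("modalityName must be a single string")
    TRUE
})

#' Integer parcellation volume
#'
#' @slot regionId integer 3D array of region ids (0 outside any region).
#' @slot regionNames named character vector mapping region id to label.
#' @exportClass AnnotationVolume
setClass("AnnotationVolume", representation(
    regionId = "array", regionNames = "character"))

setValidity("AnnotationVolume", function(object) {
    if (length(dim(object@regionId)) != 3L)
        return("regionId must be a 3D array")
    ids <- setdiff(unique(as.integer(object@regionId)), 0L)
    if (!all(as.character(ids) %in% names(object@regionNames)))
        return("every non-zero region id must be present in regionNames")
    TRUE
})

#' Specification of a synthetic voxel-linked dataset
#'
#' Describes the study conditions under which a multimodal dataset with
#' planted ground truth is generated: grid geometry, mask fill, number of
#' shared sparse spatial sources, per-modality feature counts,
#' signal-to-noise ratios, source sparsity, missing-value fraction in
#' modality 1, parcellation size and the RNG seed. Components listed in
#' \code{uniqueComponents} have their weight zeroed in one modality, creating
#' modality-unique sources.
#'
#' @slot gridDims integer(3) grid dimensions.
#' @slot maskFill fraction of grid voxels inside the brain-like mask.
#' @slot L number of shared spatial sources.
#' @slot R integer vector of feature counts per modality.
#' @slot snr numeric signal-to-noise ratio per modality (recycled);
#'   \code{Inf} means noise-free.
#' @slot sourceSparsity fraction of in-mask voxels active per source.
#' @slot missingFraction fraction of in-mask modality-1 entries set to the
#'   background sentinel, emulating unmeasured expression values.
#' @slot nRegions number of parcellation regions.
#' @slot seed integer RNG seed.
#' @slot uniqueComponents integer matrix with columns \code{component} and
#'   \code{modality}; each row zeroes one component's weight in one modality.
#' @exportClass SyntheticSpec
setClass("SyntheticSpec", representation(
    gridDims = "integer", maskFill = "numeric", L = "integer", R = "integer",
    snr = "numeric", sourceSparsity = "numeric", missingFraction = "numeric",
    nRegions = "integer", seed = "integer", uniqueComponents = "matrix"))

setValidity("SyntheticSpec", function(object) {
    if (length(object@gridDims) != 3L || any(object@gridDims < 1L))
        return("gridDims must be three positive integers")
    if (object@maskFill <= 0 || object@maskFill > 1)
        return("maskFill must be in (0, 1]")
    if (object@L < 1L) return("L must be >= 1")
    if (length(object@R) < 1L || any(object@R < 1L))
        return("R must contain positive feature counts")
    if (any(object@snr <= 0)) return("snr must be positive")
    if (object@sourceSparsity <= 0 || object@sourceSparsity > 1)
        return("sourceSparsity must be in (0, 1]")
    if (object@missingFraction < 0 || object@missingFraction >= 1)
        return("missingFraction must be in [0, 1)")
    if (object@nRegions < 1L) return("nRegions must be >= 1")
    if (nrow(object@uniqueComponents) > 0) {
        if (!all(c("component", "modality") %in% colnames(object@uniqueComponents)))
            return("uniqueComponents needs 'component' and 'modality' columns")
        if (any(object@uniqueComponents[, "component"] > object@L) ||
            any(object@uniqueComponents[, "modality"] > length(object@R)))
            return("uniqueComponents indices out of range")
    }
    TRUE
})

#' Planted ground truth of a synthetic dataset
#'
#' @slot H numeric L x N matrix of shared spatial sources (unit-norm rows),
#'   columns in the row-major voxel order of the dataset mask.
#' @slot X list of feature-coefficient matrices (R_k x L), one per modality.
#' @slot W list of length-L non-negative modality weight vectors.
#' @slot noiseSd numeric per-modality noise standard deviations.
#' @slot signalVar,noiseVar numeric per-modality empirical variances of the
#'   signal and noise parts at generation time.
#' @slot seed integer seed the dataset was generated with.
#' @exportClass GroundTruth
setClass("GroundTruth", representation(
    H = "matrix", X = "list", W = "list", noiseSd = "numeric",
    signalVar = "numeric", noiseVar = "numeric", seed = "integer"))

setValidity("GroundTruth", function(object) {
    L <- nrow(object@H)
    if (length(object@X) != length(object@W))
        return("X and W must have one element per modality")
    for (k in seq_along(object@X)) {
        if (ncol(object@X[[k]]) != L) return("X matrices must have L columns")
        if (length(object@W[[k]]) != L) return("W vectors must have length L")
        if (any(object@W[[k]] < 0)) return("W entries must be non-negative")
    }
    nrm <- sqrt(rowSums(object@H^2))
    if (any(abs(nrm - 1) > 1e-12))
        return("rows of H must have unit Euclidean norm")
    TRUE
})

#' Configuration of a linked ICA fit
#'
#' @slot L number of components.
#' @slot maxIter maximum number of variational updates (default 3000).
#' @slot relTol relative free-energy change declaring convergence
#'   (default 1e-6).
#' @slot seed integer seed controlling initialisation.
#' @slot dofScale per-modality likelihood weight implementing a spatial
#'   degrees-of-freedom correction; 1 means no correction.
#' @slot mogComponents number of Gaussians in the source mixture prior.
#' @slot init either \code{"svd"} (deterministic SVD + varimax start) or
#'   \code{"random"}.
#' @exportClass LinkedICAConfig
setClass("LinkedICAConfig", representation(
    L = "integer", maxIter = "integer", relTol = "numeric", seed = "integer",
    dofScale = "numeric", mogComponents = "integer", init = "character"))

setValidity("LinkedICAConfig", function(object) {
    if (object@L < 1L) return("L must be >= 1")
    if (object@relTol <= 0) return("relTol must be positive")
    if (any(object@dofScale <= 0)) return("dofScale must be positive")
    if (object@mogComponents < 2L) return("mogComponents must be >= 2")
    if (!object@init %in% c("svd", "random"))
        return("init must be 'svd' or 'random'")
    TRUE
})

#' Fitted linked ICA decomposition
#'
#' Point summary of the variational posterior of the voxel-linked model
#' Y^k = X^k W^k H + E^k: shared spatial maps H (unit-norm, sign-fixed,
#' sorted by total explained variance), per-modality feature coefficients X^k
#' (unit-norm columns), non-negative modality weights W^k, noise precisions,
#' the free-energy trace and explained-variance bookkeeping.
#'
#' @slot H numeric L x N matrix of shared spatial maps.
#' @slot X list of R_k x L coefficient matrices, one per modality.
#' @slot W list of length-L non-negative weight vectors, one per modality.
#' @slot noisePrecision numeric per-modality posterior mean noise precision
#'   (in the standardized data scale).
#' @slot freeEnergy numeric per-iteration variational free energy.
#' @slot componentOrder integer permutation that sorted the raw components.
#' @slot converged logical; TRUE if the relative free-energy change fell
#'   below the tolerance before the iteration cap.
#' @slot explainedVariance numeric L x K matrix of variance fractions.
#' @slot modalityNames character modality labels.
#' @slot featureIds list of per-modality feature labels.
#' @slot rowCenter,rowScale lists of per-feature standardization constants
#'   retained so reconstructions can be returned in original units.
#' @slot config the \linkS4class{LinkedICAConfig} used.
#' @slot mog list with the fitted source-mixture parameters (pi, sigma2).
#' @exportClass LinkedDecomposition
setClass("LinkedDecomposition", representation(
    H = "matrix", X = "list", W = "list", noisePrecision = "numeric",
    freeEnergy = "numeric", componentOrder = "integer", converged = "logical",
    explainedVariance = "matrix", modalityNames = "character",
    featureIds = "list", rowCenter = "list", rowScale = "list",
    config = "LinkedICAConfig", mog = "list"))

setValidity("LinkedDecomposition", function(object) {
    L <- nrow(object@H)
    if (any(vapply(object@W, function(w) any(w < 0), logical(1))))
        return("W entries must be non-negative")
    nrm <- sqrt(rowSums(object@H^2))
    if (any(abs(nrm - 1) > 1e-8))
        return("rows of H must be unit-norm")
    if (nrow(object@explainedVariance) != L)
        return("explainedVariance must have one row per component")
    TRUE
})

#' Dictionary learning and sparse coding model
#'
#' @slot atoms numeric D x N dictionary of spatial atoms (unit-norm rows).
#' @slot codes numeric R x D sparse coefficient matrix.
#' @slot penalty numeric L1 sparsity weight used.
#' @slot modalityNames character modality labels.
#' @slot featureSplit list of integer row-index vectors per modality.
#' @slot featureIds character row labels of \code{codes}.
#' @slot objective numeric per-iteration objective trace.
#' @exportClass DictionaryModel
setClass("DictionaryModel", representation(
    atoms = "matrix", codes = "matrix", penalty = "numeric",
    modalityNames = "character", featureSplit = "list",
    featureIds = "character", objective = "numeric"))

setValidity("DictionaryModel", function(object) {
    if (ncol(object@codes) != nrow(object@atoms))
        return("codes columns must match the number of atoms")
    nrm <- sqrt(rowSums(object@atoms^2))
    if (any(nrm > 0 & abs(nrm - 1) > 1e-8))
        return("non-degenerate atoms must be unit-norm")
    if (object@penalty < 0) return("penalty must be non-negative")
    TRUE
})

#' Gene annotation universe
#'
#' Flat term-to-gene-set mapping over a stated gene universe, the form used
#' by over-representation analysis.
#'
#' @slot terms named list of character gene-id vectors.
#' @slot universe character vector of all gene ids.
#' @slot termNames named character vector of term descriptions.
#' @exportClass AnnotationMap
setClass("AnnotationMap", representation(
    terms = "list", universe = "character", termNames = "character"))

setValidity("AnnotationMap", function(object) {
    bad <- vapply(object@terms, function(g) !all(g %in% object@universe),
                  logical(1))
    if (any(bad))
        return(paste("terms annotate genes outside the universe:",
                     paste(names(object@terms)[bad], collapse = ", ")))
    TRUE
})

#' Percentile-thresholded spatial map
#'
#' @slot componentId integer id of the thresholded component.
#' @slot lowCut,highCut numeric values at the low/high percentiles.
#' @slot negativeVoxels,positiveVoxels integer voxel indices below/above the
#'   cuts; values inside the band are treated as zero.
#' @slot nVoxels integer total number of voxels in the map.
#' @slot zScored logical whether the map values were z-scored first.
#' @exportClass ThresholdedMap
setClass("ThresholdedMap", representation(
    componentId = "integer", lowCut = "numeric", highCut = "numeric",
    negativeVoxels = "integer", positiveVoxels = "integer",
    nVoxels = "integer", zScored = "logical"))

#' Modality-dominance labels of thresholded voxels
#'
#' @slot voxels integer indices of the labelled voxels.
#' @slot labels factor with levels shared / gene_dominated /
#'   projection_dominated (modality 1 plays the gene role, modality 2 the
#'   projection role).
#' @slot ratioCut numeric energy-ratio cut used.
#' @exportClass DominanceMap
setClass("DominanceMap", representation(
    voxels = "integer", labels = "factor", ratioCut = "numeric"))

#' Pairwise Pearson correlation table between two factorizations
#'
#' @slot rho,p numeric matrices of Pearson correlations and two-sided
#'   p-values.
#' @slot alpha numeric significance level (default 0.004).
#' @slot significant logical matrix, \code{p < alpha}.
#' @exportClass CrossCorrelationTable
setClass("CrossCorrelationTable", representation(
    rho = "matrix", p = "matrix", alpha = "numeric", significant = "matrix"))
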
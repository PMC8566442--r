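#' Number of in-mask voxels
#' @param object a \linkS4class{VoxelMask}, \linkS4class{ModalityMatrix} or
#'   \linkS4class{LinkedDecomposition}.
#' @return integer voxel count.
#' @export
setGeneric("nVoxels", function(object) standardGeneric("nVoxels"))

#' Feature labels
#' @param object an object carrying feature labels.
#' @return character vector (or list of vectors for multimodal objects).
#' @export
setGeneric("featureIds", function(object) standardGeneric("featureIds"))

#' Shared spatial maps
#' @param object a fitted decomposition or ground truth.
#' @return numeric L x N matrix.
#' @export
setGeneric("spatialMaps", function(object) standardGeneric("spatialMaps"))

#' Modality weight vectors
#' @param object a fitted decomposition or ground truth.
#' @return list of length-L non-negative vectors, one per modality.
#' @export
setGeneric("modalityWeights", function(object)
    standardGeneric("modalityWeights"))

#' Feature coefficient matrices
#' @param object a fitted decomposition or ground truth.
#' @return list of R_k x L matrices, one per modality.
#' @export
setGeneric("featureCoefficients", function(object)
    standardGeneric("featureCoefficients"))

#' Per-component, per-modality explained variance
#'
#' Fraction of each modality's total variance explained by each component's
#' rank-one term; row-normalising gives the relative modality contribution of
#' each component.
#'
#' @param object a \linkS4class{LinkedDecomposition}.
#' @param relative logical; if TRUE rows are normalised to sum to one.
#' @return numeric L x K matrix.
#' @export
setGeneric("explainedVariance", function(object, relative = FALSE)
    standardGeneric("explainedVariance"))

#' Free-energy trace of a variational fit
#' @param object a \linkS4class{LinkedDecomposition}.
#' @return numeric vector, one value per iteration.
#' @export
setGeneric("freeEnergyTrace", function(object)
    standardGeneric("freeEnergyTrace"))

#' Noise-free reconstruction of one modality
#'
#' Computes X^k diag(W^k) H restricted to a component subset.
#'
#' @param object a fitted \linkS4class{LinkedDecomposition}.
#' @param k modality index.
#' @param components optional integer vector of components (default all); an
#'   empty vector yields the zero matrix.
#' @param originalUnits logical; if TRUE the per-feature standardization is
#'   undone so the result lives in the input data units.
#' @return numeric R_k x N matrix.
#' @export
setGeneric("reconstruct",
    function(object, k = 1L, components = NULL, originalUnits = FALSE)
        standardGeneric("reconstruct"))

# ---- accessors ----

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "VoxelMask", function(object) nrow(object@coords))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "ModalityMatrix", function(object) ncol(object@values))

#' @rdname nVoxels
#' @export
setMethod("nVoxels", "LinkedDecomposition", function(object) ncol(object@H))

#' @rdname featureIds
#' @export
setMethod("featureIds", "VolumeStack", function(object) object@featureIds)

#' @rdname featureIds
#' @export
setMethod("featureIds", "ModalityMatrix", function(object) object@featureIds)

#' @rdname featureIds
#' @export
setMethod("featureIds", "LinkedDecomposition",
    function(object) object@featureIds)

#' @rdname spatialMaps
#' @export
setMethod("spatialMaps", "LinkedDecomposition", function(object) object@H)

#' @rdname spatialMaps
#' @export
setMethod("spatialMaps", "GroundTruth", function(object) object@H)

#' @rdname spatialMaps
#' @export
setMethod("spatialMaps", "DictionaryModel", function(object) object@atoms)

#' @rdname modalityWeights
#' @export
setMethod("modalityWeights", "LinkedDecomposition",
    function(object) object@W)

#' @rdname modalityWeights
#' @export
setMethod("modalityWeights", "GroundTruth", function(object) object@W)

#' @rdname featureCoefficients
#' @export
setMethod("featureCoefficients", "LinkedDecomposition",
    function(object) object@X)

#' @rdname featureCoefficients
#' @export
setMethod("featureCoefficients", "GroundTruth", function(object) object@X)

#' @rdname explainedVariance
#' @export
setMethod("explainedVariance", "LinkedDecomposition",
    function(object, relative = FALSE) {
        ev <- object@explainedVariance
        if (relative) {
            tot <- rowSums(ev)
            ev <- ev / ifelse(tot > 0, tot, 1)
        }
        ev
    })

#' @rdname freeEnergyTrace
#' @export
setMethod("freeEnergyTrace", "LinkedDecomposition",
    function(object) object@freeEnergy)

#' Values of a modality matrix
#' @param object a \linkS4class{ModalityMatrix}.
#' @return numeric features x voxels matrix with feature-id rownames.
#' @export
matrixValues <- function(object) {
    stopifnot(is(object, "ModalityMatrix"))
    v <- object@values
    rownames(v) <- object@featureIds
    v
}

#' Mask of a modality matrix
#' @param object a \linkS4class{ModalityMatrix}.
#' @return the associated \linkS4class{VoxelMask}.
#' @export
maskOf <- function(object) {
    stopifnot(is(object, "ModalityMatrix"))
    object@mask
}

# ---- show methods ----

setMethod("show", "VoxelMask", function(object) {
    d <- dim(object@grid)
    cat(sprintf("VoxelMask: %d x %d x %d grid, %d in-mask voxels (%.1f%%)\n",
                d[1], d[2], d[3], nVoxels(object),
                100 * nVoxels(object) / prod(d)))
})

setMethod("show", "VolumeStack", function(object) {
    d <- dim(object@data)
    cat(sprintf(
        "VolumeStack: %d features on a %d x %d x %d grid (%g um voxels)\n",
        d[1], d[2], d[3], d[4], object@voxelSizeUm))
    cat(sprintf("  background sentinel: %g; axes: %s\n",
                object@backgroundValue,
                paste(object@axisOrder, collapse = ", ")))
})

setMethod("show", "ModalityMatrix", function(object) {
    cat(sprintf("ModalityMatrix '%s': %d features x %d voxels\n",
                object@modalityName, nrow(object@values), nVoxels(object)))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(
        "SyntheticSpec: grid %s, fill %.2f, L=%d, R=[%s], snr=[%s], seed=%d\n",
        paste(object@gridDims, collapse = "x"), object@maskFill, object@L,
        paste(object@R, collapse = ","), paste(object@snr, collapse = ","),
        object@seed))
})

setMethod("show", "LinkedDecomposition", function(object) {
    cat(sprintf(
        "LinkedDecomposition: %d components, %d voxels, %d modalities (%s)\n",
        nrow(object@H), ncol(object@H), length(object@X),
        paste(object@modalityNames, collapse = ", ")))
    cat(sprintf("  converged: %s after %d iterations (final F = %.6g)\n",
                object@converged, length(object@freeEnergy),
                tail(object@freeEnergy, 1)))
    ev <- round(100 * object@explainedVariance, 1)
    cat("  explained variance (%) by component x modality:\n")
    print(utils::head(ev, 10))
})

setMethod("show", "DictionaryModel", function(object) {
    cat(sprintf(
        "DictionaryModel: %d atoms x %d voxels, %d code rows, penalty %.4g\n",
        nrow(object@atoms), ncol(object@atoms), nrow(object@codes),
        object@penalty))
    cat(sprintf("  code sparsity: %.1f%% zeros\n",
                100 * mean(object@codes == 0)))
})

setMethod("show", "AnnotationMap", function(object) {
    cat(sprintf("AnnotationMap: %d terms over a universe of %d genes\n",
                length(object@terms), length(object@universe)))
})

setMethod("show", "ThresholdedMap", function(object) {
    cat(sprintf(
        "ThresholdedMap (component %d): cuts [%.4g, %.4g], %d neg / %d pos of %d voxels\n",
        object@componentId, object@lowCut, object@highCut,
        length(object@negativeVoxels), length(object@positiveVoxels),
        object@nVoxels))
})

setMethod("show", "CrossCorrelationTable", function(object) {
    cat(sprintf(
        "CrossCorrelationTable: %d x %d pairs, %d significant at p < %g\n",
        nrow(object@rho), ncol(object@rho),
        sum(object@significant, na.rm = TRUE), object@alpha))
})
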
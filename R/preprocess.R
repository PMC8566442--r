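# Volumetric preprocessing: masked trilinear downsampling, voxel masking,
# row-major flattening, region-mean imputation and feature subsetting.
# These steps turn 4D feature stacks into the voxel-aligned 2D matrices the
# factorizations consume.

#' Downsample a volume stack by an integer factor
#'
#' Trilinear (continuous) interpolation evaluated at the centres of the
#' coarse-grid cells. Background voxels (holding the sentinel) are excluded
#' from the interpolation support: their weights are zeroed and the remaining
#' weights renormalised, so mask borders are not dragged towards the
#' sentinel. Coarse cells whose entire support is background stay at the
#' sentinel. Trailing partial cells are allowed; output dimensions are
#' \code{ceiling(dim / factor)}.
#'
#' @param vol a \linkS4class{VolumeStack}.
#' @param factor integer downsampling factor, >= 1 (1 is the identity).
#' @return a \linkS4class{VolumeStack} on the coarse grid.
#' @export
downsampleVolume <- function(vol, factor) {
    stopifnot(is(vol, "VolumeStack"))
    if (length(factor) != 1L || factor < 1 || factor != round(factor))
        stop("argument error: factor must be a single integer >= 1")
    factor <- as.integer(factor)
    if (factor == 1L) return(vol)
    bg <- vol@backgroundValue
    d <- dim(vol@data)[2:4]
    outDims <- as.integer(ceiling(d / factor))

    # 0-based fine coordinate of each coarse cell centre, per axis
    axisInterp <- function(nOut, nIn) {
        x <- (seq_len(nOut) - 0.5) * factor - 0.5
        lo <- pmin(pmax(floor(x), 0), nIn - 1)
        hi <- pmin(lo + 1, nIn - 1)
        w <- x - lo                       # weight of hi
        w[hi == lo] <- 0
        list(lo = as.integer(lo) + 1L, hi = as.integer(hi) + 1L, w = w)
    }
    ax <- lapply(seq_len(3), function(a) axisInterp(outDims[a], d[a]))
    gx <- expand.grid(i = seq_len(outDims[1]), j = seq_len(outDims[2]),
                      k = seq_len(outDims[3]))

    R <- dim(vol@data)[1]
    out <- array(bg, c(R, outDims))
    nOut <- nrow(gx)
    for (r in seq_len(R)) {
        v <- vol@data[r, , , ]
        num <- numeric(nOut)
        den <- numeric(nOut)
        for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
            ix <- if (cx == 0) ax[[1]]$lo[gx$i] else ax[[1]]$hi[gx$i]
            iy <- if (cy == 0) ax[[2]]$lo[gx$j] else ax[[2]]$hi[gx$j]
            iz <- if (cz == 0) ax[[3]]$lo[gx$k] else ax[[3]]$hi[gx$k]
            wx <- if (cx == 0) 1 - ax[[1]]$w[gx$i] else ax[[1]]$w[gx$i]
            wy <- if (cy == 0) 1 - ax[[2]]$w[gx$j] else ax[[2]]$w[gx$j]
            wz <- if (cz == 0) 1 - ax[[3]]$w[gx$k] else ax[[3]]$w[gx$k]
            w <- wx * wy * wz
            val <- v[cbind(ix, iy, iz)]
            keep <- val != bg & w > 0
            num[keep] <- num[keep] + w[keep] * val[keep]
            den[keep] <- den[keep] + w[keep]
        }
        slab <- ifelse(den > 0, num / den, bg)
        out[r, , , ] <- array(slab, outDims)
    }
    new("VolumeStack", data = out, featureIds = vol@featureIds,
        backgroundValue = bg, axisOrder = vol@axisOrder,
        voxelSizeUm = vol@voxelSizeUm * factor)
}

#' Build the voxel mask of a volume stack
#'
#' A voxel is in the mask if any feature holds a non-sentinel value there,
#' matching the use of a single shared brain mask across all features.
#'
#' @param vol a \linkS4class{VolumeStack}.
#' @return a \linkS4class{VoxelMask}.
#' @export
buildMask <- function(vol) {
    stopifnot(is(vol, "VolumeStack"))
    grid <- apply(vol@data != vol@backgroundValue, c(2, 3, 4), any)
    if (!any(grid))
        stop("empty-mask error: every voxel holds the background value")
    new("VoxelMask", grid = grid, coords = .rowMajorCoords(grid))
}

#' Flatten a volume stack into a feature-by-voxel matrix
#'
#' Extracts the in-mask voxels of every feature in the row-major order fixed
#' by the mask, yielding voxel-aligned columns across modalities that share
#' the mask. The round trip through \code{\link{unflattenMatrix}} restores
#' in-mask values exactly.
#'
#' @param vol a \linkS4class{VolumeStack} on the mask's grid.
#' @param mask a \linkS4class{VoxelMask}.
#' @param modalityName label stored on the result.
#' @return a \linkS4class{ModalityMatrix}.
#' @export
flattenVolume <- function(vol, mask, modalityName = "modality") {
    stopifnot(is(vol, "VolumeStack"), is(mask, "VoxelMask"))
    if (!identical(dim(vol@data)[2:4], dim(mask@grid)))
        stop("shape error: volume grid does not match mask grid")
    R <- dim(vol@data)[1]
    vals <- matrix(0, R, nrow(mask@coords))
    for (r in seq_len(R))
        vals[r, ] <- vol@data[r, , , ][mask@coords]
    new("ModalityMatrix", values = vals, featureIds = vol@featureIds,
        modalityName = modalityName, mask = mask)
}

#' Restore matrix rows to volume form
#'
#' Inverse of \code{\link{flattenVolume}} on in-mask entries: places each row
#' back onto the 3D grid, with out-of-mask voxels set to \code{background}.
#'
#' @param values numeric matrix (rows x voxels) or a single vector.
#' @param mask the \linkS4class{VoxelMask} the values were flattened with.
#' @param background fill value outside the mask (default -1).
#' @return a 4D array (rows, nx, ny, nz), or a 3D array for vector input.
#' @export
unflattenMatrix <- function(values, mask, background = -1) {
    stopifnot(is(mask, "VoxelMask"))
    vec <- is.null(dim(values))
    values <- rbind(values)
    if (ncol(values) != nrow(mask@coords))
        stop("shape error: values do not match the mask voxel count")
    arr <- .volumize(values, mask@coords, dim(mask@grid), background)
    if (vec) array(arr[1, , , ], dim(mask@grid)) else arr
}

#' Impute missing in-mask values by anatomical region means
#'
#' Sentinel entries of each feature are replaced by the mean of that
#' feature's non-missing values within the same parcellation region. If a
#' feature has no expressed voxel at all in some region, the feature's
#' global in-mask mean is used instead and a warning is raised.
#'
#' @param mat a \linkS4class{ModalityMatrix} whose sentinel entries mark
#'   missing values.
#' @param annot an \linkS4class{AnnotationVolume} covering the mask.
#' @param sentinel the missing-value marker (default -1).
#' @return a \linkS4class{ModalityMatrix} with no sentinel values left; the
#'   operation is idempotent and never alters non-missing entries.
#' @export
imputeMissing <- function(mat, annot, sentinel = -1) {
    stopifnot(is(mat, "ModalityMatrix"), is(annot, "AnnotationVolume"))
    region <- annot@regionId[mat@mask@coords]
    if (any(region == 0L))
        stop("annotation volume does not cover the mask")
    vals <- mat@values
    fellBack <- FALSE
    for (r in seq_len(nrow(vals))) {
        miss <- vals[r, ] == sentinel
        if (!any(miss)) next
        ok <- !miss
        gmean <- mean(vals[r, ok])
        rmeans <- tapply(vals[r, ok], region[ok], mean)
        fill <- rmeans[as.character(region[miss])]
        if (anyNA(fill)) {
            fellBack <- TRUE
            fill[is.na(fill)] <- gmean
        }
        vals[r, miss] <- fill
    }
    if (fellBack)
        warning("some regions had no expressed voxel for a feature; ",
                "global feature means used as fallback")
    initialize(mat, values = vals)
}

#' Subset and reorder the features of a modality matrix
#'
#' @param mat a \linkS4class{ModalityMatrix}.
#' @param ids character vector of feature ids to keep, in the requested
#'   order (e.g. an injection group).
#' @return a \linkS4class{ModalityMatrix} restricted to \code{ids}; the mask
#'   is unchanged.
#' @export
subsetFeatures <- function(mat, ids) {
    stopifnot(is(mat, "ModalityMatrix"))
    idx <- match(ids, mat@featureIds)
    if (anyNA(idx))
        stop("key error: unknown feature ids: ",
             paste(ids[is.na(idx)], collapse = ", "))
    initialize(mat, values = mat@values[idx, , drop = FALSE],
               featureIds = mat@featureIds[idx])
}
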
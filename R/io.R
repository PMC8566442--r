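# Serialization: NIfTI-1 for volumes (uncompressed, so byte-identical
# re-runs are checksummable), TSV for labelled matrices, JSON for structured
# results and GMT for annotation sets. No bespoke binary formats.

#' Write a volume stack as a 4D NIfTI file
#'
#' Spatial axes first, features along the 4th dimension; background voxels
#' keep the sentinel value. A companion \code{<path>.features.txt} stores
#' the feature ids, one per line.
#'
#' @param vol a \linkS4class{VolumeStack}.
#' @param path output path (".nii" recommended; ".nii.gz" also works).
#' @return the path, invisibly.
#' @export
writeVolumeStack <- function(vol, path) {
    stopifnot(is(vol, "VolumeStack"))
    arr <- aperm(vol@data, c(2, 3, 4, 1))
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "double"), path)
    writeLines(vol@featureIds, paste0(path, ".features.txt"))
    invisible(path)
}

#' Read a volume stack from a 4D NIfTI file
#'
#' @param path NIfTI path written by \code{\link{writeVolumeStack}}.
#' @param backgroundValue sentinel (default -1).
#' @return a \linkS4class{VolumeStack}.
#' @export
readVolumeStack <- function(path, backgroundValue = -1) {
    arr <- as.array(RNifti::readNifti(path))
    if (length(dim(arr)) == 3L) dim(arr) <- c(dim(arr), 1L)
    arr <- aperm(arr, c(4, 1, 2, 3))
    fIdsPath <- paste0(path, ".features.txt")
    featureIds <- if (file.exists(fIdsPath)) readLines(fIdsPath)
                  else sprintf("f%03d", seq_len(dim(arr)[1]))
    new("VolumeStack", data = arr, featureIds = featureIds,
        backgroundValue = backgroundValue,
        axisOrder = c("P-A", "I-S", "R-L"), voxelSizeUm = NA_real_)
}

#' Write a voxel mask as an integer NIfTI volume
#' @param mask a \linkS4class{VoxelMask}.
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeMask <- function(mask, path) {
    stopifnot(is(mask, "VoxelMask"))
    arr <- array(0L, dim(mask@grid))
    arr[mask@grid] <- 1L
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"), path)
    invisible(path)
}

#' Read a voxel mask from a NIfTI volume
#' @param path NIfTI path; non-zero voxels are in-mask.
#' @return a \linkS4class{VoxelMask}.
#' @export
readMask <- function(path) {
    grid <- as.array(RNifti::readNifti(path)) != 0
    new("VoxelMask", grid = grid, coords = .rowMajorCoords(grid))
}

#' Write an annotation volume (parcellation) as NIfTI plus a region table
#' @param annot an \linkS4class{AnnotationVolume}.
#' @param path NIfTI output path; region names go to \code{<path>.regions.tsv}.
#' @return the path, invisibly.
#' @export
writeAnnotationVolume <- function(annot, path) {
    stopifnot(is(annot, "AnnotationVolume"))
    arr <- annot@regionId
    storage.mode(arr) <- "integer"
    RNifti::writeNifti(RNifti::asNifti(arr, datatype = "int32"), path)
    write.table(data.frame(region = names(annot@regionNames),
                           name = unname(annot@regionNames)),
                paste0(path, ".regions.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    invisible(path)
}

#' Read an annotation volume written by \code{\link{writeAnnotationVolume}}
#' @param path NIfTI path.
#' @return an \linkS4class{AnnotationVolume}.
#' @export
readAnnotationVolume <- function(path) {
    img <- RNifti::readNifti(path)
    arr <- array(as.integer(img), dim = dim(img))
    tab <- read.delim(paste0(path, ".regions.tsv"),
                      colClasses = c("character", "character"))
    new("AnnotationVolume", regionId = arr,
        regionNames = setNames(tab$name, tab$region))
}

#' Write a fitted decomposition as a directory bundle
#'
#' Spatial maps become a 4D NIfTI (one volume per component, via the mask);
#' feature coefficients and modality weights are TSV with feature labels;
#' configuration, free-energy trace, convergence flag, explained variance
#' and noise precisions go to a JSON file.
#'
#' @param object a \linkS4class{LinkedDecomposition}.
#' @param dir output directory (created if needed).
#' @param mask the \linkS4class{VoxelMask} the fit's voxels refer to.
#' @return the directory, invisibly.
#' @export
writeDecomposition <- function(object, dir, mask) {
    stopifnot(is(object, "LinkedDecomposition"), is(mask, "VoxelMask"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    vols <- unflattenMatrix(object@H, mask, background = 0)
    RNifti::writeNifti(RNifti::asNifti(aperm(vols, c(2, 3, 4, 1)),
                                       datatype = "double"),
                       file.path(dir, "spatial_maps.nii"))
    for (k in seq_along(object@X)) {
        nm <- object@modalityNames[k]
        X <- object@X[[k]]
        colnames(X) <- sprintf("comp%02d", seq_len(ncol(X)))
        write.table(data.frame(feature = object@featureIds[[k]], X),
                    file.path(dir, sprintf("coefficients_%s.tsv", nm)),
                    sep = "\t", quote = FALSE, row.names = FALSE)
    }
    W <- do.call(cbind, object@W)
    colnames(W) <- object@modalityNames
    write.table(data.frame(component = seq_len(nrow(W)), W),
                file.path(dir, "weights.tsv"), sep = "\t", quote = FALSE,
                row.names = FALSE)
    meta <- list(
        L = object@config@L, maxIter = object@config@maxIter,
        relTol = object@config@relTol, seed = object@config@seed,
        dofScale = object@config@dofScale,
        mogComponents = object@config@mogComponents,
        init = object@config@init, converged = object@converged,
        iterations = length(object@freeEnergy),
        freeEnergy = object@freeEnergy,
        noisePrecision = as.list(object@noisePrecision),
        explainedVariance = object@explainedVariance,
        componentOrder = object@componentOrder,
        modalityNames = object@modalityNames)
    jsonlite::write_json(meta, file.path(dir, "model.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    invisible(dir)
}

#' Write the ground truth of a synthetic dataset
#'
#' Scalars and weight vectors go to \code{truth.json}; the source and
#' coefficient matrices to TSV files next to it.
#'
#' @param truth a \linkS4class{GroundTruth}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
writeGroundTruth <- function(truth, dir) {
    stopifnot(is(truth, "GroundTruth"))
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
        list(W = truth@W, noiseSd = truth@noiseSd,
             signalVar = truth@signalVar, noiseVar = truth@noiseVar,
             seed = truth@seed, L = nrow(truth@H)),
        file.path(dir, "truth.json"), digits = NA, pretty = TRUE)
    write.table(truth@H, file.path(dir, "truth_H.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    for (k in seq_along(truth@X))
        write.table(truth@X[[k]],
                    file.path(dir, sprintf("truth_X_%d.tsv", k)),
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    invisible(dir)
}

#' Read a ground truth bundle written by \code{\link{writeGroundTruth}}
#' @param dir bundle directory.
#' @return a \linkS4class{GroundTruth}.
#' @export
readGroundTruth <- function(dir) {
    meta <- jsonlite::read_json(file.path(dir, "truth.json"),
                                simplifyVector = TRUE)
    H <- as.matrix(read.delim(file.path(dir, "truth_H.tsv"),
                              header = FALSE))
    dimnames(H) <- NULL
    W <- if (is.list(meta$W)) lapply(meta$W, as.numeric)
         else lapply(seq_len(nrow(meta$W)), function(k)
                  as.numeric(meta$W[k, ]))
    K <- length(W)
    X <- lapply(seq_len(K), function(k) {
        m <- as.matrix(read.delim(file.path(dir, sprintf("truth_X_%d.tsv",
                                                         k)),
                                  header = FALSE))
        dimnames(m) <- NULL
        m
    })
    new("GroundTruth", H = H, X = X, W = W,
        noiseSd = as.numeric(meta$noiseSd),
        signalVar = as.numeric(meta$signalVar),
        noiseVar = as.numeric(meta$noiseVar),
        seed = as.integer(meta$seed))
}
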
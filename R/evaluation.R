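# Reconstruction and comparison metrics: the coefficient of determination
# aggregated over all entries of a modality, mean squared error, and the
# cross-method comparison harness between linked ICA and DLSC fits.

#' Coefficient of determination of a reconstruction
#'
#' r^2 = 1 - sum((y - f)^2) / sum((y - mean(y))^2), summed over all entries
#' (voxels x features) of the modality: the fraction of total variance of
#' the original data explained by the reconstruction.
#'
#' @param y numeric vector or matrix of original values (non-constant).
#' @param f reconstruction of the same shape.
#' @return a single r-squared value (at most 1).
#' @export
rSquared <- function(y, f) {
    y <- as.numeric(y)
    f <- as.numeric(f)
    if (length(y) != length(f)) stop("shape error: unequal lengths")
    tss <- sum((y - mean(y))^2)
    if (tss == 0) stop("r-squared undefined for constant data")
    1 - sum((y - f)^2) / tss
}

#' Mean squared error of a reconstruction
#'
#' @param y numeric vector or matrix of original values.
#' @param f reconstruction of the same shape.
#' @return mean of squared residuals.
#' @export
mse <- function(y, f) {
    y <- as.numeric(y)
    f <- as.numeric(f)
    if (length(y) != length(f)) stop("shape error: unequal lengths")
    mean((y - f)^2)
}

# reconstruction of one modality from a dictionary model, rows restricted
# to that modality's feature split
.dlscReconstruct <- function(dict, k) {
    rows <- dict@featureSplit[[k]]
    dict@codes[rows, , drop = FALSE] %*% dict@atoms
}

#' Compare linked ICA and DLSC factorizations
#'
#' Computes per-method, per-modality reconstruction r^2 and MSE on the
#' z-scored data, plus Pearson cross-correlation tables between the linked
#' components and every dictionary at the spatial-map level and (for
#' dictionaries covering a modality) at the coefficient level.
#'
#' @param linked a fitted \linkS4class{LinkedDecomposition}.
#' @param dicts named list of \linkS4class{DictionaryModel} fits. Exclusive
#'   fits cover one modality; a concat fit covers all.
#' @param modalities list of \linkS4class{ModalityMatrix} objects or
#'   matrices, the data all fits were trained on.
#' @return list with \code{metrics} (data.frame method, modality, r2, mse),
#'   \code{spatialCor} (list of \linkS4class{CrossCorrelationTable}) and
#'   \code{coefCor}.
#' @export
compareMethods <- function(linked, dicts, modalities) {
    stopifnot(is(linked, "LinkedDecomposition"))
    if (!is.list(modalities)) modalities <- list(modalities)
    Ys <- lapply(.asValuesList(modalities), .zscoreRows)
    modNames <- linked@modalityNames
    K <- length(Ys)
    if (any(vapply(Ys, ncol, integer(1)) != ncol(linked@H)))
        stop("shape error: voxel dimensions differ between fits and data")

    rows <- list()
    for (k in seq_len(K)) {
        rec <- reconstruct(linked, k)
        rows[[length(rows) + 1L]] <- data.frame(
            method = "linked_ica", modality = modNames[k],
            r2 = rSquared(Ys[[k]], rec), mse = mse(Ys[[k]], rec))
    }
    spatialCor <- coefCor <- list()
    for (nm in names(dicts)) {
        dict <- dicts[[nm]]
        for (k in seq_along(dict@featureSplit)) {
            mk <- match(dict@modalityNames[k], modNames)
            if (is.na(mk))
                stop("dictionary modality '", dict@modalityNames[k],
                     "' not present in the linked fit")
            rec <- .dlscReconstruct(dict, k)
            rows[[length(rows) + 1L]] <- data.frame(
                method = nm, modality = modNames[mk],
                r2 = rSquared(Ys[[mk]], rec), mse = mse(Ys[[mk]], rec))
            coefCor[[paste(nm, modNames[mk], sep = ".")]] <-
                crossCorrelate(t(linked@X[[mk]]),
                               t(dict@codes[dict@featureSplit[[k]], ,
                                            drop = FALSE]))
        }
        spatialCor[[nm]] <- crossCorrelate(linked@H, dict@atoms)
    }
    list(metrics = do.call(rbind, rows), spatialCor = spatialCor,
         coefCor = coefCor)
}
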
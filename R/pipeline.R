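# Pipeline glue: dataset bundles on disk, a validated pipeline
# configuration, and the end-to-end run (preprocess -> linked ICA ->
# component analysis -> enrichment -> DLSC comparison -> reports). Every
# output is reproducible from (bundle, config, seed); a manifest records
# checksums of everything written.

#' Validated pipeline configuration
#'
#' Unknown options are rejected up front, before any computation.
#'
#' @param L number of linked ICA components.
#' @param maxIter,relTol VB iteration cap and convergence tolerance.
#' @param seed integer seed used for the fit and the DLSC comparisons.
#' @param impute logical; impute missing (-1) in-mask values of modality 1
#'   by region means before fitting.
#' @param coiFloor relative-contribution floor for components of interest.
#' @param lowPct,highPct thresholding percentiles for maps and coefficients.
#' @param dlscAtoms number of dictionary atoms (default: L).
#' @param dlscPenalty L1 penalty (NULL = data-driven default).
#' @param enrichAlpha fixed p-value cutoff for enrichment significance.
#' @param ... unknown options (an error).
#' @return a named list of validated options.
#' @export
pipelineConfig <- function(L, maxIter = 3000L, relTol = 1e-6, seed = 1L,
                           impute = TRUE, coiFloor = 0.01, lowPct = 1,
                           highPct = 99, dlscAtoms = NULL,
                           dlscPenalty = NULL, enrichAlpha = 3.8e-5, ...) {
    extra <- list(...)
    if (length(extra) > 0)
        stop("validation error: unknown pipeline options: ",
             paste(names(extra), collapse = ", "))
    if (length(L) != 1L || is.na(L) || L < 1)
        stop("validation error: L must be a positive integer")
    if (maxIter < 1) stop("validation error: maxIter must be >= 1")
    if (relTol <= 0) stop("validation error: relTol must be positive")
    list(L = as.integer(L), maxIter = as.integer(maxIter), relTol = relTol,
         seed = as.integer(seed), impute = isTRUE(impute),
         coiFloor = coiFloor, lowPct = lowPct, highPct = highPct,
         dlscAtoms = if (is.null(dlscAtoms)) as.integer(L)
                     else as.integer(dlscAtoms),
         dlscPenalty = dlscPenalty, enrichAlpha = enrichAlpha)
}

.manifest <- function(dir, files, params = list()) {
    info <- lapply(files, function(f) {
        list(file = f, md5 = unname(tools::md5sum(file.path(dir, f))),
             bytes = file.size(file.path(dir, f)))
    })
    jsonlite::write_json(list(params = params, files = info),
                         file.path(dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    file.path(dir, "manifest.json")
}

#' Generate a synthetic dataset bundle on disk
#'
#' Writes the modality volumes, mask and parcellation as NIfTI, the ground
#' truth as a JSON + TSV bundle, a GMT annotation universe with terms
#' planted from the top modality-1 coefficients of the first components
#' (so downstream enrichment has recoverable signal), and a manifest with
#' checksums.
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @param outdir output directory (created).
#' @param nTerms number of annotation terms in the universe.
#' @param plantedSize genes per planted term.
#' @return invisibly, the manifest path.
#' @export
generateDatasetBundle <- function(spec, outdir, nTerms = 30L,
                                  plantedSize = 10L) {
    ds <- generateLinkedDataset(spec)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    files <- character(0)
    for (k in seq_along(ds$volumes)) {
        f <- sprintf("modality_%d_%s.nii", k, names(ds$volumes)[k])
        writeVolumeStack(ds$volumes[[k]], file.path(outdir, f))
        files <- c(files, f, paste0(f, ".features.txt"))
    }
    writeMask(ds$mask, file.path(outdir, "mask.nii"))
    writeAnnotationVolume(ds$annotation, file.path(outdir, "annotation.nii"))
    writeGroundTruth(ds$truth, outdir)
    files <- c(files, "mask.nii", "annotation.nii",
               "annotation.nii.regions.tsv", "truth.json", "truth_H.tsv",
               sprintf("truth_X_%d.tsv", seq_along(ds$truth@X)))
    # annotation universe: plant one term per leading component, made of the
    # genes with the largest absolute coefficients on that component
    genes <- ds$volumes[[1]]@featureIds
    planted <- list()
    for (i in seq_len(min(2L, nrow(ds$truth@H)))) {
        top <- order(abs(ds$truth@X[[1]][, i]),
                     decreasing = TRUE)[seq_len(plantedSize)]
        planted[[sprintf("planted_comp_%d", i)]] <- genes[top]
    }
    universe <- generateAnnotationUniverse(
        nGenes = length(genes), nTerms = nTerms, planted = planted,
        sizeRange = c(5L, min(20L, length(genes))), seed = spec@seed + 1L,
        universe = genes)
    writeGMT(universe, file.path(outdir, "universe.gmt"))
    files <- c(files, "universe.gmt")
    mf <- .manifest(outdir, files,
                    params = list(gridDims = spec@gridDims,
                                  maskFill = spec@maskFill, L = spec@L,
                                  R = spec@R, snr = spec@snr,
                                  sourceSparsity = spec@sourceSparsity,
                                  missingFraction = spec@missingFraction,
                                  nRegions = spec@nRegions,
                                  seed = spec@seed))
    invisible(mf)
}

#' Read a dataset bundle written by \code{\link{generateDatasetBundle}}
#'
#' @param dir bundle directory.
#' @return list with \code{volumes}, \code{mask}, \code{annotation},
#'   \code{truth} (if present) and \code{universe} (if present).
#' @export
readDatasetBundle <- function(dir) {
    volFiles <- sort(list.files(dir, pattern = "^modality_\\d+_.*\\.nii$"))
    if (length(volFiles) == 0)
        stop("no modality volumes found in ", dir)
    volumes <- lapply(volFiles, function(f)
        readVolumeStack(file.path(dir, f)))
    names(volumes) <- sub("^modality_\\d+_(.*)\\.nii$", "\\1", volFiles)
    out <- list(volumes = volumes,
                mask = readMask(file.path(dir, "mask.nii")),
                annotation = readAnnotationVolume(file.path(dir,
                                                            "annotation.nii")))
    if (file.exists(file.path(dir, "truth.json")))
        out$truth <- readGroundTruth(dir)
    if (file.exists(file.path(dir, "universe.gmt")))
        out$universe <- readGMT(file.path(dir, "universe.gmt"))
    out
}

# genes whose component coefficients fall outside the low/high percentile
# band, aggregated over the components of interest
.selectQueryGenes <- function(fit, coi, lowPct, highPct) {
    X1 <- fit@X[[1]]
    sel <- character(0)
    for (i in coi) {
        cuts <- quantile(X1[, i], c(lowPct, highPct) / 100, names = FALSE)
        keep <- X1[, i] < cuts[1] | X1[, i] > cuts[2]
        sel <- union(sel, fit@featureIds[[1]][keep])
    }
    sel
}

#' Run the full analysis pipeline on a dataset bundle
#'
#' Preprocesses (mask, flatten, optional imputation), fits linked ICA, runs
#' the component analyses (thresholding, dominance, region summaries),
#' enrichment of the selected genes against the bundle's annotation
#' universe, the DLSC comparison fits and the cross-method report, and
#' writes every stage's outputs plus a checksum manifest to \code{outdir}.
#'
#' @param bundle a bundle directory path, or the list returned by
#'   \code{\link{generateLinkedDataset}} /
#'   \code{\link{readDatasetBundle}}.
#' @param config a \code{\link{pipelineConfig}} list.
#' @param outdir output directory.
#' @return invisibly, a list with the fitted objects and result tables
#'   (elements \code{fit}, \code{coi}, \code{thresholds},
#'   \code{regionSummaries}, \code{enrichment}, \code{dlsc},
#'   \code{comparison}, \code{recovery}, \code{manifest}).
#' @export
runPipeline <- function(bundle, config, outdir) {
    if (is.character(bundle)) bundle <- readDatasetBundle(bundle)
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    mask <- bundle$mask
    mats <- lapply(seq_along(bundle$volumes), function(k)
        flattenVolume(bundle$volumes[[k]], mask,
                      modalityName = names(bundle$volumes)[k]))
    if (config$impute && !is.null(bundle$annotation))
        mats[[1]] <- imputeMissing(mats[[1]], bundle$annotation)

    fit <- fitLinkedICA(mats, linkedICAConfig(
        L = config$L, maxIter = config$maxIter, relTol = config$relTol,
        seed = config$seed))
    writeDecomposition(fit, file.path(outdir, "linked_ica"), mask)
    files <- file.path("linked_ica",
                       list.files(file.path(outdir, "linked_ica")))

    coi <- selectComponentsOfInterest(fit, floor = config$coiFloor)
    thresholds <- lapply(seq_len(config$L), function(i)
        thresholdMap(fit@H[i, ], config$lowPct, config$highPct,
                     componentId = i))
    thrTab <- do.call(rbind, lapply(thresholds, function(tm)
        data.frame(component = tm@componentId, lowCut = tm@lowCut,
                   highCut = tm@highCut,
                   nNegative = length(tm@negativeVoxels),
                   nPositive = length(tm@positiveVoxels))))
    write.table(thrTab, file.path(outdir, "thresholds.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    files <- c(files, "thresholds.tsv")

    regionTabs <- do.call(rbind, lapply(coi, function(i) {
        rs <- regionSummary(thresholds[[i]], bundle$annotation, mask)
        if (nrow(rs)) cbind(component = i, rs) else NULL
    }))
    if (!is.null(regionTabs)) {
        write.table(regionTabs, file.path(outdir, "region_summary.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, "region_summary.tsv")
    }

    enrichment <- NULL
    if (!is.null(bundle$universe) && length(coi) > 0) {
        query <- .selectQueryGenes(fit, coi, config$lowPct, config$highPct)
        enrichment <- enrich(query, bundle$universe,
                             alpha = config$enrichAlpha)
        write.table(enrichment, file.path(outdir, "enrichment.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, "enrichment.tsv")
    }

    dlsc <- list()
    for (k in seq_along(mats))
        dlsc[[paste0("exclusive_", fit@modalityNames[k])]] <-
            fitDLSCExclusive(mats[[k]], nAtoms = config$dlscAtoms,
                             penalty = config$dlscPenalty,
                             seed = config$seed)
    dlsc$concat <- fitDLSCConcat(mats, nAtoms = config$dlscAtoms,
                                 penalty = config$dlscPenalty,
                                 seed = config$seed)
    comparison <- compareMethods(fit, dlsc, mats)
    write.table(comparison$metrics, file.path(outdir, "comparison.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, "comparison.tsv")

    recovery <- NULL
    if (!is.null(bundle$truth)) {
        recovery <- matchedRecoveryScore(fit@H, bundle$truth@H)
        write.table(recovery$matching, file.path(outdir, "recovery.tsv"),
                    sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, "recovery.tsv")
    }

    report <- list(
        converged = fit@converged, iterations = length(fit@freeEnergy),
        finalFreeEnergy = tail(fit@freeEnergy, 1),
        componentsOfInterest = coi,
        explainedVariance = fit@explainedVariance,
        meanMatchedAbsRho = if (!is.null(recovery)) recovery$meanAbsRho
                            else NULL,
        config = config)
    jsonlite::write_json(report, file.path(outdir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <- c(files, "report.json")
    mf <- .manifest(outdir, files, params = config)
    invisible(list(fit = fit, coi = coi, thresholds = thresholds,
                   regionSummaries = regionTabs, enrichment = enrichment,
                   dlsc = dlsc, comparison = comparison,
                   recovery = recovery, manifest = mf))
}
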
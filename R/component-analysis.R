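# Post-hoc analysis of factorizations: percentile thresholding of spatial
# maps, component-of-interest selection, modality-dominance labelling,
# cross-factorization Pearson statistics, per-region summaries and the
# recovery-matching harness used against planted ground truth.

#' Threshold a spatial map at low/high percentiles
#'
#' Values between the percentile cuts are treated as zero; voxels below the
#' low cut form the negative set and voxels above the high cut the positive
#' set, highlighting the locations most involved in a component. Percentiles
#' use the linear-interpolation convention between order statistics
#' (\code{quantile} type 7).
#'
#' @param mapValues numeric length-N vector of spatial map values.
#' @param lowPct,highPct percentile cuts (defaults 1 and 99).
#' @param componentId integer id stored on the result.
#' @param zScored logical flag stored on the result.
#' @return a \linkS4class{ThresholdedMap}.
#' @export
thresholdMap <- function(mapValues, lowPct = 1, highPct = 99,
                         componentId = 1L, zScored = FALSE) {
    n <- length(mapValues)
    if (n < 100L)
        warning("fewer than 100 voxels: 1/99 percentiles are not meaningful")
    if (max(mapValues) == min(mapValues)) {
        warning("constant map: threshold sets are empty")
        return(new("ThresholdedMap", componentId = as.integer(componentId),
                   lowCut = mapValues[1], highCut = mapValues[1],
                   negativeVoxels = integer(0), positiveVoxels = integer(0),
                   nVoxels = as.integer(n), zScored = zScored))
    }
    cuts <- quantile(mapValues, c(lowPct, highPct) / 100, names = FALSE,
                     type = 7)
    new("ThresholdedMap", componentId = as.integer(componentId),
        lowCut = cuts[1], highCut = cuts[2],
        negativeVoxels = which(mapValues < cuts[1]),
        positiveVoxels = which(mapValues > cuts[2]),
        nVoxels = as.integer(n), zScored = zScored)
}

#' Select components with non-zero contribution from every modality
#'
#' Components of interest are those whose relative explained-variance
#' contribution exceeds a floor (default 1\%) in every modality; components
#' driven by a single modality are excluded.
#'
#' @param object a fitted \linkS4class{LinkedDecomposition}.
#' @param floor minimum relative contribution per modality (0 returns all
#'   components).
#' @return integer vector of component ids (possibly empty).
#' @export
selectComponentsOfInterest <- function(object, floor = 0.01) {
    stopifnot(is(object, "LinkedDecomposition"))
    rel <- explainedVariance(object, relative = TRUE)
    which(apply(rel >= floor, 1, all))
}

#' Label thresholded voxels by modality dominance
#'
#' For each selected voxel j of component i, the per-modality reconstruction
#' energy e_k(j) = sum_r (X^k_{r,i} W^k_i H_{i,j})^2 is compared between the
#' first two modalities: a voxel is gene-dominated if e_1/e_2 exceeds
#' \code{ratioCut}, projection-dominated if e_2/e_1 exceeds it, and shared
#' otherwise (modality 1 plays the gene-expression role, modality 2 the
#' projection-density role). Voxels with zero energy in both modalities are
#' dropped with a warning. Labels are invariant to joint rescaling of both
#' modalities.
#'
#' @param object a fitted \linkS4class{LinkedDecomposition}.
#' @param component component id.
#' @param thresholded the \linkS4class{ThresholdedMap} of that component.
#' @param ratioCut energy-ratio cut (default 2).
#' @return a \linkS4class{DominanceMap}.
#' @export
dominanceLabels <- function(object, component, thresholded, ratioCut = 2) {
    stopifnot(is(object, "LinkedDecomposition"),
              is(thresholded, "ThresholdedMap"))
    vox <- sort(c(thresholded@negativeVoxels, thresholded@positiveVoxels))
    h <- object@H[component, vox]
    e <- vapply(1:2, function(k) {
        sum(object@X[[k]][, component]^2) * object@W[[k]][component]^2 * h^2
    }, numeric(length(vox)))
    e <- matrix(e, ncol = 2)
    dead <- e[, 1] == 0 & e[, 2] == 0
    if (any(dead)) {
        warning(sum(dead), " voxel(s) with zero energy in both modalities ",
                "dropped")
        vox <- vox[!dead]
        e <- e[!dead, , drop = FALSE]
    }
    lab <- rep("shared", length(vox))
    lab[e[, 1] > ratioCut * e[, 2]] <- "gene_dominated"
    lab[e[, 2] > ratioCut * e[, 1]] <- "projection_dominated"
    new("DominanceMap", voxels = as.integer(vox),
        labels = factor(lab, levels = c("shared", "gene_dominated",
                                        "projection_dominated")),
        ratioCut = ratioCut)
}

# Pearson correlation with a two-sided p-value from the t distribution.
.pearsonWithP <- function(x, y) {
    n <- length(x)
    if (sd(x) == 0 || sd(y) == 0) return(c(NA_real_, NA_real_))
    r <- cor(x, y)
    if (abs(r) >= 1) return(c(r, 0))
    t <- r * sqrt((n - 2) / (1 - r^2))
    c(r, 2 * pt(-abs(t), df = n - 2))
}

#' Pairwise Pearson correlations between two sets of maps or coefficients
#'
#' Correlates every row of \code{mapsA} with every row of \code{mapsB} over
#' their shared columns (voxels for spatial maps, features for coefficient
#' vectors), reporting Pearson's rho, the two-sided p-value and a
#' significance flag at \code{alpha} (default 0.004, the cross-factorization
#' comparison level). Zero-variance vectors yield missing entries.
#'
#' @param mapsA,mapsB numeric matrices with compared vectors in rows.
#' @param alpha significance level.
#' @return a \linkS4class{CrossCorrelationTable}.
#' @export
crossCorrelate <- function(mapsA, mapsB, alpha = 0.004) {
    mapsA <- rbind(mapsA)
    mapsB <- rbind(mapsB)
    if (ncol(mapsA) != ncol(mapsB))
        stop("shape error: compared maps must share their column dimension")
    nA <- nrow(mapsA)
    nB <- nrow(mapsB)
    rho <- p <- matrix(NA_real_, nA, nB,
                       dimnames = list(rownames(mapsA), rownames(mapsB)))
    for (i in seq_len(nA)) for (j in seq_len(nB)) {
        rp <- .pearsonWithP(mapsA[i, ], mapsB[j, ])
        rho[i, j] <- rp[1]
        p[i, j] <- rp[2]
    }
    new("CrossCorrelationTable", rho = rho, p = p, alpha = alpha,
        significant = !is.na(p) & p < alpha)
}

#' Summarise a thresholded selection by parcellation region
#'
#' Counts the selected (supra-threshold) voxels inside every region of a
#' parcellation and reports their share of each region's in-mask volume, the
#' per-region statistic used to characterise a component's anatomy.
#'
#' @param thresholded a \linkS4class{ThresholdedMap}.
#' @param annot an \linkS4class{AnnotationVolume}.
#' @param mask the \linkS4class{VoxelMask} the map was flattened with.
#' @return data.frame with columns region, regionName, nSelected,
#'   regionVoxels, pctOfRegion; regions without selected voxels are omitted.
#' @export
regionSummary <- function(thresholded, annot, mask) {
    stopifnot(is(thresholded, "ThresholdedMap"),
              is(annot, "AnnotationVolume"), is(mask, "VoxelMask"))
    region <- annot@regionId[mask@coords]
    sel <- c(thresholded@negativeVoxels, thresholded@positiveVoxels)
    if (length(sel) == 0)
        return(data.frame(region = integer(0), regionName = character(0),
                          nSelected = integer(0), regionVoxels = integer(0),
                          pctOfRegion = numeric(0)))
    cnt <- table(region[sel])
    tot <- table(region)
    ids <- as.integer(names(cnt))
    data.frame(
        region = ids,
        regionName = unname(annot@regionNames[as.character(ids)]),
        nSelected = as.integer(cnt),
        regionVoxels = as.integer(tot[names(cnt)]),
        pctOfRegion = 100 * as.integer(cnt) / as.integer(tot[names(cnt)]),
        row.names = NULL)
}

#' Match estimated spatial maps against reference maps
#'
#' Greedy assignment maximising total absolute Pearson correlation between
#' the rows of two map matrices (rectangular matching allowed), the recovery
#' score used to validate fits against planted ground truth. The score is
#' invariant to component permutation and sign flips.
#'
#' @param estimated,reference numeric matrices of maps in rows, sharing N.
#' @return list with \code{matching} (data.frame estimated, reference,
#'   absRho), \code{perComponent} absolute correlations and \code{meanAbsRho}.
#' @export
matchedRecoveryScore <- function(estimated, reference) {
    estimated <- rbind(estimated)
    reference <- rbind(reference)
    if (ncol(estimated) != ncol(reference))
        stop("shape error: maps must share the voxel dimension")
    cm <- abs(cor(t(estimated), t(reference)))
    nPair <- min(nrow(estimated), nrow(reference))
    est <- ref <- integer(nPair)
    rho <- numeric(nPair)
    work <- cm
    for (p in seq_len(nPair)) {
        ij <- arrayInd(which.max(work), dim(work))
        est[p] <- ij[1]
        ref[p] <- ij[2]
        rho[p] <- cm[ij[1], ij[2]]
        work[ij[1], ] <- -Inf
        work[, ij[2]] <- -Inf
    }
    ord <- order(ref)
    matching <- data.frame(estimated = est[ord], reference = ref[ord],
                           absRho = rho[ord])
    list(matching = matching, perComponent = matching$absRho,
         meanAbsRho = mean(rho))
}
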
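# Dictionary learning and sparse coding over voxels.
#
# Alternating minimisation of
#   0.5 * || Y - C A ||_F^2 + penalty * || C ||_1
# with spatial atoms A (D x N, unit-norm rows) and sparse codes C (R x D).
# The sparse-coding step solves the row-wise lasso exactly by cyclic
# coordinate descent (vectorised across rows); the dictionary step minimises
# over each unit-norm atom with the codes fixed. Both half-steps solve their
# subproblem exactly, so the objective trace is non-increasing — a tested
# contract. "Exclusive" fits decompose one modality; "concat" fits stack the
# feature rows of all modalities along the shared voxel dimension before
# fitting a single dictionary.

# Exact row-wise lasso by cyclic coordinate descent, all rows at once.
# G = A A', B = Y A'. Returns the code matrix C.
.lassoCodes <- function(B, G, penalty, C, maxIter = 200L, tol = 1e-10) {
    D <- ncol(B)
    if (penalty == 0) {
        Gr <- G
        diag(Gr) <- diag(Gr) + 1e-12 * mean(diag(G))
        return(B %*% chol2inv(chol(Gr)))
    }
    for (it in seq_len(maxIter)) {
        delta <- 0
        for (d in seq_len(D)) {
            rho <- B[, d] - C %*% G[, d] + C[, d] * G[d, d]
            cd <- sign(rho) * pmax(abs(rho) - penalty, 0) / G[d, d]
            delta <- max(delta, max(abs(cd - C[, d])))
            C[, d] <- cd
        }
        if (delta < tol) break
    }
    C
}

.dlscObjective <- function(Y, C, A, penalty) {
    0.5 * sum((Y - C %*% A)^2) + penalty * sum(abs(C))
}

.zscoreRows <- function(Y) {
    scl <- apply(Y, 1, sd)
    if (any(scl == 0)) stop("data error: zero-variance feature row(s)")
    (Y - rowMeans(Y)) / scl
}

.fitDLSC <- function(Y, nAtoms, penalty, seed, maxIter, tol,
                     penaltyFactor = 0.55) {
    N <- ncol(Y)
    set.seed(seed)
    sv <- svd(Y, nu = 0, nv = nAtoms)
    # varimax-rotate the leading right singular vectors: a plain SVD basis
    # is an arbitrary rotation of any sparse structure, while the rotated
    # basis concentrates atom energy and starts the alternation near sparse
    # spatial configurations
    V <- sv$v
    if (nAtoms > 1L) V <- V %*% stats::varimax(V, normalize = FALSE)$rotmat
    A <- t(V)
    A <- A / sqrt(rowSums(A^2))
    if (is.null(penalty)) {
        # data-driven penalty: a fraction of the median (over feature rows)
        # of the smallest penalty that zeroes that row's codes. The default
        # factor 0.55 makes codes come out strongly sparse on
        # blob-structured fixtures; small factors (~0.03) keep just enough
        # L1 pressure to break rotational invariance with minimal
        # shrinkage, which preserves atom-to-source alignment when the
        # true codes are dense.
        lamMax <- apply(abs(Y %*% t(A)), 1, max)
        penalty <- penaltyFactor * median(lamMax)
    }
    if (penalty < 0) stop("argument error: penalty must be non-negative")
    C <- matrix(0, nrow(Y), nAtoms)
    G <- tcrossprod(A)
    C <- .lassoCodes(Y %*% t(A), G, penalty, C)
    obj <- .dlscObjective(Y, C, A, penalty)
    trace <- obj
    for (it in seq_len(maxIter)) {
        # dictionary update: exact minimiser per unit-norm atom, codes fixed
        CtY <- crossprod(C, Y)
        M <- crossprod(C)
        for (d in seq_len(nAtoms)) {
            v <- CtY[d, ] - M[d, ] %*% A + M[d, d] * A[d, ]
            nv <- sqrt(sum(v^2))
            if (nv > 1e-12) A[d, ] <- v / nv
        }
        # sparse coding: exact row-wise lasso given the dictionary
        G <- tcrossprod(A)
        C <- .lassoCodes(Y %*% t(A), G, penalty, C)
        objNew <- .dlscObjective(Y, C, A, penalty)
        trace <- c(trace, objNew)
        if (abs(obj - objNew) < tol * max(1, abs(obj))) {
            obj <- objNew
            break
        }
        obj <- objNew
    }
    list(atoms = A, codes = C, penalty = penalty, objective = trace)
}

#' Fit an exclusive (single-modality) DLSC factorization
#'
#' @param mat a \linkS4class{ModalityMatrix} or a feature-by-voxel matrix;
#'   feature rows are z-scored before fitting.
#' @param nAtoms number of dictionary atoms (defaults comparable to the
#'   linked ICA component count are typical).
#' @param penalty L1 sparsity weight; \code{NULL} picks a data-driven
#'   default, \code{penaltyFactor} times the median over feature rows of
#'   the smallest penalty zeroing that row's codes.
#' @param seed integer seed.
#' @param maxIter,tol outer-loop iteration cap and relative objective
#'   tolerance.
#' @param penaltyFactor scale of the data-driven default penalty; the
#'   default 0.55 yields strongly sparse codes, while small values (around
#'   0.03) retain just enough sparsity pressure to orient atoms and are
#'   preferable when comparing atoms against densely loaded sources.
#' @return a \linkS4class{DictionaryModel}.
#' @export
fitDLSCExclusive <- function(mat, nAtoms, penalty = NULL, seed = 1L,
                             maxIter = 100L, tol = 1e-8,
                             penaltyFactor = 0.55) {
    Y <- if (is(mat, "ModalityMatrix")) mat@values else as.matrix(mat)
    ids <- if (is(mat, "ModalityMatrix")) mat@featureIds
           else if (!is.null(rownames(Y))) rownames(Y)
           else sprintf("f%03d", seq_len(nrow(Y)))
    nm <- if (is(mat, "ModalityMatrix")) mat@modalityName else "modality_1"
    if (nAtoms > min(dim(Y)))
        stop("model-order error: nAtoms exceeds min(features, voxels)")
    Y <- .zscoreRows(Y)
    fit <- .fitDLSC(Y, nAtoms, penalty, seed, maxIter, tol, penaltyFactor)
    new("DictionaryModel", atoms = fit$atoms, codes = fit$codes,
        penalty = fit$penalty, modalityNames = nm,
        featureSplit = setNames(list(seq_len(nrow(Y))), nm),
        featureIds = ids, objective = fit$objective)
}

#' Fit a concatenated (fused) DLSC factorization
#'
#' Stacks the feature rows of all modalities along the shared voxel
#' dimension (after per-row z-scoring) and fits a single dictionary;
#' \code{featureSplit} records which code rows belong to which modality.
#' With a single modality this reduces exactly to
#' \code{\link{fitDLSCExclusive}}.
#'
#' @param mats list of \linkS4class{ModalityMatrix} objects or matrices
#'   sharing the voxel dimension.
#' @inheritParams fitDLSCExclusive
#' @return a \linkS4class{DictionaryModel}.
#' @export
fitDLSCConcat <- function(mats, nAtoms, penalty = NULL, seed = 1L,
                          maxIter = 100L, tol = 1e-8,
                          penaltyFactor = 0.55) {
    if (!is.list(mats)) mats <- list(mats)
    Ys <- .asValuesList(mats)
    N <- ncol(Ys[[1]])
    if (!all(vapply(Ys, ncol, integer(1)) == N))
        stop("shape error: modalities must share the voxel dimension")
    nm <- .modalityNamesOf(mats)
    ids <- .featureIdsOf(mats)
    Ys <- lapply(Ys, .zscoreRows)
    Y <- do.call(rbind, Ys)
    if (nAtoms > min(dim(Y)))
        stop("model-order error: nAtoms exceeds min(features, voxels)")
    R <- vapply(Ys, nrow, integer(1))
    ends <- cumsum(R)
    starts <- c(1L, head(ends, -1L) + 1L)
    split <- lapply(seq_along(R), function(k) seq(starts[k], ends[k]))
    names(split) <- nm
    fit <- .fitDLSC(Y, nAtoms, penalty, seed, maxIter, tol, penaltyFactor)
    new("DictionaryModel", atoms = fit$atoms, codes = fit$codes,
        penalty = fit$penalty, modalityNames = nm, featureSplit = split,
        featureIds = unlist(ids), objective = fit$objective)
}
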
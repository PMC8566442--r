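# Variational-Bayes linked ICA.
#
# Generative model, shared over K modalities:
#   Y^k = X^k W^k H + E^k,   k = 1..K
# with Y^k an R_k x N feature-by-voxel matrix, H an L x N matrix of shared
# spatial sources, X^k feature coefficients, W^k a diagonal non-negative
# modality weight matrix and E^k i.i.d. Gaussian noise with per-modality
# precision. Inference works on the product loadings A^k = X^k W^k, whose
# columns carry Gaussian priors with per-component, per-modality ARD
# precisions (the weight scale is folded into the ARD shrinkage and read off
# afterwards as the column norm, which is non-negative by construction).
# Rows of H carry a shared zero-mean mixture-of-Gaussians source prior whose
# parameters are re-estimated during the fit; the super-Gaussian mixture is
# what breaks rotational degeneracy and yields independent sparse sources.
# All posteriors are updated by coordinate-ascent variational Bayes and the
# variational free energy (monitored every iteration) is the convergence
# criterion and the primary correctness oracle: it can never decrease.

#' Construct a linked ICA configuration
#'
#' @param L number of components.
#' @param maxIter maximum number of VB iterations (default 3000).
#' @param relTol relative free-energy change declaring convergence
#'   (default 1e-6, a change of machine-precision order per parameter).
#' @param seed integer seed for the initialisation.
#' @param dofScale per-modality likelihood weight (spatial
#'   degrees-of-freedom correction); default 1, no correction.
#' @param mogComponents number of Gaussians in the source prior (default 3).
#' @param init \code{"svd"} (deterministic SVD + varimax start) or
#'   \code{"random"}.
#' @return a validated \linkS4class{LinkedICAConfig}.
#' @export
linkedICAConfig <- function(L, maxIter = 3000L, relTol = 1e-6, seed = 1L,
                            dofScale = 1, mogComponents = 3L, init = "svd") {
    new("LinkedICAConfig", L = as.integer(L), maxIter = as.integer(maxIter),
        relTol = relTol, seed = as.integer(seed),
        dofScale = as.numeric(dofScale),
        mogComponents = as.integer(mogComponents), init = init)
}

.PREC_FLOOR <- 1e-10
.RESP_FLOOR <- 1e-12

# negative KL divergence between Gamma(a, b) and Gamma(a0, b0), summed
.negKLGamma <- function(a, b, a0, b0) {
    -sum((a - a0) * digamma(a) - lgamma(a) + lgamma(a0) +
         a0 * (log(b) - log(b0)) + a * (b0 - b) / b)
}

.asValuesList <- function(modalities) {
    lapply(modalities, function(m) {
        if (is(m, "ModalityMatrix")) m@values else as.matrix(m)
    })
}

.modalityNamesOf <- function(modalities) {
    nm <- vapply(seq_along(modalities), function(k) {
        m <- modalities[[k]]
        if (is(m, "ModalityMatrix")) m@modalityName
        else if (!is.null(names(modalities)) && nzchar(names(modalities)[k]))
            names(modalities)[k]
        else paste0("modality_", k)
    }, character(1))
    make.unique(nm)
}

.featureIdsOf <- function(modalities) {
    lapply(seq_along(modalities), function(k) {
        m <- modalities[[k]]
        if (is(m, "ModalityMatrix")) m@featureIds
        else if (!is.null(rownames(m))) rownames(m)
        else sprintf("f%d_%03d", k, seq_len(nrow(m)))
    })
}

# Initialise the variational state. Rows of every modality are z-scored
# (standardization constants kept), the stacked matrix is decomposed by SVD
# and the leading spatial singular vectors are varimax-rotated towards
# sparsity: a cheap, deterministic start close to the independent sources.
.vbInit <- function(Ys, config, standardize = TRUE) {
    K <- length(Ys)
    N <- ncol(Ys[[1]])
    L <- config@L
    nu <- rep_len(config@dofScale, K)
    M <- config@mogComponents
    rowCenter <- rowScale <- vector("list", K)
    for (k in seq_len(K)) {
        Y <- Ys[[k]]
        if (!all(is.finite(Y))) stop("data error: non-finite input values")
        if (ncol(Y) != N) stop("shape error: modalities must share N voxels")
        if (standardize) {
            ctr <- rowMeans(Y)
            scl <- apply(Y, 1, sd)
            if (any(scl == 0))
                stop("data error: zero-variance feature row(s)")
            Ys[[k]] <- (Y - ctr) / scl
        } else {
            ctr <- numeric(nrow(Y))
            scl <- rep(1, nrow(Y))
        }
        rowCenter[[k]] <- ctr
        rowScale[[k]] <- scl
    }
    R <- vapply(Ys, nrow, integer(1))
    if (L > min(R, N))
        stop("model-order error: L exceeds min(features, voxels)")

    set.seed(config@seed)
    if (config@init == "svd") {
        sv <- svd(do.call(rbind, Ys), nu = 0, nv = L)
        V <- sv$v
        if (L > 1L) {
            rot <- stats::varimax(V, normalize = FALSE)
            V <- V %*% rot$rotmat
        }
        H0 <- t(V)
    } else {
        H0 <- matrix(rnorm(L * N), L, N)
    }
    H0 <- H0 / apply(H0, 1, sd)

    XtX <- H0 %*% t(H0)
    diag(XtX) <- diag(XtX) + 1e-8
    solveH <- chol2inv(chol(XtX))

    state <- list(
        Y = Ys, K = K, L = L, N = N, R = R, nu = nu, M = M,
        a0 = 1e-3, b0 = 1e-3, c0 = 1e-3, d0 = 1e-3,
        EH = H0,
        VH = matrix(1e-2, L, N),
        SH = diag(rowSums(matrix(1e-2, L, N)), L),
        logdetH = sum(log(matrix(1e-2, L, N))),
        resp = array(1 / M, c(L, N, M)),
        mogPi = rep(1 / M, M),
        mogSigma2 = exp(seq(log(0.05), log(2), length.out = M)),
        MA = vector("list", K), SigmaA = vector("list", K),
        alphaA = vector("list", K), alphaB = vector("list", K),
        lamC = numeric(K), lamD = numeric(K),
        Tk = numeric(K),
        rowCenter = rowCenter, rowScale = rowScale)

    for (k in seq_len(K)) {
        MA <- Ys[[k]] %*% t(H0) %*% solveH
        state$MA[[k]] <- MA
        state$SigmaA[[k]] <- diag(1e-4, L)
        alphaBar <- pmax(R[k] / (colSums(MA^2) + 1e-8), .PREC_FLOOR)
        state$alphaA[[k]] <- rep(state$a0 + R[k] / 2, L)
        state$alphaB[[k]] <- state$alphaA[[k]] / alphaBar
        resid <- Ys[[k]] - MA %*% H0
        tk <- sum(resid^2) + 1e-8
        state$Tk[k] <- tk
        state$lamC[k] <- state$c0 + nu[k] * R[k] * N / 2
        state$lamD[k] <- state$lamC[k] / (R[k] * N / tk)
    }
    state
}

.lamBar <- function(state) state$lamC / state$lamD

# One full coordinate-ascent sweep over all variational factors.
.vbSweep <- function(state) {
    K <- state$K; L <- state$L; N <- state$N; M <- state$M
    nu <- state$nu
    lamBar <- .lamBar(state)

    # --- q(H): per-voxel Gaussian posteriors -------------------------------
    M0 <- matrix(0, L, L)
    C <- matrix(0, L, N)
    for (k in seq_len(K)) {
        EAA <- crossprod(state$MA[[k]]) + state$R[k] * state$SigmaA[[k]]
        M0 <- M0 + nu[k] * lamBar[k] * EAA
        C <- C + nu[k] * lamBar[k] * crossprod(state$MA[[k]], state$Y[[k]])
    }
    Beta <- matrix(0, L, N)
    for (m in seq_len(M))
        Beta <- Beta + state$resp[, , m] / state$mogSigma2[m]
    up <- vb_update_H(M0, C, Beta)
    state$EH <- up$mu
    state$VH <- up$var
    state$SH <- up$S
    state$logdetH <- up$logdet

    # --- q(z): mixture responsibilities ------------------------------------
    H2 <- state$EH^2 + state$VH
    logr <- array(0, c(L, N, M))
    for (m in seq_len(M))
        logr[, , m] <- log(state$mogPi[m]) -
            0.5 * log(2 * pi * state$mogSigma2[m]) -
            H2 / (2 * state$mogSigma2[m])
    mx <- logr[, , 1]
    for (m in seq_len(M)[-1]) mx <- pmax(mx, logr[, , m])
    r <- array(0, c(L, N, M))
    for (m in seq_len(M)) r[, , m] <- pmax(exp(logr[, , m] - mx), .RESP_FLOOR)
    tot <- r[, , 1]
    for (m in seq_len(M)[-1]) tot <- tot + r[, , m]
    for (m in seq_len(M)) r[, , m] <- r[, , m] / tot
    state$resp <- r

    # --- mixture parameters (empirical-Bayes M-step) -----------------------
    sm <- colSums(matrix(state$resp, ncol = M))
    state$mogPi <- pmax(sm / (L * N), .RESP_FLOOR)
    state$mogPi <- state$mogPi / sum(state$mogPi)
    for (m in seq_len(M))
        state$mogSigma2[m] <- min(max(
            sum(state$resp[, , m] * H2) / sm[m], .PREC_FLOOR), 1 / .PREC_FLOOR)

    # --- per-modality loadings, ARD and noise ------------------------------
    EHH <- tcrossprod(state$EH) + state$SH
    for (k in seq_len(K)) {
        Rk <- state$R[k]
        alphaBar <- pmax(state$alphaA[[k]] / state$alphaB[[k]], .PREC_FLOOR)
        P <- nu[k] * lamBar[k] * EHH
        diag(P) <- diag(P) + alphaBar
        SigmaA <- chol2inv(chol(P))
        MA <- nu[k] * lamBar[k] * state$Y[[k]] %*% t(state$EH) %*% SigmaA
        state$SigmaA[[k]] <- SigmaA
        state$MA[[k]] <- MA

        EA2 <- colSums(MA^2) + Rk * diag(SigmaA)
        state$alphaA[[k]] <- rep(state$a0 + Rk / 2, L)
        state$alphaB[[k]] <- state$b0 + EA2 / 2

        EAA <- crossprod(MA) + Rk * SigmaA
        state$Tk[k] <- sum(state$Y[[k]]^2) -
            2 * sum(state$Y[[k]] * (MA %*% state$EH)) + sum(EAA * EHH)
        state$lamC[k] <- state$c0 + nu[k] * Rk * N / 2
        state$lamD[k] <- state$d0 + nu[k] * state$Tk[k] / 2
        lamBar[k] <- state$lamC[k] / state$lamD[k]
    }
    state
}

# Variational free energy of the current state, with its additive parts.
# This is the evidence lower bound: expected (dof-weighted) complete-data
# log-likelihood minus the KL divergences of all variational factors.
.vbFreeEnergy <- function(state) {
    K <- state$K; L <- state$L; N <- state$N; M <- state$M
    nu <- state$nu
    lamBar <- .lamBar(state)
    elogLam <- digamma(state$lamC) - log(state$lamD)
    loglik <- numeric(K)
    Fa <- 0
    for (k in seq_len(K)) {
        Rk <- state$R[k]
        loglik[k] <- nu[k] * (Rk * N / 2 * (elogLam[k] - log(2 * pi)) -
                              0.5 * lamBar[k] * state$Tk[k])
        alphaBar <- state$alphaA[[k]] / state$alphaB[[k]]
        elogAlpha <- digamma(state$alphaA[[k]]) - log(state$alphaB[[k]])
        EA2 <- colSums(state$MA[[k]]^2) + Rk * diag(state$SigmaA[[k]])
        ElogpA <- sum(Rk / 2 * (elogAlpha - log(2 * pi)) -
                      0.5 * alphaBar * EA2)
        HqA <- 0.5 * Rk * (L * (1 + log(2 * pi)) +
                           determinant(state$SigmaA[[k]])$modulus[1])
        klAlpha <- .negKLGamma(state$alphaA[[k]], state$alphaB[[k]],
                               state$a0, state$b0)
        klLam <- .negKLGamma(state$lamC[k], state$lamD[k],
                             state$c0, state$d0)
        Fa <- Fa + ElogpA + HqA + klAlpha + klLam
    }
    H2 <- state$EH^2 + state$VH
    EpHz <- 0
    Hqz <- 0
    for (m in seq_len(M)) {
        r <- state$resp[, , m]
        EpHz <- EpHz + sum(r * (log(state$mogPi[m]) -
                                0.5 * log(2 * pi * state$mogSigma2[m]) -
                                H2 / (2 * state$mogSigma2[m])))
        Hqz <- Hqz - sum(r * log(r))
    }
    HqH <- 0.5 * (N * L * (1 + log(2 * pi)) + state$logdetH)
    total <- sum(loglik) + Fa + EpHz + Hqz + HqH
    list(total = total, loglik = loglik)
}

#' Fit the voxel-linked ICA model by variational Bayes
#'
#' Factorises two or more feature-by-voxel matrices sharing the voxel
#' dimension into shared sparse spatial sources H, per-modality feature
#' coefficients X^k and non-negative modality weights W^k, with automatic
#' relevance determination over components and a Gaussian noise model per
#' modality. Coordinate-ascent VB updates are cycled until the relative
#' free-energy change drops below \code{relTol} or \code{maxIter} is
#' reached; the trace is retained and is non-decreasing (up to numerical
#' slack), which is the fit's built-in correctness check.
#'
#' Each feature row is z-scored before fitting (constants retained for
#' reconstruction in original units). Returned components have unit-norm,
#' positively-skewed H rows and are sorted by total explained variance
#' across modalities.
#'
#' @param modalities list of \linkS4class{ModalityMatrix} objects (or plain
#'   feature-by-voxel matrices) sharing the voxel dimension.
#' @param config a \linkS4class{LinkedICAConfig}.
#' @param standardize logical; z-score feature rows before fitting
#'   (default TRUE).
#' @return a \linkS4class{LinkedDecomposition}.
#' @examples
#' set.seed(1)
#' H <- matrix(rnorm(2 * 300), 2, 300)
#' Y1 <- matrix(rnorm(20 * 2), 20, 2) %*% H + 0.1 * matrix(rnorm(6000), 20)
#' Y2 <- matrix(rnorm(10 * 2), 10, 2) %*% H + 0.1 * matrix(rnorm(3000), 10)
#' fit <- fitLinkedICA(list(Y1, Y2), linkedICAConfig(L = 2, maxIter = 50))
#' fit
#' @export
fitLinkedICA <- function(modalities, config, standardize = TRUE) {
    stopifnot(is(config, "LinkedICAConfig"))
    if (!is.list(modalities)) modalities <- list(modalities)
    Ys <- .asValuesList(modalities)
    modNames <- .modalityNamesOf(modalities)
    featIds <- .featureIdsOf(modalities)

    state <- .vbInit(Ys, config, standardize = standardize)
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(config@maxIter)) {
        state <- .vbSweep(state)
        f <- .vbFreeEnergy(state)$total
        trace <- c(trace, f)
        if (it >= 2L) {
            rel <- abs(f - trace[it - 1L]) / abs(trace[it - 1L])
            if (rel < config@relTol) {
                converged <- TRUE
                break
            }
        }
    }
    .finalizeFit(state, config, trace, converged, modNames, featIds)
}

# Resolve scale/sign/order ambiguities and package the point estimates.
.finalizeFit <- function(state, config, trace, converged, modNames,
                         featIds) {
    K <- state$K
    H <- state$EH
    A <- state$MA
    s <- sqrt(rowSums(H^2))
    s[s == 0] <- 1
    H <- H / s
    for (k in seq_len(K)) A[[k]] <- sweep(A[[k]], 2, s, `*`)
    # sign convention: positive skewness of every spatial map
    ctr <- H - rowMeans(H)
    skew <- rowSums(ctr^3) / (rowSums(ctr^2)^1.5 + 1e-300)
    flip <- ifelse(skew < 0, -1, 1)
    H <- H * flip
    for (k in seq_len(K)) A[[k]] <- sweep(A[[k]], 2, flip, `*`)

    W <- X <- vector("list", K)
    ev <- matrix(0, state$L, K,
                 dimnames = list(NULL, modNames))
    for (k in seq_len(K)) {
        w <- sqrt(colSums(A[[k]]^2))
        W[[k]] <- w
        X[[k]] <- sweep(A[[k]], 2, ifelse(w > 0, w, 1), `/`)
        totVar <- mean(state$Y[[k]]^2) - mean(state$Y[[k]])^2
        for (i in seq_len(state$L)) {
            a <- A[[k]][, i]
            h <- H[i, ]
            compVar <- mean(a^2) * mean(h^2) - (mean(a) * mean(h))^2
            ev[i, k] <- compVar / totVar
        }
    }
    ord <- order(rowSums(ev), decreasing = TRUE)
    H <- H[ord, , drop = FALSE]
    ev <- ev[ord, , drop = FALSE]
    for (k in seq_len(K)) {
        W[[k]] <- W[[k]][ord]
        X[[k]] <- X[[k]][, ord, drop = FALSE]
        rownames(X[[k]]) <- featIds[[k]]
    }
    names(W) <- names(X) <- modNames
    new("LinkedDecomposition", H = H, X = X, W = W,
        noisePrecision = setNames(.lamBar(state), modNames),
        freeEnergy = trace, componentOrder = as.integer(ord),
        converged = converged, explainedVariance = ev,
        modalityNames = modNames, featureIds = setNames(featIds, modNames),
        rowCenter = setNames(state$rowCenter, modNames),
        rowScale = setNames(state$rowScale, modNames),
        config = config,
        mog = list(pi = state$mogPi, sigma2 = state$mogSigma2))
}

#' @rdname reconstruct
#' @export
setMethod("reconstruct", "LinkedDecomposition",
    function(object, k = 1L, components = NULL, originalUnits = FALSE) {
        L <- nrow(object@H)
        if (length(k) != 1L || k < 1 || k > length(object@X))
            stop("index error: modality index out of range")
        if (is.null(components)) components <- seq_len(L)
        if (length(components) > 0 &&
            (any(components < 1) || any(components > L)))
            stop("index error: component index out of range")
        A <- sweep(object@X[[k]], 2, object@W[[k]], `*`)
        if (length(components) == 0) {
            rec <- matrix(0, nrow(A), ncol(object@H))
        } else {
            rec <- A[, components, drop = FALSE] %*%
                object@H[components, , drop = FALSE]
        }
        if (originalUnits)
            rec <- rec * object@rowScale[[k]] + object@rowCenter[[k]]
        rownames(rec) <- object@featureIds[[k]]
        rec
    })

#' Project unseen feature rows onto a fitted component basis
#'
#' Regresses each new voxel pattern onto the modality-k component basis
#' diag(W^k) H by least squares, yielding component coefficients, fitted
#' reconstructions and the per-row mean squared residual. Rows are z-scored
#' first by default, so the MSE is in units of the row variance (set
#' \code{standardize = FALSE} to work in raw units).
#'
#' @param object a fitted \linkS4class{LinkedDecomposition}.
#' @param newRows numeric M x N matrix of held-out voxel patterns.
#' @param k modality index whose weight scaling is used.
#' @param standardize z-score the rows before projecting (default TRUE).
#' @return list with \code{coefficients} (M x L), \code{reconstruction}
#'   (M x N) and \code{mse} (length M).
#' @export
predictUnseenFeatures <- function(object, newRows, k = 1L,
                                  standardize = TRUE) {
    stopifnot(is(object, "LinkedDecomposition"))
    newRows <- rbind(newRows)
    if (ncol(newRows) != ncol(object@H))
        stop("shape error: new rows must have N voxel columns")
    if (standardize) {
        ctr <- rowMeans(newRows)
        scl <- apply(newRows, 1, sd)
        scl[scl == 0] <- 1
        newRows <- (newRows - ctr) / scl
    }
    B <- object@W[[k]] * object@H          # L x N basis
    sv <- svd(B)
    pos <- sv$d > max(sv$d, 1e-300) * 1e-12
    if (!any(pos)) {
        coeff <- matrix(0, nrow(newRows), nrow(B))
    } else {
        # least-squares row-wise projection via the pseudo-inverse
        Bpinv <- sv$v[, pos, drop = FALSE] %*%
            (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
        coeff <- newRows %*% Bpinv
    }
    rec <- coeff %*% B
    mse <- rowMeans((newRows - rec)^2)
    list(coefficients = coeff, reconstruction = rec, mse = mse)
}

#' In-silico perturbation of gene expression patterns
#'
#' Scales the coefficients of the selected modality-1 features, re-expresses
#' the implied change in the shared component activations by least squares
#' on modality 1, and propagates it through modality 2's reconstruction.
#' The result is the predicted change (perturbed minus baseline) in the
#' modality-2 reconstruction.
#'
#' @param object a fitted \linkS4class{LinkedDecomposition} with at least
#'   two modalities.
#' @param geneIds character ids of modality-1 features to perturb.
#' @param scale multiplicative factor applied to their coefficients
#'   (1 = no change, 0 = knock-out).
#' @return numeric R_2 x N matrix of reconstruction differences.
#' @export
perturbGenes <- function(object, geneIds, scale) {
    stopifnot(is(object, "LinkedDecomposition"))
    if (length(object@X) < 2L)
        stop("perturbation propagation needs at least two modalities")
    idx <- match(geneIds, object@featureIds[[1]])
    if (anyNA(idx))
        stop("key error: unknown gene ids: ",
             paste(geneIds[is.na(idx)], collapse = ", "))
    A1 <- sweep(object@X[[1]], 2, object@W[[1]], `*`)
    A2 <- sweep(object@X[[2]], 2, object@W[[2]], `*`)
    deltaA1 <- matrix(0, nrow(A1), ncol(A1))
    deltaA1[idx, ] <- (scale - 1) * A1[idx, , drop = FALSE]
    sv <- svd(A1)
    pos <- sv$d > max(sv$d) * 1e-12
    A1pinv <- sv$v[, pos, drop = FALSE] %*%
        (t(sv$u[, pos, drop = FALSE]) / sv$d[pos])
    deltaH <- (A1pinv %*% deltaA1) %*% object@H
    delta <- A2 %*% deltaH
    rownames(delta) <- object@featureIds[[2]]
    delta
}
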
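# Shared fixtures (computed once per session) and independent brute-force
# oracles used across the test files.

.fixtureCache <- new.env(parent = emptyenv())

.cached <- function(key, expr) {
    if (!exists(key, envir = .fixtureCache))
        assign(key, expr, envir = .fixtureCache)
    get(key, envir = .fixtureCache)
}

# The default planted-ground-truth dataset: 12x10x10 grid, 80% mask fill,
# 5 shared sources, 60 + 30 features, SNR 10, default seed.
fixtureDataset <- function() {
    .cached("dataset", generateLinkedDataset(syntheticSpec()))
}

# Voxel-aligned, imputed modality matrices of the default dataset.
fixtureModalities <- function() {
    .cached("modalities", {
        ds <- fixtureDataset()
        lapply(seq_along(ds$volumes), function(k)
            imputeMissing(flattenVolume(ds$volumes[[k]], ds$mask,
                                        names(ds$volumes)[k]),
                          ds$annotation))
    })
}

# The linked ICA fit of the default dataset at the true model order.
fixtureFit <- function() {
    .cached("fit", fitLinkedICA(fixtureModalities(),
                                linkedICAConfig(L = 5, seed = 2)))
}

# A dataset with one component planted as unique to modality 1 (weight
# zeroed in modality 2).
fixtureUniqueDataset <- function() {
    .cached("uniqueDataset", generateLinkedDataset(
        syntheticSpec(uniqueComponents = cbind(component = 2L,
                                               modality = 2L))))
}

fixtureUniqueFit <- function() {
    .cached("uniqueFit", {
        ds <- fixtureUniqueDataset()
        mods <- lapply(seq_along(ds$volumes), function(k)
            imputeMissing(flattenVolume(ds$volumes[[k]], ds$mask,
                                        names(ds$volumes)[k]),
                          ds$annotation))
        fitLinkedICA(mods, linkedICAConfig(L = 5, seed = 2))
    })
}

## ---- independent oracles -------------------------------------------------

# Exact hypergeometric upper tail by direct enumeration of the probability
# mass function (valid for small universes).
oracleHypergeom <- function(k, K, n, N) {
    js <- 0:min(K, n)
    pmf <- choose(K, js) * choose(N - K, n - js) / choose(N, n)
    sum(pmf[js >= k])
}

# Benjamini-Hochberg step-up adjustment written from the definition.
oracleBH <- function(p) {
    m <- length(p)
    o <- order(p)
    ranked <- p[o] * m / seq_len(m)
    adj <- rev(cummin(rev(ranked)))
    adj <- pmin(adj, 1)
    out <- numeric(m)
    out[o] <- adj
    out
}

# Pearson correlation and two-sided t-test p-value from the textbook
# formulas.
oraclePearson <- function(x, y) {
    n <- length(x)
    sx <- x - mean(x)
    sy <- y - mean(y)
    r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    c(rho = r, p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# r-squared and mse from their definitions.
oracleR2 <- function(y, f) 1 - sum((y - f)^2) / sum((y - mean(y))^2)
oracleMSE <- function(y, f) mean((y - f)^2)

# Trilinear interpolation of a single 3D volume at one coarse-cell centre,
# written independently with explicit corner loops. Background-aware:
# sentinel corners are excluded and weights renormalised.
oracleTrilinear <- function(v, factor, i, j, k, bg = -1) {
    d <- dim(v)
    x <- (c(i, j, k) - 0.5) * factor - 0.5   # 0-based fine coordinate
    lo <- pmin(pmax(floor(x), 0), d - 1)
    hi <- pmin(lo + 1, d - 1)
    fr <- x - lo
    fr[hi == lo] <- 0
    num <- 0
    den <- 0
    for (cx in 0:1) for (cy in 0:1) for (cz in 0:1) {
        idx <- c(if (cx) hi[1] else lo[1],
                 if (cy) hi[2] else lo[2],
                 if (cz) hi[3] else lo[3]) + 1
        w <- (if (cx) fr[1] else 1 - fr[1]) *
             (if (cy) fr[2] else 1 - fr[2]) *
             (if (cz) fr[3] else 1 - fr[3])
        val <- v[idx[1], idx[2], idx[3]]
        if (val != bg && w > 0) {
            num <- num + w * val
            den <- den + w
        }
    }
    if (den > 0) num / den else bg
}
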
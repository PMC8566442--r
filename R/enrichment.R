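# Over-representation analysis of gene groups against a flat annotation
# universe: exact hypergeometric upper-tail test with Benjamini-Hochberg FDR
# control, plus GMT-format I/O for annotation sets. Only enrichment (upper
# tail) is tested, matching standard gene-ontology practice.

#' Hypergeometric upper-tail probability
#'
#' P[X >= k] for X ~ Hypergeometric(N, K, n): the probability of drawing at
#' least k annotated genes when n genes are drawn from a universe of N of
#' which K are annotated. Exact and numerically stable in log space for
#' large arguments.
#'
#' @param k observed overlap.
#' @param K annotation term size.
#' @param n query size.
#' @param N universe size.
#' @return the upper-tail p-value.
#' @examples
#' hypergeomUpperTail(3, 4, 5, 10)   # 66/252
#' @export
hypergeomUpperTail <- function(k, K, n, N) {
    if (any(K < 0) || any(n < 0) || any(K > N) || any(n > N))
        stop("argument error: need 0 <= K, n <= N")
    if (any(k < 0) || any(k > pmin(K, n)))
        stop("argument error: need 0 <= k <= min(K, n)")
    phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment; adjusted values are elementwise no smaller than
#' the raw p-values and monotone after sorting.
#'
#' @param pvals numeric vector of p-values in (0, 1].
#' @return adjusted q-values in the input order.
#' @export
fdrAdjust <- function(pvals) {
    if (any(pvals <= 0) || any(pvals > 1) || anyNA(pvals))
        stop("argument error: p-values must lie in (0, 1]")
    p.adjust(pvals, method = "BH")
}

#' Family-wise fixed p-value cutoff from BH at a stated FDR level
#'
#' Pools raw p-values across a family of enrichment analyses (all terms and
#' all analysed groups) and returns the largest raw p-value still rejected
#' by the Benjamini-Hochberg procedure at level \code{alpha}; using this
#' single cutoff across the family reproduces the fixed-cutoff reporting
#' style of corrected enrichment analyses.
#'
#' @param pvals numeric vector of raw p-values pooled over the family.
#' @param alpha target false discovery rate.
#' @return the fixed cutoff, or 0 if nothing is rejected.
#' @export
fdrCutoff <- function(pvals, alpha = 0.05) {
    q <- fdrAdjust(pvals)
    if (!any(q <= alpha)) return(0)
    max(pvals[q <= alpha])
}

#' Over-representation analysis of a gene set
#'
#' Tests every annotation term for enrichment of the query genes by the
#' hypergeometric upper-tail test, reports BH q-values, and flags
#' significance at a fixed p-value cutoff \code{alpha} (default 3.8e-5, the
#' FDR-derived fixed-cutoff mode; set \code{alpha} to an FDR level and use
#' the q column for the step-up mode). Query genes outside the universe are
#' dropped with a warning.
#'
#' @param query character vector of gene ids.
#' @param annot an \linkS4class{AnnotationMap}.
#' @param alpha fixed significance cutoff on the raw p-value.
#' @param allTerms if TRUE report terms with zero overlap as well.
#' @return data.frame with columns term, termName, k, K, n, N, p, q,
#'   significant, ordered by p; empty for an empty query.
#' @export
enrich <- function(query, annot, alpha = 3.8e-5, allTerms = FALSE) {
    stopifnot(is(annot, "AnnotationMap"))
    query <- unique(query)
    out <- !(query %in% annot@universe)
    if (any(out)) {
        warning("dropping ", sum(out), " query gene(s) outside the universe")
        query <- query[!out]
    }
    empty <- data.frame(term = character(0), termName = character(0),
                        k = integer(0), K = integer(0), n = integer(0),
                        N = integer(0), p = numeric(0), q = numeric(0),
                        significant = logical(0))
    if (length(query) == 0) return(empty)
    N <- length(annot@universe)
    n <- length(query)
    k <- vapply(annot@terms, function(g) length(intersect(g, query)),
                integer(1))
    K <- vapply(annot@terms, length, integer(1))
    keep <- if (allTerms) rep(TRUE, length(k)) else k > 0
    if (!any(keep)) return(empty)
    k <- k[keep]; K <- K[keep]
    terms <- names(annot@terms)[keep]
    p <- hypergeomUpperTail(k, K, n, N)
    res <- data.frame(term = terms,
                      termName = unname(annot@termNames[terms]),
                      k = unname(k), K = unname(K), n = n, N = N,
                      p = unname(p), q = unname(fdrAdjust(p)),
                      significant = unname(p < alpha))
    res[order(res$p, res$term), , drop = FALSE]
}

#' Read an annotation universe from a GMT file
#'
#' One term per line: term, description and gene ids, tab-separated. The
#' universe defaults to the union of all annotated genes unless given.
#'
#' @param path GMT file path.
#' @param universe optional explicit gene universe.
#' @return an \linkS4class{AnnotationMap}.
#' @export
readGMT <- function(path, universe = NULL) {
    lines <- readLines(path)
    lines <- lines[nzchar(lines)]
    parts <- strsplit(lines, "\t", fixed = TRUE)
    terms <- lapply(parts, function(x) unique(x[-(1:2)]))
    names(terms) <- vapply(parts, `[`, character(1), 1L)
    termNames <- setNames(vapply(parts, `[`, character(1), 2L), names(terms))
    if (is.null(universe)) universe <- unique(unlist(terms))
    new("AnnotationMap", terms = terms, universe = universe,
        termNames = termNames)
}

#' Write an annotation universe to a GMT file
#'
#' @param annot an \linkS4class{AnnotationMap}.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
writeGMT <- function(annot, path) {
    stopifnot(is(annot, "AnnotationMap"))
    lines <- vapply(names(annot@terms), function(tm) {
        paste(c(tm, annot@termNames[tm], annot@terms[[tm]]),
              collapse = "\t")
    }, character(1))
    writeLines(lines, path)
    invisible(path)
}
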
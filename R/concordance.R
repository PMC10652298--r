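# Concordance statistics: the "same sign" flag, exact two-sided binomial
# tests against 50%, correlation measures, and a generic hypergeometric
# over-representation utility.

#' Directional concordance of a coefficient/fold-change pair
#'
#' `TRUE` iff both values are strictly positive or both strictly negative:
#' the gene's H3K9ac response to amyloid burden and its transcriptional
#' change point the same way. Undefined (`NA`) when either value is exactly
#' zero; such records are excluded from concordance counts.
#'
#' @param coef_abeta,log2fc Numeric vectors (recycled to common length).
#' @return Logical vector with `NA` where undefined.
#' @export
same_sign <- function(coef_abeta, log2fc) {
  out <- sign(coef_abeta) * sign(log2fc)
  ifelse(out == 0, NA, out > 0)
}

#' Exact two-sided binomial p-value
#'
#' Minimum-likelihood exact test (default): the p-value is the sum of
#' `Binomial(n, p0)` probabilities of all outcomes whose probability does
#' not exceed that of the observed `k` (within relative tolerance `1e-7`).
#' This is the standard definition of the two-sided exact test and is
#' symmetric for `p0 = 0.5`: `p(k) = p(n - k)`. The central (doubled
#' smaller tail) variant is available via `method = "central"`.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n >= 1`.
#' @param p0 Null success probability.
#' @param method `"minlik"` (default) or `"central"`.
#' @return p-value in `[0, 1]`.
#' @export
binom_exact_two_sided <- function(k, n, p0 = 0.5,
                                  method = c("minlik", "central")) {
  method <- match.arg(method)
  if (length(k) != 1L || length(n) != 1L || !is.finite(k) || !is.finite(n) ||
      k != round(k) || n != round(n) || n < 1 || k < 0 || k > n)
    stop("k must be an integer in [0, n] and n an integer >= 1", call. = FALSE)
  stopifnot(p0 > 0, p0 < 1)
  if (method == "minlik") {
    pmf <- stats::dbinom(0:n, n, p0)
    p <- sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
  } else {
    lo <- stats::pbinom(k, n, p0)
    hi <- stats::pbinom(k - 1, n, p0, lower.tail = FALSE)
    p <- 2 * min(lo, hi, 0.5)
  }
  min(1, p)
}

#' Correlation with a two-sided p-value
#'
#' Pearson is the product-moment estimate with the t-distribution p-value.
#' Spearman is Pearson on mid-ranks (ties receive their average rank) with
#' the same t approximation, so tied data are handled without exact-test
#' warnings; a perfect monotone relation gives `p = 0`.
#'
#' @param x,y Numeric vectors of equal length `>= 3`; neither may be
#'   constant.
#' @param method `"pearson"` or `"spearman"`.
#' @return List with elements `r`, `p` and `n`.
#' @export
cor_with_p <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for a constant vector", call. = FALSE)
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
    if (stats::sd(x) == 0 || stats::sd(y) == 0)
      stop("correlation undefined for a constant vector", call. = FALSE)
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(r = r, p = p, n = n)
}

#' Concordance statistics per scope
#'
#' For the pooled record set ("all") and for each cell type with records:
#' the number of sign-classifiable records, how many have coefficient and
#' fold change with the same sign, the percentage, the exact two-sided
#' binomial p-value against 50%, and the Pearson correlation between
#' `coef_abeta` and `log2fc` with its two-sided p-value. Records whose
#' `same_sign` is undefined (a value exactly zero) are excluded from the
#' scope entirely. Scopes with fewer than 3 records report `NA`
#' correlations but still report counts. Per-cell-type binomial p-values
#' are reported raw (no multiplicity correction), matching how such tests
#' are conventionally read; Benjamini-Hochberg adjustment is available via
#' `adjust = "BH"`.
#'
#' @param records Integrated-record data.frame.
#' @param binom_method Passed to [binom_exact_two_sided()].
#' @param adjust `"none"` (default) or `"BH"`: multiplicity adjustment of
#'   the per-cell-type binomial p-values (reported in `binom_p_adj`).
#' @return A `concordance_table` data.frame, one row per scope.
#' @export
concordance_by_scope <- function(records, binom_method = c("minlik", "central"),
                                 adjust = c("none", "BH")) {
  binom_method <- match.arg(binom_method)
  adjust <- match.arg(adjust)
  defined <- records[!is.na(records$same_sign), , drop = FALSE]
  one_scope <- function(scope, sub) {
    n <- nrow(sub)
    k <- sum(sub$same_sign)
    ct <- tryCatch(cor_with_p(sub$coef_abeta, sub$log2fc, "pearson"),
                   error = function(e) list(r = NA_real_, p = NA_real_))
    data.frame(
      scope = scope, n = n, k_same_sign = k,
      pct_same_sign = if (n > 0) 100 * k / n else NA_real_,
      binom_p = if (n > 0) binom_exact_two_sided(k, n, 0.5, binom_method)
                else NA_real_,
      pearson_r = ct$r, pearson_p = ct$p,
      stringsAsFactors = FALSE
    )
  }
  scopes <- list(one_scope("all", defined))
  for (ct in CELL_TYPES) {
    sub <- defined[defined$cell_type == ct, , drop = FALSE]
    if (nrow(sub) > 0L) scopes <- c(scopes, list(one_scope(ct, sub)))
  }
  out <- do.call(rbind, scopes)
  if (adjust == "BH") {
    cell_rows <- out$scope != "all"
    out$binom_p_adj <- NA_real_
    out$binom_p_adj[cell_rows] <- stats::p.adjust(out$binom_p[cell_rows], "BH")
  }
  rownames(out) <- NULL
  class(out) <- c("concordance_table", "data.frame")
  out
}

#' @export
print.concordance_table <- function(x, digits = 3, ...) {
  cat("Coefficient-Abeta / log2FC concordance\n")
  df <- as.data.frame(x)
  df$pct_same_sign <- round(df$pct_same_sign, 1)
  df$binom_p <- signif(df$binom_p, digits)
  df$pearson_r <- round(df$pearson_r, digits)
  df$pearson_p <- signif(df$pearson_p, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Hypergeometric over-representation of a gene set
#'
#' Generic one-sided over-representation analysis: for each annotation
#' term, the upper-tail hypergeometric probability of observing at least
#' the overlap between the query set and the term's genes, drawing
#' `|query|` genes from the universe. Benjamini-Hochberg adjusted p-values
#' are reported alongside.
#'
#' @param query Character vector of genes; must be a subset of `universe`.
#' @param annotations GO annotation data.frame (long format).
#' @param universe Character vector of background genes (non-empty).
#' @return data.frame with one row per term: `term_id`, `term_name`,
#'   `n_term`, `overlap`, `p`, `p_adj`, ordered by `p`.
#' @export
hypergeom_overrep <- function(query, annotations, universe) {
  validate_go(annotations)
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  query <- unique(query)
  if (!all(query %in% universe))
    stop("query genes must be a subset of the universe", call. = FALSE)
  terms <- unique(annotations[c("term_id", "term_name")])
  res <- lapply(seq_len(nrow(terms)), function(i) {
    genes <- unique(annotations$gene_symbol[annotations$term_id == terms$term_id[i]])
    genes <- intersect(genes, universe)
    K <- length(genes)
    k <- length(intersect(genes, query))
    p <- stats::phyper(k - 1, K, length(universe) - K, length(query),
                       lower.tail = FALSE)
    data.frame(term_id = terms$term_id[i], term_name = terms$term_name[i],
               n_term = K, overlap = k, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- stats::p.adjust(out$p, "BH")
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
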
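#' Between-sample signal-intensity normalization
#'
#' Adjusts for global differences in overall signal intensity between ROIs
#' before any factor-based correction.
#'
#' Methods:
#' \describe{
#'   \item{`upper`}{each ROI column is scaled so that the 75th percentile of
#'     its nonzero values equals the across-column geometric mean of those
#'     percentiles (robust with many zeros, the default).}
#'   \item{`median`}{same with the 50th percentile of nonzero values.}
#'   \item{`full`}{full-quantile normalization: each column's sorted values
#'     are replaced by the across-column mean of order statistics, ties
#'     receiving the average of their tied positions; afterwards every
#'     column has an identical multiset of values.}
#' }
#'
#' @param x an [roi_matrix()] or a numeric genes x ROIs matrix
#' @param method `"upper"` (default), `"full"` or `"median"`
#' @return same container as `x`, with real-valued normalized expression;
#'   gene and ROI ordering preserved
#' @export
between_lane_normalize <- function(x, method = c("upper", "full", "median")) {
  method <- match.arg(method)
  m <- as_count_matrix(x)
  zero_cols <- colSums(m) == 0
  if (any(zero_cols))
    abort("all-zero ROI column(s): %s",
          paste(colnames(m)[zero_cols], collapse = ", "))
  out <- switch(method,
    upper = scale_to_quantile(m, 0.75),
    median = scale_to_quantile(m, 0.5),
    full = full_quantile(m))
  dimnames(out) <- dimnames(m)
  if (inherits(x, "roi_matrix")) set_counts(x, out) else out
}

scale_to_quantile <- function(m, p) {
  q <- apply(m, 2, function(col) stats::quantile(col[col > 0], p, names = FALSE))
  target <- geometric_mean(q)
  sweep(m, 2, target / q, "*")
}

full_quantile <- function(m) {
  n <- nrow(m)
  ref <- rowMeans(apply(m, 2, sort))
  apply(m, 2, function(col) {
    r <- rank(col, ties.method = "average")
    # half-integer ranks from ties interpolate to the mean of the two
    # neighboring reference order statistics
    stats::approx(seq_len(n), ref, xout = r)$y
  })
}

#' Estimate unwanted-variation factors from replicate structure
#'
#' Log-transforms the normalized matrix (`log(x + 1)`), centers each gene
#' within every replicate group (removing the biology shared by replicates),
#' and takes the singular value decomposition of the centered matrix. The
#' first `k` right-singular vectors (ROI space) are the unwanted factors.
#' Replicate groups must span the nuisance structure of interest: ROIs of
#' the same biological condition measured on different slides are replicates
#' with respect to slide-level batch effects.
#'
#' @param x an [roi_matrix()] or numeric matrix of normalized expression
#' @param replicate_groups vector (length = #ROIs) assigning each ROI to a
#'   replicate group; if `NULL` and `x` is an `roi_matrix`, defaults to the
#'   interaction of `group` and `compartment` (slides pooled, so
#'   slide-level factors survive the centering and are estimable)
#' @param k number of factors to return (`>= 1`)
#' @return an `unwanted_factors` object: `k`, `factors` (ROIs x k, columns
#'   orthonormal), `singular_values` (non-increasing)
#' @export
estimate_unwanted_variation <- function(x, replicate_groups = NULL, k = 1) {
  m <- as_count_matrix(x)
  if (is.null(replicate_groups)) {
    if (!inherits(x, "roi_matrix"))
      abort("`replicate_groups` is required when `x` is a bare matrix")
    replicate_groups <- paste(x$metadata$group, x$metadata$compartment, sep = ":")
  }
  if (length(replicate_groups) != ncol(m))
    abort("`replicate_groups` must have one entry per ROI")
  if (!is_pos_count(k)) abort("`k` must be a positive integer")
  sizes <- table(replicate_groups)
  if (any(sizes < 2))
    abort("singleton replicate group(s): %s",
          paste(names(sizes)[sizes < 2], collapse = ", "))
  if (k > min(dim(m)))
    abort("k = %d exceeds the maximum possible rank %d", k, min(dim(m)))
  L <- log1p(m)
  for (g in unique(replicate_groups)) {
    idx <- replicate_groups == g
    L[, idx] <- L[, idx] - rowMeans(L[, idx, drop = FALSE])
  }
  sv <- svd(L, nu = 0, nv = min(dim(m)))
  W <- sv$v[, seq_len(k), drop = FALSE]
  rownames(W) <- colnames(m)
  colnames(W) <- sprintf("W%d", seq_len(k))
  structure(list(k = k, factors = W, singular_values = sv$d[seq_len(k)]),
            class = "unwanted_factors")
}

#' @export
print.unwanted_factors <- function(x, ...) {
  cat(sprintf("unwanted_factors: k = %d over %d ROIs; singular values: %s\n",
              x$k, nrow(x$factors),
              paste(signif(x$singular_values, 4), collapse = ", ")))
  invisible(x)
}

#' Remove estimated unwanted variation from the expression matrix
#'
#' Per gene, the `log(x + 1)` expression profile is regressed by ordinary
#' least squares on the factor columns (with an intercept, so gene means are
#' untouched) and the fitted factor component is subtracted; the result is
#' mapped back with `exp(.) - 1` and floored at 0. Projection makes the
#' operation idempotent. Alternatively, pass the factors as covariates to
#' [nb_wald_test()] instead of adjusting the matrix (the default route in
#' [run_pipeline()]).
#'
#' @param x an [roi_matrix()] or numeric matrix (normalized expression)
#' @param w an `unwanted_factors` object, or `NULL`/`k = 0` for identity
#' @return same container as `x`, adjusted
#' @export
remove_unwanted <- function(x, w) {
  m <- as_count_matrix(x)
  if (is.null(w) || w$k == 0L) return(x)
  stopifnot(inherits(w, "unwanted_factors"))
  if (nrow(w$factors) != ncol(m))
    abort("factor matrix has %d ROIs but the expression matrix has %d",
          nrow(w$factors), ncol(m))
  L <- log1p(m)
  M <- cbind(1, w$factors)
  # per-gene OLS: coef is (1 + k) x genes; drop the intercept row when
  # subtracting so only the factor component is removed
  coef <- solve(crossprod(M), crossprod(M, t(L)))
  L_adj <- L - t(M[, -1, drop = FALSE] %*% coef[-1, , drop = FALSE])
  out <- pmax(expm1(L_adj), 0)
  dimnames(out) <- dimnames(m)
  if (inherits(x, "roi_matrix")) set_counts(x, out) else out
}

#' Write unwanted factors as TSV (roi_id + one column per factor)
#' @param w an `unwanted_factors` object
#' @param path file path
#' @return `path`, invisibly
#' @export
write_factors_tsv <- function(w, path) {
  stopifnot(inherits(w, "unwanted_factors"))
  df <- data.frame(roi_id = rownames(w$factors), w$factors,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_full(df, path)
  invisible(path)
}
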
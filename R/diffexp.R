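#' Median-of-ratios size factors
#'
#' For each ROI, the factor is the median over genes of the ratio of its
#' count to the gene's geometric mean across ROIs, using only genes with
#' all-positive counts. When no gene is positive everywhere, a
#' positive-count-only variant is used: per-gene geometric means are taken
#' over the positive entries (zeros contributing nothing to the numerator
#' but kept in the denominator) and the median ratio is computed over
#' positive counts. Factors are normalized to geometric mean 1.
#'
#' @param x an [roi_matrix()] or numeric genes x ROIs matrix
#' @return named numeric vector of positive per-ROI size factors
#' @export
size_factors <- function(x) {
  m <- as_count_matrix(x)
  if (all(m == 0)) abort("cannot compute size factors of an all-zero matrix")
  all_pos <- rowSums(m > 0) == ncol(m)
  if (any(all_pos)) {
    lg <- rowMeans(log(m[all_pos, , drop = FALSE]))
    sf <- apply(log(m[all_pos, , drop = FALSE]) - lg, 2, stats::median)
  } else {
    any_pos <- rowSums(m > 0) > 0
    mm <- m[any_pos, , drop = FALSE]
    ll <- log(mm)
    ll[mm == 0] <- 0
    lg <- rowSums(ll) / ncol(mm)
    sf <- vapply(seq_len(ncol(mm)), function(j) {
      r <- log(mm[, j]) - lg
      stats::median(r[mm[, j] > 0])
    }, numeric(1))
  }
  sf <- exp(sf - mean(sf))
  stats::setNames(sf, colnames(m))
}

#' Gene-wise negative-binomial dispersion estimates
#'
#' Method-of-moments on size-factor-normalized counts:
#' `alpha_hat = max(0, (s^2 - mean) / mean^2)` per gene. A smooth trend
#' `a1/mean + a0` is fitted by least squares to the strictly positive raw
#' estimates, and the final dispersion is a weighted shrinkage of the raw
#' estimate toward the trend. Genes showing no overdispersion
#' (`s^2 <= mean`, including constant genes) keep `alpha = 0`.
#'
#' @param x an [roi_matrix()] or numeric matrix of counts
#' @param sf size factors (default [size_factors()])
#' @param shrink_weight weight on the trend in `[0, 1]`; 0 returns the raw
#'   method-of-moments estimates
#' @return numeric vector of dispersions (one per gene) with attributes
#'   `raw` and `trend`
#' @export
estimate_dispersions <- function(x, sf = NULL, shrink_weight = 0.5) {
  m <- as_count_matrix(x)
  if (ncol(m) < 2) abort("dispersion estimation needs at least 2 ROIs")
  if (!is_prob(shrink_weight)) abort("`shrink_weight` must be in [0, 1]")
  sf <- sf %||% size_factors(m)
  q <- sweep(m, 2, sf, "/")
  mu <- rowMeans(q)
  s2 <- rowSums((q - mu)^2) / (ncol(q) - 1)
  raw <- ifelse(mu > 0, pmax(0, (s2 - mu) / mu^2), 0)

  use <- raw > 0 & mu > 0
  if (sum(use) >= 2) {
    fit <- stats::lm.fit(cbind(1, 1 / mu[use]), raw[use])
    trend <- pmax(fit$coefficients[1] + fit$coefficients[2] / mu, 1e-8)
  } else {
    fallback <- if (any(use)) mean(raw[use]) else 0
    trend <- rep(pmax(fallback, 1e-8), length(mu))
  }
  final <- ifelse(raw > 0,
                  (1 - shrink_weight) * raw + shrink_weight * trend,
                  0)
  names(final) <- rownames(m)
  attr(final, "raw") <- stats::setNames(raw, rownames(m))
  attr(final, "trend") <- stats::setNames(as.numeric(trend), rownames(m))
  final
}

#' Negative-binomial Wald test for group differences
#'
#' Per-gene NB regression with log link, fitted by iteratively reweighted
#' least squares at fixed gene-wise dispersion, with log size factors as
#' offset. The design is intercept + group indicator (PD = 1, so positive
#' log2 fold changes mean higher in PD) + optional covariates such as
#' unwanted-variation factors. The Wald p-value comes from the standard
#' normal applied to coefficient/SE. Genes with all-zero counts get `NA`
#' p-values and are excluded from the Benjamini-Hochberg denominator.
#'
#' Simplifications relative to full DESeq2-style machinery, by design: no
#' independent filtering, no outlier handling, no fold-change shrinkage.
#'
#' @param x an [roi_matrix()] or numeric genes x ROIs matrix (raw or
#'   normalized; values must be non-negative)
#' @param group vector of `"PD"`/`"control"` per ROI; taken from the
#'   metadata when `x` is an `roi_matrix` and `group` is `NULL`
#' @param covariates optional numeric matrix (ROIs x c), e.g.
#'   `unwanted_factors$factors`
#' @param sf size factors (default [size_factors()])
#' @param dispersions per-gene dispersions (default [estimate_dispersions()])
#' @param alpha,lfc_min thresholds forwarded to [select_degs()]
#' @param max_iter,tol IRLS iteration cap and relative deviance tolerance
#' @return a `DegTable` data.frame: `gene`, `base_mean`, `log2fc`, `se`
#'   (log2 scale), `wald_stat`, `p`, `adj_p`, `is_deg`, `direction`,
#'   `converged`
#' @export
nb_wald_test <- function(x, group = NULL, covariates = NULL, sf = NULL,
                         dispersions = NULL, alpha = 0.05, lfc_min = 0.5,
                         max_iter = 100, tol = 1e-8) {
  m <- as_count_matrix(x)
  if (is.null(group)) {
    if (!inherits(x, "roi_matrix"))
      abort("`group` is required when `x` is a bare matrix")
    group <- x$metadata$group
  }
  if (length(group) != ncol(m)) abort("`group` must have one entry per ROI")
  if (!all(group %in% c("PD", "control")))
    abort("`group` entries must be 'PD' or 'control'")
  if (length(unique(group)) < 2) abort("both groups must be present")

  X <- cbind("(Intercept)" = 1, groupPD = as.numeric(group == "PD"))
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (nrow(covariates) != ncol(m))
      abort("`covariates` must have one row per ROI")
    if (is.null(colnames(covariates)))
      colnames(covariates) <- sprintf("C%d", seq_len(ncol(covariates)))
    X <- cbind(X, covariates)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X))
    abort("design is rank-deficient; collinear column(s): %s",
          paste(colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]], collapse = ", "))

  sf <- sf %||% size_factors(m)
  if (is.null(dispersions)) dispersions <- estimate_dispersions(m, sf)
  if (length(dispersions) == 1L) dispersions <- rep(dispersions, nrow(m))

  base_mean <- rowMeans(sweep(m, 2, sf, "/"))
  nz <- rowSums(m) > 0

  fit <- nb_irls(m[nz, , drop = FALSE], X, offset = log(sf),
                 alpha_disp = dispersions[nz], max_iter = max_iter, tol = tol)

  G <- nrow(m)
  log2fc <- numeric(G)
  se <- rep(NA_real_, G)
  wald <- rep(NA_real_, G)
  p <- rep(NA_real_, G)
  conv <- rep(NA, G)
  log2fc[nz] <- fit$beta[, 2] / log(2)
  se[nz] <- fit$se2 / log(2)
  wald[nz] <- fit$beta[, 2] / fit$se2
  p[nz] <- 2 * stats::pnorm(-abs(wald[nz]))
  conv[nz] <- fit$converged

  tab <- data.frame(gene = rownames(m), base_mean = base_mean,
                    log2fc = log2fc, se = se, wald_stat = wald, p = p,
                    adj_p = bh_adjust(p), is_deg = FALSE,
                    direction = "none", converged = conv,
                    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  attr(tab, "size_factors") <- sf
  attr(tab, "dispersions") <- dispersions
  select_degs(tab, alpha = alpha, lfc_min = lfc_min)
}

# Vectorized IRLS across genes sharing one design matrix.
# Y: G x n response; X: n x p design; offset: length-n; alpha_disp: length-G.
# Returns beta (G x p), se2 (SE of column 2, natural-log scale), converged.
nb_irls <- function(Y, X, offset, alpha_disp, max_iter = 100, tol = 1e-8) {
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  O <- matrix(offset, G, n, byrow = TRUE)
  pairs <- which(upper.tri(matrix(0, p, p), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]

  mu <- Y + 0.5
  eta <- log(mu)
  dev <- nb_deviance(Y, mu, alpha_disp)
  converged <- rep(FALSE, G)
  beta <- matrix(0, G, p)
  A <- NULL

  for (iter in seq_len(max_iter)) {
    w <- mu / (1 + mu * alpha_disp)          # alpha recycles along rows
    z <- (eta - O) + (Y - mu) / mu
    A <- w %*% XX                            # G x p(p+1)/2 : X'WX entries
    B <- (w * z) %*% X                       # G x p        : X'Wz
    beta <- solve_small(A, B, p, pairs)
    eta <- pmin(pmax(beta %*% t(X) + O, -30), 30)
    mu <- exp(eta)
    dev_new <- nb_deviance(Y, mu, alpha_disp)
    converged <- abs(dev_new - dev) / (abs(dev_new) + 0.1) < tol
    dev <- dev_new
    if (all(converged)) break
  }

  se2 <- se_beta2(A, p, pairs)
  list(beta = beta, se2 = se2, converged = converged, iterations = iter)
}

# solve the per-gene p x p normal equations; closed form for p = 2
solve_small <- function(A, B, p, pairs) {
  if (p == 2L) {
    a11 <- A[, 1]; a12 <- A[, 2]; a22 <- A[, 3]
    det <- a11 * a22 - a12^2
    det[det <= 0] <- NA_real_
    cbind((a22 * B[, 1] - a12 * B[, 2]) / det,
          (a11 * B[, 2] - a12 * B[, 1]) / det)
  } else {
    G <- nrow(A)
    beta <- matrix(0, G, p)
    S <- matrix(0, p, p)
    for (g in seq_len(G)) {
      S[cbind(pairs[, 1], pairs[, 2])] <- A[g, ]
      S[cbind(pairs[, 2], pairs[, 1])] <- A[g, ]
      beta[g, ] <- tryCatch(solve(S, B[g, ]), error = function(e) rep(NA_real_, p))
    }
    beta
  }
}

# SE of the group coefficient (column 2) from (X'WX)^{-1}[2,2]
se_beta2 <- function(A, p, pairs) {
  if (p == 2L) {
    a11 <- A[, 1]; a12 <- A[, 2]; a22 <- A[, 3]
    det <- a11 * a22 - a12^2
    out <- sqrt(a11 / det)
    out[det <= 0] <- NA_real_
    out
  } else {
    G <- nrow(A)
    S <- matrix(0, p, p)
    vapply(seq_len(G), function(g) {
      S[cbind(pairs[, 1], pairs[, 2])] <- A[g, ]
      S[cbind(pairs[, 2], pairs[, 1])] <- A[g, ]
      tryCatch(sqrt(solve(S)[2, 2]), error = function(e) NA_real_)
    }, numeric(1))
  }
}

# NB deviance at fixed dispersion (Poisson when alpha = 0); rowwise over genes
nb_deviance <- function(Y, mu, alpha_disp) {
  t1 <- Y * log(ifelse(Y > 0, Y / mu, 1))
  pois <- alpha_disp == 0
  out <- numeric(nrow(Y))
  if (any(pois)) {
    yy <- Y[pois, , drop = FALSE]
    out[pois] <- 2 * rowSums(t1[pois, , drop = FALSE] -
                               (yy - mu[pois, , drop = FALSE]))
  }
  if (any(!pois)) {
    a <- alpha_disp[!pois]
    yy <- Y[!pois, , drop = FALSE]
    mm <- mu[!pois, , drop = FALSE]
    out[!pois] <- 2 * rowSums(t1[!pois, , drop = FALSE] -
      (yy + 1 / a) * log((1 + a * yy) / (1 + a * mm)))
  }
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `NA` entries (untested genes) are ignored in the denominator and
#' propagated as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]`, `NA` allowed
#' @return adjusted p-values, same length and order
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) abort("`p` must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) abort("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  pp <- p[ok]
  m <- length(pp)
  if (m) {
    o <- order(pp, decreasing = TRUE)
    adj <- pmin(1, cummin(pp[o] * m / seq(m, 1)))
    tmp <- numeric(m)
    tmp[o] <- adj
    out[ok] <- tmp
  }
  out
}

#' Flag differentially expressed genes
#'
#' A gene is a DEG when `adj_p < alpha` (strict) and `|log2fc| > lfc_min`
#' (strict); `direction` follows the sign of `log2fc` for DEGs, `"none"`
#' otherwise.
#'
#' @param tab a `DegTable` from [nb_wald_test()]
#' @param alpha adjusted-p threshold (default 0.05)
#' @param lfc_min absolute log2-fold-change threshold (default 0.5)
#' @return the table with `is_deg` and `direction` set
#' @export
select_degs <- function(tab, alpha = 0.05, lfc_min = 0.5) {
  stopifnot(is.data.frame(tab), all(c("adj_p", "log2fc") %in% names(tab)))
  tab$is_deg <- !is.na(tab$adj_p) & tab$adj_p < alpha & abs(tab$log2fc) > lfc_min
  tab$direction <- ifelse(tab$is_deg,
                          ifelse(tab$log2fc > 0, "up", "down"),
                          "none")
  attr(tab, "n_up") <- sum(tab$direction == "up")
  attr(tab, "n_down") <- sum(tab$direction == "down")
  tab
}
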
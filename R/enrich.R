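#' Gene-set library container
#'
#' @param terms named list; each element a list with `description` (string)
#'   and `genes` (unique character vector, non-empty)
#' @param background_size background universe size `N`; defaults to 20,003,
#'   the background consistent with standard GO Biological Process
#'   over-representation statistics; every term must fit inside it
#' @param universe optional explicit background gene list (used to intersect
#'   queries before testing when available)
#' @return a `gene_set_library`
#' @export
gene_set_library <- function(terms, background_size = 20003, universe = NULL) {
  stopifnot(is.list(terms))
  if (length(terms) && is.null(names(terms))) abort("terms must be named")
  for (nm in names(terms)) {
    t <- terms[[nm]]
    if (is.null(t$genes) || length(t$genes) == 0)
      abort("term '%s' has an empty gene set", nm)
    terms[[nm]]$genes <- unique(as.character(t$genes))
    if (length(terms[[nm]]$genes) > background_size)
      abort("term '%s' is larger than the background (N = %d)", nm, background_size)
  }
  structure(list(terms = terms, background_size = background_size,
                 universe = universe),
            class = "gene_set_library")
}

#' @export
print.gene_set_library <- function(x, ...) {
  cat(sprintf("gene_set_library: %d terms, background N = %d\n",
              length(x$terms), x$background_size))
  invisible(x)
}

#' Read / write GMT gene-set files
#'
#' One term per line: id, description, then member genes, tab-separated.
#' Duplicate genes within a term are collapsed; case is preserved.
#'
#' @param path file path
#' @param background_size background size for the resulting library
#' @param lib a `gene_set_library` (for the writer)
#' @return `read_gmt` returns a `gene_set_library`; `write_gmt` returns
#'   `path`, invisibly
#' @export
read_gmt <- function(path, background_size = 20003) {
  if (!file.exists(path)) abort("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  terms <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      abort("GMT parse error at line %d: expected >= 3 tab-separated fields", i)
    terms[[f[1]]] <- list(description = f[2], genes = unique(f[-(1:2)]))
  }
  gene_set_library(terms, background_size = background_size)
}

#' @rdname read_gmt
#' @export
write_gmt <- function(lib, path) {
  stopifnot(inherits(lib, "gene_set_library"))
  lines <- vapply(names(lib$terms), function(nm) {
    t <- lib$terms[[nm]]
    paste(c(nm, t$description, t$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` for `X ~ Hypergeometric(N, K, n)`:
#' the chance of drawing at least `k` members of a `K`-gene set in an
#' `n`-gene query from an `N`-gene background.
#'
#' @param k overlap; @param K gene-set size; @param n query size;
#' @param N background size
#' @return p-value in `[0, 1]`
#' @export
hypergeom_p <- function(k, K, n, N) {
  check_counts_knN(k, K, n, N)
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

check_counts_knN <- function(k, K, n, N) {
  if (!all(vapply(list(k, K, n, N), is_count, logical(1))))
    abort("k, K, n, N must be non-negative integers")
  if (K > N || n > N) abort("K and n must not exceed the background N")
  if (k > min(K, n)) abort("overlap k exceeds min(K, n)")
  invisible(TRUE)
}

#' Enrichment odds ratio
#'
#' `k (N - K - n + k) / ((K - k)(n - k))`, the cross-product ratio of the
#' 2 x 2 overlap table. Returns 0 when `k = 0` and `+Inf` when a denominator
#' factor vanishes with a positive numerator.
#'
#' @inheritParams hypergeom_p
#' @return non-negative real, possibly `Inf`
#' @export
odds_ratio <- function(k, K, n, N) {
  check_counts_knN(k, K, n, N)
  if (k == 0) return(0)
  num <- k * (N - K - n + k)
  den <- (K - k) * (n - k)
  if (den == 0) return(if (num > 0) Inf else 0)
  num / den
}

#' Combined enrichment score
#'
#' `odds_ratio * (-ln p)`: the conventional ranking statistic combining
#' effect size and significance. 0 when `p = 1`; `+Inf` with a warning when
#' `p = 0`.
#'
#' @param or odds ratio (`>= 0`)
#' @param p p-value in `[0, 1]`
#' @return non-negative real, possibly `Inf`
#' @export
combined_score <- function(or, p) {
  if (!is.numeric(or) || length(or) != 1L || is.na(or) || or < 0)
    abort("`or` must be a non-negative number")
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p < 0 || p > 1)
    abort("`p` must lie in [0, 1]")
  if (p == 0) {
    warning("p = 0: combined score is infinite")
    return(Inf)
  }
  if (p == 1) return(0)
  or * (-log(p))
}

#' Gene-set over-representation analysis
#'
#' Tests each library term with overlap `k >= 1` against the query using the
#' hypergeometric upper tail, computes the odds ratio and combined score,
#' and applies Benjamini-Hochberg adjustment across the tested terms. The
#' query is deduplicated and, when the library carries an explicit universe,
#' intersected with it first; the post-intersection count is the query size
#' `n`. The full table (sorted by p ascending) is returned; use
#' [significant_enrichment()] for the `adj_p < 0.05` reporting filter.
#'
#' @param query character vector of gene ids (e.g. up-regulated DEGs)
#' @param lib a `gene_set_library`
#' @param background_size override for the library's `N`
#' @return data.frame with columns `term`, `description`, `overlap` (k/K),
#'   `k`, `K`, `n`, `p`, `adj_p`, `odds_ratio`, `combined_score`, `genes`
#'   (overlapping genes, `;`-separated), sorted by `p`
#' @export
enrich <- function(query, lib, background_size = NULL) {
  stopifnot(inherits(lib, "gene_set_library"))
  if (length(query) == 0) abort("empty query")
  query <- unique(as.character(query))
  if (!is.null(lib$universe)) query <- intersect(query, lib$universe)
  if (length(query) == 0) abort("query is empty after intersection with the background universe")
  N <- background_size %||% lib$background_size
  n <- length(query)

  rows <- lapply(names(lib$terms), function(nm) {
    t <- lib$terms[[nm]]
    hit <- sort(intersect(query, t$genes))
    k <- length(hit)
    if (k == 0) return(NULL)
    K <- length(t$genes)
    p <- hypergeom_p(k, K, n, N)
    or <- odds_ratio(k, K, n, N)
    data.frame(term = nm, description = t$description,
               overlap = sprintf("%d/%d", k, K), k = k, K = K, n = n,
               p = p, adj_p = NA_real_, odds_ratio = or,
               combined_score = if (p == 1) 0 else or * (-log(p)),
               genes = paste(hit, collapse = ";"),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) {
    return(data.frame(term = character(), description = character(),
                      overlap = character(), k = integer(), K = integer(),
                      n = integer(), p = numeric(), adj_p = numeric(),
                      odds_ratio = numeric(), combined_score = numeric(),
                      genes = character(), stringsAsFactors = FALSE))
  }
  tab <- do.call(rbind, rows)
  tab$adj_p <- bh_adjust(tab$p)
  tab <- tab[order(tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}

#' Reporting filter: significantly enriched terms
#'
#' @param tab an enrichment table from [enrich()]
#' @param alpha adjusted-p threshold (default 0.05)
#' @return the filtered table
#' @export
significant_enrichment <- function(tab, alpha = 0.05) {
  tab[!is.na(tab$adj_p) & tab$adj_p < alpha, , drop = FALSE]
}
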
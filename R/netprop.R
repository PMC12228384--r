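#' Protein-protein interaction network container
#'
#' Undirected, unweighted gene-symbol graph. Self-edges are dropped and
#' duplicate (including reversed) edges collapsed on construction.
#'
#' @param edges 2-column character matrix or data.frame of interacting
#'   symbol pairs; may be empty
#' @param nodes optional node universe (a superset of the edge endpoints;
#'   extra entries become isolated nodes)
#' @return a `ppi_network`: list with `nodes` (character) and `edges`
#'   (2-column character matrix)
#' @export
ppi_network <- function(edges, nodes = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) && ncol(edges) != 2)
    abort("`edges` must have exactly 2 columns")
  storage.mode(edges) <- "character"
  if (nrow(edges)) {
    edges <- edges[edges[, 1] != edges[, 2], , drop = FALSE]   # self-loops
    if (nrow(edges)) {
      a <- pmin(edges[, 1], edges[, 2])
      b <- pmax(edges[, 1], edges[, 2])
      keep <- !duplicated(paste(a, b, sep = "\r"))
      edges <- cbind(a, b)[keep, , drop = FALSE]
    }
  }
  endpoint <- if (nrow(edges)) unique(as.vector(edges)) else character(0)
  if (!is.null(nodes)) {
    nodes <- unique(as.character(nodes))
    if (!all(endpoint %in% nodes))
      abort("`nodes` must contain every edge endpoint")
  } else {
    nodes <- sort(endpoint)
  }
  colnames(edges) <- c("a", "b")
  structure(list(nodes = nodes, edges = edges), class = "ppi_network")
}

#' @export
print.ppi_network <- function(x, ...) {
  cat(sprintf("ppi_network: %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Read a PPI network from disk
#'
#' `edge_list`: two tab-separated symbols per line, no header.
#' `biogrid_tab3`: a tab-separated table whose header contains the columns
#' `Official Symbol Interactor A` and `Official Symbol Interactor B`;
#' multi-edges from repeated physical evidence are collapsed. Symbols are
#' upper-cased in both formats.
#'
#' @param path file path
#' @param format `"edge_list"` (default) or `"biogrid_tab3"`
#' @return a [ppi_network()]
#' @export
read_network <- function(path, format = c("edge_list", "biogrid_tab3")) {
  format <- match.arg(format)
  if (!file.exists(path)) abort("network file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (format == "edge_list") {
    lines <- lines[nzchar(lines)]
    if (!length(lines)) return(ppi_network(matrix(character(0), 0, 2)))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2)
    if (length(bad))
      abort("edge-list parse error at line %d: expected 2 tab-separated symbols", bad[1])
    m <- toupper(do.call(rbind, parts))
    ppi_network(m)
  } else {
    if (!length(lines)) return(ppi_network(matrix(character(0), 0, 2)))
    header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
    ia <- match("official symbol interactor a", tolower(header))
    ib <- match("official symbol interactor b", tolower(header))
    if (is.na(ia) || is.na(ib))
      abort("TAB3 header lacks 'Official Symbol Interactor A/B' columns")
    body <- lines[-1]
    body <- body[nzchar(body)]
    if (!length(body)) return(ppi_network(matrix(character(0), 0, 2)))
    parts <- strsplit(body, "\t", fixed = TRUE)
    bad <- which(lengths(parts) < max(ia, ib))
    if (length(bad))
      abort("TAB3 parse error at line %d: too few fields", bad[1] + 1L)
    m <- toupper(cbind(vapply(parts, `[`, character(1), ia),
                       vapply(parts, `[`, character(1), ib)))
    ppi_network(m)
  }
}

#' Write a network as a 2-column tab-separated edge list
#' @param net a `ppi_network`
#' @param path file path
#' @return `path`, invisibly
#' @export
write_network <- function(net, path) {
  stopifnot(inherits(net, "ppi_network"))
  writeLines(paste(net$edges[, 1], net$edges[, 2], sep = "\t"), path)
  invisible(path)
}

# adjacency list as a list of integer neighbor vectors, in node order
adjacency_list <- function(net) {
  idx <- seq_along(net$nodes)
  names(idx) <- net$nodes
  adj <- vector("list", length(idx))
  if (nrow(net$edges)) {
    a <- idx[net$edges[, 1]]
    b <- idx[net$edges[, 2]]
    half <- split(c(b, a), c(a, b))
    adj[as.integer(names(half))] <- lapply(half, as.integer)
  }
  adj[vapply(adj, is.null, logical(1))] <- list(integer(0))
  adj
}

#' Column-normalized adjacency (transition) matrix
#'
#' `W'[i, j] = A[i, j] / degree(j)`: column `j` spreads mass evenly over the
#' neighbors of node `j`. Isolated nodes get an all-zero column; the restart
#' term of [rwr()] re-injects any mass they would swallow.
#'
#' @param net a `ppi_network` (non-empty)
#' @return dense numeric matrix with node dimnames; every non-isolated
#'   column sums to 1
#' @export
column_normalize <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- length(net$nodes)
  if (n == 0) abort("empty network")
  A <- matrix(0, n, n, dimnames = list(net$nodes, net$nodes))
  if (nrow(net$edges)) {
    idx <- seq_len(n)
    names(idx) <- net$nodes
    a <- idx[net$edges[, 1]]
    b <- idx[net$edges[, 2]]
    A[cbind(a, b)] <- 1
    A[cbind(b, a)] <- 1
  }
  deg <- colSums(A)
  nzc <- deg > 0
  A[, nzc] <- sweep(A[, nzc, drop = FALSE], 2, deg[nzc], "/")
  A
}

#' Fold-change seed vector for network propagation
#'
#' Maps the tested genes onto the network and initializes each mapped node
#' with its fold change: `abs` mode (default) uses `|log2fc|` (a probability
#' vector must be non-negative, so magnitudes are the minimal faithful use
#' of signed fold changes); `signed_positive` floors negative fold changes
#' at 0 first. The vector is normalized to sum 1 over all network nodes.
#'
#' @param deg a `DegTable` from [nb_wald_test()]
#' @param net a `ppi_network`
#' @param mode `"abs"` or `"signed_positive"`
#' @return named numeric seed vector over `net$nodes`, summing to 1
#' @export
initialize_seed <- function(deg, net, mode = c("abs", "signed_positive")) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(deg), inherits(net, "ppi_network"))
  hit <- deg$gene %in% net$nodes
  if (!any(hit)) abort("no tested gene maps onto the network")
  n_unmapped <- sum(!hit)
  if (n_unmapped)
    message(sprintf("initialize_seed: %d gene(s) not on the network", n_unmapped))
  val <- switch(mode,
                abs = abs(deg$log2fc[hit]),
                signed_positive = pmax(deg$log2fc[hit], 0))
  p0 <- stats::setNames(numeric(length(net$nodes)), net$nodes)
  p0[deg$gene[hit]] <- val
  s <- sum(p0)
  if (s <= 0) abort("seed vector is all zero")
  p0 / s
}

#' Random walk with restart
#'
#' Iterates `p_{t+1} = (1 - r) W' p_t + r p_0` until the L1 change drops
#' below `tol`. Mass lost into all-zero (isolated-node) columns is
#' re-injected through the seed distribution, so iterates conserve total
#' mass. `method = "exact"` instead solves the fixed-point linear system
#' `(I - (1 - r) W'') p = r p_0` directly (`W''` being `W'` with the
#' seed-reinjection columns filled in).
#'
#' @param W column-normalized transition matrix from [column_normalize()]
#' @param p0 seed vector (non-negative, sums to 1), aligned with `W`
#' @param r restart probability in `(0, 1]`; 0.5 by default (never stated in
#'   the source analyses; sweep it via [rwr_stability()])
#' @param tol L1 convergence tolerance
#' @param max_iter iteration cap; non-convergence is an error carrying the
#'   last residual
#' @param method `"iterative"` (default) or `"exact"`
#' @return named steady-state probability vector
#' @export
rwr <- function(W, p0, r = 0.5, tol = 1e-8, max_iter = 1000,
                method = c("iterative", "exact")) {
  method <- match.arg(method)
  if (!is.numeric(r) || length(r) != 1L || r <= 0 || r > 1)
    abort("restart rate r must lie in (0, 1]")
  if (length(p0) != nrow(W)) abort("p0 length does not match W")
  if (any(p0 < 0) || abs(sum(p0) - 1) > 1e-8)
    abort("p0 must be non-negative and sum to 1")
  dangling <- colSums(W) == 0
  if (method == "exact") {
    W2 <- W
    if (any(dangling)) W2[, dangling] <- p0
    p <- solve(diag(nrow(W)) - (1 - r) * W2, r * p0)
    return(stats::setNames(as.numeric(p), rownames(W)))
  }
  p <- p0
  for (iter in seq_len(max_iter)) {
    lost <- if (any(dangling)) sum(p[dangling]) else 0
    p_new <- as.numeric((1 - r) * (W %*% p)) + (r + (1 - r) * lost) * p0
    delta <- sum(abs(p_new - p))
    p <- p_new
    if (delta < tol)
      return(stats::setNames(p, rownames(W)))
  }
  stop(structure(class = c("rwr_no_convergence", "error", "condition"),
                 list(message = sprintf(
                   "random walk did not converge in %d iterations (last L1 residual %.3g)",
                   max_iter, delta), call = NULL, residual = delta)))
}

#' Betweenness centrality (ordered pairs)
#'
#' Shortest-path betweenness `BC(v) = sum over ordered pairs s != v != t of
#' sigma_st(v) / sigma_st`, with `sigma_st` the number of shortest paths
#' from `s` to `t` and `sigma_st(v)` those passing through `v`. Computed by
#' breadth-first accumulation (Brandes) in O(VE); disconnected pairs
#' contribute 0. Ordered-pair counting means values are twice the
#' unordered-pair convention; downstream use is rank-based, so the scale is
#' immaterial.
#'
#' @param net a `ppi_network` (non-empty)
#' @return named numeric vector of non-negative centralities over the nodes
#' @export
betweenness_centrality <- function(net) {
  stopifnot(inherits(net, "ppi_network"))
  n <- length(net$nodes)
  if (n == 0) abort("empty network")
  adj <- adjacency_list(net)
  bc <- numeric(n)
  for (s in seq_len(n)) {
    dist <- rep(-1L, n)
    sigma <- numeric(n)
    dist[s] <- 0L
    sigma[s] <- 1
    order_visited <- integer(n)
    head <- 1L; tail <- 1L
    order_visited[1L] <- s
    while (head <= tail) {
      v <- order_visited[head]; head <- head + 1L
      for (w in adj[[v]]) {
        if (dist[w] < 0L) {
          dist[w] <- dist[v] + 1L
          tail <- tail + 1L
          order_visited[tail] <- w
          sigma[w] <- sigma[v]
        } else if (dist[w] == dist[v] + 1L) {
          sigma[w] <- sigma[w] + sigma[v]
        }
      }
    }
    delta <- numeric(n)
    for (i in seq.int(tail, 1L)) {
      v <- order_visited[i]
      for (w in adj[[v]]) {
        if (dist[w] == dist[v] + 1L)
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
      }
      if (v != s) bc[v] <- bc[v] + delta[v]
    }
  }
  stats::setNames(bc, net$nodes)
}

#' Key-gene selection from propagation and pathway evidence
#'
#' Ranks genes by steady-state propagation probability (descending), ties
#' broken by betweenness centrality (descending) then gene name, takes the
#' top `top_n`, and intersects with the union of overlapping genes of the
#' significantly enriched terms (`adj_p < alpha`).
#'
#' @param prob named steady-state vector from [rwr()]
#' @param bc named betweenness vector from [betweenness_centrality()]
#' @param enrichment enrichment table(s) from [enrich()] (a data.frame or a
#'   list of them, e.g. up- and down-regulated results)
#' @param top_n number of top-probability genes to keep (default 20)
#' @param alpha significance threshold on `adj_p` (default 0.05)
#' @return a `key_gene_report`: `ranked` data.frame (gene, probability, bc,
#'   rank), `top` genes, `pathway_genes`, `key_genes`
#' @export
select_key_genes <- function(prob, bc, enrichment, top_n = 20, alpha = 0.05) {
  if (!is_pos_count(top_n)) abort("`top_n` must be a positive integer")
  genes <- names(prob)
  if (is.null(genes)) abort("`prob` must be named by gene")
  bc <- bc[genes]
  bc[is.na(bc)] <- 0
  o <- order(-prob, -bc, genes)
  ranked <- data.frame(gene = genes[o], probability = as.numeric(prob[o]),
                       bc = as.numeric(bc[o]), rank = seq_along(o),
                       stringsAsFactors = FALSE)
  top <- ranked$gene[seq_len(min(top_n, nrow(ranked)))]

  if (is.data.frame(enrichment)) enrichment <- list(enrichment)
  sig_genes <- character(0)
  n_rows <- 0L
  for (tab in enrichment) {
    if (!nrow(tab)) next
    n_rows <- n_rows + nrow(tab)
    sig <- significant_enrichment(tab, alpha)
    if (nrow(sig))
      sig_genes <- union(sig_genes, unlist(strsplit(sig$genes, ";", fixed = TRUE)))
  }
  if (n_rows == 0L)
    warning("empty enrichment results: key gene set will be empty")
  key <- top[top %in% sig_genes]
  structure(list(ranked = ranked, top = top,
                 pathway_genes = sort(sig_genes), key_genes = key),
            class = "key_gene_report")
}

#' @export
print.key_gene_report <- function(x, ...) {
  cat(sprintf("key_gene_report: %d ranked genes; top %d; %d pathway genes; %d key genes\n",
              nrow(x$ranked), length(x$top), length(x$pathway_genes),
              length(x$key_genes)))
  if (length(x$key_genes))
    cat("key genes:", paste(x$key_genes, collapse = ", "), "\n")
  invisible(x)
}

#' Key-gene stability across restart rates
#'
#' Re-runs [rwr()] at several restart rates and reports the key genes from
#' each, as a cheap sensitivity check on the (unknown) restart rate.
#'
#' @param W,p0,bc,enrichment as in [rwr()] / [select_key_genes()]
#' @param rates restart rates to sweep (default 0.3, 0.5, 0.7)
#' @param top_n,alpha forwarded to [select_key_genes()]
#' @return named list (one element per rate) of key-gene character vectors
#' @export
rwr_stability <- function(W, p0, bc, enrichment, rates = c(0.3, 0.5, 0.7),
                          top_n = 20, alpha = 0.05) {
  out <- lapply(rates, function(r) {
    p <- rwr(W, p0, r = r)
    select_key_genes(p, bc, enrichment, top_n = top_n, alpha = alpha)$key_genes
  })
  names(out) <- sprintf("r=%g", rates)
  out
}
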
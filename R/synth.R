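#' Simulation parameters for the synthetic ROI study
#'
#' Defaults emulate the profiled colon cohort: 5 PD and 5 control specimens,
#' one slide each, 6 ROIs per compartment (myenteric plexus and intestinal
#' epithelium) for 120 ROIs total, and 18,677 gene targets. Counts follow a
#' negative binomial with `Var = mu + dispersion * mu^2`; per-gene baseline
#' means are log-normal; slide-level batch factors act on the log-mean scale;
#' the per-ROI library factor scales with ROI area times log-normal noise.
#'
#' @param n_pd,n_ctrl number of PD / control specimens (one slide each)
#' @param rois_per_compartment ROIs drawn per compartment on each slide
#' @param n_genes number of gene targets
#' @param baseline_log_mean,baseline_log_sd natural-log mean and sd of the
#'   per-gene baseline expected count (defaults give a median baseline of
#'   ~20 counts, a realistic shallow whole-transcriptome ROI depth)
#' @param dispersion negative-binomial dispersion `alpha` (`Var = mu + alpha mu^2`);
#'   0 gives Poisson counts
#' @param n_deg number of genes carrying a planted group effect
#' @param lfc_magnitude absolute planted log2 fold change (PD vs control);
#'   signs alternate so half the planted genes go up, half down
#' @param n_batch_factors number of slide-level batch factors (0 disables)
#' @param batch_sd sd of the per-gene loadings on each batch factor
#'   (log-mean scale)
#' @param libsize_sd sd of the log-normal noise multiplying the area-driven
#'   library size factor
#' @param seed integer seed; all randomness in the module flows from it
#' @return a validated list of class `sim_params`
#' @export
sim_params <- function(n_pd = 5, n_ctrl = 5, rois_per_compartment = 6,
                       n_genes = 18677,
                       baseline_log_mean = 3, baseline_log_sd = 1.5,
                       dispersion = 0.2,
                       n_deg = 200, lfc_magnitude = 1,
                       n_batch_factors = 1, batch_sd = 0.5,
                       libsize_sd = 0.2,
                       seed = 1) {
  p <- list(n_pd = n_pd, n_ctrl = n_ctrl,
            rois_per_compartment = rois_per_compartment,
            n_genes = n_genes,
            baseline_log_mean = baseline_log_mean,
            baseline_log_sd = baseline_log_sd,
            dispersion = dispersion,
            n_deg = n_deg, lfc_magnitude = lfc_magnitude,
            n_batch_factors = n_batch_factors, batch_sd = batch_sd,
            libsize_sd = libsize_sd,
            seed = seed)
  for (f in c("n_pd", "n_ctrl", "rois_per_compartment", "n_genes"))
    if (!is_pos_count(p[[f]])) abort("sim_params: `%s` must be a positive integer", f)
  for (f in c("n_deg", "n_batch_factors"))
    if (!is_count(p[[f]])) abort("sim_params: `%s` must be a non-negative integer", f)
  for (f in c("baseline_log_sd", "dispersion", "lfc_magnitude", "batch_sd", "libsize_sd"))
    if (!is.numeric(p[[f]]) || length(p[[f]]) != 1L || !is.finite(p[[f]]) || p[[f]] < 0)
      abort("sim_params: `%s` must be a non-negative number", f)
  if (!is.numeric(p$baseline_log_mean) || !is.finite(p$baseline_log_mean))
    abort("sim_params: `baseline_log_mean` must be finite")
  if (p$n_deg > p$n_genes) abort("sim_params: n_deg exceeds n_genes")
  if (!is.numeric(p$seed) || length(p$seed) != 1L || !is.finite(p$seed))
    abort("sim_params: `seed` must be an integer scalar")
  structure(p, class = "sim_params")
}

default_universe <- function(n_genes) sprintf("G%06d", seq_len(n_genes))

#' Generate the ROI design table
#'
#' Lays out the slides and ROIs of the synthetic study: each specimen
#' contributes one slide with `rois_per_compartment` ROIs per compartment.
#' Plexus areas are drawn uniformly in [5,000, 30,000] um^2 with nuclei in
#' (20, 100]; epithelium areas in [15,000, 150,000] um^2 with nuclei in
#' (100, 1,000], matching the observed size and cellularity contrast between
#' the two compartments.
#'
#' @param params a [sim_params()] object
#' @return data.frame with columns `roi_id`, `slide_id`, `group`,
#'   `compartment`, `area`, `nuclei`; deterministic given `params$seed`
#' @export
generate_design <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  slides <- c(sprintf("PD%02d", seq_len(params$n_pd)),
              sprintf("CT%02d", seq_len(params$n_ctrl)))
  groups <- rep(c("PD", "control"), c(params$n_pd, params$n_ctrl))
  nr <- params$rois_per_compartment
  with_seed(params$seed, {
    rows <- lapply(seq_along(slides), function(s) {
      per_comp <- lapply(c("plexus", "epithelium"), function(comp) {
        if (comp == "plexus") {
          area <- stats::runif(nr, 5000, 30000)
          nuclei <- sample(21:100, nr, replace = TRUE)
        } else {
          area <- stats::runif(nr, 15000, 150000)
          nuclei <- sample(101:1000, nr, replace = TRUE)
        }
        data.frame(
          roi_id = sprintf("%s_%s_%02d", slides[s], comp, seq_len(nr)),
          slide_id = slides[s], group = groups[s], compartment = comp,
          area = area, nuclei = nuclei, stringsAsFactors = FALSE)
      })
      do.call(rbind, per_comp)
    })
    design <- do.call(rbind, rows)
    rownames(design) <- NULL
    design
  })
}

#' Simulate ROI-level negative-binomial counts with planted structure
#'
#' Per-gene expected counts follow
#' `mu = baseline * 2^(lfc * group * deg) * exp(batch) * libfactor`, where
#' `lfc` is the signed planted log2 fold change of the `n_deg` chosen genes,
#' `batch` is the sum of slide-level factor x gene-loading products, and
#' `libfactor = area / mean(area) * lognormal(0, libsize_sd)`. Counts are
#' negative binomial with `size = 1/dispersion` (Poisson when
#' `dispersion = 0`).
#'
#' @param design design table from [generate_design()]
#' @param params a [sim_params()] object
#' @param universe optional character vector of gene ids (length
#'   `params$n_genes`); default `G000001...`
#' @return list with elements `data` (an [roi_matrix()]) and `truth`
#'   (a `ground_truth`: `deg_genes` data.frame of gene + true_log2fc,
#'   `batch_factor_matrix` (ROIs x k, columns centered),
#'   `library_size_factors`)
#' @export
simulate_counts <- function(design, params = sim_params(), universe = NULL) {
  stopifnot(inherits(params, "sim_params"))
  if (!is.data.frame(design) || nrow(design) == 0L)
    abort("`design` must be a non-empty design data.frame")
  genes <- universe %||% default_universe(params$n_genes)
  if (length(genes) != params$n_genes)
    abort("`universe` must have length n_genes = %d", params$n_genes)
  G <- params$n_genes
  n <- nrow(design)
  slides <- design$slide_id
  is_pd <- as.numeric(design$group == "PD")

  with_seed(params$seed + 1L, {
    base_log <- stats::rnorm(G, params$baseline_log_mean, params$baseline_log_sd)

    true_lfc <- numeric(G)
    deg_idx <- integer(0)
    if (params$n_deg > 0) {
      deg_idx <- sort(sample.int(G, params$n_deg))
      signs <- rep(c(1, -1), length.out = params$n_deg)
      true_lfc[deg_idx] <- signs * params$lfc_magnitude
    }

    k <- params$n_batch_factors
    batch_log <- matrix(0, G, n)
    Fmat <- matrix(0, n, 0)
    if (k > 0) {
      uslides <- unique(slides)
      Fmat <- vapply(seq_len(k), function(j) {
        f <- stats::rnorm(length(uslides))[match(slides, uslides)]
        f - mean(f)
      }, numeric(n))
      lambda <- matrix(stats::rnorm(G * k, 0, params$batch_sd), G, k)
      batch_log <- lambda %*% t(Fmat)
    }

    lib <- design$area / mean(design$area) *
      exp(stats::rnorm(n, 0, params$libsize_sd))

    log_mu <- base_log + outer(true_lfc * log(2), is_pd) + batch_log +
      matrix(log(lib), G, n, byrow = TRUE)
    mu <- exp(log_mu)

    counts <- if (params$dispersion > 0) {
      matrix(stats::rnbinom(G * n, mu = mu, size = 1 / params$dispersion), G, n)
    } else {
      matrix(stats::rpois(G * n, lambda = mu), G, n)
    }
    dimnames(counts) <- list(genes, design$roi_id)
    rownames(Fmat) <- design$roi_id
    if (ncol(Fmat)) colnames(Fmat) <- sprintf("W%d", seq_len(ncol(Fmat)))

    truth <- structure(list(
      deg_genes = data.frame(gene = genes[deg_idx],
                             true_log2fc = true_lfc[deg_idx],
                             stringsAsFactors = FALSE),
      batch_factor_matrix = Fmat,
      library_size_factors = stats::setNames(lib, design$roi_id)
    ), class = "ground_truth")

    list(data = roi_matrix(counts, design), truth = truth)
  })
}

#' Write / read simulation ground truth
#'
#' Three plain TSVs under `dir`: the planted genes with their signed true
#' log2 fold changes, the ROI x factor batch matrix, and the per-ROI library
#' size factors. Numerics are written at full double precision so the
#' round-trip is lossless.
#'
#' @param truth a `ground_truth` object from [simulate_counts()]
#' @param dir directory (created if missing)
#' @return `read_ground_truth` returns the `ground_truth`; the writer
#'   returns `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
  stopifnot(inherits(truth, "ground_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_tsv_full(truth$deg_genes, file.path(dir, "deg_genes.tsv"))
  bf <- data.frame(roi_id = rownames(truth$batch_factor_matrix),
                   truth$batch_factor_matrix,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv_full(bf, file.path(dir, "batch_factors.tsv"))
  lf <- data.frame(roi_id = names(truth$library_size_factors),
                   library_size_factor = unname(truth$library_size_factors),
                   stringsAsFactors = FALSE)
  write_tsv_full(lf, file.path(dir, "library_factors.tsv"))
  invisible(dir)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(dir) {
  deg <- read_tsv(file.path(dir, "deg_genes.tsv"))
  deg$gene <- as.character(deg$gene)
  deg$true_log2fc <- as.numeric(deg$true_log2fc)
  bf <- read_tsv(file.path(dir, "batch_factors.tsv"))
  fm <- as.matrix(bf[, -1, drop = FALSE])
  rownames(fm) <- bf$roi_id
  lf <- read_tsv(file.path(dir, "library_factors.tsv"))
  structure(list(
    deg_genes = deg,
    batch_factor_matrix = fm,
    library_size_factors = stats::setNames(lf$library_size_factor, lf$roi_id)
  ), class = "ground_truth")
}

#' Simulate a scale-free protein-protein interaction network
#'
#' Barabasi-Albert preferential attachment: connected, undirected,
#' scale-free, a standard stand-in for curated physical-interaction
#' networks. Node labels are drawn from the simulated gene universe.
#'
#' @param n_nodes number of nodes (`>= 2`)
#' @param attach_m edges added per incoming node (`1 <= attach_m < n_nodes`)
#' @param seed integer seed
#' @param universe optional gene ids to label nodes with (first `n_nodes`
#'   used after a seeded shuffle); default `G000001...`
#' @return a [ppi_network()]
#' @export
simulate_ppi <- function(n_nodes, attach_m = 2, seed = 1, universe = NULL) {
  if (!is_pos_count(n_nodes) || n_nodes < 2) abort("`n_nodes` must be an integer >= 2")
  if (!is_pos_count(attach_m) || attach_m >= n_nodes)
    abort("`attach_m` must satisfy 1 <= attach_m < n_nodes")
  with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
    labels <- if (is.null(universe)) {
      default_universe(n_nodes)
    } else {
      if (length(universe) < n_nodes)
        abort("`universe` must supply at least n_nodes labels")
      sample(universe, n_nodes)
    }
    e <- igraph::as_edgelist(g, names = FALSE)
    edges <- cbind(labels[e[, 1]], labels[e[, 2]])
    ppi_network(edges, nodes = labels)
  })
}

#' Simulate a gene-set library with optional planted enrichment
#'
#' Random terms draw their members uniformly from the universe; designated
#' enriched terms are seeded with a supplied gene list (e.g. planted
#' differentially expressed genes) topped up with random fillers, so the
#' over-representation stage has detectable signal at a known level.
#'
#' @param universe character vector of gene ids (the background)
#' @param n_terms number of random terms
#' @param size_range integer length-2, inclusive term-size bounds
#' @param enriched optional list of planted terms, each a list with `name`,
#'   `genes` (members forced into the term) and `size` (total term size)
#' @param seed integer seed
#' @return a `gene_set_library`: named list of terms (each with
#'   `description` and `genes`), plus `background_size` and the `universe`
#' @export
simulate_gene_sets <- function(universe, n_terms, size_range = c(10, 200),
                               enriched = NULL, seed = 1) {
  if (length(universe) == 0) abort("`universe` must be non-empty")
  if (!is_count(n_terms)) abort("`n_terms` must be a non-negative integer")
  if (length(size_range) != 2 || size_range[1] > size_range[2] ||
      size_range[2] > length(universe) || size_range[1] < 1)
    abort("`size_range` must lie within [1, |universe|]")
  with_seed(seed, {
    terms <- list()
    if (n_terms > 0) {
      sizes <- sample(seq(size_range[1], size_range[2]), n_terms, replace = TRUE)
      terms <- lapply(seq_len(n_terms), function(i) {
        list(description = sprintf("random term %d", i),
             genes = sort(sample(universe, sizes[i])))
      })
      names(terms) <- sprintf("RT%04d", seq_len(n_terms))
    }
    for (e in enriched) {
      stopifnot(!is.null(e$name), !is.null(e$genes), !is.null(e$size))
      if (!all(e$genes %in% universe))
        abort("enriched term '%s' contains genes outside the universe", e$name)
      if (e$size < length(e$genes))
        abort("enriched term '%s': size smaller than its planted gene list", e$name)
      fillers <- sample(setdiff(universe, e$genes), e$size - length(e$genes))
      terms[[e$name]] <- list(description = "planted enriched term",
                              genes = sort(c(e$genes, fillers)))
    }
    gene_set_library(terms, background_size = length(universe),
                     universe = universe)
  })
}
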
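#' Build a pipeline run configuration
#'
#' A flat set of paths and per-stage parameters; [validate_config()] checks
#' it and [run_pipeline()] executes it. On-disk form is a plain
#' `key = value` text file ([read_run_config()] / [write_run_config()]).
#'
#' @param counts,metadata,gmt,network input paths (TSV counts, TSV metadata,
#'   GMT gene sets, 2-column TSV edge list)
#' @param outdir output directory (created on run)
#' @param normalization_method between-sample method: `"upper"`, `"full"`
#'   or `"median"`
#' @param ruv_k number of unwanted-variation factors (0 disables)
#' @param ruv_mode `"covariates"` (factors enter the NB design, default) or
#'   `"adjust"` (matrix adjusted before testing)
#' @param alpha,lfc_min DEG thresholds (adjusted p and |log2fc|)
#' @param background_n enrichment background size N
#' @param restart_rate RWR restart probability in (0, 1]
#' @param top_n key-gene candidate pool size
#' @param seed_mode propagation seed mode: `"abs"` or `"signed_positive"`
#' @param compartments compartments to analyse, comma-free character vector
#' @param seed integer seed recorded for provenance (the pipeline itself is
#'   deterministic given its inputs)
#' @return a `run_config` list
#' @export
run_config <- function(counts, metadata, gmt, network, outdir,
                       normalization_method = "upper",
                       ruv_k = 1, ruv_mode = "covariates",
                       alpha = 0.05, lfc_min = 0.5,
                       background_n = 20003,
                       restart_rate = 0.5, top_n = 20,
                       seed_mode = "abs",
                       compartments = c("plexus", "epithelium"),
                       seed = 1) {
  structure(list(counts = counts, metadata = metadata, gmt = gmt,
                 network = network, outdir = outdir,
                 normalization_method = normalization_method,
                 ruv_k = ruv_k, ruv_mode = ruv_mode,
                 alpha = alpha, lfc_min = lfc_min,
                 background_n = background_n,
                 restart_rate = restart_rate, top_n = top_n,
                 seed_mode = seed_mode,
                 compartments = compartments, seed = seed),
            class = "run_config")
}

config_numeric_keys <- c("ruv_k", "alpha", "lfc_min", "background_n",
                         "restart_rate", "top_n", "seed")

#' @rdname run_config
#' @param path config file path
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort("config file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  kv <- regmatches(lines, regexec("^([A-Za-z_]+)\\s*=\\s*(.*)$", lines))
  bad <- which(lengths(kv) != 3)
  if (length(bad)) abort("config parse error at entry %d: '%s'", bad[1], lines[bad[1]])
  vals <- stats::setNames(lapply(kv, `[`, 3), vapply(kv, `[`, character(1), 2))
  for (k in intersect(names(vals), config_numeric_keys))
    vals[[k]] <- as.numeric(vals[[k]])
  if ("compartments" %in% names(vals))
    vals$compartments <- trimws(strsplit(vals$compartments[[1]], ",")[[1]])
  do.call(run_config, vals)
}

#' @rdname run_config
#' @param cfg a `run_config`
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  vals <- cfg
  vals$compartments <- paste(vals$compartments, collapse = ",")
  writeLines(sprintf("%s = %s", names(vals),
                     vapply(vals, as.character, character(1))), path)
  invisible(path)
}

#' Validate a run configuration
#'
#' @param cfg a `run_config`
#' @return character vector of problems; empty when the config is runnable
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  say <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  for (key in c("counts", "metadata", "gmt", "network")) {
    p <- cfg[[key]]
    if (is.null(p) || !nzchar(p)) say("%s: path not set", key)
    else if (!file.exists(p)) say("%s: file not found: %s", key, p)
  }
  if (is.null(cfg$outdir) || !nzchar(cfg$outdir)) say("outdir: not set")
  if (!cfg$normalization_method %in% c("upper", "full", "median"))
    say("normalization_method: must be upper, full or median")
  if (!is_count(cfg$ruv_k)) say("ruv_k: must be a non-negative integer")
  if (!cfg$ruv_mode %in% c("covariates", "adjust"))
    say("ruv_mode: must be covariates or adjust")
  if (!is.numeric(cfg$alpha) || cfg$alpha <= 0 || cfg$alpha >= 1)
    say("alpha: must lie in (0, 1)")
  if (!is.numeric(cfg$lfc_min) || cfg$lfc_min < 0)
    say("lfc_min: must be >= 0")
  if (!is_pos_count(cfg$background_n)) say("background_n: must be a positive integer")
  if (!is.numeric(cfg$restart_rate) || cfg$restart_rate <= 0 || cfg$restart_rate > 1)
    say("restart_rate: must lie in (0, 1]")
  if (!is_pos_count(cfg$top_n)) say("top_n: must be a positive integer")
  if (!cfg$seed_mode %in% c("abs", "signed_positive"))
    say("seed_mode: must be abs or signed_positive")
  if (!length(cfg$compartments) ||
      !all(cfg$compartments %in% c("plexus", "epithelium")))
    say("compartments: must be a subset of plexus, epithelium")
  problems
}

#' Run the full analysis pipeline
#'
#' Per compartment: between-sample normalization, unwanted-variation
#' estimation from replicate structure, negative-binomial Wald differential
#' expression (factors as covariates by default), over-representation
#' analysis of up- and down-regulated DEGs, and key-gene prioritization by
#' fold-change-seeded random walk with restart plus betweenness centrality
#' on the PPI network. All intermediate tables are written under
#' `cfg$outdir`; the run is deterministic given its inputs.
#'
#' @param cfg a [run_config()]
#' @param quiet suppress per-stage progress messages
#' @return a `run_report`: per-compartment summaries, package version and
#'   the resolved config
#' @export
run_pipeline <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  problems <- validate_config(cfg)
  if (length(problems))
    abort("invalid config:\n%s", paste(" -", problems, collapse = "\n"))
  note <- function(stage, fmt, ...) {
    if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
  }

  dat <- read_roi_matrix(cfg$counts, cfg$metadata)
  lib <- read_gmt(cfg$gmt, background_size = cfg$background_n)
  net <- read_network(cfg$network, format = "edge_list")
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  note("input", "%d genes x %d ROIs; %d gene sets; network %d nodes / %d edges",
       nrow(dat$counts), ncol(dat$counts), length(lib$terms),
       length(net$nodes), nrow(net$edges))

  W <- column_normalize(net)
  bc <- betweenness_centrality(net)

  summaries <- list()
  for (comp in cfg$compartments) {
    stage <- function(s) sprintf("%s/%s", comp, s)
    sub <- subset_compartment(dat, comp)
    norm <- between_lane_normalize(sub, method = cfg$normalization_method)
    note(stage("normalize"), "method=%s on %d ROIs",
         cfg$normalization_method, ncol(norm$counts))

    covariates <- NULL
    if (cfg$ruv_k > 0) {
      uv <- estimate_unwanted_variation(norm, k = cfg$ruv_k)
      write_factors_tsv(uv, file.path(cfg$outdir, sprintf("factors_%s.tsv", comp)))
      if (cfg$ruv_mode == "adjust") {
        norm <- remove_unwanted(norm, uv)
      } else {
        covariates <- uv$factors
      }
      note(stage("ruv"), "k=%d, mode=%s, leading singular value %.3g",
           cfg$ruv_k, cfg$ruv_mode, uv$singular_values[1])
    }
    write_roi_matrix(norm,
                     file.path(cfg$outdir, sprintf("normalized_%s.tsv", comp)),
                     file.path(cfg$outdir, sprintf("metadata_%s.tsv", comp)))

    deg <- nb_wald_test(norm, covariates = covariates,
                        alpha = cfg$alpha, lfc_min = cfg$lfc_min)
    write_tsv_full(deg, file.path(cfg$outdir, sprintf("deg_%s.tsv", comp)))
    n_up <- attr(deg, "n_up"); n_down <- attr(deg, "n_down")
    note(stage("diffexp"), "%d up / %d down DEGs of %d genes",
         n_up, n_down, nrow(deg))

    enr <- list()
    for (dir_ in c("up", "down")) {
      q <- deg$gene[deg$direction == dir_]
      tab <- if (length(q)) enrich(q, lib) else
        enrich_empty_table()
      enr[[dir_]] <- tab
      write_tsv_full(tab, file.path(cfg$outdir,
                                    sprintf("enrichment_%s_%s.tsv", comp, dir_)))
      note(stage("enrich"), "%s: %d tested terms, %d significant",
           dir_, nrow(tab), nrow(significant_enrichment(tab, cfg$alpha)))
    }

    p0 <- initialize_seed(deg, net, mode = cfg$seed_mode)
    prob <- rwr(W, p0, r = cfg$restart_rate)
    report <- select_key_genes(prob, bc, enr, top_n = cfg$top_n,
                               alpha = cfg$alpha)
    write_tsv_full(report$ranked,
                   file.path(cfg$outdir, sprintf("ranked_%s.tsv", comp)))
    writeLines(report$key_genes,
               file.path(cfg$outdir, sprintf("key_genes_%s.tsv", comp)))
    note(stage("netprop"), "r=%.2f; %d key genes of top %d",
         cfg$restart_rate, length(report$key_genes), length(report$top))

    summaries[[comp]] <- list(
      n_rois = ncol(sub$counts), n_genes = nrow(sub$counts),
      n_deg_up = n_up, n_deg_down = n_down,
      n_sig_terms_up = nrow(significant_enrichment(enr$up, cfg$alpha)),
      n_sig_terms_down = nrow(significant_enrichment(enr$down, cfg$alpha)),
      top = report$top, key_genes = report$key_genes)
  }

  rep <- structure(list(compartments = summaries,
                        version = as.character(utils::packageVersion("roikey")),
                        config = cfg),
                   class = "run_report")
  write_run_report(rep, file.path(cfg$outdir, "report.txt"))
  rep
}

enrich_empty_table <- function() {
  data.frame(term = character(), description = character(),
             overlap = character(), k = integer(), K = integer(),
             n = integer(), p = numeric(), adj_p = numeric(),
             odds_ratio = numeric(), combined_score = numeric(),
             genes = character(), stringsAsFactors = FALSE)
}

write_run_report <- function(rep, path) {
  lines <- c(sprintf("roikey version %s", rep$version), "")
  for (comp in names(rep$compartments)) {
    s <- rep$compartments[[comp]]
    lines <- c(lines,
      sprintf("[%s]", comp),
      sprintf("rois = %d", s$n_rois),
      sprintf("genes = %d", s$n_genes),
      sprintf("deg_up = %d", s$n_deg_up),
      sprintf("deg_down = %d", s$n_deg_down),
      sprintf("significant_terms_up = %d", s$n_sig_terms_up),
      sprintf("significant_terms_down = %d", s$n_sig_terms_down),
      sprintf("top_genes = %s", paste(s$top, collapse = ",")),
      sprintf("key_genes = %s", paste(s$key_genes, collapse = ",")),
      "")
  }
  lines <- c(lines, "[config]",
             sprintf("%s = %s", names(rep$config),
                     vapply(rep$config, function(v)
                       paste(as.character(v), collapse = ","), character(1))))
  writeLines(lines, path)
  invisible(path)
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("run_report (roikey %s)\n", x$version))
  for (comp in names(x$compartments)) {
    s <- x$compartments[[comp]]
    cat(sprintf("  %s: %d ROIs, %d up / %d down DEGs, %d+%d significant terms, key genes: %s\n",
                comp, s$n_rois, s$n_deg_up, s$n_deg_down,
                s$n_sig_terms_up, s$n_sig_terms_down,
                if (length(s$key_genes)) paste(s$key_genes, collapse = ", ") else "(none)"))
  }
  invisible(x)
}

#' Simulate a complete demo study on disk
#'
#' Generates a synthetic ROI study (counts + metadata), a scale-free PPI
#' network whose hub nodes carry the planted differentially expressed
#' genes, and a gene-set library with planted enriched terms, writes
#' everything in the pipeline's file dialects under `dir`, and returns a
#' ready [run_config()]. This is the one-stop fixture generator used by the
#' tests, the acceptance script and the README example.
#'
#' @param dir output directory (created)
#' @param params a [sim_params()]; the seed inside it drives everything
#' @param n_network_nodes PPI network size
#' @param attach_m preferential-attachment edges per node
#' @param n_terms random gene-set terms
#' @param planted_term_size size of each planted enriched term
#' @param n_planted_terms planted enriched terms (their member genes are
#'   drawn from the planted DEGs, split between up- and down-regulated)
#' @param ... forwarded to [run_config()] (e.g. `ruv_k`, `restart_rate`)
#' @return list with `config` (a `run_config`), `truth` (the simulation
#'   `ground_truth`), and `paths`
#' @export
simulate_study <- function(dir, params = sim_params(), n_network_nodes = 600,
                           attach_m = 2, n_terms = 50,
                           planted_term_size = 30, n_planted_terms = 2, ...) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  design <- generate_design(params)
  sim <- simulate_counts(design, params)
  genes <- rownames(sim$data$counts)
  deg_genes <- sim$truth$deg_genes$gene

  # hub-planted network: order nodes by degree and put planted DEGs on hubs
  net0 <- with_seed(params$seed + 2L, {
    g <- igraph::sample_pa(n_network_nodes, m = attach_m, directed = FALSE)
    deg_order <- order(igraph::degree(g), decreasing = TRUE)
    labels <- character(n_network_nodes)
    hubs <- deg_order[seq_len(min(length(deg_genes), n_network_nodes))]
    labels[hubs] <- deg_genes[seq_along(hubs)]
    rest <- setdiff(seq_len(n_network_nodes), hubs)
    labels[rest] <- sample(setdiff(genes, deg_genes), length(rest))
    e <- igraph::as_edgelist(g, names = FALSE)
    ppi_network(cbind(labels[e[, 1]], labels[e[, 2]]), nodes = labels)
  })

  up <- sim$truth$deg_genes$gene[sim$truth$deg_genes$true_log2fc > 0]
  down <- sim$truth$deg_genes$gene[sim$truth$deg_genes$true_log2fc < 0]
  planted <- list()
  for (i in seq_len(n_planted_terms)) {
    src <- if (i %% 2 == 1) up else down
    take <- src[seq_len(min(10, length(src)))]
    planted[[i]] <- list(name = sprintf("PT%02d", i), genes = take,
                         size = max(planted_term_size, length(take)))
  }
  lib <- simulate_gene_sets(genes, n_terms = n_terms,
                            size_range = c(10, min(200, length(genes))),
                            enriched = planted, seed = params$seed + 3L)

  paths <- list(counts = file.path(dir, "counts.tsv"),
                metadata = file.path(dir, "metadata.tsv"),
                gmt = file.path(dir, "gene_sets.gmt"),
                network = file.path(dir, "network.tsv"),
                truth = file.path(dir, "truth"),
                outdir = file.path(dir, "out"))
  write_roi_matrix(sim$data, paths$counts, paths$metadata)
  write_gmt(lib, paths$gmt)
  write_network(net0, paths$network)
  write_ground_truth(sim$truth, paths$truth)

  cfg <- run_config(counts = paths$counts, metadata = paths$metadata,
                    gmt = paths$gmt, network = paths$network,
                    outdir = paths$outdir,
                    background_n = length(genes), seed = params$seed, ...)
  list(config = cfg, truth = sim$truth, paths = paths)
}
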
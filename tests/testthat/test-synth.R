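test_that("design cardinalities, balance and field invariants hold across parameters", {
  grid <- list(c(5, 5, 6), c(1, 1, 1), c(2, 3, 4))
  for (g in grid) {
    p <- sim_params(n_pd = g[1], n_ctrl = g[2], rois_per_compartment = g[3],
                    n_genes = 10, n_deg = 0, seed = 3)
    d <- generate_design(p)
    expect_equal(nrow(d), (g[1] + g[2]) * 2 * g[3])
    expect_false(anyDuplicated(d$roi_id) > 0)
    counts <- table(d$slide_id, d$compartment)
    expect_true(all(counts == g[3]))
    expect_true(all(d$nuclei > 20))
    plex <- d$compartment == "plexus"
    expect_true(all(d$area[plex] >= 5000 & d$area[plex] <= 30000))
    expect_true(all(d$area[!plex] >= 15000 & d$area[!plex] <= 150000))
    # one group per slide, balanced overall
    expect_equal(length(unique(paste(d$slide_id, d$group))),
                 length(unique(d$slide_id)))
  }
  # default design reproduces the full cohort: 120 ROIs
  expect_equal(nrow(generate_design(sim_params(n_genes = 10, n_deg = 0))), 120)
})

test_that("the design is deterministic given the seed", {
  p <- sim_params(n_genes = 10, n_deg = 0, seed = 99)
  expect_identical(generate_design(p), generate_design(p))
  p2 <- sim_params(n_genes = 10, n_deg = 0, seed = 100)
  expect_false(identical(generate_design(p), generate_design(p2)))
})

test_that("parameter validation rejects bad configurations", {
  expect_error(sim_params(n_pd = 0), "positive integer")
  expect_error(sim_params(rois_per_compartment = -1), "positive integer")
  expect_error(sim_params(n_deg = 50, n_genes = 10), "n_deg")
  expect_error(sim_params(dispersion = -0.1), "non-negative")
})

test_that("null simulation has statistically equal group means", {
  # no planted effects, no batch: a two-sample test on library-corrected
  # counts should be non-significant for >= 95% of genes
  p <- sim_params(n_genes = 2000, n_deg = 0, lfc_magnitude = 0,
                  n_batch_factors = 0, rois_per_compartment = 3, seed = 42)
  s <- simulate_counts(generate_design(p), p)
  cc <- sweep(s$data$counts, 2, s$truth$library_size_factors, "/")
  g <- s$data$metadata$group
  pv <- apply(cc, 1, function(y) stats::t.test(y[g == "PD"], y[g == "control"])$p.value)
  expect_gte(mean(pv >= 0.05), 0.95)
})

test_that("dispersion = 0 gives Poisson counts; dispersion > 0 is overdispersed", {
  # Pearson statistic against the fitted per-ROI means: ~1 under Poisson
  pearson_ratio <- function(disp) {
    p <- sim_params(n_genes = 500, n_deg = 0, dispersion = disp,
                    n_batch_factors = 0, libsize_sd = 0,
                    rois_per_compartment = 10, seed = 11)
    s <- simulate_counts(generate_design(p), p)
    cc <- s$data$counts
    l <- s$truth$library_size_factors
    mhat <- rowSums(cc) / sum(l)
    mu <- outer(mhat, l)
    x2 <- rowSums((cc - mu)^2 / mu)
    stats::median(x2[mhat > 1] / (ncol(cc) - 1))
  }
  expect_lt(abs(pearson_ratio(0) - 1), 0.1)
  expect_gt(pearson_ratio(0.2), 2)
})

test_that("a vanishing baseline yields an all-zero count matrix", {
  p <- sim_params(n_genes = 50, baseline_log_mean = -30, baseline_log_sd = 0,
                  n_deg = 0, n_batch_factors = 0,
                  n_pd = 1, n_ctrl = 1, rois_per_compartment = 2, seed = 1)
  s <- simulate_counts(generate_design(p), p)
  expect_true(all(s$data$counts == 0))
})

test_that("empirical gene means converge to the specified mean structure", {
  # at ~10,000 ROIs, library-corrected group-mean ratios reproduce the
  # planted fold changes within 5% relative error, and split-half gene
  # means agree within 5%
  p <- sim_params(n_genes = 100, n_deg = 50, lfc_magnitude = 1,
                  n_batch_factors = 0, baseline_log_mean = 3,
                  baseline_log_sd = 1, rois_per_compartment = 500, seed = 21)
  d <- generate_design(p)
  s <- simulate_counts(d, p)
  cc <- sweep(s$data$counts, 2, s$truth$library_size_factors, "/")
  pd <- s$data$metadata$group == "PD"
  ratio <- rowMeans(cc[, pd]) / rowMeans(cc[, !pd])
  truth <- s$truth$deg_genes
  est <- log2(ratio[truth$gene])
  expect_lt(max(abs(est - truth$true_log2fc)), log2(1.05))

  ctrl <- which(!pd)
  half1 <- rowMeans(cc[, ctrl[ctrl %% 2 == 0]])
  half2 <- rowMeans(cc[, ctrl[ctrl %% 2 == 1]])
  bright <- (half1 + half2) / 2 >= 20  # sampling noise dominates dim genes
  expect_lt(max(abs(half1[bright] / half2[bright] - 1)), 0.05)
})

test_that("ground truth and count matrices round-trip through disk losslessly", {
  p <- sim_params(n_genes = 40, n_deg = 5, n_pd = 2, n_ctrl = 2,
                  rois_per_compartment = 2, seed = 5)
  s <- simulate_counts(generate_design(p), p)
  dir <- withr::local_tempdir()
  write_ground_truth(s$truth, file.path(dir, "truth"))
  back <- read_ground_truth(file.path(dir, "truth"))
  expect_identical(back$deg_genes, s$truth$deg_genes)
  expect_identical(back$batch_factor_matrix, s$truth$batch_factor_matrix)
  expect_identical(back$library_size_factors, s$truth$library_size_factors)

  write_roi_matrix(s$data, file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  back2 <- read_roi_matrix(file.path(dir, "c.tsv"), file.path(dir, "m.tsv"))
  expect_identical(back2$counts, s$data$counts)
  expect_identical(back2$metadata, s$data$metadata)
})

test_that("simulated PPI networks are connected scale-free graphs", {
  net <- simulate_ppi(5, attach_m = 1, seed = 2)
  expect_equal(nrow(net$edges), 4)  # preferential-attachment tree
  for (n in c(10, 50, 200)) {
    net <- simulate_ppi(n, attach_m = 2, seed = n)
    g <- igraph::graph_from_edgelist(net$edges, directed = FALSE)
    expect_equal(igraph::components(g)$no, 1)
  }
  expect_identical(simulate_ppi(30, seed = 7)$edges, simulate_ppi(30, seed = 7)$edges)
  expect_error(simulate_ppi(1), ">= 2")
  expect_error(simulate_ppi(5, attach_m = 5), "attach_m")
})

test_that("simulated gene sets respect sizes and plant detectable enrichment", {
  expect_error(simulate_gene_sets(character(0), 5), "non-empty")
  universe <- sprintf("G%04d", 1:2000)
  empty <- simulate_gene_sets(universe, n_terms = 0, seed = 1)
  expect_length(empty$terms, 0)

  lib <- simulate_gene_sets(universe, n_terms = 25, size_range = c(10, 60), seed = 3)
  sizes <- lengths(lapply(lib$terms, `[[`, "genes"))
  expect_true(all(sizes >= 10 & sizes <= 60))
  expect_equal(lib$background_size, 2000)

  # planted term: 8 of a 36-gene query inside a 40-gene term is detectable
  query <- sprintf("G%04d", 1:36)
  lib2 <- simulate_gene_sets(universe, n_terms = 25, size_range = c(10, 60),
                             enriched = list(list(name = "PT1",
                                                  genes = query[1:8],
                                                  size = 40)),
                             seed = 4)
  res <- enrich(query, lib2)
  expect_lt(res$adj_p[res$term == "PT1"], 0.05)
})
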
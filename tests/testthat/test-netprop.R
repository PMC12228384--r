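test_that("network construction drops self-loops and duplicate edges", {
  net <- ppi_network(rbind(c("A", "B"), c("B", "A"), c("A", "A")))
  expect_equal(nrow(net$edges), 1)
  expect_setequal(net$nodes, c("A", "B"))
})

test_that("edge lists and BioGRID TAB3 files parse with clean errors", {
  path <- withr::local_tempfile()
  writeLines(c("a\tb", "b\tc"), path)
  net <- read_network(path)
  expect_setequal(net$nodes, c("A", "B", "C"))  # upper-cased
  expect_equal(nrow(net$edges), 2)

  empty <- withr::local_tempfile()
  writeLines(character(0), empty)
  e <- read_network(empty)
  expect_length(e$nodes, 0)
  expect_error(column_normalize(e), "empty")

  bad <- withr::local_tempfile()
  writeLines(c("a\tb", "lonely"), bad)
  expect_error(read_network(bad), "line 2")

  tab3 <- withr::local_tempfile()
  writeLines(c(paste("#BioGRID Interaction ID", "Official Symbol Interactor A",
                     "Official Symbol Interactor B", "Experimental System",
                     sep = "\t"),
               "1\tSnca\tTubb2a\tTwo-hybrid",
               "2\tSNCA\tTUBB2A\tAffinity Capture-MS",
               "3\tLAMP1\tS100B\tTwo-hybrid"), tab3)
  # header column lookup must tolerate the leading comment marker column
  nt <- read_network(tab3, format = "biogrid_tab3")
  expect_setequal(nt$nodes, c("SNCA", "TUBB2A", "LAMP1", "S100B"))
  expect_equal(nrow(nt$edges), 2)  # case-insensitive multi-edge collapsed

  # round-trip through the edge-list writer
  out <- withr::local_tempfile()
  write_network(nt, out)
  expect_equal(read_network(out)$edges, nt$edges)
})

test_that("column normalization spreads each node's mass over its neighbors", {
  path3 <- ppi_network(rbind(c("A", "B"), c("B", "C")))
  W <- column_normalize(path3)
  expect_equal(W[, "B"], c(A = 0.5, B = 0, C = 0.5))
  expect_equal(colSums(W), c(A = 1, B = 1, C = 1))

  star <- ppi_network(rbind(c("HUB", "L1"), c("HUB", "L2"), c("HUB", "L3")))
  Ws <- column_normalize(star)
  expect_equal(sort(Ws[, "HUB"]), c(HUB = 0, L1 = 1/3, L2 = 1/3, L3 = 1/3))

  iso <- ppi_network(rbind(c("A", "B")), nodes = c("A", "B", "LONER"))
  Wi <- column_normalize(iso)
  expect_equal(unname(colSums(Wi)), c(1, 1, 0))
})

test_that("seed initialization normalizes fold-change magnitudes over mapped genes", {
  net <- ppi_network(rbind(c("A", "B"), c("B", "C")))
  deg <- data.frame(gene = c("A", "B", "X"), log2fc = c(-1, 3, 9))
  expect_message(p0 <- initialize_seed(deg, net), "1 gene")
  expect_equal(p0, c(A = 0.25, B = 0.75, C = 0))

  signed <- suppressMessages(initialize_seed(deg, net, mode = "signed_positive"))
  expect_equal(signed, c(A = 0, B = 1, C = 0))

  flat <- data.frame(gene = c("A", "B", "C"), log2fc = c(2, 2, 2))
  expect_equal(initialize_seed(flat, net), c(A = 1, B = 1, C = 1) / 3)

  one <- data.frame(gene = "C", log2fc = -2)
  expect_equal(initialize_seed(one, net), c(A = 0, B = 0, C = 1))

  expect_error(initialize_seed(data.frame(gene = "Z", log2fc = 1), net),
               "maps onto")
  expect_error(suppressMessages(
    initialize_seed(data.frame(gene = c("A", "Z"), log2fc = c(0, 1)), net)),
    "all zero")
})

test_that("random walk with restart solves its fixed-point equation", {
  net <- ppi_network(rbind(c("A", "B")))
  W <- column_normalize(net)
  p0 <- c(A = 1, B = 0)
  expect_equal(rwr(W, p0, r = 1), p0)  # full restart returns the seed
  expect_equal(rwr(W, p0, r = 0.5), c(A = 2/3, B = 1/3), tolerance = 1e-7)
  expect_equal(rwr(W, p0, r = 0.5, method = "exact"), c(A = 2/3, B = 1/3))

  set.seed(71)
  for (i in 1:10) {
    n <- sample(5:60, 1)
    g <- random_connected_graph(n)
    W <- column_normalize(g$net)
    p0 <- stats::setNames(numeric(n), g$net$nodes)
    p0[sample(n, 2)] <- 0.5
    tol <- 1e-8
    it <- rwr(W, p0, r = 0.4, tol = tol)
    ex <- rwr(W, p0, r = 0.4, method = "exact")
    expect_lt(sum(abs(it - ex)), 10 * tol)
    # mass conservation and fixed-point residual
    expect_equal(sum(it), 1, tolerance = 1e-10)
    resid <- ex - (0.6 * as.numeric(W %*% ex) + 0.4 * p0)
    expect_lt(max(abs(resid)), 1e-8)
  }
  expect_error(rwr(W, p0, r = 0), "restart")
  expect_error(rwr(W, p0, r = 0.01, max_iter = 2), "converge")
})

test_that("restart mass re-injection conserves probability with isolated nodes", {
  net <- ppi_network(rbind(c("A", "B")), nodes = c("A", "B", "LONER"))
  W <- column_normalize(net)
  p0 <- c(A = 0.5, B = 0, LONER = 0.5)
  it <- rwr(W, p0, r = 0.3)
  ex <- rwr(W, p0, r = 0.3, method = "exact")
  expect_equal(sum(it), 1, tolerance = 1e-10)
  expect_equal(it, ex, tolerance = 1e-7)
})

test_that("increasing a gene's seed weight never decreases its steady state", {
  set.seed(72)
  g <- random_connected_graph(30)
  W <- column_normalize(g$net)
  v <- g$net$nodes[7]
  base <- stats::setNames(rep(1 / 30, 30), g$net$nodes)
  prev <- -Inf
  for (extra in c(0, 0.2, 0.5, 0.9)) {
    p0 <- base * (1 - extra)
    p0[v] <- p0[v] + extra
    p <- rwr(W, p0, r = 0.5)
    expect_gte(p[[v]], prev - 1e-12)
    prev <- p[[v]]
  }
})

test_that("betweenness matches hand-enumerated ordered-pair values", {
  path3 <- ppi_network(rbind(c("A", "B"), c("B", "C")))
  expect_equal(betweenness_centrality(path3), c(A = 0, B = 2, C = 0))

  star <- ppi_network(rbind(c("HUB", "L1"), c("HUB", "L2"), c("HUB", "L3")))
  bc <- betweenness_centrality(star)
  expect_equal(bc[["HUB"]], 6)
  expect_equal(unname(bc[c("L1", "L2", "L3")]), c(0, 0, 0))

  k4 <- t(utils::combn(c("A", "B", "C", "D"), 2))
  expect_equal(unname(betweenness_centrality(ppi_network(k4))), rep(0, 4))

  # tree leaves always have zero betweenness
  tree <- simulate_ppi(20, attach_m = 1, seed = 3)
  bc <- betweenness_centrality(tree)
  degs <- table(factor(as.vector(tree$edges), levels = tree$nodes))
  expect_true(all(bc[degs == 1] == 0))
})

test_that("betweenness equals the exhaustive path-counting oracle", {
  set.seed(73)
  for (i in 1:40) {
    n <- sample(2:8, 1)
    g <- random_connected_graph(n, extra = sample(0:6, 1))
    bc <- betweenness_centrality(g$net)
    expect_equal(unname(bc[rownames(g$A)]), betweenness_oracle(g$A),
                 tolerance = 1e-10)
  }
})

test_that("key genes are the top-ranked genes backed by significant pathways", {
  set.seed(74)
  genes <- sprintf("G%02d", 1:25)
  prob <- stats::setNames(seq(25, 1) / sum(1:25), genes)
  bc <- stats::setNames(rep(0, 25), genes)
  pathway <- genes[c(2, 5, 11, 19, 21, 22, 23, 24, 25)]
  enr <- data.frame(term = "T", description = "d", overlap = "9/9",
                    k = 9, K = 9, n = 9, p = 1e-6, adj_p = 1e-5,
                    odds_ratio = 10, combined_score = 100,
                    genes = paste(pathway, collapse = ";"))
  rep <- select_key_genes(prob, bc, enr, top_n = 20)
  expect_equal(rep$key_genes, genes[c(2, 5, 11, 19)])
  expect_equal(rep$top, genes[1:20])

  # top_n beyond the gene count: intersection with all mapped genes
  rep2 <- select_key_genes(prob, bc, enr, top_n = 100)
  expect_setequal(rep2$key_genes, pathway)

  # probability ties break by higher betweenness
  prob_tie <- c(A = 0.5, B = 0.5)
  bc_tie <- c(A = 1, B = 5)
  rep3 <- select_key_genes(prob_tie, bc_tie, enr, top_n = 1)
  expect_equal(rep3$top, "B")

  expect_warning(select_key_genes(prob, bc, enr[0, ]), "empty")
})

test_that("key genes are stable across nearby restart rates on a hub-planted graph", {
  set.seed(75)
  net <- simulate_ppi(80, attach_m = 2, seed = 12)
  W <- column_normalize(net)
  bc <- betweenness_centrality(net)
  seeds <- net$nodes[1:10]
  p0 <- stats::setNames(numeric(80), net$nodes)
  p0[seeds] <- 1 / 10
  enr <- data.frame(term = "T", description = "d", overlap = "", k = 10,
                    K = 10, n = 10, p = 1e-8, adj_p = 1e-7, odds_ratio = 5,
                    combined_score = 50, genes = paste(seeds, collapse = ";"))
  keys <- rwr_stability(W, p0, bc, enr)
  expect_named(keys, c("r=0.3", "r=0.5", "r=0.7"))
  core <- Reduce(intersect, keys)
  expect_gte(length(core), 5)
})
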
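# Small fixtures built in code.

# minimal roi_matrix with ng genes and per-group ROI counts
tiny_roi_matrix <- function(counts, groups = NULL, slides = NULL,
                            compartment = "plexus") {
  n <- ncol(counts)
  if (is.null(groups)) groups <- rep(c("PD", "control"), length.out = n)
  if (is.null(slides)) slides <- paste0("S", seq_len(n))
  if (is.null(colnames(counts))) colnames(counts) <- paste0("R", seq_len(n))
  if (is.null(rownames(counts))) rownames(counts) <- paste0("G", seq_len(nrow(counts)))
  md <- data.frame(roi_id = colnames(counts), slide_id = slides,
                   group = groups, compartment = compartment,
                   area = 10000, nuclei = 50, stringsAsFactors = FALSE)
  roi_matrix(counts, md)
}

read_tsv_df <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}

# NB counts for a two-group design with chosen per-gene log2 fold changes
nb_two_group <- function(n_genes, n_per_group, base_mean = 50,
                         dispersion = 0.2, log2fc = 0) {
  mu_ctrl <- rep(base_mean, length.out = n_genes)
  lfc <- rep(log2fc, length.out = n_genes)
  mu <- cbind(matrix(mu_ctrl, n_genes, n_per_group),
              matrix(mu_ctrl * 2^lfc, n_genes, n_per_group))
  counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                   n_genes, 2 * n_per_group)
  dimnames(counts) <- list(sprintf("G%04d", seq_len(n_genes)),
                           sprintf("R%03d", seq_len(2 * n_per_group)))
  list(counts = counts,
       group = rep(c("control", "PD"), each = n_per_group))
}
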
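#' ROI-level expression container
#'
#' An `roi_matrix` bundles a genes x ROIs expression matrix with per-ROI
#' metadata (slide, disease group, tissue compartment, area, nuclei count).
#' Raw input holds non-negative integer counts; after normalization the
#' values are non-negative reals but the container is unchanged.
#'
#' @param counts numeric matrix, genes in rows (rownames = gene ids), ROIs in
#'   columns (colnames = ROI ids); all values finite and `>= 0`.
#' @param metadata data.frame with one row per ROI and at least the columns
#'   `roi_id`, `slide_id`, `group` (`"PD"`/`"control"`), `compartment`
#'   (`"plexus"`/`"epithelium"`), `area` (positive, um^2), `nuclei`
#'   (positive integer). Rows are matched to `counts` columns by `roi_id`.
#'
#' @return an object of class `roi_matrix`: a list with elements `counts`
#'   and `metadata` (metadata reordered to the column order of `counts`).
#' @export
#' @examples
#' m <- matrix(rpois(12, 10), 3, 4,
#'             dimnames = list(paste0("G", 1:3), paste0("R", 1:4)))
#' md <- data.frame(roi_id = paste0("R", 1:4), slide_id = "S1",
#'                  group = c("PD", "PD", "control", "control"),
#'                  compartment = "plexus", area = 10000, nuclei = 50)
#' roi_matrix(m, md)
roi_matrix <- function(counts, metadata) {
  if (!is.matrix(counts) || !is.numeric(counts))
    abort("`counts` must be a numeric matrix")
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    abort("`counts` must have gene rownames and ROI colnames")
  if (anyDuplicated(rownames(counts)))
    abort("duplicate gene ids in `counts` rownames")
  if (anyDuplicated(colnames(counts)))
    abort("duplicate ROI ids in `counts` colnames")
  if (any(!is.finite(counts)) || any(counts < 0))
    abort("`counts` must be finite and non-negative")
  required <- c("roi_id", "slide_id", "group", "compartment", "area", "nuclei")
  missing_cols <- setdiff(required, names(metadata))
  if (length(missing_cols))
    abort("metadata is missing column(s): %s", paste(missing_cols, collapse = ", "))
  if (anyDuplicated(metadata$roi_id))
    abort("duplicate roi_id in metadata")
  if (!setequal(metadata$roi_id, colnames(counts)))
    abort("metadata roi_ids do not match the ROI columns of `counts`")
  metadata <- metadata[match(colnames(counts), metadata$roi_id), , drop = FALSE]
  rownames(metadata) <- NULL
  if (!all(metadata$group %in% c("PD", "control")))
    abort("metadata `group` must be 'PD' or 'control'")
  if (!all(metadata$compartment %in% c("plexus", "epithelium")))
    abort("metadata `compartment` must be 'plexus' or 'epithelium'")
  if (any(metadata$area <= 0)) abort("metadata `area` must be positive")
  if (any(metadata$nuclei <= 0)) abort("metadata `nuclei` must be positive")
  structure(list(counts = counts, metadata = metadata), class = "roi_matrix")
}

#' @export
print.roi_matrix <- function(x, ...) {
  cat(sprintf("roi_matrix: %d genes x %d ROIs\n", nrow(x$counts), ncol(x$counts)))
  tab <- table(x$metadata$group, x$metadata$compartment)
  cat("ROIs by group x compartment:\n")
  print(tab)
  invisible(x)
}

#' @export
dim.roi_matrix <- function(x) dim(x$counts)

# replace the matrix, keeping metadata and class
set_counts <- function(x, counts) {
  stopifnot(inherits(x, "roi_matrix"),
            identical(dimnames(counts), dimnames(x$counts)))
  x$counts <- counts
  x
}

# accept either an roi_matrix or a plain matrix; return the matrix
as_count_matrix <- function(x) {
  if (inherits(x, "roi_matrix")) x$counts
  else if (is.matrix(x) && is.numeric(x)) x
  else abort("expected an `roi_matrix` or a numeric matrix")
}

#' Subset an `roi_matrix` to one tissue compartment
#'
#' @param x an `roi_matrix`
#' @param compartment `"plexus"` or `"epithelium"`
#' @return an `roi_matrix` with only the matching ROIs
#' @export
subset_compartment <- function(x, compartment) {
  stopifnot(inherits(x, "roi_matrix"))
  compartment <- match.arg(compartment, c("plexus", "epithelium"))
  keep <- x$metadata$compartment == compartment
  if (!any(keep)) abort("no ROIs in compartment '%s'", compartment)
  roi_matrix(x$counts[, keep, drop = FALSE],
             x$metadata[keep, , drop = FALSE])
}

#' Write / read the count-matrix TSV dialect
#'
#' Counts are written genes x ROIs with a leading `gene` column; metadata as
#' a plain TSV with the per-ROI design fields. Numeric values are written at
#' full precision so write/read round-trips are lossless.
#'
#' @param x an `roi_matrix` (or, for `write_counts_tsv`, a numeric matrix)
#' @param counts_path,metadata_path file paths
#' @return `read_roi_matrix` returns an `roi_matrix`; the writers return
#'   their path(s), invisibly.
#' @export
write_roi_matrix <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "roi_matrix"))
  write_counts_tsv(x$counts, counts_path)
  write_tsv_full(x$metadata, metadata_path)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_roi_matrix
#' @export
read_roi_matrix <- function(counts_path, metadata_path) {
  counts <- read_counts_tsv(counts_path)
  md <- read_tsv(metadata_path)
  roi_matrix(counts, md)
}

#' @rdname write_roi_matrix
#' @export
write_counts_tsv <- function(x, counts_path) {
  m <- as_count_matrix(x)
  df <- data.frame(gene = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_full(df, counts_path)
  invisible(counts_path)
}

#' @rdname write_roi_matrix
#' @export
read_counts_tsv <- function(counts_path) {
  df <- read_tsv(counts_path)
  if (names(df)[1] != "gene")
    abort("count TSV must have a leading 'gene' column")
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "double"
  m
}
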
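# Reading and writing the tabular formats the pipeline consumes: a
# genes x samples expression matrix (tab-delimited, GEO series-matrix-like
# layout) and a per-sample metadata table (CSV).

#' Read a genes-by-samples expression matrix
#'
#' Expects tab-delimited text with gene identifiers in the first column and
#' one column per sample (header row of sample ids). Values are normalized
#' expression intensities on the linear scale; if the file stores log2
#' values, set `log_scale = TRUE` and values are converted back to the
#' linear scale (`2^x`) so that downstream fold changes are ratios of group
#' means. The original scale is recorded in the `"log_scale_input"`
#' attribute.
#'
#' The loader is strict: duplicated gene ids, non-numeric cells and missing
#' values are errors (missing values can instead be imputed by the per-gene
#' median with `impute = "median"`; imputation is off by default because the
#' kNN classifier is distance-based and silent imputation distorts
#' neighbourhoods).
#'
#' @param path Path to a tab-delimited text file.
#' @param log_scale Logical; `TRUE` if the stored values are log2.
#' @param impute Either `"none"` (default, missing values are an error) or
#'   `"median"` (impute per-gene median).
#' @return A numeric matrix with gene ids as rownames and sample ids as
#'   colnames, and attribute `log_scale_input`.
#' @export
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' m <- matrix(1:6, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
#' write_expression_matrix(m, f)
#' x <- read_expression_matrix(f)
#' stopifnot(identical(dim(x), c(3L, 2L)))
read_expression_matrix <- function(path, log_scale = FALSE,
                                   impute = c("none", "median")) {
  impute <- match.arg(impute)
  df <- read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (nrow(df) == 0L || ncol(df) < 2L)
    stop("expression file must have a gene id column and >= 1 sample column")
  gene_ids <- as.character(df[[1L]])
  dup <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup))
    stop("duplicated gene id(s): ", paste(dup, collapse = ", "))
  sample_ids <- colnames(df)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicated sample id(s) in header")
  vals <- df[-1L]
  for (j in seq_along(vals)) {
    v <- vals[[j]]
    if (!is.numeric(v)) {
      suppressWarnings(vn <- as.numeric(v))
      bad <- which(is.na(vn) & !is.na(v) & trimws(v) != "" &
                     !toupper(trimws(v)) %in% c("NA", "NAN"))
      if (length(bad))
        stop(sprintf("non-numeric value '%s' at gene '%s', sample '%s'",
                     v[bad[1L]], gene_ids[bad[1L]], sample_ids[j]))
      vals[[j]] <- vn
    }
  }
  x <- as.matrix(vals)
  dimnames(x) <- list(gene_ids, sample_ids)
  if (anyNA(x)) {
    if (impute == "none") {
      bad <- which(is.na(x), arr.ind = TRUE)[1L, ]
      stop(sprintf("missing value at gene '%s', sample '%s' (set impute = 'median' to impute)",
                   gene_ids[bad[1L]], sample_ids[bad[2L]]))
    }
    for (i in which(rowSums(is.na(x)) > 0L)) {
      med <- stats::median(x[i, ], na.rm = TRUE)
      if (is.na(med)) stop("gene '", gene_ids[i], "' has no observed values")
      x[i, is.na(x[i, ])] <- med
    }
  }
  if (log_scale) x <- 2^x
  if (!all(is.finite(x))) stop("expression matrix contains non-finite values")
  attr(x, "log_scale_input") <- log_scale
  x
}

#' Write an expression matrix to tab-delimited text
#'
#' Inverse of [read_expression_matrix()]: gene ids in the first column
#' (named `gene_id`), sample ids as the header.
#'
#' @param x Numeric matrix with gene rownames and sample colnames.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(x, path) {
  stopifnot(is.matrix(x), !is.null(rownames(x)), !is.null(colnames(x)))
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-sample metadata
#'
#' CSV with required columns `sample_id` and `class_label`; recognised
#' optional columns are `nihss` (non-negative integer severity score),
#' `hours_to_draw` (non-negative real) and `age`, and any further columns
#' are kept as covariates (binary covariates as 0/1). Class labels are
#' normalised case-insensitively onto `AIS`, `control`, `mimic` via a small
#' alias table (e.g. `"stroke_mimic"` -> `"mimic"`); unknown labels are an
#' error.
#'
#' @param path Path to a CSV file.
#' @return A data.frame with one row per sample, `class_label` a factor with
#'   levels `control`, `mimic`, `AIS`.
#' @export
#' @examples
#' md <- read_metadata(system.file("extdata", "example_metadata.csv",
#'                                 package = "gaknn"))
#' table(md$class_label)
read_metadata <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0L) stop("no samples in metadata file")
  req <- c("sample_id", "class_label")
  miss <- setdiff(req, colnames(df))
  if (length(miss))
    stop("metadata is missing required column(s): ", paste(miss, collapse = ", "))
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id))
    stop("duplicated sample_id in metadata")
  if (anyNA(df$class_label)) stop("class_label missing for some samples")
  df$class_label <- factor(normalize_class_label(df$class_label),
                           levels = c("control", "mimic", "AIS"))
  if ("nihss" %in% names(df) && any(df$nihss < 0, na.rm = TRUE))
    stop("nihss must be non-negative")
  if ("hours_to_draw" %in% names(df) && any(df$hours_to_draw < 0, na.rm = TRUE))
    stop("hours_to_draw must be non-negative")
  df
}

#' Write per-sample metadata as CSV
#' @param metadata Data frame as returned by [read_metadata()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Align an expression matrix with a metadata table
#'
#' Checks that the two describe the same samples (order-independent) and
#' returns the matrix with columns reordered to the metadata row order.
#'
#' @param x Expression matrix (samples in columns).
#' @param metadata Metadata data.frame with a `sample_id` column.
#' @return The matrix with columns in metadata order.
#' @export
align_samples <- function(x, metadata) {
  mx <- colnames(x)
  mm <- metadata$sample_id
  if (!setequal(mx, mm) || length(mx) != length(mm))
    stop("expression matrix and metadata describe different sample sets")
  x[, mm, drop = FALSE]
}

#' Run configuration for the discovery pipeline
#'
#' Bundles the tunable parameters of the whole pipeline with the defaults
#' used throughout: a fold-change pre-filter at 1.7 (strict `>`), evaluation
#' of the top 50 ranked genes, a reported panel of 10 genes, and 5-nearest-
#' neighbour majority-vote classification.
#'
#' @param seed Integer seed controlling all randomness.
#' @param ga GA parameters from [ga_params()].
#' @param fold_threshold Absolute fold-difference pre-filter; must be > 1.
#' @param top_n_eval Panel-size curve is computed for 1..`top_n_eval`.
#' @param panel_size_report Size of the reported panel.
#' @param k Number of nearest neighbours (odd).
#' @param log_scale_input Whether expression input files store log2 values.
#' @return A list of class `"gaknn_config"`.
#' @export
run_config <- function(seed = 1L, ga = ga_params(), fold_threshold = 1.7,
                       top_n_eval = 50L, panel_size_report = 10L, k = 5L,
                       log_scale_input = FALSE) {
  stopifnot(fold_threshold > 1, top_n_eval >= 1, panel_size_report >= 1)
  if (k < 1 || k %% 2 == 0) stop("k must be odd and >= 1")
  structure(list(seed = as.integer(seed), ga = ga,
                 fold_threshold = fold_threshold,
                 top_n_eval = as.integer(top_n_eval),
                 panel_size_report = as.integer(panel_size_report),
                 k = as.integer(k), log_scale_input = log_scale_input),
            class = "gaknn_config")
}
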
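#' Read an expression matrix from a tab-separated file
#'
#' Expression files are plain TSV: a header row of sample identifiers and a
#' first column of gene identifiers. Genes are rows and samples are columns,
#' both on disk and in memory (the usual omics convention); set
#' `orientation = "samples_in_rows"` to transpose on load. Values are assumed
#' to be on a log scale already; `log2_plus1 = TRUE` applies log2(x + 1) for
#' raw-intensity inputs. Rows containing any non-finite value are dropped and
#' counted (no imputation is attempted); fully-empty rows are dropped
#' silently.
#'
#' @param path path to a TSV file (UTF-8; header = sample IDs, column 1 =
#'   gene IDs).
#' @param orientation `"genes_in_rows"` (default) or `"samples_in_rows"`.
#' @param modality one of `"mRNA"`, `"wProtein"`, `"pProtein"`; stored as an
#'   attribute and carried through downstream tables.
#' @param log2_plus1 apply a log2(x + 1) transform after load. Default
#'   `FALSE`.
#' @return a numeric genes x samples matrix with gene IDs as rownames and
#'   sample IDs as colnames; attributes `modality` and `n_dropped_nonfinite`
#'   record the modality tag and how many rows were removed for non-finite
#'   values.
#' @export
load_expression <- function(path, orientation = c("genes_in_rows", "samples_in_rows"),
                            modality = c("mRNA", "wProtein", "pProtein"),
                            log2_plus1 = FALSE) {
  orientation <- match.arg(orientation)
  modality <- match.arg(modality)
  if (!file.exists(path)) stop("expression file not found: ", path)
  header <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1]]
  if (length(header) < 2L) stop("malformed header in ", path,
                                ": expected gene-ID column plus >=1 sample column")
  tab <- utils::read.delim(path, header = TRUE, sep = "\t", check.names = FALSE,
                           stringsAsFactors = FALSE, quote = "", comment.char = "")
  ids <- as.character(tab[[1L]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop("duplicate gene IDs in ", path, ": ", paste(dup, collapse = ", "))
  vals <- tab[, -1L, drop = FALSE]
  bad_col <- names(vals)[!vapply(vals, is.numeric, logical(1))]
  if (length(bad_col))
    stop("non-numeric cells in column(s): ", paste(bad_col, collapse = ", "))
  m <- as.matrix(vals)
  rownames(m) <- ids
  if (orientation == "samples_in_rows") m <- t(m)
  if (anyDuplicated(colnames(m)))
    stop("duplicate sample IDs in ", path)
  empty <- rowSums(!is.na(m)) == 0L
  m <- m[!empty, , drop = FALSE]
  finite <- rowSums(!is.finite(m)) == 0L
  n_dropped <- sum(!finite)
  m <- m[finite, , drop = FALSE]
  if (log2_plus1) m <- log2(m + 1)
  structure(m, modality = modality, n_dropped_nonfinite = n_dropped)
}

#' Write an expression (or activity) matrix as TSV
#'
#' Inverse of [load_expression()]: first column `geneid`, header = sample IDs.
#'
#' @param m numeric matrix with rownames and colnames.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path) {
  df <- data.frame(geneid = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a two-column sample/group annotation
#'
#' @param path TSV with columns `sample_id` and `group` (header optional but
#'   recommended).
#' @return named character vector: group label per sample ID.
#' @export
read_groups <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("group file must have two columns (sample_id, group)")
  stats::setNames(as.character(tab[[2L]]), as.character(tab[[1L]]))
}

#' Filter genes on variability and coverage
#'
#' Removes genes whose row standard deviation (denominator n - 1) is below
#' `min_sd` or whose fraction of finite values is below `min_frac_expressed`.
#' Survivor order is preserved. Idempotent.
#'
#' @param m genes x samples matrix.
#' @param min_sd minimum row standard deviation (>= 0). Default `1e-8`.
#' @param min_frac_expressed minimum fraction of finite entries per row
#'   (>= 0). Default `0`.
#' @return the filtered matrix (attributes preserved).
#' @export
filter_genes <- function(m, min_sd = 1e-8, min_frac_expressed = 0) {
  stopifnot(min_sd >= 0, min_frac_expressed >= 0)
  frac <- rowMeans(is.finite(m))
  sds <- apply(m, 1L, function(r) stats::sd(r[is.finite(r)]))
  sds[is.na(sds)] <- 0
  keep <- sds >= min_sd & frac >= min_frac_expressed
  if (!any(keep)) stop("filter_genes removed every gene")
  out <- m[keep, , drop = FALSE]
  attributes(out)[c("modality", "n_dropped_nonfinite")] <-
    attributes(m)[c("modality", "n_dropped_nonfinite")]
  out
}

#' Row-standardize an expression matrix
#'
#' Scales every gene row to mean 0 and standard deviation 1 (denominator
#' n - 1). This is the `std = TRUE` preprocessing that activity inference
#' applies by default.
#'
#' @param m genes x samples matrix; every row must have positive sd (run
#'   [filter_genes()] first).
#' @return matrix of the same shape.
#' @export
z_transform <- function(m) {
  mu <- rowMeans(m)
  sds <- apply(m, 1L, stats::sd)
  zero <- sds == 0 | !is.finite(sds)
  if (any(zero))
    stop("zero-sd rows cannot be z-transformed: ",
         paste(utils::head(rownames(m)[zero], 5L), collapse = ", "))
  out <- (m - mu) / sds
  attributes(out)[c("modality", "n_dropped_nonfinite")] <-
    attributes(m)[c("modality", "n_dropped_nonfinite")]
  out
}

#' Quality-control summary of an expression matrix
#'
#' Computes per-sample location/spread statistics, the pairwise Spearman
#' sample-correlation matrix, and a low-variance gene count, and raises a
#' warning flag when the sample size is at or below 20 — network
#' reconstruction wants more samples than that to be reproducible.
#'
#' @param m genes x samples matrix.
#' @param low_sd_threshold row-sd threshold counted as "low variance".
#'   Default `0.1`.
#' @return an object of class `qc_summary`: a list with `n_genes`,
#'   `n_samples`, `per_sample` (data.frame of mean/median/IQR),
#'   `sample_correlation` (Spearman), `n_low_variance_genes`, `flags`.
#' @export
qc_summary <- function(m, low_sd_threshold = 0.1) {
  flags <- character(0)
  if (ncol(m) <= 20L)
    flags <- c(flags, sprintf(
      "small sample size (n=%d <= 20): networks built from this matrix may not be reproducible",
      ncol(m)))
  sds <- apply(m, 1L, stats::sd)
  per_sample <- data.frame(
    sample_id = colnames(m),
    mean = colMeans(m),
    median = apply(m, 2L, stats::median),
    iqr = apply(m, 2L, stats::IQR),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(
    n_genes = nrow(m),
    n_samples = ncol(m),
    per_sample = per_sample,
    sample_correlation = stats::cor(m, method = "spearman"),
    n_low_variance_genes = sum(sds < low_sd_threshold),
    flags = flags), class = "qc_summary")
}

#' @export
print.qc_summary <- function(x, ...) {
  cat(sprintf("Expression QC: %d genes x %d samples\n", x$n_genes, x$n_samples))
  cat(sprintf("  low-variance genes: %d\n", x$n_low_variance_genes))
  cat(sprintf("  median inter-sample Spearman rho: %.3f\n",
              stats::median(x$sample_correlation[lower.tri(x$sample_correlation)])))
  for (f in x$flags) cat("  WARNING: ", f, "\n", sep = "")
  invisible(x)
}

#' Serialize a QC summary as JSON
#'
#' @param x a `qc_summary`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_qc_summary <- function(x, path) {
  obj <- list(
    n_genes = x$n_genes, n_samples = x$n_samples,
    per_sample = x$per_sample,
    sample_correlation = as.data.frame(x$sample_correlation),
    n_low_variance_genes = x$n_low_variance_genes,
    flags = as.list(x$flags))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
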
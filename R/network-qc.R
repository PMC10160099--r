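#' Scale-free goodness of fit of a degree sequence
#'
#' A robust interactome tends to be scale-free: the log-log relationship
#' between degree k and its empirical frequency p(k) is near-linear. The
#' statistic is the R-squared of the ordinary least-squares fit of
#' log10 p(k) on log10 k over the distinct observed degrees — the higher,
#' the more scale-free the network.
#'
#' @param degrees positive-integer degree multiset (>= 3 distinct values).
#' @return R-squared in \[0, 1\].
#' @export
scale_free_r2 <- function(degrees) {
  degrees <- degrees[degrees >= 1]
  tab <- table(degrees)
  if (length(tab) < 3L)
    stop("scale-free fit needs at least 3 distinct degree values")
  k <- as.numeric(names(tab))
  pk <- as.numeric(tab) / sum(tab)
  fit <- stats::lm(log10(pk) ~ log10(k))
  # summary.lm warns on an exactly linear (pure power-law) input; the R^2
  # of 1 it returns there is the correct answer
  suppressWarnings(summary(fit)$r.squared)
}

#' Quality-control report for an inferred interactome
#'
#' Size, density, degree statistics, per-node degree/eigenvector/PageRank
#' centralities, per-driver target sizes, and the scale-free R-squared.
#' Degree for the scale-free fit is total degree (in + out) on the directed
#' driver -> target graph, isolated nodes excluded. A practitioner's rule of
#' thumb is that the mean regulon size of a useful genome-wide network sits
#' around several hundred targets; `mean_target_size_flag` is raised when
#' the mean falls outside \[100, 1000\].
#'
#' @param net an `interactome` with at least one edge.
#' @return object of class `network_qc`: list with `n_nodes`, `n_edges`,
#'   `density`, `degree_stats`, `centralities` (data.frame `node`, `degree`,
#'   `eigenvector`, `pagerank`), `target_sizes` (named integer),
#'   `scale_free_r2`, `mean_target_size`, `mean_target_size_flag`.
#' @export
qc_report <- function(net) {
  ed <- net$edges
  if (is.null(ed) || nrow(ed) == 0L) stop("empty network")
  g <- igraph::graph_from_data_frame(ed[, c("source", "target")],
                                     directed = TRUE)
  n_nodes <- igraph::vcount(g)
  n_edges <- igraph::ecount(g)
  deg <- igraph::degree(g, mode = "all")
  eig <- igraph::eigen_centrality(g, directed = FALSE)$vector
  eig <- abs(eig) / sqrt(sum(eig^2)) # L2-normalized, non-negative
  pr <- igraph::page_rank(g, damping = 0.85)$vector # L1-normalized by construction
  target_sizes <- table(factor(ed$source, levels = names(net$driver_type)))
  target_sizes <- stats::setNames(as.integer(target_sizes), names(target_sizes))
  mean_ts <- mean(target_sizes[target_sizes > 0])
  structure(list(
    n_nodes = n_nodes,
    n_edges = n_edges,
    density = n_edges / (n_nodes * (n_nodes - 1)),
    degree_stats = c(mean = mean(deg), median = stats::median(deg),
                     max = max(deg)),
    centralities = data.frame(node = names(deg), degree = as.integer(deg),
                              eigenvector = as.numeric(eig[names(deg)]),
                              pagerank = as.numeric(pr[names(deg)]),
                              row.names = NULL, stringsAsFactors = FALSE),
    target_sizes = target_sizes,
    # degenerate degree sequences (< 3 distinct values) leave the fit
    # undefined; the report carries NA rather than failing
    scale_free_r2 = tryCatch(scale_free_r2(deg),
                             error = function(e) NA_real_),
    mean_target_size = mean_ts,
    mean_target_size_flag = mean_ts < 100 || mean_ts > 1000),
    class = "network_qc")
}

#' @export
print.network_qc <- function(x, ...) {
  cat(sprintf("Network QC: %d nodes, %d edges (density %.4g)\n",
              x$n_nodes, x$n_edges, x$density))
  cat(sprintf("  degree mean/median/max: %.1f / %g / %g\n",
              x$degree_stats["mean"], x$degree_stats["median"],
              x$degree_stats["max"]))
  cat(sprintf("  mean target size: %.1f%s\n", x$mean_target_size,
              if (x$mean_target_size_flag) "  [outside the several-hundred rule of thumb]" else ""))
  cat(sprintf("  scale-free R^2: %.3f\n", x$scale_free_r2))
  invisible(x)
}

#' Serialize a network QC report (JSON) and its per-driver table (TSV)
#'
#' @param x a `network_qc`.
#' @param json_path output JSON path.
#' @param tsv_path optional path for the per-driver target-size table.
#' @return `json_path`, invisibly.
#' @export
write_qc_report <- function(x, json_path, tsv_path = NULL) {
  obj <- list(n_nodes = x$n_nodes, n_edges = x$n_edges, density = x$density,
              degree_stats = as.list(x$degree_stats),
              scale_free_r2 = x$scale_free_r2,
              mean_target_size = x$mean_target_size,
              mean_target_size_flag = x$mean_target_size_flag,
              centralities = x$centralities)
  jsonlite::write_json(obj, json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(tsv_path)) {
    df <- data.frame(driver = names(x$target_sizes),
                     n_targets = as.integer(x$target_sizes),
                     stringsAsFactors = FALSE)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
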
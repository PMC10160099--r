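#' Stouffer combination of signed z statistics
#'
#' z_comb = sum(w_i * z_i) / sqrt(sum(w_i^2)); p_comb is its two-tailed
#' normal tail. The default weights are equal across inputs; pass
#' `weights = sqrt(n)` for sample-size weighting.
#'
#' @param z vector of signed z statistics (NAs dropped).
#' @param weights optional positive weights, recycled against `z`.
#' @return list with `z_comb` and `p_comb` (both `NA` if no finite z).
#' @export
stouffer_combine <- function(z, weights = NULL) {
  if (is.null(weights)) weights <- rep(1, length(z))
  stopifnot(length(weights) == length(z), all(weights > 0, na.rm = TRUE))
  ok <- is.finite(z)
  if (!any(ok)) return(list(z_comb = NA_real_, p_comb = NA_real_))
  zc <- sum(weights[ok] * z[ok]) / sqrt(sum(weights[ok]^2))
  list(z_comb = zc, p_comb = 2 * stats::pnorm(-abs(zc)))
}

#' Fisher combination of p-values
#'
#' X^2 = -2 sum(log p_i) referred to chi-square with 2k df. Loses sign;
#' offered as a secondary combination only.
#'
#' @param p vector of p-values in (0, 1]; values are floored at 1e-300
#'   before the log (a p of exactly 0 is an error upstream).
#' @return combined p-value.
#' @export
fisher_combine <- function(p) {
  p <- p[is.finite(p)]
  if (!length(p)) return(NA_real_)
  if (any(p <= 0)) stop("p-values must be > 0 (floor them before combining)")
  if (any(p > 1)) stop("p-values must be <= 1")
  p <- pmax(p, 1e-300)
  x2 <- -2 * sum(log(p))
  stats::pchisq(x2, df = 2 * length(p), lower.tail = FALSE)
}

#' Combine an effect statistic across differential tables
#'
#' Sample-size-weighted mean of `logFC` or `AveExpr` across tables, keyed by
#' feature; a feature missing from some tables is combined over the tables
#' where it is present.
#'
#' @param tables list of `differential_table`s.
#' @param stat `"logFC"` or `"AveExpr"`.
#' @return named numeric vector over the union of feature keys.
#' @export
combine_effects <- function(tables, stat = c("logFC", "AveExpr")) {
  stat <- match.arg(stat)
  feats <- unique(unlist(lapply(tables, `[[`, "feature")))
  if (!length(feats)) stop("no features to combine")
  num <- stats::setNames(numeric(length(feats)), feats)
  den <- num
  any_present <- stats::setNames(logical(length(feats)), feats)
  for (tb in tables) {
    w <- attr(tb, "n0") + attr(tb, "n1")
    idx <- tb$feature
    num[idx] <- num[idx] + w * tb[[stat]]
    den[idx] <- den[idx] + w
    any_present[idx] <- TRUE
  }
  if (!any(any_present)) stop("no overlapping features across tables")
  out <- num / den
  out[!any_present] <- NA_real_
  out
}

#' Assemble the per-driver master table
#'
#' One row per driver with usable statistics in at least one modality:
#' driver type, per-modality regulon size, per-modality DA and DE z/p/adj_p,
#' and — when two or more modalities are supplied — Stouffer-integrated DA
#' and DE z/p with BH re-applied across drivers. Rows are sorted by
#' decreasing |integrated DA z| (falling back to the single modality when
#' only one is given), ties broken by driver ID.
#'
#' @param da named list of `differential_table`s over drivers (names =
#'   modality tags, e.g. `mRNA`, `wProtein`, `pProtein`).
#' @param de optional named list of `differential_table`s over genes (same
#'   names); a driver's DE row is looked up by its own gene ID.
#' @param net an `interactome` (regulon sizes and driver types).
#' @param weights optional Stouffer weights, one per modality.
#' @return a `master_table` data.frame.
#' @export
build_master_table <- function(da, de = NULL, net, weights = NULL) {
  mods <- names(da)
  if (is.null(mods)) stop("`da` must be a named list (modality tags)")
  if (!is.null(weights)) stopifnot(length(weights) == length(mods))
  drivers <- unique(unlist(lapply(da, `[[`, "feature")))
  drivers <- drivers[order(drivers)]
  reg_size <- table(factor(net$edges$source, levels = drivers))
  out <- data.frame(driver = drivers,
                    driver_type = unname(net$driver_type[drivers]),
                    regulon_size = as.integer(reg_size[drivers]),
                    stringsAsFactors = FALSE)
  pull <- function(tb, what, keys) {
    v <- tb[[what]][match(keys, tb$feature)]
    if (is.null(v)) rep(NA_real_, length(keys)) else v
  }
  da_z <- sapply(mods, function(mm) pull(da[[mm]], "z", drivers))
  da_z <- matrix(da_z, nrow = length(drivers),
                 dimnames = list(NULL, mods))
  for (mm in mods) {
    out[[paste0("DA_z_", mm)]] <- da_z[, mm]
    out[[paste0("DA_p_", mm)]] <- pull(da[[mm]], "p", drivers)
    out[[paste0("DA_adj_p_", mm)]] <- pull(da[[mm]], "adj_p", drivers)
  }
  if (!is.null(de)) {
    for (mm in intersect(mods, names(de))) {
      out[[paste0("DE_z_", mm)]] <- pull(de[[mm]], "z", drivers)
      out[[paste0("DE_p_", mm)]] <- pull(de[[mm]], "p", drivers)
      out[[paste0("DE_adj_p_", mm)]] <- pull(de[[mm]], "adj_p", drivers)
    }
  }
  if (length(mods) >= 2L) {
    comb <- apply(da_z, 1L, function(zz) stouffer_combine(zz, weights)$z_comb)
    out$DA_z_integrated <- comb
    out$DA_p_integrated <- 2 * stats::pnorm(-abs(comb))
    out$DA_adj_p_integrated <- bh_adjust(out$DA_p_integrated)
    if (!is.null(de)) {
      de_z <- sapply(intersect(mods, names(de)),
                     function(mm) pull(de[[mm]], "z", drivers))
      de_z <- matrix(de_z, nrow = length(drivers))
      combe <- apply(de_z, 1L, function(zz) stouffer_combine(zz, weights)$z_comb)
      out$DE_z_integrated <- combe
      out$DE_p_integrated <- 2 * stats::pnorm(-abs(combe))
      out$DE_adj_p_integrated <- bh_adjust(out$DE_p_integrated)
    }
    rank_on <- out$DA_z_integrated
  } else {
    rank_on <- da_z[, 1L]
  }
  ord <- order(-abs(rank_on), out$driver)
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  class(out) <- c("master_table", "data.frame")
  out
}

#' @export
print.master_table <- function(x, n = 10L, ...) {
  cat(sprintf("Master table: %d drivers, %d columns\n", nrow(x), ncol(x)))
  if ("DA_adj_p_integrated" %in% names(x))
    cat(sprintf("  significant integrated DA at adj_p < 0.05: %d\n",
                sum(x$DA_adj_p_integrated < 0.05, na.rm = TRUE)))
  show <- intersect(c("rank", "driver", "driver_type", "regulon_size",
                      "DA_z_integrated", "DA_adj_p_integrated",
                      "DE_z_integrated", "DE_adj_p_integrated"), names(x))
  print.data.frame(utils::head(x[, show, drop = FALSE], n))
  invisible(x)
}

#' Write a master table as TSV (and optionally JSON)
#'
#' @param x a `master_table`.
#' @param path TSV output path.
#' @param json_path optional JSON output path.
#' @return `path`, invisibly.
#' @export
write_master_table <- function(x, path, json_path = NULL) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(x, json_path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
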
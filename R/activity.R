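#' Infer driver activity from an expression matrix and an interactome
#'
#' A driver's activity in a sample summarizes the expression pattern of its
#' regulon: the higher the expression of its positively regulated targets
#' and the lower the expression of its negatively regulated targets, the
#' higher the activity. With z the (row-standardized when `std = TRUE`,
#' the default) expression of target t in sample s, and each regulon edge
#' carrying an MI weight `mi_t >= 0` and a Spearman sign `sign_t`:
#'
#' * `weighted_mean` (default): sum_t sign_t * mi_t * z_ts / sum_t mi_t —
#'   MI-weighted, sign-directed; the recommended estimator.
#' * `mean`: (1/|T|) sum_t sign_t * z_ts — sign-directed, unweighted.
#' * `mean_unsigned`: (1/|T|) sum_t z_ts — the strict prototype form that
#'   ignores both weight and direction.
#' * `absmean`: (1/|T|) sum_t |z_ts|.
#' * `maxmean`: of the mean of positive parts and the mean of negative
#'   parts of sign_t * z_ts (both over all usable targets), whichever is
#'   larger in magnitude, with its sign.
#'
#' Targets absent from the matrix are dropped; for the sign-directed
#' estimators (`weighted_mean`, `mean`) zero-sign targets are also dropped
#' (an undirected edge carries no directional evidence). Drivers left with
#' fewer than `min_targets` usable targets are excluded and reported in the
#' `dropped_drivers` attribute.
#'
#' @param m genes x samples expression matrix.
#' @param net an `interactome`.
#' @param method activity estimator (see above).
#' @param std z-transform the expression rows first (default `TRUE`).
#' @param min_targets minimum usable regulon size (default 5).
#' @return drivers x samples activity matrix with attributes `method`,
#'   `n_targets_used` (named integer) and `dropped_drivers`.
#' @export
cal_activity <- function(m, net,
                         method = c("weighted_mean", "mean", "mean_unsigned",
                                    "absmean", "maxmean"),
                         std = TRUE, min_targets = 5L) {
  method <- match.arg(method)
  if (std) m <- z_transform(filter_genes(m, min_sd = 1e-12))
  ed <- net$edges
  drivers <- names(net$driver_type)
  ed <- ed[ed$target %in% rownames(m), , drop = FALSE]
  if (method %in% c("weighted_mean", "mean")) {
    ed <- ed[ed$sign != 0L, , drop = FALSE]
  }
  n_use <- table(factor(ed$source, levels = drivers))
  usable <- names(n_use)[as.integer(n_use) >= min_targets]
  dropped <- setdiff(drivers, usable)
  if (!length(usable)) stop("no driver has >= min_targets usable targets")
  act <- matrix(NA_real_, length(usable), ncol(m),
                dimnames = list(usable, colnames(m)))
  for (d in usable) {
    sub <- ed[ed$source == d, , drop = FALSE]
    z <- m[sub$target, , drop = FALSE]
    act[d, ] <- switch(method,
      weighted_mean = colSums(sub$sign * sub$mi * z) / sum(abs(sub$mi)),
      mean = colMeans(sub$sign * z),
      mean_unsigned = colMeans(z),
      absmean = colMeans(abs(z)),
      maxmean = {
        sz <- sub$sign * z
        pos <- colSums(sz * (sz > 0)) / nrow(sz)
        neg <- colSums(sz * (sz < 0)) / nrow(sz)
        ifelse(abs(pos) >= abs(neg), pos, neg)
      })
  }
  structure(act, method = method,
            n_targets_used = stats::setNames(as.integer(n_use[usable]), usable),
            dropped_drivers = dropped)
}
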
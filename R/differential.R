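#' Benjamini-Hochberg adjustment
#'
#' Thin wrapper over `stats::p.adjust(method = "BH")` so every table in the
#' package adjusts identically.
#'
#' @param p vector of p-values in (0, 1].
#' @return adjusted p-values (monotone step-up, capped at 1).
#' @export
bh_adjust <- function(p) stats::p.adjust(p, method = "BH")

.check_two_groups <- function(m, groups, min_per_group = 2L) {
  groups <- groups[colnames(m)]
  if (anyNA(groups)) stop("group labels missing for some samples")
  lv <- sort(unique(as.character(groups)))
  if (length(lv) != 2L)
    stop("exactly 2 groups required, got ", length(lv),
         " (multi-group designs are not supported)")
  n0 <- sum(groups == lv[1L]); n1 <- sum(groups == lv[2L])
  if (min(n0, n1) < min_per_group)
    stop("each group needs >= ", min_per_group, " samples")
  list(labels = lv, g0 = groups == lv[1L], g1 = groups == lv[2L],
       n0 = n0, n1 = n1)
}

# Moment-matching estimate of the scaled inverse-chi-square prior
# (d0, s0_sq) from per-feature sample variances s2 on d residual df,
# via the log-variance digamma/trigamma relations. d0 clamped to [0.1, 500].
.estimate_ebayes_prior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 3L) return(list(d0 = 0.1, s0_sq = stats::median(s2[ok], na.rm = TRUE)))
  z <- log(s2[ok])
  e_z <- mean(z)
  v_z <- stats::var(z)
  t_half_d <- v_z - trigamma(d / 2)
  if (!is.finite(t_half_d) || t_half_d <= trigamma(500 / 2)) {
    d0 <- 500
  } else {
    d0 <- 2 * .trigamma_inverse(t_half_d)
    d0 <- min(max(d0, 0.1), 500)
  }
  s0_sq <- exp(e_z - digamma(d / 2) + digamma(d0 / 2) + log(d / d0))
  list(d0 = d0, s0_sq = s0_sq)
}

# Newton inversion of the trigamma function (decreasing on (0, Inf)).
.trigamma_inverse <- function(x) {
  if (x > 1e7) return(1 / sqrt(x))
  if (x < 1e-6) return(1 / x)
  y <- 0.5 + 1 / x
  for (i in 1:50) {
    tri <- trigamma(y)
    dif <- tri * (1 - tri / x) / psigamma(y, 2L)
    y <- y + dif
    if (abs(dif / y) < 1e-10) break
  }
  y
}

.diff_table <- function(feature, logFC, AveExpr, t, df, n0, n1, method,
                        normal_ref = FALSE) {
  p <- if (normal_ref) 2 * stats::pnorm(-abs(t)) else 2 * stats::pt(-abs(t), df)
  p <- pmin(pmax(p, 1e-300), 1)
  z <- sign(t) * stats::qnorm(p / 2, lower.tail = FALSE)
  z[t == 0] <- 0
  out <- data.frame(feature = feature, logFC = logFC, AveExpr = AveExpr,
                    t = t, z = z, p = p, adj_p = bh_adjust(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "n0") <- n0
  attr(out, "n1") <- n1
  attr(out, "method") <- method
  class(out) <- c("differential_table", "data.frame")
  out
}

#' Two-group differential expression / activity (moderated t)
#'
#' Per-feature two-sample comparison with pooled variance. With
#' `moderated = TRUE` (the default), residual variances are shrunk toward a
#' common prior by empirical Bayes: the prior (d0, s0_sq) is estimated from
#' the ensemble of per-feature variances by moment matching on log
#' variances, each feature's variance becomes the convex combination
#' (d0 * s0_sq + d * s2) / (d0 + d), and t is referred to d0 + n0 + n1 - 2
#' degrees of freedom. This borrowing of strength is what makes tiny
#' designs (n = 2 per group, the proteomics regime) testable. logFC is
#' group1 mean - group0 mean (groups ordered lexicographically); the signed
#' normal deviate z = sign(t) * qnorm(1 - p/2) puts every modality on a
#' common scale for later integration.
#'
#' @param m features x samples matrix (expression or activity).
#' @param groups named group labels (exactly 2 distinct values), names =
#'   sample IDs.
#' @param moderated use empirical-Bayes variance shrinkage (default `TRUE`).
#' @param d0_override test hook: force the prior df (0 reproduces the
#'   ordinary pooled t exactly).
#' @return a `differential_table` data.frame: `feature`, `logFC`,
#'   `AveExpr`, `t`, `z`, `p`, `adj_p`, with `n0`, `n1`, `method` and
#'   (when moderated) `d0`, `s0_sq` attributes.
#' @export
de_two_group <- function(m, groups, moderated = TRUE, d0_override = NULL) {
  gr <- .check_two_groups(m, groups,
                          min_per_group = if (moderated) 1L else 2L)
  if (gr$n0 + gr$n1 < 3L) stop("need at least 3 samples in total")
  m0 <- m[, gr$g0, drop = FALSE]
  m1 <- m[, gr$g1, drop = FALSE]
  mu0 <- rowMeans(m0); mu1 <- rowMeans(m1)
  d <- gr$n0 + gr$n1 - 2L
  ss0 <- rowSums((m0 - mu0)^2)
  ss1 <- rowSums((m1 - mu1)^2)
  s2 <- (ss0 + ss1) / d
  if (moderated) {
    pr <- .estimate_ebayes_prior(s2, d)
    if (!is.null(d0_override)) pr$d0 <- d0_override
    s2_tilde <- if (is.infinite(pr$d0)) rep(pr$s0_sq, length(s2)) else
      (pr$d0 * pr$s0_sq + d * s2) / (pr$d0 + d)
    df_t <- pr$d0 + d
  } else {
    if (any(s2 == 0))
      stop("zero residual variance for feature(s) ",
           paste(utils::head(rownames(m)[s2 == 0], 5L), collapse = ", "),
           " with moderation off")
    s2_tilde <- s2
    df_t <- d
  }
  se <- sqrt(s2_tilde * (1 / gr$n0 + 1 / gr$n1))
  tt <- (mu1 - mu0) / se
  out <- .diff_table(rownames(m), mu1 - mu0, rowMeans(m), tt, df_t,
                     gr$n0, gr$n1,
                     if (moderated) "ebayes" else "pooled_t")
  if (moderated) {
    attr(out, "d0") <- pr$d0
    attr(out, "s0_sq") <- pr$s0_sq
  }
  out
}

#' Two-group differential statistics by Bayesian (or MLE) linear regression
#'
#' Fits value ~ intercept + beta * group per feature. `method = "MLE"` is
#' ordinary least squares: beta-hat and its standard error coincide with the
#' unmoderated pooled-t quantities, and z = beta / se is referred to the
#' normal. `method = "Bayesian"` (the default) places a flat prior on the
#' coefficients and a weakly informative scaled inverse-chi-square prior on
#' the residual variance (prior df a0 = 1, prior scale = the ensemble mean
#' of per-feature residual variances); z is the posterior mean of beta over
#' its posterior sd, with a two-tailed normal p. The variance prior
#' regularizes features with zero residual variance, and as a0 -> 0 the
#' Bayesian route converges to MLE.
#'
#' @param m features x samples matrix.
#' @param groups named two-level group labels.
#' @param method `"Bayesian"` (default) or `"MLE"`.
#' @param a0 prior degrees of freedom for the Bayesian route. Default 1.
#' @return a `differential_table` (see [de_two_group()]).
#' @export
bid_two_group <- function(m, groups, method = c("Bayesian", "MLE"), a0 = 1) {
  method <- match.arg(method)
  gr <- .check_two_groups(m, groups,
                          min_per_group = if (method == "Bayesian") 1L else 2L)
  if (gr$n0 + gr$n1 < 3L) stop("need at least 3 samples in total")
  m0 <- m[, gr$g0, drop = FALSE]
  m1 <- m[, gr$g1, drop = FALSE]
  mu0 <- rowMeans(m0); mu1 <- rowMeans(m1)
  d <- gr$n0 + gr$n1 - 2L
  s2 <- (rowSums((m0 - mu0)^2) + rowSums((m1 - mu1)^2)) / d
  beta <- mu1 - mu0
  lev <- 1 / gr$n0 + 1 / gr$n1
  if (method == "MLE") {
    if (any(s2 == 0))
      stop("zero residual variance for feature(s) ",
           paste(utils::head(rownames(m)[s2 == 0], 5L), collapse = ", "))
    zstat <- beta / sqrt(s2 * lev)
  } else {
    s0_sq <- mean(s2[is.finite(s2)])
    if (!is.finite(s0_sq) || s0_sq <= 0) s0_sq <- 1
    s2_post <- (a0 * s0_sq + d * s2) / (a0 + d)
    zstat <- beta / sqrt(s2_post * lev)
  }
  .diff_table(rownames(m), beta, rowMeans(m), zstat, df = NULL,
              gr$n0, gr$n1, paste0("bid_", tolower(method)),
              normal_ref = TRUE)
}

#' @export
print.differential_table <- function(x, n = 6L, ...) {
  cat(sprintf("Differential table (%s): %d features, groups n0=%d n1=%d\n",
              attr(x, "method"), nrow(x), attr(x, "n0"), attr(x, "n1")))
  cat(sprintf("  significant at adj_p < 0.05: %d\n", sum(x$adj_p < 0.05)))
  print.data.frame(utils::head(x[order(x$p), ], n))
  invisible(x)
}

#' Write a differential table as TSV (fixed column order)
#'
#' @param x a `differential_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_differential <- function(x, path) {
  utils::write.table(x[, c("feature", "logFC", "AveExpr", "t", "z", "p", "adj_p")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
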
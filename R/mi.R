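#' Mutual information between two expression profiles
#'
#' Two estimators, both returning MI in nats:
#'
#' * `"adaptive"` (default): ranks are mapped onto a uniform grid and the
#'   rank square is partitioned recursively — a cell is split into four
#'   quadrants at its marginal medians while a chi-square uniformity test on
#'   the quadrant counts rejects at alpha = 0.05 (cells with fewer than 8
#'   points are never split); leaf contributions are summed. This is the
#'   estimator family used by ARACNe-style network reverse-engineering.
#' * `"fixed_bins"`: the plug-in estimate
#'   sum p(i,j) log\[p(i,j) / (p(i) p(j))\] over a k x k equal-frequency
#'   grid. When a vector has at most `k` distinct values its distinct values
#'   are used as categories directly, so discrete data are scored on their
#'   exact support. Retained mainly as an analytic oracle and as a
#'   CLI-selectable option.
#'
#' Rank ties are broken by position, deterministically.
#'
#' @param x,y numeric vectors of equal length >= 8.
#' @param estimator `"adaptive"` or `"fixed_bins"`.
#' @param k number of equal-frequency bins for `"fixed_bins"`. Default 4.
#' @return MI in nats (>= 0). A constant input vector yields 0 with a
#'   warning (MI with a constant is undefined/zero).
#' @export
compute_mi <- function(x, y, estimator = c("adaptive", "fixed_bins"), k = 4L) {
  estimator <- match.arg(estimator)
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 8L) stop("need at least 8 observations for MI estimation")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("non-finite values in input")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: MI defined as 0")
    return(0)
  }
  if (estimator == "adaptive") {
    .mi_adaptive_ranks(.strict_ranks(x), .strict_ranks(y))
  } else {
    .mi_plugin_bins(.freq_bins(x, k), .freq_bins(y, k), k, k)
  }
}

# ranks 0..n-1, ties broken by position (stable)
.strict_ranks <- function(x) {
  ord <- order(x)
  r <- integer(length(x))
  r[ord] <- seq_along(x) - 1L
  r
}

# 0-based equal-frequency bin labels; <=k distinct values -> one bin per value
.freq_bins <- function(x, k) {
  ux <- unique(x)
  if (length(ux) <= k) return(match(x, sort(ux)) - 1L)
  as.integer(floor(.strict_ranks(x) * k / length(x)))
}

#' MI significance threshold from a permutation null
#'
#' Estimates the MI value whose exceedance probability under independence is
#' `p_cutoff`, by scoring `n_permutations` independently permuted rank pairs
#' at the given sample size. For cutoffs beyond the empirical resolution
#' (`p_cutoff < 1/n_permutations`) an exponential tail is fitted to the upper
#' exceedances (mean-excess/MLE rate) and extrapolated. Because both
#' estimators operate on tie-broken ranks, the null depends only on the
#' sample size and the estimator, not on the data distribution.
#'
#' @param n_samples sample size the threshold applies to.
#' @param p_cutoff tail probability in (0, 1].
#' @param n_permutations number of null pairs. Default 20000.
#' @param seed integer RNG seed.
#' @param estimator,k as in [compute_mi()].
#' @return MI threshold in nats (0 when `p_cutoff = 1`).
#' @export
mi_null_threshold <- function(n_samples, p_cutoff, n_permutations = 20000L,
                              seed = 1L, estimator = c("adaptive", "fixed_bins"),
                              k = 4L) {
  estimator <- match.arg(estimator)
  stopifnot(p_cutoff > 0, p_cutoff <= 1)
  if (p_cutoff == 1) return(0)
  null_mi <- with_local_seed(seed, {
    chunk <- 2000L
    done <- 0L
    acc <- vector("list", ceiling(n_permutations / chunk))
    i <- 0L
    while (done < n_permutations) {
      b <- min(chunk, n_permutations - done)
      xr <- .row_ranks(matrix(stats::runif(b * n_samples), b, n_samples))
      yr <- .row_ranks(matrix(stats::runif(b * n_samples), b, n_samples))
      i <- i + 1L
      acc[[i]] <- if (estimator == "adaptive") {
        .mi_paired_ranks(xr, yr)
      } else {
        kk <- as.integer(k)
        bx <- matrix(as.integer(floor(xr * kk / n_samples)), b, n_samples)
        by <- matrix(as.integer(floor(yr * kk / n_samples)), b, n_samples)
        vapply(seq_len(b), function(j)
          .mi_plugin_bins(bx[j, ], by[j, ], kk, kk), numeric(1))
      }
      done <- done + b
    }
    unlist(acc)
  })
  # empirical quantile where resolvable, exponential tail fit beyond
  if (p_cutoff >= 10 / n_permutations)
    return(stats::quantile(null_mi, probs = 1 - p_cutoff, names = FALSE,
                           type = 1))
  n_exc <- 100L
  srt <- sort(null_mi, decreasing = TRUE)
  u <- srt[n_exc + 1L]
  exc <- srt[seq_len(n_exc)] - u
  if (u <= 0 || mean(exc) == 0)
    return(max(srt[1L], stats::quantile(null_mi, probs = 1 - p_cutoff,
                                        names = FALSE, type = 1)))
  q_u <- n_exc / n_permutations
  u + mean(exc) * log(q_u / p_cutoff)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards.
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(expr)
}
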
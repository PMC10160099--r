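two_group_mat <- function(g0, g1, features = 1L) {
  m <- matrix(rep(c(g0, g1), each = features), features, byrow = FALSE)
  m <- matrix(c(g0, g1), features, length(g0) + length(g1), byrow = TRUE)
  rownames(m) <- sprintf("F%03d", seq_len(features))
  colnames(m) <- sprintf("S%d", seq_len(ncol(m)))
  m
}
grp <- function(n0, n1, ids) setNames(rep(c("A", "B"), c(n0, n1)), ids)

test_that("unmoderated route reproduces the textbook pooled t", {
  m <- two_group_mat(c(1, 2, 3), c(4, 5, 6))
  g <- grp(3, 3, colnames(m))
  tab <- de_two_group(m, g, moderated = FALSE)
  tt <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(tab$logFC, 3)
  expect_equal(tab$AveExpr, 3.5)
  expect_equal(tab$t, unname(tt$statistic), tolerance = 1e-9)
  expect_equal(tab$t, 3.674, tolerance = 1e-3)
  expect_equal(tab$p, tt$p.value, tolerance = 1e-9)
  expect_equal(tab$p, 0.0212, tolerance = 1e-2)
  expect_equal(tab$z, qnorm(1 - tab$p / 2), tolerance = 1e-9)
})

test_that("identical group means give the exact null row", {
  m <- two_group_mat(c(1, 3), c(0, 4))
  tab <- de_two_group(m, grp(2, 2, colnames(m)), moderated = FALSE)
  expect_equal(tab$logFC, 0)
  expect_equal(tab$t, 0)
  expect_equal(tab$p, 1)
  expect_equal(tab$z, 0)
})

test_that("moderation with d0 = 0 reduces exactly to the ordinary t", {
  set.seed(91)
  m <- matrix(rnorm(200 * 12), 200, 12,
              dimnames = list(sprintf("F%03d", 1:200), sprintf("S%d", 1:12)))
  g <- grp(6, 6, colnames(m))
  plain <- de_two_group(m, g, moderated = FALSE)
  mod0 <- de_two_group(m, g, moderated = TRUE, d0_override = 0)
  expect_equal(mod0$t, plain$t, tolerance = 1e-9)
  expect_equal(mod0$p, plain$p, tolerance = 1e-9)
})

test_that("moderated variance is the documented convex combination", {
  set.seed(92)
  m <- matrix(rnorm(100 * 8), 100, 8,
              dimnames = list(sprintf("F%03d", 1:100), sprintf("S%d", 1:8)))
  g <- grp(4, 4, colnames(m))
  tab <- de_two_group(m, g, moderated = TRUE)
  d0 <- attr(tab, "d0"); s0 <- attr(tab, "s0_sq")
  d <- 6
  s2 <- apply(m, 1, function(r) (sum((r[1:4] - mean(r[1:4]))^2) +
                                   sum((r[5:8] - mean(r[5:8]))^2)) / d)
  s2_tilde <- (d0 * s0 + d * s2) / (d0 + d)
  t_manual <- (rowMeans(m[, 5:8]) - rowMeans(m[, 1:4])) /
    sqrt(s2_tilde * (1 / 4 + 1 / 4))
  expect_equal(tab$t, unname(t_manual), tolerance = 1e-9)
})

test_that("moderated statistics agree closely with the limma reference", {
  skip_if_not_installed("limma")
  set.seed(93)
  m <- matrix(rnorm(400 * 8, sd = rep(sqrt(rchisq(400, 5) / 5), 8)), 400, 8,
              dimnames = list(sprintf("F%03d", 1:400), sprintf("S%d", 1:8)))
  g <- grp(4, 4, colnames(m))
  ours <- de_two_group(m, g, moderated = TRUE)
  design <- cbind(1, as.numeric(g == "B"))
  fit <- limma::eBayes(limma::lmFit(m, design))
  expect_gt(cor(ours$t, fit$t[, 2]), 0.999)
  expect_equal(attr(ours, "d0"), fit$df.prior, tolerance = 0.35 * fit$df.prior)
  expect_equal(attr(ours, "s0_sq"), fit$s2.prior,
               tolerance = 0.2 * fit$s2.prior)
})

test_that("null type-I error is calibrated at alpha = 0.05", {
  set.seed(94)
  m <- matrix(rnorm(2000 * 20), 2000, 20,
              dimnames = list(sprintf("F%04d", 1:2000), sprintf("S%d", 1:20)))
  g <- grp(10, 10, colnames(m))
  for (moderated in c(TRUE, FALSE)) {
    tab <- de_two_group(m, g, moderated = moderated)
    rate <- mean(tab$p < 0.05)
    ci <- qbinom(c(0.005, 0.995), 2000, 0.05) / 2000
    expect_gte(rate, ci[1])
    expect_lte(rate, ci[2])
  }
})

test_that("swapping group labels negates effects and keeps p", {
  set.seed(95)
  m <- matrix(rnorm(50 * 10), 50, 10,
              dimnames = list(sprintf("F%02d", 1:50), sprintf("S%d", 1:10)))
  g <- grp(5, 5, colnames(m))
  g_swapped <- setNames(ifelse(g == "A", "Z", "A"), names(g)) # B->A, A->Z flips order
  a <- de_two_group(m, g, moderated = TRUE)
  b <- de_two_group(m, g_swapped, moderated = TRUE)
  expect_equal(b$logFC, -a$logFC, tolerance = 1e-12)
  expect_equal(b$t, -a$t, tolerance = 1e-9)
  expect_equal(b$z, -a$z, tolerance = 1e-9)
  expect_equal(b$p, a$p, tolerance = 1e-12)
})

test_that("moderation keeps calibration and boosts power in tiny designs", {
  set.seed(96)
  n_feat <- 600
  m <- matrix(rnorm(n_feat * 4, sd = rep(sqrt(rchisq(n_feat, 4) / 4), 4)),
              n_feat, 4,
              dimnames = list(sprintf("F%03d", 1:n_feat), sprintf("S%d", 1:4)))
  shifted <- 1:200
  m[shifted, 3:4] <- m[shifted, 3:4] + 2
  g <- grp(2, 2, colnames(m))
  mod <- de_two_group(m, g, moderated = TRUE)
  plain <- de_two_group(m, g, moderated = FALSE)
  null_idx <- setdiff(seq_len(n_feat), shifted)
  expect_lte(mean(mod$p[null_idx] < 0.05), 0.08)
  expect_gte(mean(mod$p[shifted] < 0.05), mean(plain$p[shifted] < 0.05))
})

test_that("degenerate designs are rejected", {
  m <- two_group_mat(c(1, 1), c(2, 2), features = 2)
  g <- grp(2, 2, colnames(m))
  expect_error(de_two_group(m, g, moderated = FALSE), "zero residual variance")
  g3 <- setNames(c("A", "A", "B", "C"), colnames(m))
  expect_error(de_two_group(m, g3), "exactly 2 groups")
  expect_error(de_two_group(m, g[1:3]), "missing")
})

test_that("BID MLE equals the pooled-t effect and its standard error", {
  set.seed(97)
  m <- matrix(rnorm(40 * 9), 40, 9,
              dimnames = list(sprintf("F%02d", 1:40), sprintf("S%d", 1:9)))
  g <- grp(4, 5, colnames(m))
  mle <- bid_two_group(m, g, "MLE")
  plain <- de_two_group(m, g, moderated = FALSE)
  expect_equal(mle$logFC, plain$logFC, tolerance = 1e-12)
  expect_equal(mle$t, plain$t, tolerance = 1e-12) # same beta / se(beta)
  # but MLE refers z to the normal
  expect_equal(mle$p, 2 * pnorm(-abs(mle$t)), tolerance = 1e-12)
})

test_that("Bayesian BID washes out to MLE as the prior df vanishes", {
  set.seed(98)
  m <- matrix(rnorm(30 * 8), 30, 8,
              dimnames = list(sprintf("F%02d", 1:30), sprintf("S%d", 1:8)))
  g <- grp(4, 4, colnames(m))
  mle <- bid_two_group(m, g, "MLE")
  bay <- bid_two_group(m, g, "Bayesian", a0 = 1e-10)
  expect_equal(bay$z, mle$z, tolerance = 1e-6)
})

test_that("the variance prior regularizes zero-residual features", {
  m <- two_group_mat(c(0, 0), c(1, 1), features = 1)
  m <- rbind(m, F002 = c(0.1, -0.2, 0.9, 1.3)) # one ordinary feature for the prior
  g <- grp(2, 2, colnames(m))
  tab <- bid_two_group(m, g, "Bayesian")
  expect_true(all(is.finite(tab$z)))
  expect_gt(tab$z[1], 0)
})

test_that("BH adjustment matches the hand step-up computation", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  set.seed(99)
  p <- runif(50)
  expect_true(all(bh_adjust(p) >= p))
  # independent step-up oracle
  ord <- order(p)
  stepup <- rev(cummin(rev(p[ord] * 50 / seq_len(50))))
  expect_equal(bh_adjust(p)[ord], pmin(stepup, 1))
})
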
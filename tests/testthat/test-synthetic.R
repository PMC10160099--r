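test_that("planted truth generation is seeded and honors its knobs", {
  t1 <- generate_truth(20, 6, frac_negative_edges = 0, n_hidden = 3, seed = 2)
  t2 <- generate_truth(20, 6, frac_negative_edges = 0, n_hidden = 3, seed = 2)
  expect_identical(t1, t2)
  # all-positive when frac_negative = 0 (except the deliberately balanced
  # first hidden driver)
  others <- t1$edges$driver != t1$balanced_driver
  expect_true(all(t1$edges$sign[others] == 1L))
  bal <- t1$edges$sign[!others]
  expect_equal(sum(bal == 1L), sum(bal == -1L))
  expect_identical(sum(t1$hidden), 3L)
  # every target belongs to exactly one driver
  expect_false(anyDuplicated(t1$edges$target) > 0)
  # regulon floors respected
  sizes <- table(t1$edges$driver)
  expect_true(all(sizes[names(t1$hidden)[t1$hidden]] >= 30))
  expect_true(all(sizes >= 5))
})

test_that("preferential target assignment yields a heavy-tailed, scale-free-ish
           regulon-size distribution", {
  truth <- generate_truth(500, 8, n_hidden = 0, seed = 3)
  sizes <- as.integer(table(truth$edges$driver))
  expect_gt(scale_free_r2(sizes), 0.6)
  expect_gt(max(sizes), 5 * median(sizes))
})

test_that("simulated expression obeys the linear-Gaussian plant", {
  truth <- generate_truth(10, 8, frac_negative_edges = 0.4, n_hidden = 2,
                          seed = 4, min_hidden_regulon = 8)
  spec <- modality_spec("mRNA", n_samples = 2000)
  m <- simulate_expression(truth, spec, seed = 5)
  lat <- attr(m, "latent_activity")
  # hidden drivers' own expression is decoupled from activity ...
  for (d in names(truth$hidden)[truth$hidden])
    expect_lt(abs(cor(m[d, ], lat[d, ])), 3 / sqrt(2000))
  # ... non-hidden drivers' own expression tracks it
  for (d in names(truth$hidden)[!truth$hidden])
    expect_gt(cor(m[d, ], lat[d, ]), 0.5)
  # target/driver-activity MI matches the closed form within the estimator's
  # documented bias band
  ed <- truth$edges[1:5, ]
  for (i in seq_len(5)) {
    rho <- ed$weight[i] / sqrt(ed$weight[i]^2 + 1)
    closed <- -0.5 * log(1 - rho^2)
    est <- compute_mi(lat[ed$driver[i], ], m[ed$target[i], ])
    expect_gt(est, 0.4 * closed)
    expect_lt(est, 1.1 * closed)
  }
})

test_that("two-group simulation shifts only the planted drivers' activity", {
  truth <- generate_truth(12, 6, n_hidden = 4, seed = 6,
                          min_hidden_regulon = 6)
  spec <- modality_spec("mRNA", n_per_group = c(50, 50))
  m <- simulate_expression(truth, spec, group_effect = 2, seed = 7)
  groups <- attr(m, "groups")
  lat <- attr(m, "latent_activity")
  g1 <- groups == "G1"
  for (d in truth$drivers) {
    diffm <- mean(lat[d, g1]) - mean(lat[d, !g1])
    if (truth$hidden[d]) expect_gt(diffm, 1) else expect_lt(abs(diffm), 0.6)
  }
  # coverage subsampling keeps the requested fraction
  spec30 <- modality_spec("pProtein", n_per_group = c(2, 2), coverage = 0.3)
  m30 <- simulate_expression(truth, spec30, group_effect = 2, seed = 8)
  expect_equal(nrow(m30) / nrow(m), 0.3, tolerance = 0.02)
})

test_that("null simulations keep differential expression calibrated", {
  truth <- generate_truth(10, 8, n_hidden = 3, seed = 9,
                          min_hidden_regulon = 8)
  spec <- modality_spec("mRNA", n_per_group = c(10, 10))
  m <- simulate_expression(truth, spec, group_effect = 0, seed = 10)
  tab <- de_two_group(m, attr(m, "groups"), moderated = TRUE)
  rate <- mean(tab$p < 0.05)
  ci <- qbinom(c(0.005, 0.995), nrow(m), 0.05) / nrow(m)
  expect_gte(rate, ci[1])
  expect_lte(rate, ci[2])
})

test_that("hidden drivers show differential activity but no differential
           expression (the core phenomenon), across seeds", {
  ok <- vapply(1:50, function(s) {
    truth <- generate_truth(15, 6, n_hidden = 1, seed = 300 + s,
                            min_hidden_regulon = 12)
    spec <- modality_spec("mRNA", n_per_group = c(20, 20))
    m <- simulate_expression(truth, spec, group_effect = 2, seed = 600 + s)
    groups <- attr(m, "groups")
    hid <- names(truth$hidden)[truth$hidden]
    act <- cal_activity(m, truth_network(truth), "weighted_mean",
                        std = TRUE, min_targets = 5)
    da <- de_two_group(act, groups)
    de <- de_two_group(z_transform(filter_genes(m, 1e-12)), groups)
    da$adj_p[da$feature == hid] < 0.01 &&
      de$p[de$feature == hid] > 0.05
  }, logical(1))
  expect_gte(mean(ok), 0.9)
})

test_that("benchmark bundles load cleanly and match the declared shape", {
  d <- withr::local_tempdir()
  bench <- make_benchmark_suite(seed = 3, dir = d,
                                n_drivers = 30, n_hidden = 3)
  expect_no_warning({
    mats <- lapply(bench$paths[c("construction", "mRNA", "wProtein",
                                 "pProtein")], load_expression)
  })
  expect_identical(ncol(mats$construction), 200L)
  expect_identical(vapply(mats[c("mRNA", "wProtein", "pProtein")], ncol,
                          integer(1), USE.NAMES = FALSE), c(8L, 4L, 4L))
  g <- read_groups(bench$paths$mRNA_groups)
  expect_identical(as.integer(table(g)["G0"]), 4L)
  expect_true(file.exists(bench$paths$truth))
  gsc <- read_gmt(bench$paths$gmt)
  expect_gte(length(gsc$sets), 3)
  tf <- readLines(bench$paths$tf)
  sig <- readLines(bench$paths$sig)
  expect_identical(sort(c(tf, sig)), bench$truth$drivers)
  # byte-stable for a fixed seed
  d2 <- withr::local_tempdir()
  make_benchmark_suite(seed = 3, dir = d2, n_drivers = 30, n_hidden = 3)
  for (f in list.files(d)) {
    expect_identical(unname(tools::md5sum(file.path(d, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
})

test_that("larger construction cohorts recover planted edges better", {
  recall_at <- function(n, s) {
    truth <- generate_truth(8, 6, n_hidden = 0, seed = 40 + s)
    spec <- modality_spec("mRNA", n_samples = n, driver_noise_sd = 0)
    m <- simulate_expression(truth, spec, seed = 50 + s)
    net <- reconstruct_network(m, tf_drivers = truth$drivers,
                               params = network_params(n_bootstraps = 40,
                                                       seed = 60 + s))
    mean(edge_keys(truth$edges, "driver", "target") %in%
           edge_keys(net$edges))
  }
  med_recall <- vapply(c(20, 100, 200), function(n)
    median(vapply(1:3, function(s) recall_at(n, s), numeric(1))), numeric(1))
  expect_true(all(diff(med_recall) >= 0))
  expect_gt(med_recall[3], med_recall[1])
})
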
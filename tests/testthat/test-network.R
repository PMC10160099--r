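test_that("DPI removes the weakest edge of a triangle and nothing else", {
  tri <- data.frame(a = c("A", "B", "A"), b = c("B", "C", "C"),
                    mi = c(0.9, 0.8, 0.3), stringsAsFactors = FALSE)
  out <- apply_dpi(tri, tolerance = 0)
  expect_identical(sort(out$mi), c(0.8, 0.9))
  # no triangles -> unchanged
  chain <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "D"),
                      mi = c(0.5, 0.1, 0.4), stringsAsFactors = FALSE)
  expect_identical(apply_dpi(chain, 0), chain)
})

test_that("DPI agrees with the exhaustive triangle oracle on random graphs", {
  set.seed(31)
  for (rep in 1:100) {
    nn <- sample(5:30, 1)
    nodes <- sprintf("N%02d", seq_len(nn))
    pairs <- t(combn(nodes, 2))
    pick <- runif(nrow(pairs)) < 0.25
    if (!any(pick)) next
    edges <- data.frame(a = pairs[pick, 1], b = pairs[pick, 2],
                        mi = runif(sum(pick)), stringsAsFactors = FALSE)
    tol <- sample(c(0, 0.1, 0.3), 1)
    got <- apply_dpi(edges, tol)
    want <- dpi_oracle(edges, tol)
    expect_identical(got, want)
    # output is always a subset of input
    expect_true(all(rownames(got) %in% rownames(edges)))
  }
})

test_that("DPI with tolerance near 1 approaches identity", {
  set.seed(32)
  nodes <- sprintf("N%d", 1:12)
  pairs <- t(combn(nodes, 2))
  edges <- data.frame(a = pairs[, 1], b = pairs[, 2], mi = runif(nrow(pairs)),
                      stringsAsFactors = FALSE)
  expect_lt(nrow(apply_dpi(edges, 0)), nrow(edges))
  expect_identical(apply_dpi(edges, 0.999), edges)
})

test_that("bootstrap networks are deterministic and respect preconditions", {
  pl <- make_planted_linear(n_drivers = 2, targets_per_driver = 5, n = 60,
                            seed = 41)
  params <- network_params(n_bootstraps = 5, seed = 7,
                           n_permutations = 5000)
  b1 <- bootstrap_networks(pl$m, pl$drivers, params)
  b2 <- bootstrap_networks(pl$m, pl$drivers, params)
  expect_identical(b1, b2)
  expect_error(bootstrap_networks(pl$m[, 1:5], pl$drivers, params),
               "at least 8 samples")
  expect_error(bootstrap_networks(pl$m, "NOPE", params), "no drivers")
})

test_that("a single unresampled bootstrap reproduces the full-data network", {
  pl <- make_planted_linear(n_drivers = 2, targets_per_driver = 6, n = 80,
                            seed = 43)
  params <- network_params(n_bootstraps = 1, seed = 5, n_permutations = 5000)
  be <- bootstrap_networks(pl$m, pl$drivers, params, resample = FALSE)
  expect_length(be, 1)
  thr <- attr(be, "mi_threshold")
  # recompute by hand: MI of every driver-gene pair on the full data
  ed <- be[[1]]
  for (i in seq_len(nrow(ed)))
    expect_equal(ed$mi[i],
                 compute_mi(pl$m[ed$driver[i], ], pl$m[ed$target[i], ]),
                 tolerance = 1e-12)
  expect_true(all(ed$mi >= thr))
})

test_that("consensus p-values match a direct Poisson survival computation", {
  set.seed(51)
  for (i in 1:1000) {
    count <- sample(0:100, 1)
    mu <- runif(1, 0.1, 60)
    got <- ppois(count - 1, mu, lower.tail = FALSE)
    expect_equal(got, poisson_tail_oracle(count, mu), tolerance = 1e-10)
  }
})

test_that("consensus retains recurrent edges, drops support-0, attaches signs", {
  # hand-built bootstrap edge sets: edge D>T1 in all 10, D>T2 in 1
  mk <- function(edges) data.frame(driver = "D", target = edges,
                                   mi = 0.5, stringsAsFactors = FALSE)
  boots <- c(replicate(10, mk(c("T1", "T2"))[1, , drop = FALSE],
                       simplify = FALSE))
  boots[[1]] <- mk(c("T1", "T2"))
  set.seed(52)
  m <- rbind(D = rnorm(30), T1 = rnorm(30), T2 = rnorm(30))
  colnames(m) <- sprintf("S%02d", 1:30)
  m["T1", ] <- m["D", ] + rnorm(30, sd = 0.2)
  net <- consensus(boots, pc = 0.1, m, driver_type = c(D = "TF"))
  expect_identical(net$edges$target, "T1")
  expect_identical(net$edges$support, 10L)
  expect_identical(net$edges$sign, 1L)
  expect_equal(net$edges$spearman_rho,
               cor(m["D", ], m["T1", ], method = "spearman"))
  # retention is monotone in support at fixed mu
  mu <- 3
  cp <- ppois(0:20 - 1, mu, lower.tail = FALSE)
  expect_true(all(diff(cp) <= 0))
})

test_that("fused reconstruction equals the two-stage bootstrap+consensus path", {
  pl <- make_planted_linear(n_drivers = 3, targets_per_driver = 6, n = 60,
                            seed = 61, b = 1.2)
  params <- network_params(n_bootstraps = 12, consensus_p_cutoff = 1e-3,
                           per_bootstrap_mi_p = 1e-4, seed = 3,
                           n_permutations = 5000)
  fused <- reconstruct_network(pl$m, tf_drivers = pl$drivers, params = params)
  be <- bootstrap_networks(pl$m, pl$drivers, params)
  twostage <- consensus(be, params$consensus_p_cutoff, pl$m,
                        setNames(rep("TF", 3), pl$drivers), params)
  expect_equal(fused$edges, twostage$edges, tolerance = 1e-12)
  expect_equal(attr(fused, "mi_threshold"), attr(be, "mi_threshold"))
})

test_that("planted edges recur across most bootstraps", {
  pl <- make_planted_linear(n_drivers = 3, targets_per_driver = 10, n = 200,
                            b = 1, noise_sd = 1, seed = 71)
  params <- network_params(n_bootstraps = 20, seed = 11)
  be <- bootstrap_networks(pl$m, pl$drivers, params)
  keys <- lapply(be, edge_keys, from = "driver", to = "target")
  truth_keys <- edge_keys(pl$truth, from = "driver", to = "target")
  frac <- vapply(truth_keys, function(k)
    mean(vapply(keys, function(kk) k %in% kk, logical(1))), numeric(1))
  expect_gte(median(frac), 0.85)
  expect_gte(mean(frac), 0.8)
  expect_true(all(frac >= 0.4))
})

test_that("regulon extraction is an exact out-edge view", {
  edges <- data.frame(
    source = c("D1", "D1", "D2"), target = c("T1", "T2", "T1"),
    mi = c(0.5, 0.2, 0.4), spearman_rho = c(0.9, -0.8, 0.7),
    sign = c(1L, -1L, 1L), support = c(10L, 9L, 8L),
    consensus_p = c(1e-8, 1e-7, 1e-6), stringsAsFactors = FALSE)
  net <- structure(list(edges = edges,
                        driver_type = c(D1 = "TF", D2 = "SIG", D3 = "SIG"),
                        params = NULL), class = "interactome")
  r <- get_regulon(net, "D1")
  expect_identical(r$targets$target, c("T1", "T2"))
  expect_identical(r$targets$sign, c(1L, -1L))
  expect_message(r0 <- get_regulon(net, "D3"), "empty regulon")
  expect_identical(nrow(r0$targets), 0L)
  expect_error(get_regulon(net, "NOPE"), "unknown driver")
  # regulon sizes sum to the edge count
  sizes <- vapply(names(net$driver_type),
                  function(d) nrow(suppressMessages(get_regulon(net, d))$targets),
                  integer(1))
  expect_identical(sum(sizes), nrow(edges))
})

test_that("network TSV round trip preserves edges and driver classes", {
  edges <- data.frame(
    source = c("D1", "D1", "D2"), target = c("T1", "T2", "T1"),
    mi = c(0.5, 0.2, 0.4), spearman_rho = c(0.9, -0.8, 0.7),
    sign = c(1L, -1L, 1L), support = c(10L, 9L, 8L),
    consensus_p = c(1e-8, 1e-7, 1e-6), stringsAsFactors = FALSE)
  net <- structure(list(edges = edges,
                        driver_type = c(D1 = "TF", D2 = "SIG"),
                        params = NULL), class = "interactome")
  d <- withr::local_tempdir()
  paths <- write_network(net, d)
  expect_identical(readLines(paths[["TF"]], n = 1),
                   "source\ttarget\tmi\tspearman_rho\tsign\tsupport\tconsensus_p")
  net2 <- read_network(paths)
  expect_equal(net2$edges, edges, tolerance = 1e-12)
  expect_identical(unname(net2$driver_type[c("D1", "D2")]), c("TF", "SIG"))
})
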
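# Shared fixtures and independent oracles for the test suite.

# small named expression matrix
toy_matrix <- function(g = 5L, n = 6L, seed = 1L) {
  set.seed(seed)
  m <- matrix(rnorm(g * n), g, n,
              dimnames = list(sprintf("G%02d", seq_len(g)),
                              sprintf("S%02d", seq_len(n))))
  m
}

# plug-in MI oracle from a joint contingency table (nats)
mi_from_table <- function(tab) {
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p)))
    if (p[i, j] > 0) s <- s + p[i, j] * log(p[i, j] / (px[i] * py[j]))
  unname(s)
}

# exhaustive O(n^3) DPI oracle: edge df (a, b, mi), undirected
dpi_oracle <- function(edges, tolerance = 0) {
  nodes <- unique(c(edges$a, edges$b))
  mi_of <- function(x, y) {
    hit <- (edges$a == x & edges$b == y) | (edges$a == y & edges$b == x)
    if (any(hit)) edges$mi[which(hit)[1L]] else NA_real_
  }
  keep <- rep(TRUE, nrow(edges))
  for (e in seq_len(nrow(edges))) {
    i <- edges$a[e]; j <- edges$b[e]; mij <- edges$mi[e]
    for (k in setdiff(nodes, c(i, j))) {
      mik <- mi_of(i, k); mkj <- mi_of(k, j)
      if (!is.na(mik) && !is.na(mkj) &&
          mij < min(mik, mkj) * (1 - tolerance)) {
        keep[e] <- FALSE
        break
      }
    }
  }
  edges[keep, , drop = FALSE]
}

# upper-tail Poisson survival by direct summation (independent of ppois)
poisson_tail_oracle <- function(count, mu, kmax = 2000L) {
  if (count <= 0) return(1)
  k <- seq.int(count, count + kmax)
  sum(exp(-mu + k * log(mu) - lgamma(k + 1)))
}

# tiny planted linear network: each target = b * driver + noise
make_planted_linear <- function(n_drivers = 3L, targets_per_driver = 10L,
                                n = 200L, b = 1, noise_sd = 1, seed = 1L) {
  set.seed(seed)
  drivers <- sprintf("D%d", seq_len(n_drivers))
  act <- matrix(rnorm(n_drivers * n), n_drivers, n, dimnames = list(drivers, NULL))
  tgt_names <- sprintf("T%03d", seq_len(n_drivers * targets_per_driver))
  owner <- rep(drivers, each = targets_per_driver)
  tgt <- b * act[owner, , drop = FALSE] +
    matrix(rnorm(length(owner) * n, sd = noise_sd), length(owner), n)
  rownames(tgt) <- tgt_names
  m <- rbind(act, tgt)
  colnames(m) <- sprintf("S%03d", seq_len(n))
  list(m = m, drivers = drivers,
       truth = data.frame(driver = owner, target = tgt_names,
                          stringsAsFactors = FALSE))
}

edge_keys <- function(df, from = "source", to = "target")
  paste0(df[[from]], ">", df[[to]])
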
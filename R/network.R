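#' Default network-reconstruction parameters
#'
#' Bootstraps n = 100 and consensus p-value cutoff pc = 1e-5 are the
#' recommended defaults for MI-based interactome reverse-engineering; the
#' per-bootstrap MI significance cutoff (1e-7) and DPI tolerance (0) follow
#' the ARACNe lineage.
#'
#' @param n_bootstraps number of bootstrap resamples.
#' @param consensus_p_cutoff Poisson consensus retention cutoff (pc).
#' @param per_bootstrap_mi_p per-bootstrap MI significance level.
#' @param dpi_tolerance data-processing-inequality tolerance in \[0, 1).
#' @param n_permutations permutations for the MI null threshold.
#' @param seed master seed; bootstrap b uses `seed + b`, the permutation
#'   null uses `seed + 1e6`.
#' @return a named list of parameters.
#' @export
network_params <- function(n_bootstraps = 100L, consensus_p_cutoff = 1e-5,
                           per_bootstrap_mi_p = 1e-7, dpi_tolerance = 0,
                           n_permutations = 20000L, seed = 1L) {
  stopifnot(n_bootstraps >= 1L, consensus_p_cutoff > 0, consensus_p_cutoff <= 1,
            per_bootstrap_mi_p > 0, per_bootstrap_mi_p <= 1,
            dpi_tolerance >= 0, dpi_tolerance < 1)
  list(n_bootstraps = as.integer(n_bootstraps),
       consensus_p_cutoff = consensus_p_cutoff,
       per_bootstrap_mi_p = per_bootstrap_mi_p,
       dpi_tolerance = dpi_tolerance,
       n_permutations = as.integer(n_permutations),
       seed = as.integer(seed))
}

#' Data-processing-inequality pruning
#'
#' For every triangle (i, j, k) in the undirected MI-weighted graph, the edge
#' (i, j) is removed iff `mi(i,j) < min(mi(i,k), mi(k,j)) * (1 - tolerance)`
#' — the weakest edge of a triangle is presumed indirect. Removal decisions
#' are evaluated against the input graph and applied simultaneously.
#'
#' @param edges data.frame with columns `a`, `b`, `mi` (one row per
#'   unordered pair; MI >= 0).
#' @param tolerance real in \[0, 1); 0 is strict DPI, values near 1 disable
#'   pruning.
#' @return the surviving subset of `edges` (row order preserved).
#' @export
apply_dpi <- function(edges, tolerance = 0) {
  stopifnot(tolerance >= 0, tolerance < 1)
  if (nrow(edges) == 0L) return(edges)
  a <- as.character(edges$a); b <- as.character(edges$b); mi <- edges$mi
  key <- ifelse(a < b, paste0(a, "\r", b), paste0(b, "\r", a))
  if (anyDuplicated(key)) stop("duplicate undirected pairs in edge set")
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  tri <- matrix(as.integer(igraph::triangles(g)), nrow = 3L)
  if (ncol(tri) == 0L) return(edges)
  nm <- igraph::V(g)$name
  eid <- stats::setNames(seq_along(key), key)
  ekey <- function(i, j) {
    ni <- nm[i]; nj <- nm[j]
    ifelse(ni < nj, paste0(ni, "\r", nj), paste0(nj, "\r", ni))
  }
  e12 <- eid[ekey(tri[1L, ], tri[2L, ])]
  e13 <- eid[ekey(tri[1L, ], tri[3L, ])]
  e23 <- eid[ekey(tri[2L, ], tri[3L, ])]
  scale <- 1 - tolerance
  drop <- logical(length(key))
  flag <- function(e, o1, o2) {
    hit <- mi[e] < pmin(mi[o1], mi[o2]) * scale
    drop[e[hit]] <<- TRUE
  }
  flag(e12, e13, e23)
  flag(e13, e12, e23)
  flag(e23, e12, e13)
  edges[!drop, , drop = FALSE]
}

#' Bootstrap ensemble of thresholded, DPI-pruned MI networks
#'
#' For each bootstrap b in 1..n, samples are resampled with replacement
#' (seeded `seed + b`), MI is computed between every driver and every other
#' gene, edges below the permutation-null MI threshold are discarded, and
#' DPI pruning is applied. Candidate edges are restricted to driver -> gene
#' pairs (drivers = union of the TF and SIG lists); driver-driver edges are
#' allowed and appear in both drivers' out-edge sets.
#'
#' @param m genes x samples numeric matrix (network-construction cohort;
#'   >= 8 samples).
#' @param drivers character vector of driver gene IDs present in `m` (union
#'   of TF and SIG lists).
#' @param params a [network_params()] list.
#' @param resample test hook; `FALSE` disables resampling so a single
#'   bootstrap reproduces the full-data network.
#' @return list of per-bootstrap directed edge data.frames
#'   (`driver`, `target`, `mi`), with the MI threshold in attribute
#'   `mi_threshold`.
#' @export
bootstrap_networks <- function(m, drivers, params = network_params(),
                               resample = TRUE) {
  if (ncol(m) < 8L) stop("need at least 8 samples for network reconstruction")
  drivers <- intersect(drivers, rownames(m))
  if (!length(drivers)) stop("no drivers present in the expression matrix")
  thr <- mi_null_threshold(ncol(m), params$per_bootstrap_mi_p,
                           n_permutations = params$n_permutations,
                           seed = params$seed + 1e6)
  didx <- match(drivers, rownames(m))
  genes <- rownames(m)
  out <- vector("list", params$n_bootstraps)
  for (b in seq_len(params$n_bootstraps)) {
    idx <- if (resample) {
      with_local_seed(params$seed + b, sample.int(ncol(m), replace = TRUE))
    } else seq_len(ncol(m))
    rk <- .row_ranks(m[, idx, drop = FALSE])
    miM <- .mi_cross_ranks(rk, didx - 1L)
    hit <- which(miM >= thr & !is.na(miM), arr.ind = TRUE)
    ed <- data.frame(driver = drivers[hit[, 1L]], target = genes[hit[, 2L]],
                     mi = miM[hit], stringsAsFactors = FALSE)
    # collapse to unordered pairs for DPI (MI is symmetric in its arguments)
    und_a <- pmin(ed$driver, ed$target)
    und_b <- pmax(ed$driver, ed$target)
    kk <- paste0(und_a, "\r", und_b)
    first <- !duplicated(kk)
    und <- data.frame(a = und_a[first], b = und_b[first], mi = ed$mi[first],
                      stringsAsFactors = FALSE)
    surv <- apply_dpi(und, params$dpi_tolerance)
    surv_key <- paste0(surv$a, "\r", surv$b)
    out[[b]] <- ed[kk %in% surv_key, , drop = FALSE]
  }
  structure(out, mi_threshold = thr)
}

#' Poisson consensus over bootstrap networks
#'
#' Edge recurrence across bootstraps is modeled as Poisson: with T total
#' edge occurrences over the E candidate edges (every driver -> gene pair,
#' drivers restricted to those present in the matrix) and mu = T/E, each
#' edge's consensus p-value is the
#' upper-tail Poisson(mu) probability at its support count; edges with
#' `consensus_p < pc` are retained. Retained edges carry the mean MI over
#' supporting bootstraps and the Spearman correlation (average ranks for
#' ties) computed on the full, unresampled matrix; the edge sign is the sign
#' of that correlation.
#'
#' @param bootstrap_edges list from [bootstrap_networks()].
#' @param pc consensus p-value cutoff (default 1e-5).
#' @param m the full genes x samples matrix (for Spearman direction).
#' @param driver_type named character vector mapping driver -> "TF"/"SIG".
#' @param params the [network_params()] used (stored in the result).
#' @return an object of class `interactome`: list with `edges` (data.frame
#'   `source`, `target`, `mi`, `spearman_rho`, `sign`, `support`,
#'   `consensus_p`), `driver_type`, `params`.
#' @export
consensus <- function(bootstrap_edges, pc = 1e-5, m, driver_type,
                      params = network_params()) {
  B <- length(bootstrap_edges)
  stopifnot(B >= 1L)
  all_ed <- do.call(rbind, bootstrap_edges)
  if (is.null(all_ed) || nrow(all_ed) == 0L) {
    edges <- data.frame(source = character(0), target = character(0),
                        mi = numeric(0), spearman_rho = numeric(0),
                        sign = integer(0), support = integer(0),
                        consensus_p = numeric(0), stringsAsFactors = FALSE)
    return(structure(list(edges = edges, driver_type = driver_type,
                          params = params), class = "interactome"))
  }
  key <- paste0(all_ed$driver, "\r", all_ed$target)
  support <- table(key)
  drivers_in_m <- intersect(names(driver_type), rownames(m))
  E <- length(drivers_in_m) * (nrow(m) - 1)
  mu <- sum(support) / E
  mean_mi <- tapply(all_ed$mi, key, mean)
  cp <- stats::ppois(as.integer(support) - 1L, mu, lower.tail = FALSE)
  keep <- cp < pc & as.integer(support) > 0L
  kn <- names(support)[keep]
  parts <- do.call(rbind, strsplit(kn, "\r", fixed = TRUE))
  if (is.null(parts)) parts <- matrix(character(0), ncol = 2)
  rho <- numeric(length(kn))
  if (length(kn)) {
    rk <- apply(m, 1L, rank) # samples x genes, average ranks for ties
    colnames(rk) <- rownames(m)
    for (i in seq_along(kn))
      rho[i] <- stats::cor(rk[, parts[i, 1L]], rk[, parts[i, 2L]])
  }
  edges <- data.frame(
    source = parts[, 1L], target = parts[, 2L],
    mi = as.numeric(mean_mi[kn]),
    spearman_rho = rho,
    sign = as.integer(sign(rho)),
    support = as.integer(support[kn]),
    consensus_p = as.numeric(cp[keep]),
    stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, driver_type = driver_type, params = params),
            class = "interactome")
}

#' Reverse-engineer TF and SIG interactomes from an expression matrix
#'
#' High-level wrapper: bootstraps + MI thresholding + DPI + Poisson
#' consensus. Internally the bootstrap loop accumulates support counts in
#' matrices rather than materializing per-bootstrap edge tables; the result
#' is identical to `consensus(bootstrap_networks(...))` (the two paths are
#' cross-checked in the test suite).
#'
#' @param m genes x samples matrix (network-construction cohort).
#' @param tf_drivers,sig_drivers character vectors of transcription-factor
#'   and signaling-factor gene IDs.
#' @param params a [network_params()] list.
#' @return an `interactome` (see [consensus()]); drivers in both lists are
#'   typed "TF;SIG".
#' @export
reconstruct_network <- function(m, tf_drivers, sig_drivers = character(0),
                                params = network_params()) {
  drivers <- union(tf_drivers, sig_drivers)
  dtype <- ifelse(drivers %in% tf_drivers & drivers %in% sig_drivers, "TF;SIG",
                  ifelse(drivers %in% tf_drivers, "TF", "SIG"))
  names(dtype) <- drivers
  .bootstrap_consensus_fast(m, intersect(drivers, rownames(m)), dtype, params)
}

# Fused bootstrap + DPI + Poisson consensus. Equivalent to
# consensus(bootstrap_networks(m, drivers, params), ...) but accumulates
# edge support and MI sums in drivers x genes matrices. DPI exploits that
# candidate edges always have a driver endpoint, so every triangle contains
# a driver-driver edge: triangles are enumerated from the (few) candidate
# driver-driver pairs only.
.bootstrap_consensus_fast <- function(m, drivers, dtype, params) {
  if (ncol(m) < 8L) stop("need at least 8 samples for network reconstruction")
  if (!length(drivers)) stop("no drivers present in the expression matrix")
  thr <- mi_null_threshold(ncol(m), params$per_bootstrap_mi_p,
                           n_permutations = params$n_permutations,
                           seed = params$seed + 1e6)
  didx <- match(drivers, rownames(m))
  D <- length(drivers); G <- nrow(m)
  sup <- matrix(0L, D, G)
  msum <- matrix(0, D, G)
  scale <- 1 - params$dpi_tolerance
  for (b in seq_len(params$n_bootstraps)) {
    idx <- with_local_seed(params$seed + b,
                           sample.int(ncol(m), replace = TRUE))
    rk <- .row_ranks(m[, idx, drop = FALSE])
    miM <- .mi_cross_ranks(rk, didx - 1L)
    hits <- !is.na(miM) & miM >= thr
    # DPI: scan candidate driver-driver edges for triangles. Removal
    # decisions are evaluated against the pre-pruning graph and applied
    # simultaneously, as in apply_dpi().
    dd <- which(hits[, didx, drop = FALSE], arr.ind = TRUE)
    if (nrow(dd)) {
      dd <- dd[dd[, 1L] < dd[, 2L], , drop = FALSE] # each unordered pair once
      drop_idx <- integer(0)
      for (r in seq_len(nrow(dd))) {
        a <- dd[r, 1L]; b2 <- dd[r, 2L]
        mab <- miM[a, didx[b2]]
        common <- which(hits[a, ] & hits[b2, ])
        common <- setdiff(common, didx[c(a, b2)])
        if (!length(common)) next
        mag <- miM[a, common]; mbg <- miM[b2, common]
        rem_ag <- mag < pmin(mab, mbg) * scale
        rem_bg <- mbg < pmin(mab, mag) * scale
        mark <- function(row, col) drop_idx <<- c(drop_idx, (col - 1L) * D + row)
        if (any(mab < pmin(mag, mbg) * scale)) {
          mark(a, didx[b2])
          mark(b2, didx[a])
        }
        for (g in common[rem_ag]) {
          mark(a, g)
          gi <- match(g, didx)
          if (!is.na(gi)) mark(gi, didx[a])
        }
        for (g in common[rem_bg]) {
          mark(b2, g)
          gi <- match(g, didx)
          if (!is.na(gi)) mark(gi, didx[b2])
        }
      }
      if (length(drop_idx)) hits[drop_idx] <- FALSE
    }
    sup <- sup + hits
    msum <- msum + miM * hits
  }
  E <- D * (G - 1) # candidate driver -> gene pairs
  edges <- data.frame(source = character(0), target = character(0),
                      mi = numeric(0), spearman_rho = numeric(0),
                      sign = integer(0), support = integer(0),
                      consensus_p = numeric(0), stringsAsFactors = FALSE)
  if (any(sup > 0L)) {
    mu <- sum(sup) / E
    cpM <- stats::ppois(sup - 1L, mu, lower.tail = FALSE)
    keep <- which(sup > 0L & cpM < params$consensus_p_cutoff, arr.ind = TRUE)
    if (nrow(keep)) {
      rk_full <- t(apply(m, 1L, rank)) # average ranks for ties
      src <- drivers[keep[, 1L]]
      tgt <- rownames(m)[keep[, 2L]]
      rho <- vapply(seq_len(nrow(keep)), function(i)
        stats::cor(rk_full[src[i], ], rk_full[tgt[i], ]), numeric(1))
      edges <- data.frame(
        source = src, target = tgt,
        mi = msum[keep] / sup[keep],
        spearman_rho = rho,
        sign = as.integer(sign(rho)),
        support = as.integer(sup[keep]),
        consensus_p = cpM[keep],
        stringsAsFactors = FALSE)
      edges <- edges[order(edges$source, edges$target), , drop = FALSE]
      rownames(edges) <- NULL
    }
  }
  structure(list(edges = edges, driver_type = dtype[drivers],
                 params = params),
            class = "interactome", mi_threshold = thr)
}

#' Extract one driver's regulon
#'
#' @param net an `interactome`.
#' @param driver driver gene ID (must be a known driver of `net`).
#' @return object of class `regulon`: list with `driver` and `targets`
#'   (data.frame `target`, `mi`, `sign`). An empty regulon is valid and is
#'   flagged with a message.
#' @export
get_regulon <- function(net, driver) {
  if (!driver %in% names(net$driver_type))
    stop("unknown driver: ", driver)
  sub <- net$edges[net$edges$source == driver,
                   c("target", "mi", "sign"), drop = FALSE]
  rownames(sub) <- NULL
  if (nrow(sub) == 0L)
    message("driver ", driver, " has an empty regulon")
  structure(list(driver = driver, targets = sub), class = "regulon")
}

#' @export
print.interactome <- function(x, ...) {
  cat(sprintf("Interactome: %d edges, %d drivers (%d with >=1 target)\n",
              nrow(x$edges), length(x$driver_type),
              length(unique(x$edges$source))))
  tt <- table(x$driver_type)
  cat("  driver types: ", paste(names(tt), tt, sep = "=", collapse = ", "), "\n")
  cat(sprintf("  bootstraps=%d, pc=%g\n", x$params$n_bootstraps,
              x$params$consensus_p_cutoff))
  invisible(x)
}

#' @export
print.regulon <- function(x, ...) {
  cat(sprintf("Regulon of %s: %d targets (%d positive, %d negative)\n",
              x$driver, nrow(x$targets), sum(x$targets$sign > 0),
              sum(x$targets$sign < 0)))
  invisible(x)
}

#' Write an interactome to TSV (one file per driver class)
#'
#' Column order is fixed: `source target mi spearman_rho sign support
#' consensus_p`. Drivers typed "TF;SIG" are written to both files.
#'
#' @param net an `interactome`.
#' @param dir output directory (created if needed).
#' @return named character vector of written file paths, invisibly.
#' @export
write_network <- function(net, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  for (cls in c("TF", "SIG")) {
    ds <- names(net$driver_type)[grepl(cls, net$driver_type, fixed = TRUE)]
    if (!length(ds)) next
    sub <- net$edges[net$edges$source %in% ds, , drop = FALSE]
    path <- file.path(dir, paste0(tolower(cls), "_network.tsv"))
    utils::write.table(sub, path, sep = "\t", quote = FALSE, row.names = FALSE)
    written[cls] <- path
  }
  invisible(written)
}

#' Read interactome edge files written by [write_network()]
#'
#' @param paths named character vector (names "TF"/"SIG") or plain paths.
#' @return an `interactome` (params not recoverable from TSV; stored as NA).
#' @export
read_network <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- toupper(sub("_network\\.tsv$", "", basename(paths)))
  pieces <- lapply(names(paths), function(cls) {
    ed <- utils::read.delim(paths[[cls]], stringsAsFactors = FALSE)
    ed$.cls <- cls
    ed
  })
  all_ed <- do.call(rbind, pieces)
  dtype <- tapply(all_ed$.cls, all_ed$source,
                  function(v) paste(sort(unique(v)), collapse = ";"))
  dtype <- vapply(dtype, function(v) if (v == "SIG;TF") "TF;SIG" else v,
                  character(1))
  key <- paste0(all_ed$source, "\r", all_ed$target)
  edges <- all_ed[!duplicated(key),
                  c("source", "target", "mi", "spearman_rho", "sign",
                    "support", "consensus_p"), drop = FALSE]
  edges <- edges[order(edges$source, edges$target), , drop = FALSE]
  rownames(edges) <- NULL
  structure(list(edges = edges, driver_type = dtype, params = NULL),
            class = "interactome")
}
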
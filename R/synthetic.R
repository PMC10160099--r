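#' Generate a planted driver -> target regulatory network
#'
#' Builds a bipartite driver -> target network with heavy-tailed regulon
#' sizes: each of `n_drivers * targets_per_driver` edges is assigned to a
#' driver preferentially (probability proportional to current regulon size
#' + 1), every driver is then topped up to `min_regulon` targets, and each
#' target belongs to exactly one driver so planted truth is unambiguous.
#' Edge weights (the MI proxies) are log-normal; signs are negative with
#' probability `frac_negative_edges`. The first `n_hidden` drivers are
#' flagged hidden: in group-comparison data their own-gene expression stays
#' flat while their targets move. Hidden drivers are modeled as master-
#' regulator hubs — their regulons are topped up to `min_hidden_regulon`
#' targets so they stay observable in low-coverage proteomic modalities —
#' and the first hidden driver gets an exactly sign-balanced regulon (half
#' positive, half negative targets), the configuration that defeats
#' unsigned activity averaging.
#'
#' @param n_drivers number of drivers.
#' @param targets_per_driver mean regulon size.
#' @param frac_negative_edges probability an edge is repressive, in
#'   \[0, 1\].
#' @param n_hidden number of planted hidden drivers (0 to `n_drivers`).
#' @param seed integer seed.
#' @param min_regulon regulon-size floor for every driver. Default 5.
#' @param min_hidden_regulon regulon-size floor for hidden drivers.
#'   Default 30.
#' @param weight_meanlog,weight_sdlog log-normal parameters of the edge
#'   weights. Defaults 0 and 0.4; `weight_sdlog = 0` gives unit weights.
#' @return object of class `synthetic_truth`: list with `edges`
#'   (data.frame `driver`, `target`, `weight`, `sign`), `drivers`,
#'   `targets`, `genes`, `hidden` (named logical), `balanced_driver`
#'   (ID or NA), `params`.
#' @export
generate_truth <- function(n_drivers, targets_per_driver,
                           frac_negative_edges = 0.3, n_hidden = 0L,
                           seed = 1L, min_regulon = 5L,
                           min_hidden_regulon = 30L,
                           weight_meanlog = 0, weight_sdlog = 0.4) {
  stopifnot(n_drivers >= 1, targets_per_driver >= 1,
            frac_negative_edges >= 0, frac_negative_edges <= 1,
            n_hidden >= 0, n_hidden <= n_drivers)
  drivers <- sprintf("D%03d", seq_len(n_drivers))
  hidden <- stats::setNames(seq_len(n_drivers) <= n_hidden, drivers)
  with_local_seed(seed, {
    n_edges <- n_drivers * targets_per_driver
    size <- stats::setNames(integer(n_drivers), drivers)
    for (e in seq_len(n_edges)) {
      d <- sample.int(n_drivers, 1L, prob = size + 1)
      size[d] <- size[d] + 1L
    }
    floor_sz <- ifelse(hidden, max(min_regulon, min_hidden_regulon), min_regulon)
    size <- pmax(size, floor_sz)
    total <- sum(size)
    targets <- sprintf("T%04d", seq_len(total))
    edge_driver <- rep(drivers, times = size)
    w <- stats::rlnorm(total, weight_meanlog, weight_sdlog)
    sgn <- ifelse(stats::runif(total) < frac_negative_edges, -1L, 1L)
    balanced <- NA_character_
    if (n_hidden >= 1L) {
      balanced <- drivers[1L]
      idx <- which(edge_driver == balanced)
      sgn[idx] <- rep_len(c(1L, -1L), length(idx))
    }
    edges <- data.frame(driver = edge_driver, target = targets,
                        weight = w, sign = sgn, stringsAsFactors = FALSE)
    structure(list(
      edges = edges, drivers = drivers, targets = targets,
      genes = c(drivers, targets), hidden = hidden,
      balanced_driver = balanced,
      params = list(n_drivers = n_drivers,
                    targets_per_driver = targets_per_driver,
                    frac_negative_edges = frac_negative_edges,
                    n_hidden = n_hidden, seed = seed,
                    min_regulon = min_regulon,
                    min_hidden_regulon = min_hidden_regulon,
                    weight_meanlog = weight_meanlog,
                    weight_sdlog = weight_sdlog)),
      class = "synthetic_truth")
  })
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("Synthetic truth: %d drivers (%d hidden), %d targets, %d edges\n",
              length(x$drivers), sum(x$hidden), length(x$targets),
              nrow(x$edges)))
  invisible(x)
}

#' Describe one simulated omics modality
#'
#' @param modality `"mRNA"`, `"wProtein"` or `"pProtein"`.
#' @param n_per_group integer vector `c(n0, n1)` for a two-group design, or
#'   `NULL` with `n_samples` for an unstructured cohort.
#' @param n_samples total samples when `n_per_group` is `NULL`.
#' @param coverage fraction of non-driver genes retained (proteomic
#'   modalities measure only part of the genome). Drivers are subsampled at
#'   the same rate.
#' @param noise_sd target-level residual noise sd.
#' @param driver_noise_sd noise sd on a non-hidden (or coupled) driver's own
#'   expression around its activity. Default = `noise_sd`.
#' @param decouple_hidden when `TRUE` (default) hidden drivers' own-gene
#'   expression is standard normal, independent of their latent activity —
#'   the hidden-driver phenomenon. Set `FALSE` for the network-construction
#'   cohort, where reverse-engineering a driver's regulon requires its own
#'   expression to track its activity.
#' @return a named list.
#' @export
modality_spec <- function(modality = "mRNA", n_per_group = NULL,
                          n_samples = NULL, coverage = 1, noise_sd = 1,
                          driver_noise_sd = noise_sd,
                          decouple_hidden = TRUE) {
  stopifnot(xor(is.null(n_per_group), is.null(n_samples)),
            coverage > 0, coverage <= 1, noise_sd >= 0)
  list(modality = modality, n_per_group = n_per_group,
       n_samples = n_samples, coverage = coverage, noise_sd = noise_sd,
       driver_noise_sd = driver_noise_sd, decouple_hidden = decouple_hidden)
}

#' Simulate an expression matrix from a planted truth
#'
#' Linear-Gaussian generative model. Latent activity of driver d in sample
#' s is `a_ds ~ Normal(shift_d * 1[s in group 1], 1)`. A target with edge
#' (driver d, weight w, sign s) has expression `s * w * a_ds +
#' Normal(0, noise_sd)`. A driver's own expression is `a_ds +
#' Normal(0, driver_noise_sd)` unless it is hidden and the spec decouples
#' hidden drivers, in which case it is independent standard normal (flat
#' across groups). Under this model the MI between a driver's activity and
#' a target has the closed form -0.5 * log(1 - rho^2) with
#' rho = w / sqrt(w^2 + noise_sd^2).
#'
#' @param truth a `synthetic_truth`.
#' @param spec a [modality_spec()].
#' @param group_effect per-driver activity shift: single number applied to
#'   all hidden drivers, or a named vector over drivers. Ignored for
#'   unstructured cohorts.
#' @param seed integer seed.
#' @return genes x samples matrix with attributes `groups` (named vector,
#'   or NULL), `latent_activity` (drivers x samples), `modality`.
#' @export
simulate_expression <- function(truth, spec, group_effect = 0, seed = 1L) {
  nd <- length(truth$drivers)
  shifts <- stats::setNames(numeric(nd), truth$drivers)
  if (length(group_effect) == 1L && is.null(names(group_effect))) {
    shifts[truth$hidden] <- group_effect
  } else {
    shifts[names(group_effect)] <- group_effect
  }
  stopifnot(all(is.finite(shifts)))
  two_group <- !is.null(spec$n_per_group)
  n <- if (two_group) sum(spec$n_per_group) else spec$n_samples
  with_local_seed(seed, {
    if (two_group) {
      groups <- rep(c("G0", "G1"), times = spec$n_per_group)
      sample_ids <- sprintf("%s_S%03d", spec$modality, seq_len(n))
      shift_mat <- outer(shifts, as.numeric(groups == "G1"))
    } else {
      groups <- NULL
      sample_ids <- sprintf("%s_S%03d", spec$modality, seq_len(n))
      shift_mat <- matrix(0, nd, n)
    }
    act <- shift_mat + matrix(stats::rnorm(nd * n), nd, n)
    dimnames(act) <- list(truth$drivers, sample_ids)
    ed <- truth$edges
    tgt <- ed$sign * ed$weight * act[ed$driver, , drop = FALSE] +
      matrix(stats::rnorm(nrow(ed) * n, sd = spec$noise_sd), nrow(ed), n)
    rownames(tgt) <- ed$target
    own <- act + matrix(stats::rnorm(nd * n, sd = spec$driver_noise_sd), nd, n)
    if (spec$decouple_hidden && any(truth$hidden)) {
      hn <- sum(truth$hidden)
      own[truth$hidden, ] <- matrix(stats::rnorm(hn * n), hn, n)
    }
    m <- rbind(own, tgt)
    if (spec$coverage < 1) {
      keep <- sort(sample.int(nrow(m), max(2L, round(spec$coverage * nrow(m)))))
      m <- m[keep, , drop = FALSE]
    }
    colnames(m) <- sample_ids
    structure(m,
              groups = if (two_group) stats::setNames(groups, sample_ids) else NULL,
              latent_activity = act, modality = spec$modality)
  })
}

#' Interactome view of a planted truth
#'
#' Maps the planted network onto the `interactome` container (|weight| as
#' the MI column, planted sign as direction) so activity inference can run
#' against ground truth directly.
#'
#' @param truth a `synthetic_truth`.
#' @return an `interactome`; odd-indexed drivers are labeled TF,
#'   even-indexed SIG (deterministic).
#' @export
truth_network <- function(truth) {
  nd <- length(truth$drivers)
  dtype <- stats::setNames(ifelse(seq_len(nd) %% 2 == 1, "TF", "SIG"),
                           truth$drivers)
  edges <- data.frame(source = truth$edges$driver,
                      target = truth$edges$target,
                      mi = abs(truth$edges$weight),
                      spearman_rho = truth$edges$sign *
                        (truth$edges$weight /
                           sqrt(truth$edges$weight^2 + 1)),
                      sign = as.integer(truth$edges$sign),
                      support = NA_integer_,
                      consensus_p = NA_real_,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$source, edges$target), ]
  rownames(edges) <- NULL
  structure(list(edges = edges, driver_type = dtype, params = NULL),
            class = "interactome")
}

#' Write a complete synthetic benchmark bundle
#'
#' Emulates the shape of a real hidden-driver study: a 200-sample
#' unstructured cohort for network construction, and three two-group
#' driver-inference modalities sized like a small stimulation experiment —
#' mRNA n = 4 + 4 at full gene coverage, whole proteome n = 2 + 2 at 70%
#' coverage, phosphoproteome n = 2 + 2 at 30% coverage. 160 drivers with 8
#' planted hidden drivers (activity shift `shift` between groups, flat
#' own-gene expression), one of them with a sign-balanced regulon. Writes
#' TSV matrices, group annotations, TF/SIG driver lists, a small GMT (the
#' largest regulons plus random sets), and the truth as JSON.
#'
#' @param seed integer seed; every random choice in the bundle derives
#'   from it.
#' @param dir output directory (created).
#' @param n_drivers,targets_per_driver,n_hidden,shift bundle shape
#'   parameters; the defaults are the benchmark conditions.
#' @return invisibly, a list with `truth`, file `paths`, and the per-
#'   modality specs.
#' @export
make_benchmark_suite <- function(seed = 1L, dir = tempfile("bench"),
                                 n_drivers = 160L, targets_per_driver = 6L,
                                 n_hidden = 8L, shift = 4) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  truth <- generate_truth(n_drivers, targets_per_driver,
                          frac_negative_edges = 0.3, n_hidden = n_hidden,
                          seed = seed)
  specs <- list(
    construction = modality_spec("mRNA", n_samples = 200, coverage = 1,
                                 noise_sd = 1, driver_noise_sd = 0.25,
                                 decouple_hidden = FALSE),
    mRNA = modality_spec("mRNA", n_per_group = c(4L, 4L), coverage = 1,
                         noise_sd = 1),
    wProtein = modality_spec("wProtein", n_per_group = c(2L, 2L),
                             coverage = 0.7, noise_sd = 1),
    pProtein = modality_spec("pProtein", n_per_group = c(2L, 2L),
                             coverage = 0.3, noise_sd = 1))
  mats <- list(
    construction = simulate_expression(truth, specs$construction,
                                       group_effect = 0, seed = seed + 101L),
    mRNA = simulate_expression(truth, specs$mRNA, group_effect = shift,
                               seed = seed + 102L),
    wProtein = simulate_expression(truth, specs$wProtein,
                                   group_effect = shift, seed = seed + 103L),
    pProtein = simulate_expression(truth, specs$pProtein,
                                   group_effect = shift, seed = seed + 104L))
  paths <- list()
  for (nm in names(mats)) {
    paths[[nm]] <- file.path(dir, paste0(nm, ".tsv"))
    write_expression(mats[[nm]], paths[[nm]])
    gr <- attr(mats[[nm]], "groups")
    if (!is.null(gr)) {
      gp <- file.path(dir, paste0(nm, "_groups.tsv"))
      utils::write.table(
        data.frame(sample_id = names(gr), group = gr),
        gp, sep = "\t", quote = FALSE, row.names = FALSE)
      paths[[paste0(nm, "_groups")]] <- gp
    }
  }
  nd <- length(truth$drivers)
  tf <- truth$drivers[seq_len(nd) %% 2 == 1]
  sig <- truth$drivers[seq_len(nd) %% 2 == 0]
  paths$tf <- file.path(dir, "tf_drivers.txt")
  paths$sig <- file.path(dir, "sig_drivers.txt")
  writeLines(tf, paths$tf)
  writeLines(sig, paths$sig)
  reg_sizes <- sort(table(truth$edges$driver), decreasing = TRUE)
  big <- names(reg_sizes)[seq_len(min(3L, length(reg_sizes)))]
  sets <- lapply(big, function(d) truth$edges$target[truth$edges$driver == d])
  names(sets) <- paste0("REGULON_", big)
  rnd <- with_local_seed(seed + 105L, {
    lapply(1:2, function(i) sample(truth$genes, 25L))
  })
  names(rnd) <- paste0("RANDOM_SET_", 1:2)
  paths$gmt <- file.path(dir, "gene_sets.gmt")
  write_gmt(c(sets, rnd), paths$gmt)
  paths$truth <- file.path(dir, "truth.json")
  jsonlite::write_json(list(
    edges = truth$edges,
    hidden = as.list(truth$hidden),
    balanced_driver = truth$balanced_driver,
    shift = shift,
    params = truth$params), paths$truth, auto_unbox = TRUE, digits = NA)
  invisible(list(truth = truth, paths = paths, specs = specs,
                 matrices = mats, shift = shift, dir = dir))
}
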
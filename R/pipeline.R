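#' Read and validate a pipeline configuration
#'
#' YAML with the blocks `seed`, `network` (expression, tf_list, sig_list,
#' and optional n_bootstraps / consensus_p_cutoff / per_bootstrap_mi_p /
#' dpi_tolerance), `modalities` (named blocks with `expression` and
#' `groups` paths), and optional `activity` (method/std/min_targets),
#' `differential` (method: ebayes | bid-bayes | bid-mle), `integration`
#' (weights: equal | sqrt_n), `enrichment` (gmt, top_n). Defaults are
#' filled in; file paths are checked before any computation.
#'
#' @param path YAML file, or a list with the same structure.
#' @return validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  need <- function(x, what) if (is.null(x)) stop("config missing ", what) else x
  need(cfg$network, "network block")
  need(cfg$network$expression, "network$expression path")
  need(cfg$network$tf_list, "network$tf_list path")
  need(cfg$modalities, "modalities block")
  defaults <- list(n_bootstraps = 100L, consensus_p_cutoff = 1e-5,
                   per_bootstrap_mi_p = 1e-7, dpi_tolerance = 0,
                   n_permutations = 20000L)
  for (nm in names(defaults))
    if (is.null(cfg$network[[nm]])) cfg$network[[nm]] <- defaults[[nm]]
  if (is.null(cfg$activity)) cfg$activity <- list()
  if (is.null(cfg$activity$method)) cfg$activity$method <- "weighted_mean"
  if (is.null(cfg$activity$std)) cfg$activity$std <- TRUE
  if (is.null(cfg$activity$min_targets)) cfg$activity$min_targets <- 5L
  if (is.null(cfg$differential)) cfg$differential <- list(method = "ebayes")
  if (!cfg$differential$method %in% c("ebayes", "bid-bayes", "bid-mle"))
    stop("unknown differential method: ", cfg$differential$method)
  if (is.null(cfg$integration)) cfg$integration <- list(weights = "equal")
  files <- c(cfg$network$expression, cfg$network$tf_list, cfg$network$sig_list,
             unlist(lapply(cfg$modalities, function(mo) c(mo$expression, mo$groups))),
             cfg$enrichment$gmt)
  missing <- files[!file.exists(files)]
  if (length(missing))
    stop("config validation: input file(s) not found: ",
         paste(missing, collapse = ", "))
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

.diff_fun <- function(method) {
  switch(method,
         "ebayes" = function(m, g) de_two_group(m, g, moderated = TRUE),
         "bid-bayes" = function(m, g) bid_two_group(m, g, "Bayesian"),
         "bid-mle" = function(m, g) bid_two_group(m, g, "MLE"))
}

#' Run the full hidden-driver workflow
#'
#' QC of inputs -> TF/SIG network reconstruction -> network QC -> per-
#' modality activity inference -> differential activity and expression ->
#' cross-modality integration into the master table -> functional
#' enrichment of the top drivers. All intermediates are written under
#' `output_dir` together with a manifest (parameters, seed, input
#' checksums); an identical manifest implies byte-identical outputs.
#'
#' @param config a [read_pipeline_config()] result, a path to YAML, or an
#'   equivalent list.
#' @param output_dir output directory (created).
#' @param quiet suppress stage logging. Default `FALSE`.
#' @return invisibly, a list with `network`, `network_qc`, `activity`,
#'   `da`, `de`, `master`, `enrichment`, and the written paths.
#' @export
run_pipeline <- function(config, output_dir, quiet = FALSE) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else read_pipeline_config(config)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file.path(output_dir, "run.log")
  cat("", file = logf)
  say <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(msg, "\n", file = logf, append = TRUE)
    if (!quiet) message(msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  say("stage qc: loading inputs")
  net_expr <- stage("qc", load_expression(cfg$network$expression))
  net_expr <- filter_genes(net_expr, min_sd = 1e-8)
  qc_in <- qc_summary(net_expr)
  write_qc_summary(qc_in, file.path(output_dir, "expression_qc.json"))
  tf <- readLines(cfg$network$tf_list)
  sig <- if (!is.null(cfg$network$sig_list)) readLines(cfg$network$sig_list)
         else character(0)

  say("stage network: %d bootstraps over %d genes x %d samples",
      cfg$network$n_bootstraps, nrow(net_expr), ncol(net_expr))
  params <- network_params(
    n_bootstraps = cfg$network$n_bootstraps,
    consensus_p_cutoff = cfg$network$consensus_p_cutoff,
    per_bootstrap_mi_p = cfg$network$per_bootstrap_mi_p,
    dpi_tolerance = cfg$network$dpi_tolerance,
    n_permutations = cfg$network$n_permutations,
    seed = cfg$seed)
  net <- stage("network", reconstruct_network(net_expr, tf, sig, params))
  write_network(net, file.path(output_dir, "network"))
  say("stage network: %d consensus edges", nrow(net$edges))

  say("stage netqc")
  nqc <- stage("netqc", qc_report(net))
  write_qc_report(nqc, file.path(output_dir, "network_qc.json"),
                  file.path(output_dir, "driver_target_sizes.tsv"))

  dfun <- .diff_fun(cfg$differential$method)
  act <- list(); da <- list(); de <- list(); ns <- integer(0)
  for (mm in names(cfg$modalities)) {
    say("stage activity/da/de: modality %s", mm)
    mo <- cfg$modalities[[mm]]
    m <- stage("activity", load_expression(mo$expression))
    m <- filter_genes(m, min_sd = 1e-8)
    groups <- read_groups(mo$groups)
    a <- stage("activity", cal_activity(
      m, net, method = cfg$activity$method, std = cfg$activity$std,
      min_targets = cfg$activity$min_targets))
    write_expression(a, file.path(output_dir, paste0("activity_", mm, ".tsv")))
    da[[mm]] <- stage("da", dfun(a, groups))
    de[[mm]] <- stage("de", dfun(if (cfg$activity$std) z_transform(m) else m,
                                 groups))
    write_differential(da[[mm]], file.path(output_dir, paste0("da_", mm, ".tsv")))
    write_differential(de[[mm]], file.path(output_dir, paste0("de_", mm, ".tsv")))
    act[[mm]] <- a
    ns[mm] <- ncol(m)
  }

  say("stage integrate: %d modalities", length(da))
  weights <- if (identical(cfg$integration$weights, "sqrt_n")) sqrt(ns) else NULL
  master <- stage("integrate", build_master_table(da, de, net, weights))
  write_master_table(master, file.path(output_dir, "master_table.tsv"),
                     file.path(output_dir, "master_table.json"))

  enr <- NULL
  if (!is.null(cfg$enrichment$gmt)) {
    top_n <- if (is.null(cfg$enrichment$top_n)) 20L else cfg$enrichment$top_n
    say("stage enrich: top %d drivers", top_n)
    gsc <- read_gmt(cfg$enrichment$gmt)
    top <- utils::head(master$driver, top_n)
    top_targets <- unique(net$edges$target[net$edges$source %in% top])
    enr <- stage("enrich", fisher_enrich(unique(c(top, top_targets)), gsc,
                                         universe = rownames(net_expr)))
    utils::write.table(enr, file.path(output_dir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  manifest <- list(
    seed = cfg$seed,
    network_params = params[setdiff(names(params), "")],
    activity = cfg$activity,
    differential = cfg$differential,
    integration = cfg$integration,
    inputs = as.list(tools::md5sum(c(
      cfg$network$expression, cfg$network$tf_list,
      unlist(lapply(cfg$modalities, function(mo) c(mo$expression, mo$groups)))))),
    n_consensus_edges = nrow(net$edges),
    n_drivers_ranked = nrow(master))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  say("done: master table with %d drivers", nrow(master))
  invisible(list(network = net, network_qc = nqc, activity = act,
                 da = da, de = de, master = master, enrichment = enr,
                 output_dir = output_dir))
}
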
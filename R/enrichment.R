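#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line — name, description, then tab-separated
#' member gene IDs.
#'
#' @param path GMT file path.
#' @return object of class `gene_set_collection`: list with `sets` (named
#'   list of character vectors) and `descriptions` (named character).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3L
  if (any(bad)) stop("malformed GMT line(s): ", paste(which(bad), collapse = ", "))
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, character(1), 1L)
  desc <- stats::setNames(vapply(parts, `[[`, character(1), 2L), names(sets))
  structure(list(sets = sets, descriptions = desc),
            class = "gene_set_collection")
}

#' Write a gene-set collection as GMT
#'
#' @param gsc a `gene_set_collection` (or plain named list of character
#'   vectors).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(gsc, path) {
  sets <- if (inherits(gsc, "gene_set_collection")) gsc$sets else gsc
  desc <- if (inherits(gsc, "gene_set_collection")) gsc$descriptions else
    stats::setNames(rep("na", length(sets)), names(sets))
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, desc[[nm]], sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Fisher's exact overlap enrichment against a gene-set collection
#'
#' One-sided (enrichment) hypergeometric test per set from the 2x2 overlap
#' table of query vs set within an explicit universe, with BH adjustment
#' across sets. The universe should be the genes actually measured (e.g.,
#' the rows of the supplying expression matrix), not the whole genome —
#' unmeasured genes inflate enrichment.
#'
#' @param query character vector of gene IDs (intersected with the
#'   universe; empty intersection is an error).
#' @param gsc a `gene_set_collection`.
#' @param universe character vector of background gene IDs.
#' @return data.frame: `set`, `set_size`, `overlap`, `odds_ratio`, `p`,
#'   `adj_p`, `overlap_genes` (comma-joined), sorted by p.
#' @export
fisher_enrich <- function(query, gsc, universe) {
  universe <- unique(universe)
  query <- intersect(unique(query), universe)
  if (!length(query)) stop("query is empty after intersection with universe")
  N <- length(universe)
  nq <- length(query)
  rows <- lapply(names(gsc$sets), function(nm) {
    s <- intersect(gsc$sets[[nm]], universe)
    ov <- intersect(query, s)
    k <- length(ov); K <- length(s)
    # P(X >= k), X ~ Hypergeom(N, K, nq)
    p <- stats::phyper(k - 1, K, N - K, nq, lower.tail = FALSE)
    orr <- (k * (N - K - nq + k)) / max((K - k) * (nq - k), .Machine$double.eps)
    data.frame(set = nm, set_size = K, overlap = k, odds_ratio = orr,
               p = min(p, 1), overlap_genes = paste(sort(ov), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$set),
             c("set", "set_size", "overlap", "odds_ratio", "p", "adj_p",
               "overlap_genes")]
  rownames(out) <- NULL
  out
}

#' GSEA-style enrichment score of a gene set in a ranked list
#'
#' Walk down the ranking: at a set member ("hit") the running sum rises by
#' |score|^exponent / sum over hits of |score|^exponent; at a non-member it
#' falls by 1 / (N - |set|). The enrichment score is the signed extreme
#' deviation of the running sum. With exponent 0 the running sum ends at 0
#' exactly.
#'
#' @param ranked character vector of feature IDs, ordered by a signed score
#'   (most positive first).
#' @param weights score magnitudes aligned with `ranked` (absolute values
#'   are used).
#' @param set character vector of member IDs; the intersection with
#'   `ranked` must be non-empty and must not cover all of `ranked`.
#' @param exponent weighting exponent (default 1; 0 = classic Kolmogorov-
#'   Smirnov form).
#' @return list with `es` and `running` (the running-sum vector).
#' @export
gsea_es <- function(ranked, weights, set, exponent = 1) {
  stopifnot(length(ranked) == length(weights))
  hit <- ranked %in% set
  n_hit <- sum(hit)
  if (n_hit == 0L) stop("gene set does not intersect the ranked list")
  if (n_hit == length(ranked))
    stop("gene set covers the whole ranked list: ES undefined (no misses)")
  w <- abs(weights)^exponent
  inc <- numeric(length(ranked))
  inc[hit] <- w[hit] / sum(w[hit])
  inc[!hit] <- -1 / (length(ranked) - n_hit)
  running <- cumsum(inc)
  es <- running[which.max(abs(running))]
  list(es = es, running = running)
}

#' GSEA enrichment with a gene-label permutation p-value
#'
#' The null keeps the ranking and weights fixed and redraws which positions
#' are set members (gene-label permutation); two-sided
#' p = (1 + #\{|ES_perm| >= |ES|\}) / (1 + n_perm). Gene-label (rather than
#' phenotype) permutation is used because the group sizes in driver
#' inference are often far too small to permute.
#'
#' @param ranked,weights,set,exponent as in [gsea_es()].
#' @param n_perm number of permutations (>= 100). Default 1000.
#' @param seed RNG seed.
#' @return list with `es`, `p`, `n_perm`.
#' @export
gsea_permutation_p <- function(ranked, weights, set, exponent = 1,
                               n_perm = 1000L, seed = 1L) {
  stopifnot(n_perm >= 100L)
  obs <- gsea_es(ranked, weights, set, exponent)$es
  n_hit <- sum(ranked %in% set)
  null_es <- with_local_seed(seed, vapply(seq_len(n_perm), function(i) {
    fake <- sample(ranked, n_hit)
    gsea_es(ranked, weights, fake, exponent)$es
  }, numeric(1)))
  p <- (1 + sum(abs(null_es) >= abs(obs))) / (1 + n_perm)
  list(es = obs, p = p, n_perm = n_perm)
}

#' GSEA enrichment of several sets with BH adjustment
#'
#' @param ranked,weights,exponent,n_perm,seed as in
#'   [gsea_permutation_p()].
#' @param gsc a `gene_set_collection`.
#' @return data.frame: `set`, `es`, `p`, `adj_p`, sorted by p.
#' @export
gsea_enrich <- function(ranked, weights, gsc, exponent = 1,
                        n_perm = 1000L, seed = 1L) {
  rows <- lapply(names(gsc$sets), function(nm) {
    r <- gsea_permutation_p(ranked, weights, gsc$sets[[nm]], exponent,
                            n_perm, seed)
    data.frame(set = nm, es = r$es, p = r$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- bh_adjust(out$p)
  out <- out[order(out$p, out$set), ]
  rownames(out) <- NULL
  out
}
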
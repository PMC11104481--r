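#' Genomic filtering configuration
#'
#' Thresholds for the sample- and locus-level quality filters: coverage
#' outlier removal (individuals more than `coverage_sd_threshold` SDs below
#' the mean `depth_fraction`), identity-by-state relative/replicate pruning
#' (single-linkage clusters below `ibs_prune_threshold` keep one
#' representative), locus presence and minor-allele-count filters, and the
#' admixture-coefficient membership threshold.
#'
#' @param ibs_prune_threshold IBS distance below which individuals are
#'   clustered for pruning (default 0.15).
#' @param coverage_sd_threshold SDs below the mean that trigger discarding.
#' @param depth_fraction_min_depth Read depth defining `depth_fraction`
#'   (metadata; default 5 reads).
#' @param locus_presence_min Minimum fraction of individuals with a called
#'   genotype for a locus to be kept.
#' @param minor_allele_count_min Minimum minor allele count.
#' @param admixture_assign_threshold Minimum admixture coefficient for cluster
#'   membership (default 0.25).
#' @return A list of class `filter_config`.
#' @export
filter_config <- function(ibs_prune_threshold = 0.15,
                          coverage_sd_threshold = 3,
                          depth_fraction_min_depth = 5,
                          locus_presence_min = 0.5,
                          minor_allele_count_min = 5,
                          admixture_assign_threshold = 0.25) {
  stopifnot(ibs_prune_threshold >= 0, ibs_prune_threshold <= 1,
            coverage_sd_threshold > 0,
            locus_presence_min >= 0, locus_presence_min <= 1,
            minor_allele_count_min >= 0,
            admixture_assign_threshold > 0, admixture_assign_threshold <= 1)
  structure(as.list(environment()), class = "filter_config")
}

#' Coverage outlier filter
#'
#' Discards individuals whose coverage (fraction of loci with sequencing
#' depth at or above the reference depth) lies more than
#' `coverage_sd_threshold` population SDs below the mean. A single pass: the
#' mean, SD and cutoff are computed once from all individuals, so removing a
#' non-outlier never changes another individual's fate.
#'
#' @param x A `genotype_dataset`, or a data frame with columns `id` and
#'   `depth_fraction`.
#' @param config A [filter_config()].
#' @return A tibble `id`, `depth_fraction`, `kept`, with the numeric cutoff in
#'   `attr(, "cutoff")`.
#' @export
coverage_filter <- function(x, config = filter_config()) {
  df <- if (inherits(x, "genotype_dataset")) x$indiv else tibble::as_tibble(x)
  stopifnot(all(c("id", "depth_fraction") %in% names(df)),
            nrow(df) >= 2)
  v <- df$depth_fraction
  mu <- mean(v)
  sdv <- sqrt(mean((v - mu)^2)) # population SD over all individuals
  cutoff <- mu - config$coverage_sd_threshold * sdv
  out <- tibble::tibble(id = df$id, depth_fraction = v,
                        kept = !(v < cutoff))
  attr(out, "cutoff") <- cutoff
  out
}

#' Pairwise identity-by-state distance matrix
#'
#' Expected mode (default): for a pair of individuals the distance is the
#' mean, over loci called in both, of `p1 (1 - p2) + p2 (1 - p1)` with
#' `p = dosage / 2` — the probability that one allele sampled from each
#' individual mismatches. Sampled mode draws one allele per individual per
#' locus (seeded) and reports the realized mismatch fraction, emulating
#' single-read IBS sampling; its expectation is the expected mode. Missing
#' genotypes are excluded pairwise.
#'
#' @param x A `genotype_dataset` or a dosage matrix (individuals x loci,
#'   values 0/1/2, `NA` missing).
#' @param mode `"expected"` or `"sampled"`.
#' @param seed Seed for sampled mode.
#' @return A symmetric matrix of distances in `[0, 1]` with zero diagonal.
#' @export
ibs_distance <- function(x, mode = c("expected", "sampled"), seed = 1) {
  mode <- match.arg(mode)
  dos <- if (inherits(x, "genotype_dataset")) x$dosages else as.matrix(x)
  n <- nrow(dos)
  if (n < 2) stop_lc("need at least 2 individuals")
  M <- !is.na(dos)
  called <- M %*% t(M)
  if (any(called[upper.tri(called)] == 0)) {
    bad <- which(called == 0 & upper.tri(called), arr.ind = TRUE)[1, ]
    stop_lc("no co-called loci for pair (", rownames(dos)[bad[1]], ", ",
            rownames(dos)[bad[2]], ")")
  }
  if (mode == "expected") {
    P <- dos / 2
  } else {
    P <- with_seed(seed, matrix(rbinom(length(dos), 1,
                                       ifelse(is.na(dos), 0.5, dos / 2)),
                                n, ncol(dos)))
    P[!M] <- NA
  }
  P0 <- P; P0[!M] <- 0
  Q0 <- 1 - P; Q0[!M] <- 0
  D <- (P0 %*% t(Q0) + Q0 %*% t(P0)) / called
  diag(D) <- 0
  dimnames(D) <- list(rownames(dos), rownames(dos))
  D
}

#' Prune technical replicates and close relatives by IBS distance
#'
#' Single-linkage clustering of the IBS distance matrix cut strictly below the
#' pruning threshold (equivalently: connected components of the graph joining
#' pairs with distance < threshold). In each multi-member cluster the
#' individual with the highest coverage metric is kept (ties broken by
#' lexicographically smallest id); all others are pruned.
#'
#' @param ibs An [ibs_distance()] matrix.
#' @param coverage Named numeric vector (or tibble `id`, `depth_fraction`) of
#'   the coverage ranking metric.
#' @param threshold Pruning threshold (default 0.15).
#' @return A tibble `id`, `cluster`, `kept`, ordered as the input matrix.
#' @export
prune_relatives <- function(ibs, coverage, threshold = 0.15) {
  ids <- rownames(ibs) %||% as.character(seq_len(nrow(ibs)))
  if (is.data.frame(coverage))
    coverage <- setNames(coverage$depth_fraction, coverage$id)
  cov <- coverage[ids]
  n <- nrow(ibs)
  # Union-find over pairs below threshold = single-linkage components at the
  # strict cut.
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  pairs <- which(ibs < threshold & upper.tri(ibs), arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    a <- find(pairs[r, 1]); b <- find(pairs[r, 2])
    if (a != b) parent[max(a, b)] <- min(a, b)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  comp <- match(comp, unique(comp))
  kept <- logical(n)
  for (cl in unique(comp)) {
    members <- which(comp == cl)
    if (length(members) == 1) {
      kept[members] <- TRUE
    } else {
      o <- members[order(-cov[members], ids[members])]
      kept[o[1]] <- TRUE
    }
  }
  tibble::tibble(id = ids, cluster = comp, kept = kept)
}

#' Locus presence and minor-allele-count filters
#'
#' Keeps a locus iff it is called in at least `locus_presence_min` of the
#' individuals and its minor allele count (over called individuals) is at
#' least `minor_allele_count_min`. Monomorphic loci are dropped. The filter is
#' idempotent: re-applying it to the kept loci changes nothing.
#'
#' @param x A `genotype_dataset` or dosage matrix.
#' @param config A [filter_config()].
#' @return A tibble `locus`, `called_fraction`, `mac`, `kept`.
#' @export
locus_filters <- function(x, config = filter_config()) {
  dos <- if (inherits(x, "genotype_dataset")) x$dosages else as.matrix(x)
  loci <- colnames(dos) %||% as.character(seq_len(ncol(dos)))
  called <- unname(colSums(!is.na(dos)))
  alt <- unname(colSums(dos, na.rm = TRUE))
  mac <- pmin(alt, 2 * called - alt)
  called_fraction <- called / nrow(dos)
  tibble::tibble(
    locus = loci,
    called_fraction = called_fraction,
    mac = as.numeric(mac),
    kept = called_fraction >= config$locus_presence_min &
      mac >= config$minor_allele_count_min
  )
}

#' Assign individuals to admixture clusters and extract a pure-lineage subset
#'
#' An individual is a member of every cluster in which its admixture
#' coefficient is at least the assignment threshold (so between 1 and K
#' memberships). The pure-target subset keeps individuals whose summed
#' non-target coefficients are below the threshold — individuals with more
#' foreign ancestry than that are removed.
#'
#' @param admixture Individuals x K matrix (or data frame with an `id` column
#'   and K coefficient columns) of admixture proportions; rows must sum to 1.
#' @param target Target cluster (name or index) for the purity call.
#' @param threshold Assignment threshold (default 0.25).
#' @return A tibble: `id`, one logical `member_*` column per cluster,
#'   `n_clusters`, `pure_target`.
#' @export
assign_lineages <- function(admixture, target = 1, threshold = 0.25) {
  if (is.data.frame(admixture)) {
    ids <- as.character(admixture$id)
    Q <- as.matrix(admixture[setdiff(names(admixture), "id")])
  } else {
    Q <- as.matrix(admixture)
    ids <- rownames(Q) %||% as.character(seq_len(nrow(Q)))
  }
  if (any(abs(rowSums(Q) - 1) > 1e-6))
    stop_lc("admixture rows must sum to 1")
  if (is.null(colnames(Q))) colnames(Q) <- paste0("K", seq_len(ncol(Q)))
  tidx <- if (is.character(target)) match(target, colnames(Q)) else as.integer(target)
  if (is.na(tidx) || tidx < 1 || tidx > ncol(Q))
    stop_lc("unknown target cluster: ", target)
  member <- Q >= threshold
  non_target <- rowSums(Q[, -tidx, drop = FALSE])
  out <- tibble::as_tibble(member, .name_repair = "minimal")
  names(out) <- paste0("member_", colnames(Q))
  dplyr::bind_cols(tibble::tibble(id = ids), out) |>
    dplyr::mutate(n_clusters = unname(rowSums(member)),
                  pure_target = unname(non_target < threshold))
}

#' Full sample- and locus-filter pipeline report
#'
#' Applies, in order: coverage outlier removal, IBS-based replicate/relative
#' pruning (on the coverage-passing individuals), then the locus filters on
#' the surviving individuals. Returns the surviving dataset and a log of every
#' discarded individual and locus with the rule that removed it.
#'
#' @param x A `genotype_dataset`.
#' @param config A [filter_config()].
#' @param ibs_mode Passed to [ibs_distance()].
#' @return A list: `dosages` (filtered matrix), `kept_individuals`,
#'   `kept_loci`, and `log` (tibble: `item`, `type`, `rule`).
#' @export
filter_pipeline <- function(x, config = filter_config(), ibs_mode = "expected") {
  stopifnot(inherits(x, "genotype_dataset"))
  cov <- coverage_filter(x, config)
  keep1 <- cov$id[cov$kept]
  log <- tibble::tibble(item = cov$id[!cov$kept], type = "individual",
                        rule = sprintf("coverage < mean - %g SD",
                                       config$coverage_sd_threshold))
  dos <- x$dosages[keep1, , drop = FALSE]
  ibs <- ibs_distance(dos, mode = ibs_mode)
  pr <- prune_relatives(ibs, setNames(cov$depth_fraction, cov$id)[keep1],
                        threshold = config$ibs_prune_threshold)
  log <- dplyr::bind_rows(log, tibble::tibble(
    item = pr$id[!pr$kept], type = "individual",
    rule = sprintf("IBS distance < %g (replicate/relative)",
                   config$ibs_prune_threshold)))
  keep2 <- pr$id[pr$kept]
  dos <- dos[keep2, , drop = FALSE]
  lf <- locus_filters(dos, config)
  log <- dplyr::bind_rows(log, tibble::tibble(
    item = lf$locus[!lf$kept], type = "locus",
    rule = sprintf("presence < %g or MAC < %g", config$locus_presence_min,
                   config$minor_allele_count_min)))
  list(dosages = dos[, lf$kept, drop = FALSE],
       kept_individuals = keep2, kept_loci = lf$locus[lf$kept], log = log)
}
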
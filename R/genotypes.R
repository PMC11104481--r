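#' Simulate a multi-lineage genotype dataset
#'
#' Generates diploid alternate-allele dosages (0/1/2) for individuals drawn
#' from K divergent source populations under the F-model: ancestral allele
#' frequencies are Uniform(0.05, 0.95) and population frequencies are Beta
#' with mean p and variance F p (1 - p) (Balding–Nichols). Individual dosages
#' are Binomial(2, pi) with pi the ancestry-weighted frequency. The dataset
#' carries the structures the downstream filters assume: admixed individuals
#' (with their true admixture proportions recorded), technical replicate
#' pairs (identical called dosages), parent–offspring pairs (one shared
#' gamete), and per-individual coverage (`depth_fraction`, the fraction of
#' loci with sequencing depth >= 5 reads) including low-coverage outliers;
#' per-locus missingness increases as coverage drops.
#'
#' Default lineage labels mirror a north-European blue-mussel setting: a
#' locally dominant *M. edulis* lineage, a second *M. edulis* lineage, and
#' the strongly diverged *M. trossulus* and *M. galloprovincialis*.
#'
#' @param n_per_pop Integer vector: individuals per population (length K >= 2).
#' @param n_loci Number of loci (>= 100).
#' @param F_drift Per-population drift parameters (length K, in (0, 1); 0
#'   allowed and means no drift).
#' @param pop_names Population (lineage) labels.
#' @param admixed Tibble describing admixed individuals: columns `pop_a`,
#'   `pop_b`, `n`; admixture proportions are drawn Uniform(0.25, 0.75).
#'   `NULL` for none.
#' @param n_replicate_pairs Technical replicate pairs (duplicated dosages,
#'   fresh coverage/missingness).
#' @param n_relative_pairs Parent–offspring pairs (the offspring receives one
#'   gamete from the parent and one from its population).
#' @param coverage_mean,coverage_sd Beta-distributed `depth_fraction` moments
#'   for ordinary individuals.
#' @param n_low_coverage Number of low-coverage outlier individuals
#'   (`depth_fraction` ~ Uniform(0.2, 0.4)).
#' @param missing_scale Per-individual missing-call probability is
#'   `missing_scale * (1 - depth_fraction)`.
#' @param seed Integer seed; identical configuration and seed give bitwise
#'   identical datasets.
#' @return An object of class `genotype_dataset`: `dosages` (individuals x
#'   loci, `NA` = missing), `indiv` (tibble: `id`, `pop_label`,
#'   `depth_fraction`, `replicate_of`), `true_admixture` (individuals x K),
#'   and `pop_freqs` (K x loci simulated truth).
#' @export
simulate_genotypes <- function(n_per_pop = c(40, 15, 10, 10), n_loci = 2000,
                               F_drift = c(0.3, 0.3, 0.45, 0.45),
                               pop_names = c("edulis_skagerrak",
                                             "edulis_northsea",
                                             "trossulus",
                                             "galloprovincialis"),
                               admixed = tibble::tibble(pop_a = 1, pop_b = 2,
                                                        n = 8),
                               n_replicate_pairs = 6, n_relative_pairs = 3,
                               coverage_mean = 0.85, coverage_sd = 0.05,
                               n_low_coverage = 2, missing_scale = 0.3,
                               seed = 1) {
  K <- length(n_per_pop)
  if (K < 2) stop_lc("need K >= 2 populations")
  if (n_loci < 100) stop_lc("need n_loci >= 100")
  stopifnot(length(F_drift) == K, length(pop_names) == K,
            all(F_drift >= 0), all(F_drift < 1))
  if (!is.null(admixed)) {
    stopifnot(all(admixed$pop_a %in% seq_len(K)),
              all(admixed$pop_b %in% seq_len(K)), all(admixed$n >= 0))
  }

  with_seed(seed, {
    p_anc <- runif(n_loci, 0.05, 0.95)
    pop_freqs <- matrix(NA_real_, K, n_loci,
                        dimnames = list(pop_names, NULL))
    for (k in seq_len(K)) {
      if (F_drift[k] == 0) {
        pop_freqs[k, ] <- p_anc
      } else {
        shape_scale <- (1 - F_drift[k]) / F_drift[k]
        pop_freqs[k, ] <- rbeta(n_loci, p_anc * shape_scale,
                                (1 - p_anc) * shape_scale)
      }
    }

    adm_rows <- list()
    for (k in seq_len(K)) {
      if (n_per_pop[k] > 0) {
        q <- matrix(0, n_per_pop[k], K)
        q[, k] <- 1
        adm_rows[[length(adm_rows) + 1]] <-
          list(q = q, label = rep(pop_names[k], n_per_pop[k]))
      }
    }
    if (!is.null(admixed)) {
      for (r in seq_len(nrow(admixed))) {
        n_r <- admixed$n[r]
        if (n_r > 0) {
          alpha <- runif(n_r, 0.25, 0.75)
          q <- matrix(0, n_r, K)
          q[, admixed$pop_a[r]] <- alpha
          q[, admixed$pop_b[r]] <- 1 - alpha
          adm_rows[[length(adm_rows) + 1]] <-
            list(q = q, label = rep("admixed", n_r))
        }
      }
    }
    Q <- do.call(rbind, lapply(adm_rows, `[[`, "q"))
    labels <- unlist(lapply(adm_rows, `[[`, "label"))
    n_base <- nrow(Q)

    pi_mat <- Q %*% pop_freqs # individual-specific allele frequencies
    dos <- matrix(rbinom(n_base * n_loci, 2, as.vector(pi_mat)),
                  n_base, n_loci)

    # Parent-offspring pairs: parent sampled from population 1 individuals;
    # offspring gets one gamete from the parent, one from the population.
    rel_of <- rep(NA_character_, n_base)
    pool <- which(labels == pop_names[1])
    rel_parent <- utils::head(pool, n_relative_pairs)
    if (n_relative_pairs > 0 && length(rel_parent) < n_relative_pairs)
      stop_lc("not enough population-1 individuals for relative pairs")
    for (pp in rel_parent) {
      gam_parent <- rbinom(n_loci, 1, dos[pp, ] / 2)
      gam_pop <- rbinom(n_loci, 1, pop_freqs[1, ])
      dos <- rbind(dos, gam_parent + gam_pop)
      Q <- rbind(Q, Q[pp, ])
      labels <- c(labels, pop_names[1])
      rel_of <- c(rel_of, paste0("parent:", pp))
    }

    # Technical replicates: identical dosages, independent coverage.
    rep_src <- utils::head(seq_len(n_base), n_replicate_pairs)
    rep_of_idx <- rep(NA_integer_, nrow(dos))
    for (src in rep_src) {
      dos <- rbind(dos, dos[src, ])
      Q <- rbind(Q, Q[src, ])
      labels <- c(labels, labels[src])
      rel_of <- c(rel_of, NA_character_)
      rep_of_idx <- c(rep_of_idx, src)
    }

    n <- nrow(dos)
    ids <- sprintf("I%03d", seq_len(n))
    depth_fraction <- pmin(pmax(rnorm(n, coverage_mean, coverage_sd), 0.05), 1)
    if (n_low_coverage > 0) {
      lows <- order(runif(n))[seq_len(min(n_low_coverage, n))]
      depth_fraction[lows] <- runif(length(lows), 0.2, 0.4)
    }
    miss_p <- pmin(pmax(missing_scale * (1 - depth_fraction), 0), 0.95)
    miss <- matrix(runif(n * n_loci), n, n_loci) <
      matrix(miss_p, n, n_loci)
    dos[miss] <- NA_integer_

    rownames(dos) <- ids
    colnames(dos) <- sprintf("L%05d", seq_len(n_loci))
    rownames(Q) <- ids
    colnames(Q) <- pop_names
    indiv <- tibble::tibble(
      id = ids, pop_label = labels, depth_fraction = depth_fraction,
      replicate_of = ifelse(is.na(rep_of_idx), NA_character_,
                            ids[rep_of_idx]),
      relative_of = rel_of
    )
    structure(list(dosages = dos, indiv = indiv, true_admixture = Q,
                   pop_freqs = pop_freqs, seed = seed),
              class = "genotype_dataset")
  })
}

#' @export
print.genotype_dataset <- function(x, ...) {
  cat("<genotype_dataset> ", nrow(x$dosages), " individuals x ",
      ncol(x$dosages), " loci; ", ncol(x$true_admixture),
      " source populations; ",
      sum(!is.na(x$indiv$replicate_of)), " technical replicate(s)\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.genotype_dataset <- function(x, ...) {
  tibble::as_tibble(x$dosages, rownames = "id") |>
    tidyr::pivot_longer(-"id", names_to = "locus", values_to = "dosage")
}
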
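test_that("coverage filtering is a single pass with a population-SD cutoff", {
  cov_equal <- tibble::tibble(id = paste0("i", 1:5),
                              depth_fraction = rep(0.8, 5))
  out <- coverage_filter(cov_equal)
  expect_true(all(out$kept))

  # 99 individuals at 0.9 and one at 0.1: only the straggler is discarded
  df <- tibble::tibble(id = sprintf("i%03d", 1:100),
                       depth_fraction = c(rep(0.9, 99), 0.1))
  out2 <- coverage_filter(df)
  expect_equal(out2$id[!out2$kept], "i100")
  mu <- mean(df$depth_fraction)
  sdp <- sqrt(mean((df$depth_fraction - mu)^2))
  expect_equal(attr(out2, "cutoff"), mu - 3 * sdp)
  # single-pass contract: dropping a non-outlier does not change other calls
  out3 <- coverage_filter(df[-1, ])
  expect_equal(out3$id[!out3$kept], "i100")
})

test_that("expected IBS distances hit the boundary cases", {
  # identical all-homozygous individuals: distance 0
  m <- rbind(a = c(0, 2, 0, 2), b = c(0, 2, 0, 2))
  expect_equal(ibs_distance(m)["a", "b"], 0)
  # opposite homozygotes at every locus: distance 1
  m2 <- rbind(a = c(0, 0, 2), b = c(2, 2, 0))
  expect_equal(ibs_distance(m2)["a", "b"], 1)
  # het-vs-het contributes 1/2 per locus even for identical vectors
  m3 <- rbind(a = c(1, 1, 0, 0), b = c(1, 1, 0, 0))
  expect_equal(ibs_distance(m3)["a", "b"], 0.25)
  # missing loci are excluded pairwise
  m4 <- rbind(a = c(0, NA, 2), b = c(2, 2, NA))
  expect_equal(ibs_distance(m4)["a", "b"], 1)
  # matrix properties
  g <- simulate_genotypes(seed = 2)
  D <- ibs_distance(g)
  expect_true(isSymmetric(D))
  expect_true(all(diag(D) == 0))
  expect_true(all(D >= 0 & D <= 1))
  # a pair sharing no called locus is an error naming the pair
  m5 <- rbind(x = c(0, NA), y = c(NA, 2))
  expect_error(ibs_distance(m5), "x.*y|no co-called")
})

test_that("sampled-mode IBS averages to the expected-mode distance", {
  set.seed(8)
  m <- matrix(rbinom(2 * 100, 2, 0.4), 2, 100)
  rownames(m) <- c("a", "b")
  exp_d <- ibs_distance(m, mode = "expected")["a", "b"]
  draws <- vapply(1:300, function(s) {
    ibs_distance(m, mode = "sampled", seed = s)["a", "b"]
  }, 1)
  se <- sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - exp_d), 3 * se)
})

test_that("relative pruning keeps one representative per linked cluster", {
  ids <- c("A", "B", "C", "D")
  D <- matrix(1, 4, 4, dimnames = list(ids, ids)); diag(D) <- 0
  cov <- setNames(c(0.9, 0.8, 0.7, 0.6), ids)
  # all pairs above threshold: nobody pruned
  out <- prune_relatives(D, cov, threshold = 0.15)
  expect_true(all(out$kept))
  # chain A-B 0.10, B-C 0.10, A-C 0.30: one single-linkage cluster, one kept
  D2 <- D
  D2["A", "B"] <- D2["B", "A"] <- 0.10
  D2["B", "C"] <- D2["C", "B"] <- 0.10
  D2["A", "C"] <- D2["C", "A"] <- 0.30
  out2 <- prune_relatives(D2, cov, threshold = 0.15)
  expect_equal(sum(out2$kept[out2$id %in% c("A", "B", "C")]), 1)
  expect_equal(out2$id[out2$kept & out2$id %in% c("A", "B", "C")], "A")
  expect_true(out2$kept[out2$id == "D"])
  # agreement with hclust single linkage at the same cut
  hc <- stats::hclust(stats::as.dist(D2), method = "single")
  comp <- stats::cutree(hc, h = 0.15 - 1e-9)
  expect_equal(length(unique(comp)), length(unique(out2$cluster)))
  # ties in coverage break to the lexicographically smallest id
  cov_tie <- setNames(rep(0.5, 4), ids)
  D3 <- D
  D3["C", "D"] <- D3["D", "C"] <- 0.01
  out3 <- prune_relatives(D3, cov_tie, threshold = 0.15)
  expect_true(out3$kept[out3$id == "C"])
  expect_false(out3$kept[out3$id == "D"])
})

test_that("planted technical replicates are pruned exactly", {
  for (seed in 1:5) {
    g <- simulate_genotypes(seed = seed)
    D <- ibs_distance(g)
    out <- prune_relatives(D, setNames(g$indiv$depth_fraction, g$indiv$id))
    rep_ids <- g$indiv$id[!is.na(g$indiv$replicate_of)]
    src_ids <- g$indiv$replicate_of[!is.na(g$indiv$replicate_of)]
    # exactly one member of each replicate pair survives
    for (k in seq_along(rep_ids)) {
      pair_kept <- out$kept[out$id %in% c(rep_ids[k], src_ids[k])]
      expect_equal(sum(pair_kept), 1)
    }
    # nobody outside the planted pairs is pruned
    pruned <- out$id[!out$kept]
    expect_true(all(pruned %in% c(rep_ids, src_ids)))
    expect_equal(length(pruned), length(rep_ids))
  }
})

test_that("locus filters apply presence and MAC rules and are idempotent", {
  # 10 individuals; build loci with controlled properties
  n <- 10
  loci <- cbind(
    low_presence = c(rep(NA, 6), 1, 1, 1, 1),     # called 40% -> dropped
    mac4 = c(rep(0, 6), 2, 2, 0, 0),              # MAC 4 -> dropped
    mac5 = c(rep(0, 5), 2, 2, 1, 0, 0),           # MAC 5 -> kept
    mono = rep(0, n),                             # monomorphic -> dropped
    good = c(rep(1, 5), rep(0, 5))                # kept
  )
  rownames(loci) <- sprintf("i%02d", 1:n)
  out <- locus_filters(loci)
  expect_equal(out$kept, c(FALSE, FALSE, TRUE, FALSE, TRUE))
  expect_equal(out$mac, c(4, 4, 5, 0, 5))
  # MAC counts the minor allele over called individuals
  expect_equal(out$called_fraction[1], 0.4)
  # idempotence
  kept <- loci[, out$kept, drop = FALSE]
  out2 <- locus_filters(kept)
  expect_true(all(out2$kept))
})

test_that("admixture membership and purity follow the coefficient threshold", {
  Q <- rbind(
    pure = c(1, 0, 0, 0),
    half = c(0.5, 0.5, 0, 0),
    mostly = c(0.80, 0.10, 0.06, 0.04)
  )
  colnames(Q) <- c("skag", "north", "tross", "gallo")
  out <- assign_lineages(Q, target = "skag", threshold = 0.25)
  expect_equal(out$n_clusters, c(1, 2, 1))
  expect_true(out$member_skag[1] && !out$member_north[1])
  expect_true(out$member_skag[2] && out$member_north[2])
  expect_equal(out$pure_target, c(TRUE, FALSE, TRUE))
  expect_error(assign_lineages(rbind(c(0.5, 0.2))), "sum to 1")
  expect_error(assign_lineages(Q, target = "nope"), "unknown target")
})

test_that("simulated truth recovers the planted pure-lineage subset exactly", {
  g <- simulate_genotypes(seed = 11)
  out <- assign_lineages(g$true_admixture, target = "edulis_skagerrak")
  truth <- g$true_admixture[, "edulis_skagerrak"] > 0.75
  expect_equal(out$pure_target, unname(truth))
})

test_that("the full pipeline logs every discarded item with its rule", {
  g <- simulate_genotypes(seed = 4)
  res <- filter_pipeline(g)
  expect_true(all(c("dosages", "kept_individuals", "kept_loci", "log") %in%
                    names(res)))
  n_cov <- sum(grepl("coverage", res$log$rule))
  n_ibs <- sum(grepl("IBS", res$log$rule))
  expect_equal(nrow(res$dosages),
               nrow(g$dosages) - n_cov - n_ibs)
  expect_gt(n_ibs, 0)
  expect_true(all(res$log$item[res$log$type == "locus"] %in%
                    colnames(g$dosages)))
})
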
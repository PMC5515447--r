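test_that("p-distance counts differing sites under pairwise deletion", {
  expect_equal(p_distance("ACGT", "ACGT", aligned = TRUE), 0)
  expect_equal(p_distance("ACGT", "AGGT", aligned = TRUE), 0.25)
  # gapped column excluded: 1 difference over 4 compared sites
  expect_equal(p_distance("AC-GT", "ACAGA", aligned = TRUE), 0.25)
  expect_error(p_distance("--", "AA", aligned = TRUE), "comparable")
  expect_error(p_distance("ACG", "AC", aligned = TRUE), "equal length")
})

test_that("p-distance is symmetric, zero on identity, and matches the Hamming oracle", {
  for (s in 1:8) {
    a <- random_seq(60, seed = s)
    b <- random_seq(60, seed = s + 100)
    expect_equal(p_distance(a, b, aligned = TRUE),
                 p_distance(b, a, aligned = TRUE))
    expect_equal(p_distance(a, a, aligned = TRUE), 0)
    ham <- mean(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    expect_equal(p_distance(a, b, aligned = TRUE), ham)
  }
  # cross-check the matrix against the established distance implementation
  seqs <- setNames(vapply(1:5, function(s) random_seq(80, s), character(1)),
                   paste0("t", 1:5))
  d1 <- p_distance_matrix(seqs, aligned = TRUE)
  bin <- ape::as.DNAbin(t(sapply(seqs, function(x) strsplit(x, "")[[1]])))
  d2 <- as.matrix(ape::dist.dna(bin, model = "raw", pairwise.deletion = TRUE))
  expect_equal(d1, d2[rownames(d1), colnames(d1)], tolerance = 1e-12)
})

test_that("unaligned sequences are pairwise aligned before the distance", {
  a <- random_seq(100, seed = 3)
  b <- paste0(substr(a, 1, 49), substr(a, 51, 100)) # one deletion
  expect_equal(p_distance(a, b), 0) # gap column excluded, rest identical
})

test_that("group summaries reproduce the published grand means exactly", {
  # exact to the printed 9-decimal precision
  ds_lineage <- distance_summary_from_values(lineage_within_means,
                                             lineage_between_means)
  expect_identical(round(ds_lineage$grand_within_mean, 9), 0.016579356)
  ds_isolate <- distance_summary_from_values(isolate_within_means,
                                             isolate_between_means)
  expect_identical(round(ds_isolate$grand_within_mean, 9), 0.010791175)
  expect_identical(round(ds_isolate$grand_between_mean, 9), 0.011695443)
})

test_that("group_mean_distances averages all pairwise comparisons per group", {
  base <- random_seq(120, seed = 11)
  mut <- function(s, positions) {
    x <- strsplit(s, "")[[1]]
    for (p in positions) x[p] <- setdiff(c("A", "C", "G", "T"), x[p])[1]
    paste(x, collapse = "")
  }
  data <- tibble::tibble(
    id = c("a1", "a2", "b1", "b2", "c1"),
    sequence = c(base, mut(base, 1:6), mut(base, 61:72),
                 mut(base, c(61:72, 1:6)), mut(base, 90)),
    group = c("A", "A", "B", "B", "C"))
  ds <- group_mean_distances(data, aligned = TRUE, id = "id")
  expect_equal(ds$within$mean_p[ds$within$group == "A"], 6 / 120)
  expect_equal(ds$within$mean_p[ds$within$group == "B"], 6 / 120)
  expect_true(is.na(ds$within$mean_p[ds$within$group == "C"])) # singleton
  ab <- ds$between$mean_p[ds$between$group1 == "A" & ds$between$group2 == "B"]
  # cross pairs differ at 12, 18, 18 and 12 of 120 sites (b2 shares a2's
  # first six flips)
  expect_equal(ab, mean(c(12, 18, 18, 12)) / 120)
  expect_equal(ds$grand_within_mean, 6 / 120)
  td <- tidy(ds)
  expect_identical(nrow(td), 3L + 3L)
  # identical sequences in both groups: zero within, between = their p
  d0 <- tibble::tibble(sequence = c(base, base, mut(base, 1), mut(base, 1)),
                       group = c("x", "x", "y", "y"))
  ds0 <- group_mean_distances(d0, aligned = TRUE)
  expect_true(all(ds0$within$mean_p == 0))
  expect_equal(ds0$between$mean_p, 1 / 120)
})

test_that("the two-sample test reproduces the published comparisons", {
  # within- vs between-isolate means: not significant, P = 0.48
  tt <- compare_groups_ttest(unname(isolate_within_means),
                             isolate_between_means)
  expect_equal(tt$p_value, 0.48, tolerance = 0.01)
  # within- vs between-lineage means: P = 1.32e-7
  tt2 <- compare_groups_ttest(unname(lineage_within_means),
                              lineage_between_means)
  expect_equal(tt2$p_value, 1.32e-7, tolerance = 0.01)
  # and the same number via the distance-summary glance
  g <- glance(distance_summary_from_values(lineage_within_means,
                                           lineage_between_means))
  expect_equal(g$p_within_vs_between, tt2$p_value)
})

test_that("t-test variants behave at their analytic edges", {
  x <- c(0.1, 0.2, 0.3)
  tt <- compare_groups_ttest(x, x, variant = "pooled")
  expect_equal(tt$t_statistic, 0)
  expect_equal(tt$p_value, 1)
  # pooled and unequal-variance forms coincide for equal n and variance
  y <- x + 0.05
  expect_equal(compare_groups_ttest(x, y, "welch")$t_statistic,
               compare_groups_ttest(x, y, "pooled")$t_statistic)
  # separation: p tends to 0 as the jitter shrinks
  p_at <- function(eps) {
    compare_groups_ttest(c(0, eps, -eps), c(1, 1 + eps, 1 - eps))$p_value
  }
  expect_true(p_at(1e-4) < p_at(1e-2))
  expect_lt(p_at(1e-6), 1e-10)
  expect_error(compare_groups_ttest(c(1, 1), c(1, 1)), "degenerate")
  expect_error(compare_groups_ttest(1, c(1, 2)), "at least two")
})

test_that("replicate summaries use sample SD and SE = SD/sqrt(n)", {
  rs <- replicate_summary(tibble::tibble(
    haplotype = "H1", frequency = replicate_freqs_rubicundus_h1))
  expect_equal(round(rs$mean, 3), 0.716)
  expect_equal(round(rs$sd, 3), 0.065)
  expect_equal(round(rs$se, 3), 0.046)

  rs2 <- replicate_summary(tibble::tibble(
    haplotype = "H1", frequency = replicate_freqs_pluvialis_h1))
  expect_equal(round(rs2$mean, 3), 0.363)

  rs3 <- replicate_summary(tibble::tibble(haplotype = "c",
                                          frequency = c(0.5, 0.5, 0.5)))
  expect_equal(rs3$sd, 0)
  expect_equal(rs3$se, 0)
  # se * sqrt(n) == sd for every row
  many <- replicate_summary(tibble::tibble(
    haplotype = rep(c("a", "b"), each = 4),
    frequency = c(0.1, 0.2, 0.15, 0.12, 0.5, 0.55, 0.6, 0.52)))
  expect_equal(many$se * sqrt(many$n_runs), many$sd, tolerance = 1e-12)
  # single run: mean only
  one <- replicate_summary(tibble::tibble(haplotype = "x", frequency = 0.4))
  expect_equal(one$mean, 0.4)
  expect_true(is.na(one$sd) && is.na(one$se))
})
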
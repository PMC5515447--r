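make_profiles <- function(keys) {
  tibble::tibble(id = sprintf("r%05d", seq_along(keys)),
                 bases = "", key = keys, n_events = NA_integer_,
                 mapped = TRUE, divergence = 0)
}

test_that("subsampling draws exact, distinct, seed-stable subsets", {
  prof <- make_profiles(rep("", 5000))
  ss <- subsample_profiles(prof, subsample_size = 1000, n_subsamples = 5,
                           seed = 2)
  expect_identical(nrow(ss), 5000L)
  by_rep <- split(ss$id, ss$replicate)
  expect_true(all(lengths(by_rep) == 1000L))
  expect_true(all(vapply(by_rep, anyDuplicated, integer(1)) == 0L))
  ss2 <- subsample_profiles(prof, subsample_size = 1000, n_subsamples = 5,
                            seed = 2)
  expect_identical(ss, ss2)
  expect_false(identical(
    ss, subsample_profiles(prof, subsample_size = 1000, n_subsamples = 5,
                           seed = 3)))
})

test_that("short pools clamp to the full set with a warning", {
  prof <- make_profiles(rep("", 800))
  expect_warning(
    ss <- subsample_profiles(prof, subsample_size = 1000, n_subsamples = 3),
    "full set")
  expect_true(all(table(ss$replicate) == 800L))
  expect_error(subsample_profiles(make_profiles(character(0))), "no mapped")
})

test_that("haplotype calling counts unique event sets with frequencies summing to 1", {
  prof <- make_profiles(c(rep("", 7000), rep("61G>T", 3000)))
  ss <- subsample_profiles(prof, subsample_size = 10000, n_subsamples = 1,
                           seed = 1)
  calls <- call_haplotypes(ss)
  expect_identical(sort(calls$key), c("", "61G>T"))
  expect_equal(calls$frequency[calls$key == ""], 0.7)
  expect_equal(calls$frequency[calls$key == "61G>T"], 0.3)
  expect_equal(sum(calls$frequency), 1)
})

test_that("subsampled frequencies track a simulated mixture binomially", {
  truth <- c(0.55, 0.30, 0.10, 0.04, 0.01)
  keys <- c("", "61G>T", "100GC>AT", "224insC", "220delAC")
  n <- 10000
  counts <- withr::with_seed(42, as.integer(rmultinom(1, n, truth)))
  prof <- make_profiles(sample(rep(keys, counts)))
  calls <- call_haplotypes(
    subsample_profiles(prof, subsample_size = n, n_subsamples = 1, seed = 1))
  for (i in seq_along(keys)) {
    f <- calls$frequency[calls$key == keys[i]]
    expect_lt(abs(f - truth[i]), 3 * sqrt(truth[i] * (1 - truth[i]) / n))
  }
  expect_equal(sum(calls$frequency), 1)
})

test_that("profiles average replicates, threshold inclusively and label by rank", {
  # one haplotype only
  p1 <- build_profile(calls_from(c(REF = 1)), threshold = 0.01)
  expect_identical(p1$haplotypes$haplotype_id, "H1")
  expect_equal(p1$haplotypes$mean_frequency, 1)
  expect_equal(p1$background_mean, 0)

  # averaged 0.003 variant is excluded and its reads fold into the parent
  cl <- calls_from(c(REF = 0.997, `61G>T` = 0.003),
                   c(REF = 0.997, `61G>T` = 0.003))
  p2 <- build_profile(cl, threshold = 0.01)
  expect_identical(p2$haplotypes$haplotype_id, "H1")
  expect_equal(p2$haplotypes$mean_frequency, 1) # masked reads rejoin reference
  expect_false(p2$events$demonstrable[p2$events$event == "61G>T"])

  # averaged exactly at the threshold is retained (inclusive >=)
  cl3 <- calls_from(c(REF = 0.99, `61G>T` = 0.01),
                    c(REF = 0.99, `61G>T` = 0.01))
  p3 <- build_profile(cl3, threshold = 0.01)
  expect_setequal(p3$haplotypes$key, c("", "61G>T"))
  expect_equal(sort(p3$haplotypes$mean_frequency), c(0.01, 0.99))

  # absent-in-one-replicate haplotypes count as zero there
  cl4 <- calls_from(c(REF = 0.9, `61G>T` = 0.1), c(REF = 1))
  p4 <- build_profile(cl4, threshold = 0.01)
  h2 <- p4$haplotypes[p4$haplotypes$key == "61G>T", ]
  expect_equal(h2$mean_frequency, 0.05)
  expect_equal(unname(h2$replicate_frequencies[[1]]), c(0.1, 0))
  # labels ordered by descending averaged frequency
  expect_identical(p4$haplotypes$haplotype_id,
                   c("H1", "H2")[order(-p4$haplotypes$mean_frequency)])
})

test_that("event masking reassigns error reads to their parent haplotype", {
  # reads of a true 30% haplotype that also carry a rare error variant
  cl <- calls_from(
    c(REF = 0.69, `61G>T` = 0.295, `61G>T;150A>C` = 0.005, `200T>G` = 0.01))
  p <- build_profile(cl, threshold = 0.01)
  expect_setequal(p$haplotypes$key, c("", "61G>T", "200T>G"))
  expect_equal(p$haplotypes$mean_frequency[p$haplotypes$key == "61G>T"], 0.30)
  # with masking off the error set stays separate
  p_raw <- build_profile(cl, threshold = 0.01, mask_events = FALSE)
  expect_equal(
    p_raw$haplotypes$mean_frequency[p_raw$haplotypes$key == "61G>T"], 0.295)
  expect_equal(p_raw$background_mean, 0.005)
})

test_that("lowering the threshold never loses haplotypes", {
  cl <- calls_from(c(REF = 0.90, `61G>T` = 0.06, `100A>C` = 0.03,
                     `150T>A` = 0.008, `200G>C` = 0.002))
  n_at <- function(th) nrow(build_profile(cl, threshold = th)$haplotypes)
  counts <- vapply(c(0.05, 0.02, 0.01, 0.005, 0.001), n_at, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("per-subsample frequencies sum to one across retained and background", {
  cl <- calls_from(c(REF = 0.6, `61G>T` = 0.38, `9A>T` = 0.02),
                   c(REF = 0.62, `61G>T` = 0.37, `9A>T` = 0.01))
  p <- build_profile(cl, threshold = 0.01)
  tot <- colSums(do.call(rbind, p$haplotypes$replicate_frequencies))
  expect_equal(unname(tot) + p$background_mean * 0, c(1, 1))
  expect_equal(sum(p$haplotypes$mean_frequency) + p$background_mean, 1)
})

test_that("dominance and co-dominance follow the top-two margin", {
  p1 <- build_profile(calls_from(c(REF = 0.95, `61G>T` = 0.03, `100A>C` = 0.02)),
                      threshold = 0.01)
  d1 <- dominant_haplotype(p1)
  expect_identical(d1$haplotype_id, "H1")
  expect_false(d1$co_dominant)

  p2 <- build_profile(
    calls_from(c(REF = 0.43, `61G>T` = 0.42, `100A>C` = 0.14, `150T>A` = 0.01)),
    threshold = 0.01)
  d2 <- dominant_haplotype(p2)
  expect_identical(d2$haplotype_id, "H1")
  expect_true(d2$co_dominant)
  expect_equal(d2$frequency, 0.43)

  p3 <- build_profile(calls_from(c(REF = 1)), threshold = 0.01)
  expect_false(dominant_haplotype(p3)$co_dominant)
})

test_that("tidy and glance expose the profile as tibbles", {
  cl <- calls_from(c(REF = 0.7, `61G>T` = 0.3), c(REF = 0.72, `61G>T` = 0.28))
  p <- build_profile(cl, threshold = 0.01, sample_id = "iso1")
  td <- tidy(p)
  expect_identical(nrow(td), 4L)
  expect_identical(unique(td$haplotype_id), c("H1", "H2"))
  g <- glance(p)
  expect_identical(g$sample_id, "iso1")
  expect_identical(g$n_retained, 2L)
  expect_equal(g$dominant_frequency, 0.71)
  expect_s3_class(autoplot(p), "ggplot")
})
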
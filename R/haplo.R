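#' Draw repeated random subsamples of mapped read profiles
#'
#' Draws `n_subsamples` independent subsets of `subsample_size` reads,
#' uniformly without replacement, from the mapped reads. Replicate r uses the
#' derived seed `seed + r`, so subsets are independent across replicates and
#' exactly repeatable. When fewer than `subsample_size` mapped reads exist,
#' the full set is used once per replicate and a warning is emitted.
#'
#' @param profiles A profile tibble from [map_reads()] (rows with
#'   `mapped == FALSE` are excluded first).
#' @param subsample_size Reads per subsample.
#' @param n_subsamples Number of replicate subsamples.
#' @param seed Integer seed.
#' @return The subsampled profiles stacked in one tibble with a leading
#'   `replicate` column.
#' @export
subsample_profiles <- function(profiles, subsample_size = 10000L,
                               n_subsamples = 5L, seed = 1L) {
  if ("mapped" %in% names(profiles)) {
    profiles <- profiles[profiles$mapped, , drop = FALSE]
  }
  n <- nrow(profiles)
  if (n == 0L) abort("no mapped reads to subsample")
  size <- as.integer(subsample_size)
  if (n < size) {
    warn(sprintf(
      "only %d mapped reads available; using the full set in each of the %d replicates",
      n, n_subsamples))
    size <- n
  }
  purrr::map_dfr(seq_len(n_subsamples), function(r) {
    idx <- withr::with_seed(seed + r, sample.int(n, size))
    dplyr::bind_cols(tibble(replicate = r), profiles[idx, , drop = FALSE])
  })
}

#' Call haplotypes in a subsample
#'
#' Groups reads by their canonical event-set key; every distinct set is a
#' haplotype (the empty set is the reference haplotype) and its frequency is
#' the group size over the subsample size. No threshold is applied here.
#'
#' @param subset A profile tibble (one subsample, or stacked subsamples with
#'   a `replicate` column, in which case calling is per replicate).
#' @return A tibble `replicate` (if present), `key`, `n`, `frequency`;
#'   frequencies within each subsample sum to 1.
#' @export
call_haplotypes <- function(subset) {
  if (nrow(subset) == 0L) abort("cannot call haplotypes on an empty subsample")
  grp <- if ("replicate" %in% names(subset)) c("replicate", "key") else "key"
  out <- subset |>
    dplyr::count(dplyr::across(dplyr::all_of(grp)), name = "n") |>
    dplyr::group_by(dplyr::across(dplyr::all_of(setdiff(grp, "key")))) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::ungroup()
  out
}

#' Build a haplotype frequency profile from replicate subsample calls
#'
#' Implements the demonstrable-variant rule: per-subsample frequencies are
#' first computed for every individual variant event (the frequency of an
#' event is the summed frequency of all haplotypes carrying it) and averaged
#' across subsamples; events below `threshold` are not demonstrable and are
#' masked from every read's event set, so that sequencing-error reads rejoin
#' their parent haplotype. Haplotypes are then re-grouped on the masked sets,
#' frequencies averaged across subsamples (an absent haplotype counts 0 in a
#' subsample), and the `threshold` applied to the averaged frequency
#' (inclusive: exactly the threshold is retained). Retained haplotypes are
#' labelled H1, H2, ... by descending averaged frequency; the remaining
#' sub-threshold mass is reported as a single background bucket.
#'
#' @param calls Per-subsample haplotype calls from [call_haplotypes()]
#'   (columns `replicate`, `key`, `frequency`).
#' @param threshold Retention threshold on the averaged frequency.
#' @param reference Optional reference used to realise haplotype sequences.
#' @param sample_id Sample label carried into reports.
#' @param mask_events If `FALSE`, skip event masking and group on raw sets.
#' @return A `haplotype_profile` object; see [tidy.haplotype_profile()].
#' @export
build_profile <- function(calls, threshold = 0.01, reference = NULL,
                          sample_id = "sample", mask_events = TRUE) {
  stopifnot(all(c("key", "frequency") %in% names(calls)))
  if (!"replicate" %in% names(calls)) {
    calls <- dplyr::mutate(calls, replicate = 1L, .before = 1L)
  }
  n_reps <- dplyr::n_distinct(calls$replicate)
  eps <- 1e-12

  # averaged per-event (site) frequencies over subsamples
  ev_long <- calls |>
    dplyr::filter(.data$key != "") |>
    dplyr::mutate(event = strsplit(.data$key, ";", fixed = TRUE)) |>
    tidyr::unnest("event") |>
    dplyr::group_by(.data$replicate, .data$event) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop")
  events <- ev_long |>
    dplyr::group_by(.data$event) |>
    dplyr::summarise(mean_frequency = sum(.data$frequency) / n_reps,
                     .groups = "drop") |>
    dplyr::mutate(demonstrable = .data$mean_frequency >= threshold - eps) |>
    dplyr::arrange(dplyr::desc(.data$mean_frequency))
  demonstrable <- events$event[events$demonstrable]

  keys <- unique(calls$key)
  masked <- vapply(keys, function(k) {
    if (!mask_events || k == "") return(k)
    parts <- strsplit(k, ";", fixed = TRUE)[[1]]
    paste(parts[parts %in% demonstrable], collapse = ";")
  }, character(1))
  hap <- calls |>
    dplyr::mutate(key = unname(masked[match(.data$key, keys)])) |>
    dplyr::group_by(.data$replicate, .data$key) |>
    dplyr::summarise(frequency = sum(.data$frequency), .groups = "drop") |>
    tidyr::complete(replicate = unique(calls$replicate),
                    key = unique(masked),
                    fill = list(frequency = 0)) |>
    dplyr::group_by(.data$key) |>
    dplyr::summarise(
      mean_frequency = mean(.data$frequency),
      replicate_frequencies = list(
        setNames(.data$frequency, paste0("r", .data$replicate))),
      .groups = "drop") |>
    dplyr::mutate(retained = .data$mean_frequency >= threshold - eps) |>
    dplyr::arrange(dplyr::desc(.data$mean_frequency), .data$key)

  retained <- hap[hap$retained, , drop = FALSE]
  retained$haplotype_id <- paste0("H", seq_len(nrow(retained)))
  if (!is.null(reference)) {
    retained$sequence <- vapply(retained$key, function(k) {
      apply_variants(reference, k)
    }, character(1), USE.NAMES = FALSE)
  }
  background <- hap[!hap$retained, , drop = FALSE]
  structure(list(
    sample_id = sample_id,
    haplotypes = retained[, c("haplotype_id",
                              intersect("sequence", names(retained)),
                              "key", "mean_frequency",
                              "replicate_frequencies")],
    events = events,
    background_mean = sum(background$mean_frequency),
    n_background_sets = nrow(background),
    n_subsamples = n_reps,
    threshold = threshold,
    mask_events = mask_events
  ), class = "haplotype_profile")
}

#' @export
print.haplotype_profile <- function(x, ...) {
  cat(sprintf(
    "<haplotype profile '%s': %d retained haplotype(s) over %d subsample(s), threshold %.3g, background %.4f>\n",
    x$sample_id, nrow(x$haplotypes), x$n_subsamples, x$threshold,
    x$background_mean))
  print(tidy(x))
  invisible(x)
}

#' Tidy a haplotype profile
#'
#' One row per retained haplotype and subsample replicate, with the averaged
#' frequency repeated per haplotype. `glance()` gives the one-row summary
#' (retained count, dominant haplotype and its frequency, co-dominance flag,
#' background mass).
#'
#' @param x A `haplotype_profile`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.haplotype_profile <- function(x, ...) {
  if (nrow(x$haplotypes) == 0L) {
    return(tibble(haplotype_id = character(), key = character(),
                  replicate = integer(), frequency = numeric(),
                  mean_frequency = numeric()))
  }
  purrr::map_dfr(seq_len(nrow(x$haplotypes)), function(i) {
    f <- x$haplotypes$replicate_frequencies[[i]]
    tibble(haplotype_id = x$haplotypes$haplotype_id[i],
           key = x$haplotypes$key[i],
           replicate = seq_along(f),
           frequency = unname(f),
           mean_frequency = x$haplotypes$mean_frequency[i])
  })
}

#' @rdname tidy.haplotype_profile
#' @param codominance_margin Margin used for the co-dominance flag.
#' @export
glance.haplotype_profile <- function(x, codominance_margin = 0.05, ...) {
  dom <- dominant_haplotype(x, codominance_margin = codominance_margin)
  tibble(sample_id = x$sample_id,
         n_retained = nrow(x$haplotypes),
         dominant_id = dom$haplotype_id,
         dominant_frequency = dom$frequency,
         co_dominant = dom$co_dominant,
         background_mean = x$background_mean,
         n_subsamples = x$n_subsamples,
         threshold = x$threshold)
}

#' Dominant haplotype and co-dominance
#'
#' The dominant haplotype is the retained haplotype with the greatest
#' averaged frequency. Two haplotypes are co-dominant when the top two
#' averaged frequencies differ by less than `codominance_margin` (and at
#' least two haplotypes are retained) — the pattern seen when two variants
#' of a multi-copy array occur at nearly equal copy number.
#'
#' @param profile A `haplotype_profile`.
#' @param codominance_margin Frequency margin for co-dominance.
#' @return A one-row tibble: `haplotype_id`, `frequency`, `co_dominant`.
#' @export
dominant_haplotype <- function(profile, codominance_margin = 0.05) {
  h <- profile$haplotypes
  if (nrow(h) == 0L) abort("profile has no retained haplotypes")
  co <- nrow(h) >= 2L &&
    abs(h$mean_frequency[1] - h$mean_frequency[2]) < codominance_margin
  tibble(haplotype_id = h$haplotype_id[1],
         frequency = h$mean_frequency[1],
         co_dominant = co)
}

#' Profile a sample end-to-end from mapped reads
#'
#' Convenience chain: [subsample_profiles()] then [call_haplotypes()] then
#' [build_profile()].
#'
#' @inheritParams subsample_profiles
#' @inheritParams build_profile
#' @return A `haplotype_profile`.
#' @export
profile_sample <- function(profiles, subsample_size = 10000L,
                           n_subsamples = 5L, seed = 1L, threshold = 0.01,
                           reference = NULL, sample_id = "sample",
                           mask_events = TRUE) {
  profiles |>
    subsample_profiles(subsample_size = subsample_size,
                       n_subsamples = n_subsamples, seed = seed) |>
    call_haplotypes() |>
    build_profile(threshold = threshold, reference = reference,
                  sample_id = sample_id, mask_events = mask_events)
}
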
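#' Pipeline configuration
#'
#' Central parameter list with the protocol defaults: read filtering at
#' minimum length 250 bp and minimum mean quality Q30; overlap merging with
#' minimum overlap 30 bp and mismatch fraction <= 0.1; affine-gap alignment
#' (+1/-2, gap 5 + 2L) with a 0.25 divergence ceiling; five random
#' subsamples of 10,000 mapped reads; 1% retention threshold; 0.05
#' co-dominance margin. Simulation defaults describe the canonical study
#' condition (350-bp amplicon, 2x300 reads, 50,000 pairs, per-base
#' substitution error 0.001). Unknown keys are rejected.
#'
#' @param ... Named overrides of the defaults.
#' @return A named list of class `amplihap_config`.
#' @export
amplihap_config <- function(...) {
  defaults <- list(
    # readprep
    min_length = 250L, min_mean_quality = 30,
    min_overlap = 30L, max_mismatch_frac = 0.1,
    trim = TRUE,
    # varmap
    match = 1, mismatch = -2, gap_opening = 5, gap_extension = 2,
    max_divergence = 0.25,
    # haplo
    subsample_size = 10000L, n_subsamples = 5L, threshold = 0.01,
    codominance_margin = 0.05, mask_events = TRUE,
    # simdata
    ref_length = 350L, gc_fraction = 0.5, n_pairs = 50000L,
    read_length = 300L, error_rate = 0.001, indel_error_rate = 1e-5,
    frequencies = c(0.55, 0.30, 0.10, 0.04, 0.01),
    quality_decay = FALSE,
    # phylo
    n_bootstrap = 1000L,
    # global
    seed = 1L
  )
  overrides <- list(...)
  if (anyDuplicated(names(overrides))) {
    abort("duplicated config key(s) in overrides")
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")))
  }
  cfg <- utils::modifyList(defaults, overrides)
  structure(cfg, class = "amplihap_config")
}

config_echo <- function(config) {
  vals <- vapply(config, function(v) paste(format(v), collapse = "|"),
                 character(1))
  tibble(key = names(config), value = unname(vals))
}

write_run_log <- function(out_dir, config, extra = character(0)) {
  lines <- c(
    sprintf("amplihap %s", as.character(utils::packageVersion("amplihap"))),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    sprintf("seed: %d", config$seed),
    "config:",
    sprintf("  %s = %s", config_echo(config)$key, config_echo(config)$value),
    extra
  )
  writeLines(lines, file.path(out_dir, "run_log.txt"))
}

#' Simulate a ground-truthed library to disk
#'
#' Generates a reference and the default truth mixture under `config` and
#' writes the reference FASTA, paired FASTQ files, truth table and manifest.
#'
#' @param out_dir Output directory.
#' @param config An [amplihap_config()].
#' @param mixture Optional [truth_mixture()] overriding the default one.
#' @return Invisibly, the list of output paths plus the in-memory library.
#' @export
run_simulate <- function(out_dir, config = amplihap_config(), mixture = NULL) {
  if (config$n_pairs < 1L) abort("`n_pairs` must be at least 1")
  reference <- generate_reference(config$ref_length, config$gc_fraction,
                                  seed = config$seed)
  if (is.null(mixture)) {
    mixture <- default_truth_mixture(
      reference, frequencies = config$frequencies,
      error_rate = config$error_rate,
      indel_error_rate = config$indel_error_rate,
      read_length = config$read_length, n_pairs = config$n_pairs)
  }
  res <- simulate_library(reference, mixture, out_dir, seed = config$seed,
                          quality_decay = config$quality_decay)
  write_run_log(out_dir, config)
  invisible(res)
}

#' Run the profiling pipeline: filter, merge, map, subsample, call
#'
#' Executes the full read-to-haplotype protocol on a paired FASTQ library and
#' writes the profile table (per-replicate and averaged frequencies), the
#' retained haplotype sequences as FASTA, and filter/merge/map statistics.
#'
#' @param r1,r2 Paired FASTQ paths (or read tibbles).
#' @param reference Reference FASTA path, `amplicon_reference`, or sequence.
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param config An [amplihap_config()].
#' @param sample_id Sample label.
#' @return A `haplotype_profile` with a `pipeline_stats` attribute.
#' @export
run_profile <- function(r1, r2, reference, out_dir = NULL,
                        config = amplihap_config(), sample_id = "sample") {
  fwd <- if (is.character(r1)) read_fastq(r1) else r1
  rev <- if (is.character(r2)) read_fastq(r2) else r2
  if (is.character(reference) && file.exists(reference)) {
    reference <- read_reference(reference)
  }
  if (config$trim) {
    fwd <- trim_adapters(fwd)
    rev <- trim_adapters(rev)
  }
  flt <- filter_read_pairs(fwd, rev, min_length = config$min_length,
                           min_mean_quality = config$min_mean_quality)
  if (nrow(flt$forward) == 0L) abort("pipeline failure: no read pair passed filtering")
  merged <- merge_pairs(flt$forward, flt$reverse,
                        min_overlap = config$min_overlap,
                        max_mismatch_frac = config$max_mismatch_frac)
  ok <- merged[merged$merged, , drop = FALSE]
  if (nrow(ok) == 0L) abort("pipeline failure: no read pair could be merged")
  profiles <- map_reads(ok, reference, max_divergence = config$max_divergence,
                        match = config$match, mismatch = config$mismatch,
                        gap_opening = config$gap_opening,
                        gap_extension = config$gap_extension)
  profile <- profile_sample(
    profiles, subsample_size = config$subsample_size,
    n_subsamples = config$n_subsamples, seed = config$seed,
    threshold = config$threshold, reference = reference,
    sample_id = sample_id, mask_events = config$mask_events)
  stats <- tibble(
    input_pairs = nrow(fwd),
    filtered_pairs = nrow(flt$forward),
    merged_reads = nrow(ok),
    merge_rate = nrow(ok) / nrow(flt$forward),
    mapped_reads = sum(profiles$mapped),
    unmapped_fraction = mean(!profiles$mapped)
  )
  attr(profile, "pipeline_stats") <- stats
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wide <- tidy(profile) |>
      tidyr::pivot_wider(names_from = "replicate", names_prefix = "frequency_r",
                         values_from = "frequency") |>
      dplyr::rename(Haplotype = "haplotype_id", Mean = "mean_frequency")
    readr::write_tsv(wide, file.path(out_dir, "haplotype_profile.tsv"))
    readr::write_tsv(profile$events, file.path(out_dir, "site_frequencies.tsv"))
    readr::write_tsv(stats, file.path(out_dir, "pipeline_stats.tsv"))
    if (nrow(profile$haplotypes) > 0L && "sequence" %in% names(profile$haplotypes)) {
      Biostrings::writeXStringSet(
        Biostrings::DNAStringSet(setNames(profile$haplotypes$sequence,
                                          profile$haplotypes$haplotype_id)),
        file.path(out_dir, "haplotypes.fasta"))
    }
    write_run_log(out_dir, config)
  }
  profile
}

#' Distance, reproducibility and tree reports for labelled haplotypes
#'
#' Reads haplotype sequences (FASTA) and a grouping table (TSV: `id`,
#' `group`), computes within/between-group mean p-distances, and writes a
#' neighbor-joining tree (with bootstrap supports when the input is a
#' multiple alignment of equal-length sequences).
#'
#' @param fasta Haplotype FASTA path or named character vector.
#' @param groups Grouping TSV path or tibble (`id`, `group`).
#' @param out_dir Output directory (`NULL` to skip writing).
#' @param config An [amplihap_config()].
#' @return A list: `distances` (a `distance_summary`) and `tree`
#'   (`ape::phylo`, `NULL` when fewer than 3 sequences).
#' @export
run_stats <- function(fasta, groups, out_dir = NULL,
                      config = amplihap_config()) {
  seqs <- if (is.character(fasta) && length(fasta) == 1L && file.exists(fasta)) {
    x <- Biostrings::readDNAStringSet(fasta)
    setNames(as.character(x), names(x))
  } else fasta
  grp <- if (is.character(groups) && length(groups) == 1L && file.exists(groups)) {
    readr::read_tsv(groups, show_col_types = FALSE)
  } else as_tibble(groups)
  stopifnot(all(c("id", "group") %in% names(grp)))
  missing <- setdiff(grp$id, names(seqs))
  if (length(missing)) {
    abort(paste0("grouping ids missing from FASTA: ",
                 paste(missing, collapse = ", ")))
  }
  data <- tibble(id = grp$id, sequence = unname(seqs[grp$id]),
                 group = grp$group)
  aligned <- dplyr::n_distinct(nchar(data$sequence)) == 1L
  ds <- group_mean_distances(data, aligned = aligned, id = "id")
  tree <- NULL
  if (nrow(data) >= 3L) {
    if (aligned && nrow(data) >= 4L) {
      tree <- bootstrap_supports(setNames(data$sequence, data$id),
                                 n_replicates = config$n_bootstrap,
                                 seed = config$seed)
    } else {
      tree <- nj_tree(p_distance_matrix(setNames(data$sequence, data$id),
                                        aligned = aligned))
    }
  }
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    readr::write_tsv(ds$within, file.path(out_dir, "within_group.tsv"))
    readr::write_tsv(ds$between, file.path(out_dir, "between_group.tsv"))
    readr::write_tsv(glance(ds), file.path(out_dir, "distance_summary.tsv"))
    if (!is.null(tree)) write_newick(tree, file.path(out_dir, "tree.nwk"))
    write_run_log(out_dir, config)
  }
  list(distances = ds, tree = tree)
}
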
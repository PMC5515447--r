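# fixtures are built in code; nothing is read from disk

random_seq <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("A", "C", "G", "T"), n, TRUE),
                               collapse = ""))
}

# read tibble with constant quality
reads_tbl <- function(bases, q = 37L, ids = NULL) {
  tibble::tibble(
    id = ids %||% sprintf("r%03d", seq_along(bases)),
    bases = bases,
    quals = vapply(nchar(bases),
                   function(L) strrep(intToUtf8(q + 33L), L), character(1))
  )
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# error-free paired reads covering `amplicon` with mate length `rl`
pair_from_amplicon <- function(amplicon, rl, id = "p1") {
  L <- nchar(amplicon)
  fwd <- substr(amplicon, 1L, min(rl, L))
  rev <- amplihap:::revcomp(substr(amplicon, max(1L, L - rl + 1L), L))
  list(forward = reads_tbl(fwd, ids = id), reverse = reads_tbl(rev, ids = id))
}

# per-subsample call tibble from named frequency vectors; the name REF
# stands for the reference haplotype (empty event set)
calls_from <- function(...) {
  reps <- list(...)
  purrr::map_dfr(seq_along(reps), function(r) {
    k <- names(reps[[r]])
    k[k == "REF"] <- ""
    tibble::tibble(replicate = r, key = k, frequency = unname(reps[[r]]))
  })
}

# Published group-mean p-distances for the six Haematococcus ITS2 lineages
# (within-lineage), the fifteen lineage pairs (between), and the three
# isolates of the pluvialis lineage (within/between): the inputs for the
# summary-statistics reproductions.
lineage_within_means <- c(
  PLUVIALIS = 0.011461282, RUBICUNDIS = 0.00763203, C_lineage = 0.022749559,
  RUBENS = 0.040381791, D_lineage = 0.007980508, B_lineage = 0.009270965)
lineage_between_means <- c(0.101, 0.088, 0.042, 0.043, 0.091, 0.076, 0.167,
                           0.126, 0.118, 0.155, 0.116, 0.104, 0.093, 0.097,
                           0.153)
isolate_within_means <- c(`SAG 34-1b` = 0.011758569, HP111 = 0.008810573,
                          `SAG 49.94` = 0.011804383)
isolate_between_means <- c(0.012467350, 0.010637853, 0.011981126)

# replicate-run haplotype frequencies from the published reproducibility
# comparisons (dominant haplotype rows)
replicate_freqs_rubicundus_h1 <- c(0.67, 0.762)   # two same-template runs
replicate_freqs_pluvialis_h1 <- c(0.39, 0.35, 0.35) # three runs
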
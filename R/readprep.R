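#' Read and write FASTQ files as tibbles
#'
#' Reads are represented throughout the package as tibbles with columns
#' `id`, `bases` and `quals` (Phred+33 quality string of equal length).
#'
#' @param path FASTQ file path (Phred+33).
#' @return `read_fastq()`: a read tibble; `write_fastq()`: the path,
#'   invisibly.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("FASTQ file '%s' does not exist", path))
  }
  n_lines <- length(readLines(path, warn = FALSE))
  if (n_lines == 0L || n_lines %% 4L != 0L) {
    abort(sprintf(
      "malformed FASTQ file '%s': %d lines (truncated record after read %d?)",
      path, n_lines, n_lines %/% 4L))
  }
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) {
      abort(sprintf("malformed FASTQ file '%s': %s", path, conditionMessage(e)))
    }
  )
  q <- S4Vectors::mcols(x)$qualities
  short <- which(Biostrings::width(q) != Biostrings::width(x))
  if (length(short)) {
    abort(sprintf(
      "malformed FASTQ file '%s': record '%s' has %d bases but %d quality values (truncated file?)",
      path, names(x)[short[1]], Biostrings::width(x)[short[1]],
      Biostrings::width(q)[short[1]]))
  }
  tibble(id = names(x),
         bases = unname(as.character(x)),
         quals = unname(as.character(q)))
}

#' @rdname read_fastq
#' @param reads A read tibble (`id`, `bases`, `quals`).
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$bases, reads$id))
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$quals))
  invisible(path)
}

#' Mean Phred quality of each read
#'
#' @param quals Character vector of Phred+33 quality strings.
#' @return Numeric vector of mean qualities.
#' @export
mean_quality <- function(quals) {
  vapply(quals, function(q) {
    if (!nzchar(q)) return(NA_real_)
    mean(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Trim adapter read-through from read 3' ends
#'
#' Any read suffix matching a prefix of one of the adapter sequences (at
#' least `min_match` bases, at most `max_mismatch` mismatches) is removed,
#' with qualities truncated in lockstep. Reads without adapter content are
#' returned unchanged. The earliest (longest) qualifying match wins.
#'
#' @param reads A read tibble.
#' @param adapters Character vector of adapter sequences as they appear when
#'   read through (see [readthrough_adapters()]).
#' @param min_match Minimum matching length in bases.
#' @param max_mismatch Maximum mismatches tolerated in the match.
#' @return The trimmed read tibble.
#' @export
trim_adapters <- function(reads, adapters = readthrough_adapters(),
                          min_match = 8L, max_mismatch = 1L) {
  if (length(adapters) == 0L || any(!nzchar(adapters))) {
    abort("`adapters` must be non-empty sequences")
  }
  cut <- trim_suffix_cpp(reads$bases, unname(adapters),
                         as.integer(min_match), as.integer(max_mismatch))
  keep <- cut > 0L
  out <- reads
  out$bases <- ifelse(keep, substr(reads$bases, 1L, cut), "")
  out$quals <- ifelse(keep, substr(reads$quals, 1L, cut), "")
  out
}

#' Filter reads on length and mean quality
#'
#' Retains reads with length >= `min_length` and mean Phred quality >=
#' `min_mean_quality`. The "minimum QC value" of the protocol is read as a
#' minimum *mean* quality per read: a per-base floor of Q30 would discard
#' essentially all 2x300 data. Filtering is idempotent.
#'
#' @param reads A read tibble.
#' @param min_length Minimum read length in bases.
#' @param min_mean_quality Minimum mean Phred quality.
#' @return The retained reads, with a `filter_stats` attribute (tibble with
#'   `input`, `passed`, `failed_length`, `failed_quality`) readable via
#'   [filter_stats()].
#' @export
filter_reads <- function(reads, min_length = 250L, min_mean_quality = 30) {
  if (min_length < 0L || min_mean_quality < 0) {
    abort("filter thresholds must be non-negative")
  }
  len_ok <- nchar(reads$bases) >= min_length
  q_ok <- mean_quality(reads$quals) >= min_mean_quality
  q_ok[is.na(q_ok)] <- FALSE
  out <- reads[len_ok & q_ok, , drop = FALSE]
  attr(out, "filter_stats") <- tibble(
    input = nrow(reads), passed = nrow(out),
    failed_length = sum(!len_ok),
    failed_quality = sum(len_ok & !q_ok)
  )
  out
}

#' @rdname filter_reads
#' @param x A filtered read tibble or pair list.
#' @export
filter_stats <- function(x) attr(x, "filter_stats")

#' Filter a read pair jointly
#'
#' A pair is dropped when either mate fails the length or mean-quality
#' criterion.
#'
#' @param forward,reverse Read tibbles with matching `id` order.
#' @inheritParams filter_reads
#' @return List with retained `forward` and `reverse` tibbles and a
#'   `filter_stats` attribute counting pairs.
#' @export
filter_read_pairs <- function(forward, reverse, min_length = 250L,
                              min_mean_quality = 30) {
  stopifnot(nrow(forward) == nrow(reverse))
  ok_f <- nchar(forward$bases) >= min_length &
    mean_quality(forward$quals) >= min_mean_quality
  ok_r <- nchar(reverse$bases) >= min_length &
    mean_quality(reverse$quals) >= min_mean_quality
  ok_f[is.na(ok_f)] <- FALSE
  ok_r[is.na(ok_r)] <- FALSE
  keep <- ok_f & ok_r
  out <- list(forward = forward[keep, , drop = FALSE],
              reverse = reverse[keep, , drop = FALSE])
  attr(out, "filter_stats") <- tibble(
    input = nrow(forward), passed = sum(keep),
    failed_forward = sum(!ok_f), failed_reverse = sum(!ok_r)
  )
  out
}

#' Merge overlapping read pairs into amplicon-spanning sequences
#'
#' The reverse read is reverse-complemented and the overlap offset maximising
#' overlap length, subject to a mismatch fraction at most
#' `max_mismatch_frac`, is chosen. Within the overlap the base with the
#' higher quality wins (ties go to the forward read) and the consensus
#' quality is the maximum of the two. Pairs with no admissible overlap are
#' reported unmerged, not errored.
#'
#' @param forward,reverse Read tibbles with matching `id` order (reverse in
#'   sequencer orientation).
#' @param min_overlap Minimum admissible overlap in bases.
#' @param max_mismatch_frac Maximum mismatch fraction within the overlap.
#' @return A tibble `id`, `bases`, `quals`, `overlap`, `merged` (logical);
#'   unmerged rows carry empty sequences and `overlap = NA`.
#' @export
merge_pairs <- function(forward, reverse, min_overlap = 30L,
                        max_mismatch_frac = 0.1) {
  stopifnot(nrow(forward) == nrow(reverse))
  if (nrow(forward) == 0L) {
    return(tibble(id = character(), bases = character(), quals = character(),
                  overlap = integer(), merged = logical()))
  }
  if (any(!nzchar(forward$bases)) || any(!nzchar(reverse$bases))) {
    abort("cannot merge empty reads")
  }
  rvc <- revcomp(reverse$bases)
  res <- merge_pairs_cpp(forward$bases, forward$quals, rvc, reverse$quals,
                         as.integer(min_overlap), max_mismatch_frac)
  tibble(id = forward$id, bases = res$bases, quals = res$quals,
         overlap = ifelse(res$overlap > 0L, res$overlap, NA_integer_),
         merged = res$overlap > 0L)
}

#' Merge one read pair
#'
#' Single-pair convenience over [merge_pairs()].
#'
#' @param forward,reverse One-row read tibbles (or lists with `id`, `bases`,
#'   `quals`).
#' @inheritParams merge_pairs
#' @return A one-row merge tibble; `merged` is `FALSE` on merge failure.
#' @export
merge_pair <- function(forward, reverse, min_overlap = 30L,
                       max_mismatch_frac = 0.1) {
  merge_pairs(as_tibble(forward[c("id", "bases", "quals")]),
              as_tibble(reverse[c("id", "bases", "quals")]),
              min_overlap = min_overlap, max_mismatch_frac = max_mismatch_frac)
}
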
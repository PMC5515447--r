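#' Proportional (p-) distance between two sequences
#'
#' p = differing compared sites / compared sites, where any alignment column
#' containing a gap in either sequence is excluded (pairwise deletion).
#' Unaligned sequences are first pairwise-aligned with the package's
#' affine-gap scheme (see [align_to_reference()]).
#'
#' @param a,b Nucleotide strings; if `aligned = TRUE`, equal-length gapped
#'   strings.
#' @param aligned Set `TRUE` when `a` and `b` are already aligned.
#' @return The p-distance in \[0, 1\]; symmetric; 0 for identical sequences.
#' @examples
#' p_distance("ACGT", "AGGT", aligned = TRUE)
#' @export
p_distance <- function(a, b, aligned = FALSE) {
  if (!aligned) {
    if (a == b) return(0)
    aln <- Biostrings::pairwiseAlignment(
      pattern = Biostrings::DNAString(a), subject = Biostrings::DNAString(b),
      type = "global",
      substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
        match = 1, mismatch = -2, baseOnly = FALSE),
      gapOpening = 5, gapExtension = 2)
    a <- as.character(Biostrings::alignedPattern(aln))
    b <- as.character(Biostrings::alignedSubject(aln))
  }
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  if (length(ca) != length(cb)) {
    abort("aligned sequences must have equal length")
  }
  cmp <- ca != "-" & cb != "-"
  if (!any(cmp)) abort("no comparable (gap-free) sites between the sequences")
  sum(ca[cmp] != cb[cmp]) / sum(cmp)
}

#' Pairwise p-distance matrix for a sequence set
#'
#' @param sequences Named character vector of sequences.
#' @param aligned `TRUE` when the set is a multiple alignment (equal
#'   lengths, `-` gaps); otherwise each pair is aligned independently.
#' @return A symmetric distance matrix with zero diagonal.
#' @export
p_distance_matrix <- function(sequences, aligned = FALSE) {
  n <- length(sequences)
  if (n < 2L) abort("need at least two sequences")
  if (is.null(names(sequences))) names(sequences) <- paste0("seq", seq_len(n))
  d <- matrix(0, n, n, dimnames = list(names(sequences), names(sequences)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- p_distance(sequences[[i]], sequences[[j]],
                                       aligned = aligned)
    }
  }
  d
}

#' Within- and between-group mean p-distances
#'
#' Computes, over all possible pairwise comparisons, the mean p-distance
#' within each group (requires >= 2 members; singleton groups get `NA`) and
#' between each unordered pair of groups. The grand means are unweighted
#' arithmetic means of the listed group-level values, matching how summary
#' "Mean" rows of such tables are conventionally computed.
#'
#' @param data A tibble with one row per sequence.
#' @param sequence,group,id Column names (strings) for the sequence, group
#'   label and optional sequence id.
#' @param aligned Passed to [p_distance_matrix()].
#' @return A `distance_summary` object with tibbles `within` (`group`, `n`,
#'   `mean_p`) and `between` (`group1`, `group2`, `mean_p`) plus grand means;
#'   see [tidy.distance_summary()].
#' @export
group_mean_distances <- function(data, sequence = "sequence", group = "group",
                                 id = NULL, aligned = FALSE) {
  stopifnot(is.data.frame(data), sequence %in% names(data),
            group %in% names(data))
  if (nrow(data) < 2L) abort("need at least two sequences")
  seqs <- data[[sequence]]
  names(seqs) <- if (!is.null(id)) data[[id]] else paste0("s", seq_len(nrow(data)))
  grp <- as.character(data[[group]])
  d <- p_distance_matrix(seqs, aligned = aligned)
  groups <- unique(grp)
  within <- purrr::map_dfr(groups, function(g) {
    idx <- which(grp == g)
    m <- if (length(idx) >= 2L) {
      mean(d[idx, idx][upper.tri(d[idx, idx])])
    } else NA_real_
    tibble(group = g, n = length(idx), mean_p = m)
  })
  pairs <- utils::combn(groups, 2L, simplify = FALSE)
  between <- purrr::map_dfr(pairs, function(p) {
    tibble(group1 = p[1], group2 = p[2],
           mean_p = mean(d[grp == p[1], grp == p[2], drop = FALSE]))
  })
  new_distance_summary(within, between, d)
}

new_distance_summary <- function(within, between, matrix = NULL) {
  structure(list(
    within = within,
    between = between,
    grand_within_mean = mean(within$mean_p, na.rm = TRUE),
    grand_between_mean = if (nrow(between)) mean(between$mean_p) else NA_real_,
    matrix = matrix
  ), class = "distance_summary")
}

#' Assemble a distance summary from already-computed group means
#'
#' Values-only entry point for re-deriving the summary statistics of
#' published within/between group mean tables: the grand means and the
#' within-vs-between comparison, without access to the underlying sequences.
#'
#' @param within Numeric vector of within-group mean p-distances (optionally
#'   named by group).
#' @param between Numeric vector of between-group-pair mean p-distances.
#' @return A `distance_summary`.
#' @export
distance_summary_from_values <- function(within, between = numeric(0)) {
  w <- tibble(group = names(within) %||% paste0("g", seq_along(within)),
              n = NA_integer_, mean_p = unname(within))
  b <- if (length(between)) {
    tibble(group1 = names(between) %||% paste0("p", seq_along(between)),
           group2 = NA_character_, mean_p = unname(between))
  } else {
    tibble(group1 = character(), group2 = character(), mean_p = numeric())
  }
  new_distance_summary(w, b)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.distance_summary <- function(x, ...) {
  cat(sprintf("<distance summary: %d group(s), grand within mean %.9f",
              nrow(x$within), x$grand_within_mean))
  if (!is.na(x$grand_between_mean)) {
    cat(sprintf(", grand between mean %.9f", x$grand_between_mean))
  }
  cat(">\n")
  invisible(x)
}

#' Tidy a distance summary
#'
#' `tidy()` stacks the within- and between-group mean rows; `glance()` gives
#' the grand means and, when both sides are present, the Welch test of
#' within- vs between-group values.
#'
#' @param x A `distance_summary`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.distance_summary <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(
      dplyr::rename(x$within, group1 = "group"),
      group2 = NA_character_, comparison = "within", .before = "mean_p"),
    dplyr::mutate(x$between, comparison = "between", n = NA_integer_)
  )[, c("comparison", "group1", "group2", "n", "mean_p")]
}

#' @rdname tidy.distance_summary
#' @export
glance.distance_summary <- function(x, ...) {
  out <- tibble(n_groups = nrow(x$within),
                grand_within_mean = x$grand_within_mean,
                grand_between_mean = x$grand_between_mean,
                p_within_vs_between = NA_real_)
  w <- x$within$mean_p[!is.na(x$within$mean_p)]
  if (length(w) >= 2L && nrow(x$between) >= 2L) {
    out$p_within_vs_between <-
      compare_groups_ttest(w, x$between$mean_p)$p_value
  }
  out
}

#' Two-sample t-test between group-mean sets
#'
#' Standard two-sample t-test (both the unequal-variance Welch form, the
#' default, and the pooled-variance form) for comparing two collections of
#' group mean distances, e.g. within-group vs between-group means.
#'
#' @param x,y Numeric vectors (each length >= 2).
#' @param variant `"welch"` (unequal variance) or `"pooled"`.
#' @return A one-row tibble: `t_statistic`, `df`, `p_value`, `variant`,
#'   `mean_x`, `mean_y`.
#' @export
compare_groups_ttest <- function(x, y, variant = c("welch", "pooled")) {
  variant <- match.arg(variant)
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least two values")
  }
  if (sd(x) == 0 && sd(y) == 0 && mean(x) == mean(y)) {
    abort("degenerate test: both groups constant with equal means")
  }
  tt <- t.test(x, y, var.equal = variant == "pooled")
  tibble(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, variant = variant,
         mean_x = mean(x), mean_y = mean(y))
}

#' Replicate reproducibility summary
#'
#' Per-haplotype mean, sample standard deviation (n - 1 denominator) and
#' standard error of the mean (SD / sqrt(n)) of frequencies across
#' independent sequencing runs. With a single run the mean is reported and
#' SD/SE are `NA`.
#'
#' @param data A tibble with one row per haplotype and run.
#' @param haplotype,frequency Column names (strings).
#' @return A tibble `haplotype`, `n_runs`, `mean`, `sd`, `se`.
#' @examples
#' replicate_summary(tibble::tibble(
#'   haplotype = c("H1", "H1"), frequency = c(0.67, 0.762)))
#' @export
replicate_summary <- function(data, haplotype = "haplotype",
                              frequency = "frequency") {
  stopifnot(haplotype %in% names(data), frequency %in% names(data))
  data |>
    dplyr::group_by(haplotype = .data[[haplotype]]) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      mean = mean(.data[[frequency]]),
      sd = if (dplyr::n() >= 2L) sd(.data[[frequency]]) else NA_real_,
      se = if (dplyr::n() >= 2L) sd(.data[[frequency]]) / sqrt(dplyr::n())
           else NA_real_,
      .groups = "drop")
}
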
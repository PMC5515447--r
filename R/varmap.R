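#' Align sequences globally to the amplicon reference
#'
#' Optimal global alignment under affine-gap scoring (defaults: match +1,
#' mismatch -2, gap open -5, gap extend -2 per base; a gap of length L costs
#' 5 + 2L). Amplicon reads are primer-defined and should span the locus, so
#' the alignment is global, not local.
#'
#' @param sequences Character vector of read sequences.
#' @param reference An `amplicon_reference` or character scalar.
#' @param match,mismatch,gap_opening,gap_extension Scoring parameters
#'   (`gap_opening`/`gap_extension` as positive penalties).
#' @return A `Biostrings::PairwiseAlignments` object (one alignment per
#'   input sequence).
#' @export
align_to_reference <- function(sequences, reference, match = 1, mismatch = -2,
                               gap_opening = 5, gap_extension = 2) {
  if (length(sequences) == 0L) abort("no sequences to align")
  if (any(!nzchar(sequences))) abort("cannot align empty sequences")
  refseq <- reference_sequence(reference)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = FALSE)
  Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(sequences),
    subject = Biostrings::DNAString(refseq),
    type = "global", substitutionMatrix = mat,
    gapOpening = gap_opening, gapExtension = gap_extension
  )
}

#' Extract a canonical variant profile from one gapped alignment
#'
#' Turns an aligned read/reference pair into the canonical event set:
#' mismatch runs over consecutive reference sites collapse into a single
#' substitution (adjacent SNVs become a DNP/MNV), and indels are left-aligned
#' to their lowest-position equivalent placement (a deletion inside a
#' homopolymer is anchored at its leftmost copy). The profile is flagged
#' unmapped when the divergence — (mismatched + gapped columns) / reference
#' length — exceeds `max_divergence`, or when a terminal gap run longer than
#' 5 columns shows the read does not span the reference.
#'
#' @param aligned_read,aligned_ref Equal-length gapped strings (`-` gaps).
#' @param max_divergence Divergence above which the read is unmapped.
#' @return A list: `events` (tibble), `key`, `mapped`, `divergence`.
#' @export
extract_variant_profile <- function(aligned_read, aligned_ref,
                                    max_divergence = 0.25) {
  pc <- strsplit(aligned_read, "")[[1]]
  sc <- strsplit(aligned_ref, "")[[1]]
  if (length(pc) != length(sc)) abort("aligned strings differ in length")
  refseq <- paste(sc[sc != "-"], collapse = "")
  ref_len <- nchar(refseq)
  refpos <- cumsum(sc != "-")
  state <- integer(length(pc)) # 0 match, 1 mismatch, 2 del, 3 ins
  state[sc != "-" & pc != "-" & sc != pc] <- 1L
  state[pc == "-"] <- 2L
  state[sc == "-"] <- 3L

  divergence <- sum(state != 0L) / ref_len
  term_gap <- function(v) {
    r <- rle(v == "-")
    max(if (r$values[1]) r$lengths[1] else 0L,
        if (r$values[length(r$values)]) r$lengths[length(r$lengths)] else 0L)
  }
  mapped <- divergence <= max_divergence &&
    term_gap(pc) <= 5L && term_gap(sc) <= 5L

  runs <- rle(state)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  ev <- list()
  for (k in seq_along(runs$values)) {
    st <- runs$values[k]
    if (st == 0L) next
    i <- starts[k]:ends[k]
    if (st == 1L) {
      ev[[length(ev) + 1L]] <- variant("sub", refpos[starts[k]],
                                       paste(sc[i], collapse = ""),
                                       paste(pc[i], collapse = ""))
    } else if (st == 2L) {
      ev[[length(ev) + 1L]] <- variant("del", refpos[starts[k]],
                                       ref = paste(sc[i], collapse = ""))
    } else {
      ev[[length(ev) + 1L]] <- variant("ins", refpos[starts[k]],
                                       alt = paste(pc[i], collapse = ""))
    }
  }
  events <- if (length(ev)) left_align_events(dplyr::bind_rows(ev), refseq)
            else empty_events()
  if (!mapped) events <- empty_events()
  list(events = events, key = event_key(events), mapped = mapped,
       divergence = divergence)
}

# canonical left-alignment of indels; a shift never crosses the previous
# event's reference span, so sets stay non-overlapping
left_align_events <- function(events, refseq) {
  ev <- sort_events(events)
  floor_pos <- 0L
  for (i in seq_len(nrow(ev))) {
    kind <- ev$kind[i]
    if (kind == "del") {
      pos <- ev$position[i]
      len <- nchar(ev$ref[i])
      while (pos - 1L > floor_pos &&
             substr(refseq, pos - 1L, pos - 1L) ==
             substr(refseq, pos + len - 1L, pos + len - 1L)) {
        pos <- pos - 1L
      }
      ev$position[i] <- pos
      ev$ref[i] <- substr(refseq, pos, pos + len - 1L)
      floor_pos <- pos + len - 1L
    } else if (kind == "ins") {
      pos <- ev$position[i]
      alt <- strsplit(ev$alt[i], "")[[1]]
      while (pos > floor_pos && pos >= 1L &&
             substr(refseq, pos, pos) == alt[length(alt)]) {
        alt <- c(alt[length(alt)], alt[-length(alt)])
        pos <- pos - 1L
      }
      ev$position[i] <- pos
      ev$alt[i] <- paste(alt, collapse = "")
      floor_pos <- pos
    } else {
      floor_pos <- ev$position[i] + nchar(ev$ref[i]) - 1L
    }
  }
  sort_events(ev)
}

#' Map merged reads to the reference and profile their variants
#'
#' Aligns each distinct merged sequence once ([align_to_reference()]),
#' extracts canonical variant profiles ([extract_variant_profile()]) and
#' joins them back onto the reads. The resulting event-set key strings are
#' the haplotype identities used downstream.
#'
#' @param reads A merged-read tibble (`id`, `bases`); unmerged rows (empty
#'   `bases`) are dropped.
#' @param reference An `amplicon_reference` or character scalar.
#' @param max_divergence Per-read divergence ceiling; beyond it the read is
#'   flagged unmapped (not an error).
#' @inheritParams align_to_reference
#' @return A tibble `id`, `bases`, `key`, `n_events`, `mapped`, `divergence`.
#' @export
map_reads <- function(reads, reference, max_divergence = 0.25, match = 1,
                      mismatch = -2, gap_opening = 5, gap_extension = 2) {
  reads <- reads[nzchar(reads$bases), , drop = FALSE]
  if (nrow(reads) == 0L) abort("no non-empty reads to map")
  refseq <- reference_sequence(reference)
  useq <- unique(reads$bases)
  is_ref <- useq == refseq
  prof <- vector("list", length(useq))
  prof[is_ref] <- list(list(key = "", n_events = 0L, mapped = TRUE,
                            divergence = 0))
  if (any(!is_ref)) {
    aln <- align_to_reference(useq[!is_ref], refseq, match = match,
                              mismatch = mismatch, gap_opening = gap_opening,
                              gap_extension = gap_extension)
    ap <- as.character(Biostrings::alignedPattern(aln))
    as_ <- as.character(Biostrings::alignedSubject(aln))
    prof[!is_ref] <- purrr::map2(ap, as_, function(p, s) {
      pr <- extract_variant_profile(p, s, max_divergence = max_divergence)
      list(key = pr$key, n_events = nrow(pr$events), mapped = pr$mapped,
           divergence = pr$divergence)
    })
  }
  lut <- tibble(
    bases = useq,
    key = vapply(prof, `[[`, character(1), "key"),
    n_events = vapply(prof, `[[`, integer(1), "n_events"),
    mapped = vapply(prof, `[[`, logical(1), "mapped"),
    divergence = vapply(prof, `[[`, numeric(1), "divergence")
  )
  dplyr::left_join(reads[, c("id", "bases")], lut, by = "bases")
}
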
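#' Variant events
#'
#' A variant event is one polymorphism relative to the amplicon reference, in
#' 1-based reference coordinates: a substitution of length >= 1 (length 1 is a
#' SNV, length 2 the classic "DNP", longer an MNV), an insertion (anchored to
#' the reference site *after which* the bases are inserted; 0 means before the
#' first base), or a deletion. Event sets are the identity of a haplotype:
#' the empty set is the reference haplotype itself.
#'
#' Events are plain tibbles with columns `kind` ("sub", "ins", "del"),
#' `position` (1-based; insertion anchor may be 0), `ref` (reference allele,
#' "" for insertions) and `alt` (alternate allele, "" for deletions).
#'
#' @param kind One of `"sub"`, `"ins"`, `"del"`.
#' @param position 1-based reference site (insertion: anchor site, may be 0).
#' @param ref Reference allele ("" for insertions).
#' @param alt Alternate allele ("" for deletions).
#' @return A one-row events tibble.
#' @examples
#' variant("sub", 61, "G", "T")
#' variant("ins", 224, "", "C")
#' @export
variant <- function(kind, position, ref = "", alt = "") {
  kind <- match.arg(kind, c("sub", "ins", "del"))
  position <- as.integer(position)
  if (is.na(position) || position < 0L) {
    abort("`position` must be a non-negative integer site.")
  }
  ok <- switch(kind,
    sub = nchar(ref) >= 1L && nchar(ref) == nchar(alt) && position >= 1L,
    ins = nchar(ref) == 0L && nchar(alt) >= 1L,
    del = nchar(ref) >= 1L && nchar(alt) == 0L && position >= 1L
  )
  if (!ok) {
    abort(sprintf("invalid alleles for a '%s' event (ref='%s', alt='%s')",
                  kind, ref, alt))
  }
  tibble(kind = kind, position = position, ref = ref, alt = alt)
}

#' Combine variant events into a canonical event set
#'
#' @param ... One-row event tibbles from [variant()], or event tibbles.
#' @return An events tibble sorted by position then kind.
#' @export
variants <- function(...) {
  ev <- dplyr::bind_rows(...)
  if (nrow(ev) == 0L) return(empty_events())
  sort_events(ev)
}

empty_events <- function() {
  tibble(kind = character(), position = integer(),
         ref = character(), alt = character())
}

sort_events <- function(events) {
  dplyr::arrange(events, .data$position, match(.data$kind, c("sub", "del", "ins")))
}

# reference span [start, end] occupied by each event; insertions occupy the
# zero-width boundary after `position`
event_span <- function(events) {
  start <- events$position + ifelse(events$kind == "ins", 1L, 0L)
  end <- ifelse(events$kind == "ins",
                events$position,
                events$position + nchar(events$ref) - 1L)
  list(start = start, end = end)
}

check_events <- function(events, ref_length) {
  if (nrow(events) == 0L) return(invisible(events))
  sp <- event_span(events)
  if (any(events$position > ref_length) || any(sp$end > ref_length)) {
    abort("variant event outside the reference bounds")
  }
  ev <- sort_events(events)
  sp <- event_span(ev)
  if (nrow(ev) > 1L) {
    # overlap when one event's span starts before the previous span has ended;
    # an insertion and a substitution may share a boundary but not a base
    prev_end <- cummax(c(-1L, utils::head(sp$end, -1L)))
    if (any(sp$start <= prev_end)) abort("overlapping variant events")
  }
  invisible(ev)
}

#' Compact string keys for event sets
#'
#' `event_key()` serialises an event set into the canonical compact string
#' used to group reads into haplotypes (and in TSV reports), e.g.
#' `"61G>T;220delAC;224insC"`. The empty string is the reference haplotype.
#' `parse_event_key()` is its inverse.
#'
#' @param events An events tibble.
#' @return `event_key()`: a length-1 string; `parse_event_key()`: an events
#'   tibble.
#' @export
event_key <- function(events) {
  if (nrow(events) == 0L) return("")
  ev <- sort_events(events)
  part <- ifelse(ev$kind == "sub", paste0(ev$position, ev$ref, ">", ev$alt),
          ifelse(ev$kind == "ins", paste0(ev$position, "ins", ev$alt),
                 paste0(ev$position, "del", ev$ref)))
  paste(part, collapse = ";")
}

#' @rdname event_key
#' @param key A compact event-set string.
#' @export
parse_event_key <- function(key) {
  stopifnot(length(key) == 1L)
  if (is.na(key) || key == "") return(empty_events())
  parts <- strsplit(key, ";", fixed = TRUE)[[1]]
  ev <- lapply(parts, function(p) {
    if (grepl("ins", p, fixed = TRUE)) {
      m <- regmatches(p, regexec("^([0-9]+)ins([ACGTN]+)$", p))[[1]]
      variant("ins", m[2], alt = m[3])
    } else if (grepl("del", p, fixed = TRUE)) {
      m <- regmatches(p, regexec("^([0-9]+)del([ACGTN]+)$", p))[[1]]
      variant("del", m[2], ref = m[3])
    } else {
      m <- regmatches(p, regexec("^([0-9]+)([ACGTN]+)>([ACGTN]+)$", p))[[1]]
      variant("sub", m[2], ref = m[3], alt = m[4])
    }
  })
  sort_events(dplyr::bind_rows(ev))
}

#' Apply a variant set to a reference sequence
#'
#' Realises the full-length sequence of a haplotype from its event set.
#' Substitutions preserve length; each insertion/deletion changes the length
#' by its allele length. The empty event set returns the reference unchanged.
#'
#' @param reference Reference sequence: a character scalar (optionally named)
#'   or an object from [generate_reference()].
#' @param events An events tibble (see [variant()]) or a compact key string.
#' @return The realised nucleotide string.
#' @examples
#' apply_variants("ACGTACGT", variant("sub", 2, "C", "T"))
#' @export
apply_variants <- function(reference, events) {
  refseq <- reference_sequence(reference)
  if (is.character(events) && length(events) == 1L) {
    events <- parse_event_key(events)
  }
  if (nrow(events) == 0L) return(unname(refseq))
  ev <- check_events(events, nchar(refseq))
  # verify ref alleles against the reference, then splice left to right
  out <- character(0)
  cursor <- 1L
  for (i in seq_len(nrow(ev))) {
    e <- ev[i, ]
    if (e$kind == "ins") {
      out <- c(out, substr(refseq, cursor, e$position), e$alt)
      cursor <- e$position + 1L
    } else {
      claimed <- substr(refseq, e$position, e$position + nchar(e$ref) - 1L)
      if (claimed != e$ref) {
        abort(sprintf("event at site %d claims ref '%s' but reference has '%s'",
                      e$position, e$ref, claimed))
      }
      out <- c(out, substr(refseq, cursor, e$position - 1L),
               if (e$kind == "sub") e$alt else "")
      cursor <- e$position + nchar(e$ref)
    }
  }
  paste0(paste(out, collapse = ""), substr(refseq, cursor, nchar(refseq)))
}

reference_sequence <- function(reference) {
  if (inherits(reference, "amplicon_reference")) return(reference$sequence)
  if (is.character(reference) && length(reference) == 1L) return(unname(reference))
  abort("`reference` must be a single sequence or an amplicon reference object")
}

reference_name <- function(reference, default = "amplicon") {
  if (inherits(reference, "amplicon_reference")) return(reference$name)
  nm <- names(reference)
  if (!is.null(nm) && nzchar(nm[1])) nm[1] else default
}
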
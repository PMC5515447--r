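#' Generate a random amplicon reference
#'
#' Draws a reference of i.i.d. bases with the requested GC content. The
#' realised GC fraction is binomial around `gc_fraction`, so for sequences of
#' a few hundred bases it lands within a few points of the request.
#'
#' @param length Reference length in bases (50 to 5000).
#' @param gc_fraction Target GC fraction, strictly between 0 and 1.
#' @param seed Integer seed; the same seed always yields the same sequence.
#' @param name Sequence name used in FASTA output.
#' @return An `amplicon_reference` object (list with `name` and `sequence`).
#' @examples
#' ref <- generate_reference(300, 0.5, seed = 7)
#' nchar(ref$sequence)
#' @export
generate_reference <- function(length, gc_fraction = 0.5, seed = 1,
                               name = "amplicon") {
  length <- as.integer(length)
  if (is.na(length) || length < 50L || length > 5000L) {
    abort("`length` must be between 50 and 5000 bases")
  }
  if (!(gc_fraction > 0 && gc_fraction < 1)) {
    abort("`gc_fraction` must be strictly between 0 and 1")
  }
  seq <- withr::with_seed(seed, {
    p <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
           G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
    paste(sample(names(p), length, replace = TRUE, prob = p), collapse = "")
  })
  structure(list(name = name, sequence = seq), class = "amplicon_reference")
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("<amplicon reference '%s': %d bp, GC %.3f>\n", x$name,
              nchar(x$sequence), gc_fraction_of(x$sequence)))
  invisible(x)
}

gc_fraction_of <- function(seq) {
  b <- strsplit(seq, "")[[1]]
  mean(b %in% c("G", "C"))
}

#' Read or write an amplicon reference as FASTA
#'
#' @param path FASTA file path.
#' @return `read_reference()`: an `amplicon_reference`; `write_reference()`:
#'   the path, invisibly.
#' @export
read_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) != 1L) abort("reference FASTA must contain exactly one record")
  structure(list(name = names(x)[1], sequence = as.character(x[[1]])),
            class = "amplicon_reference")
}

#' @rdname read_reference
#' @param reference An `amplicon_reference` or named character scalar.
#' @export
write_reference <- function(reference, path) {
  seq <- reference_sequence(reference)
  x <- Biostrings::DNAStringSet(setNames(seq, reference_name(reference)))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Define a ground-truth haplotype mixture
#'
#' A truth mixture fixes the haplotypes of a simulated library (each a variant
#' set relative to the reference), their true frequencies, the sequencing
#' error model and the library geometry.
#'
#' @param haplotypes A tibble with columns `haplotype_id`, `events` (list
#'   column of event tibbles, see [variant()]) and `frequency`.
#' @param error_rate Per-base substitution error probability.
#' @param indel_error_rate Per-base probability of a 1-bp spurious indel.
#' @param read_length Read length in bases (each mate).
#' @param n_pairs Number of read pairs.
#' @return A `truth_mixture` object.
#' @export
truth_mixture <- function(haplotypes, error_rate = 0.001,
                          indel_error_rate = 1e-5, read_length = 300,
                          n_pairs = 50000) {
  stopifnot(is.data.frame(haplotypes),
            all(c("haplotype_id", "events", "frequency") %in% names(haplotypes)))
  if (nrow(haplotypes) < 1L || any(haplotypes$frequency <= 0)) {
    abort("all haplotype frequencies must be positive")
  }
  if (abs(sum(haplotypes$frequency) - 1) > 1e-9) {
    abort("haplotype frequencies must sum to 1")
  }
  if (anyDuplicated(vapply(haplotypes$events, event_key, character(1)))) {
    abort("duplicate haplotype event sets in the mixture")
  }
  structure(list(haplotypes = as_tibble(haplotypes),
                 error_rate = error_rate,
                 indel_error_rate = indel_error_rate,
                 read_length = as.integer(read_length),
                 n_pairs = as.integer(n_pairs)),
            class = "truth_mixture")
}

#' Default five-haplotype study mixture
#'
#' Builds the package's canonical simulated condition: a dominant reference
#' haplotype plus four minor haplotypes carrying, respectively, a SNV, an
#' adjacent-pair substitution (DNP), a 1-bp insertion, and a 2-bp deletion,
#' at true frequencies 0.55/0.30/0.10/0.04/0.01. Variant sites follow the
#' conventions of published intragenomic ITS2 profiles (SNV near site 61,
#' insertion after site 224, deletion at site 220), scaled to the reference
#' length when the reference is shorter.
#'
#' @param reference An `amplicon_reference` (length >= 250 recommended).
#' @param frequencies True haplotype frequencies, summing to 1; the first is
#'   the reference haplotype.
#' @inheritParams truth_mixture
#' @return A `truth_mixture`.
#' @export
default_truth_mixture <- function(reference,
                                  frequencies = c(0.55, 0.30, 0.10, 0.04, 0.01),
                                  error_rate = 0.001, indel_error_rate = 1e-5,
                                  read_length = 300, n_pairs = 50000) {
  refseq <- reference_sequence(reference)
  L <- nchar(refseq)
  if (length(frequencies) > 5L) abort("at most five default haplotypes")
  site <- function(s) max(2L, min(L - 2L, as.integer(s)))
  base_at <- function(p, n = 1L) substr(refseq, p, p + n - 1L)
  other <- function(b) setdiff(c("A", "C", "G", "T"), strsplit(b, "")[[1]])[1]
  ev <- list(
    empty_events(),
    variants(variant("sub", site(61), base_at(site(61)), other(base_at(site(61))))),
    {
      p <- site(round(L * 0.35))
      b <- base_at(p, 2L)
      variants(variant("sub", p, b,
                       paste0(other(substr(b, 1, 1)), other(substr(b, 2, 2)))))
    },
    variants(variant("ins", site(224), alt = "C")),
    variants(variant("del", site(220) - 6L, ref = base_at(site(220) - 6L, 2L)))
  )
  # canonicalise (left-align indels) so truth keys match extracted profiles
  ev <- lapply(ev, left_align_events, refseq = refseq)
  hap <- tibble(
    haplotype_id = paste0("hap", seq_along(frequencies)),
    events = ev[seq_along(frequencies)],
    frequency = frequencies
  )
  truth_mixture(hap, error_rate = error_rate,
                indel_error_rate = indel_error_rate,
                read_length = read_length, n_pairs = n_pairs)
}

#' Illumina overhang adapter pair
#'
#' The forward/reverse overhang sequences placed 5' of the locus-specific
#' primers in two-stage amplicon library preparation. A read that runs past
#' the far end of a short fragment continues into the reverse complement of
#' the opposite overhang; [readthrough_adapters()] returns those read-through
#' sequences, which is what [trim_adapters()] should be given.
#'
#' @return Named character vector of length 2 (`forward`, `reverse`).
#' @export
illumina_overhangs <- function() {
  c(forward = "TCGTCGGCAGCGTCAGATGTGTATAAGAGACAG",
    reverse = "GTCTCGTGGGCTCGGAGATGTGTATAAGAGACAG")
}

#' @rdname illumina_overhangs
#' @param adapters Named pair of overhang sequences.
#' @export
readthrough_adapters <- function(adapters = illumina_overhangs()) {
  c(forward = revcomp(adapters[["reverse"]]),
    reverse = revcomp(adapters[["forward"]]))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Simulate a paired-end amplicon library in memory
#'
#' Each read pair is drawn from one haplotype by multinomial sampling on the
#' true frequencies. The forward read is the 5' prefix of the fragment and
#' the reverse read the reverse complement of its 3' suffix; when the fragment
#' is shorter than the read length the read runs through into the opposite
#' adapter. Substitution errors are injected per base at `error_rate` (the
#' erroneous base gets a low quality score; correct bases get Q37, with an
#' optional linear 3' decay), and 1-bp indel errors at `indel_error_rate`.
#'
#' @param reference An `amplicon_reference`.
#' @param mixture A [truth_mixture()].
#' @param seed Integer seed; fixes reads, errors and qualities.
#' @param adapters Overhang pair, see [illumina_overhangs()].
#' @param quality_decay If `TRUE`, base quality decays linearly from Q37 to
#'   Q30 over the final third of each read (errors are unaffected).
#' @return A list with tibbles `forward`, `reverse` (columns `id`, `bases`,
#'   `quals`) and `truth` (columns `read_id`, `haplotype_id`).
#' @export
simulate_reads <- function(reference, mixture, seed = 1,
                           adapters = illumina_overhangs(),
                           quality_decay = FALSE) {
  stopifnot(inherits(mixture, "truth_mixture"))
  refseq <- reference_sequence(reference)
  n <- mixture$n_pairs
  if (n < 1L) abort("`n_pairs` must be at least 1")
  rl <- mixture$read_length
  frags <- vapply(mixture$haplotypes$events, function(e) {
    apply_variants(refseq, e)
  }, character(1))
  if (any(nchar(frags) >= 2L * rl - 10L)) {
    abort("amplicon too long for the read length to merge (needs < 2*read_length - 10)")
  }
  rt <- readthrough_adapters(adapters)
  withr::with_seed(seed, {
    counts <- as.integer(rmultinom(1, n, mixture$haplotypes$frequency))
    hap_of <- sample(rep.int(seq_along(counts), counts))
    fwd_t <- substr(paste0(frags, rt[["forward"]]), 1L, rl)
    rev_t <- substr(paste0(vapply(frags, revcomp, character(1)), rt[["reverse"]]),
                    1L, rl)
    fwd <- inject_errors(fwd_t[hap_of], mixture$error_rate,
                         mixture$indel_error_rate)
    rev <- inject_errors(rev_t[hap_of], mixture$error_rate,
                         mixture$indel_error_rate)
    ids <- sprintf("read_%06d", seq_len(n))
    list(
      forward = tibble(id = ids, bases = fwd$bases,
                       quals = quality_strings(fwd, quality_decay)),
      reverse = tibble(id = ids, bases = rev$bases,
                       quals = quality_strings(rev, quality_decay)),
      truth = tibble(read_id = ids,
                     haplotype_id = mixture$haplotypes$haplotype_id[hap_of])
    )
  })
}

# substitution + 1-bp indel errors; returns bases plus per-read error positions
inject_errors <- function(reads, error_rate, indel_error_rate) {
  n <- length(reads)
  len <- nchar(reads)
  err_pos <- vector("list", n)
  if (error_rate > 0 || indel_error_rate > 0) {
    n_sub <- rbinom(n, len, error_rate)
    n_ind <- rbinom(n, len, indel_error_rate)
    hit <- which(n_sub > 0L | n_ind > 0L)
    bases <- c("A", "C", "G", "T")
    for (i in hit) {
      ch <- strsplit(reads[i], "")[[1]]
      pos <- integer(0)
      if (n_sub[i] > 0L) {
        pos <- sample.int(length(ch), min(n_sub[i], length(ch)))
        for (p in pos) ch[p] <- sample(setdiff(bases, ch[p]), 1L)
      }
      if (n_ind[i] > 0L) {
        p <- sample.int(length(ch), 1L)
        if (stats::runif(1) < 0.5 && length(ch) > 1L) {
          ch <- ch[-p]
          pos <- c(pos[pos < p], pos[pos > p] - 1L)
        } else {
          ch <- append(ch, sample(bases, 1L), after = p)
          pos <- c(pos[pos <= p], pos[pos > p] + 1L, p + 1L)
        }
      }
      reads[i] <- paste(ch, collapse = "")
      err_pos[[i]] <- pos
    }
  }
  list(bases = reads, err_pos = err_pos)
}

# Q37 baseline ('F'), optional decay to Q30 over the final third, error
# positions drawn in Q5..Q20 so that overlap consensus can out-vote them
quality_strings <- function(x, quality_decay) {
  len <- nchar(x$bases)
  qvec_for <- function(L) {
    q <- rep.int(37L, L)
    if (quality_decay && L > 3L) {
      ts <- ceiling(2 * L / 3)
      idx <- ts:L
      q[idx] <- 37L - round(7 * (idx - ts) / max(1L, L - ts))
    }
    q
  }
  out <- character(length(len))
  nerr <- lengths(x$err_pos)
  clean <- nerr == 0L
  if (any(clean)) {
    cache <- vapply(sort(unique(len[clean])),
                    function(L) intToUtf8(qvec_for(L) + 33L), character(1))
    names(cache) <- sort(unique(len[clean]))
    out[clean] <- cache[as.character(len[clean])]
  }
  for (i in which(!clean)) {
    q <- qvec_for(len[i])
    ep <- x$err_pos[[i]]
    ep <- ep[ep >= 1L & ep <= len[i]]
    if (length(ep)) q[ep] <- 4L + sample.int(16L, length(ep), replace = TRUE)
    out[i] <- intToUtf8(q + 33L)
  }
  out
}

#' Simulate a library and write it to disk
#'
#' Writes the reference FASTA, the paired FASTQ files (Phred+33), the truth
#' table (TSV: `read_id`, `haplotype_id`) and a manifest echoing every
#' parameter and seed. Output is byte-identical for a fixed seed.
#'
#' @inheritParams simulate_reads
#' @param out_dir Output directory (created if missing).
#' @return Invisibly, a list of file paths plus the in-memory library.
#' @export
simulate_library <- function(reference, mixture, out_dir, seed = 1,
                             adapters = illumina_overhangs(),
                             quality_decay = FALSE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  lib <- simulate_reads(reference, mixture, seed = seed, adapters = adapters,
                        quality_decay = quality_decay)
  paths <- list(
    reference = file.path(out_dir, "reference.fasta"),
    r1 = file.path(out_dir, "reads_R1.fastq"),
    r2 = file.path(out_dir, "reads_R2.fastq"),
    truth = file.path(out_dir, "truth.tsv"),
    manifest = file.path(out_dir, "manifest.tsv")
  )
  write_reference(reference, paths$reference)
  write_fastq(lib$forward, paths$r1)
  write_fastq(lib$reverse, paths$r2)
  readr::write_tsv(lib$truth, paths$truth)
  manifest <- tibble(
    key = c("reference_name", "reference_length", "n_pairs", "read_length",
            "error_rate", "indel_error_rate", "seed", "n_haplotypes",
            "haplotype_keys", "true_frequencies"),
    value = c(reference_name(reference),
              nchar(reference_sequence(reference)),
              mixture$n_pairs, mixture$read_length, mixture$error_rate,
              mixture$indel_error_rate, seed, nrow(mixture$haplotypes),
              paste(vapply(mixture$haplotypes$events, event_key, character(1)),
                    collapse = "|"),
              paste(mixture$haplotypes$frequency, collapse = "|"))
  )
  readr::write_tsv(manifest, paths$manifest)
  invisible(c(paths, list(library = lib)))
}
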
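---
title: "Profiling intragenomic amplicon variation: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling intragenomic amplicon variation: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(amplihap)
```

## The measurement model

A multi-copy locus such as the rRNA ITS2 is amplified from one genome and
sequenced deeply with overlapping paired reads. Under the model, each merged
read pair is a (noisy) observation of one repeat copy, drawn independently
from the genome's copy pool. The quantity of interest is the *haplotype
frequency spectrum*: the set of distinct full-length amplicon sequences
present and the fraction of copies carrying each. A haplotype is identified
with its set of variant events relative to a reference sequence —
substitutions of length ≥ 1 (length 2 being the classic DNP), insertions and
deletions, in 1-based reference coordinates — because the full-length
sequence, not the individual polymorphism, is the unit that downstream
phylogenetic analysis uses. The empty event set is the reference haplotype.

Three noise processes separate observations from the copy pool: sequencing
error (per-base substitutions and rarer indels), the binomial/multinomial
sampling of copies into reads, and read-pair merging artefacts. The pipeline
addresses them, respectively, with a frequency threshold on *demonstrable*
variants, with repeated random subsampling that makes the sampling scale
explicit and reproducible, and with quality-weighted overlap consensus.

## Pipeline stages and the parameters that matter

**Filtering** (`filter_read_pairs()`): reads shorter than `min_length`
(default 250 bases) or with mean Phred quality below `min_mean_quality`
(default Q30) are dropped, a pair failing when either mate fails. The
quality criterion is deliberately a *mean*: a per-base floor of Q30 would
discard essentially every 2×300 read, which is incompatible with the read
yields such protocols report. This interpretation is recorded here as an
assumption; vendor "QC value" semantics are not standardised.

**Adapter trimming** (`trim_adapters()`): a read that runs past a short
fragment continues into the reverse complement of the opposite library
adapter. Any read suffix matching an adapter prefix with ≥ 8 bases and ≤ 1
mismatch is removed. With the default 350-bp amplicon and 300-bp reads no
read-through occurs; the stage matters for fragments shorter than the read.

**Merging** (`merge_pairs()`): the reverse mate is reverse-complemented and
the overlap maximising length subject to a mismatch fraction ≤
`max_mismatch_frac` (default 0.1) is selected, scanning from the largest
conceivable overlap downward; ties cannot arise because overlap length is
strictly monotone in the offset, and the first admissible offset is taken —
a deterministic rule. Within the overlap the higher-quality base wins, ties
going to the forward read, and the consensus quality is the maximum of the
two. Failure to find an admissible overlap marks the pair unmerged rather
than raising an error. Defaults `min_overlap = 30` and mismatch fraction 0.1
are conventional amplicon-merging values and configurable.

**Mapping** (`map_reads()`): merged reads are aligned globally to the
reference under affine-gap scoring (+1 match, −2 mismatch, gap cost
5 + 2·L). Global alignment is the right shape because primer-defined
amplicons span the locus; a read whose alignment has a terminal gap run
longer than 5 columns does not span it and is flagged unmapped, as is any
read whose divergence — (mismatched + gapped columns)/reference length —
exceeds `max_divergence` (default 0.25, chosen so that even the most
divergent within-genus haplotypes, with p-distances below ~0.17, map
comfortably while unrelated sequence does not). Each alignment is reduced to
a canonical event set: runs of adjacent mismatches collapse into one
multi-nucleotide substitution, and indels are left-aligned to their
lowest-position equivalent placement. Left-alignment replaces the
arbitrariness of indel placement inside homopolymers with a fixed
convention, so that identical sequences always yield identical event sets —
the property haplotype identity rests on. Alignment itself is delegated to
`Biostrings::pairwiseAlignment()`; the extraction and canonicalisation
rules are this package's.

**Subsampling and calling** (`subsample_profiles()`, `call_haplotypes()`,
`build_profile()`): `n_subsamples` (default 5) subsets of `subsample_size`
(default 10,000) mapped reads are drawn uniformly without replacement,
replicate *r* using the derived seed `seed + r`; when fewer mapped reads
exist the full set is used once per replicate with a warning. Mapping
every merged read once and then subsampling read profiles is statistically
identical to subsampling reads and re-mapping, and exactly repeatable.
Within each subsample every distinct event set is a haplotype and its
frequency is its share of the subsample; frequencies therefore sum to 1 by
construction. Averaging across subsamples, absent haplotypes counting as 0,
gives the profile.

**The demonstrable-variant threshold.** The retention rule operates at two
levels, both on *averaged* frequencies and both inclusive (≥ `threshold`,
default 1%):

1. every individual variant event below the threshold is *not
   demonstrable* and is masked from every read's event set;
2. haplotypes are re-grouped on the masked sets, and those below the
   threshold are reported as a single background bucket.

Step 1 is what makes the estimator usable at realistic error rates. A
per-base error of 10⁻³ on a 350-bp amplicon leaves roughly a quarter to a
third of merged reads carrying at least one error even after overlap
consensus (errors in single-coverage segments cannot be corrected). Without
masking, each such read would found its own spurious singleton haplotype
and the true haplotype frequencies would be deflated by tens of percentage
points; with masking, error-bearing reads rejoin their parent haplotype,
because each *specific* error variant is rare (~e/3 per site per base, well
under 0.1%) even though errors in aggregate are common. Sub-threshold true
variants are indistinguishable from this background by construction and are
absorbed the same way — that is the stated detection limit of the protocol,
not a defect. `build_profile(mask_events = FALSE)` exposes the raw
unmasked grouping for diagnostics.

**Dominance** (`dominant_haplotype()`): the retained haplotype with the
highest averaged frequency. Two haplotypes are *co-dominant* when the top
two averaged frequencies differ by less than `codominance_margin` (default
0.05, chosen because a top-two gap of ~0.03–0.04 is the scale at which
replicate runs of the same template disagree about which haplotype leads).

## Diversity statistics

`p_distance()` is the proportion of differing sites among compared sites,
excluding per pair every alignment column with a gap in either sequence
(pairwise deletion). Pairwise deletion keeps indel-bearing haplotypes
comparable with their relatives; a complete-deletion treatment would
discard every gapped column for all pairs. Unaligned inputs are pairwise
aligned with the same affine scheme as mapping. `group_mean_distances()`
averages over all unordered pairs within a group (singleton groups are
marked undefined) and all cross pairs between groups; the grand means are
*unweighted* means of the listed group values, matching how summary "Mean"
rows of such tables are conventionally formed. `replicate_summary()` uses
the sample (n−1) standard deviation and SE = SD/√n. The group comparison
test (`compare_groups_ttest()`) defaults to the unequal-variance Welch
form — which is also the form that reproduces published within- vs
between-group comparisons of this kind — with the pooled form available.

## Trees

`nj_tree()` validates the distance matrix (symmetry to 1e−12, zero
diagonal, non-negativity) and runs classic Saitou–Nei neighbor joining via
`ape::nj()`. The occasional negative branch length is clamped to zero with
the deficit moved to its sibling edge, the standard deterministic repair.
`bootstrap_supports()` resamples alignment columns with replacement,
rebuilds the tree per replicate and reports the percentage of replicates
containing each internal split of the original tree. Zero-length internal
edges are collapsed before split counting, so an alignment with no variable
columns yields a star tree with no resolved, supportable edges rather than
a spuriously "100%-supported" arbitrary topology. Supports are invariant to
taxon order for a fixed seed-to-column mapping.

## The simulator: what it emulates and what it does not

`simulate_library()` draws each read pair's source haplotype from a
multinomial on the true frequencies (deliberately not fixed proportions:
frequency-recovery tests need genuine sampling noise), takes the forward
read as the fragment's 5′ prefix and the reverse read as the reverse
complement of its 3′ suffix, appends adapter read-through only when the
fragment is shorter than the read, and injects substitution errors per base
at `error_rate` plus 1-bp indels at `indel_error_rate`. Base qualities are
Q37, with an optional linear 3′ decay to Q30 over the final third of the
read; error positions are emitted with low quality (Q4–Q19), consistent
with the error model, which lets overlap consensus correct double-covered
errors the way real merging software does.

Defaults describe the canonical study condition: a 350-bp reference at GC
0.5, 2×300 reads, 50,000 pairs, substitution error 10⁻³ per base (chosen so
that individual spurious variants sit around or below 0.1% of reads — the
background level at which sub-threshold variants are observed in deep
amplicon profiles), indel error 10⁻⁵, and truth frequencies
0.55/0.30/0.10/0.04/0.01 with a variant repertoire containing an SNV, an
adjacent-pair DNP, a 1-bp insertion and a 2-bp deletion (left-aligned at
construction so truth keys equal extracted keys).

The simulator does **not** model PCR amplification bias between primer
variants, chimera formation, quality-dependent error spectra beyond the
low-quality flag, or copy-number drift between extracts. Passing tests
therefore demonstrate correctness of the estimator under multinomial
sampling plus independent per-base error — they bound, but cannot certify,
behaviour on real libraries where PCR bias can systematically under-sample
haplotypes whose priming sites vary.

## Numerical and degenerate-input choices

- Thresholds are inclusive (≥) at both the event and haplotype level, with
  a 1e−12 guard against floating-point undershoot of exact ratios.
- Haplotype labels H1, H2, … are assigned by descending averaged frequency
  with lexicographic key order breaking exact ties — stable under re-runs
  with the same seed.
- Consensus base on equal qualities: the forward read wins (documented,
  deterministic).
- An empty read, an empty mapped-read pool, a singleton group asked for a
  within-mean, a degenerate t-test (both groups constant and equal), and a
  grouping id missing from the FASTA all raise explicit errors; merge
  failure and unmapped reads are *states*, not errors, and are reported in
  the pipeline statistics.
- A truth frequency lying exactly on the threshold is retained or masked
  according to the realised multinomial draw of the library — the estimator
  is unbiased there, so over repeated libraries it is retained about half
  the time; this is the knife-edge inherent in any sharp threshold.

## Problem sizes

The test suite exercises the full study-scale condition once (50,000 pairs,
5 × 10,000 subsampling) and otherwise uses reduced but structurally
identical libraries (hundreds to thousands of pairs, subsamples of
300–10,000, bootstrap replicates of 50–500), sizes at which every binomial
tolerance in the tests is still meaningful. `scripts/acceptance.R` re-runs
the study-scale condition end to end.

## Known limitations

- Per-read agreement with any specific vendor mapping tool is not claimed;
  the affine-gap scheme is a documented substitute for undocumented
  commercial defaults.
- Haplotypes rarer than the threshold are invisible by design; lowering the
  threshold trades error robustness for sensitivity.
- Sequence-structure-aware alignment and maximum-likelihood tree search are
  out of scope; the distance trees here are sequence-only.
- With co-dominant haplotypes the identity of H1 can flip between replicate
  libraries whose top-two frequencies differ by less than the sampling
  noise; `dominant_haplotype()` flags exactly this situation.
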
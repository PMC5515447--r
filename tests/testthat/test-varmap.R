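test_that("alignment scores follow the affine scheme", {
  ref <- generate_reference(200, 0.5, seed = 1)
  a0 <- align_to_reference(ref$sequence, ref)
  expect_equal(Biostrings::score(a0), 200)

  mut <- apply_variants(ref, variant("sub", 61, substr(ref$sequence, 61, 61),
                                     setdiff(c("A", "C", "G", "T"),
                                             substr(ref$sequence, 61, 61))[1]))
  expect_equal(Biostrings::score(align_to_reference(mut, ref)),
               (200 - 1) * 1 - 2)

  del1 <- paste0(substr(ref$sequence, 1, 99), substr(ref$sequence, 101, 200))
  expect_equal(Biostrings::score(align_to_reference(del1, ref)),
               199 * 1 - (5 + 2))
})

test_that("single-base deletions are recovered at their left-aligned site", {
  ref <- generate_reference(120, 0.5, seed = 5)
  for (cut in c(30L, 60L, 90L)) {
    read <- paste0(substr(ref$sequence, 1, cut - 1),
                   substr(ref$sequence, cut + 1, 120))
    aln <- align_to_reference(read, ref)
    prof <- extract_variant_profile(
      as.character(Biostrings::alignedPattern(aln)),
      as.character(Biostrings::alignedSubject(aln)))
    expect_true(prof$mapped)
    expect_identical(nrow(prof$events), 1L)
    expect_identical(prof$events$kind, "del")
    expect_identical(nchar(prof$events$ref), 1L)
    # brute-force oracle: the canonical site is the smallest deletion
    # position that reproduces the read
    sites <- which(vapply(seq_len(120), function(p) {
      paste0(substr(ref$sequence, 1, p - 1),
             substr(ref$sequence, p + 1, 120)) == read
    }, logical(1)))
    expect_identical(prof$events$position, min(sites))
    # round trip
    expect_identical(apply_variants(ref, prof$events), read)
  }
})

test_that("adjacent mismatches collapse into one multi-base substitution", {
  ref <- generate_reference(300, 0.5, seed = 9)
  b <- substr(ref$sequence, 100, 101)
  alt <- paste0(setdiff(c("A", "C", "G", "T"), substr(b, 1, 1))[1],
                setdiff(c("A", "C", "G", "T"), substr(b, 2, 2))[1])
  read <- apply_variants(ref, variant("sub", 100, b, alt))
  prof <- map_reads(reads_tbl(read), ref)
  expect_identical(prof$key, paste0("100", b, ">", alt))
  expect_identical(prof$n_events, 1L)
})

test_that("insertions anchor to the preceding reference site", {
  ref <- generate_reference(300, 0.5, seed = 10)
  # ensure the insertion is not absorbed into a homopolymer: use a base
  # different from site 224 and site 225
  ins_base <- setdiff(c("A", "C", "G", "T"),
                      c(substr(ref$sequence, 224, 224),
                        substr(ref$sequence, 225, 225)))[1]
  read <- apply_variants(ref, variant("ins", 224, alt = ins_base))
  prof <- map_reads(reads_tbl(read), ref)
  expect_identical(prof$key, paste0("224ins", ins_base))
})

test_that("indels left-align inside homopolymers", {
  ref <- paste0(random_seq(40, 3), "AAAAA", random_seq(40, 4))
  # delete the last A of the run (positions 41..45): canonical site is 41
  read <- paste0(substr(ref, 1, 44), substr(ref, 46, nchar(ref)))
  aln <- align_to_reference(read, ref)
  prof <- extract_variant_profile(
    as.character(Biostrings::alignedPattern(aln)),
    as.character(Biostrings::alignedSubject(aln)))
  expect_identical(prof$key, "41delA")
  # insert one more A anywhere in the run: canonical anchor is site 40
  read2 <- paste0(substr(ref, 1, 43), "A", substr(ref, 44, nchar(ref)))
  aln2 <- align_to_reference(read2, ref)
  prof2 <- extract_variant_profile(
    as.character(Biostrings::alignedPattern(aln2)),
    as.character(Biostrings::alignedSubject(aln2)))
  expect_identical(prof2$key, "40insA")
})

test_that("profile extraction round-trips on randomly mutated reads", {
  ref <- generate_reference(250, 0.5, seed = 20)
  for (s in 1:12) {
    read <- withr::with_seed(s, {
      x <- strsplit(ref$sequence, "")[[1]]
      # up to 3 random substitutions plus possibly a small indel
      for (p in sample(20:230, sample(0:3, 1))) {
        x[p] <- sample(setdiff(c("A", "C", "G", "T"), x[p]), 1)
      }
      if (s %% 3 == 0) {
        p <- sample(30:220, 1)
        x <- append(x, sample(c("A", "C", "G", "T"), 1), after = p)
      }
      if (s %% 4 == 0) {
        p <- sample(30:220, 1)
        x <- x[-p]
      }
      paste(x, collapse = "")
    })
    prof <- map_reads(reads_tbl(read), ref)
    expect_true(prof$mapped)
    expect_identical(apply_variants(ref, prof$key), read)
  }
})

test_that("identical event sets imply identical sequences and vice versa", {
  ref <- generate_reference(200, 0.5, seed = 30)
  reads <- c(
    ref$sequence,
    apply_variants(ref, variant("sub", 50, substr(ref$sequence, 50, 50),
                                setdiff(c("A", "C", "G", "T"),
                                        substr(ref$sequence, 50, 50))[1])),
    ref$sequence)
  prof <- map_reads(reads_tbl(reads), ref)
  expect_identical(prof$key[1], prof$key[3])
  expect_false(prof$key[1] == prof$key[2])
  expect_identical(prof$key[1], "")
})

test_that("divergent and non-spanning reads are flagged unmapped", {
  ref <- generate_reference(200, 0.5, seed = 31)
  junk <- random_seq(200, seed = 99)
  prof <- map_reads(reads_tbl(junk), ref)
  expect_false(prof$mapped)
  expect_identical(prof$key, "")
  # a read missing 30 leading bases does not span the reference
  partial <- substr(ref$sequence, 31, 200)
  prof2 <- map_reads(reads_tbl(partial), ref)
  expect_false(prof2$mapped)
})
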
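test_that("linear comparison resolves identity and single substitutions", {
  r <- linear_compare("ACGTACGT", "ACGTACGT")
  expect_equal(r$status, "resolved")
  expect_equal(nrow(r$variants), 0)

  r <- linear_compare("ACGAACGT", "ACGTACGT", chrom = "chr1", ref_start = 10L)
  expect_equal(r$status, "resolved")
  expect_equal(r$variants$pos, 13L)
  expect_equal(r$variants$ref, "T")
  expect_equal(r$variants$alt, "A")
  expect_equal(r$variants$vclass, "SNV")

  # two mismatches (offsets 3 and 6) force the fallback in thorough mode
  r <- linear_compare("ACTTAGGT", "ACGTACGT")
  expect_equal(r$status, "fallback")

  # masked bases never mismatch
  r <- linear_compare("ACNTACGT", "ACGTACGT")
  expect_equal(nrow(r$variants), 0)
})

test_that("fast mode accepts well-separated mismatches and rejects clusters", {
  ref <- strrep("A", 30)
  far <- mutate_base(mutate_base(ref, 5, "C"), 25, "G")     # separation 20
  near <- mutate_base(mutate_base(ref, 5, "C"), 8, "G")     # separation 3

  expect_equal(linear_compare(far, ref, mode = "thorough")$status, "fallback")
  rf <- linear_compare(far, ref, mode = "fast", fast_gap = 5)
  expect_equal(rf$status, "resolved")
  expect_equal(rf$variants$pos, c(5L, 25L))
  expect_equal(linear_compare(near, ref, mode = "fast", fast_gap = 5)$status,
               "fallback")

  # with a huge fast_gap and <= 1 mismatch, fast behaves like thorough
  one <- mutate_base(ref, 9, "T")
  expect_equal(linear_compare(one, ref, mode = "fast", fast_gap = 10000L),
               linear_compare(one, ref, mode = "thorough"))
})

test_that("gapped alignment matches exhaustive enumeration on tiny cases", {
  sc <- align_scoring()
  # identity: no gaps, score = match * length
  g <- gapped_align("ACGT", "ACGT", sc)
  expect_equal(g$score, 4 * sc$match)
  expect_equal(g$read, g$ref)

  cases <- list(c("ACTT", "ACGTT"),      # 1-base deletion in the read
                c("ACGTTA", "ACTA"),     # 2-base insertion
                c("ACGGT", "ACGGGT"),    # deletion in a homopolymer
                c("TTACG", "TTCG"))
  for (cs in cases) {
    g <- gapped_align(cs[1], cs[2], sc)
    best <- best_alignments(cs[1], cs[2], sc)
    expect_equal(g$score, score_alignment(best[[1]], sc))
    expect_true(any(vapply(best, function(al)
      identical(al$read, g$read) && identical(al$ref, g$ref), logical(1))))
  }
})

test_that("alignment columns convert to anchored, left-normalised variants", {
  # single substitution column
  g <- gapped_align("ACGTAG", "ACGTAC")
  v <- alignment_variants(g, "chr1", 100L)
  expect_equal(v, tibble::tibble(chrom = "chr1", pos = 105L, ref = "C",
                                 alt = "G", vclass = "SNV"))

  # identical sequences: nothing
  expect_equal(nrow(alignment_variants(gapped_align("ACGT", "ACGT"))), 0)

  # 2-base deletion inside a homopolymer lands at the homopolymer start
  ref <- "TACGGGGGTA"
  read <- "TACGGGTA"
  v <- alignment_variants(gapped_align(read, ref), "chr1", 1L, ref_seq = ref)
  expect_equal(v$pos, 3L)
  expect_equal(v$ref, "CGG")
  expect_equal(v$alt, "C")
  expect_equal(v$vclass, "deletion")

  # consistency check against a wrong reference errors
  expect_error(alignment_variants(gapped_align("ACGT", "ACGT"), ref_seq = "TTTT"),
               "does not match")
})

test_that("indel left-normalisation is correct and idempotent", {
  ref <- "TTAGGGGACT"
  # deletion of one G reported at the rightmost slot of the homopolymer
  v <- left_align_indel(6L, "GG", "G", ref, 1L)
  expect_equal(v, list(pos = 3L, ref = "AG", alt = "A"))
  # idempotent
  expect_equal(left_align_indel(v$pos, v$ref, v$alt, ref, 1L), v)

  # insertion of GG in the homopolymer
  vi <- left_align_indel(6L, "G", "GGG", ref, 1L)
  expect_equal(vi, list(pos = 3L, ref = "A", alt = "AGG"))
  expect_equal(left_align_indel(vi$pos, vi$ref, vi$alt, ref, 1L), vi)

  # normalisation respects the left bound of the provided context
  vb <- left_align_indel(6L, "GG", "G", substring(ref, 5), 5L)
  expect_equal(vb$pos, 5L)
})

test_that("resolved linear comparisons agree with the gapped route", {
  withr::with_seed(31, {
    for (i in 1:60) {
      ref <- rand_dna(sample(20:50, 1))
      read <- if (i %% 2 == 0) ref else mutate_base(ref, sample(nchar(ref), 1))
      lin <- linear_compare(read, ref, chrom = "c", ref_start = 1L)
      expect_equal(lin$status, "resolved")
      via_aln <- alignment_variants(gapped_align(read, ref), "c", 1L,
                                    ref_seq = ref)
      expect_equal(lin$variants, via_aln)
    }
  })
})

test_that("compare_insert confines variants to tile coordinates", {
  idx <- toy_index(insert = "ACGTTGCAACGGATTACGGATCGTTAGGCA")
  tile <- idx$tiles[1, ]

  # clean insert resolves with no variants
  r <- compare_insert(tile$insert_ref, tile, "fwd")
  expect_equal(r$status, "resolved")
  expect_equal(nrow(r$variants), 0)

  # a truncated reverse-side read maps to the 3' end of the tile
  tail_ins <- substring(tile$insert_ref, 6)
  pos_in_tile <- 10L
  mut <- mutate_base(tail_ins, pos_in_tile)
  r <- compare_insert(mut, tile, "rev")
  expect_equal(r$variants$pos, tile$start + 5L + pos_in_tile - 1L)

  # an interior deletion falls back and is reported in tile coordinates
  del_ins <- paste0(substr(tile$insert_ref, 1, 14), substring(tile$insert_ref, 18))
  r <- compare_insert(del_ins, tile, "fwd")
  expect_equal(r$status, "fallback")
  expect_equal(r$variants$vclass, "deletion")
  orc <- oracle_single_indel(del_ins, tile$insert_ref, tile$chrom, tile$start)
  expect_equal(r$variants$pos, orc$pos)
  expect_equal(r$variants$ref, orc$ref)
  expect_equal(r$variants$alt, orc$alt)
})
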
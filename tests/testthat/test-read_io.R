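test_that("paired FASTQ files stream in lock-step, plain or gzipped", {
  d <- withr::local_tempdir()
  f1 <- write_fastq_plain(file.path(d, "r1.fastq"), c("a/1", "b/1"),
                          c("ACGT", "GGGG"), c("IIII", "IIII"))
  f2 <- write_fastq_plain(file.path(d, "r2.fastq"), c("a/2", "b/2"),
                          c("TTTT", "CCCC"), c("IIII", "IIII"))
  pairs <- stream_pairs(f1, f2)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$id, c("a", "b"))
  expect_equal(pairs$read1, c("ACGT", "GGGG"))
  expect_equal(pairs$read2, c("TTTT", "CCCC"))

  # gzip-compressed input gives identical output
  g1 <- file.path(d, "r1.fastq.gz"); g2 <- file.path(d, "r2.fastq.gz")
  for (fg in list(c(f1, g1), c(f2, g2))) {
    con <- gzfile(fg[2], "w"); writeLines(readLines(fg[1]), con); close(con)
  }
  expect_equal(stream_pairs(g1, g2), pairs)

  # unequal record counts are fatal
  f3 <- write_fastq_plain(file.path(d, "r3.fastq"), "a/1", "ACGT", "IIII")
  expect_error(stream_pairs(f3, f2), "unequal record counts")
})

test_that("perfect pairs bind to their tile with plus-strand inserts", {
  idx <- toy_index()
  tile <- idx$tiles[1, ]
  pair <- perfect_pair(tile)
  b <- bin_pair(pair, idx)
  expect_equal(b$status, "bound")
  expect_equal(b$ins_fwd, tile$insert_ref)
  expect_equal(b$ins_rev, tile$insert_ref)
  expect_equal(b$len_fwd, tile$insert_len)

  # swapped mates (read 1 carries the reverse primer) still bind
  swapped <- pair
  swapped$read1 <- pair$read2; swapped$read2 <- pair$read1
  swapped$qual1 <- pair$qual2; swapped$qual2 <- pair$qual1
  b2 <- bin_pair(swapped, idx)
  expect_equal(b2$status, "bound")
  expect_equal(b2$ins_fwd, tile$insert_ref)
})

test_that("prefix mismatches, chimeras and same-orientation pairs are unassigned", {
  insert2 <- rand_dna(30)
  withr::with_seed(42, {
    idx2 <- build_tile_index(
      tibble::tibble(chrom = "chr1", start = c(16L, 76L), end = c(45L, 105L),
                     fwd_name = c("T1_F", "T2_F"), rev_name = c("T1_R", "T2_R")),
      tibble::tibble(name = c("T1_F", "T1_R", "T2_F", "T2_R"),
                     sequence = c("GGATCCTTAG", revcomp("CCTAGGATCC"),
                                  "ATTGCAGTCA", revcomp("GACTGCAATT"))),
      list(chr1 = paste0("TTTTT", "GGATCCTTAG",
                         "ACGTACGTACGTACGTACGTACGTACGTAC", "CCTAGGATCC",
                         "TTTTTTTTTT", "ATTGCAGTCA", insert2, "GACTGCAATT",
                         "TTTTT")),
      prefix_len = 10)
  })
  t1 <- idx2$tiles[1, ]; t2 <- idx2$tiles[2, ]
  p <- perfect_pair(t1)

  # any mutation within the first N bases of a mate -> unassigned
  for (pos in c(1, 5, 10)) {
    pm <- p; pm$read1 <- mutate_base(p$read1, pos)
    expect_equal(bin_pair(pm, idx2)$status, "no_primer")
  }

  # cross-tile chimera: read1 from tile 1, read2 from tile 2
  chim <- p; chim$read2 <- perfect_pair(t2)$read2
  expect_equal(bin_pair(chim, idx2)$status, "cross_tile")

  # both mates forward-oriented
  so <- p; so$read2 <- p$read1
  expect_equal(bin_pair(so, idx2)$status, "orientation")
})

test_that("binning is order-independent", {
  withr::with_seed(11, {
    panel <- make_panel(3, insert_len = 40, primer_len = 12, seed = 8)
    sim <- simulate_reads(panel, make_truth(panel, "s", seed = 1), "s",
                          depth = 20, error_rate = 0.01, seed = 2)
  })
  idx <- build_tile_index(
    panel$tiles[, c("chrom", "start", "end", "fwd_name", "rev_name")],
    primercall:::panel_primer_seqs(panel), panel$reference, 12)
  pairs <- tibble::tibble(id = sim$reads$id, read1 = sim$reads$read1,
                          qual1 = sim$reads$qual1, read2 = sim$reads$read2,
                          qual2 = sim$reads$qual2)
  b <- bin_pairs(pairs, idx)
  perm <- withr::with_seed(3, sample(nrow(pairs)))
  b2 <- bin_pairs(pairs[perm, ], idx)
  expect_equal(b2, b[perm, ])
})

test_that("quality masking replaces exactly the sub-threshold bases", {
  idx <- toy_index()
  pair <- perfect_pair(idx$tiles[1, ])
  b <- bin_pair(pair, idx)

  expect_identical(mask_low_quality(b, 0), b)          # threshold 0: unchanged
  expect_identical(mask_low_quality(b, 20)$ins_fwd, b$ins_fwd)  # all Q40

  # drop one forward-insert base to Phred 5
  plen <- nchar(idx$tiles$fwd_seq[1])
  q <- b$qual_fwd
  substr(q, 4, 4) <- intToUtf8(5 + 33)
  b$qual_fwd <- q
  masked <- mask_low_quality(b, 20)
  expect_equal(substr(masked$ins_fwd, 4, 4), "N")
  expect_equal(paste0(substr(masked$ins_fwd, 1, 3), substring(masked$ins_fwd, 5)),
               paste0(substr(b$ins_fwd, 1, 3), substring(b$ins_fwd, 5)))
})

test_that("reverse complement is a self-inverse over random sequences", {
  withr::with_seed(5, {
    for (i in 1:20) {
      s <- rand_dna(sample(1:80, 1))
      expect_identical(revcomp(revcomp(s)), s)
    }
  })
  expect_identical(revcomp("ANC"), "GNT")
})
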
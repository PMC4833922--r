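make_bound_row <- function(idx, ins_fwd = NULL, ins_rev = NULL) {
  tile <- idx$tiles[1, ]
  if (is.null(ins_fwd)) ins_fwd <- tile$insert_ref
  if (is.null(ins_rev)) ins_rev <- tile$insert_ref
  tid <- tile$tile_id
  ilen <- tile$insert_len
  tibble::tibble(
    id = "p", status = "bound", tile = 1L, tile_id = tid,
    insert_len = ilen,
    ins_fwd = ins_fwd, qual_fwd = strrep("I", nchar(ins_fwd)),
    ins_rev = ins_rev, qual_rev = strrep("I", nchar(ins_rev)),
    len_fwd = nchar(ins_fwd), len_rev = nchar(ins_rev))
}

test_that("overlap filter requires both mates, boundary inclusive", {
  idx <- toy_index(insert = rand_dna(50))
  tile <- idx$tiles[1, ]
  full <- make_bound_row(idx)
  expect_true(overlap_ok(full))

  # 45 of 50 = 0.90 exactly: inclusive pass
  b45 <- make_bound_row(idx, ins_fwd = substr(tile$insert_ref, 1, 45))
  expect_true(overlap_ok(b45))

  # 40 of 50 = 0.80: fail, regardless of the other mate
  b40 <- make_bound_row(idx, ins_fwd = substr(tile$insert_ref, 1, 40))
  expect_false(overlap_ok(b40))
})

test_that("anchor filter passes when at least one mate matches exactly", {
  idx <- toy_index(insert = rand_dna(60))
  thr <- calling_thresholds(anchor = TRUE, anchor_len = 30)
  tile <- idx$tiles[1, ]

  clean <- make_bound_row(idx)
  expect_true(anchor_ok(clean, idx, thr))

  # forward anchor window dirty, reverse clean -> still passes
  fwd_dirty <- make_bound_row(idx, ins_fwd = mutate_base(tile$insert_ref, 12))
  expect_true(anchor_ok(fwd_dirty, idx, thr))

  # both primer-proximal windows dirty -> fails
  both_dirty <- make_bound_row(
    idx,
    ins_fwd = mutate_base(tile$insert_ref, 12),
    ins_rev = mutate_base(tile$insert_ref, tile$insert_len - 12))
  expect_false(anchor_ok(both_dirty, idx, thr))

  # a mismatch outside both anchor windows is irrelevant
  mid <- make_bound_row(idx, ins_fwd = mutate_base(tile$insert_ref, 31))
  expect_true(anchor_ok(mid, idx, calling_thresholds(anchor = TRUE,
                                                     anchor_len = 30)))
})

test_that("pair concordance keeps shared variants and drops single-mate artefacts", {
  idx <- toy_index(insert = withr::with_seed(9, paste0(rand_dna(19), "G",
                                                       rand_dna(40))))
  tile <- idx$tiles[1, ]   # reference base at insert offset 20 is G
  mut <- mutate_base(tile$insert_ref, 20, "A")

  both <- concordant_variants(mut, mut, tile)
  expect_equal(nrow(both), 1)
  expect_equal(both$pos, tile$start + 19L)
  expect_equal(both$ref, "G")
  expect_equal(both$alt, "A")

  expect_equal(nrow(concordant_variants(mut, tile$insert_ref, tile)), 0)
  expect_equal(nrow(concordant_variants(tile$insert_ref, tile$insert_ref, tile)), 0)

  # same locus, different alleles: discordant
  mut2 <- mutate_base(tile$insert_ref, 20, "C")
  expect_equal(nrow(concordant_variants(mut, mut2, tile)), 0)

  # masked position on one mate cannot be concordant
  masked <- mutate_base(mut, 20, "N")
  expect_equal(nrow(concordant_variants(mut, masked, tile)), 0)
})

test_that("per-tile tallying applies inclusive thresholds and labels failures", {
  v <- variant <- tibble::tibble(chrom = "c", pos = 5L, ref = "A", alt = "T",
                                 vclass = "SNV")
  none <- tibble::tibble(chrom = character(), pos = integer(),
                         ref = character(), alt = character(),
                         vclass = character())
  mk <- function(k, depth) c(rep(list(v), k), rep(list(none), depth - k))

  # 10 of 100 at defaults: PASS
  calls <- call_tile(mk(10, 100), 100)
  expect_equal(calls$filters, "")
  expect_equal(calls$proportion, 0.10)

  # 1 of 100: below both thresholds
  expect_equal(call_tile(mk(1, 100), 100)$filters, "at;pt")

  # 2 of 40 = 0.05: both boundaries inclusive -> PASS
  expect_equal(call_tile(mk(2, 40), 40)$filters, "")

  # 2 of 100 = 0.02: absolute ok, proportion fails
  expect_equal(call_tile(mk(2, 100), 100)$filters, "pt")

  # 1 of 10 = 0.1: proportion ok, absolute fails
  expect_equal(call_tile(mk(1, 10), 10)$filters, "at")

  # zero depth: no calls
  expect_equal(nrow(call_tile(list(), 0)), 0)
})

test_that("raising thresholds never turns a filtered variant into PASS", {
  v <- tibble::tibble(chrom = "c", pos = 5L, ref = "A", alt = "T", vclass = "SNV")
  none <- v[0, ]
  pp <- c(rep(list(v), 3), rep(list(none), 37))
  grid <- expand.grid(abs = c(0L, 2L, 3L, 4L, 10L),
                      prop = c(0, 0.05, 0.075, 0.1, 0.5))
  pass <- mapply(function(a, p) {
    call_tile(pp, 40, calling_thresholds(min_abs_pairs = a,
                                         min_prop_pairs = p))$filters == ""
  }, grid$abs, grid$prop)
  # monotone: pass status never increases as either threshold rises
  for (i in seq_len(nrow(grid))) for (j in seq_len(nrow(grid))) {
    if (grid$abs[j] >= grid$abs[i] && grid$prop[j] >= grid$prop[i]) {
      expect_true(!pass[j] || pass[i])
    }
  }
})

test_that("depth accounting reconciles along the filter chain", {
  withr::with_seed(21, {
    panel <- make_panel(4, insert_len = 80, primer_len = 15, seed = 61)
    truth <- make_truth(panel, "s1", seed = 62)
    sim <- simulate_reads(panel, truth, "s1", depth = 40, error_rate = 0.002,
                          offpanel_frac = 0.1, seed = 63)
  })
  idx <- build_tile_index(
    panel$tiles[, c("chrom", "start", "end", "fwd_name", "rev_name")],
    primercall:::panel_primer_seqs(panel), panel$reference, 15)
  pairs <- tibble::tibble(id = sim$reads$id, read1 = sim$reads$read1,
                          qual1 = sim$reads$qual1, read2 = sim$reads$read2,
                          qual2 = sim$reads$qual2)
  bound <- bin_pairs(pairs, idx)
  res <- call_sample(bound, idx)
  lg <- as.list(res$log)
  expect_equal(lg$pairs_seen, nrow(pairs))
  expect_equal(lg$pairs_bound + lg$pairs_unassigned, lg$pairs_seen)
  expect_equal(lg$no_primer + lg$cross_tile + lg$orientation, lg$pairs_unassigned)
  expect_equal(lg$pairs_bound - lg$overlap_failed - lg$anchor_failed,
               lg$depth_total)
  expect_equal(sum(res$coverage$pairs_bound), lg$pairs_bound)
  expect_equal(sum(res$coverage$depth), lg$depth_total)
  expect_true(all(res$coverage$pairs_bound >= res$coverage$pairs_overlap))
  expect_true(all(res$coverage$pairs_overlap >= res$coverage$depth))
})
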
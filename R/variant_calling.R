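# Stringency filters and per-tile variant aggregation.

#' Calling thresholds
#'
#' Bundles the stringency parameters of the caller. All comparisons
#' against thresholds are inclusive (`>=`).
#'
#' @param min_overlap_frac Fraction of the tile each read of a pair must
#'   cover (default 0.9).
#' @param anchor Enable the optional post-primer anchor check (default
#'   off; an additional-stringency filter).
#' @param anchor_len Length of the post-primer window that must exactly
#'   match the reference in at least one mate (default 30).
#' @param min_abs_pairs Minimum number of concordant read pairs carrying a
#'   variant (default 2); failing variants are labelled `at`.
#' @param min_prop_pairs Minimum fraction of overlapping pairs carrying
#'   the variant (default 0.05); failing variants are labelled `pt`.
#' @param qual_threshold Phred threshold for base masking (default 0 =
#'   off).
#' @return A list of class `calling_thresholds`.
#' @export
calling_thresholds <- function(min_overlap_frac = 0.9, anchor = FALSE,
                               anchor_len = 30L, min_abs_pairs = 2L,
                               min_prop_pairs = 0.05, qual_threshold = 0) {
  stopifnot(min_overlap_frac > 0, min_overlap_frac <= 1,
            min_prop_pairs >= 0, min_prop_pairs <= 1,
            min_abs_pairs >= 0, anchor_len >= 1)
  structure(list(min_overlap_frac = min_overlap_frac, anchor = anchor,
                 anchor_len = as.integer(anchor_len),
                 min_abs_pairs = as.integer(min_abs_pairs),
                 min_prop_pairs = min_prop_pairs,
                 qual_threshold = qual_threshold),
            class = "calling_thresholds")
}

#' Per-pair overlap filter
#'
#' A pair survives when *both* plus-strand inserts cover at least
#' `min_overlap_frac` of the tile insert (boundary inclusive). Failing
#' pairs contribute neither depth nor evidence.
#'
#' @param bound Tibble of bound pairs from [bin_pairs()].
#' @param thresholds A [calling_thresholds()] object.
#' @return Logical vector, one element per row of `bound`.
#' @export
overlap_ok <- function(bound, thresholds = calling_thresholds()) {
  need <- thresholds$min_overlap_frac * bound$insert_len
  # small epsilon so exact fractional boundaries (e.g. 45/50 at 0.9) pass
  bound$len_fwd >= need - 1e-9 & bound$len_rev >= need - 1e-9
}

#' Per-pair post-primer anchor filter
#'
#' True when at least one mate's post-primer window exactly matches the
#' reference: the forward mate is checked over the first `anchor_len`
#' bases of the tile, the reverse mate over the last `anchor_len` bases
#' (its own primer-proximal end). Windows are clipped to the available
#' read length.
#'
#' @inheritParams overlap_ok
#' @param index The `tile_index` the pairs were bound against.
#' @return Logical vector, one element per row of `bound`.
#' @export
anchor_ok <- function(bound, index, thresholds = calling_thresholds(anchor = TRUE)) {
  a <- thresholds$anchor_len
  tl <- index$tiles[bound$tile, ]
  af <- pmin(a, bound$len_fwd)
  ar <- pmin(a, bound$len_rev)
  fwd_ok <- substr(bound$ins_fwd, 1L, af) == substr(tl$insert_ref, 1L, af)
  rev_ok <- substr(bound$ins_rev, bound$len_rev - ar + 1L, bound$len_rev) ==
    substr(tl$insert_ref, tl$insert_len - ar + 1L, tl$insert_len)
  fwd_ok | rev_ok
}

#' Concordant variants of one read pair
#'
#' Compares each mate's insert to the tile reference and returns only the
#' variants reported identically (same chrom/pos/ref/alt) by *both*
#' mates. A sequencing artefact on a single mate, a masked position on
#' one mate, or the same locus with different alleles all yield nothing.
#'
#' @param ins_fwd,ins_rev Plus-strand inserts of the two mates.
#' @param tile One row of `index$tiles`.
#' @param mode,fast_gap,scoring See [compare_insert()].
#' @return A variant tibble.
#' @export
concordant_variants <- function(ins_fwd, ins_rev, tile, mode = "thorough",
                                fast_gap = 5L, scoring = align_scoring()) {
  vf <- compare_insert(ins_fwd, tile, "fwd", mode, fast_gap, scoring)$variants
  vr <- compare_insert(ins_rev, tile, "rev", mode, fast_gap, scoring)$variants
  intersect_variants(vf, vr)
}

intersect_variants <- function(v1, v2) {
  if (nrow(v1) == 0 || nrow(v2) == 0) return(variant_tbl())
  k1 <- paste(v1$chrom, v1$pos, v1$ref, v1$alt, v1$vclass, sep = "\r")
  k2 <- paste(v2$chrom, v2$pos, v2$ref, v2$alt, v2$vclass, sep = "\r")
  out <- v1[k1 %in% k2 & !duplicated(k1), , drop = FALSE]
  out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
}

#' Aggregate per-pair variants into calls for one tile
#'
#' Tallies, per distinct variant, the number of concordant pairs carrying
#' it, and applies the frequency thresholds: label `at` when the pair
#' count is below `min_abs_pairs`, `pt` when the proportion of overlapping
#' pairs is below `min_prop_pairs` (both inclusive `>=` to pass). All
#' concordant variants are reported with their filter status rather than
#' suppressed.
#'
#' @param per_pair_variants List of variant tibbles, one per surviving
#'   read pair of the tile.
#' @param depth Number of read pairs that survived the overlap/anchor
#'   filters for this tile (the denominator).
#' @param thresholds A [calling_thresholds()] object.
#' @return Tibble with `chrom`, `pos`, `ref`, `alt`, `vclass`,
#'   `pair_count`, `depth`, `proportion`, `filters` (`""` = PASS, else
#'   semicolon-joined labels).
#' @export
call_tile <- function(per_pair_variants, depth, thresholds = calling_thresholds()) {
  empty <- mutate(variant_tbl(), pair_count = integer(), depth = integer(),
                  proportion = double(), filters = character())
  if (depth == 0 || length(per_pair_variants) == 0) return(empty)
  nonempty <- per_pair_variants[vapply(per_pair_variants, nrow, integer(1)) > 0]
  if (length(nonempty) == 0) return(empty)
  # each pair contributes each distinct variant at most once
  deduped <- lapply(nonempty, function(v) {
    k <- paste(v$chrom, v$pos, v$ref, v$alt, v$vclass, sep = "\r")
    v[!duplicated(k), , drop = FALSE]
  })
  all_v <- bind_rows(deduped)
  key <- paste(all_v$chrom, all_v$pos, all_v$ref, all_v$alt, all_v$vclass,
               sep = "\r")
  cnt <- table(key)
  first <- !duplicated(key)
  tallied <- all_v[first, , drop = FALSE]
  tallied$pair_count <- as.integer(cnt[key[first]])
  tallied$depth <- as.integer(depth)
  tallied$proportion <- tallied$pair_count / depth
  at_ok <- tallied$pair_count >= thresholds$min_abs_pairs
  pt_ok <- tallied$proportion >= thresholds$min_prop_pairs - 1e-12
  tallied$filters <- paste0(ifelse(at_ok, "", "at"),
                            ifelse(pt_ok, "", ifelse(at_ok, "pt", ";pt")))
  sort_variants(tallied)
}

# Base contributed by one mate at reference position `pos`, accounting for
# the mate's own indels; NA when the position is not covered, deleted, or
# masked.
mate_base_at <- function(insert, span_start, variants, pos) {
  offset <- pos - span_start + 1L
  if (nrow(variants) > 0) {
    for (k in seq_len(nrow(variants))) {
      vp <- variants$pos[k]
      lr <- nchar(variants$ref[k]); la <- nchar(variants$alt[k])
      if (lr == la) next  # SNV: no frame shift
      if (la > lr) {      # insertion after vp
        if (vp < pos) offset <- offset + (la - lr)
      } else {            # deletion of bases (vp, vp + lr - 1]
        if (vp < pos && pos <= vp + lr - 1L) return(NA_character_)
        if (vp < pos) offset <- offset - (lr - la)
      }
    }
  }
  if (is.na(offset) || offset < 1L || offset > nchar(insert)) return(NA_character_)
  b <- substr(insert, offset, offset)
  if (b == "N") NA_character_ else b
}

# Per-pair consensus pileup of bases at one reference position.
pileup_at <- function(rows, pos) {
  counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
  for (i in seq_len(nrow(rows))) {
    b1 <- mate_base_at(rows$ins_fwd[i], rows$span_fwd[i], rows$v_fwd[[i]], pos)
    b2 <- mate_base_at(rows$ins_rev[i], rows$span_rev[i], rows$v_rev[[i]], pos)
    b <- if (!is.na(b1) && !is.na(b2)) {
      if (b1 == b2) b1 else NA_character_
    } else if (!is.na(b1)) b1 else b2
    if (!is.na(b) && b %in% names(counts)) counts[b] <- counts[b] + 1L
  }
  counts
}

#' Call variants for one sample
#'
#' Runs the full per-sample stage: quality masking, overlap and optional
#' anchor filters, per-mate comparison with fallback alignment, pair
#' concordance, per-tile tallying and thresholding, and optional G-test
#' genotyping of SNVs.
#'
#' @param bound Output of [bin_pairs()] for one sample (all statuses; the
#'   function selects the bound rows itself).
#' @param index The `tile_index`.
#' @param thresholds A [calling_thresholds()] object.
#' @param mode,fast_gap,scoring See [compare_insert()].
#' @param genotype Logical; genotype SNV calls with the G-test model.
#' @param model A [genotype_model()] used when `genotype = TRUE`.
#' @return List with `calls` (call tibble, plus `gt`/`g_statistic` when
#'   genotyping), `coverage` (per-tile filter-chain counts), and `log`
#'   (named totals for the run log).
#' @export
call_sample <- function(bound, index, thresholds = calling_thresholds(),
                        mode = "thorough", fast_gap = 5L,
                        scoring = align_scoring(),
                        genotype = FALSE, model = genotype_model()) {
  n_seen <- nrow(bound)
  b <- filter(bound, .data$status == "bound")
  n_bound <- nrow(b)
  b <- mask_low_quality(b, thresholds$qual_threshold)

  ov <- if (n_bound > 0) overlap_ok(b, thresholds) else logical()
  n_overlap_failed <- sum(!ov)
  b <- b[ov, , drop = FALSE]
  if (thresholds$anchor && nrow(b) > 0) {
    an <- anchor_ok(b, index, thresholds)
    n_anchor_failed <- sum(!an)
    b <- b[an, , drop = FALSE]
  } else {
    n_anchor_failed <- 0L
  }

  tiles <- index$tiles
  calls <- list()

  for (t in seq_len(nrow(tiles))) {
    tile <- tiles[t, ]
    rows <- b[!is.na(b$tile) & b$tile == t, , drop = FALSE]
    depth <- nrow(rows)
    if (depth == 0) next

    # memoised comparison over unique insert strings, per side
    cmp_side <- function(ins, side) {
      u <- unique(ins)
      res <- lapply(u, function(s)
        compare_insert(s, tile, side, mode, fast_gap, scoring)$variants)
      res[match(ins, u)]
    }
    rows$v_fwd <- cmp_side(rows$ins_fwd, "fwd")
    rows$v_rev <- cmp_side(rows$ins_rev, "rev")
    rows$span_fwd <- rep(tile$start, depth)
    rows$span_rev <- tile$start + pmax(0L, tile$insert_len - rows$len_rev)

    per_pair <- map2(rows$v_fwd, rows$v_rev, intersect_variants)
    tile_calls <- call_tile(per_pair, depth, thresholds)
    if (nrow(tile_calls) > 0) {
      tile_calls$tile_id <- tile$tile_id
      if (genotype) {
        gt <- rep(NA_character_, nrow(tile_calls))
        gs <- rep(NA_real_, nrow(tile_calls))
        for (k in seq_len(nrow(tile_calls))) {
          if (tile_calls$vclass[k] != "SNV") next
          pu <- pileup_at(rows, tile_calls$pos[k])
          if (sum(pu) < 1) next
          gc <- genotype_call(pu, tile_calls$ref[k], tile_calls$alt[k], model)
          gt[k] <- gc$gt
          gs[k] <- gc$g_statistic
        }
        tile_calls$gt <- gt
        tile_calls$g_statistic <- gs
      }
      calls[[length(calls) + 1L]] <- tile_calls
    }
  }

  # coverage: recompute the filter chain per tile cleanly
  cov_tbl <- coverage_chain(bound, b, index, thresholds)

  calls_tbl <- if (length(calls) > 0) bind_rows(calls) else {
    k <- mutate(variant_tbl(), pair_count = integer(), depth = integer(),
                proportion = double(), filters = character(),
                tile_id = character())
    if (genotype) k <- mutate(k, gt = character(), g_statistic = double())
    k
  }
  list(
    calls = sort_variants(calls_tbl),
    coverage = cov_tbl,
    log = c(pairs_seen = n_seen, pairs_bound = n_bound,
            pairs_unassigned = n_seen - n_bound,
            no_primer = sum(bound$status == "no_primer"),
            cross_tile = sum(bound$status == "cross_tile"),
            orientation = sum(bound$status == "orientation"),
            overlap_failed = n_overlap_failed,
            anchor_failed = n_anchor_failed,
            depth_total = nrow(b))
  )
}

# Per-tile counts along the filter chain (bound -> overlap -> anchor).
coverage_chain <- function(bound, surviving, index, thresholds) {
  tiles <- index$tiles
  all_bound <- filter(bound, .data$status == "bound")
  ov_pass <- all_bound[overlap_ok(all_bound, thresholds), , drop = FALSE]
  an_pass <- if (thresholds$anchor && nrow(ov_pass) > 0) {
    ov_pass[anchor_ok(ov_pass, index, thresholds), , drop = FALSE]
  } else ov_pass
  count_by_tile <- function(d) {
    if (nrow(d) == 0) return(integer(nrow(tiles)))
    tabulate(d$tile, nbins = nrow(tiles))
  }
  tibble(
    tile_id = tiles$tile_id, chrom = tiles$chrom, start = tiles$start,
    end = tiles$end, fwd_name = tiles$fwd_name, rev_name = tiles$rev_name,
    pairs_bound = count_by_tile(all_bound),
    pairs_overlap = count_by_tile(ov_pass),
    pairs_anchor = count_by_tile(an_pass),
    depth = count_by_tile(an_pass)
  )
}
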
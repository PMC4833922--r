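# Read-vs-reference comparison: linear scan first, gapped fallback.
#
# The common case is a read identical to its reference insert or differing
# by a single substitution, so an index-by-index scan resolves most reads
# without touching the quadratic aligner. Reads whose mismatch pattern
# suggests an indel fall back to a global affine-gap alignment.

#' Alignment scoring parameters
#'
#' Defaults penalise gaps much more heavily than mismatches so that an
#' isolated substitution is never represented as a pair of gaps.
#'
#' @param match Match score.
#' @param mismatch Mismatch penalty (negative).
#' @param gap_open Gap opening penalty (negative); a gap of length k costs
#'   `gap_open + k * gap_extend`.
#' @param gap_extend Per-base gap extension penalty (negative).
#' @return A list of class `align_scoring`.
#' @export
align_scoring <- function(match = 2, mismatch = -1, gap_open = -5, gap_extend = -0.5) {
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "align_scoring")
}

#' Linear comparison of a read insert against its reference span
#'
#' Compares the two sequences index by index. Positions where either side
#' is `N` (masked or ambiguous) never mismatch. In `thorough` mode at most
#' one mismatch is accepted; in `fast` mode any number is accepted
#' provided every two consecutive mismatches are separated by more than
#' `fast_gap` bases (clustered mismatches are the signature of an indel
#' and trigger the gapped fallback).
#'
#' @param read_insert Plus-strand primer-trimmed read sequence.
#' @param ref_insert Reference sequence of the same span; must be at least
#'   as long as `read_insert` (the read is compared over its own length).
#' @param mode `"thorough"` or `"fast"`.
#' @param fast_gap Minimum separation (exclusive) between consecutive
#'   mismatches accepted in fast mode.
#' @param chrom,ref_start Coordinates of the first compared reference
#'   base; emitted variants are absolute in this system.
#' @return A list with `status` (`"resolved"` or `"fallback"`) and
#'   `variants` (tibble of SNVs; empty unless resolved).
#' @export
linear_compare <- function(read_insert, ref_insert,
                           mode = c("thorough", "fast"), fast_gap = 5L,
                           chrom = "seq", ref_start = 1L) {
  mode <- match.arg(mode)
  L <- nchar(read_insert)
  if (L > nchar(ref_insert)) {
    abort("`read_insert` is longer than `ref_insert`; truncate upstream")
  }
  x <- utf8ToInt(read_insert)
  y <- utf8ToInt(substr(ref_insert, 1L, L))
  nmask <- utf8ToInt("N")
  mm <- which(x != y & x != nmask & y != nmask)
  ok <- if (mode == "thorough") {
    length(mm) <= 1L
  } else {
    length(mm) <= 1L || all(diff(mm) > fast_gap)
  }
  if (!ok) {
    return(list(status = "fallback", variants = variant_tbl()))
  }
  if (length(mm) == 0) {
    return(list(status = "resolved", variants = variant_tbl()))
  }
  list(status = "resolved",
       variants = variant_tbl(
         chrom = rep(chrom, length(mm)),
         pos = ref_start + mm - 1L,
         ref = substring(ref_insert, mm, mm),
         alt = substring(read_insert, mm, mm),
         vclass = rep("SNV", length(mm))
       ))
}

#' Global gapped alignment (Needleman-Wunsch style, affine gaps)
#'
#' @param read_insert,ref_insert Sequences to align (plus strand).
#' @param scoring An [align_scoring()] object.
#' @return A `gotoh_alignment`: list with gapped `read` and `ref` strings
#'   of equal length and the alignment `score`.
#' @export
gapped_align <- function(read_insert, ref_insert, scoring = align_scoring()) {
  if (!nzchar(read_insert) || !nzchar(ref_insert)) {
    abort("both sequences must be non-empty")
  }
  res <- gotoh_align_cpp(read_insert, ref_insert,
                         scoring$match, scoring$mismatch,
                         scoring$gap_open, scoring$gap_extend)
  structure(list(read = res$read, ref = res$ref, score = res$score,
                 scoring = scoring),
            class = "gotoh_alignment")
}

#' @export
print.gotoh_alignment <- function(x, ...) {
  cat(sprintf("<gotoh_alignment> score=%g\n  read: %s\n  ref:  %s\n",
              x$score, x$read, x$ref))
  invisible(x)
}

#' Left-align a VCF-anchored indel
#'
#' Shifts an anchored insertion/deletion to its leftmost equivalent
#' position within the provided reference context (standard VCF
#' normalisation). Idempotent on already-normalised records.
#'
#' @param pos 1-based position of the anchor base.
#' @param ref,alt Anchored allele strings (one of them length 1).
#' @param ref_seq Reference sequence providing left context.
#' @param ref_start Coordinate of `ref_seq`'s first base; normalisation
#'   never shifts the anchor left of this bound.
#' @return A list with normalised `pos`, `ref`, `alt`.
#' @export
left_align_indel <- function(pos, ref, alt, ref_seq, ref_start = 1L) {
  repeat {
    lr <- nchar(ref); la <- nchar(alt)
    if (lr > 0 && la > 0 && lr != la &&
        substr(ref, lr, lr) == substr(alt, la, la)) {
      if (lr > 1 && la > 1) {
        ref <- substr(ref, 1L, lr - 1L)
        alt <- substr(alt, 1L, la - 1L)
      } else if (pos > ref_start) {
        prev <- substr(ref_seq, pos - ref_start, pos - ref_start)
        ref <- paste0(prev, substr(ref, 1L, lr - 1L))
        alt <- paste0(prev, substr(alt, 1L, la - 1L))
        pos <- pos - 1L
      } else break
    } else break
  }
  list(pos = as.integer(pos), ref = ref, alt = alt)
}

#' Convert a global alignment into normalised variants
#'
#' Walks the alignment columns, emitting substitutions as SNVs and merging
#' runs of adjacent gap columns into single indel events anchored on the
#' preceding reference base (VCF convention) and left-aligned within the
#' tile. Terminal gap runs at either end of the alignment arise from read
#' truncation at tile edges and produce no variants; columns involving `N`
#' never produce evidence.
#'
#' @param alignment A `gotoh_alignment` from [gapped_align()].
#' @param chrom Chromosome name for emitted variants.
#' @param ref_start Reference coordinate of the first (ungapped) base of
#'   the alignment's reference side.
#' @param ref_seq Optional full reference string starting at `ref_start`;
#'   when supplied it is checked against the alignment's ungapped
#'   reference side (internal consistency) and used as normalisation
#'   context. Defaults to the alignment's own reference side.
#' @return A variant tibble (`chrom`, `pos`, `ref`, `alt`, `vclass`).
#' @export
alignment_variants <- function(alignment, chrom = "seq", ref_start = 1L,
                               ref_seq = NULL) {
  a <- strsplit(alignment$read, "", fixed = TRUE)[[1]]
  b <- strsplit(alignment$ref, "", fixed = TRUE)[[1]]
  if (length(a) != length(b)) abort("ragged alignment")
  ungapped_ref <- paste(b[b != "-"], collapse = "")
  if (is.null(ref_seq)) {
    ref_seq <- ungapped_ref
  } else if (substr(ref_seq, 1L, nchar(ungapped_ref)) != ungapped_ref) {
    abort("alignment reference side does not match the supplied reference sequence")
  }

  ncol <- length(a)
  gapcol <- a == "-" | b == "-"
  first <- 1L; last <- ncol
  while (first <= ncol && gapcol[first]) first <- first + 1L
  while (last >= first && gapcol[last]) last <- last - 1L
  if (first > last) return(variant_tbl())

  # reference position before each column (cumulative ref bases consumed)
  ref_consumed <- cumsum(b != "-")

  out <- list()
  i <- first
  while (i <= last) {
    if (!gapcol[i]) {
      if (a[i] != b[i] && a[i] != "N" && b[i] != "N") {
        pos <- ref_start - 1L + ref_consumed[i]
        out[[length(out) + 1L]] <-
          variant_tbl(chrom, pos, b[i], a[i], "SNV")
      }
      i <- i + 1L
    } else {
      read_gap <- a[i] == "-"
      j <- i
      while (j < last && gapcol[j + 1L] && (a[j + 1L] == "-") == read_gap) j <- j + 1L
      anchor_pos <- ref_start - 1L + ref_consumed[i] - if (read_gap) 1L else 0L
      if (anchor_pos >= ref_start) {
        anchor <- substr(ref_seq, anchor_pos - ref_start + 1L,
                         anchor_pos - ref_start + 1L)
        if (read_gap) {
          deleted <- paste(b[i:j], collapse = "")
          v <- left_align_indel(anchor_pos, paste0(anchor, deleted), anchor,
                                ref_seq, ref_start)
          out[[length(out) + 1L]] <-
            variant_tbl(chrom, v$pos, v$ref, v$alt, "deletion")
        } else {
          inserted <- paste(a[i:j], collapse = "")
          if (!grepl("N", inserted, fixed = TRUE)) {
            v <- left_align_indel(anchor_pos, anchor, paste0(anchor, inserted),
                                  ref_seq, ref_start)
            out[[length(out) + 1L]] <-
              variant_tbl(chrom, v$pos, v$ref, v$alt, "insertion")
          }
        }
      }
      i <- j + 1L
    }
  }
  if (length(out) == 0) return(variant_tbl())
  sort_variants(bind_rows(out))
}

#' Compare one mate's insert to its tile reference
#'
#' The full comparison pipeline for a single plus-strand insert: linear
#' scan over the mate's span (anchored at its primer end), falling back to
#' a global gapped alignment against the complete tile insert when the
#' scan cannot explain the differences as well-separated substitutions.
#'
#' @param read_insert Plus-strand primer-trimmed (and truncated) insert.
#' @param tile One row of `index$tiles`.
#' @param side `"fwd"` (covers the tile from its 5' end) or `"rev"`
#'   (covers the tile from its 3' end).
#' @param mode,fast_gap See [linear_compare()].
#' @param scoring See [gapped_align()].
#' @return A list with `status` (`"resolved"` or `"fallback"`) and
#'   `variants` (tibble in reference coordinates).
#' @export
compare_insert <- function(read_insert, tile, side = c("fwd", "rev"),
                           mode = "thorough", fast_gap = 5L,
                           scoring = align_scoring()) {
  side <- match.arg(side)
  L <- nchar(read_insert)
  if (L == 0) return(list(status = "resolved", variants = variant_tbl()))
  ilen <- tile$insert_len
  if (side == "fwd") {
    ref_span <- substr(tile$insert_ref, 1L, min(L, ilen))
    span_start <- tile$start
  } else {
    ref_span <- substr(tile$insert_ref, max(1L, ilen - L + 1L), ilen)
    span_start <- tile$start + max(0L, ilen - L)
  }
  if (read_insert == ref_span) {
    return(list(status = "resolved", variants = variant_tbl()))
  }
  if (L <= ilen) {
    lc <- linear_compare(read_insert, ref_span, mode = mode, fast_gap = fast_gap,
                         chrom = tile$chrom, ref_start = span_start)
    if (lc$status == "resolved") return(lc)
  }
  aln <- gapped_align(read_insert, tile$insert_ref, scoring)
  list(status = "fallback",
       variants = alignment_variants(aln, chrom = tile$chrom,
                                     ref_start = tile$start,
                                     ref_seq = tile$insert_ref))
}
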
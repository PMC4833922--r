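# Paired FASTQ input, prefix binning into tiles, and base-quality masking.

read_fastq_tbl <- function(path) {
  if (!file.exists(path)) abort(sprintf("FASTQ file not found: '%s'", path))
  res <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE),
    error = function(e) abort(sprintf("malformed FASTQ in '%s': %s",
                                      path, conditionMessage(e)))
  )
  tibble(id = unname(names(res)),
         bases = unname(toupper(as.character(res))),
         quals = unname(as.character(S4Vectors::mcols(res)$qualities)))
}

# Strip a mate suffix (/1, /2, or everything after the first whitespace)
# from a FASTQ identifier.
fragment_id <- function(id) sub("/[12]$", "", sub("\\s.*$", "", id))

#' Read a pair of FASTQ files into a read-pair table
#'
#' The i-th record of file 1 is paired with the i-th record of file 2
#' (standard paired-FASTQ convention). Files may be plain or
#' gzip-compressed; qualities are Phred+33.
#'
#' @param fastq1,fastq2 Paths to the two FASTQ files of one sample.
#' @return A tibble with columns `id` (fragment identifier with the mate
#'   suffix removed), `read1`, `qual1`, `read2`, `qual2`.
#' @export
stream_pairs <- function(fastq1, fastq2) {
  r1 <- read_fastq_tbl(fastq1)
  r2 <- read_fastq_tbl(fastq2)
  if (nrow(r1) != nrow(r2)) {
    abort(sprintf("unequal record counts: '%s' has %d records, '%s' has %d",
                  fastq1, nrow(r1), fastq2, nrow(r2)))
  }
  tibble(id = fragment_id(r1$id),
         read1 = r1$bases, qual1 = r1$quals,
         read2 = r2$bases, qual2 = r2$quals)
}

#' Assign read pairs to amplicon tiles by their primer prefix
#'
#' Each mate's first `prefix_len` bases are looked up in the tile index.
#' A pair is bound only when both mates hit the same tile in complementary
#' orientations (one forward, one reverse); everything else is kept with
#' an `unassigned` status and a reason. For bound pairs the full primer is
#' trimmed (variants under the primer are unobservable), the read is
#' truncated at the tile's insert length (adapter read-through), and the
#' reverse-oriented mate is reverse-complemented so both inserts are
#' expressed on the plus strand.
#'
#' @param pairs Tibble from [stream_pairs()].
#' @param index A `tile_index` from [build_tile_index()].
#' @return The input tibble extended with `status` (`"bound"`,
#'   `"no_primer"`, `"cross_tile"`, `"orientation"`), `tile` (row index
#'   into `index$tiles`), `tile_id`, `insert_len`, and the plus-strand
#'   primer-trimmed inserts `ins_fwd`/`ins_rev` with qualities
#'   `qual_fwd`/`qual_rev` and lengths `len_fwd`/`len_rev`. `ins_fwd`
#'   always comes from the forward-primer mate (covers the tile 5' side),
#'   `ins_rev` from the reverse-primer mate (covers the 3' side).
#' @export
bin_pairs <- function(pairs, index) {
  n <- nrow(pairs)
  N <- index$prefix_len
  out <- pairs
  out$status <- rep("no_primer", n)
  out$tile <- rep(NA_integer_, n)
  out$tile_id <- rep(NA_character_, n)
  out$insert_len <- rep(NA_integer_, n)
  out$ins_fwd <- out$qual_fwd <- out$ins_rev <- out$qual_rev <- rep(NA_character_, n)
  out$len_fwd <- out$len_rev <- rep(NA_integer_, n)
  if (n == 0 || nrow(index$keys) == 0) return(out)

  i1 <- match(substr(pairs$read1, 1L, N), index$keys$prefix)
  i2 <- match(substr(pairs$read2, 1L, N), index$keys$prefix)
  t1 <- index$keys$tile[i1]; o1 <- index$keys$orientation[i1]
  t2 <- index$keys$tile[i2]; o2 <- index$keys$orientation[i2]

  hit <- !is.na(i1) & !is.na(i2)
  cross <- hit & t1 != t2
  sameo <- hit & !cross & o1 == o2
  bound <- hit & !cross & !sameo
  out$status[cross] <- "cross_tile"
  out$status[sameo] <- "orientation"
  out$status[bound] <- "bound"
  if (!any(bound)) return(out)

  b <- which(bound)
  tl <- index$tiles[t1[b], ]
  fwd_is_r1 <- o1[b] == "forward"
  raw_fwd <- ifelse(fwd_is_r1, pairs$read1[b], pairs$read2[b])
  qra_fwd <- ifelse(fwd_is_r1, pairs$qual1[b], pairs$qual2[b])
  raw_rev <- ifelse(fwd_is_r1, pairs$read2[b], pairs$read1[b])
  qra_rev <- ifelse(fwd_is_r1, pairs$qual2[b], pairs$qual1[b])

  f_plen <- nchar(tl$fwd_seq)
  r_plen <- nchar(tl$rev_seq)
  ins_f <- substr(substring(raw_fwd, f_plen + 1L), 1L, tl$insert_len)
  qual_f <- substr(substring(qra_fwd, f_plen + 1L), 1L, tl$insert_len)
  ins_r_raw <- substr(substring(raw_rev, r_plen + 1L), 1L, tl$insert_len)
  qual_r_raw <- substr(substring(qra_rev, r_plen + 1L), 1L, tl$insert_len)

  out$tile[b] <- t1[b]
  out$tile_id[b] <- tl$tile_id
  out$insert_len[b] <- tl$insert_len
  out$ins_fwd[b] <- ins_f
  out$qual_fwd[b] <- qual_f
  out$ins_rev[b] <- revcomp(ins_r_raw)
  out$qual_rev[b] <- stringi::stri_reverse(qual_r_raw)
  out$len_fwd[b] <- nchar(ins_f)
  out$len_rev[b] <- nchar(ins_r_raw)
  out
}

#' @rdname bin_pairs
#' @param pair A single-row tibble (one read pair).
#' @export
bin_pair <- function(pair, index) bin_pairs(pair[1, , drop = FALSE], index)

#' Mask low-quality insert bases
#'
#' Replaces insert bases whose Phred score falls below `qual_threshold`
#' with `N`. An `N` never mismatches the reference during comparison and
#' never supports a variant, so a masked base can neither create evidence
#' nor break pair concordance; masked pairs still count toward depth.
#' `qual_threshold = 0` disables masking.
#'
#' @param bound Tibble from [bin_pairs()].
#' @param qual_threshold Minimum Phred score to keep a base unmasked.
#' @return `bound` with `ins_fwd`/`ins_rev` masked where required.
#' @export
mask_low_quality <- function(bound, qual_threshold = 0) {
  if (qual_threshold <= 0) return(bound)
  mask_one <- function(bases, quals) {
    idx <- which(!is.na(bases) & nzchar(bases))
    for (i in idx) {
      q <- phred_scores(quals[i])
      low <- q < qual_threshold
      if (any(low)) {
        b <- strsplit(bases[i], "", fixed = TRUE)[[1]]
        b[low] <- "N"
        bases[i] <- paste(b, collapse = "")
      }
    }
    bases
  }
  bound$ins_fwd <- mask_one(bound$ins_fwd, bound$qual_fwd)
  bound$ins_rev <- mask_one(bound$ins_rev, bound$qual_rev)
  bound
}
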
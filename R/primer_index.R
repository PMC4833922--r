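# Panel metadata parsing and the primer-prefix hash that replaces read mapping.
#
# Coordinate convention: the primer-coordinates file gives the *insert*
# (primer-intervening) span of each tile as 1-based inclusive start/end,
# matching VCF coordinates. This is documented prominently because the
# upstream file dialect itself does not state a convention.

#' Parse a primer-coordinates file
#'
#' Reads the 5-column tab-delimited panel description: chromosome, tile
#' (insert) start, tile end (both 1-based inclusive), forward-primer name,
#' reverse-primer name. No header. Blank lines are ignored.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `chrom`, `start`, `end`, `fwd_name`,
#'   `rev_name`, one row per tile, in file order.
#' @export
parse_primer_coords <- function(path) {
  if (!file.exists(path)) abort(sprintf("primer-coordinates file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  fwd_name = character(), rev_name = character()))
  }
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  rows <- map2(fields, keep, function(f, ln) {
    if (length(f) < 5) {
      abort(sprintf("line %d: expected at least 5 tab-separated fields, got %d", ln, length(f)))
    }
    start <- suppressWarnings(as.integer(f[2]))
    end <- suppressWarnings(as.integer(f[3]))
    if (is.na(start) || is.na(end)) {
      abort(sprintf("line %d: non-integer tile coordinates '%s', '%s'", ln, f[2], f[3]))
    }
    if (start > end) {
      abort(sprintf("line %d: tile start (%d) greater than end (%d)", ln, start, end))
    }
    if (f[4] == f[5]) {
      abort(sprintf("line %d: forward and reverse primer share the name '%s'", ln, f[4]))
    }
    tibble(chrom = f[1], start = start, end = end, fwd_name = f[4], rev_name = f[5])
  })
  specs <- bind_rows(rows)
  dup <- duplicated(specs[, c("fwd_name", "rev_name")])
  if (any(dup)) {
    abort(sprintf("duplicate primer-pair name(s): %s",
                  paste(specs$fwd_name[dup], specs$rev_name[dup], sep = "/", collapse = ", ")))
  }
  specs
}

#' Parse a primer-sequences file
#'
#' Reads the 2-column tab-delimited file matching primer names to their
#' gene-specific oligo sequences written 5'->3' as synthesized. Sequences
#' are upper-cased; only `A`, `C`, `G`, `T`, `N` are allowed.
#'
#' @param path Path to the TSV file.
#' @return A tibble with columns `name` and `sequence`.
#' @export
parse_primer_sequences <- function(path) {
  if (!file.exists(path)) abort(sprintf("primer-sequences file not found: '%s'", path))
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) return(tibble(name = character(), sequence = character()))
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  rows <- map2(fields, keep, function(f, ln) {
    if (length(f) < 2) abort(sprintf("line %d: expected 2 tab-separated fields", ln))
    seq <- toupper(f[2])
    if (!nzchar(seq)) abort(sprintf("line %d: empty primer sequence for '%s'", ln, f[1]))
    if (grepl("[^ACGTN]", seq)) {
      abort(sprintf("line %d: primer '%s' contains characters outside {A,C,G,T,N}", ln, f[1]))
    }
    tibble(name = f[1], sequence = seq)
  })
  seqs <- bind_rows(rows)
  dup <- unique(seqs$name[duplicated(seqs$name)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate primer name(s): %s", paste(dup, collapse = ", ")))
  }
  seqs
}

#' Write panel metadata back to the TSV dialects
#'
#' Inverse of [parse_primer_coords()] / [parse_primer_sequences()]:
#' headerless tab-separated files that re-parse to identical tibbles.
#'
#' @param specs Tibble as returned by [parse_primer_coords()].
#' @param seqs Tibble as returned by [parse_primer_sequences()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_primer_coords <- function(specs, path) {
  readr::write_tsv(specs[, c("chrom", "start", "end", "fwd_name", "rev_name")],
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_primer_coords
#' @export
write_primer_sequences <- function(seqs, path) {
  readr::write_tsv(seqs[, c("name", "sequence")], path, col_names = FALSE)
  invisible(path)
}

#' Build the primer-prefix tile index
#'
#' Constructs the hash table at the heart of mapping-free binning: the
#' first `prefix_len` bases of every primer become a key pointing at its
#' tile and orientation, and each tile's reference insert is extracted
#' verbatim from the reference. Binning later requires an exact match of a
#' read's first `prefix_len` bases against one of these keys.
#'
#' @param specs Tile table from [parse_primer_coords()].
#' @param seqs Primer table from [parse_primer_sequences()].
#' @param reference Reference genome: FASTA path, `DNAStringSet`, or named
#'   list of chromosome strings. Chromosome names must match `specs$chrom`.
#' @param prefix_len Number of 5' primer bases used as the hash key. Must
#'   not exceed the shortest primer in the panel.
#' @return A `tile_index` object: list with `prefix_len`, `tiles` (tibble
#'   with primer sequences, reference insert and `insert_len`), and `keys`
#'   (tibble mapping each prefix to a tile row and orientation).
#' @export
build_tile_index <- function(specs, seqs, reference, prefix_len = 20L) {
  prefix_len <- as.integer(prefix_len)
  if (is.na(prefix_len) || prefix_len < 1) abort("`prefix_len` must be a positive integer")
  seq_lookup <- stats::setNames(seqs$sequence, seqs$name)

  used <- unique(c(specs$fwd_name, specs$rev_name))
  missing <- setdiff(used, names(seq_lookup))
  if (length(missing) > 0) {
    abort(sprintf("primer name(s) in coordinates file missing from sequences file: %s",
                  paste(missing, collapse = ", ")))
  }
  if (nrow(specs) > 0) {
    min_len <- min(nchar(seq_lookup[used]))
    if (prefix_len > min_len) {
      abort(sprintf("`prefix_len` (%d) exceeds the shortest primer length (%d)",
                    prefix_len, min_len))
    }
  }

  ref <- load_reference(reference)
  tiles <- specs
  tiles$fwd_seq <- unname(seq_lookup[specs$fwd_name])
  tiles$rev_seq <- unname(seq_lookup[specs$rev_name])
  tiles$insert_len <- tiles$end - tiles$start + 1L
  tiles$insert_ref <- pmap(list(tiles$chrom, tiles$start, tiles$end), function(ch, s, e) {
    if (!ch %in% names(ref)) abort(sprintf("chromosome '%s' not present in the reference", ch))
    if (e > nchar(ref[[ch]])) {
      abort(sprintf("tile %s:%d-%d extends beyond the end of the reference sequence", ch, s, e))
    }
    substr(ref[[ch]], s, e)
  })
  tiles$insert_ref <- unlist(tiles$insert_ref)
  tiles$tile_id <- sprintf("%s:%d-%d", tiles$chrom, tiles$start, tiles$end)

  keys <- tibble(
    prefix = c(substr(tiles$fwd_seq, 1L, prefix_len), substr(tiles$rev_seq, 1L, prefix_len)),
    primer = c(tiles$fwd_name, tiles$rev_name),
    tile = rep(seq_len(nrow(tiles)), 2L),
    orientation = rep(c("forward", "reverse"), each = nrow(tiles))
  )
  with_n <- grepl("N", keys$prefix, fixed = TRUE)
  if (any(with_n)) {
    abort(sprintf("primer(s) with N within the first %d bases cannot be hash keys: %s",
                  prefix_len, paste(unique(keys$primer[with_n]), collapse = ", ")))
  }
  dup_keys <- unique(keys$prefix[duplicated(keys$prefix)])
  if (length(dup_keys) > 0) {
    offenders <- keys$primer[keys$prefix %in% dup_keys]
    abort(sprintf(
      "ambiguous primer prefixes at prefix_len=%d; colliding primers: %s",
      prefix_len, paste(sort(unique(offenders)), collapse = ", ")))
  }

  structure(list(prefix_len = prefix_len, tiles = tiles, keys = keys),
            class = "tile_index")
}

#' @export
print.tile_index <- function(x, ...) {
  cat(sprintf("<tile_index> %d tile(s), prefix_len=%d, %d hash key(s)\n",
              nrow(x$tiles), x$prefix_len, nrow(x$keys)))
  if (nrow(x$tiles) > 0) {
    cat(sprintf("  insert lengths: %d-%d bp\n",
                min(x$tiles$insert_len), max(x$tiles$insert_len)))
  }
  invisible(x)
}
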
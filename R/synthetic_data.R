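# Self-contained simulator: random amplicon panels, paired reads with
# planted variants and sequencing errors, and truth sets. Emulates the
# statistical structure the caller assumes: a fragment is
# fwd_primer + insert + revcomp(rev_primer) (+ adapter), and the two reads
# of a pair start at opposite fragment ends, each beginning with its
# gene-specific primer and overlapping the insert completely.

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE), collapse = "")

#' Generate a random amplicon panel
#'
#' Builds a synthetic reference chromosome carrying `n_tiles`
#' non-overlapping tiles, each flanked by primer sites. Primer sequences
#' are the true reference flanks: the forward primer is the plus-strand
#' 5' flank, the reverse primer the reverse complement of the 3' flank
#' (the oligo as synthesized). Primer prefixes are guaranteed unique at
#' `prefix_len`. Deterministic per seed.
#'
#' @param n_tiles Number of tiles.
#' @param insert_len Insert (tile) length in bp (default 100).
#' @param primer_len Primer length in bp (default 20).
#' @param prefix_len Prefix length whose uniqueness is enforced.
#' @param chrom Chromosome name of the synthetic reference.
#' @param gap Spacer between consecutive amplicons (default 25 bp).
#' @param seed RNG seed.
#' @return A `sim_panel`: list with `tiles` (tibble: coordinates, primer
#'   names/sequences, `insert_ref`, `insert_len`, `tile_id`), `reference`
#'   (named list of chromosome strings) and `config`.
#' @export
make_panel <- function(n_tiles, insert_len = 100L, primer_len = 20L,
                       prefix_len = primer_len, chrom = "chrT",
                       gap = 25L, seed = 1L) {
  stopifnot(n_tiles >= 0, insert_len > 0, primer_len > 0,
            prefix_len <= primer_len, gap >= 0)
  withr::with_seed(seed, {
    margin <- 25L
    pieces <- character()
    cursor <- margin + 1L
    rows <- list()
    prefixes <- character()
    for (t in seq_len(n_tiles)) {
      repeat {
        fwd_site <- random_dna(primer_len)
        insert <- random_dna(insert_len)
        rev_site <- random_dna(primer_len)
        fwd <- fwd_site
        rev <- revcomp(rev_site)
        pr <- c(substr(fwd, 1L, prefix_len), substr(rev, 1L, prefix_len))
        if (!anyDuplicated(c(prefixes, pr))) break
      }
      prefixes <- c(prefixes, pr)
      start <- cursor + primer_len
      rows[[t]] <- tibble(
        chrom = chrom, start = start, end = start + insert_len - 1L,
        fwd_name = sprintf("T%03d_F", t), rev_name = sprintf("T%03d_R", t),
        fwd_seq = fwd, rev_seq = rev, insert_len = insert_len,
        insert_ref = insert,
        tile_id = sprintf("%s:%d-%d", chrom, start, start + insert_len - 1L))
      pieces <- c(pieces, fwd_site, insert, rev_site, random_dna(gap))
      cursor <- cursor + 2L * primer_len + insert_len + gap
    }
    ref_seq <- paste0(random_dna(margin), paste(pieces, collapse = ""))
    tiles <- if (n_tiles > 0) bind_rows(rows) else
      tibble(chrom = character(), start = integer(), end = integer(),
             fwd_name = character(), rev_name = character(),
             fwd_seq = character(), rev_seq = character(),
             insert_len = integer(), insert_ref = character(),
             tile_id = character())
    structure(list(
      tiles = tiles,
      reference = stats::setNames(list(ref_seq), chrom),
      config = list(n_tiles = n_tiles, insert_len = insert_len,
                    primer_len = primer_len, prefix_len = prefix_len,
                    chrom = chrom, gap = gap, seed = seed)),
      class = "sim_panel")
  })
}

#' Write a panel's files
#'
#' Emits the reference FASTA, primer-coordinates TSV and primer-sequences
#' TSV in exactly the dialects consumed by [parse_primer_coords()],
#' [parse_primer_sequences()] and [build_tile_index()].
#'
#' @param panel A `sim_panel` from [make_panel()].
#' @param dir Output directory (created if needed).
#' @return Named list of the three paths.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ref_path <- file.path(dir, "reference.fa")
  coords_path <- file.path(dir, "coords.tsv")
  seqs_path <- file.path(dir, "seqs.tsv")
  ref <- Biostrings::DNAStringSet(unlist(panel$reference))
  names(ref) <- names(panel$reference)
  Biostrings::writeXStringSet(ref, ref_path, width = 70L)
  write_primer_coords(panel$tiles, coords_path)
  write_primer_sequences(panel_primer_seqs(panel), seqs_path)
  list(reference = ref_path, coords = coords_path, seqs = seqs_path)
}

# Primer-sequences table of a panel in parse_primer_sequences() layout.
panel_primer_seqs <- function(panel) {
  tibble(name = c(rbind(panel$tiles$fwd_name, panel$tiles$rev_name)),
         sequence = c(rbind(panel$tiles$fwd_seq, panel$tiles$rev_seq)))
}

#' Plant a truth set of variants on a panel
#'
#' Assigns at most one variant per tile: an SNV with probability
#' `1 - p_indel`, otherwise an indel of 1-`max_indel` bp, placed away
#' from tile edges and left-normalised. Each sample then carries each
#' tile's variant with probability `p_carrier`, at a variant allele
#' fraction drawn from `vafs`.
#'
#' @param panel A `sim_panel`.
#' @param samples Character vector of sample names.
#' @param p_indel Probability a tile's variant is an indel (default 0.3).
#' @param max_indel Maximum indel length (default 3).
#' @param vafs Candidate VAFs (default `c(0.5, 1)`).
#' @param p_carrier Probability a sample carries a tile's variant
#'   (default 0.5).
#' @param edge_margin Minimum distance of the variant from either tile
#'   edge (default 10 bp).
#' @param seed RNG seed.
#' @return Truth tibble: `sample`, `tile_id`, `chrom`, `pos`, `ref`,
#'   `alt`, `vclass`, `vaf`.
#' @export
make_truth <- function(panel, samples, p_indel = 0.3, max_indel = 3L,
                       vafs = c(0.5, 1), p_carrier = 0.5,
                       edge_margin = 10L, seed = 1L) {
  withr::with_seed(seed, {
    tiles <- panel$tiles
    out <- list()
    for (t in seq_len(nrow(tiles))) {
      tile <- tiles[t, ]
      v <- random_tile_variant(tile, p_indel, max_indel, edge_margin)
      for (sm in samples) {
        if (stats::runif(1) > p_carrier) next
        out[[length(out) + 1L]] <- tibble(
          sample = sm, tile_id = tile$tile_id, chrom = v$chrom, pos = v$pos,
          ref = v$ref, alt = v$alt, vclass = v$vclass,
          vaf = sample(vafs, 1))
      }
    }
    if (length(out) == 0) {
      return(tibble(sample = character(), tile_id = character(),
                    chrom = character(), pos = integer(), ref = character(),
                    alt = character(), vclass = character(), vaf = double()))
    }
    arrange(bind_rows(out), .data$sample, .data$chrom, .data$pos)
  })
}

# One random, left-normalised variant within a tile's interior.
random_tile_variant <- function(tile, p_indel, max_indel, edge_margin) {
  ilen <- tile$insert_len
  off <- sample(seq.int(edge_margin + 1L, ilen - edge_margin), 1)
  pos <- tile$start + off - 1L
  refb <- substr(tile$insert_ref, off, off)
  if (stats::runif(1) > p_indel) {
    alt <- sample(setdiff(BASES, refb), 1)
    return(list(chrom = tile$chrom, pos = pos, ref = refb, alt = alt,
                vclass = "SNV"))
  }
  k <- sample.int(max_indel, 1)
  if (stats::runif(1) < 0.5 && off + k <= ilen - edge_margin) {
    ref <- substr(tile$insert_ref, off, off + k)
    v <- left_align_indel(pos, ref, refb, tile$insert_ref, tile$start)
    list(chrom = tile$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
         vclass = "deletion")
  } else {
    alt <- paste0(refb, random_dna(k))
    v <- left_align_indel(pos, refb, alt, tile$insert_ref, tile$start)
    list(chrom = tile$chrom, pos = v$pos, ref = v$ref, alt = v$alt,
         vclass = "insertion")
  }
}

# Apply a set of variants (tibble, absolute coords) to a tile's insert.
apply_variants_to_insert <- function(insert, tile_start, variants) {
  if (nrow(variants) == 0) return(insert)
  v <- arrange(variants, dplyr::desc(.data$pos))
  for (k in seq_len(nrow(v))) {
    off <- v$pos[k] - tile_start + 1L
    lr <- nchar(v$ref[k])
    insert <- paste0(substr(insert, 1L, off - 1L), v$alt[k],
                     substring(insert, off + lr))
  }
  insert
}

#' Simulate paired reads for a panel and truth set
#'
#' For every sample and tile, `depth` read pairs are generated: each pair
#' carries the tile's planted variant with probability VAF (per-pair
#' Bernoulli; `exact_counts = TRUE` plants it in exactly
#' `round(vaf * depth)` pairs for boundary tests), the fragment is
#' assembled as `fwd_primer + insert + revcomp(rev_primer) + adapter`,
#' read 1 is its 5' prefix and read 2 the 5' prefix of its reverse
#' complement, and independent per-base substitution errors are applied
#' to each read. Optionally a fraction of off-panel pairs (random
#' sequence matching no primer) is appended. Deterministic per seed.
#'
#' @param panel A `sim_panel`.
#' @param truth Truth tibble from [make_truth()] (may be empty).
#' @param samples Character vector of sample names.
#' @param depth Read pairs per tile (default 100).
#' @param error_rate Per-base substitution error probability
#'   (default 0.001).
#' @param read_len Read length (default `primer_len + insert_len`, so
#'   reads overlap the insert completely).
#' @param offpanel_frac Fraction of the emitted pairs that are off-panel
#'   (random sequence matching no primer; default 0).
#' @param qual High-quality Phred score used for all bases (default 40).
#' @param low_qual_tail Number of 3' bases per read written at Phred 2 to
#'   exercise quality masking (default 0).
#' @param exact_counts Logical; see above.
#' @param seed RNG seed.
#' @return A `sim_reads`: list with `reads` (tibble: `sample`, `id`,
#'   `read1`, `qual1`, `read2`, `qual2`), `truth`, and `config`.
#' @export
simulate_reads <- function(panel, truth, samples, depth = 100L,
                           error_rate = 0.001, read_len = NULL,
                           offpanel_frac = 0, qual = 40L,
                           low_qual_tail = 0L, exact_counts = FALSE,
                           seed = 1L) {
  cfg <- panel$config
  if (is.null(read_len)) read_len <- cfg$primer_len + cfg$insert_len
  if (read_len < cfg$primer_len + 1L) {
    abort("`read_len` must exceed the primer length")
  }
  adapter <- strrep("AGATCGGAAGAGCACACGTCTGAACTCCAGTCA", 4)
  qual_str <- paste0(
    strrep(intToUtf8(qual + 33L), read_len - low_qual_tail),
    strrep(intToUtf8(2L + 33L), low_qual_tail))

  withr::with_seed(seed, {
    prefixes <- c(substr(panel$tiles$fwd_seq, 1, cfg$prefix_len),
                  substr(panel$tiles$rev_seq, 1, cfg$prefix_len))
    chunks <- list()
    for (sm in samples) {
      for (t in seq_len(nrow(panel$tiles))) {
        tile <- panel$tiles[t, ]
        tv <- filter(truth, .data$sample == sm, .data$tile_id == tile$tile_id)
        carries <- if (nrow(tv) == 0) rep(FALSE, depth) else if (exact_counts) {
          k <- round(tv$vaf[1] * depth)
          sample(rep(c(TRUE, FALSE), c(k, depth - k)))
        } else stats::runif(depth) < tv$vaf[1]
        # two fragment templates per tile: reference and mutated allele
        mk_tpl <- function(ins) {
          frag <- paste0(tile$fwd_seq, ins, revcomp(tile$rev_seq))
          c(substr(paste0(frag, adapter), 1L, read_len),
            substr(paste0(revcomp(frag), adapter), 1L, read_len))
        }
        tpl_ref <- mk_tpl(tile$insert_ref)
        tpl_mut <- if (nrow(tv) > 0) {
          mk_tpl(apply_variants_to_insert(tile$insert_ref, tile$start, tv))
        } else tpl_ref
        chunks[[length(chunks) + 1L]] <- tibble(
          sample = sm,
          id = sprintf("%s_t%03d_p%04d", sm, t, seq_len(depth)),
          read1 = ifelse(carries, tpl_mut[1], tpl_ref[1]),
          read2 = ifelse(carries, tpl_mut[2], tpl_ref[2]))
      }
      n_on <- nrow(panel$tiles) * depth
      n_off <- round(offpanel_frac / (1 - offpanel_frac) * n_on)
      if (n_off > 0) {
        off1 <- off2 <- character(n_off)
        for (p in seq_len(n_off)) {
          repeat {
            r1 <- random_dna(read_len); r2 <- random_dna(read_len)
            if (!substr(r1, 1, cfg$prefix_len) %in% prefixes &&
                !substr(r2, 1, cfg$prefix_len) %in% prefixes) break
          }
          off1[p] <- r1; off2[p] <- r2
        }
        chunks[[length(chunks) + 1L]] <- tibble(
          sample = sm, id = sprintf("%s_off_p%04d", sm, seq_len(n_off)),
          read1 = off1, read2 = off2)
      }
    }
    reads <- bind_rows(chunks)
    reads$read1 <- add_read_errors(reads$read1, error_rate)
    reads$read2 <- add_read_errors(reads$read2, error_rate)
    reads$qual1 <- reads$qual2 <- rep(qual_str, nrow(reads))
    reads <- reads[, c("sample", "id", "read1", "qual1", "read2", "qual2")]
    structure(list(reads = reads, truth = truth,
                   config = list(depth = depth, error_rate = error_rate,
                                 read_len = read_len,
                                 offpanel_frac = offpanel_frac, qual = qual,
                                 low_qual_tail = low_qual_tail,
                                 exact_counts = exact_counts, seed = seed)),
              class = "sim_reads")
  })
}

# Independent per-base substitution errors, vectorised over reads.
add_read_errors <- function(reads, rate) {
  if (rate <= 0 || length(reads) == 0) return(reads)
  L <- nchar(reads)
  k <- stats::rbinom(length(reads), L, rate)
  for (i in which(k > 0)) {
    pos <- sample.int(L[i], k[i])
    b <- strsplit(reads[i], "", fixed = TRUE)[[1]]
    for (p in pos) b[p] <- sample(setdiff(BASES, b[p]), 1)
    reads[i] <- paste(b, collapse = "")
  }
  reads
}

#' Write simulated reads as paired FASTQ files
#'
#' One pair of files per sample (`<sample>_R1.fastq`, `<sample>_R2.fastq`;
#' gzipped when `gz = TRUE`), Phred+33.
#'
#' @param sim A `sim_reads` from [simulate_reads()].
#' @param dir Output directory.
#' @param gz Write gzip-compressed files.
#' @return Tibble with `sample`, `fastq1`, `fastq2`.
#' @export
write_fastq <- function(sim, dir, gz = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- if (gz) ".fastq.gz" else ".fastq"
  out <- list()
  for (sm in unique(sim$reads$sample)) {
    d <- filter(sim$reads, .data$sample == sm)
    f1 <- file.path(dir, paste0(sm, "_R1", ext))
    f2 <- file.path(dir, paste0(sm, "_R2", ext))
    write_one <- function(path, ids, seqs, quals, mate) {
      con <- if (gz) gzfile(path, "w") else file(path, "w")
      on.exit(close(con))
      writeLines(paste0("@", ids, "/", mate, "\n", seqs, "\n+\n", quals), con)
    }
    write_one(f1, d$id, d$read1, d$qual1, 1L)
    write_one(f2, d$id, d$read2, d$qual2, 2L)
    out[[length(out) + 1L]] <- tibble(sample = sm, fastq1 = f1, fastq2 = f2)
  }
  bind_rows(out)
}

#' Write a truth set as a VCF
#'
#' Per-sample GT is derived from the VAF (1 -> `1/1`, otherwise `0/1`)
#' and the VAF itself is carried in the `VF` FORMAT field.
#'
#' @param truth Truth tibble from [make_truth()].
#' @param sample_names Sample column order.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(truth, sample_names, path) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=primercall simulator truth",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Planted genotype\">",
    "##FORMAT=<ID=VF,Number=1,Type=Float,Description=\"Planted variant allele fraction\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t"))
  body <- character()
  if (nrow(truth) > 0) {
    sites <- sort_variants(distinct(truth[, c("chrom", "pos", "ref", "alt", "vclass")]))
    body <- vapply(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      rows <- filter(truth, .data$chrom == s$chrom, .data$pos == s$pos,
                     .data$ref == s$ref, .data$alt == s$alt)
      cells <- vapply(sample_names, function(sm) {
        r <- rows[rows$sample == sm, , drop = FALSE]
        if (nrow(r) == 0) return(".")
        gt <- if (r$vaf[1] >= 1) "1/1" else "0/1"
        paste(gt, fmt_num(r$vaf[1]), sep = ":")
      }, character(1))
      paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", "PASS",
              sprintf("VC=%s", s$vclass), "GT:VF", cells), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}
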
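# Fixtures and independent oracles used across the suite. Everything is
# generated in code; no data files.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

# A minimal hand-built single-tile index: reference is
# <pad><fwd site><insert><rev site><pad>.
toy_index <- function(insert = "ACGTACGTACGTACGTACGTACGTACGTAC",
                      fwd = "GGATCCTTAG", rev_site = "CCTAGGATCC",
                      prefix_len = 10) {
  ref <- paste0("TTTTT", fwd, insert, rev_site, "TTTTT")
  start <- 5L + nchar(fwd) + 1L
  specs <- tibble::tibble(chrom = "chr1", start = start,
                          end = start + nchar(insert) - 1L,
                          fwd_name = "T1_F", rev_name = "T1_R")
  seqs <- tibble::tibble(name = c("T1_F", "T1_R"),
                         sequence = c(fwd, revcomp(rev_site)))
  build_tile_index(specs, seqs, list(chr1 = ref), prefix_len = prefix_len)
}

# Perfect read pair for a tile row (optionally with a mutated insert).
perfect_pair <- function(tile, insert = tile$insert_ref, read_len = NULL) {
  frag <- paste0(tile$fwd_seq, insert, revcomp(tile$rev_seq))
  if (is.null(read_len)) read_len <- nchar(frag)
  r1 <- substr(frag, 1, read_len)
  r2 <- substr(revcomp(frag), 1, read_len)
  tibble::tibble(id = "p1", read1 = r1, qual1 = strrep("I", nchar(r1)),
                 read2 = r2, qual2 = strrep("I", nchar(r2)))
}

mutate_base <- function(seq, pos, to = NULL) {
  from <- substr(seq, pos, pos)
  if (is.null(to)) to <- setdiff(c("A", "C", "G", "T"), from)[1]
  paste0(substr(seq, 1, pos - 1), to, substring(seq, pos + 1))
}

write_fastq_plain <- function(path, ids, seqs, quals) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n", quals), path)
  path
}

# ---- brute-force alignment oracle (tiny sequences) ----
# Enumerates every global alignment of a and b recursively, scores it with
# the affine scheme (gap of length k costs open + k * extend), and returns
# all optimum-scoring alignments as list(read=, ref=).
enumerate_alignments <- function(a, b) {
  n <- nchar(a); m <- nchar(b)
  if (n == 0 && m == 0) return(list(list(read = "", ref = "")))
  out <- list()
  if (n > 0 && m > 0) {
    for (al in enumerate_alignments(substring(a, 2), substring(b, 2))) {
      out[[length(out) + 1]] <- list(read = paste0(substr(a, 1, 1), al$read),
                                     ref = paste0(substr(b, 1, 1), al$ref))
    }
  }
  if (m > 0) {
    for (al in enumerate_alignments(a, substring(b, 2))) {
      out[[length(out) + 1]] <- list(read = paste0("-", al$read),
                                     ref = paste0(substr(b, 1, 1), al$ref))
    }
  }
  if (n > 0) {
    for (al in enumerate_alignments(substring(a, 2), b)) {
      out[[length(out) + 1]] <- list(read = paste0(substr(a, 1, 1), al$read),
                                     ref = paste0("-", al$ref))
    }
  }
  out
}

score_alignment <- function(al, sc = align_scoring()) {
  x <- strsplit(al$read, "")[[1]]
  y <- strsplit(al$ref, "")[[1]]
  s <- 0
  in_gap_x <- in_gap_y <- FALSE
  for (i in seq_along(x)) {
    if (x[i] == "-") {
      s <- s + sc$gap_extend + if (!in_gap_x) sc$gap_open else 0
      in_gap_x <- TRUE; in_gap_y <- FALSE
    } else if (y[i] == "-") {
      s <- s + sc$gap_extend + if (!in_gap_y) sc$gap_open else 0
      in_gap_y <- TRUE; in_gap_x <- FALSE
    } else {
      s <- s + if (x[i] == y[i]) sc$match else sc$mismatch
      in_gap_x <- in_gap_y <- FALSE
    }
  }
  s
}

best_alignments <- function(a, b, sc = align_scoring()) {
  alns <- enumerate_alignments(a, b)
  scores <- vapply(alns, score_alignment, numeric(1), sc = sc)
  alns[scores == max(scores)]
}

# ---- brute-force single-indel oracle ----
# Given a reference and a read known to differ by exactly one indel,
# enumerate every placement that reproduces the read and return the
# leftmost one as a VCF-anchored variant. Independent of the aligner and
# of left_align_indel().
oracle_single_indel <- function(read, ref, chrom = "seq", ref_start = 1L) {
  L <- nchar(ref); R <- nchar(read)
  stopifnot(L != R)
  if (R < L) {           # deletion of k = L - R bases
    k <- L - R
    for (p in 2:(L - k + 1)) {   # p = first deleted base (need anchor at p-1)
      cand <- paste0(substr(ref, 1, p - 1), substring(ref, p + k))
      if (cand == read) {
        return(list(pos = ref_start + p - 2L,
                    ref = substr(ref, p - 1, p + k - 1),
                    alt = substr(ref, p - 1, p - 1), vclass = "deletion"))
      }
    }
  } else {               # insertion of k = R - L bases
    k <- R - L
    for (p in 2:(L + 1)) {       # inserted after ref position p-1
      ins <- substr(read, p, p + k - 1)
      cand <- paste0(substr(ref, 1, p - 1), ins, substring(ref, p))
      if (cand == read) {
        return(list(pos = ref_start + p - 2L,
                    ref = substr(ref, p - 1, p - 1),
                    alt = paste0(substr(ref, p - 1, p - 1), ins),
                    vclass = "insertion"))
      }
    }
  }
  NULL
}
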
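# Small sequence helpers shared across modules.

#' Reverse-complement DNA strings
#'
#' Vectorised reverse complement over `{A,C,G,T,N}` (case-insensitive;
#' output upper case). `N` maps to `N`.
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp(c("ACGT", "GGN"))
revcomp <- function(x) {
  if (length(x) == 0) return(character())
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  if (any(ok)) {
    out[ok] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(toupper(x[ok])))
    )
  }
  unname(out)
}

# Phred+33 decode of a single quality string.
phred_scores <- function(qual) utf8ToInt(qual) - 33L

# Canonical empty/constructor for the variant table used everywhere:
# one row per variant, VCF-style anchored alleles.
variant_tbl <- function(chrom = character(), pos = integer(),
                        ref = character(), alt = character(),
                        vclass = character()) {
  n <- max(length(chrom), length(pos), length(ref), length(alt), length(vclass))
  if (n == 0) {
    return(tibble::new_tibble(list(chrom = character(), pos = integer(),
                                   ref = character(), alt = character(),
                                   vclass = character()), nrow = 0L))
  }
  tibble::new_tibble(list(chrom = rep_len(as.character(chrom), n),
                          pos = rep_len(as.integer(pos), n),
                          ref = rep_len(as.character(ref), n),
                          alt = rep_len(as.character(alt), n),
                          vclass = rep_len(as.character(vclass), n)),
                     nrow = n)
}

sort_variants <- function(v) {
  if (nrow(v) < 2) return(v)
  v[order(v$chrom, v$pos, v$ref, v$alt), , drop = FALSE]
}

# Load a reference as a named list of upper-case chromosome strings.
# Accepts a FASTA path, a DNAStringSet, or an already-converted list.
load_reference <- function(reference) {
  if (is.character(reference) && length(reference) == 1) {
    if (!file.exists(reference)) {
      abort(sprintf("reference FASTA not found: '%s'", reference))
    }
    reference <- Biostrings::readDNAStringSet(reference)
  }
  if (methods::is(reference, "DNAStringSet")) {
    seqs <- toupper(as.character(reference))
    names(seqs) <- sub("\\s.*$", "", names(reference))
    return(as.list(seqs))
  }
  if (is.list(reference) && all(vapply(reference, is.character, logical(1)))) {
    return(lapply(reference, toupper))
  }
  abort("`reference` must be a FASTA file path, a DNAStringSet, or a named list of sequences.")
}
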
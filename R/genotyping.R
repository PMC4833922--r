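# Optional SNV genotyping: G-test against candidate genotype expectations
# under a constant-error model.

#' Genotype model
#'
#' A read's base is drawn uniformly from the genotype's alleles, then
#' corrupted with probability `error_rate` into one of the three other
#' bases (uniformly, `error_rate/3` each).
#'
#' @param ploidy 1 (haploid) or 2 (diploid, default).
#' @param error_rate Constant per-read error probability (default 1/500).
#' @return A list of class `genotype_model`.
#' @export
genotype_model <- function(ploidy = 2L, error_rate = 1 / 500) {
  ploidy <- as.integer(ploidy)
  if (!ploidy %in% c(1L, 2L)) abort("`ploidy` must be 1 or 2")
  if (error_rate < 0 || error_rate >= 1) abort("`error_rate` must be in [0, 1)")
  structure(list(ploidy = ploidy, error_rate = error_rate),
            class = "genotype_model")
}

BASES <- c("A", "C", "G", "T")

#' Expected base distribution of a genotype
#'
#' @param genotype Character vector of alleles (length = ploidy), e.g.
#'   `c("A", "C")` for a heterozygote.
#' @param model A [genotype_model()].
#' @return Named probability vector over A, C, G, T summing to 1.
#' @export
expected_distribution <- function(genotype, model = genotype_model()) {
  if (!all(genotype %in% BASES)) abort("genotype alleles must be A, C, G or T")
  e <- model$error_rate
  p <- stats::setNames(numeric(4), BASES)
  for (a in genotype) {
    contrib <- stats::setNames(rep(e / 3, 4), BASES)
    contrib[a] <- 1 - e
    p <- p + contrib / length(genotype)
  }
  p
}

#' G-test statistic between an observed pileup and an expected distribution
#'
#' `G = 2 * sum(O * ln(O / (n * E)))` over bases with observed count
#' `O > 0` (the `0 * ln 0 = 0` convention). Non-negative; zero exactly
#' when observed proportions equal the expectation. An observed base with
#' zero expected probability yields `Inf` (that candidate is maximally
#' disfavoured).
#'
#' @param observed Named (A,C,G,T) non-negative counts.
#' @param expected Named probability vector from [expected_distribution()].
#' @return The G statistic (non-negative, possibly `Inf`).
#' @export
g_statistic <- function(observed, expected) {
  o <- as.numeric(observed[BASES])
  o[is.na(o)] <- 0
  e <- as.numeric(expected[BASES])
  n <- sum(o)
  if (n < 1) abort("pileup must contain at least one observation")
  nz <- o > 0
  if (any(nz & e == 0)) return(Inf)
  g <- 2 * sum(o[nz] * log(o[nz] / (n * e[nz])))
  max(g, 0)  # clamp tiny negative rounding noise
}

#' Genotype an SNV pileup by minimum-G selection
#'
#' Evaluates the candidate genotypes built from the reference and
#' alternate allele (hom-ref, het, hom-alt for diploid; ref, alt for
#' haploid), computes each candidate's G statistic, and reports the
#' genotype with the smallest distance to the observed pileup. Ties
#' prefer the candidate with more reference alleles.
#'
#' @param pileup Named (A,C,G,T) base counts at the variant position.
#' @param ref_base,alt_base The two alleles (distinct single bases).
#' @param model A [genotype_model()].
#' @return A `genotype_call`: list with `genotype` (allele vector), `gt`
#'   (VCF GT string: `0/0`, `0/1`, `1/1`, or haploid `0`/`1`),
#'   `g_statistic`, and `candidates` (tibble of all evaluated genotypes
#'   with their G values).
#' @export
genotype_call <- function(pileup, ref_base, alt_base, model = genotype_model()) {
  if (ref_base == alt_base) abort("`ref_base` and `alt_base` must differ")
  cands <- if (model$ploidy == 2L) {
    list(list(g = c(ref_base, ref_base), gt = "0/0", nref = 2L),
         list(g = c(ref_base, alt_base), gt = "0/1", nref = 1L),
         list(g = c(alt_base, alt_base), gt = "1/1", nref = 0L))
  } else {
    list(list(g = ref_base, gt = "0", nref = 1L),
         list(g = alt_base, gt = "1", nref = 0L))
  }
  gvals <- vapply(cands, function(cc)
    g_statistic(pileup, expected_distribution(cc$g, model)), numeric(1))
  nrefs <- vapply(cands, function(cc) cc$nref, integer(1))
  best <- order(gvals, -nrefs)[1]
  structure(list(
    genotype = cands[[best]]$g,
    gt = cands[[best]]$gt,
    g_statistic = gvals[best],
    candidates = tibble(
      gt = vapply(cands, function(cc) cc$gt, character(1)),
      genotype = vapply(cands, function(cc) paste(cc$g, collapse = "/"), character(1)),
      g_statistic = gvals)
  ), class = "genotype_call")
}

#' @export
print.genotype_call <- function(x, ...) {
  cat(sprintf("<genotype_call> %s (G = %.4g)\n", x$gt, x$g_statistic))
  invisible(x)
}

#' @export
tidy.genotype_call <- function(x, ...) x$candidates

#' @export
glance.genotype_call <- function(x, ...) {
  tibble(gt = x$gt, genotype = paste(x$genotype, collapse = "/"),
         g_statistic = x$g_statistic)
}
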
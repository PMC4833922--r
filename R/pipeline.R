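# End-to-end driver: panel metadata -> index -> per-sample calling ->
# merged outputs. Samples are called independently; the index is built
# once.

#' Run the full variant-calling pipeline
#'
#' @param coords Path to the primer-coordinates TSV (or a parsed tibble).
#' @param seqs Path to the primer-sequences TSV (or a parsed tibble).
#' @param reference Reference FASTA path, `DNAStringSet`, or named list.
#' @param samples Tibble with columns `sample`, `fastq1`, `fastq2` (one
#'   row per sample), or a named list of `c(fastq1, fastq2)` pairs.
#' @param prefix_len Primer-prefix hash key length.
#' @param mode `"thorough"` (at most one linear-scan mismatch) or
#'   `"fast"` (multiple well-separated mismatches accepted).
#' @param fast_gap Fast-mode separation parameter.
#' @param thresholds A [calling_thresholds()] object.
#' @param scoring An [align_scoring()] object for the gapped fallback.
#' @param genotype Logical; G-test genotyping of SNVs.
#' @param model A [genotype_model()].
#' @return A `primercall_run`: list with `calls` (tibble over all
#'   samples), `coverage` (per sample x tile), `log` (per-sample totals),
#'   `config`, `index`, and timestamps.
#' @export
call_variants <- function(coords, seqs, reference, samples,
                          prefix_len = 20L, mode = c("thorough", "fast"),
                          fast_gap = 5L, thresholds = calling_thresholds(),
                          scoring = align_scoring(), genotype = FALSE,
                          model = genotype_model()) {
  mode <- match.arg(mode)
  started <- Sys.time()
  specs <- if (is.character(coords)) parse_primer_coords(coords) else coords
  pseqs <- if (is.character(seqs)) parse_primer_sequences(seqs) else seqs
  if (is.list(samples) && !is.data.frame(samples)) {
    samples <- tibble(sample = names(samples),
                      fastq1 = vapply(samples, `[`, character(1), 1),
                      fastq2 = vapply(samples, `[`, character(1), 2))
  }
  for (f in c(samples$fastq1, samples$fastq2)) {
    if (!file.exists(f)) abort(sprintf("FASTQ file not found: '%s'", f))
  }
  index <- build_tile_index(specs, pseqs, reference, prefix_len)

  calls <- list(); cov <- list(); logs <- list()
  for (i in seq_len(nrow(samples))) {
    sm <- samples$sample[i]
    pairs <- stream_pairs(samples$fastq1[i], samples$fastq2[i])
    bound <- bin_pairs(pairs, index)
    res <- call_sample(bound, index, thresholds, mode, fast_gap, scoring,
                       genotype, model)
    if (nrow(res$calls) > 0) {
      calls[[length(calls) + 1L]] <- mutate(res$calls, sample = sm, .before = 1)
    }
    cov[[i]] <- mutate(res$coverage, sample = sm, .before = 1)
    logs[[i]] <- c(list(sample = sm), as.list(res$log))
  }

  calls_tbl <- if (length(calls) > 0) bind_rows(calls) else {
    k <- mutate(variant_tbl(), pair_count = integer(), depth = integer(),
                proportion = double(), filters = character(),
                tile_id = character())
    if (genotype) k <- mutate(k, gt = character(), g_statistic = double())
    mutate(k, sample = character(), .before = 1)
  }
  structure(list(
    calls = arrange(calls_tbl, .data$sample, .data$chrom, .data$pos,
                    .data$ref, .data$alt),
    coverage = bind_rows(cov),
    log = bind_rows(lapply(logs, as_tibble)),
    config = list(prefix_len = prefix_len, mode = mode, fast_gap = fast_gap,
                  min_overlap_frac = thresholds$min_overlap_frac,
                  anchor = thresholds$anchor,
                  anchor_len = thresholds$anchor_len,
                  min_abs_pairs = thresholds$min_abs_pairs,
                  min_prop_pairs = thresholds$min_prop_pairs,
                  qual_threshold = thresholds$qual_threshold,
                  genotype = genotype, ploidy = model$ploidy,
                  error_rate = model$error_rate),
    index = index, samples = samples$sample,
    started = started, finished = Sys.time()),
    class = "primercall_run")
}

#' @export
print.primercall_run <- function(x, ...) {
  cat(sprintf("<primercall_run> %d sample(s), %d tile(s)\n",
              length(x$samples), nrow(x$index$tiles)))
  cat(sprintf("  calls: %d (%d PASS)\n", nrow(x$calls),
              sum(x$calls$filters == "")))
  invisible(x)
}

#' Broom-style accessors for a run
#'
#' `tidy()` returns the call table (one row per sample x variant);
#' `glance()` a one-row run summary.
#'
#' @param x A `primercall_run`.
#' @param ... Unused.
#' @export
tidy.primercall_run <- function(x, ...) x$calls

#' @rdname tidy.primercall_run
#' @export
glance.primercall_run <- function(x, ...) {
  tibble(n_samples = length(x$samples),
         n_tiles = nrow(x$index$tiles),
         pairs_seen = sum(x$log$pairs_seen),
         pairs_bound = sum(x$log$pairs_bound),
         primer_match_rate = sum(x$log$pairs_bound) / max(1, sum(x$log$pairs_seen)),
         n_calls = nrow(x$calls),
         n_pass = sum(x$calls$filters == ""))
}

#' Write all pipeline outputs
#'
#' @param run A `primercall_run`.
#' @param vcf,coverage,log Output paths (`NULL` to skip).
#' @param reference_name,command Header echoes for the VCF.
#' @param date Write a dated VCF header line.
#' @return `run`, invisibly.
#' @export
write_outputs <- function(run, vcf = NULL, coverage = NULL, log = NULL,
                          reference_name = NULL, command = NULL, date = TRUE) {
  if (!is.null(vcf)) {
    write_vcf(run$calls, run$samples, vcf, reference_name = reference_name,
              command = command, date = date)
  }
  if (!is.null(coverage)) write_coverage(run$coverage, coverage)
  if (!is.null(log)) write_run_log(run, log)
  invisible(run)
}
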
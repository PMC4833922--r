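# VCF, per-amplicon coverage and run-log output.

fmt_num <- function(x) ifelse(is.na(x), ".", sprintf("%.6g", x))

#' Write variant calls to a multi-sample VCF 4.2 file
#'
#' Samples are called independently and merged at write time into one
#' VCF with a genotype column per sample. Site-level FILTER is `PASS`
#' when the variant passes in at least one sample, otherwise the union of
#' failed-filter labels; the per-sample filter status is carried in the
#' `FT` FORMAT field. QUAL is left missing (the caller defines no call
#' quality). Duplicate identical records within a sample are merged by
#' summing pair counts.
#'
#' @param calls Call tibble with a `sample` column (as assembled by
#'   [call_variants()]), optionally with `gt`/`g_statistic`.
#' @param sample_names Character vector fixing the sample column order.
#' @param path Output path.
#' @param reference_name Optional reference identifier for the header.
#' @param command Optional command-line echo for the header.
#' @param date Logical; write a `##fileDate` line (disable for
#'   byte-reproducible output).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(calls, sample_names, path, reference_name = NULL,
                      command = NULL, date = TRUE) {
  if (!"gt" %in% names(calls)) calls$gt <- NA_character_
  if (!"g_statistic" %in% names(calls)) calls$g_statistic <- NA_real_
  if (nrow(calls) > 0) {
    calls <- summarise(
      group_by(calls, .data$sample, .data$chrom, .data$pos, .data$ref,
               .data$alt, .data$vclass),
      pair_count = sum(.data$pair_count),
      depth = .data$depth[1], proportion = .data$proportion[1],
      filters = .data$filters[1], gt = .data$gt[1],
      g_statistic = .data$g_statistic[1], .groups = "drop")
  }

  header <- c(
    "##fileformat=VCFv4.2",
    if (date) sprintf("##fileDate=%s", format(Sys.Date(), "%Y%m%d")),
    sprintf("##source=primercall %s", as.character(utils::packageVersion("primercall"))),
    if (!is.null(reference_name)) sprintf("##reference=%s", reference_name),
    if (!is.null(command)) sprintf("##commandline=%s", command),
    "##FILTER=<ID=at,Description=\"Concordant pair count below the minimum absolute threshold\">",
    "##FILTER=<ID=pt,Description=\"Concordant pair proportion below the minimum proportion threshold\">",
    "##INFO=<ID=VC,Number=1,Type=String,Description=\"Variant class (SNV, insertion, deletion)\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=NP,Number=1,Type=Integer,Description=\"Concordant read pairs carrying the variant\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read pairs overlapping the tile after filters\">",
    "##FORMAT=<ID=PP,Number=1,Type=Float,Description=\"NP / DP\">",
    "##FORMAT=<ID=GS,Number=1,Type=Float,Description=\"G statistic of the reported genotype\">",
    "##FORMAT=<ID=FT,Number=1,Type=String,Description=\"Per-sample filter status\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", sample_names), collapse = "\t")
  )

  body <- character()
  if (nrow(calls) > 0) {
    sites <- sort_variants(distinct(calls[, c("chrom", "pos", "ref", "alt", "vclass")]))
    body <- vapply(seq_len(nrow(sites)), function(i) {
      s <- sites[i, ]
      rows <- filter(calls, .data$chrom == s$chrom, .data$pos == s$pos,
                     .data$ref == s$ref, .data$alt == s$alt)
      site_filter <- if (any(rows$filters == "")) "PASS" else {
        paste(sort(unique(unlist(strsplit(rows$filters, ";", fixed = TRUE)))),
              collapse = ";")
      }
      cells <- vapply(sample_names, function(sm) {
        r <- rows[rows$sample == sm, , drop = FALSE]
        if (nrow(r) == 0) return(".")
        paste(
          ifelse(is.na(r$gt[1]), ".", r$gt[1]),
          r$pair_count[1], r$depth[1], fmt_num(r$proportion[1]),
          fmt_num(r$g_statistic[1]),
          ifelse(r$filters[1] == "", "PASS", r$filters[1]),
          sep = ":")
      }, character(1))
      paste(c(s$chrom, s$pos, ".", s$ref, s$alt, ".", site_filter,
              sprintf("VC=%s", s$vclass), "GT:NP:DP:PP:GS:FT", cells),
            collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a primercall (or truth) VCF back into a call tibble
#'
#' Minimal reader for the dialect written by [write_vcf()] and
#' [write_truth_vcf()]: returns one row per (sample, variant) with data,
#' reconstructing the per-sample fields. Used for round trips and truth
#' comparisons.
#'
#' @param path VCF path.
#' @return A tibble with `sample`, `chrom`, `pos`, `ref`, `alt` and any
#'   of `vclass`, `pair_count`, `depth`, `proportion`, `g_statistic`,
#'   `gt`, `filters`, `vaf` present in the file. Sample names are in
#'   `attr(, "sample_names")`.
#' @export
parse_vcf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#CHROM", lines)
  if (length(hdr) != 1) abort(sprintf("'%s' is not a valid VCF: missing #CHROM line", path))
  cols <- strsplit(lines[hdr], "\t", fixed = TRUE)[[1]]
  samples <- if (length(cols) > 9) cols[10:length(cols)] else character()
  data_lines <- lines[-seq_len(hdr)]
  data_lines <- data_lines[nzchar(data_lines)]
  out <- list()
  for (ln in data_lines) {
    f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    info <- f[8]
    vclass <- if (grepl("VC=", info)) sub(".*VC=([^;]+).*", "\\1", info) else NA_character_
    fmt <- strsplit(f[9], ":", fixed = TRUE)[[1]]
    for (si in seq_along(samples)) {
      cell <- f[9 + si]
      if (cell == ".") next
      vals <- strsplit(cell, ":", fixed = TRUE)[[1]]
      names(vals) <- fmt[seq_along(vals)]
      num <- function(k) if (k %in% names(vals) && vals[[k]] != ".")
        as.numeric(vals[[k]]) else NA_real_
      row <- tibble(
        sample = samples[si], chrom = f[1], pos = as.integer(f[2]),
        ref = f[4], alt = f[5], vclass = vclass,
        pair_count = as.integer(num("NP")), depth = as.integer(num("DP")),
        proportion = num("PP"), g_statistic = num("GS"),
        gt = if ("GT" %in% names(vals) && vals[["GT"]] != ".")
          vals[["GT"]] else NA_character_,
        filters = if ("FT" %in% names(vals))
          ifelse(vals[["FT"]] == "PASS", "", vals[["FT"]]) else NA_character_,
        vaf = num("VF"))
      out[[length(out) + 1L]] <- row
    }
  }
  res <- if (length(out) > 0) bind_rows(out) else
    tibble(sample = character(), chrom = character(), pos = integer(),
           ref = character(), alt = character(), vclass = character(),
           pair_count = integer(), depth = integer(), proportion = double(),
           g_statistic = double(), gt = character(), filters = character(),
           vaf = double())
  attr(res, "sample_names") <- samples
  res
}

#' Write / read the per-amplicon coverage table
#'
#' One row per (sample, tile) with the counts along the filter chain;
#' headered TSV with stable column order. Tiles with zero bound pairs are
#' written with zeros, not omitted.
#'
#' @param records Coverage tibble (with `sample` column).
#' @param path Output path.
#' @return `path` invisibly; `read_coverage` returns the tibble.
#' @export
write_coverage <- function(records, path) {
  cols <- c("sample", "tile_id", "chrom", "start", "end", "fwd_name",
            "rev_name", "pairs_bound", "pairs_overlap", "pairs_anchor", "depth")
  readr::write_tsv(records[, cols], path)
  invisible(path)
}

#' @rdname write_coverage
#' @export
read_coverage <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    sample = "c", tile_id = "c", chrom = "c", start = "i",
                    end = "i", fwd_name = "c", rev_name = "c",
                    pairs_bound = "i", pairs_overlap = "i",
                    pairs_anchor = "i", depth = "i"))
}

#' Write the run log
#'
#' Plain-text summary of a [call_variants()] run: timestamps, the full
#' configuration echo, and per-sample totals of the read-pair accounting
#' (seen = bound + unassigned).
#'
#' @param run A `primercall_run` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_log <- function(run, path) {
  cfg <- run$config
  lines <- c(
    sprintf("primercall %s run log", as.character(utils::packageVersion("primercall"))),
    sprintf("started: %s", format(run$started, "%Y-%m-%d %H:%M:%S")),
    sprintf("finished: %s", format(run$finished, "%Y-%m-%d %H:%M:%S")),
    "configuration:",
    vapply(names(cfg), function(k)
      sprintf("  %s = %s", k, paste(format(cfg[[k]]), collapse = " ")),
      character(1)),
    "per-sample totals:")
  for (i in seq_len(nrow(run$log))) {
    r <- run$log[i, ]
    lines <- c(lines,
      sprintf("  sample %s: seen=%d bound=%d unassigned=%d (no_primer=%d cross_tile=%d orientation=%d) overlap_failed=%d anchor_failed=%d depth_total=%d",
              r$sample, r$pairs_seen, r$pairs_bound, r$pairs_unassigned,
              r$no_primer, r$cross_tile, r$orientation,
              r$overlap_failed, r$anchor_failed, r$depth_total))
  }
  writeLines(lines, path)
  invisible(path)
}
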
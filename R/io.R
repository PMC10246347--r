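# Readers for the BED-family formats the pipeline consumes and writers for
# its outputs. p-values are carried internally only as -log10(p): MACS2
# emits that scale directly and Fisher combination / BH work in log space
# without underflow.

read_filtered_lines <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  list(lines = lines[keep], lineno = which(keep))
}

split_fields <- function(lines) {
  strsplit(lines, "\t", fixed = TRUE)
}

field_matrix <- function(path, n_min, what) {
  lf <- read_filtered_lines(path)
  if (length(lf$lines) == 0) {
    return(list(fields = list(), lineno = integer(0)))
  }
  fields <- split_fields(lf$lines)
  nf <- lengths(fields)
  bad <- which(nf < n_min)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s:%d: expected at least %d tab-separated columns for %s, found %d.",
      path, lf$lineno[bad[1]], n_min, what, nf[bad[1]]
    ))
  }
  list(fields = fields, lineno = lf$lineno)
}

parse_num <- function(x, path, lineno, what) {
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    abort(sprintf(
      "%s:%d: non-numeric %s field: '%s'.",
      path, lineno[bad[1]], what, x[bad[1]]
    ))
  }
  out
}

empty_peaks <- function() {
  tibble::tibble(
    chrom = character(0), start = double(0), end = double(0),
    name = character(0), score = double(0), neg_log10_p = double(0),
    rank = integer(0)
  )
}

check_peak_intervals <- function(x, path, lineno) {
  bad <- which(x$start < 0 | x$start >= x$end)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s:%d: invalid interval [%g, %g).",
      path, lineno[bad[1]], x$start[bad[1]], x$end[bad[1]]
    ))
  }
  invisible(x)
}

#' Read an ENCODE narrowPeak file
#'
#' Parses the BED6+4 narrowPeak dialect: chrom, start, end, name, score,
#' strand, signalValue, pValue, qValue, peak. Column 8 holds -log10 of the
#' calling p-value and becomes `neg_log10_p`. Comment, `track` and `browser`
#' lines are skipped; any malformed line is a hard error naming the file and
#' line. Peaks overlapping each other within the file are kept as-is.
#'
#' @param path Path to a narrowPeak file.
#'
#' @return A tibble with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `neg_log10_p` and `rank` (record number in file order).
#' @export
read_narrowpeak <- function(path) {
  fm <- field_matrix(path, 10, "narrowPeak")
  if (length(fm$fields) == 0) {
    return(empty_peaks())
  }
  col <- function(i) vapply(fm$fields, `[[`, character(1), i)
  out <- tibble::tibble(
    chrom = col(1),
    start = parse_num(col(2), path, fm$lineno, "start"),
    end = parse_num(col(3), path, fm$lineno, "end"),
    name = col(4),
    score = parse_num(col(5), path, fm$lineno, "score"),
    neg_log10_p = parse_num(col(8), path, fm$lineno, "pValue"),
    rank = seq_along(fm$fields)
  )
  check_peak_intervals(out, path, fm$lineno)
  bad <- which(out$neg_log10_p < 0)
  if (length(bad) > 0) {
    abort(sprintf(
      "%s:%d: narrowPeak column 8 must be -log10(p) >= 0, found %g.",
      path, fm$lineno[bad[1]], out$neg_log10_p[bad[1]]
    ))
  }
  out
}

#' Read peaks from a generic BED file with a p-value column
#'
#' For peak callers that do not emit narrowPeak. The designated column holds
#' either a linear p-value in (0, 1] or -log10(p), per `p_scale`. A literal
#' p-value of 0 on the linear scale is a hard error rather than a silent
#' clamp, since clamping would change Fisher sums invisibly.
#'
#' @param path Path to a tab-separated BED-like file (>= 3 columns).
#' @param pcol 1-based index of the column holding the p-value.
#' @param p_scale `"neglog10"` (default) or `"linear"`.
#'
#' @return A tibble as from [read_narrowpeak()].
#' @export
read_bed_peaks <- function(path, pcol, p_scale = c("neglog10", "linear")) {
  p_scale <- match.arg(p_scale)
  pcol <- as.integer(pcol)
  if (is.na(pcol) || pcol < 4) {
    abort("`pcol` must be a column index past the three BED coordinates.")
  }
  fm <- field_matrix(path, pcol, "BED with p-value column")
  if (length(fm$fields) == 0) {
    return(empty_peaks())
  }
  col <- function(i) vapply(fm$fields, `[[`, character(1), i)
  n <- length(fm$fields)
  nf <- lengths(fm$fields)
  pval <- parse_num(col(pcol), path, fm$lineno, "p-value")
  if (p_scale == "linear") {
    bad <- which(pval <= 0 | pval > 1)
    if (length(bad) > 0) {
      abort(sprintf(
        "%s:%d: linear-scale p-value outside (0, 1]: %g.",
        path, fm$lineno[bad[1]], pval[bad[1]]
      ))
    }
    nlp <- -log10(pval)
  } else {
    bad <- which(pval < 0)
    if (length(bad) > 0) {
      abort(sprintf(
        "%s:%d: -log10(p) must be >= 0, found %g.",
        path, fm$lineno[bad[1]], pval[bad[1]]
      ))
    }
    nlp <- pval
  }
  out <- tibble::tibble(
    chrom = col(1),
    start = parse_num(col(2), path, fm$lineno, "start"),
    end = parse_num(col(3), path, fm$lineno, "end"),
    name = if (all(nf >= 4)) col(4) else paste0("peak_", seq_len(n)),
    score = if (all(nf >= 5)) {
      parse_num(col(5), path, fm$lineno, "score")
    } else {
      rep(0, n)
    },
    neg_log10_p = nlp,
    rank = seq_len(n)
  )
  check_peak_intervals(out, path, fm$lineno)
  out
}

#' Read an annotation track (BED3+)
#'
#' @param path Path to a BED file; only the first three columns are used.
#' @param label Annotation name (e.g. `"enhancers"`); defaults to the file
#'   name without extension.
#'
#' @return A tibble of intervals with a `label` column.
#' @export
read_annotation <- function(path, label = NULL) {
  if (is.null(label)) {
    label <- sub("\\.[^.]*$", "", basename(path))
  }
  fm <- field_matrix(path, 3, "BED annotation")
  if (length(fm$fields) == 0) {
    return(tibble::tibble(
      chrom = character(0), start = double(0), end = double(0),
      label = character(0)
    ))
  }
  col <- function(i) vapply(fm$fields, `[[`, character(1), i)
  out <- tibble::tibble(
    chrom = col(1),
    start = parse_num(col(2), path, fm$lineno, "start"),
    end = parse_num(col(3), path, fm$lineno, "end"),
    label = label
  )
  check_peak_intervals(out, path, fm$lineno)
  out
}

#' Read a UCSC chrom.sizes table
#'
#' @param path Two-column TSV: chromosome name, length in nucleotides.
#' @return A genome layout tibble (see [genome_layout()]).
#' @export
read_chrom_sizes <- function(path) {
  fm <- field_matrix(path, 2, "chrom.sizes")
  if (length(fm$fields) == 0) {
    abort(sprintf("%s: empty chrom.sizes file.", path))
  }
  col <- function(i) vapply(fm$fields, `[[`, character(1), i)
  genome_layout(col(1), parse_num(col(2), path, fm$lineno, "length"))
}

format_bed_score <- function(neg_log10_p) {
  pmin(1000, round(10 * neg_log10_p))
}

#' Write consensus regions to BED6+2
#'
#' Columns: chrom, start, end, name (`consensus_N`), display score
#' `min(1000, round(-10 log10 p_combined))`, strand `"."`, then the Fisher
#' chi-squared statistic and -log10 of the combined p-value, both to six
#' decimal places.
#'
#' @param consensus Tibble of consensus regions as produced by [run_mspc()]
#'   (must be sorted by chrom, start and carry `chi2` and
#'   `combined_neg_log10_p`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_consensus <- function(consensus, path) {
  lines <- if (nrow(consensus) == 0) {
    character(0)
  } else {
    sprintf(
      "%s\t%d\t%d\t%s\t%d\t.\t%.6f\t%.6f",
      consensus$chrom, as.integer(consensus$start), as.integer(consensus$end),
      consensus$name, as.integer(format_bed_score(consensus$combined_neg_log10_p)),
      consensus$chi2, consensus$combined_neg_log10_p
    )
  }
  wrote <- tryCatch(
    {
      writeLines(lines, path)
      TRUE
    },
    error = function(e) FALSE,
    warning = function(e) FALSE
  )
  if (!wrote) {
    abort(sprintf("Cannot write consensus file: %s", path))
  }
  invisible(path)
}

#' Read back a consensus BED6+2 file
#'
#' Inverse of [write_consensus()]; used for round-tripping results between
#' pipeline stages (e.g. feeding consensus regions to the enrichment test).
#'
#' @param path Path written by [write_consensus()].
#' @return Tibble with `chrom`, `start`, `end`, `name`, `score`, `chi2`,
#'   `combined_neg_log10_p`.
#' @export
read_consensus <- function(path) {
  fm <- field_matrix(path, 8, "consensus BED6+2")
  if (length(fm$fields) == 0) {
    return(tibble::tibble(
      chrom = character(0), start = double(0), end = double(0),
      name = character(0), score = double(0), chi2 = double(0),
      combined_neg_log10_p = double(0)
    ))
  }
  col <- function(i) vapply(fm$fields, `[[`, character(1), i)
  out <- tibble::tibble(
    chrom = col(1),
    start = parse_num(col(2), path, fm$lineno, "start"),
    end = parse_num(col(3), path, fm$lineno, "end"),
    name = col(4),
    score = parse_num(col(5), path, fm$lineno, "score"),
    chi2 = parse_num(col(7), path, fm$lineno, "chi2"),
    combined_neg_log10_p = parse_num(col(8), path, fm$lineno, "combined p")
  )
  check_peak_intervals(out, path, fm$lineno)
  out
}

#' Write all outputs of a run to a directory
#'
#' Writes `consensus.bed` (BED6+2), per-replicate `repN_confirmed.bed`,
#' `repN_discarded.bed` and `repN_truepositives.bed` (input columns plus a
#' decision column), and `run_log.json` with the configuration and
#' per-replicate counts by class and status.
#'
#' @param result An `mspc_result` from [run_mspc()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_mspc_result <- function(result, dir) {
  stopifnot(inherits(result, "mspc_result"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  write_consensus(result$consensus, file.path(dir, "consensus.bed"))
  d <- result$decisions
  write_peak_bed <- function(rows, path) {
    lines <- if (nrow(rows) == 0) {
      character(0)
    } else {
      sprintf(
        "%s\t%d\t%d\t%s\t%d\t.\t%.6f\t%s",
        rows$chrom, as.integer(rows$start), as.integer(rows$end),
        rows$name, as.integer(round(rows$score)), rows$neg_log10_p,
        rows$status
      )
    }
    writeLines(lines, path)
  }
  for (r in sort(unique(d$replicate))) {
    dr <- d[d$replicate == r, , drop = FALSE]
    write_peak_bed(
      dr[dr$status == "confirmed", ],
      file.path(dir, sprintf("rep%d_confirmed.bed", r))
    )
    write_peak_bed(
      dr[dr$status %in% c("discarded", "background"), ],
      file.path(dir, sprintf("rep%d_discarded.bed", r))
    )
    write_peak_bed(
      dr[dr$true_positive, ],
      file.path(dir, sprintf("rep%d_truepositives.bed", r))
    )
  }
  counts <- d %>%
    dplyr::count(.data$replicate, .data$class, .data$status) %>%
    dplyr::arrange(.data$replicate, .data$class, .data$status)
  log <- list(
    config = unclass(result$config),
    n_replicates = length(unique(d$replicate)),
    n_consensus = nrow(result$consensus),
    counts = counts
  )
  jsonlite::write_json(
    log, file.path(dir, "run_log.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(dir)
}
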
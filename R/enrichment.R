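# Annotation-enrichment z-test: compares the per-nucleotide conditional
# probability of carrying an annotation inside a peak set (p) against the
# same probability outside it (a). beta = p - a measures annotation recall
# over the genomic background; z = beta / sigma with sigma the unpooled
# two-proportion standard error, approximately N(0, 1) under the null of
# peaks placed independently of annotations.

#' Annotation-enrichment z-test for a peak set
#'
#' Partitions the genome into nucleotides covered by the peak set and
#' nucleotides not covered by it, and computes for each part the probability
#' of carrying the annotation: `p = k_peak_bp / n_peak_bp` within peaks,
#' `a = k_bg_bp / n_bg_bp` outside. The enrichment effect is
#' `beta = p - a` (`beta > 0`: a random annotated position is more likely to
#' lie under a peak) and the score is `z = beta / sigma` with
#' `sigma = sqrt(p(1-p)/n_peak_bp + a(1-a)/n_bg_bp)`. Peaks and annotation
#' intervals are union-merged first, so each nucleotide counts at most once
#' on each side.
#'
#' @param peaks Data frame of peak intervals (e.g. consensus regions).
#' @param annotation Data frame of annotation intervals, optionally with a
#'   `label` column (as from [read_annotation()]).
#' @param genome Genome layout (see [genome_layout()]); all intervals must
#'   lie within its bounds.
#'
#' @return A one-row tibble: `label`, `n_peak_bp`, `k_peak_bp`, `n_bg_bp`,
#'   `k_bg_bp`, `p_hat`, `a_hat`, `beta`, `sigma`, `z`. When `sigma` is 0,
#'   `z` is 0 if `beta` is 0 and signed infinity otherwise.
#' @export
#'
#' @examples
#' genome <- genome_layout("chr1", 1000)
#' peaks <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
#' enrichment_test(peaks, peaks, genome) # perfect recall: beta = 1
enrichment_test <- function(peaks, annotation, genome) {
  genome <- as_genome_layout(genome)
  peaks <- check_intervals(peaks, genome, arg = "peaks")
  annotation <- check_intervals(annotation, genome, arg = "annotation")
  label <- if ("label" %in% names(annotation) && nrow(annotation) > 0) {
    annotation$label[1]
  } else {
    "annotation"
  }
  G <- genome_size(genome)
  n_peak_bp <- coverage_bp(peaks)
  n_bg_bp <- G - n_peak_bp
  if (n_peak_bp == 0 || n_bg_bp == 0) {
    abort(paste(
      "Peak coverage must be strictly between 0 and the genome size;",
      "conditional probabilities are undefined otherwise."
    ))
  }
  ann_bp <- coverage_bp(annotation)
  k_peak_bp <- intersect_bp(peaks, annotation)
  k_bg_bp <- ann_bp - k_peak_bp
  p_hat <- k_peak_bp / n_peak_bp
  a_hat <- k_bg_bp / n_bg_bp
  beta <- p_hat - a_hat
  sigma <- sqrt(
    p_hat * (1 - p_hat) / n_peak_bp + a_hat * (1 - a_hat) / n_bg_bp
  )
  z <- if (sigma > 0) {
    beta / sigma
  } else if (beta == 0) {
    0
  } else {
    sign(beta) * Inf
  }
  tibble::tibble(
    label = label,
    n_peak_bp = n_peak_bp, k_peak_bp = k_peak_bp,
    n_bg_bp = n_bg_bp, k_bg_bp = k_bg_bp,
    p_hat = p_hat, a_hat = a_hat,
    beta = beta, sigma = sigma, z = z
  )
}

#' Split consensus regions into common and method-specific sets
#'
#' A consensus region is *common* when it overlaps (>= 1 nucleotide) at
#' least one interval of a conservative reference peak set (e.g. the output
#' of a reproducibility-based method); regions without any reference overlap
#' are *specific* -- the rescued regions whose functional relevance the
#' enrichment test probes. Membership is at whole-region granularity.
#'
#' @param consensus Data frame of consensus regions (or any intervals).
#' @param reference Data frame of reference intervals; may be empty, in
#'   which case every region is specific.
#'
#' @return `consensus` as a tibble with an added character column `subset`
#'   (`"common"` or `"specific"`).
#' @export
split_common_specific <- function(consensus, reference) {
  consensus <- check_intervals(consensus, arg = "consensus")
  reference <- check_intervals(reference, arg = "reference")
  consensus$subset <- "specific"
  if (nrow(consensus) > 0 && nrow(reference) > 0) {
    idx <- overlap_index(reference)
    hits <- query_overlaps(idx, consensus)
    consensus$subset[unique(hits$query)] <- "common"
  }
  consensus
}

#' Enrichment panel over peak subsets and annotation tracks
#'
#' Runs [enrichment_test()] for every combination of peak subset (from
#' [split_common_specific()]) and annotation track, yielding the tidy table
#' behind common-versus-specific enrichment comparisons. A subset with zero
#' coverage is skipped with a warning rather than an error.
#'
#' @param split Output of [split_common_specific()] (intervals plus a
#'   `subset` column).
#' @param annotations Named list of annotation data frames, or a single data
#'   frame with a `label` column to be split by label.
#' @param genome Genome layout.
#'
#' @return A tibble with one row per (subset, annotation): the
#'   [enrichment_test()] columns plus `subset`.
#' @export
enrichment_panel <- function(split, annotations, genome) {
  split <- tibble::as_tibble(split)
  if (!"subset" %in% names(split)) {
    abort("`split` must carry a `subset` column; see split_common_specific().")
  }
  if (is.data.frame(annotations)) {
    if (!"label" %in% names(annotations)) {
      abort("A single annotation data frame must carry a `label` column.")
    }
    annotations <- base::split(annotations, annotations$label)
  }
  if (is.null(names(annotations)) || any(!nzchar(names(annotations)))) {
    abort("`annotations` must be a named list of interval tables.")
  }
  rows <- list()
  subsets <- if (is.factor(split$subset)) {
    levels(split$subset)
  } else {
    unique(split$subset)
  }
  for (sub in subsets) {
    sub_peaks <- split[split$subset == sub, , drop = FALSE]
    if (nrow(sub_peaks) == 0 || coverage_bp(sub_peaks) == 0) {
      warn(sprintf("Subset '%s' has zero coverage; skipping.", sub))
      next
    }
    for (lab in names(annotations)) {
      ann <- tibble::as_tibble(annotations[[lab]])
      ann$label <- lab
      res <- enrichment_test(sub_peaks, ann, genome)
      res$subset <- sub
      rows[[length(rows) + 1]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    out <- out[, c("subset", setdiff(names(out), "subset"))]
  }
  out
}
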
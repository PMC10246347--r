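# Core of the multi-sample peak-calling method: classify peaks by calling
# p-value, jointly test colocalized peaks across replicates with Fisher's
# combined probability test, confirm or discard per replicate type, select
# true positives per sample with Benjamini-Hochberg, and merge selected
# peaks into combined-stringency consensus regions.

LN10 <- log(10)

#' Configuration for a multi-sample peak-calling run
#'
#' Thresholds are given on the p-value scale and mirror the command-line
#' flags of the method: `w` (weak), `s` (stringent) and `g` (combined). The
#' defaults (`w = 1e-4`, `s = 1e-8`, `g = 1e-6`) are the threshold set that
#' maximised annotation enrichment across a panel of ENCODE transcription
#' factors, paired with peak calling at the permissive threshold 1e-4.
#'
#' @param w Weak significance threshold: peaks with `p > w` are background
#'   and take no part in testing.
#' @param s Stringent significance threshold (`s <= w`): peaks with
#'   `p <= s` are stringent, those with `s < p <= w` are weak candidates
#'   for rescue.
#' @param g Combined significance threshold: a test tuple passes when its
#'   Fisher-combined p-value is `<= g`.
#' @param c Minimum number of peaks in a test tuple, counting the assessed
#'   peak itself. `NULL` (default) resolves to the number of replicates at
#'   run time, i.e. support is required from every replicate.
#' @param alpha Benjamini-Hochberg false-discovery-rate level applied per
#'   replicate to confirmed peaks.
#' @param replicate_type `"biological"` (confirm on >= 1 passing test,
#'   tolerating heterogeneity) or `"technical"` (discard on any failing
#'   test, demanding homogeneity).
#'
#' @return An object of class `mspc_config`.
#' @export
#'
#' @examples
#' mspc_config()
#' mspc_config(replicate_type = "technical", c = 2)
mspc_config <- function(w = 1e-4, s = 1e-8, g = 1e-6, c = NULL,
                        alpha = 0.05,
                        replicate_type = c("biological", "technical")) {
  replicate_type <- match.arg(replicate_type)
  if (!(s > 0 && s <= w && w <= 1)) {
    abort("Thresholds must satisfy 0 < s <= w <= 1.")
  }
  if (!(g > 0 && g < 1)) {
    abort("`g` must lie in (0, 1).")
  }
  if (!(alpha > 0 && alpha < 1)) {
    abort("`alpha` must lie in (0, 1).")
  }
  if (!is.null(c)) {
    c <- as.integer(c)
    if (is.na(c) || c < 1) {
      abort("`c` must be an integer >= 1 (or NULL).")
    }
  }
  structure(
    list(
      w = w, s = s, g = g, c = c, alpha = alpha,
      replicate_type = replicate_type
    ),
    class = "mspc_config"
  )
}

#' @export
print.mspc_config <- function(x, ...) {
  cat("<mspc_config>\n")
  cat(sprintf("  weak threshold (w):      %g\n", x$w))
  cat(sprintf("  stringent threshold (s): %g\n", x$s))
  cat(sprintf("  combined threshold (g):  %g\n", x$g))
  cat(sprintf(
    "  min tuple size (c):      %s\n",
    if (is.null(x$c)) "number of replicates" else x$c
  ))
  cat(sprintf("  BH level (alpha):        %g\n", x$alpha))
  cat(sprintf("  replicate type:          %s\n", x$replicate_type))
  invisible(x)
}

#' Classify peaks as stringent, weak or background
#'
#' A peak with calling p-value `p` is stringent when `p <= s`, weak when
#' `s < p <= w`, and background otherwise. A p-value exactly at a threshold
#' is assigned to the more significant class. Comparisons run on the
#' -log10(p) scale the peaks carry.
#'
#' @param peaks Data frame with a `neg_log10_p` column.
#' @param config An [mspc_config()].
#'
#' @return `peaks` as a tibble with an added character column `class`.
#' @export
#'
#' @examples
#' peaks <- tibble::tibble(
#'   chrom = "chr1", start = c(0, 100, 200), end = c(50, 150, 250),
#'   neg_log10_p = c(9, 5, 3)
#' )
#' classify_peaks(peaks, mspc_config())$class
classify_peaks <- function(peaks, config = mspc_config()) {
  stopifnot(inherits(config, "mspc_config"))
  peaks <- tibble::as_tibble(peaks)
  if (!"neg_log10_p" %in% names(peaks)) {
    abort("`peaks` must carry a `neg_log10_p` column.")
  }
  if (any(peaks$neg_log10_p < 0, na.rm = TRUE) || anyNA(peaks$neg_log10_p)) {
    abort("`neg_log10_p` must be non-negative and non-missing.")
  }
  s_nlp <- -log10(config$s)
  w_nlp <- -log10(config$w)
  peaks$class <- dplyr::case_when(
    peaks$neg_log10_p >= s_nlp ~ "stringent",
    peaks$neg_log10_p >= w_nlp ~ "weak",
    TRUE ~ "background"
  )
  peaks
}

# vectorised chi-squared right tail on the -log10 scale (no linear p)
fisher_cnlp <- function(chi2, k) {
  -stats::pchisq(chi2, df = 2 * k, lower.tail = FALSE, log.p = TRUE) / LN10
}

#' Fisher's combined probability test on the -log10 scale
#'
#' Combines the member p-values of one test tuple:
#' `chi2 = -2 sum(ln p) = 2 ln(10) sum(-log10 p)`, referred to the
#' right tail of a chi-squared distribution with `2k` degrees of freedom
#' (`k` = number of members). All arithmetic stays in log space, so combined
#' p-values far below double underflow are representable. A single member
#' reduces to the identity (combined p equals the input p).
#'
#' @param neg_log10_p Non-empty numeric vector of -log10 p-values, one per
#'   tuple member.
#'
#' @return A one-row tibble with `k`, `chi2` and `combined_neg_log10_p`.
#' @export
#'
#' @examples
#' fisher_combine(-log10(c(0.01, 0.02)))
fisher_combine <- function(neg_log10_p) {
  if (length(neg_log10_p) == 0) {
    abort("Fisher combination needs at least one p-value.")
  }
  if (anyNA(neg_log10_p) || any(neg_log10_p < 0)) {
    abort("`neg_log10_p` must be non-negative and non-missing.")
  }
  k <- length(neg_log10_p)
  chi2 <- 2 * LN10 * sum(neg_log10_p)
  tibble::tibble(
    k = k, chi2 = chi2, combined_neg_log10_p = fisher_cnlp(chi2, k)
  )
}

#' Enumerate the Fisher tests of one assessed peak
#'
#' For each other replicate, the peaks overlapping the assessed peak are
#' collected; every test tuple consists of the assessed peak plus one
#' overlapping peak from each replicate contributing at least one overlap
#' (the Cartesian product across contributing replicates). Tuples smaller
#' than `c` members yield no tests. Each tuple is Fisher-combined and
#' compared against the combined threshold `g`.
#'
#' @param peak One-row data frame: the assessed peak (interval plus
#'   `neg_log10_p`).
#' @param others List of data frames, one per *other* replicate, holding
#'   that replicate's candidate (non-background) peaks.
#' @param config An [mspc_config()]; `c = NULL` resolves to
#'   `length(others) + 1`.
#'
#' @return A tibble with one row per test: `k`, `chi2`,
#'   `combined_neg_log10_p`, `passed`, and a `members` list-column of
#'   member-peak tibbles (assessed peak first).
#' @export
enumerate_tests <- function(peak, others, config = mspc_config()) {
  stopifnot(inherits(config, "mspc_config"))
  peak <- tibble::as_tibble(peak)
  if (nrow(peak) != 1) {
    abort("`peak` must be a single assessed peak (one row).")
  }
  cmin <- if (is.null(config$c)) length(others) + 1L else config$c
  ov <- lapply(others, function(tb) {
    tb <- tibble::as_tibble(tb)
    if (nrow(tb) == 0) {
      return(tb)
    }
    hit <- tb$chrom == peak$chrom & tb$start < peak$end & peak$start < tb$end
    tb[hit, , drop = FALSE]
  })
  ov <- ov[vapply(ov, nrow, integer(1)) > 0]
  empty <- tibble::tibble(
    k = integer(0), chi2 = double(0), combined_neg_log10_p = double(0),
    passed = logical(0), members = list()
  )
  k <- length(ov) + 1L
  if (k < cmin) {
    return(empty)
  }
  sizes <- vapply(ov, nrow, integer(1))
  n_tuples <- prod(sizes)
  if (n_tuples > 10000) {
    abort(paste0(
      "More than 10,000 test tuples for one peak (", n_tuples, "); ",
      "the input likely contains pathological within-replicate overlaps - ",
      "clean it up before testing."
    ))
  }
  idx <- if (length(ov) == 0) {
    data.frame(row.names = 1)
  } else {
    expand.grid(lapply(sizes, seq_len), KEEP.OUT.ATTRS = FALSE)
  }
  g_nlp <- -log10(config$g)
  tests <- lapply(seq_len(nrow(idx)), function(i) {
    members <- dplyr::bind_rows(
      peak,
      purrr::map2(ov, as.integer(idx[i, ]), function(tb, j) tb[j, , drop = FALSE])
    )
    ft <- fisher_combine(members$neg_log10_p)
    ft$passed <- ft$combined_neg_log10_p >= g_nlp
    ft$members <- list(members)
    ft
  })
  dplyr::bind_rows(tests)
}

#' Confirm or discard one assessed peak from its tests
#'
#' Biological replicates tolerate heterogeneity: a peak is confirmed if it
#' passes at least one test. Technical replicates demand homogeneity: a peak
#' is discarded if any test fails. A peak with no tests (insufficient
#' cross-replicate support) is discarded in either mode.
#'
#' @param tests Tibble of tests from [enumerate_tests()].
#' @param config An [mspc_config()].
#'
#' @return `"confirmed"` or `"discarded"`.
#' @export
decide_peak <- function(tests, config = mspc_config()) {
  stopifnot(inherits(config, "mspc_config"))
  if (nrow(tests) == 0) {
    return("discarded")
  }
  ok <- if (config$replicate_type == "biological") {
    any(tests$passed)
  } else {
    all(tests$passed)
  }
  if (ok) "confirmed" else "discarded"
}

#' Benjamini-Hochberg step-up selection on the -log10 scale
#'
#' Standard BH at level `alpha`: with the `m` p-values sorted ascending,
#' find the largest rank `i` with `p_(i) <= i * alpha / m` and select all
#' p-values of rank at most `i`. Comparisons run in -log10 space so
#' selection works for combined p-values far below double underflow. Ties
#' are ordered by input position for full determinism (step-up makes the
#' selected set independent of tie order).
#'
#' @param neg_log10_p Numeric vector of -log10 p-values.
#' @param alpha FDR level in (0, 1).
#'
#' @return Logical vector in input order: `TRUE` for selected entries.
#' @export
#'
#' @examples
#' bh_select(-log10(c(0.001, 0.002, 0.03)), alpha = 0.05)
bh_select <- function(neg_log10_p, alpha = 0.05) {
  m <- length(neg_log10_p)
  if (m == 0) {
    return(logical(0))
  }
  if (anyNA(neg_log10_p)) {
    abort("`neg_log10_p` must be non-missing.")
  }
  ord <- order(-neg_log10_p, seq_len(m), method = "radix")
  thresh <- log10(m / (seq_len(m) * alpha)) # -log10(i * alpha / m)
  ok <- neg_log10_p[ord] >= thresh
  imax <- if (any(ok)) max(which(ok)) else 0L
  out <- logical(m)
  if (imax > 0) {
    out[ord[seq_len(imax)]] <- TRUE
  }
  out
}

#' Merge selected peaks into consensus regions
#'
#' Pools the per-replicate true-positive peaks, partitions them into
#' connected components under transitive overlap (>= 1 shared nucleotide;
#' abutting peaks stay separate), and emits one region per component. A
#' region spans the union of its members, and its stringency combines every
#' member's original calling p-value once with Fisher's method (`k` =
#' component size).
#'
#' @param true_positives Data frame of selected peaks across all replicates:
#'   interval columns, `neg_log10_p`, and a `replicate` column.
#'
#' @return A tibble sorted by (chrom, start) with columns `name`
#'   (`consensus_N`), `chrom`, `start`, `end`, `n_members`,
#'   `supporting_replicates`, `chi2`, `combined_neg_log10_p`, and a
#'   `member_ids` list-column of row indices into `true_positives`.
#' @export
build_consensus <- function(true_positives) {
  tp <- tibble::as_tibble(true_positives)
  empty <- tibble::tibble(
    name = character(0), chrom = character(0), start = double(0),
    end = double(0), n_members = integer(0),
    supporting_replicates = integer(0), chi2 = double(0),
    combined_neg_log10_p = double(0), member_ids = list()
  )
  if (nrow(tp) == 0) {
    return(empty)
  }
  check_intervals(tp, arg = "true_positives")
  if (!"replicate" %in% names(tp)) {
    tp$replicate <- 1L
  }
  gr <- as_gr(tp)
  red <- GenomicRanges::reduce(gr, min.gapwidth = 0L, with.revmap = TRUE)
  revmap <- S4Vectors::mcols(red)$revmap
  nlp_sum <- sum(IRanges::extractList(tp$neg_log10_p, revmap))
  k <- lengths(revmap)
  chi2 <- 2 * LN10 * nlp_sum
  reps <- IRanges::extractList(tp$replicate, revmap)
  out <- gr_to_tbl(red)
  out$name <- paste0("consensus_", seq_along(red))
  out$n_members <- as.integer(k)
  out$supporting_replicates <- lengths(unique(reps))
  out$chi2 <- chi2
  out$combined_neg_log10_p <- fisher_cnlp(chi2, k)
  out$member_ids <- as.list(revmap)
  out[, names(empty)]
}

normalize_replicates <- function(replicates) {
  if (is.data.frame(replicates)) {
    if (!"replicate" %in% names(replicates)) {
      replicates$replicate <- 1L
    }
    reps <- sort(unique(replicates$replicate))
    peaks <- tibble::as_tibble(replicates)
    peaks$replicate <- match(peaks$replicate, reps)
    n_reps <- length(reps)
  } else if (is.list(replicates)) {
    if (length(replicates) == 0) {
      abort("At least one replicate is required.")
    }
    peaks <- dplyr::bind_rows(
      lapply(seq_along(replicates), function(i) {
        tb <- tibble::as_tibble(replicates[[i]])
        tb$replicate <- i
        tb
      })
    )
    n_reps <- length(replicates)
  } else {
    abort("`replicates` must be a data frame or a list of data frames.")
  }
  if (nrow(peaks) > 0) {
    check_intervals(peaks, arg = "replicates")
    if (!"neg_log10_p" %in% names(peaks)) {
      abort("Peaks must carry a `neg_log10_p` column.")
    }
  } else {
    for (col in c("chrom", "name")) if (!col %in% names(peaks)) peaks[[col]] <- character(0)
    for (col in c("start", "end", "neg_log10_p", "score")) {
      if (!col %in% names(peaks)) peaks[[col]] <- double(0)
    }
  }
  if (!"name" %in% names(peaks)) {
    peaks$name <- paste0("peak_", seq_len(nrow(peaks)))
  }
  if (!"score" %in% names(peaks)) {
    peaks$score <- 0
  }
  if (!"rank" %in% names(peaks)) {
    peaks <- peaks %>%
      dplyr::group_by(.data$replicate) %>%
      dplyr::mutate(rank = dplyr::row_number()) %>%
      dplyr::ungroup()
  }
  list(peaks = peaks, n_reps = n_reps)
}

#' Run the full multi-sample peak-calling pipeline
#'
#' Classifies every peak, tests stringent and weak peaks against colocalized
#' peaks in the other replicates with Fisher's combined probability test,
#' confirms or discards per the replicate type, applies Benjamini-Hochberg
#' selection per replicate, and merges the selected peaks into consensus
#' regions. Output is deterministic for fixed input and configuration; the
#' number of replicates is unbounded.
#'
#' Decisions are computed without materialising the test-tuple Cartesian
#' product: all tuples of one assessed peak share the same member count, and
#' the Fisher statistic is monotone in the summed -log10 p of the chosen
#' members, so the best (respectively worst) tuple uses the per-replicate
#' maximum (minimum) overlapping -log10 p. "Passes at least one test",
#' "passes all tests" and the best combined p used for BH ranking all follow
#' from those two extremes, which is what lets the pipeline scale to very
#' large replicate sets. [enumerate_tests()] materialises tuples explicitly
#' when the individual tests are wanted.
#'
#' @param replicates List of per-replicate peak tibbles (as read by
#'   [read_narrowpeak()]), or a single data frame with a `replicate` column.
#' @param config An [mspc_config()].
#'
#' @return An object of class `mspc_result`: a list with
#'   \describe{
#'     \item{decisions}{per-peak tibble: input columns plus `class`,
#'       `k` (tuple size), `n_tests`, `best_chi2`,
#'       `best_combined_neg_log10_p`, `worst_combined_neg_log10_p`,
#'       `status` (`background`/`discarded`/`confirmed`), `true_positive`
#'       (BH-selected) and `consensus_id`.}
#'     \item{consensus}{consensus-region tibble from [build_consensus()].}
#'     \item{config}{the configuration, with `c` resolved.}
#'     \item{n_replicates}{number of input replicates.}
#'   }
#' @export
#'
#' @examples
#' reps <- lapply(1:3, function(i) tibble::tibble(
#'   chrom = "chr1", start = c(100, 5000) + i, end = c(300, 5200) + i,
#'   neg_log10_p = c(5.5, 9)
#' ))
#' run_mspc(reps, mspc_config())
run_mspc <- function(replicates, config = mspc_config()) {
  stopifnot(inherits(config, "mspc_config"))
  norm <- normalize_replicates(replicates)
  peaks <- norm$peaks
  n_reps <- norm$n_reps
  cmin <- if (is.null(config$c)) n_reps else config$c
  config$c <- cmin
  g_nlp <- -log10(config$g)

  peaks <- classify_peaks(peaks, config)
  peaks <- peaks[chrom_order(
    peaks$chrom, peaks$start, peaks$end, peaks$replicate, peaks$rank
  ), , drop = FALSE]
  peaks$.id <- seq_len(nrow(peaks))

  cand <- peaks[peaks$class != "background", , drop = FALSE]

  n_contrib <- integer(nrow(cand))
  sum_mx <- double(nrow(cand))
  sum_mn <- double(nrow(cand))
  tuple_prod <- rep(1, nrow(cand))
  if (nrow(cand) > 0) {
    gr <- as_gr(cand)
    hits <- GenomicRanges::findOverlaps(gr, gr)
    qh <- S4Vectors::queryHits(hits)
    sh <- S4Vectors::subjectHits(hits)
    cross <- cand$replicate[qh] != cand$replicate[sh]
    qi <- qh[cross]
    orep <- cand$replicate[sh[cross]]
    nlp <- cand$neg_log10_p[sh[cross]]
    if (length(qi) > 0) {
      # segment aggregation over radix-sorted (assessed peak, other
      # replicate, nlp) triples: per pair-group min/max/count, then per
      # assessed peak the sums and the tuple-count product
      o <- order(qi, orep, nlp, method = "radix")
      q2 <- qi[o]
      r2 <- orep[o]
      v2 <- nlp[o]
      n <- length(q2)
      new_pair <- c(TRUE, q2[-1] != q2[-n] | r2[-1] != r2[-n])
      first <- which(new_pair)
      last <- c(first[-1] - 1L, n)
      pq <- q2[first]
      p_max <- v2[last]
      p_min <- v2[first]
      p_n <- last - first + 1L
      m <- length(pq)
      new_q <- c(TRUE, pq[-1] != pq[-m])
      qfirst <- which(new_q)
      qlast <- c(qfirst[-1] - 1L, m)
      uq <- pq[qfirst]
      seg_sum <- function(x) {
        cs <- cumsum(x)
        cs[qlast] - c(0, cs)[qfirst]
      }
      n_contrib[uq] <- qlast - qfirst + 1L
      sum_mx[uq] <- seg_sum(p_max)
      sum_mn[uq] <- seg_sum(p_min)
      tuple_prod[uq] <- round(exp(seg_sum(log(p_n))))
    }
  }

  k <- 1L + n_contrib
  has_tests <- k >= cmin
  best_chi2 <- 2 * LN10 * (cand$neg_log10_p + sum_mx)
  worst_chi2 <- 2 * LN10 * (cand$neg_log10_p + sum_mn)
  best_cnlp <- fisher_cnlp(best_chi2, k)
  worst_cnlp <- fisher_cnlp(worst_chi2, k)
  passed <- if (config$replicate_type == "biological") {
    best_cnlp >= g_nlp
  } else {
    worst_cnlp >= g_nlp
  }
  confirmed <- has_tests & passed

  cand$k <- k
  cand$n_tests <- ifelse(has_tests, tuple_prod, 0)
  cand$best_chi2 <- ifelse(has_tests, best_chi2, NA_real_)
  cand$best_combined_neg_log10_p <- ifelse(has_tests, best_cnlp, NA_real_)
  cand$worst_combined_neg_log10_p <- ifelse(has_tests, worst_cnlp, NA_real_)
  cand$status <- ifelse(confirmed, "confirmed", "discarded")

  # per-replicate BH over confirmed peaks, ranked by best combined p
  cand$true_positive <- FALSE
  for (r in unique(cand$replicate)) {
    rows <- which(cand$replicate == r & cand$status == "confirmed")
    if (length(rows) > 0) {
      cand$true_positive[rows] <- bh_select(
        cand$best_combined_neg_log10_p[rows], config$alpha
      )
    }
  }

  decisions <- peaks
  decisions$k <- NA_integer_
  decisions$n_tests <- 0
  decisions$best_chi2 <- NA_real_
  decisions$best_combined_neg_log10_p <- NA_real_
  decisions$worst_combined_neg_log10_p <- NA_real_
  decisions$status <- "background"
  decisions$true_positive <- FALSE
  if (nrow(cand) > 0) {
    decisions$k[cand$.id] <- cand$k
    decisions$n_tests[cand$.id] <- cand$n_tests
    decisions$best_chi2[cand$.id] <- cand$best_chi2
    decisions$best_combined_neg_log10_p[cand$.id] <-
      cand$best_combined_neg_log10_p
    decisions$worst_combined_neg_log10_p[cand$.id] <-
      cand$worst_combined_neg_log10_p
    decisions$status[cand$.id] <- cand$status
    decisions$true_positive[cand$.id] <- cand$true_positive
  }

  tp <- decisions[decisions$true_positive, , drop = FALSE]
  consensus <- build_consensus(tp)
  decisions$consensus_id <- NA_integer_
  if (nrow(consensus) > 0) {
    member_rows <- unlist(consensus$member_ids)
    region_of <- rep(seq_len(nrow(consensus)), lengths(consensus$member_ids))
    decisions$consensus_id[tp$.id[member_rows]] <- region_of
    consensus$member_ids <- lapply(consensus$member_ids, function(i) tp$.id[i])
  }
  decisions$.id <- NULL

  structure(
    list(
      decisions = decisions,
      consensus = consensus,
      config = config,
      n_replicates = n_reps
    ),
    class = "mspc_result"
  )
}

#' @export
print.mspc_result <- function(x, ...) {
  d <- x$decisions
  cat(sprintf(
    "<mspc_result: %d replicates, %d peaks>\n", x$n_replicates, nrow(d)
  ))
  cat(sprintf(
    "  classes:   %d stringent / %d weak / %d background\n",
    sum(d$class == "stringent"), sum(d$class == "weak"),
    sum(d$class == "background")
  ))
  cat(sprintf(
    "  decisions: %d confirmed, %d true positives after BH\n",
    sum(d$status == "confirmed"), sum(d$true_positive)
  ))
  cat(sprintf("  consensus: %d regions\n", nrow(x$consensus)))
  invisible(x)
}

#' Consensus regions of a run
#'
#' @param x An `mspc_result`.
#' @return The consensus-region tibble.
#' @export
consensus_regions <- function(x) {
  stopifnot(inherits(x, "mspc_result"))
  x$consensus
}

#' Per-peak decisions of a run
#'
#' @param x An `mspc_result`.
#' @return The per-peak decision tibble.
#' @export
peak_decisions <- function(x) {
  stopifnot(inherits(x, "mspc_result"))
  x$decisions
}

#' Tidy a multi-sample peak-calling result
#'
#' @param x An `mspc_result` from [run_mspc()].
#' @param type `"consensus"` (default) for the consensus-region table or
#'   `"decisions"` for the per-peak decision table.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy mspc_result
#' @export
tidy.mspc_result <- function(x, type = c("consensus", "decisions"), ...) {
  type <- match.arg(type)
  if (type == "consensus") {
    out <- x$consensus
    out$member_ids <- NULL
    out
  } else {
    x$decisions
  }
}

#' One-row summary of a multi-sample peak-calling result
#'
#' @param x An `mspc_result` from [run_mspc()].
#' @param ... Unused.
#' @return A one-row tibble with replicate, peak, class, decision and
#'   consensus counts.
#' @method glance mspc_result
#' @export
glance.mspc_result <- function(x, ...) {
  d <- x$decisions
  tibble::tibble(
    n_replicates = x$n_replicates,
    n_peaks = nrow(d),
    n_stringent = sum(d$class == "stringent"),
    n_weak = sum(d$class == "weak"),
    n_background = sum(d$class == "background"),
    n_confirmed = sum(d$status == "confirmed"),
    n_true_positive = sum(d$true_positive),
    n_consensus = nrow(x$consensus)
  )
}
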
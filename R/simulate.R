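# Ground-truth simulator: replicated peak sets with planted strong and weak
# binding sites, replicate-private noise peaks, and annotation tracks that
# preferentially cover the planted sites. Everything downstream is testable
# against the known truth without any external data.

#' Specify a replicated peak-set simulation
#'
#' Defines the genome, the planted binding sites, how reliably each
#' replicate re-emits them, the replicate-private noise, and the annotation
#' track. p-value ranges are given on the -log10 scale (the scale peaks
#' carry). Defaults describe a modest ChIP-seq-like experiment: three
#' replicates, one hundred planted sites of ~200 bp on a 1 Mb two-chromosome
#' genome, half of them strong (-log10 p in 9-12) and half weak (5-6, i.e.
#' rescuable but individually below the stringent cut), 95% per-replicate
#' reproducibility, 300 weak-range noise peaks private to each replicate,
#' and an annotation covering 80% of the planted sites.
#'
#' @param genome Genome layout (see [genome_layout()]).
#' @param n_replicates Number of replicates (>= 1).
#' @param n_true_sites Number of planted binding sites.
#' @param site_length,site_length_jitter Mean site length and uniform
#'   half-range around it, in bp.
#' @param strong_fraction Fraction of sites planted as strong.
#' @param strong_neg_log10_p,weak_neg_log10_p,noise_neg_log10_p Uniform
#'   -log10 p sampling intervals for strong-site, weak-site and noise peaks.
#' @param reproducibility Per-replicate probability that a planted site
#'   emits a peak.
#' @param n_noise_per_replicate Noise peaks private to each replicate;
#'   placed to overlap neither the planted sites nor each other, so
#'   ground-truth labels stay unambiguous.
#' @param position_jitter Per-replicate uniform jitter of each emitted peak
#'   boundary, in bp.
#' @param annotation_overlap_prob Probability a planted site lies inside an
#'   annotation interval.
#' @param n_background_annotations Annotation intervals placed away from the
#'   planted sites (the annotation's genomic background).
#' @param annotation_margin Two-element range of the margin (bp) by which an
#'   annotation interval extends past the site it covers.
#' @param seed RNG seed; identical spec and seed give identical output.
#'
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(genome = genome_layout(c("chr1", "chr2"),
                                                   c(6e5, 4e5)),
                            n_replicates = 3,
                            n_true_sites = 100,
                            site_length = 200,
                            site_length_jitter = 50,
                            strong_fraction = 0.5,
                            strong_neg_log10_p = c(9, 12),
                            weak_neg_log10_p = c(5, 6),
                            noise_neg_log10_p = c(4, 6),
                            reproducibility = 0.95,
                            n_noise_per_replicate = 300,
                            position_jitter = 10,
                            annotation_overlap_prob = 0.8,
                            n_background_annotations = 100,
                            annotation_margin = c(20, 100),
                            seed = 1L) {
  genome <- as_genome_layout(genome)
  probs <- c(strong_fraction, reproducibility, annotation_overlap_prob)
  if (any(probs < 0 | probs > 1)) {
    abort("Fractions and probabilities must lie in [0, 1].")
  }
  ranges <- list(strong_neg_log10_p, weak_neg_log10_p, noise_neg_log10_p,
                 annotation_margin)
  if (any(vapply(ranges, function(r) {
    length(r) != 2 || any(r < 0) || r[1] > r[2]
  }, logical(1)))) {
    abort("Ranges must be non-decreasing pairs of non-negative values.")
  }
  if (n_replicates < 1 || n_true_sites < 0 || n_noise_per_replicate < 0) {
    abort("Counts must be non-negative (and n_replicates >= 1).")
  }
  if (site_length - site_length_jitter < 1) {
    abort("Minimum site length must be >= 1 bp.")
  }
  structure(
    list(
      genome = genome,
      n_replicates = as.integer(n_replicates),
      n_true_sites = as.integer(n_true_sites),
      site_length = site_length,
      site_length_jitter = site_length_jitter,
      strong_fraction = strong_fraction,
      strong_neg_log10_p = strong_neg_log10_p,
      weak_neg_log10_p = weak_neg_log10_p,
      noise_neg_log10_p = noise_neg_log10_p,
      reproducibility = reproducibility,
      n_noise_per_replicate = as.integer(n_noise_per_replicate),
      position_jitter = position_jitter,
      annotation_overlap_prob = annotation_overlap_prob,
      n_background_annotations = as.integer(n_background_annotations),
      annotation_margin = annotation_margin,
      seed = as.integer(seed)
    ),
    class = "simulation_spec"
  )
}

#' @export
print.simulation_spec <- function(x, ...) {
  cat("<simulation_spec>\n")
  cat(sprintf(
    "  genome: %d chromosome(s), %g bp total\n",
    nrow(x$genome), genome_size(x$genome)
  ))
  cat(sprintf(
    "  %d replicates, %d true sites (%.0f%% strong), %d noise peaks/rep\n",
    x$n_replicates, x$n_true_sites, 100 * x$strong_fraction,
    x$n_noise_per_replicate
  ))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

runif_int <- function(n, lo, hi) {
  lo + floor(stats::runif(n) * (hi - lo + 1))
}

# rejection-sample n disjoint intervals; `avoid` intervals (already padded if
# needed) and previously accepted intervals are kept at >= min_gap bp.
place_disjoint <- function(n, lengths, genome, avoid = NULL, min_gap = 1,
                           max_failures = 10000) {
  if (n == 0) {
    return(tibble::tibble(
      chrom = character(0), start = double(0), end = double(0)
    ))
  }
  occ_chrom <- if (is.null(avoid)) character(0) else avoid$chrom
  occ_start <- if (is.null(avoid)) double(0) else avoid$start
  occ_end <- if (is.null(avoid)) double(0) else avoid$end
  out_chrom <- character(n)
  out_start <- double(n)
  out_end <- double(n)
  failures <- 0
  for (i in seq_len(n)) {
    len <- lengths[min(i, length(lengths))]
    repeat {
      ci <- sample.int(nrow(genome), 1, prob = genome$size)
      chrom <- genome$chrom[ci]
      max_start <- genome$size[ci] - len
      if (max_start < 0) {
        failures <- failures + 1
      } else {
        s <- runif_int(1, 0, max_start)
        e <- s + len
        clash <- any(
          occ_chrom == chrom & occ_start < e + min_gap & s - min_gap < occ_end
        )
        if (!clash) {
          out_chrom[i] <- chrom
          out_start[i] <- s
          out_end[i] <- e
          occ_chrom <- c(occ_chrom, chrom)
          occ_start <- c(occ_start, s)
          occ_end <- c(occ_end, e)
          break
        }
        failures <- failures + 1
      }
      if (failures > max_failures) {
        abort(paste(
          "Could not place intervals disjointly after 10,000 rejections;",
          "the requested density is infeasible for this genome."
        ))
      }
    }
  }
  tibble::tibble(chrom = out_chrom, start = out_start, end = out_end)
}

#' Simulate replicated peak sets with known ground truth
#'
#' Plants disjoint binding sites, emits a jittered peak per site and
#' replicate with the configured reproducibility (strong and weak sites
#' sample their -log10 p from the corresponding range), adds
#' replicate-private noise peaks that overlap nothing else, and builds an
#' annotation track preferentially covering the planted sites. Output is
#' deterministic for a fixed spec (the seed is applied locally and the
#' caller's RNG state is untouched).
#'
#' @param spec A [simulation_spec()].
#'
#' @return An object of class `peak_simulation`: a list with
#'   \describe{
#'     \item{replicates}{list of per-replicate peak tibbles in the
#'       [read_narrowpeak()] layout.}
#'     \item{annotations}{named list of annotation interval tibbles.}
#'     \item{truth}{list with `sites` (planted sites: `site`, interval,
#'       `class`, `annotated`) and `provenance` (one row per emitted peak:
#'       `replicate`, `rank`, `site` = `NA` for noise).}
#'     \item{spec}{the input spec.}
#'   }
#' @export
#'
#' @examples
#' sim <- simulate_peaks(simulation_spec(n_true_sites = 10,
#'                                       n_noise_per_replicate = 20))
#' sapply(sim$replicates, nrow)
simulate_peaks <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  withr::with_seed(spec$seed, simulate_peaks_impl(spec))
}

simulate_peaks_impl <- function(spec) {
  genome <- spec$genome
  n_sites <- spec$n_true_sites
  jit <- spec$position_jitter

  site_len <- runif_int(
    max(n_sites, 1),
    spec$site_length - spec$site_length_jitter,
    spec$site_length + spec$site_length_jitter
  )
  # keep jittered emissions of different sites from ever touching
  sites <- place_disjoint(
    n_sites, site_len, genome,
    min_gap = 2 * jit + 2
  )
  n_strong <- round(n_sites * spec$strong_fraction)
  class <- rep("weak", n_sites)
  if (n_strong > 0) {
    class[sample.int(n_sites, n_strong)] <- "strong"
  }
  sites$site <- seq_len(max(n_sites, 0L))[seq_len(n_sites)]
  sites$class <- class

  # noise: private to one replicate AND mutually disjoint across replicates,
  # padded away from sites so jittered site peaks cannot reach them
  n_noise_total <- spec$n_replicates * spec$n_noise_per_replicate
  noise_len <- runif_int(
    max(n_noise_total, 1),
    spec$site_length - spec$site_length_jitter,
    spec$site_length + spec$site_length_jitter
  )
  pad_sites <- sites
  if (nrow(pad_sites) > 0) {
    pad_sites$start <- pmax(0, pad_sites$start - jit)
    pad_sites$end <- pad_sites$end + jit
  }
  noise <- place_disjoint(
    n_noise_total, noise_len, genome,
    avoid = pad_sites[, c("chrom", "start", "end")], min_gap = 1
  )
  noise$replicate <- rep(seq_len(spec$n_replicates),
                         each = spec$n_noise_per_replicate)

  sample_nlp <- function(n, range) stats::runif(n, range[1], range[2])

  replicates <- vector("list", spec$n_replicates)
  provenance <- vector("list", spec$n_replicates)
  for (r in seq_len(spec$n_replicates)) {
    emitted <- if (n_sites == 0) {
      logical(0)
    } else if (spec$reproducibility >= 1) {
      rep(TRUE, n_sites)
    } else {
      stats::runif(n_sites) < spec$reproducibility
    }
    es <- sites[emitted, , drop = FALSE]
    n_e <- nrow(es)
    if (n_e > 0) {
      size <- genome$size[match(es$chrom, genome$chrom)]
      s <- pmax(0, es$start + runif_int(n_e, -jit, jit))
      e <- pmin(size, es$end + runif_int(n_e, -jit, jit))
      bad <- s >= e
      s[bad] <- es$start[bad]
      e[bad] <- es$end[bad]
      nlp <- ifelse(
        es$class == "strong",
        sample_nlp(n_e, spec$strong_neg_log10_p),
        sample_nlp(n_e, spec$weak_neg_log10_p)
      )
      site_peaks <- tibble::tibble(
        chrom = es$chrom, start = s, end = e, neg_log10_p = nlp,
        site = es$site
      )
    } else {
      site_peaks <- tibble::tibble(
        chrom = character(0), start = double(0), end = double(0),
        neg_log10_p = double(0), site = integer(0)
      )
    }
    nr <- noise[noise$replicate == r, , drop = FALSE]
    noise_peaks <- tibble::tibble(
      chrom = nr$chrom, start = nr$start, end = nr$end,
      neg_log10_p = sample_nlp(nrow(nr), spec$noise_neg_log10_p),
      site = NA_integer_
    )
    all_peaks <- dplyr::bind_rows(site_peaks, noise_peaks)
    all_peaks <- all_peaks[
      chrom_order(all_peaks$chrom, all_peaks$start, all_peaks$end), ,
      drop = FALSE
    ]
    n_p <- nrow(all_peaks)
    replicates[[r]] <- tibble::tibble(
      chrom = all_peaks$chrom, start = all_peaks$start, end = all_peaks$end,
      name = sprintf("rep%d_peak%d", r, seq_len(n_p)),
      score = pmin(1000, round(10 * all_peaks$neg_log10_p)),
      neg_log10_p = all_peaks$neg_log10_p,
      rank = seq_len(n_p)
    )
    provenance[[r]] <- tibble::tibble(
      replicate = r, rank = seq_len(n_p), site = all_peaks$site
    )
  }

  # annotation: covers each site with the configured probability, plus
  # background intervals placed away from the sites
  annotated <- if (n_sites == 0) {
    logical(0)
  } else if (spec$annotation_overlap_prob >= 1) {
    rep(TRUE, n_sites)
  } else {
    stats::runif(n_sites) < spec$annotation_overlap_prob
  }
  sites$annotated <- annotated
  as_ <- sites[annotated, , drop = FALSE]
  if (nrow(as_) > 0) {
    size <- genome$size[match(as_$chrom, genome$chrom)]
    m1 <- runif_int(nrow(as_), spec$annotation_margin[1],
                    spec$annotation_margin[2])
    m2 <- runif_int(nrow(as_), spec$annotation_margin[1],
                    spec$annotation_margin[2])
    site_ann <- tibble::tibble(
      chrom = as_$chrom,
      start = pmax(0, as_$start - m1),
      end = pmin(size, as_$end + m2)
    )
  } else {
    site_ann <- tibble::tibble(
      chrom = character(0), start = double(0), end = double(0)
    )
  }
  bg_len <- runif_int(
    max(spec$n_background_annotations, 1),
    spec$site_length - spec$site_length_jitter,
    spec$site_length + spec$site_length_jitter
  )
  bg_ann <- place_disjoint(
    spec$n_background_annotations, bg_len, genome,
    avoid = if (nrow(site_ann) > 0) site_ann else NULL, min_gap = 1
  )
  annotation <- sort_intervals(dplyr::bind_rows(site_ann, bg_ann))
  annotation$label <- "enhancers"

  structure(
    list(
      replicates = replicates,
      annotations = list(enhancers = annotation),
      truth = list(
        sites = sites[, c("site", "chrom", "start", "end", "class",
                          "annotated")],
        provenance = dplyr::bind_rows(provenance)
      ),
      spec = spec
    ),
    class = "peak_simulation"
  )
}

#' @export
print.peak_simulation <- function(x, ...) {
  cat(sprintf(
    "<peak_simulation: %d replicates, %d true sites, %d peaks total>\n",
    length(x$replicates), nrow(x$truth$sites),
    sum(vapply(x$replicates, nrow, integer(1)))
  ))
  invisible(x)
}

#' Write a simulation to disk
#'
#' Writes one narrowPeak file per replicate (`repN.narrowPeak`), one BED
#' file per annotation track, the genome as `genome.chrom.sizes`, and the
#' planted sites as `true_sites.bed` (name column `siteN_strong` /
#' `siteN_weak`).
#'
#' @param sim A `peak_simulation` from [simulate_peaks()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "peak_simulation"))
  if (!dir.exists(dir)) {
    dir.create(dir, recursive = TRUE)
  }
  for (r in seq_along(sim$replicates)) {
    p <- sim$replicates[[r]]
    writeLines(
      sprintf(
        "%s\t%d\t%d\t%s\t%d\t.\t0\t%.6f\t-1\t-1",
        p$chrom, as.integer(p$start), as.integer(p$end), p$name,
        as.integer(p$score), p$neg_log10_p
      ),
      file.path(dir, sprintf("rep%d.narrowPeak", r))
    )
  }
  for (lab in names(sim$annotations)) {
    a <- sim$annotations[[lab]]
    writeLines(
      sprintf("%s\t%d\t%d", a$chrom, as.integer(a$start), as.integer(a$end)),
      file.path(dir, paste0(lab, ".bed"))
    )
  }
  g <- sim$spec$genome
  writeLines(
    sprintf("%s\t%d", g$chrom, as.integer(g$size)),
    file.path(dir, "genome.chrom.sizes")
  )
  s <- sim$truth$sites
  writeLines(
    sprintf(
      "%s\t%d\t%d\tsite%d_%s",
      s$chrom, as.integer(s$start), as.integer(s$end), s$site, s$class
    ),
    file.path(dir, "true_sites.bed")
  )
  invisible(dir)
}

#' Score a run against simulation ground truth
#'
#' A consensus region recovers a planted site when the two overlap (>= 1
#' nucleotide). Sensitivity is reported separately for weak and strong
#' sites; the false-discovery proportion (FDP) is the fraction of consensus
#' regions overlapping no planted site. Empty denominators score 0 by
#' convention (an empty consensus has FDP 0; a class with no planted sites
#' has sensitivity `NA`).
#'
#' @param result An `mspc_result` from [run_mspc()] or a data frame of
#'   consensus intervals.
#' @param truth The `truth` element of a `peak_simulation` (or the whole
#'   simulation object).
#'
#' @return A one-row tibble: `sensitivity_weak`, `sensitivity_strong`,
#'   `sensitivity`, `fdp`, `n_consensus`, `n_true_sites`.
#' @export
score_recovery <- function(result, truth) {
  consensus <- if (inherits(result, "mspc_result")) {
    result$consensus
  } else {
    tibble::as_tibble(result)
  }
  if (inherits(truth, "peak_simulation")) {
    truth <- truth$truth
  }
  sites <- truth$sites
  n_cons <- nrow(consensus)
  hit_site <- rep(FALSE, nrow(sites))
  hit_cons <- rep(FALSE, n_cons)
  if (n_cons > 0 && nrow(sites) > 0) {
    idx <- overlap_index(sites[, c("chrom", "start", "end")])
    hits <- query_overlaps(idx, consensus[, c("chrom", "start", "end")])
    hit_site[unique(hits$rank)] <- TRUE
    hit_cons[unique(hits$query)] <- TRUE
  }
  sens_for <- function(cls) {
    sel <- sites$class == cls
    if (!any(sel)) NA_real_ else mean(hit_site[sel])
  }
  tibble::tibble(
    sensitivity_weak = sens_for("weak"),
    sensitivity_strong = sens_for("strong"),
    sensitivity = if (nrow(sites) == 0) NA_real_ else mean(hit_site),
    fdp = if (n_cons == 0) 0 else mean(!hit_cons),
    n_consensus = n_cons,
    n_true_sites = nrow(sites)
  )
}
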
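# Independent oracles used throughout the suite. None of these share code
# with the package internals they check.

# Right tail of a chi-squared distribution with even df 2k, on the -log10
# scale, via the closed form P(X > x) = exp(-x/2) * sum_{j<k} (x/2)^j / j!
# evaluated with log-sum-exp.
oracle_chisq_tail_nlp <- function(chi2, k) {
  if (chi2 == 0) {
    return(0)
  }
  h <- chi2 / 2
  terms <- (0:(k - 1)) * log(h) - lgamma(1:k)
  m <- max(terms)
  log_p <- -h + m + log(sum(exp(terms - m)))
  -log_p / log(10)
}

# Per-nucleotide bitmap of covered positions, one logical vector per
# chromosome. Only usable on small genomes.
oracle_bitmap <- function(intervals, genome) {
  bm <- lapply(seq_len(nrow(genome)), function(i) logical(genome$size[i]))
  names(bm) <- genome$chrom
  if (nrow(intervals) > 0) {
    for (i in seq_len(nrow(intervals))) {
      ch <- intervals$chrom[i]
      bm[[ch]][(intervals$start[i] + 1):intervals$end[i]] <- TRUE
    }
  }
  bm
}

oracle_coverage_bp <- function(intervals, genome) {
  sum(vapply(oracle_bitmap(intervals, genome), sum, numeric(1)))
}

oracle_intersect_bp <- function(a, b, genome) {
  ba <- oracle_bitmap(a, genome)
  bb <- oracle_bitmap(b, genome)
  sum(vapply(names(ba), function(ch) sum(ba[[ch]] & bb[[ch]]), numeric(1)))
}

# Naive all-pairs overlap scan: returns a logical matrix [i, j].
oracle_overlap_matrix <- function(a, b) {
  outer(seq_len(nrow(a)), seq_len(nrow(b)), Vectorize(function(i, j) {
    a$chrom[i] == b$chrom[j] &&
      a$start[i] < b$end[j] && b$start[j] < a$end[i]
  }))
}

# Naive Benjamini-Hochberg step-up on linear-scale p-values.
oracle_bh <- function(p, alpha) {
  m <- length(p)
  if (m == 0) {
    return(logical(0))
  }
  ord <- order(p)
  ok <- p[ord] <= seq_len(m) * alpha / m
  imax <- if (any(ok)) max(which(ok)) else 0L
  sel <- logical(m)
  if (imax > 0) {
    sel[ord[seq_len(imax)]] <- TRUE
  }
  sel
}

# Exhaustive reference implementation of the whole pipeline, written
# directly from the method's definition: explicit tuple enumeration,
# per-tuple Fisher tests, per-replicate BH, and consensus construction by
# iterated merging of transitively overlapping true positives.
brute_mspc <- function(replicates, config) {
  n_reps <- length(replicates)
  cmin <- if (is.null(config$c)) n_reps else config$c
  w_nlp <- -log10(config$w)
  s_nlp <- -log10(config$s)
  g_nlp <- -log10(config$g)

  cls <- lapply(replicates, function(tb) {
    ifelse(tb$neg_log10_p >= s_nlp, "stringent",
      ifelse(tb$neg_log10_p >= w_nlp, "weak", "background")
    )
  })
  cand <- lapply(seq_len(n_reps), function(r) {
    tb <- replicates[[r]]
    tb$rank <- seq_len(nrow(tb))
    tb[cls[[r]] != "background", , drop = FALSE]
  })

  decisions <- list()
  for (r in seq_len(n_reps)) {
    tb <- cand[[r]]
    if (nrow(tb) == 0) {
      next
    }
    for (i in seq_len(nrow(tb))) {
      ovl <- list()
      for (s in setdiff(seq_len(n_reps), r)) {
        ot <- cand[[s]]
        if (nrow(ot) == 0) next
        hit <- ot$chrom == tb$chrom[i] &
          ot$start < tb$end[i] & tb$start[i] < ot$end
        if (any(hit)) {
          ovl[[length(ovl) + 1]] <- ot$neg_log10_p[hit]
        }
      }
      k <- 1L + length(ovl)
      cnlps <- numeric(0)
      if (k >= cmin) {
        grid <- if (length(ovl) == 0) {
          matrix(0, nrow = 1, ncol = 0)
        } else {
          as.matrix(expand.grid(lapply(ovl, seq_along)))
        }
        for (t in seq_len(nrow(grid))) {
          nlps <- tb$neg_log10_p[i]
          for (s in seq_along(ovl)) {
            nlps <- c(nlps, ovl[[s]][grid[t, s]])
          }
          chi2 <- 2 * log(10) * sum(nlps)
          cnlps <- c(
            cnlps,
            -pchisq(chi2, df = 2 * k, lower.tail = FALSE, log.p = TRUE) /
              log(10)
          )
        }
      }
      passed <- cnlps >= g_nlp
      status <- if (length(cnlps) == 0) {
        "discarded"
      } else if (config$replicate_type == "biological") {
        if (any(passed)) "confirmed" else "discarded"
      } else {
        if (all(passed)) "confirmed" else "discarded"
      }
      decisions[[length(decisions) + 1]] <- data.frame(
        replicate = r, rank = tb$rank[i],
        chrom = tb$chrom[i], start = tb$start[i], end = tb$end[i],
        neg_log10_p = tb$neg_log10_p[i],
        status = status,
        best_cnlp = if (any(passed)) max(cnlps[passed]) else NA_real_
      )
    }
  }
  dec <- do.call(rbind, decisions)
  if (is.null(dec)) {
    dec <- data.frame(
      replicate = integer(0), rank = integer(0), chrom = character(0),
      start = numeric(0), end = numeric(0), neg_log10_p = numeric(0),
      status = character(0), best_cnlp = numeric(0)
    )
  }

  dec$true_positive <- logical(nrow(dec))
  for (r in unique(dec$replicate)) {
    rows <- which(dec$replicate == r & dec$status == "confirmed")
    if (length(rows) > 0) {
      dec$true_positive[rows] <- oracle_bh(
        10^(-dec$best_cnlp[rows]), config$alpha
      )
    }
  }

  tp <- dec[dec$true_positive, , drop = FALSE]
  comp <- seq_len(nrow(tp))
  if (nrow(tp) > 1) {
    repeat {
      changed <- FALSE
      for (i in seq_len(nrow(tp) - 1)) {
        for (j in (i + 1):nrow(tp)) {
          if (tp$chrom[i] == tp$chrom[j] &&
              tp$start[i] < tp$end[j] && tp$start[j] < tp$end[i] &&
              comp[i] != comp[j]) {
            comp[comp == comp[j]] <- comp[i]
            changed <- TRUE
          }
        }
      }
      if (!changed) break
    }
  }
  regions <- lapply(unique(comp), function(cp) {
    members <- tp[comp == cp, , drop = FALSE]
    k <- nrow(members)
    chi2 <- 2 * log(10) * sum(members$neg_log10_p)
    data.frame(
      chrom = members$chrom[1],
      start = min(members$start), end = max(members$end),
      n_members = k, chi2 = chi2,
      combined_neg_log10_p =
        -pchisq(chi2, 2 * k, lower.tail = FALSE, log.p = TRUE) / log(10),
      supporting_replicates = length(unique(members$replicate))
    )
  })
  cons <- do.call(rbind, regions)
  if (is.null(cons)) {
    cons <- data.frame(
      chrom = character(0), start = numeric(0), end = numeric(0),
      n_members = integer(0), chi2 = numeric(0),
      combined_neg_log10_p = numeric(0), supporting_replicates = integer(0)
    )
  }
  cons <- cons[order(cons$chrom, cons$start, method = "radix"), , drop = FALSE]
  list(decisions = dec, consensus = cons)
}
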
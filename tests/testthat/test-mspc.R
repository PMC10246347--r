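pk <- function(start, end, nlp, chrom = "chr1") {
  tibble::tibble(chrom = chrom, start = start, end = end, neg_log10_p = nlp)
}

test_that("peak classification splits at the configured thresholds", {
  cfg <- mspc_config()
  cls <- function(p) {
    classify_peaks(pk(0, 10, -log10(p)), cfg)$class
  }
  expect_equal(cls(1e-9), "stringent")
  expect_equal(cls(1e-5), "weak")
  expect_equal(cls(1e-3), "background")
  # boundary p-values join the more significant class
  expect_equal(cls(1e-8), "stringent")
  expect_equal(cls(1e-4), "weak")
})

test_that("config invariants are enforced", {
  expect_error(mspc_config(w = 1e-8, s = 1e-4), "0 < s <= w")
  expect_error(mspc_config(g = 0), "\\(0, 1\\)")
  expect_error(mspc_config(alpha = 1), "\\(0, 1\\)")
  expect_error(mspc_config(c = 0), ">= 1")
})

test_that("Fisher combination matches the closed-form tail oracle", {
  # p = 1 combines to p = 1
  ft <- fisher_combine(0)
  expect_equal(ft$chi2, 0)
  expect_equal(ft$combined_neg_log10_p, 0)

  # one p-value is the identity
  ft <- fisher_combine(-log10(0.05))
  expect_equal(ft$combined_neg_log10_p, -log10(0.05), tolerance = 1e-12)

  # two p-values 0.01 and 0.02
  ft <- fisher_combine(c(2, -log10(0.02)))
  expect_equal(ft$chi2, -2 * (log(0.01) + log(0.02)), tolerance = 1e-12)
  expect_equal(ft$chi2, 17.034386, tolerance = 1e-6)
  expect_equal(
    ft$combined_neg_log10_p,
    oracle_chisq_tail_nlp(ft$chi2, 2),
    tolerance = 1e-10
  )

  expect_error(fisher_combine(numeric(0)), "at least one")
  expect_error(fisher_combine(c(1, -2)), "non-negative")
})

test_that("Fisher combination is monotone in its members", {
  base <- fisher_combine(c(3, 4))
  more <- fisher_combine(c(3, 4, 0.5))
  expect_gt(more$chi2, base$chi2)
  # combined p strictly decreasing in chi2 at fixed k
  expect_gt(
    fisher_combine(c(3, 5))$combined_neg_log10_p,
    fisher_combine(c(3, 4))$combined_neg_log10_p
  )
})

test_that("test enumeration forms the cross-replicate Cartesian product", {
  cfg <- mspc_config(c = 3)
  assessed <- pk(100, 200, 5)
  one_each <- list(pk(150, 250, 5), pk(120, 220, 6))
  tests <- enumerate_tests(assessed, one_each, cfg)
  expect_equal(nrow(tests), 1)
  expect_equal(tests$k, 3)
  expect_equal(tests$chi2, 2 * log(10) * 16, tolerance = 1e-9)
  expect_equal(nrow(tests$members[[1]]), 3)
  # assessed peak listed first
  expect_equal(tests$members[[1]]$start[1], 100)

  # no overlap, c = 2: no tests
  cfg2 <- mspc_config(c = 2)
  expect_equal(
    nrow(enumerate_tests(assessed, list(pk(500, 600, 5)), cfg2)), 0
  )

  # 2 overlaps in one replicate, 1 in another: two tests of size 3
  two_one <- list(pk(c(90, 150), c(150, 250), c(4.5, 5)), pk(120, 220, 6))
  tests <- enumerate_tests(assessed, two_one, cfg)
  expect_equal(nrow(tests), 2)
  expect_equal(tests$k, c(3, 3))
  expect_setequal(
    round(tests$chi2 / (2 * log(10)), 6),
    round(c(5 + 4.5 + 6, 5 + 5 + 6), 6)
  )

  # a replicate with no overlap contributes nothing but does not veto
  tests <- enumerate_tests(
    assessed, list(pk(150, 250, 5), pk(5000, 5100, 6)), mspc_config(c = 2)
  )
  expect_equal(tests$k, 2)
})

test_that("tuple explosion beyond 10,000 is a hard error", {
  assessed <- pk(100, 200, 5)
  stack <- pk(rep(100, 22), rep(200, 22), rep(5, 22))
  others <- list(stack, stack, stack) # 22^3 = 10,648 tuples
  expect_error(
    enumerate_tests(assessed, others, mspc_config(c = 2)),
    "10,000"
  )
})

test_that("confirm/discard rules differ between replicate types", {
  mk_tests <- function(passed) {
    tibble::tibble(
      k = 2L, chi2 = 1, combined_neg_log10_p = 1,
      passed = passed, members = list(NULL)
    )[seq_along(passed), ]
  }
  bio <- mspc_config(replicate_type = "biological")
  tec <- mspc_config(replicate_type = "technical")
  expect_equal(decide_peak(mk_tests(c(FALSE, TRUE)), bio), "confirmed")
  expect_equal(decide_peak(mk_tests(c(TRUE, FALSE)), tec), "discarded")
  expect_equal(decide_peak(mk_tests(c(TRUE, TRUE)), tec), "confirmed")
  expect_equal(decide_peak(mk_tests(logical(0)), bio), "discarded")
  expect_equal(decide_peak(mk_tests(logical(0)), tec), "discarded")
})

test_that("BH selection reproduces the step-up definition", {
  expect_equal(
    bh_select(-log10(c(0.001, 0.002, 0.03)), alpha = 0.05),
    c(TRUE, TRUE, TRUE)
  )
  expect_equal(bh_select(numeric(0), 0.05), logical(0))
  withr::with_seed(404, {
    for (rep in 1:5) {
      p <- runif(200)
      alpha <- sample(c(0.01, 0.05, 0.2), 1)
      expect_equal(bh_select(-log10(p), alpha), oracle_bh(p, alpha))
    }
  })
  # works far below double underflow
  sel <- bh_select(c(500, 400, 0.1), alpha = 0.05)
  expect_equal(sel[1:2], c(TRUE, TRUE))
})

test_that("consensus regions combine member p-values once", {
  tp <- tibble::tibble(
    chrom = "chr1", start = c(100, 150), end = c(200, 260),
    neg_log10_p = c(6, 5), replicate = c(1L, 2L)
  )
  cons <- build_consensus(tp)
  expect_equal(nrow(cons), 1)
  expect_equal(cons$start, 100)
  expect_equal(cons$end, 260)
  expect_equal(cons$chi2, 2 * log(10) * 11, tolerance = 1e-12)
  expect_equal(
    cons$combined_neg_log10_p,
    oracle_chisq_tail_nlp(2 * log(10) * 11, 2),
    tolerance = 1e-10
  )
  expect_equal(cons$supporting_replicates, 2L)

  # isolated peak: k = 1 identity
  single <- build_consensus(tibble::tibble(
    chrom = "chr1", start = 0, end = 10, neg_log10_p = 7, replicate = 1L
  ))
  expect_equal(single$combined_neg_log10_p, 7, tolerance = 1e-9)

  # chained overlap A-B, B-C with A,C disjoint merges into one region
  chain <- build_consensus(tibble::tibble(
    chrom = "chr1", start = c(0, 80, 160), end = c(100, 180, 260),
    neg_log10_p = c(5, 5, 5), replicate = 1:3
  ))
  expect_equal(nrow(chain), 1)
  expect_equal(chain$start, 0)
  expect_equal(chain$end, 260)
  expect_equal(chain$n_members, 3L)

  # abutting true positives stay separate regions
  abut <- build_consensus(tibble::tibble(
    chrom = "chr1", start = c(0, 100), end = c(100, 200),
    neg_log10_p = c(5, 5), replicate = 1:2
  ))
  expect_equal(nrow(abut), 2)
})

test_that("a single replicate with c = 1 reduces to per-peak gating", {
  peaks <- pk(c(0, 100, 200), c(50, 150, 250), c(7, 5, 3))
  res <- run_mspc(list(peaks), mspc_config(c = 1))
  d <- res$decisions[order(res$decisions$start), ]
  # p = 1e-7 <= g = 1e-6: confirmed; p = 1e-5 > g: discarded; background
  expect_equal(d$status, c("confirmed", "discarded", "background"))
  expect_equal(d$k[1], 1L)
  expect_equal(sum(res$decisions$true_positive), 1)
  expect_equal(nrow(res$consensus), 1)
})

test_that("three replicates rescue a weak planted site and drop noise", {
  site <- lapply(1:3, function(i) {
    pk(1000 + i, 1200 + i, 5) # p = 1e-5 in each replicate
  })
  site[[1]] <- dplyr::bind_rows(site[[1]], pk(8000, 8200, 5.5)) # private noise
  res <- run_mspc(site, mspc_config()) # c defaults to 3
  d <- res$decisions
  planted <- d[d$start < 2000, ]
  expect_true(all(planted$status == "confirmed"))
  expect_true(all(planted$true_positive))
  noise <- d[d$start >= 2000, ]
  expect_equal(noise$status, "discarded")
  expect_equal(nrow(res$consensus), 1)
  expect_equal(res$consensus$n_members, 3L)
  expect_equal(
    res$consensus$combined_neg_log10_p,
    oracle_chisq_tail_nlp(2 * log(10) * 15, 3),
    tolerance = 1e-9
  )
})

test_that("result accessors and broom methods expose the tables", {
  sim <- simulate_peaks(simulation_spec(
    n_true_sites = 15, n_noise_per_replicate = 20, seed = 5
  ))
  res <- run_mspc(sim$replicates)
  expect_s3_class(tidy(res), "tbl_df")
  expect_equal(nrow(tidy(res)), nrow(consensus_regions(res)))
  expect_equal(nrow(tidy(res, "decisions")), nrow(peak_decisions(res)))
  g <- glance(res)
  expect_equal(g$n_peaks, sum(sapply(sim$replicates, nrow)))
  expect_equal(g$n_consensus, nrow(res$consensus))
  expect_output(print(res), "mspc_result")
  p <- autoplot(res)
  expect_s3_class(p, "ggplot")
  expect_s3_class(autoplot(res, "support"), "ggplot")
})
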
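iv <- function(chrom, start, end) {
  tibble::tibble(chrom = chrom, start = start, end = end)
}

test_that("enrichment degeneracies behave as documented", {
  g <- genome_layout("chr1", 1000)
  peaks <- iv("chr1", 0, 100)

  # annotation identical to peaks: perfect recall
  r <- enrichment_test(peaks, peaks, g)
  expect_equal(r$p_hat, 1)
  expect_equal(r$a_hat, 0)
  expect_equal(r$beta, 1)
  expect_gt(r$z, 0)

  # annotation covering the whole genome is uninformative
  r <- enrichment_test(peaks, iv("chr1", 0, 1000), g)
  expect_equal(r$beta, 0)
  expect_equal(r$z, 0)

  # empty annotation: p = a = 0, z = 0
  r <- enrichment_test(peaks, iv(character(0), double(0), double(0)), g)
  expect_equal(r$p_hat, 0)
  expect_equal(r$a_hat, 0)
  expect_equal(r$z, 0)

  # peak coverage must be strictly inside (0, G)
  expect_error(
    enrichment_test(iv(character(0), double(0), double(0)), peaks, g),
    "between 0"
  )
  expect_error(enrichment_test(iv("chr1", 0, 1000), peaks, g), "between 0")
})

test_that("enrichment counts match a per-nucleotide contingency tally", {
  withr::with_seed(410, {
    for (i in 1:10) {
      genome <- genome_layout(c("chr1", "chr2"), c(6000, 4000))
      peaks <- random_intervals(30, genome_len = 4000,
                               chroms = c("chr1", "chr2"))
      ann <- random_intervals(40, genome_len = 4000,
                              chroms = c("chr1", "chr2"))
      r <- enrichment_test(peaks, ann, genome)
      bp <- oracle_bitmap(peaks, genome)
      ba <- oracle_bitmap(ann, genome)
      in_peak <- unlist(bp)
      in_ann <- unlist(ba)
      expect_equal(r$n_peak_bp, sum(in_peak))
      expect_equal(r$n_bg_bp, sum(!in_peak))
      expect_equal(r$k_peak_bp, sum(in_peak & in_ann))
      expect_equal(r$k_bg_bp, sum(!in_peak & in_ann))
      p <- sum(in_peak & in_ann) / sum(in_peak)
      a <- sum(!in_peak & in_ann) / sum(!in_peak)
      sigma <- sqrt(p * (1 - p) / sum(in_peak) + a * (1 - a) / sum(!in_peak))
      expect_equal(r$z, (p - a) / sigma, tolerance = 1e-12)
    }
  })
})

test_that("moving annotated bases under peaks increases beta", {
  g <- genome_layout("chr1", 10000)
  peaks <- iv("chr1", 0, 1000)
  betas <- sapply(c(200, 500, 900), function(in_peak_bp) {
    ann <- iv(
      "chr1", c(0, 5000), c(in_peak_bp, 5000 + (1000 - in_peak_bp))
    )
    enrichment_test(peaks, ann, g)$beta
  })
  expect_true(all(diff(betas) > 0))
})

test_that("common/specific split follows reference overlap", {
  cons <- iv("chr1", c(0, 200, 400), c(100, 300, 500))
  expect_equal(
    split_common_specific(cons, cons[0, ])$subset,
    rep("specific", 3)
  )
  expect_equal(
    split_common_specific(cons, cons)$subset,
    rep("common", 3)
  )
  partial <- split_common_specific(cons, iv("chr1", 250, 260))
  expect_equal(partial$subset, c("specific", "common", "specific"))

  withr::with_seed(411, {
    regions <- random_intervals(100, genome_len = 20000)
    ref <- random_intervals(30, genome_len = 20000)
    sp <- split_common_specific(regions, ref)
    mat <- oracle_overlap_matrix(regions, ref)
    expect_equal(sp$subset == "common", apply(mat, 1, any))
  })
})

test_that("the enrichment panel is a tidy subset-by-annotation table", {
  withr::with_seed(412, {
    genome <- genome_layout("chr1", 50000)
    regions <- random_intervals(60, genome_len = 45000)
    ref <- regions[1:20, ]
    sp <- split_common_specific(regions, ref)
    anns <- lapply(1:9, function(i) random_intervals(30, genome_len = 45000))
    names(anns) <- paste0("ann", 1:9)
    pan <- enrichment_panel(sp, anns, genome)
    expect_equal(nrow(pan), 18)
    expect_setequal(unique(pan$subset), c("common", "specific"))
    # identical annotation tracks give identical z for the same subset
    pan2 <- enrichment_panel(sp, list(a = anns[[1]], b = anns[[1]]), genome)
    expect_equal(pan2$z[pan2$label == "a"], pan2$z[pan2$label == "b"])
    expect_s3_class(plot_enrichment(pan), "ggplot")
  })
})

test_that("a zero-coverage subset is skipped with a warning, not an error", {
  genome <- genome_layout("chr1", 1000)
  sp <- iv("chr1", 0, 100)
  # a factor subset can carry a level with no rows: skipped, not fatal
  sp$subset <- factor("common", levels = c("common", "specific"))
  expect_warning(
    pan <- enrichment_panel(sp, list(a = iv("chr1", 0, 50)), genome),
    "zero coverage"
  )
  expect_equal(nrow(pan), 1)
  expect_equal(pan$subset, "common")
})

test_that("annotations planted on specific peaks rank them above common", {
  # construction: the annotation covers exactly the specific regions plus
  # scattered background, so the specific subset must score higher
  genome <- genome_layout("chr1", 100000)
  common <- iv("chr1", seq(0, 19000, by = 1000), seq(200, 19200, by = 1000))
  specific <- iv(
    "chr1", seq(50000, 69000, by = 1000), seq(50200, 69200, by = 1000)
  )
  sp <- dplyr::bind_rows(
    dplyr::mutate(common, subset = "common"),
    dplyr::mutate(specific, subset = "specific")
  )
  ann <- dplyr::bind_rows(
    specific, # fully covers the specific peaks
    iv("chr1", 80000, 81000) # plus background
  )
  pan <- enrichment_panel(sp, list(enhancers = ann), genome)
  z_common <- pan$z[pan$subset == "common"]
  z_specific <- pan$z[pan$subset == "specific"]
  expect_gt(z_specific, z_common)
})
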
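# Random-case builders shared by the property and equivalence tests.
# Callers wrap these in withr::with_seed for reproducibility.

random_intervals <- function(n, genome_len = 10000, chroms = "chr1",
                             max_len = 200) {
  chrom <- sample(chroms, n, replace = TRUE)
  len <- sample.int(max_len, n, replace = TRUE)
  start <- floor(runif(n) * (genome_len - len))
  tibble::tibble(chrom = chrom, start = start, end = start + len)
}

random_peakset <- function(n, genome_len = 10000, chroms = "chr1",
                           max_nlp = 10) {
  p <- random_intervals(n, genome_len, chroms)
  p$neg_log10_p <- runif(n, 0, max_nlp)
  p
}

random_mspc_instance <- function(max_reps = 3, max_peaks = 50) {
  n_reps <- sample.int(max_reps, 1)
  replicates <- lapply(seq_len(n_reps), function(i) {
    random_peakset(sample.int(max_peaks, 1), genome_len = 5000)
  })
  w <- 10^-runif(1, 2, 5)
  s <- w * 10^-runif(1, 0, 5)
  g <- 10^-runif(1, 1, 8)
  config <- mspc_config(
    w = w, s = s, g = g,
    c = sample.int(n_reps, 1),
    alpha = sample(c(0.01, 0.05, 0.2), 1),
    replicate_type = sample(c("biological", "technical"), 1)
  )
  list(replicates = replicates, config = config)
}
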
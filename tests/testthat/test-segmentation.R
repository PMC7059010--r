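test_that("the maximal arc statistic finds a clean step region", {
  res <- max_circular_stat(c(0, 0, 0, 5, 5, 5, 0, 0, 0))
  expect_equal(res$i, 3)
  expect_equal(res$j, 6)
  expect_false(res$degenerate)
})

test_that("constant input is degenerate with statistic zero", {
  res <- max_circular_stat(c(1, 1, 1, 1))
  expect_true(res$degenerate)
  expect_equal(res$stat, 0)
  expect_equal(c(res$i, res$j), c(0, 2))
})

test_that("the arc search matches exhaustive enumeration", {
  set.seed(12)
  for (rep in 1:50) {
    n <- sample(4:15, 1)
    x <- rnorm(n)
    got <- max_circular_stat(x, min_width = 2)
    want <- brute_force_arc(x, min_width = 2)
    expect_equal(got$i, want$i)
    expect_equal(got$j, want$j)
    expect_equal(got$stat, want$stat, tolerance = 1e-12)
  }
})

test_that("noise-free step profiles segment at the exact breakpoints", {
  v <- rep(0, 100)
  v[41:60] <- 0.585
  fit <- cbs_segment(log2_profile(v), cbs_params(seed = 4))
  segs <- tidy(fit)
  expect_equal(nrow(segs), 3)
  expect_equal(segs$start_bin, c(0, 40, 60))
  expect_equal(segs$end_bin, c(40, 60, 100))
  expect_equal(segs$mean_log2, c(0, 0.585, 0))
})

test_that("constant profiles give one segment per chromosome", {
  prof <- dplyr::bind_rows(log2_profile(rep(0.3, 30), "chr1"),
                           log2_profile(rep(-0.1, 20), "chr2"))
  attr(prof, "kind") <- "log2"
  segs <- tidy(cbs_segment(prof, cbs_params(seed = 1)))
  expect_equal(nrow(segs), 2)
  expect_equal(segs$mean_log2, c(0.3, -0.1))
})

test_that("noisy breakpoints are recovered within two bins in >= 90% of runs", {
  hits <- 0L
  n_runs <- 50
  for (s in seq_len(n_runs)) {
    set.seed(1000 + s)
    v <- rnorm(300, sd = 0.15) + rep(c(0, 0.585, 0), c(120, 120, 60))
    fit <- cbs_segment(log2_profile(v), cbs_params(seed = s))
    bp <- tidy(fit)$start_bin
    if (any(abs(bp - 120) <= 2) && any(abs(bp - 240) <= 2)) hits <- hits + 1L
  }
  expect_gte(hits / n_runs, 0.9)
})

test_that("segments tile every chromosome and means match their bins", {
  lay <- mouse_genome(bin_size_bp = 2e6)
  cfg <- sim_config(seed = 31)
  sim <- simulate_karyotype(lay, cfg)
  cnt <- emit_counts(sim$track, cfg)
  lr <- log2_normalize(cnt$tumour, cnt$normal, layout = lay)
  fit <- cbs_segment(lr, cbs_params(seed = 2), layout = lay)
  segs <- tidy(fit)
  for (ch in unique(segs$chrom)) {
    s <- segs[segs$chrom == ch, ]
    nb <- lay$n_bins[lay$chrom == ch]
    expect_equal(s$start_bin[1], 0)
    expect_equal(s$end_bin[nrow(s)], nb)
    if (nrow(s) > 1) expect_equal(s$start_bin[-1], s$end_bin[-nrow(s)])
    v <- lr$log2[lr$chrom == ch]
    means <- purrr::map2_dbl(s$start_bin, s$end_bin,
                             ~ mean(v[(.x + 1):.y]))
    expect_equal(s$mean_log2, means, tolerance = 1e-12)
  }
  expect_equal(sum(segs$n_bins), sum(lay$n_bins))
  g <- glance(fit)
  expect_equal(g$n_chromosomes, 20)
})

test_that("undo pruning merges sub-threshold splits and is idempotent", {
  # three segments whose flanks differ by less than k * MAD of the bins
  set.seed(8)
  v <- rnorm(90, mean = rep(c(0, 0.01, 0), each = 30), sd = 0.1)
  prof <- log2_profile(v)
  fit <- cbs_segment(prof, cbs_params(seed = 1))
  fit$segments <- tibble::tibble(
    chrom = "chr1", start_bin = c(0L, 30L, 60L), end_bin = c(30L, 60L, 90L),
    start_bp = c(0, 30, 60) * 5e5, end_bp = c(30, 60, 90) * 5e5,
    n_bins = 30L,
    mean_log2 = c(mean(v[1:30]), mean(v[31:60]), mean(v[61:90]))
  )
  undone <- undo_splits(fit, k_mad = 1)
  expect_equal(nrow(undone$segments), 1)
  expect_equal(undone$segments$mean_log2, mean(v))
  expect_identical(undo_splits(undone, 1)$segments, undone$segments)

  # a genuine single-copy step is retained
  v2 <- rep(c(0, 0.585, 0), each = 30) + rnorm(90, sd = 0.1)
  fit2 <- cbs_segment(log2_profile(v2), cbs_params(seed = 2))
  expect_equal(nrow(undo_splits(fit2, 1)$segments), nrow(tidy(fit2)))
})

test_that("pure-noise chromosomes are split at most at twice the alpha rate", {
  n_reps <- 200
  split <- 0L
  for (s in seq_len(n_reps)) {
    set.seed(2000 + s)
    v <- rnorm(120, sd = 0.15)
    fit <- cbs_segment(log2_profile(v), cbs_params(seed = s))
    if (nrow(tidy(fit)) > 1) split <- split + 1L
  }
  expect_lte(split / n_reps, 2 * 0.01)
})
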
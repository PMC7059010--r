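test_that("all-zero event rates give a constant diploid track", {
  lay <- tiny_layout(n_chrom = 3)
  cfg <- sim_config(rates = c(WCG = 0), seed = 5)
  sim <- simulate_karyotype(lay, cfg)
  expect_true(all(sim$track$copy == 2L))
  expect_equal(nrow(sim$events), 0)
})

test_that("a forced whole-chromosome gain raises every bin of that chromosome", {
  lay <- mouse_genome(bin_size_bp = 5e6)
  forced <- tibble::tibble(chrom = "chr15", start_bp = 0,
                           end_bp = lay$length_bp[lay$chrom == "chr15"],
                           delta_copies = 1L, kind_label = "WCG")
  sim <- simulate_karyotype(lay, sim_config(rates = c(WCG = 0), seed = 1),
                            forced_events = forced)
  on15 <- sim$track$chrom == "chr15"
  expect_true(all(sim$track$copy[on15] == 3L))
  expect_true(all(sim$track$copy[!on15] == 2L))
  expect_equal(sim$events$kind_label, "WCG")
})

test_that("a forced GCR produces more than ten copy-number switches", {
  lay <- mouse_genome(bin_size_bp = 5e5)
  forced <- tibble::tibble(chrom = "chr4", start_bp = 0, end_bp = 1,
                           delta_copies = 1L, kind_label = "GCR")
  sim <- simulate_karyotype(lay, sim_config(rates = c(WCG = 0), seed = 1),
                            forced_events = forced)
  cp <- sim$track$copy[sim$track$chrom == "chr4"]
  n_switches <- sum(cp[-1] != cp[-length(cp)])
  expect_gt(n_switches, 10)
})

test_that("overlapping forced events are refused", {
  lay <- tiny_layout(n_chrom = 1, length_bp = 1e7, bin_size_bp = 1e6)
  forced <- tibble::tibble(
    chrom = "chr1", start_bp = c(0, 2e6), end_bp = c(5e6, 7e6),
    delta_copies = c(1L, 1L), kind_label = c("PCG", "PCG")
  )
  expect_error(
    simulate_karyotype(lay, sim_config(rates = c(WCG = 0)), forced),
    "overlap"
  )
})

test_that("an impossible configuration errors instead of looping", {
  # single small chromosome fully occupied: a further event cannot be placed
  lay <- tiny_layout(n_chrom = 1, length_bp = 5e6, bin_size_bp = 1e6)
  forced <- tibble::tibble(chrom = "chr1", start_bp = 0, end_bp = 5e6,
                           delta_copies = 1L, kind_label = "WCG")
  expect_error(
    simulate_karyotype(lay, sim_config(rates = c(AMP = 50), seed = 2),
                       forced_events = forced, max_tries = 20),
    "could not place"
  )
})

test_that("karyotype and counts are reproducible given the seed", {
  lay <- mouse_genome(bin_size_bp = 5e6)
  cfg <- sim_config(seed = 99)
  a <- simulate_karyotype(lay, cfg)
  b <- simulate_karyotype(lay, cfg)
  expect_identical(a$track, b$track)
  expect_identical(a$events, b$events)
  ca <- emit_counts(a$track, cfg)
  cb <- emit_counts(b$track, cfg)
  expect_identical(ca$tumour$count, cb$tumour$count)
  expect_identical(ca$normal$count, cb$normal$count)
})

test_that("Poisson emission hits its mean within CLT bounds", {
  # 10,000 diploid bins at depth 100: mean within 3 standard errors
  lay <- genome_layout(tibble::tibble(chrom = "chr1", length_bp = 1e8),
                       bin_size_bp = 1e4)
  cfg <- sim_config(mean_depth = 100, overdispersion = 0,
                    rates = c(WCG = 0), seed = 11)
  sim <- simulate_karyotype(lay, cfg)
  cnt <- emit_counts(sim$track, cfg)
  se <- sqrt(100 / nrow(cnt$tumour))
  expect_lt(abs(mean(cnt$tumour$count) - 100), 3 * se)
})

test_that("expected counts scale linearly with copy number", {
  lay <- tiny_layout(n_chrom = 2, length_bp = 1e7, bin_size_bp = 1e6)
  forced <- tibble::tibble(chrom = "chr1", start_bp = 0, end_bp = 1e7,
                           delta_copies = 2L, kind_label = "WCG")
  cfg <- sim_config(mean_depth = 500, rates = c(WCG = 0), seed = 3)
  sim <- simulate_karyotype(lay, cfg, forced_events = forced)
  exact <- emit_counts(sim$track, cfg, exact = TRUE)
  c4 <- exact$tumour$count[exact$tumour$chrom == "chr1"]
  c2 <- exact$tumour$count[exact$tumour$chrom == "chr2"]
  expect_equal(mean(c4) / mean(c2), 2)
  # conservation: total expected tumour count = depth * sum(copy) / 2
  expect_equal(sum(exact$tumour$count), 500 * sum(sim$track$copy) / 2)
})

test_that("BFB-style amplicons rise monotonically to a peak of >= 4 copies", {
  lay <- mouse_genome(bin_size_bp = 5e5)
  cfg <- sim_config(rates = c(AMP = 3), bfb_fraction = 1, seed = 21)
  sim <- simulate_karyotype(lay, cfg)
  expect_gt(nrow(sim$events), 0)
  for (r in seq_len(nrow(sim$events))) {
    ev <- sim$events[r, ]
    cp <- sim$track$copy[sim$track$chrom == ev$chrom &
                           sim$track$start >= ev$start_bp &
                           sim$track$end <= ev$end_bp]
    peak <- which.max(cp)
    expect_gte(max(cp), 4)
    expect_true(all(diff(cp[seq_len(peak)]) >= 0))
    expect_true(all(diff(cp[seq(peak, length(cp))]) <= 0))
  }
})
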
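test_that("per-chromosome frequencies use genotype cohort sizes", {
  meta <- tibble::tibble(
    tumour_id = c(paste0("K", 1:7), paste0("M", 1:4)),
    genotype = rep(c("K", "KM"), c(7, 4))
  )
  events <- tibble::tibble(
    tumour_id = c("K1", "K2", "K3", "K4", "M1", "M2", "M3", "M4"),
    chrom = "chr6",
    category = "AMP"
  )
  freq <- per_chromosome_frequency(events, meta)
  expect_equal(freq$fraction[freq$genotype == "K"], 4 / 7)
  expect_equal(freq$fraction[freq$genotype == "KM"], 1.0)
  expect_true(all(freq$fraction >= 0 & freq$fraction <= 1))
  # a genotype with no affected tumours yields no rows
  meta2 <- dplyr::mutate(meta, genotype = replace(genotype, 5:7, "X"))
  expect_false("X" %in% per_chromosome_frequency(events, meta2)$genotype)
  # duplicate events in one tumour count once
  dup <- dplyr::bind_rows(events, events[1, ])
  expect_equal(per_chromosome_frequency(dup, meta)$n_affected,
               freq$n_affected)
})

test_that("minimal common region reduces to intersection at full support", {
  ident <- tibble::tibble(chrom = "chr6", start_bp = rep(10, 3),
                          end_bp = rep(20, 3))
  r <- minimal_common_region(ident, 3)
  expect_equal(c(r$start_bp, r$end_bp), c(10, 20))

  nested <- tibble::tibble(chrom = "chr6", start_bp = c(0, 40),
                           end_bp = c(100, 60))
  r2 <- minimal_common_region(nested, 2)
  expect_equal(c(r2$start_bp, r2$end_bp), c(40, 60))

  disjoint <- tibble::tibble(chrom = "chr6", start_bp = c(0, 20),
                             end_bp = c(10, 30))
  expect_equal(nrow(minimal_common_region(disjoint, 2)), 0)
  # min_support 1 returns the leftmost maximal-support run
  r3 <- minimal_common_region(disjoint, 1)
  expect_equal(c(r3$start_bp, r3$end_bp), c(0, 10))

  expect_error(minimal_common_region(
    tibble::tibble(chrom = c("chr1", "chr2"), start_bp = 0, end_bp = 1), 1
  ), "one chromosome")
})

test_that("amplicons drawn around a shared locus intersect over it", {
  set.seed(14)
  locus <- c(17.4e6, 17.5e6)
  amp <- tibble::tibble(
    chrom = "chr6",
    start_bp = runif(10, locus[1] - 5e6, locus[1] - 1e4),
    end_bp = runif(10, locus[2] + 1e4, locus[2] + 5e6)
  )
  r <- minimal_common_region(amp, 10)
  expect_lte(r$start_bp, locus[1])
  expect_gte(r$end_bp, locus[2])
  genes <- genes_in_region(r, met_region_genes())
  expect_true("Met" %in% genes$gene)
})

test_that("gene overlap respects half-open coordinates", {
  ann <- tibble::tibble(chrom = "chr6", start_bp = c(5, 10, 30),
                        end_bp = c(8, 20, 40),
                        gene = c("inside", "spanning", "abutting"))
  region <- list(chrom = "chr6", start_bp = 0, end_bp = 30)
  hits <- genes_in_region(region, ann)
  expect_equal(hits$gene, c("inside", "spanning"))
  expect_equal(nrow(genes_in_region(region, ann[0, ])), 0)
})

test_that("the SCNA burden t-test is the pooled Student form", {
  same <- scna_count_ttest(c(2, 2, 2), c(2, 2, 2))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 1)

  cohort <- nonregressed_cohort()
  k <- cohort$n_scna[cohort$genotype == "K"]
  km <- cohort$n_scna[cohort$genotype == "KM"]
  tt <- scna_count_ttest(k, km)
  expect_equal(tt$df, 21)
  expect_equal(tt$p_value, 0.3434, tolerance = 1e-3)
  # cross-check the analytic p against a label-permutation p-value
  set.seed(3)
  pooled <- c(k, km)
  obs <- abs(tt$t)
  perm <- replicate(2000, {
    idx <- sample(length(pooled), length(k))
    abs(scna_count_ttest(pooled[idx], pooled[-idx])$t)
  })
  p_perm <- (1 + sum(perm >= obs)) / (2000 + 1)
  # ties in the discrete counts make the exact permutation null slightly
  # heavy-tailed (p ~ 0.40 vs analytic 0.34); agreement is to ~0.06
  expect_lt(abs(p_perm - tt$p_value), 0.06)
  expect_gt(p_perm, 0.05) # same conclusion: no genotype burden difference
})

test_that("the t-test holds its nominal type-I error rate", {
  set.seed(9)
  rejections <- replicate(1000, {
    a <- rnorm(8); b <- rnorm(12)
    scna_count_ttest(a, b)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.03)
  expect_lte(mean(rejections), 0.07)
})

test_that("pearson correlation matches closed forms and the null", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(pearson_correlation(x, 2 * x), 1)
  expect_equal(pearson_correlation(x, -x), -1)
  set.seed(4)
  expect_lt(abs(pearson_correlation(rnorm(1000), rnorm(1000))), 0.1)
  expect_error(pearson_correlation(c(1, 1, 1), c(1, 2, 3)), "variance")
})

test_that("caliper tumour volume is L * W^2 / 2", {
  expect_equal(tumour_volume(1, 1), 0.5)
  expect_equal(tumour_volume(2, 1), 1)
  expect_equal(tumour_volume(1, 2), 2)
  expect_error(tumour_volume(-1, 1), "positive")
})

test_that("the bundled cohort matches its published margins", {
  cohort <- nonregressed_cohort()
  expect_equal(sum(cohort$genotype == "K"), 7)
  expect_equal(sum(cohort$genotype == "KM"), 16)
  expect_equal(sum(cohort$cmet_amp[cohort$genotype == "K"]), 4)
  expect_equal(sum(cohort$cmet_amp[cohort$genotype == "KM"]), 11)
  # exactly one KM tumour owes its cMet gain to a whole-chromosome gain
  expect_equal(sum(cohort$chr6_category == "WCG", na.rm = TRUE), 1)
})
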
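#' Poisson concentration estimate from digital-PCR negative partitions
#'
#' The standard dPCR estimator: with molecules distributed Poisson across
#' partitions, the mean molecules per partition is
#' `lambda = -ln(n_negative / n_partitions)`.
#'
#' @param n_negative Number of negative partitions (> 0; a chip with no
#'   negative partitions is saturated and unquantifiable).
#' @param n_partitions Total partitions (> 0).
#' @return Estimated mean molecules per partition. Vectorized.
#' @examples
#' dpcr_lambda(5000, 10000) # ln 2
#' @export
dpcr_lambda <- function(n_negative, n_partitions) {
  if (any(n_partitions <= 0)) abort("n_partitions must be positive")
  if (any(n_negative > n_partitions)) {
    abort("n_negative cannot exceed n_partitions")
  }
  if (any(n_negative == 0)) {
    abort("chip saturated (no negative partitions): concentration unquantifiable")
  }
  -log(n_negative / n_partitions)
}

#' Digital-PCR target:reference copy ratio with confidence interval
#'
#' Estimates per-channel concentrations by [dpcr_lambda()], reports their
#' ratio, and builds a 95% interval by the delta method on the log scale
#' using `var(log lambda_hat) ~ (e^lambda - 1) / (n * lambda^2)` per
#' channel. A chip is called amplified when the interval's lower bound
#' exceeds 1.
#'
#' @param chips Tibble with one row per chip: `n_partitions`,
#'   `target_positive`, `reference_positive` (an optional `chip_id` column
#'   is carried through).
#' @param conf_level Interval coverage (default 0.95).
#' @param ci_method `"delta"` (closed form, default) or `"bootstrap"`
#'   (parametric resampling of partition counts; `n_boot` replicates).
#' @param n_boot Bootstrap replicates when `ci_method = "bootstrap"`.
#' @return Tibble with `lambda_target`, `lambda_reference`, `ratio`,
#'   `ci_low`, `ci_high`, `amplified` per chip.
#' @examples
#' dpcr_ratio(data.frame(n_partitions = 20000, target_positive = 12000,
#'                       reference_positive = 11000))
#' @export
dpcr_ratio <- function(chips, conf_level = 0.95,
                       ci_method = c("delta", "bootstrap"), n_boot = 2000) {
  ci_method <- match.arg(ci_method)
  chips <- as_tibble(chips)
  need <- c("n_partitions", "target_positive", "reference_positive")
  stopifnot(all(need %in% names(chips)))
  n <- chips$n_partitions
  for (col in c("target_positive", "reference_positive")) {
    if (any(chips[[col]] <= 0) || any(chips[[col]] >= n)) {
      abort(paste0(col, ": each channel needs >= 1 positive and >= 1 ",
                   "negative partition"))
    }
  }
  lt <- dpcr_lambda(n - chips$target_positive, n)
  lr <- dpcr_lambda(n - chips$reference_positive, n)
  ratio <- lt / lr
  alpha2 <- (1 - conf_level) / 2
  if (ci_method == "delta") {
    var_log <- (exp(lt) - 1) / (n * lt^2) + (exp(lr) - 1) / (n * lr^2)
    half <- qnorm(1 - alpha2) * sqrt(var_log)
    ci_low <- ratio * exp(-half)
    ci_high <- ratio * exp(half)
  } else {
    ci <- purrr::map2(seq_along(n), ratio, function(i, r) {
      bt <- rbinom(n_boot, n[i], chips$target_positive[i] / n[i])
      br <- rbinom(n_boot, n[i], chips$reference_positive[i] / n[i])
      ok <- bt > 0 & bt < n[i] & br > 0 & br < n[i]
      rs <- dpcr_lambda(n[i] - bt[ok], n[i]) / dpcr_lambda(n[i] - br[ok], n[i])
      stats::quantile(rs, c(alpha2, 1 - alpha2), names = FALSE)
    })
    ci_low <- purrr::map_dbl(ci, 1)
    ci_high <- purrr::map_dbl(ci, 2)
  }
  dplyr::mutate(chips,
                lambda_target = lt, lambda_reference = lr,
                ratio = ratio, ci_low = ci_low, ci_high = ci_high,
                amplified = ci_low > 1)
}

#' Simulate a two-channel digital-PCR chip
#'
#' Each channel's positive-partition count is drawn
#' `Binomial(n_partitions, 1 - exp(-lambda))`, the Poisson partition model
#' for independently quantified dyes.
#'
#' @param lambda_target,lambda_reference Mean molecules per partition
#'   (>= 0).
#' @param n_partitions Number of partitions.
#' @param seed Optional integer seed.
#' @return One-row tibble `n_partitions`, `target_positive`,
#'   `reference_positive`.
#' @export
simulate_chip <- function(lambda_target, lambda_reference,
                          n_partitions = 20000, seed = NULL) {
  if (lambda_target < 0 || lambda_reference < 0) {
    abort("lambdas must be >= 0")
  }
  if (!is.null(seed)) set.seed(seed)
  tibble(
    n_partitions = n_partitions,
    target_positive = rbinom(1, n_partitions, 1 - exp(-lambda_target)),
    reference_positive = rbinom(1, n_partitions, 1 - exp(-lambda_reference))
  )
}

#' Summarize FISH spot counts with genome-doubling exclusion
#'
#' Cells where the target shows `gd_threshold` or more spots *and* the
#' reference also shows `gd_threshold` or more are discarded as likely
#' genome-doubled before summarizing. Over retained cells the
#' target:reference ratio is `mean(target) / mean(reference)` and
#' `frac_ge_high` is the fraction of cells with at least `high_threshold`
#' target copies.
#'
#' @param cells Tibble with per-cell `target_count` and `reference_count`
#'   (non-negative integers).
#' @param gd_threshold Genome-doubling exclusion threshold (default 3).
#' @param high_threshold "High copy" threshold (default 3).
#' @return One-row tibble `ratio`, `frac_ge_high`, `n_retained`,
#'   `n_discarded`.
#' @examples
#' fish_summarize(data.frame(target_count = c(2, 2, 4),
#'                           reference_count = c(2, 2, 2)))
#' @export
fish_summarize <- function(cells, gd_threshold = 3, high_threshold = 3) {
  cells <- as_tibble(cells)
  stopifnot(all(c("target_count", "reference_count") %in% names(cells)))
  if (nrow(cells) == 0) abort("cell set is empty")
  if (any(cells$target_count < 0) || any(cells$reference_count < 0)) {
    abort("spot counts must be non-negative")
  }
  doubled <- cells$target_count >= gd_threshold &
    cells$reference_count >= gd_threshold
  kept <- cells[!doubled, ]
  if (nrow(kept) == 0) abort("all cells discarded by genome-doubling filter")
  if (mean(kept$reference_count) == 0) {
    abort("mean reference spot count is 0; ratio undefined")
  }
  tibble(
    ratio = mean(kept$target_count) / mean(kept$reference_count),
    frac_ge_high = mean(kept$target_count >= high_threshold),
    n_retained = nrow(kept),
    n_discarded = sum(doubled)
  )
}

#' Secondary FISH amplification call
#'
#' The conventional positivity criterion for gene amplification by FISH:
#' at least `min_copies` target copies in more than `min_fraction` of
#' retained nuclei (defaults 5 copies in 15%).
#'
#' @param cells As in [fish_summarize()].
#' @param min_copies Copy threshold (default 5).
#' @param min_fraction Fraction-of-nuclei threshold (default 0.15).
#' @param gd_threshold Genome-doubling exclusion threshold (default 3).
#' @return Logical.
#' @export
fish_positive <- function(cells, min_copies = 5, min_fraction = 0.15,
                          gd_threshold = 3) {
  s <- fish_summarize(cells, gd_threshold = gd_threshold,
                      high_threshold = min_copies)
  s$frac_ge_high > min_fraction
}
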
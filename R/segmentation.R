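#' CBS parameters
#'
#' Tuning parameters for [cbs_segment()]. Splits are accepted when the
#' permutation p-value `(1 + #\{perm max T >= observed T\}) / (n_perm + 1)`
#' falls below `alpha`.
#'
#' @param alpha Split significance level (default 0.01).
#' @param n_perm Number of bin-shuffling permutations per candidate split
#'   (default 1000; minimum 100).
#' @param min_width Minimum segment width in bins (default 2, which blocks
#'   single-bin noise segments at 500 kb bins while still resolving ~2 Mb
#'   amplicons).
#' @param seed Integer seed for the permutation RNG.
#' @param undo_sd Optional merge threshold in MAD units passed to
#'   [undo_splits()] after segmentation; `NULL` (default) disables pruning.
#' @return A list of class `cbs_params`.
#' @export
cbs_params <- function(alpha = 0.01, n_perm = 1000, min_width = 2,
                       seed = 1L, undo_sd = NULL) {
  if (!(alpha > 0 && alpha < 1)) abort("alpha must be in (0, 1)")
  if (n_perm < 100) abort("n_perm must be >= 100")
  if (min_width < 1) abort("min_width must be >= 1")
  structure(list(alpha = alpha, n_perm = as.integer(n_perm),
                 min_width = as.integer(min_width), seed = as.integer(seed),
                 undo_sd = undo_sd),
            class = "cbs_params")
}

#' Maximal arc statistic of a numeric sequence
#'
#' Scans all arcs (contiguous windows) `x[i..j)` with
#' `min_width <= j - i <= n - min_width` and returns the arc maximizing the
#' standardized mean difference between the window and its complement,
#' `T = |mean(in) - mean(out)| / (s * sqrt(1/k + 1/(n-k)))` with `k = j - i`
#' and `s` the overall sample SD of `x`. Ties are broken by smallest `i`,
#' then smallest `j`; statistics within a relative 1e-9 count as tied (an
#' arc and its complement have identical statistics in exact arithmetic),
#' so results are platform-independent.
#'
#' @param x Numeric vector, length >= 2.
#' @param min_width Minimum arc width in bins.
#' @return One-row tibble with `i`, `j` (0-based half-open bin indices),
#'   `stat`, and `degenerate` (`TRUE` when `x` is constant or too short to
#'   admit any arc, in which case `stat = 0` and the arc is `(0, min_width)`).
#' @examples
#' max_circular_stat(c(0, 0, 0, 5, 5, 5, 0, 0, 0))
#' @export
max_circular_stat <- function(x, min_width = 2) {
  if (length(x) < 2) abort("x must have length >= 2")
  res <- max_arc_stat_cpp(as.numeric(x), as.integer(min_width))
  tibble(i = res$i, j = res$j, stat = res$stat, degenerate = res$degenerate)
}

# Smallest exceedance count that already guarantees p >= alpha.
perm_stop_at <- function(alpha, n_perm) {
  as.integer(ceiling(alpha * (n_perm + 1))) # (1+e)/(n_perm+1) >= alpha
}

# Recursive CBS of one chromosome's bin values. Returns integer matrix-like
# tibble of 0-based half-open bin index ranges.
cbs_one_chromosome <- function(v, params) {
  pieces <- list()
  stop_at <- perm_stop_at(params$alpha, params$n_perm)
  recurse <- function(a, b) { # 1-based inclusive bin range
    n <- b - a + 1L
    piece <- v[a:b]
    if (n >= 2L * params$min_width && sd(piece) > 0) {
      cand <- max_arc_stat_cpp(piece, params$min_width)
      if (!cand$degenerate) {
        pt <- perm_test_cpp(piece, params$min_width, cand$stat,
                            params$n_perm, stop_at)
        p <- (1 + pt$exceed) / (pt$n_done + 1)
        if (pt$n_done == params$n_perm && p < params$alpha) {
          i <- cand$i; j <- cand$j # 0-based within piece
          if (i > 0L) recurse(a, a + i - 1L)
          recurse(a + i, a + j - 1L)
          if (j < n) recurse(a + j, b)
          return(invisible())
        }
      }
    }
    pieces[[length(pieces) + 1L]] <<- c(a, b)
    invisible()
  }
  recurse(1L, length(v))
  m <- do.call(rbind, pieces)
  m <- m[order(m[, 1]), , drop = FALSE]
  tibble(start_bin = m[, 1] - 1L, end_bin = m[, 2])
}

#' Circular binary segmentation of a log2 profile
#'
#' Recursively partitions each chromosome of a log2-ratio bin profile into
#' constant-mean segments. At each step the arc maximizing the standardized
#' mean-difference statistic ([max_circular_stat()]) is tested by permuting
#' the bins of the current piece; an accepted interior arc yields three
#' pieces, a boundary arc two, and recursion continues until no piece
#' splits. Segment means are arithmetic means of member bins, and segments
#' tile every chromosome.
#'
#' @param profile Log2-ratio bin profile (from [log2_normalize()] or
#'   [read_bins()] with `kind = "log2"`).
#' @param params A [cbs_params()].
#' @param layout Optional [genome_layout()] carried into the result for
#'   span-fraction computation downstream.
#' @return An object of class `cbs_fit`: list with `segments` (tibble
#'   `chrom`, `start_bin`, `end_bin`, `start_bp`, `end_bp`, `n_bins`,
#'   `mean_log2`), `profile`, `params` and `layout`. Use [tidy()] for the
#'   segment table and [autoplot()] to draw it.
#' @export
cbs_segment <- function(profile, params = cbs_params(), layout = NULL) {
  if (!identical(attr(profile, "kind"), "log2")) {
    abort("cbs_segment expects a log2 profile (see log2_normalize)")
  }
  set.seed(params$seed)
  chroms <- unique(profile$chrom)
  segs <- purrr::map_dfr(chroms, function(ch) {
    rows <- profile[profile$chrom == ch, ]
    if (nrow(rows) == 0) {
      warn(paste0("chromosome ", ch, " has no bins; skipped"))
      return(NULL)
    }
    if (nrow(rows) == 1) {
      sg <- tibble(start_bin = 0L, end_bin = 1L)
    } else {
      sg <- cbs_one_chromosome(rows$log2, params)
    }
    dplyr::mutate(
      sg,
      chrom = ch,
      start_bp = rows$start[.data$start_bin + 1L],
      end_bp = rows$end[.data$end_bin],
      n_bins = .data$end_bin - .data$start_bin,
      mean_log2 = purrr::map2_dbl(.data$start_bin, .data$end_bin,
                                  ~ mean(rows$log2[(.x + 1L):.y])),
      .before = 1L
    )
  })
  segs <- dplyr::select(segs, "chrom", "start_bin", "end_bin", "start_bp",
                        "end_bp", "n_bins", "mean_log2")
  fit <- structure(
    list(segments = segs, profile = profile, params = params,
         layout = layout),
    class = "cbs_fit"
  )
  if (!is.null(params$undo_sd)) fit <- undo_splits(fit, params$undo_sd)
  fit
}

#' Merge adjacent segments with near-identical means
#'
#' Standard CBS "undo" pruning: adjacent segments of a chromosome whose mean
#' difference is below `k_mad` times the MAD of all bin values are merged
#' (closest pair first) until stable. Idempotent; segment tiling preserved.
#'
#' @param fit A `cbs_fit`.
#' @param k_mad Positive threshold in MAD units.
#' @return The pruned `cbs_fit`.
#' @export
undo_splits <- function(fit, k_mad) {
  stopifnot(inherits(fit, "cbs_fit"), k_mad > 0)
  threshold <- k_mad * mad(fit$profile$log2)
  segs <- fit$segments
  merged <- purrr::map_dfr(unique(segs$chrom), function(ch) {
    s <- segs[segs$chrom == ch, ]
    vals <- fit$profile$log2[fit$profile$chrom == ch]
    bounds <- fit$profile[fit$profile$chrom == ch, ]
    repeat {
      if (nrow(s) < 2) break
      d <- abs(diff(s$mean_log2))
      if (min(d) >= threshold) break
      k <- which.min(d)
      s$end_bin[k] <- s$end_bin[k + 1]
      s <- s[-(k + 1), ]
      s$n_bins <- s$end_bin - s$start_bin
      s$end_bp <- bounds$end[s$end_bin]
      s$mean_log2 <- purrr::map2_dbl(s$start_bin, s$end_bin,
                                     ~ mean(vals[(.x + 1L):.y]))
    }
    s
  })
  fit$segments <- merged
  fit
}

#' @export
print.cbs_fit <- function(x, ...) {
  cat("<cbs_fit> ", nrow(x$segments), " segments on ",
      length(unique(x$segments$chrom)), " chromosomes (alpha = ",
      x$params$alpha, ", ", x$params$n_perm, " permutations)\n", sep = "")
  print(x$segments, n = 10)
  invisible(x)
}

#' Tidy a CBS fit into its segment table
#' @param x A `cbs_fit`.
#' @param ... Unused.
#' @return Segment tibble (`chrom`, `start_bin`, `end_bin`, `start_bp`,
#'   `end_bp`, `n_bins`, `mean_log2`).
#' @export
tidy.cbs_fit <- function(x, ...) {
  x$segments
}

#' One-row summary of a CBS fit
#' @param x A `cbs_fit`.
#' @param ... Unused.
#' @return Tibble with segment and chromosome counts, residual MAD of bins
#'   around their segment means, and the split-test parameters.
#' @export
glance.cbs_fit <- function(x, ...) {
  resid <- segment_residuals(x)
  tibble(
    n_segments = nrow(x$segments),
    n_chromosomes = length(unique(x$segments$chrom)),
    residual_mad = mad(resid),
    alpha = x$params$alpha,
    n_perm = x$params$n_perm
  )
}

# Per-bin residuals around the fitted segment means.
segment_residuals <- function(fit) {
  unlist(purrr::map(unique(fit$segments$chrom), function(ch) {
    v <- fit$profile$log2[fit$profile$chrom == ch]
    s <- fit$segments[fit$segments$chrom == ch, ]
    fitted <- rep(s$mean_log2, s$n_bins)
    v - fitted
  }), use.names = FALSE)
}

#' Plot a segmented log2 profile
#'
#' Bins as points, segment means as horizontal bars, faceted by chromosome.
#' @param object A `cbs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cbs_fit <- function(object, ...) {
  prof <- dplyr::mutate(object$profile,
                        chrom = factor(.data$chrom,
                                       levels = unique(.data$chrom)))
  segs <- dplyr::mutate(object$segments,
                        chrom = factor(.data$chrom, levels(prof$chrom)))
  ggplot2::ggplot(prof, ggplot2::aes(x = (.data$start + .data$end) / 2e6,
                                     y = .data$log2)) +
    ggplot2::geom_point(size = 0.3, alpha = 0.4, colour = "grey40") +
    ggplot2::geom_segment(
      data = segs,
      ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                   y = .data$mean_log2, yend = .data$mean_log2),
      colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "log2 ratio") +
    ggplot2::theme_minimal()
}
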
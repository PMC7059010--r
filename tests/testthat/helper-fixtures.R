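# Shared fixtures: small layouts, constructed profiles, and an independent
# brute-force oracle for the CBS arc search.

tiny_layout <- function(n_chrom = 2, length_bp = 5e6, bin_size_bp = 1e6) {
  genome_layout(
    tibble::tibble(chrom = paste0("chr", seq_len(n_chrom)),
                   length_bp = length_bp),
    bin_size_bp = bin_size_bp
  )
}

# A log2 profile built directly from a vector of values on one chromosome.
log2_profile <- function(values, chrom = "chr1", bin_size_bp = 5e5) {
  out <- tibble::tibble(
    chrom = chrom,
    start = (seq_along(values) - 1) * bin_size_bp,
    end = seq_along(values) * bin_size_bp,
    log2 = values
  )
  attr(out, "kind") <- "log2"
  out
}

# A counts profile on a layout from a vector of counts (layout order).
counts_profile <- function(layout, counts) {
  bins <- layout_bins(layout)
  stopifnot(length(counts) == nrow(bins))
  out <- tibble::tibble(chrom = bins$chrom, start = bins$start,
                        end = bins$end, count = counts)
  attr(out, "kind") <- "counts"
  out
}

# Independent oracle: exhaustive enumeration of every arc (i, j), same
# statistic and tie-break (smallest i, then smallest j).
brute_force_arc <- function(x, min_width = 2) {
  n <- length(x)
  s <- sd(x)
  best <- list(i = 0L, j = min_width, stat = 0)
  if (s == 0 || n < 2 * min_width) {
    return(c(best, degenerate = TRUE))
  }
  for (i in 0:(n - min_width)) {
    for (j in (i + min_width):n) {
      k <- j - i
      if (k > n - min_width) next
      inside <- mean(x[(i + 1):j])
      outside <- mean(x[-((i + 1):j)])
      T <- abs(inside - outside) / (s * sqrt(1 / k + 1 / (n - k)))
      # same near-tie rule as the implementation: an arc and its complement
      # tie exactly, so ties go to the first arc in (i, j) order
      if (T > best$stat * (1 + 1e-9)) best <- list(i = i, j = j, stat = T)
    }
  }
  c(best, degenerate = FALSE)
}

# Segment table builder for classifier tests: equal-length layout pieces by
# span fractions (fractions must sum to <= 1; remainder ignored).
segments_from_spans <- function(spans, means, chrom = "chr1",
                                chrom_length = 1e8, n_bins_each = 10) {
  stopifnot(length(spans) == length(means))
  starts <- cumsum(c(0, head(spans, -1))) * chrom_length
  tibble::tibble(
    chrom = chrom,
    start_bin = seq_along(spans) * n_bins_each - n_bins_each,
    end_bin = seq_along(spans) * n_bins_each,
    start_bp = starts,
    end_bp = starts + spans * chrom_length,
    n_bins = n_bins_each,
    mean_log2 = means
  )
}
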
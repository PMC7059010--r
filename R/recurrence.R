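#' Per-chromosome SCNA frequency by genotype and category
#'
#' Fraction of tumours of each genotype carrying at least one event of each
#' category on each chromosome. Denominators are genotype cohort sizes from
#' `meta`, so unaffected tumours count.
#'
#' @param events Event tibble with `tumour_id`, `chrom`, `category`.
#' @param meta Cohort metadata tibble with unique `tumour_id` and
#'   `genotype`.
#' @return Tibble `chrom`, `genotype`, `category`, `n_affected`, `n_total`,
#'   `fraction` (in \[0, 1\]).
#' @export
per_chromosome_frequency <- function(events, meta) {
  meta <- as_tibble(meta)
  if (anyDuplicated(meta$tumour_id) > 0) abort("tumour ids must be unique")
  sizes <- dplyr::count(meta, .data$genotype, name = "n_total")
  events %>%
    dplyr::inner_join(meta, by = "tumour_id") %>%
    dplyr::distinct(.data$chrom, .data$genotype, .data$category,
                    .data$tumour_id) %>%
    dplyr::count(.data$chrom, .data$genotype, .data$category,
                 name = "n_affected") %>%
    dplyr::left_join(sizes, by = "genotype") %>%
    dplyr::mutate(fraction = .data$n_affected / .data$n_total) %>%
    dplyr::arrange(.data$chrom, .data$genotype, .data$category)
}

#' Minimal common region of a set of amplicons
#'
#' Endpoint-sweep over intervals on one chromosome: positions covered by at
#' least `min_support` intervals are found, and the single run of highest
#' support is returned (leftmost on ties). With `min_support = n` this is
#' the mutual intersection — the approach used to pinpoint a shared driver
#' gene inside recurrent amplicons.
#'
#' @param intervals Tibble with `chrom`, `start_bp`, `end_bp` (0-based
#'   half-open), all on one chromosome.
#' @param min_support Minimum number of covering intervals (1..n).
#' @return One-row tibble `chrom`, `start_bp`, `end_bp`, `support`, or a
#'   zero-row tibble when no position reaches `min_support`.
#' @examples
#' minimal_common_region(
#'   data.frame(chrom = "chr6", start_bp = c(0, 40), end_bp = c(100, 60)),
#'   min_support = 2
#' )
#' @export
minimal_common_region <- function(intervals, min_support = nrow(intervals)) {
  intervals <- as_tibble(intervals)
  empty <- tibble(chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), support = integer())
  if (nrow(intervals) == 0) return(empty)
  if (length(unique(intervals$chrom)) > 1) {
    abort("intervals must all be on one chromosome")
  }
  if (min_support < 1 || min_support > nrow(intervals)) {
    abort("min_support must be between 1 and the number of intervals")
  }
  # sweep: +1 at starts, -1 at ends; coverage is constant between endpoints
  pts <- sort(unique(c(intervals$start_bp, intervals$end_bp)))
  starts <- head(pts, -1)
  cover <- vapply(starts, function(p) {
    sum(intervals$start_bp <= p & intervals$end_bp > p)
  }, numeric(1))
  best <- max(cover)
  if (best < min_support) return(empty)
  runs <- rle(cover == best)
  first_run <- which(runs$values)[1]
  i0 <- if (first_run == 1) 1L else sum(runs$lengths[seq_len(first_run - 1)]) + 1L
  i1 <- i0 + runs$lengths[first_run] - 1L
  tibble(chrom = intervals$chrom[1], start_bp = pts[i0],
         end_bp = pts[i1 + 1L], support = as.integer(best))
}

#' Genes intersecting a genomic region
#'
#' Half-open interval overlap: a gene abutting the region end does not
#' overlap. Results are sorted by coordinate.
#'
#' @param region One-row tibble/list with `chrom`, `start_bp`, `end_bp`.
#' @param annotation Gene annotation tibble with `chrom`, `start_bp`,
#'   `end_bp`, `gene` (BED-like, 0-based half-open).
#' @return The overlapping annotation rows, coordinate-sorted.
#' @export
genes_in_region <- function(region, annotation) {
  annotation <- as_tibble(annotation)
  hits <- annotation$chrom == region$chrom &
    annotation$start_bp < region$end_bp &
    annotation$end_bp > region$start_bp
  dplyr::arrange(annotation[hits, ], .data$start_bp)
}

#' Read a BED gene annotation
#'
#' Minimal BED reader for gene intervals: first four columns are `chrom`,
#' `start_bp`, `end_bp`, `gene` (0-based half-open).
#'
#' @param path BED file path.
#' @return Annotation tibble for [genes_in_region()].
#' @export
read_gene_bed <- function(path) {
  raw <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                         col_types = readr::cols())
  if (ncol(raw) < 4) abort("BED annotation needs at least 4 columns")
  out <- tibble(chrom = as.character(raw[[1]]), start_bp = raw[[2]],
                end_bp = raw[[3]], gene = as.character(raw[[4]]))
  if (any(out$start_bp >= out$end_bp)) abort("BED intervals must have start < end")
  out
}

#' Two-sample comparison of SCNA burden
#'
#' Student's pooled-variance unpaired t-test (two-sided) of per-tumour SCNA
#' counts between two genotypes; Welch's correction available as an option.
#' When both groups are constant and equal, `t = 0` and `p = 1`.
#'
#' @param counts_a,counts_b Numeric vectors of per-tumour SCNA counts
#'   (each length >= 2).
#' @param welch Use Welch's unequal-variance form instead of the pooled
#'   form.
#' @return One-row tibble `t`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @examples
#' scna_count_ttest(c(1, 2, 3, 4, 3, 0, 1),
#'                  c(3, 4, 4, 2, 3, 2, 6, 1, 5, 1, 4, 2, 3, 1, 2, 0))
#' @export
scna_count_ttest <- function(counts_a, counts_b, welch = FALSE) {
  if (length(counts_a) < 2 || length(counts_b) < 2) {
    abort("each group needs at least 2 tumours")
  }
  if (sd(counts_a) == 0 && sd(counts_b) == 0) {
    if (mean(counts_a) == mean(counts_b)) {
      return(tibble(t = 0, df = length(counts_a) + length(counts_b) - 2,
                    p_value = 1, mean_a = mean(counts_a),
                    mean_b = mean(counts_b)))
    }
  }
  tt <- stats::t.test(counts_a, counts_b, var.equal = !welch)
  tibble(t = unname(tt$statistic), df = unname(tt$parameter),
         p_value = tt$p.value, mean_a = mean(counts_a),
         mean_b = mean(counts_b))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3) {
    abort("x and y must have equal length >= 3")
  }
  if (sd(x) == 0 || sd(y) == 0) abort("x and y must have non-zero variance")
  stats::cor(x, y, method = "pearson")
}

#' Ellipsoid tumour volume from caliper measurements
#'
#' The standard caliper formula `V = L * W^2 / 2`.
#'
#' @param length_mm,width_mm Tumour length and width (same units; > 0).
#' @return Volume in cubic units of the input.
#' @examples
#' tumour_volume(2, 1)
#' @export
tumour_volume <- function(length_mm, width_mm) {
  if (any(length_mm <= 0) || any(width_mm <= 0)) {
    abort("length and width must be positive")
  }
  length_mm * width_mm^2 / 2
}

#' @importFrom dplyr %>%
#' @export
dplyr::`%>%`
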
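#' Define a binned genome coordinate system
#'
#' A genome layout is an ordered set of chromosomes with lengths plus a common
#' bin size; it fixes the binned coordinate system every profile, segmentation
#' and event table in the package refers to. Bins are 0-based half-open and
#' tile each chromosome; the last bin of a chromosome may be short.
#'
#' @param chromosomes Tibble or data frame with columns `chrom` (unique
#'   chromosome names, order preserved) and `length_bp` (positive integers).
#' @param bin_size_bp Bin width in base pairs (positive integer).
#'
#' @return A tibble of class `genome_layout` with columns `chrom`,
#'   `length_bp` and `n_bins`, and a `bin_size_bp` attribute.
#' @examples
#' genome_layout(data.frame(chrom = c("chr1", "chr2"),
#'                          length_bp = c(4e6, 2.5e6)), bin_size_bp = 1e6)
#' @export
genome_layout <- function(chromosomes, bin_size_bp = 5e5) {
  chromosomes <- as_tibble(chromosomes)
  stopifnot(all(c("chrom", "length_bp") %in% names(chromosomes)))
  if (anyDuplicated(chromosomes$chrom) > 0) {
    abort("chromosome names must be unique")
  }
  if (any(chromosomes$length_bp <= 0) || bin_size_bp <= 0) {
    abort("chromosome lengths and bin size must be positive")
  }
  out <- tibble(
    chrom = as.character(chromosomes$chrom),
    length_bp = as.numeric(chromosomes$length_bp),
    n_bins = as.integer(ceiling(chromosomes$length_bp / bin_size_bp))
  )
  attr(out, "bin_size_bp") <- as.numeric(bin_size_bp)
  class(out) <- c("genome_layout", class(out))
  out
}

#' Bin size of a genome layout
#' @param layout A `genome_layout`.
#' @return Bin width in base pairs.
#' @export
bin_size <- function(layout) {
  attr(layout, "bin_size_bp")
}

#' Mouse-like default genome layout
#'
#' Nineteen autosomes plus X with approximate mm10 chromosome lengths,
#' binned at 500 kb by default (about 5,450 bins genome-wide). The X
#' chromosome is treated as a diploid autosome throughout the package, the
#' appropriate baseline for an all-female cohort; `log2_normalize()`
#' nevertheless centres on autosomes only so the convention can be changed
#' without moving the baseline.
#'
#' @param bin_size_bp Bin width in base pairs; 500 kb suits ~3x coverage.
#' @return A `genome_layout`.
#' @examples
#' mouse_genome()
#' @export
mouse_genome <- function(bin_size_bp = 5e5) {
  lengths_mb <- c(
    chr1 = 195.5, chr2 = 182.1, chr3 = 160.0, chr4 = 156.5, chr5 = 151.8,
    chr6 = 149.7, chr7 = 145.4, chr8 = 129.4, chr9 = 124.6, chr10 = 130.7,
    chr11 = 122.1, chr12 = 120.1, chr13 = 120.4, chr14 = 124.9, chr15 = 104.0,
    chr16 = 98.2, chr17 = 95.0, chr18 = 90.7, chr19 = 61.4, chrX = 171.0
  )
  genome_layout(
    tibble(chrom = names(lengths_mb), length_bp = lengths_mb * 1e6),
    bin_size_bp = bin_size_bp
  )
}

#' Enumerate the bins of a layout
#'
#' @param layout A `genome_layout`.
#' @return Tibble with one row per bin: `chrom`, `start`, `end` (0-based
#'   half-open bp coordinates, last bin clipped to the chromosome end) and
#'   `bin` (0-based index within the chromosome).
#' @examples
#' layout_bins(genome_layout(data.frame(chrom = "chr1", length_bp = 2.3e6),
#'                           bin_size_bp = 1e6))
#' @export
layout_bins <- function(layout) {
  bs <- bin_size(layout)
  purrr::pmap_dfr(
    list(layout$chrom, layout$length_bp, layout$n_bins),
    function(chrom, len, nb) {
      start <- (seq_len(nb) - 1) * bs
      tibble(
        chrom = chrom,
        start = start,
        end = pmin(start + bs, len),
        bin = seq_len(nb) - 1L
      )
    }
  )
}

#' Autosome names of a layout
#'
#' Chromosomes whose name is not a sex chromosome (`chrX`, `chrY`, `X`, `Y`).
#' @param layout A `genome_layout`.
#' @return Character vector of autosome names.
#' @export
autosomes <- function(layout) {
  setdiff(layout$chrom, c("chrX", "chrY", "X", "Y"))
}

# Internal: check two bin tables describe the same coordinate system.
same_bins <- function(a, b) {
  nrow(a) == nrow(b) &&
    identical(a$chrom, b$chrom) &&
    isTRUE(all(a$start == b$start)) &&
    isTRUE(all(a$end == b$end))
}
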
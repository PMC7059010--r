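#' Reference cohort: sequenced non-regressed Kras / Kras-Mad2 tumours
#'
#' Per-tumour SCNA counts and chromosome-6 cMet-amplification calls for the
#' 23 sequenced non-regressed mammary tumours of the doxycycline-withdrawal
#' cohort this package's analysis targets (7 Kras-only "K" and 16
#' Kras+Mad2 "KM" tumours). `cmet_amp` is the published per-tumour
#' amplified-by-sequencing flag; `chr6_category` records the mechanism of
#' the chromosome-6 cMet gain: the focal ~2 Mb amplicon (`AMP`) in 4/7 K
#' and 10/16 KM tumours, and a whole-chromosome-6 gain (`WCG`) in one KM
#' tumour (KM15), whose cMet copy gain is therefore not a focal
#' amplification.
#'
#' @return Tibble with `tumour_id`, `genotype` (`K`/`KM`), `n_scna`,
#'   `cmet_amp` (logical), `chr6_category` (`AMP`, `WCG` or `NA`).
#' @examples
#' dplyr::count(nonregressed_cohort(), genotype, chr6_category)
#' @export
nonregressed_cohort <- function() {
  k <- tibble(
    tumour_id = c("K1", "K3", "K4", "K5", "K2", "K7", "K10"),
    genotype = "K",
    n_scna = c(1L, 2L, 3L, 4L, 3L, 0L, 1L),
    cmet_amp = c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  )
  km <- tibble(
    tumour_id = c("KM2", "KM3", "KM5", "KM7", "KM8", "KM11", "KM12",
                  "KM15", "KM20", "KM21", "KM22", "KM6", "KM10", "KM14",
                  "KM16", "KM19"),
    genotype = "KM",
    n_scna = c(3L, 4L, 4L, 2L, 3L, 2L, 6L, 1L, 5L, 1L, 4L, 2L, 3L, 1L,
               2L, 0L),
    cmet_amp = c(rep(TRUE, 11), rep(FALSE, 5))
  )
  out <- dplyr::bind_rows(k, km)
  dplyr::mutate(
    out,
    chr6_category = dplyr::case_when(
      .data$tumour_id == "KM15" ~ "WCG",
      .data$cmet_amp ~ "AMP",
      TRUE ~ NA_character_
    )
  )
}

#' Chromosome-6 events of the reference cohort
#'
#' The reference cohort's chromosome-6 cMet gains expressed as an event
#' table suitable for [per_chromosome_frequency()]: a focal amplification
#' (or, for KM15, a whole-chromosome gain) on chr6 per affected tumour.
#' Coordinates are nominal fixture values placing each focal amplicon over
#' the Met locus; only chromosome, category and tumour identity are
#' data-backed.
#'
#' @return Event tibble with `tumour_id`, `chrom`, `start_bp`, `end_bp`,
#'   `category`.
#' @export
nonregressed_chr6_events <- function() {
  cohort <- nonregressed_cohort()
  affected <- cohort[!is.na(cohort$chr6_category), ]
  tibble(
    tumour_id = affected$tumour_id,
    chrom = "chr6",
    start_bp = ifelse(affected$chr6_category == "WCG", 0, 17e6),
    end_bp = ifelse(affected$chr6_category == "WCG", 149.7e6, 19e6),
    category = affected$chr6_category
  )
}

#' Synthetic Met-locus gene annotation
#'
#' A small BED-like annotation placing a gene named `Met` on chr6 together
#' with two flanking genes, for exercising [genes_in_region()] and
#' [minimal_common_region()]. Coordinates are synthetic fixture choices,
#' not asserted genomic truth.
#'
#' @return Annotation tibble (`chrom`, `start_bp`, `end_bp`, `gene`).
#' @export
met_region_genes <- function() {
  tibble(
    chrom = "chr6",
    start_bp = c(15.0e6, 17.4e6, 19.5e6),
    end_bp = c(15.2e6, 17.5e6, 19.7e6),
    gene = c("Left1", "Met", "Right1")
  )
}
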
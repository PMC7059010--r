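#' Read a binned profile from TSV
#'
#' Reads a 4-column tab-separated table (`chrom`, `start`, `end`, plus one
#' value column, 0-based half-open coordinates) and validates that bins tile
#' each chromosome contiguously, in order, without gaps or overlaps.
#' Chromosome order is taken from file order.
#'
#' @param path File path.
#' @param kind Declared value kind, `"counts"` or `"log2"`; stored as an
#'   attribute and checked by downstream steps.
#' @param layout Optional [genome_layout()] to validate chromosome names
#'   and bin counts against.
#'
#' @return A bin-profile tibble (`chrom`, `start`, `end`, value column named
#'   `count` or `log2` by kind) with a `kind` attribute.
#' @export
read_bins <- function(path, kind = c("counts", "log2"), layout = NULL) {
  kind <- match.arg(kind)
  value_col <- if (kind == "counts") "count" else "log2"
  raw <- readr::read_tsv(
    path,
    col_names = c("chrom", "start", "end", value_col),
    col_types = readr::cols(
      chrom = readr::col_character(), start = readr::col_double(),
      end = readr::col_double(), .default = readr::col_double()
    ),
    progress = FALSE
  )
  validate_bins(raw, path = path, layout = layout)
  if (kind == "counts" && any(raw[[value_col]] < 0)) {
    abort("counts must be non-negative")
  }
  if (kind == "log2" && any(!is.finite(raw[[value_col]]))) {
    abort("log2 values must be finite")
  }
  attr(raw, "kind") <- kind
  raw
}

#' Write a binned profile as TSV
#'
#' @param profile Bin-profile tibble from [read_bins()], [emit_counts()] or
#'   [log2_normalize()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bins <- function(profile, path) {
  readr::write_tsv(profile, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

# Validate tiling: within each chromosome (in file order) bins must be
# ordered, contiguous and non-overlapping. Errors name the offending line.
validate_bins <- function(bins, path = "profile", layout = NULL) {
  if (nrow(bins) == 0) abort(paste0(path, ": no bins"))
  if (any(bins$end <= bins$start)) {
    bad <- which(bins$end <= bins$start)[1]
    abort(paste0(path, ": empty or inverted bin at line ", bad))
  }
  runs <- rle(bins$chrom)
  if (anyDuplicated(runs$values) > 0) {
    abort(paste0(path, ": chromosome rows are not contiguous"))
  }
  idx_end <- cumsum(runs$lengths)
  idx_start <- idx_end - runs$lengths + 1L
  for (ci in seq_along(runs$values)) {
    rows <- seq(idx_start[ci], idx_end[ci])
    s <- bins$start[rows]; e <- bins$end[rows]
    if (length(rows) > 1) {
      step <- s[-1] - e[-length(e)]
      if (any(step < 0)) {
        bad <- rows[which(step < 0)[1] + 1L]
        abort(paste0(path, ": overlapping or out-of-order bins at line ", bad))
      }
      if (any(step > 0)) {
        bad <- rows[which(step > 0)[1] + 1L]
        abort(paste0(path, ": gap before bin at line ", bad))
      }
    }
  }
  if (!is.null(layout)) {
    extra <- setdiff(runs$values, layout$chrom)
    if (length(extra) > 0) {
      abort(paste0(path, ": chromosome ", extra[1], " absent from layout"))
    }
    nb <- stats::setNames(layout$n_bins, layout$chrom)
    mismatch <- runs$values[runs$lengths != nb[runs$values]]
    if (length(mismatch) > 0) {
      abort(paste0(path, ": bin count mismatch on ", mismatch[1]))
    }
  }
  invisible(bins)
}

#' Control-normalized log2 ratio profile
#'
#' Computes per-bin `log2((t + pc) / (c + pc))` for a tumour against a
#' matched-normal control and median-centres over autosomal bins so the
#' modal (diploid) state sits at 0. This mirrors the standard low-pass WGS
#' practice of log2-normalizing tumour coverage to a normal-tissue control;
#' no GC or mappability correction is applied.
#'
#' @param tumour,control Bin-count tibbles on the same layout.
#' @param pseudocount Positive pseudocount guarding zero-count bins at low
#'   coverage (default 1).
#' @param layout Optional [genome_layout()]; used to restrict the centring
#'   median to autosomes. Without it, all chromosomes except `chrX`/`chrY`
#'   are treated as autosomes.
#' @param drop_control_quantile Optional quantile in (0, 1): bins whose
#'   control count falls below this quantile of all control counts are
#'   dropped before normalization (poorly covered bins). Off (`NULL`) by
#'   default.
#'
#' @return A log2-ratio bin profile (`chrom`, `start`, `end`, `log2`) with
#'   `kind = "log2"`.
#' @examples
#' lay <- genome_layout(data.frame(chrom = "chr1", length_bp = 5e6), 1e6)
#' sim <- simulate_karyotype(lay, sim_config(rates = c(AMP = 0), seed = 1))
#' cnt <- emit_counts(sim$track, sim_config(), exact = TRUE)
#' log2_normalize(cnt$tumour, cnt$normal)
#' @export
log2_normalize <- function(tumour, control, pseudocount = 1, layout = NULL,
                           drop_control_quantile = NULL) {
  if (pseudocount <= 0) abort("pseudocount must be positive")
  if (!same_bins(tumour, control)) {
    abort("tumour and control profiles are on different layouts")
  }
  if (!is.null(drop_control_quantile)) {
    stopifnot(drop_control_quantile > 0, drop_control_quantile < 1)
    keep <- control$count >= stats::quantile(control$count,
                                             drop_control_quantile)
    tumour <- tumour[keep, ]
    control <- control[keep, ]
  }
  ratio <- log2((tumour$count + pseudocount) / (control$count + pseudocount))
  auto <- if (is.null(layout)) {
    !tumour$chrom %in% c("chrX", "chrY", "X", "Y")
  } else {
    tumour$chrom %in% autosomes(layout)
  }
  centred <- ratio - median(ratio[auto])
  out <- tibble(chrom = tumour$chrom, start = tumour$start,
                end = tumour$end, log2 = centred)
  attr(out, "kind") <- "log2"
  out
}
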
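#' SCNA classifier parameters
#'
#' Category rules for turning segment states into events: a merged run of
#' same-sign segments is a whole-chromosome gain/loss (WCG/WCL) when it
#' spans at least `whole_fraction` of the chromosome, a partial gain/loss
#' (PCG/PCL) when it spans at least `partial_fraction` (one-fifth), and a
#' focal amplification/deletion (AMP/DEL) below that. A chromosome whose
#' number of copy-number state switches exceeds `switch_max` (ten) is
#' called a single gross chromosomal rearrangement (GCR), which supersedes
#' all other calls on that chromosome. All boundaries are inclusive.
#'
#' @param gain_log2 Segment-mean threshold for the GAIN state (default
#'   +0.25, below a clonal single-copy gain at log2(3/2) ~ 0.585 yet above
#'   segmentation noise at ~3x coverage).
#' @param loss_log2 Threshold for LOSS (default -0.25).
#' @param partial_fraction Minimum span fraction for a partial-chromosome
#'   call (default 0.2, "at least one-fifth").
#' @param whole_fraction Minimum span fraction for a whole-chromosome call
#'   (default 0.95; tolerates edge-bin artefacts).
#' @param switch_max Maximum state switches before a chromosome is called
#'   GCR (default 10; a GCR needs more than this many switches).
#' @return A list of class `scna_params`.
#' @export
scna_params <- function(gain_log2 = 0.25, loss_log2 = -0.25,
                        partial_fraction = 0.2, whole_fraction = 0.95,
                        switch_max = 10L) {
  if (!(loss_log2 < 0 && 0 < gain_log2)) {
    abort("need loss_log2 < 0 < gain_log2")
  }
  if (!(partial_fraction > 0 && partial_fraction < whole_fraction &&
        whole_fraction <= 1)) {
    abort("need 0 < partial_fraction < whole_fraction <= 1")
  }
  if (switch_max < 1) abort("switch_max must be >= 1")
  structure(list(gain_log2 = gain_log2, loss_log2 = loss_log2,
                 partial_fraction = partial_fraction,
                 whole_fraction = whole_fraction,
                 switch_max = as.integer(switch_max)),
            class = "scna_params")
}

#' Discretize segment means into copy-number states
#'
#' `GAIN` iff `mean_log2 >= gain_log2`, `LOSS` iff `mean_log2 <= loss_log2`,
#' else `NEUTRAL`; both thresholds inclusive.
#'
#' @param segments Segment tibble with a `mean_log2` column (e.g.
#'   `tidy(cbs_fit)`).
#' @param params An [scna_params()].
#' @return `segments` with a `state` factor column added.
#' @examples
#' call_states(data.frame(mean_log2 = c(0.585, -1, 0.25, 0)))
#' @export
call_states <- function(segments, params = scna_params()) {
  segments <- as_tibble(segments)
  state <- dplyr::case_when(
    segments$mean_log2 >= params$gain_log2 ~ "GAIN",
    segments$mean_log2 <= params$loss_log2 ~ "LOSS",
    TRUE ~ "NEUTRAL"
  )
  dplyr::mutate(segments,
                state = factor(state, levels = c("LOSS", "NEUTRAL", "GAIN")))
}

# Classify one chromosome's state-called segments into events.
classify_one <- function(segs, chrom_length, params) {
  switches <- sum(segs$state[-1] != segs$state[-nrow(segs)])
  chrom_mean <- sum(segs$mean_log2 * segs$n_bins) / sum(segs$n_bins)
  if (switches > params$switch_max) {
    return(tibble(
      chrom = segs$chrom[1],
      start_bp = min(segs$start_bp), end_bp = chrom_length,
      category = "GCR", sign = "mixed",
      mean_log2 = chrom_mean,
      span_fraction = 1
    ))
  }
  nz <- segs$state != "NEUTRAL"
  if (!any(nz)) return(NULL)
  run <- rle(as.character(segs$state))
  run_id <- rep(seq_along(run$values), run$lengths)
  keep <- which(run$values != "NEUTRAL")
  purrr::map_dfr(keep, function(g) {
    s <- segs[run_id == g, ]
    span <- sum(s$end_bp - s$start_bp)
    f <- span / chrom_length
    gain <- run$values[g] == "GAIN"
    category <- if (f >= params$whole_fraction) {
      if (gain) "WCG" else "WCL"
    } else if (f >= params$partial_fraction) {
      if (gain) "PCG" else "PCL"
    } else {
      if (gain) "AMP" else "DEL"
    }
    tibble(
      chrom = s$chrom[1],
      start_bp = min(s$start_bp), end_bp = max(s$end_bp),
      category = category,
      sign = if (gain) "gain" else "loss",
      mean_log2 = sum(s$mean_log2 * s$n_bins) / sum(s$n_bins),
      span_fraction = f
    )
  })
}

#' Classify segments into SCNA events
#'
#' Applies the category rules of [scna_params()] per chromosome: segments
#' are state-called, the chromosome's state-switch count is checked against
#' the GCR rule, and otherwise maximal runs of adjacent same-sign
#' non-neutral segments are merged into candidate events whose category is
#' set by their span fraction of the chromosome.
#'
#' @param fit A `cbs_fit` from [cbs_segment()], or a segment tibble with
#'   columns `chrom`, `start_bp`, `end_bp`, `n_bins`, `mean_log2`.
#' @param layout A [genome_layout()] supplying chromosome lengths (taken
#'   from the fit if present there).
#' @param params An [scna_params()].
#' @return Event tibble: `chrom`, `start_bp`, `end_bp`, `category`
#'   (WCG/WCL/PCG/PCL/AMP/DEL/GCR), `sign` (gain/loss/mixed), `mean_log2`,
#'   `span_fraction`.
#' @export
classify_scna <- function(fit, layout = NULL, params = scna_params()) {
  if (inherits(fit, "cbs_fit")) {
    layout <- layout %||% fit$layout
    segments <- fit$segments
  } else {
    segments <- as_tibble(fit)
  }
  if (is.null(layout)) abort("a genome_layout is required")
  segments <- call_states(segments, params)
  lens <- stats::setNames(layout$length_bp, layout$chrom)
  out <- purrr::map_dfr(unique(segments$chrom), function(ch) {
    classify_one(segments[segments$chrom == ch, ], lens[[ch]], params)
  })
  if (nrow(out) == 0) {
    out <- tibble(chrom = character(), start_bp = numeric(),
                  end_bp = numeric(), category = character(),
                  sign = character(), mean_log2 = numeric(),
                  span_fraction = numeric())
  }
  out
}

#' Count SCNA events per tumour
#'
#' Each event counts once (a GCR is a single SCNA regardless of its internal
#' complexity).
#'
#' @param events Event tibble from [classify_scna()]; may carry a
#'   `tumour_id` column for per-tumour counts.
#' @return If `tumour_id` is present, a tibble of per-tumour counts;
#'   otherwise a single integer.
#' @export
count_scna <- function(events) {
  if ("tumour_id" %in% names(events)) {
    dplyr::summarise(dplyr::group_by(events, .data$tumour_id),
                     n_scna = dplyr::n(), .groups = "drop")
  } else {
    nrow(events)
  }
}

#' Run the full per-tumour SCNA pipeline
#'
#' Convenience wrapper: [log2_normalize()] then [cbs_segment()] then
#' [classify_scna()].
#'
#' @param tumour,control Bin-count profiles on `layout`.
#' @param layout A [genome_layout()].
#' @param pseudocount Passed to [log2_normalize()].
#' @param cbs Passed to [cbs_segment()].
#' @param params Passed to [classify_scna()].
#' @return Event tibble (see [classify_scna()]).
#' @export
call_scna <- function(tumour, control, layout, pseudocount = 1,
                      cbs = cbs_params(), params = scna_params()) {
  lr <- log2_normalize(tumour, control, pseudocount, layout)
  fit <- cbs_segment(lr, cbs, layout)
  classify_scna(fit, layout, params)
}
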
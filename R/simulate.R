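#' Simulation configuration
#'
#' Parameters for generating ground-truthed tumour/normal binned-coverage
#' pairs. The defaults emulate the study conditions the pipeline targets:
#' ~3x low-pass single-end 50 bp sequencing of a mouse-like genome binned at
#' 500 kb (expected 30,000 reads per full bin), mild negative-binomial
#' overdispersion, and an event spectrum averaging ~2.5 SCNAs per tumour in
#' which focal amplification is the most frequent kind.
#'
#' @param mean_depth Expected read count per full-size diploid bin. The
#'   default 30,000 corresponds to 3x coverage of 50 bp reads in a 500 kb
#'   bin (3 * 500000 / 50).
#' @param overdispersion Negative-binomial inverse size (variance =
#'   mu + overdispersion * mu^2). `0` gives Poisson counts.
#' @param rates Named numeric vector of expected event counts per genome for
#'   kinds `WCG`, `WCL`, `PCG`, `PCL`, `AMP`, `DEL`, `GCR` (Poisson draws).
#' @param amp_delta_range Integer range of copy steps for simple focal
#'   amplicons (delta sampled uniformly).
#' @param focal_bins_range Integer range of focal event widths in bins
#'   (~2-6 Mb at 500 kb bins).
#' @param bfb_fraction Fraction of focal amplicons generated as stepped
#'   breakage-fusion-bridge-like profiles (nested +1 gain steps rising to a
#'   peak then falling) rather than flat-top amplicons.
#' @param bfb_steps_range Integer range for the number of nested BFB steps;
#'   the peak copy number is 2 + steps (>= 4 at the minimum of 3 steps).
#' @param seed Optional integer seed applied at the start of
#'   [simulate_karyotype()] and [emit_counts()].
#'
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(mean_depth = 30000,
                       overdispersion = 0.01,
                       rates = c(WCG = 0.5, WCL = 0.2, PCG = 0.25, PCL = 0.3,
                                 AMP = 0.8, DEL = 0.35, GCR = 0.1),
                       amp_delta_range = c(2L, 6L),
                       focal_bins_range = c(4L, 12L),
                       bfb_fraction = 0.3,
                       bfb_steps_range = c(3L, 8L),
                       seed = NULL) {
  kinds <- c("WCG", "WCL", "PCG", "PCL", "AMP", "DEL", "GCR")
  full <- stats::setNames(numeric(7), kinds)
  full[names(rates)] <- rates
  if (mean_depth <= 0) abort("mean_depth must be positive")
  if (overdispersion < 0) abort("overdispersion must be >= 0")
  if (any(full < 0)) abort("event rates must be >= 0")
  structure(
    list(mean_depth = mean_depth, overdispersion = overdispersion,
         rates = full, amp_delta_range = as.integer(amp_delta_range),
         focal_bins_range = as.integer(focal_bins_range),
         bfb_fraction = bfb_fraction,
         bfb_steps_range = as.integer(bfb_steps_range), seed = seed),
    class = "sim_config"
  )
}

# Derive the realized category label from sign and span fraction, using the
# same boundaries the classifier applies, so ground truth and calls share a
# single convention.
realized_kind <- function(delta, span_fraction,
                          partial_fraction = 0.2, whole_fraction = 0.95) {
  gain <- delta > 0
  if (span_fraction >= whole_fraction) {
    if (gain) "WCG" else "WCL"
  } else if (span_fraction >= partial_fraction) {
    if (gain) "PCG" else "PCL"
  } else {
    if (gain) "AMP" else "DEL"
  }
}

# GCR bin pattern: six interior +1 blocks separated by neutral gaps, giving
# twelve copy-number state switches on the chromosome (> 10).
gcr_blocks <- function(n_bins) {
  n_blocks <- 6L
  unit <- max(2L, n_bins %/% (2L * n_blocks + 1L))
  starts <- unit * (2L * seq_len(n_blocks) - 1L)
  tibble(start_bin = starts, end_bin = pmin(starts + unit, n_bins))
}

#' Simulate a tumour karyotype as an integer copy-number track
#'
#' Plants whole/partial chromosome gains and losses, focal amplicons
#' (optionally stepped, breakage-fusion-bridge-like) and gross chromosomal
#' rearrangements on a diploid baseline. Events are placed uniformly at
#' random, snapped to bin boundaries, and overlapping placements are
#' rejected and resampled so the ground truth stays unambiguous. Each
#' event's final label is derived from its realized span with the same
#' span-fraction boundaries the downstream classifier uses.
#'
#' @param layout A [genome_layout()].
#' @param config A [sim_config()].
#' @param forced_events Optional tibble of events to plant verbatim before
#'   any random events: columns `chrom`, `start_bp`, `end_bp`,
#'   `delta_copies`, `kind_label`. A forced `GCR` row triggers the stepped
#'   rearrangement pattern on its chromosome. Forced labels are kept as
#'   given.
#' @param max_tries Placement attempts per random event before an
#'   impossible-configuration error.
#'
#' @return A list with `track` (tibble `chrom`, `start`, `end`, `bin`,
#'   `copy`; baseline ploidy 2) and `events` (tibble `chrom`, `start_bp`,
#'   `end_bp`, `delta_copies`, `kind_label`).
#' @examples
#' lay <- mouse_genome(bin_size_bp = 5e6)
#' sim <- simulate_karyotype(lay, sim_config(seed = 1))
#' table(sim$track$copy)
#' @export
simulate_karyotype <- function(layout, config = sim_config(),
                               forced_events = NULL, max_tries = 100L) {
  stopifnot(inherits(layout, "genome_layout"))
  if (!is.null(config$seed)) set.seed(config$seed)
  bs <- bin_size(layout)
  bins <- layout_bins(layout)
  copy <- rep(2L, nrow(bins))
  # per-chromosome bookkeeping of occupied bins (overlap rejection)
  offset <- c(0L, cumsum(layout$n_bins))
  names(offset) <- c(layout$chrom, "_end_")
  occupied <- rep(FALSE, nrow(bins))
  events <- list()

  chrom_len <- stats::setNames(layout$length_bp, layout$chrom)
  chrom_nb <- stats::setNames(layout$n_bins, layout$chrom)

  bp_of <- function(chrom, b) pmin(b * bs, chrom_len[[chrom]])

  apply_blocks <- function(chrom, blocks, deltas) {
    # blocks: tibble start_bin/end_bin (0-based half-open, per chromosome)
    base <- offset[[chrom]]
    for (r in seq_len(nrow(blocks))) {
      idx <- base + seq(blocks$start_bin[r] + 1L, blocks$end_bin[r])
      copy[idx] <<- copy[idx] + deltas[r]
    }
  }

  add_event <- function(chrom, start_bin, end_bin, delta, label,
                        blocks = NULL, deltas = NULL) {
    base <- offset[[chrom]]
    idx <- base + seq(start_bin + 1L, end_bin)
    if (any(occupied[idx])) return(FALSE)
    occupied[idx] <<- TRUE
    if (is.null(blocks)) {
      blocks <- tibble(start_bin = start_bin, end_bin = end_bin)
      deltas <- delta
    }
    apply_blocks(chrom, blocks, deltas)
    if (any(copy[idx] < 0L)) abort("event would drive copy number below 0")
    events[[length(events) + 1L]] <<- tibble(
      chrom = chrom,
      start_bp = bp_of(chrom, start_bin), end_bp = bp_of(chrom, end_bin),
      delta_copies = as.integer(delta), kind_label = label
    )
    TRUE
  }

  plant_gcr <- function(chrom, forced = FALSE) {
    nb <- chrom_nb[[chrom]]
    blocks <- gcr_blocks(nb)
    ok <- add_event(chrom, 0L, nb, 1L, "GCR",
                    blocks = blocks, deltas = rep(1L, nrow(blocks)))
    # GCR occupies (and is recorded as spanning) the whole chromosome
    if (ok) {
      idx <- offset[[chrom]] + seq_len(nb)
      occupied[idx] <<- TRUE
    }
    ok
  }

  if (!is.null(forced_events)) {
    forced_events <- as_tibble(forced_events)
    for (r in seq_len(nrow(forced_events))) {
      ev <- forced_events[r, ]
      if (!ev$chrom %in% layout$chrom) {
        abort(paste0("forced event on unknown chromosome ", ev$chrom))
      }
      if (identical(ev$kind_label, "GCR")) {
        if (!plant_gcr(ev$chrom, forced = TRUE)) {
          abort("cannot place forced GCR: chromosome already occupied")
        }
        next
      }
      if (!(ev$start_bp >= 0 && ev$start_bp < ev$end_bp &&
            ev$end_bp <= chrom_len[[ev$chrom]])) {
        abort("forced event interval out of chromosome bounds")
      }
      sb <- as.integer(floor(ev$start_bp / bs))
      eb <- as.integer(min(ceiling(ev$end_bp / bs), chrom_nb[[ev$chrom]]))
      if (!add_event(ev$chrom, sb, eb, ev$delta_copies, ev$kind_label)) {
        abort("forced events overlap")
      }
    }
  }

  n_per_kind <- vapply(config$rates, function(r) rpois(1L, r), integer(1))
  kind_queue <- rep(names(n_per_kind), n_per_kind)
  if (length(kind_queue) > 0) kind_queue <- sample(kind_queue)

  for (kind in kind_queue) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      chrom <- sample(layout$chrom, 1L)
      nb <- chrom_nb[[chrom]]
      if (kind %in% c("WCG", "WCL")) {
        delta <- if (kind == "WCG") 1L else -1L
        placed <- add_event(chrom, 0L, nb, delta,
                            realized_kind(delta, 1))
      } else if (kind %in% c("PCG", "PCL")) {
        w <- max(2L, as.integer(round(runif(1, 0.2, 0.95) * nb)))
        if (w >= nb) w <- nb - 1L
        sb <- sample.int(nb - w + 1L, 1L) - 1L
        delta <- if (kind == "PCG") 1L else -1L
        f <- (bp_of(chrom, sb + w) - bp_of(chrom, sb)) / chrom_len[[chrom]]
        placed <- add_event(chrom, sb, sb + w, delta, realized_kind(delta, f))
      } else if (kind %in% c("AMP", "DEL")) {
        w <- sample(seq(config$focal_bins_range[1],
                        config$focal_bins_range[2]), 1L)
        if (w >= nb) next
        sb <- sample.int(nb - w + 1L, 1L) - 1L
        f <- (bp_of(chrom, sb + w) - bp_of(chrom, sb)) / chrom_len[[chrom]]
        if (kind == "DEL") {
          placed <- add_event(chrom, sb, sb + w, -1L, realized_kind(-1, f))
        } else if (runif(1) < config$bfb_fraction && w >= 3L) {
          # BFB-like: nested +1 steps centred on a focal locus, giving a
          # monotone rise to a peak of 2 + K copies then a monotone fall
          K <- sample(seq(config$bfb_steps_range[1],
                          config$bfb_steps_range[2]), 1L)
          widths <- unique(pmax(1L, round(w * seq(K, 1) / K)))
          centre <- sb + w / 2
          blocks <- tibble(
            start_bin = pmax(sb, as.integer(floor(centre - widths / 2))),
            end_bin = pmin(sb + w, as.integer(ceiling(centre + widths / 2)))
          )
          placed <- add_event(chrom, sb, sb + w, length(widths),
                              realized_kind(1, f), blocks = blocks,
                              deltas = rep(1L, nrow(blocks)))
        } else {
          delta <- sample(seq(config$amp_delta_range[1],
                              config$amp_delta_range[2]), 1L)
          placed <- add_event(chrom, sb, sb + w, delta, realized_kind(1, f))
        }
      } else { # GCR
        placed <- plant_gcr(chrom)
      }
      if (placed) break
    }
    if (!placed) {
      abort(paste0("could not place a ", kind,
                   " event after ", max_tries, " attempts"))
    }
  }

  events <- if (length(events) == 0) {
    tibble(chrom = character(), start_bp = numeric(), end_bp = numeric(),
           delta_copies = integer(), kind_label = character())
  } else {
    dplyr::arrange(dplyr::bind_rows(events),
                   match(.data$chrom, layout$chrom), .data$start_bp)
  }
  track <- dplyr::mutate(bins, copy = as.integer(copy))
  attr(track, "layout") <- layout
  list(track = track, events = events)
}

#' Emit tumour and matched-normal binned read counts from a copy track
#'
#' Tumour bin counts are drawn with mean `mean_depth * copy / 2` (scaled for
#' short terminal bins) and the normal with mean `mean_depth`; counts are
#' negative binomial with inverse-size `overdispersion`, Poisson when it is
#' 0, or exactly equal to their expectation when `exact = TRUE`.
#'
#' @param track Copy-number track from [simulate_karyotype()].
#' @param config A [sim_config()].
#' @param exact If `TRUE`, return noise-free expected counts.
#' @param seed Optional integer seed (defaults to `config$seed`).
#'
#' @return List with `tumour` and `normal` bin-count tibbles (`chrom`,
#'   `start`, `end`, `count`), each carrying a `kind = "counts"` attribute.
#' @export
emit_counts <- function(track, config = sim_config(), exact = FALSE,
                        seed = config$seed) {
  if (!is.null(seed)) set.seed(seed)
  bs <- max(track$end - track$start)
  size_frac <- (track$end - track$start) / bs
  mu_t <- config$mean_depth * (track$copy / 2) * size_frac
  mu_n <- config$mean_depth * size_frac
  draw <- function(mu) {
    if (exact) return(mu)
    if (config$overdispersion == 0) {
      rpois(length(mu), mu)
    } else {
      rnbinom(length(mu), mu = mu, size = 1 / config$overdispersion)
    }
  }
  make <- function(count) {
    out <- tibble(chrom = track$chrom, start = track$start,
                  end = track$end, count = as.numeric(count))
    attr(out, "kind") <- "counts"
    out
  }
  list(tumour = make(draw(mu_t)), normal = make(draw(mu_n)))
}

#' Simulate a cohort of ground-truthed tumour/normal pairs
#'
#' @param n_tumours Number of tumours.
#' @param layout A [genome_layout()].
#' @param config A [sim_config()]; its `seed` field seeds the cohort and
#'   per-tumour seeds are derived from it.
#' @param exact Noise-free emission (see [emit_counts()]).
#'
#' @return Tibble with one row per tumour: `tumour_id` and list-columns
#'   `truth` (planted events), `tumour` and `normal` (bin counts).
#' @export
simulate_cohort <- function(n_tumours, layout = mouse_genome(),
                            config = sim_config(), exact = FALSE) {
  if (!is.null(config$seed)) set.seed(config$seed)
  seeds <- sample.int(.Machine$integer.max, n_tumours)
  purrr::map_dfr(seq_len(n_tumours), function(i) {
    cfg <- config
    cfg$seed <- seeds[i]
    sim <- simulate_karyotype(layout, cfg)
    counts <- emit_counts(sim$track, cfg, exact = exact, seed = seeds[i] %% 2147483647L)
    tibble(
      tumour_id = sprintf("T%03d", i),
      truth = list(sim$events),
      tumour = list(counts$tumour),
      normal = list(counts$normal)
    )
  })
}
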
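#' Render one carrier translocation event (noise-free)
#'
#' Draws the current deflection of a single DNA-carrier translocation
#' relative to the open-pore baseline (so all values are <= 0; the baseline
#' and noise are added by [simulate_trace()]). The event is a rectangular
#' blockade of depth `carrier_blockade_depth` with raised-cosine edges.
#' A fraction `margin_frac` of the event is reserved at each end; the
#' central region is divided into `n_bits` equal temporal slots and every
#' "1" bit adds a raised-cosine dumbbell spike centred in its slot. A bound
#' oligomer adds one deeper spike centred in the protein-end margin
#' (trailing end for `orientation = "forward"`, i.e. barcode enters first).
#' `orientation = "reversed"` mirrors the whole event in time. Folded
#' carriers are rendered by doubling the blockade depth over a prefix of the
#' event.
#'
#' @param bits barcode as a 0/1 string (e.g. `"11011"`) or integer vector of
#'   length `config$n_bits`.
#' @param bound logical; add a bound-oligomer spike?
#' @param orientation `"forward"` (barcode first) or `"reversed"`.
#' @param folded logical; render a folded (depth-doubled prefix) carrier.
#' @param config a [sim_config()].
#' @param duration_s plateau duration in seconds (default: the median of the
#'   configured duration distribution).
#' @param oligomer_depth,oligomer_width_s oligomer spike depth (nA) and
#'   width (s); defaults are the medians of the configured distributions.
#'   The width is clamped so the spike stays inside the protein-end margin.
#' @param folded_frac fraction of the event over which a folded carrier is
#'   depth-doubled.
#'
#' @return Numeric vector of current deflections (nA, <= 0) with attribute
#'   `truth`: a list holding `ecd_nA_ms` (the spike area of the rendered
#'   oligomer against the carrier chord, 0 when unbound), `n`, `n_plateau`
#'   and `n_edge`.
#' @examples
#' cfg <- sim_config()
#' ev <- render_event("11011", bound = TRUE, config = cfg)
#' attr(ev, "truth")$ecd_nA_ms
#' @export
render_event <- function(bits, bound = FALSE,
                         orientation = c("forward", "reversed"),
                         folded = FALSE, config = sim_config(),
                         duration_s = NULL,
                         oligomer_depth = NULL, oligomer_width_s = NULL,
                         folded_frac = 0.5) {
  orientation <- match.arg(orientation)
  bits <- parse_bits(bits, config$n_bits)
  fs <- config$sampling_rate
  if (is.null(duration_s)) duration_s <- exp(config$duration_meanlog)
  if (is.null(oligomer_depth)) oligomer_depth <- exp(config$oligomer_depth_meanlog)
  if (is.null(oligomer_width_s)) oligomer_width_s <- exp(config$oligomer_width_meanlog)

  n_plat <- max(1L, as.integer(round(duration_s * fs)))
  slot_w <- (1 - 2 * config$margin_frac) * n_plat / config$n_bits
  if (slot_w < 4) {
    stop("event too short to hold ", config$n_bits, " bit slots at this sampling rate",
         call. = FALSE)
  }
  n_edge <- max(2L, as.integer(round(config$edge_width * fs)))
  n <- n_plat + 2L * n_edge
  p0 <- n_edge  # 0-based offset of the plateau start

  depth <- numeric(n)
  depth[(p0 + 1L):(p0 + n_plat)] <- config$carrier_blockade_depth
  ramp <- config$carrier_blockade_depth *
    0.5 * (1 - cos(pi * seq_len(n_edge) / (n_edge + 1)))
  depth[seq_len(n_edge)] <- ramp
  depth[n:(n - n_edge + 1L)] <- ramp

  # raised-cosine bump of total width `width` samples at 0-based centre
  add_bump <- function(depth, center, width, amp) {
    width <- max(3, width)
    lo <- max(p0 + 1L, as.integer(floor(center - width / 2)) + 1L)
    hi <- min(p0 + n_plat, as.integer(ceiling(center + width / 2)) + 1L)
    idx <- lo:hi
    u <- ((idx - 1L) - (center - width / 2)) / width
    u <- pmin(pmax(u, 0), 1)
    depth[idx] <- depth[idx] + amp * 0.5 * (1 - cos(2 * pi * u))
    depth
  }

  region0 <- config$margin_frac * n_plat  # slot region, 0-based plateau offsets
  for (j in seq_len(config$n_bits)) {
    if (bits[j] == 1L) {
      center <- p0 + region0 + (j - 0.5) * slot_w
      depth <- add_bump(depth, center, config$bit_spike_frac * slot_w,
                        config$bit_spike_depth)
    }
  }

  ecd <- 0
  if (isTRUE(bound)) {
    w_o <- round(oligomer_width_s * fs)
    w_o <- min(w_o, floor(0.95 * config$margin_frac * n_plat))
    center <- p0 + (1 - config$margin_frac / 2) * n_plat
    before <- depth
    depth <- add_bump(depth, center, w_o, oligomer_depth)
    spike <- depth - before
    # area of the rendered spike against the (flat) carrier chord, nA.ms
    ecd <- (sum(spike) - 0.5 * (spike[1] + spike[n])) / fs * 1000
  }

  if (isTRUE(folded)) {
    stopifnot(folded_frac > 0, folded_frac <= 1)
    k <- max(1L, as.integer(round(folded_frac * n)))
    depth[seq_len(k)] <- 2 * depth[seq_len(k)]
  }
  if (orientation == "reversed") depth <- rev(depth)

  structure(-depth,
            truth = list(ecd_nA_ms = ecd, n = n, n_plateau = n_plat,
                         n_edge = n_edge))
}
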
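#' Simulation configuration for synthetic nanopore traces
#'
#' Bundles every parameter of the synthetic-trace generator: acquisition
#' settings (sampling rate, baseline current, noise), carrier-event geometry
#' (blockade depth, bit-spike depth, number of bits, end margins), the
#' stochastic model of the event stream (duration and oligomer-spike
#' distributions, event rate, folded fraction) and the multiplexed sample
#' mixture (one row per barcode: true fraction bound and relative abundance).
#'
#' Defaults reproduce the measurement conditions the pipeline is designed
#' for: 1 MHz sampling, a 50 kHz low-pass cutoff, ~6 pA baseline noise and a
#' 5-bit barcode. The default mixture is the triplex screen (barcodes 11111,
#' 11101 and 11011 with true bound fractions 0.30, 0.42 and 0.14 at relative
#' abundances 114:43:90). Blockade and spike amplitudes are free parameters
#' of the instrument/pore combination, not calibrated values.
#'
#' @param sampling_rate samples per second (Hz).
#' @param baseline_current open-pore baseline current I0 (nA).
#' @param noise_sigma white-noise standard deviation before filtering (pA).
#' @param carrier_blockade_depth depth of the bare-carrier blockade (nA).
#' @param bit_spike_depth additional current drop of one "1"-bit dumbbell
#'   spike relative to the carrier level (nA).
#' @param n_bits number of bit positions on the carrier.
#' @param oligomer_depth_meanlog,oligomer_depth_sdlog log-normal parameters
#'   of the bound-oligomer spike depth (nA).
#' @param oligomer_width_meanlog,oligomer_width_sdlog log-normal parameters
#'   of the bound-oligomer spike width (s).
#' @param duration_meanlog,duration_sdlog log-normal parameters of the event
#'   (plateau) duration (s).
#' @param duration_range hard truncation bounds on drawn durations (s); keeps
#'   every event long enough to hold `n_bits` slots.
#' @param event_rate mean event arrival rate (events/s); gaps between events
#'   are exponential with this rate.
#' @param n_events number of translocation events to insert.
#' @param fraction_folded probability that a carrier enters the pore folded
#'   (doubled blockade over a prefix); folded events are generated so the
#'   rejection stage has something to reject.
#' @param mixture data frame with columns `bits` (character, e.g. "11011"),
#'   `fraction_bound` (true per-barcode bound probability) and `abundance`
#'   (relative; normalized to sum to 1).
#' @param lowpass_cutoff low-pass cutoff frequency (Hz); `NA` disables
#'   filtering.
#' @param margin_frac fraction of the event reserved at each end, outside
#'   the bit slots; the oligomer spike sits in the protein-end margin.
#' @param bit_spike_frac width of a bit spike as a fraction of its slot.
#' @param edge_width rise/fall time of the blockade edges (s).
#' @param blank_duration trace duration used when `n_events = 0` (s).
#' @param seed integer RNG seed; identical configurations (including seed)
#'   produce bit-identical traces and ground truth.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_trace()], [render_event()]
#' @examples
#' cfg <- sim_config(n_events = 10, seed = 1)
#' cfg$mixture
#' @export
sim_config <- function(sampling_rate = 1e6,
                       baseline_current = 6,
                       noise_sigma = 6,
                       carrier_blockade_depth = 0.35,
                       bit_spike_depth = 0.25,
                       n_bits = 5L,
                       oligomer_depth_meanlog = log(0.5),
                       oligomer_depth_sdlog = 0.2,
                       oligomer_width_meanlog = log(2e-4),
                       oligomer_width_sdlog = 0.25,
                       duration_meanlog = log(1.5e-3),
                       duration_sdlog = 0.3,
                       duration_range = c(6e-4, 4e-3),
                       event_rate = 100,
                       n_events = 200L,
                       fraction_folded = 0.7,
                       mixture = default_mixture(),
                       lowpass_cutoff = 5e4,
                       margin_frac = 0.18,
                       bit_spike_frac = 0.4,
                       edge_width = 1e-5,
                       blank_duration = 0.05,
                       seed = NULL) {
  cfg <- list(
    sampling_rate = as.numeric(sampling_rate),
    baseline_current = as.numeric(baseline_current),
    noise_sigma = as.numeric(noise_sigma),
    carrier_blockade_depth = as.numeric(carrier_blockade_depth),
    bit_spike_depth = as.numeric(bit_spike_depth),
    n_bits = as.integer(n_bits),
    oligomer_depth_meanlog = as.numeric(oligomer_depth_meanlog),
    oligomer_depth_sdlog = as.numeric(oligomer_depth_sdlog),
    oligomer_width_meanlog = as.numeric(oligomer_width_meanlog),
    oligomer_width_sdlog = as.numeric(oligomer_width_sdlog),
    duration_meanlog = as.numeric(duration_meanlog),
    duration_sdlog = as.numeric(duration_sdlog),
    duration_range = as.numeric(duration_range),
    event_rate = as.numeric(event_rate),
    n_events = as.integer(n_events),
    fraction_folded = as.numeric(fraction_folded),
    mixture = mixture,
    lowpass_cutoff = as.numeric(lowpass_cutoff),
    margin_frac = as.numeric(margin_frac),
    bit_spike_frac = as.numeric(bit_spike_frac),
    edge_width = as.numeric(edge_width),
    blank_duration = as.numeric(blank_duration),
    seed = if (!is.null(seed)) as.integer(seed)
  )
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @export
default_mixture <- function() {
  data.frame(
    bits = c("11111", "11101", "11011"),
    fraction_bound = c(0.30, 0.42, 0.14),
    abundance = c(114, 43, 90) / 247,
    stringsAsFactors = FALSE
  )
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  chk <- function(ok, msg) if (!isTRUE(ok)) stop("invalid sim_config: ", msg, call. = FALSE)
  chk(cfg$sampling_rate > 0, "sampling_rate must be > 0")
  chk(cfg$baseline_current > 0, "baseline_current must be > 0")
  chk(cfg$noise_sigma >= 0, "noise_sigma must be >= 0")
  chk(cfg$carrier_blockade_depth > 0, "carrier_blockade_depth must be > 0")
  chk(cfg$bit_spike_depth > 0, "bit_spike_depth must be > 0")
  chk(cfg$n_bits >= 1L, "n_bits must be >= 1")
  chk(cfg$event_rate >= 0, "event_rate must be >= 0")
  chk(cfg$n_events >= 0L, "n_events must be >= 0")
  chk(cfg$fraction_folded >= 0 && cfg$fraction_folded <= 1,
      "fraction_folded must be in [0, 1]")
  chk(cfg$margin_frac > 0 && cfg$margin_frac < 0.5, "margin_frac must be in (0, 0.5)")
  chk(cfg$bit_spike_frac > 0 && cfg$bit_spike_frac <= 1,
      "bit_spike_frac must be in (0, 1]")
  chk(length(cfg$duration_range) == 2 && all(cfg$duration_range > 0) &&
        diff(cfg$duration_range) > 0, "duration_range must be increasing and positive")
  if (!is.na(cfg$lowpass_cutoff)) {
    chk(cfg$lowpass_cutoff > 0 && cfg$lowpass_cutoff < cfg$sampling_rate / 2,
        "lowpass_cutoff must lie in (0, sampling_rate/2)")
  }
  m <- cfg$mixture
  chk(is.data.frame(m) && all(c("bits", "fraction_bound", "abundance") %in% names(m)),
      "mixture needs columns bits, fraction_bound, abundance")
  chk(all(nchar(m$bits) == cfg$n_bits) && all(grepl("^[01]+$", m$bits)),
      "mixture bits must be 0/1 strings of length n_bits")
  chk(!anyDuplicated(m$bits), "mixture bits must be unique")
  chk(all(m$fraction_bound >= 0 & m$fraction_bound <= 1),
      "mixture fraction_bound must be in [0, 1]")
  chk(all(m$abundance > 0), "mixture abundances must be > 0")
  cfg$mixture$abundance <- m$abundance / sum(m$abundance)
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  sampling %g Hz | baseline %.3g nA | noise %.3g pA | lowpass %s\n",
              x$sampling_rate, x$baseline_current, x$noise_sigma,
              if (is.na(x$lowpass_cutoff)) "off" else sprintf("%g Hz", x$lowpass_cutoff)))
  cat(sprintf("  carrier %.3g nA, bit spike %.3g nA, %d bits, margins %.2f\n",
              x$carrier_blockade_depth, x$bit_spike_depth, x$n_bits, x$margin_frac))
  cat(sprintf("  %d events @ %g /s, folded fraction %.2f, seed %s\n",
              x$n_events, x$event_rate, x$fraction_folded,
              if (is.null(x$seed)) "none" else x$seed))
  cat(sprintf("  mixture: %s\n",
              paste(sprintf("%s(p=%.2f, w=%.2f)", x$mixture$bits,
                            x$mixture$fraction_bound, x$mixture$abundance),
                    collapse = ", ")))
  invisible(x)
}

# parse "11011" / c(1,1,0,1,1) into an integer 0/1 vector
parse_bits <- function(bits, n_bits = NULL) {
  if (is.character(bits)) {
    stopifnot(length(bits) == 1L)
    if (!grepl("^[01]+$", bits)) stop("bits must be a string of 0s and 1s", call. = FALSE)
    bits <- as.integer(strsplit(bits, "")[[1]])
  }
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) stop("bits must be 0 or 1", call. = FALSE)
  if (!is.null(n_bits) && length(bits) != n_bits) {
    stop(sprintf("bit vector has length %d, expected %d", length(bits), n_bits),
         call. = FALSE)
  }
  bits
}

bits_to_string <- function(bits) paste(bits, collapse = "")

# run body with a locally-seeded RNG, restoring global state afterwards
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
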
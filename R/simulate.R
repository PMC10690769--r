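#' Simulate a nanopore current trace with ground truth
#'
#' Draws a stream of carrier translocation events from the configured
#' mixture, renders each with [render_event()], and embeds them in a
#' Gaussian-noise baseline at exponential inter-event gaps. Events never
#' overlap (they are placed sequentially); a configuration whose event rate
#' is incompatible with non-overlapping events is rejected up front. The
#' assembled trace is low-pass filtered at `config$lowpass_cutoff` unless
#' that is `NA`. With `config$seed` set, the output is bit-identical across
#' runs.
#'
#' @param config a [sim_config()].
#' @return A list with components `trace` (a [trace_record()]) and `truth`,
#'   a data frame with one row per inserted event: `event`, `bits`,
#'   `orientation`, `bound`, `folded`, `ecd_nA_ms` (0 when unbound),
#'   `start`/`end` (0-based half-open sample indices of the rendered extent)
#'   and `duration_s` (the drawn plateau duration), sorted by `start`.
#' @examples
#' sim <- simulate_trace(sim_config(n_events = 5, seed = 42))
#' sim$truth[, c("bits", "bound", "start", "end")]
#' @export
simulate_trace <- function(config) {
  config <- validate_sim_config(config)
  fs <- config$sampling_rate
  n_ev <- config$n_events

  if (n_ev == 0L || config$event_rate == 0) {
    return(with_local_seed(config$seed, {
      n <- max(2L, as.integer(round(config$blank_duration * fs)))
      x <- baseline_noise(n, config)
      if (!is.na(config$lowpass_cutoff))
        x <- .lowpass(x, fs, config$lowpass_cutoff)
      list(trace = sim_trace_record(x, config), truth = empty_truth())
    }))
  }

  mean_dur <- exp(config$duration_meanlog + config$duration_sdlog^2 / 2)
  if (1 / config$event_rate <= mean_dur) {
    stop("event_rate ", config$event_rate,
         " /s is too high for non-overlapping events (mean duration ",
         signif(mean_dur, 3), " s)", call. = FALSE)
  }

  with_local_seed(config$seed, {
    mix <- config$mixture
    cls <- sample.int(nrow(mix), n_ev, replace = TRUE, prob = mix$abundance)
    tab <- data.frame(
      bits = mix$bits[cls],
      bound = rbinom(n_ev, 1L, mix$fraction_bound[cls]) == 1L,
      orientation = ifelse(runif(n_ev) < 0.5, "forward", "reversed"),
      folded = rbinom(n_ev, 1L, config$fraction_folded) == 1L,
      folded_frac = runif(n_ev, 0.3, 0.7),
      duration_s = pmin(pmax(rlnorm(n_ev, config$duration_meanlog,
                                    config$duration_sdlog),
                             config$duration_range[1]), config$duration_range[2]),
      olig_depth = rlnorm(n_ev, config$oligomer_depth_meanlog,
                          config$oligomer_depth_sdlog),
      olig_width_s = rlnorm(n_ev, config$oligomer_width_meanlog,
                            config$oligomer_width_sdlog),
      gap_s = pmax(rexp(n_ev, config$event_rate), 5e-4),
      stringsAsFactors = FALSE
    )
    assemble_trace(tab, config)
  })
}

# Build a trace from a fully-specified event table (one row per event).
# Used by simulate_trace() after drawing, and by make_fixture() with
# deterministic tables. Consumes RNG only for the baseline noise.
assemble_trace <- function(tab, config) {
  fs <- config$sampling_rate
  n_ev <- nrow(tab)
  rendered <- vector("list", n_ev)
  for (i in seq_len(n_ev)) {
    rendered[[i]] <- render_event(
      tab$bits[i], bound = tab$bound[i], orientation = tab$orientation[i],
      folded = tab$folded[i], config = config,
      duration_s = tab$duration_s[i],
      oligomer_depth = tab$olig_depth[i],
      oligomer_width_s = tab$olig_width_s[i],
      folded_frac = tab$folded_frac[i]
    )
  }
  len <- vapply(rendered, length, 1L)
  gaps <- pmax(1L, as.integer(round(tab$gap_s * fs)))
  starts <- integer(n_ev)  # 0-based
  pos <- 0L
  for (i in seq_len(n_ev)) {
    pos <- pos + gaps[i]
    starts[i] <- pos
    pos <- pos + len[i]
  }
  n <- pos + as.integer(round(0.002 * fs))

  x <- baseline_noise(n, config)
  for (i in seq_len(n_ev)) {
    idx <- (starts[i] + 1L):(starts[i] + len[i])
    x[idx] <- x[idx] + as.numeric(rendered[[i]])
  }
  if (!is.na(config$lowpass_cutoff)) x <- .lowpass(x, fs, config$lowpass_cutoff)

  truth <- data.frame(
    event = seq_len(n_ev),
    bits = tab$bits,
    orientation = tab$orientation,
    bound = tab$bound,
    folded = tab$folded,
    ecd_nA_ms = vapply(rendered, function(r) attr(r, "truth")$ecd_nA_ms, 1.0),
    start = starts,
    end = starts + len,
    duration_s = tab$duration_s,
    stringsAsFactors = FALSE
  )
  truth$ecd_nA_ms[!truth$bound] <- 0
  list(trace = sim_trace_record(x, config), truth = truth)
}

baseline_noise <- function(n, config) {
  sig <- config$noise_sigma / 1000  # pA -> nA
  if (sig > 0) rnorm(n, config$baseline_current, sig)
  else rep(config$baseline_current, n)
}

sim_trace_record <- function(x, config) {
  trace_record(x, config$sampling_rate, metadata = list(
    I0 = config$baseline_current,
    voltage_mV = 500,
    pore_diameter_nm = 15,
    buffer = "2 M LiCl 1x TE pH 8.0",
    acquisition = "simulated",
    noise_sigma_pA = config$noise_sigma,
    lowpass_cutoff_Hz = config$lowpass_cutoff
  ))
}

empty_truth <- function() {
  data.frame(event = integer(), bits = character(), orientation = character(),
             bound = logical(), folded = logical(), ecd_nA_ms = numeric(),
             start = integer(), end = integer(), duration_s = numeric(),
             stringsAsFactors = FALSE)
}

#' Low-pass filter a trace
#'
#' Applies a 4th-order digital Butterworth low-pass (designed with
#' [signal::butter()]) to the trace, emulating the analogue anti-noise
#' filter of the recording chain: DC is preserved and a sinusoid at the
#' cutoff is attenuated by ~3 dB. The start-up transient is suppressed by
#' reflect-padding the leading edge before filtering.
#'
#' @param trace a [trace_record()].
#' @param cutoff cutoff frequency in Hz; must be below the Nyquist
#'   frequency.
#' @return A filtered [trace_record()].
#' @export
apply_lowpass <- function(trace, cutoff) {
  stopifnot(inherits(trace, "trace_record"))
  trace$samples <- .lowpass(trace$samples, trace$sampling_rate, cutoff)
  trace$metadata$lowpass_cutoff_Hz <- cutoff
  trace
}

.lowpass <- function(x, fs, cutoff, order = 4L) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, sampling_rate/2)", call. = FALSE)
  n <- length(x)
  bf <- signal::butter(order, cutoff / (fs / 2), type = "low")
  # filter the deviation from the first sample with a reflected lead-in:
  # zero initial filter state then matches the signal, killing the start-up
  # transient (a constant trace passes through unchanged)
  m <- x[1]
  p <- min(n - 1L, as.integer(round(6 * fs / cutoff)))
  xp <- if (p > 0L) c(rev(x[2:(p + 1L)]) - m, x - m) else x - m
  y <- as.numeric(signal::filter(bf, xp)) + m
  if (p > 0L) y <- y[-seq_len(p)]
  y
}
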
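#' Detector parameters
#'
#' Thresholds and windows for the translocation finder. The defaults are
#' the standard operating thresholds for this read-out: events must last at
#' least 0.3 ms and drop the current by at least 0.1 nA. Event boundaries
#' are placed where the excursion crosses `threshold_frac * min_drop`
#' (a hysteresis band below the detection threshold), and sub-threshold
#' gaps shorter than `min_duration * merge_gap_frac` between excursions are
#' merged so that dumbbell spikes cannot split one carrier event into many.
#'
#' @param min_duration minimum event duration (s).
#' @param min_drop minimum current drop from baseline (nA).
#' @param threshold_frac boundary-placement threshold as a fraction of
#'   `min_drop`, in (0, 1].
#' @param baseline_window running-baseline window length (samples).
#' @param merge_gap_frac sub-threshold gaps shorter than this fraction of
#'   `min_duration` are merged into one event.
#' @return An object of class `detector_params`.
#' @export
detector_params <- function(min_duration = 3e-4, min_drop = 0.1,
                            threshold_frac = 0.5, baseline_window = 20001L,
                            merge_gap_frac = 1 / 3) {
  stopifnot(min_duration > 0, min_drop > 0,
            threshold_frac > 0, threshold_frac <= 1,
            baseline_window >= 1, merge_gap_frac >= 0)
  structure(list(min_duration = min_duration, min_drop = min_drop,
                 threshold_frac = threshold_frac,
                 baseline_window = as.integer(baseline_window),
                 merge_gap_frac = merge_gap_frac),
            class = "detector_params")
}

#' Robust running baseline of a trace
#'
#' Estimates the open-pore baseline as an upper quantile (default the
#' upper quartile) over consecutive windows, linearly interpolated to every
#' sample. Translocation blockades only deflect the current downward, so a
#' high quantile stays on the baseline as long as events occupy less than
#' `1 - prob` of a window — far more than a median survives, which matters
#' when events arrive in bursts. On an event-free trace the estimate is
#' biased up by about `qnorm(prob)` noise sigmas (a few pA here), which is
#' negligible against the 0.1 nA detection threshold; the estimator tracks
#' slow baseline drift with a window-scale lag.
#'
#' @param trace a [trace_record()] or numeric vector (nA).
#' @param window window length in samples; must be in `[1, length(trace)]`.
#' @param prob quantile used within each window.
#' @return Numeric baseline series, one value per sample.
#' @export
estimate_baseline <- function(trace, window = 20001L, prob = 0.75) {
  x <- if (inherits(trace, "trace_record")) trace$samples else as.numeric(trace)
  n <- length(x)
  window <- as.integer(window)
  if (window < 1L || window > n)
    stop("window must be between 1 and the trace length (", n, ")",
         call. = FALSE)
  nb <- ceiling(n / window)
  if (nb < 2L) return(rep(unname(quantile(x, prob)), n))
  pad <- nb * window - n
  m <- matrix(c(x, rep(NA_real_, pad)), nrow = window)
  bm <- apply(m, 2L, quantile, probs = prob, na.rm = TRUE, names = FALSE)
  centers <- (seq_len(nb) - 0.5) * window
  centers[nb] <- (n + (nb - 1L) * window) / 2  # centre of the short tail block
  approx(centers, bm, xout = seq_len(n), rule = 2)$y
}

#' Find translocation events in a trace
#'
#' Thresholded excursion detector: the drop below the running baseline is
#' compared against `threshold_frac * min_drop` to delimit candidate
#' excursions; nearby excursions separated by short sub-threshold gaps are
#' merged; and candidates are kept only if they reach the full `min_drop`
#' somewhere and last at least `min_duration`. Every returned event
#' therefore satisfies both thresholds, and events are sorted and
#' non-overlapping. The local baseline `I0_local` is the median of the
#' running baseline over a window preceding the event.
#'
#' @param trace a [trace_record()].
#' @param params a [detector_params()].
#' @param baseline optional precomputed baseline series (from
#'   [estimate_baseline()]); computed if omitted.
#' @return List of [event_record()]s (possibly empty).
#' @examples
#' sim <- simulate_trace(sim_config(n_events = 3, fraction_folded = 0, seed = 7))
#' evs <- find_events(sim$trace, detector_params())
#' length(evs)
#' @export
find_events <- function(trace, params = detector_params(), baseline = NULL) {
  stopifnot(inherits(trace, "trace_record"), inherits(params, "detector_params"))
  x <- trace$samples
  n <- length(x)
  fs <- trace$sampling_rate
  if (is.null(baseline))
    baseline <- estimate_baseline(trace, min(params$baseline_window, n))
  drop <- baseline - x

  entry_thr <- params$threshold_frac * params$min_drop
  mask <- drop >= entry_thr
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values)
  if (!length(on)) return(list())
  seg <- cbind(starts[on], ends[on])  # 1-based inclusive

  # merge runs separated by short sub-threshold gaps
  max_gap <- params$min_duration * params$merge_gap_frac * fs
  if (nrow(seg) > 1L) {
    keep <- list(seg[1L, ])
    for (i in 2L:nrow(seg)) {
      last <- keep[[length(keep)]]
      if (seg[i, 1L] - last[2L] - 1L < max_gap) {
        keep[[length(keep)]] <- c(last[1L], seg[i, 2L])
      } else {
        keep[[length(keep) + 1L]] <- seg[i, ]
      }
    }
    seg <- do.call(rbind, keep)
  }

  min_len <- params$min_duration * fs
  pre <- max(50L, params$baseline_window %/% 4L)
  out <- list()
  for (i in seq_len(nrow(seg))) {
    a <- seg[i, 1L]; b <- seg[i, 2L]
    if (b - a + 1L < min_len) next
    if (max(drop[a:b]) < params$min_drop) next
    i0_idx <- max(1L, a - pre):max(1L, a - 1L)
    I0 <- median(baseline[i0_idx])
    out[[length(out) + 1L]] <- event_record(
      x_left = a - 1L, x_right = b, samples = x[a:b],
      I0_local = I0, sampling_rate = fs)
  }
  out
}

#' Estimate the baseline noise level of a trace
#'
#' Robust standard deviation (MAD) of the residual between the trace and
#' its running baseline; insensitive to the events themselves. This is the
#' noise scale the decoder thresholds default to.
#'
#' @param trace a [trace_record()].
#' @param baseline optional precomputed baseline series.
#' @return Noise sigma in nA.
#' @export
estimate_noise_sigma <- function(trace, baseline = NULL) {
  stopifnot(inherits(trace, "trace_record"))
  if (is.null(baseline))
    baseline <- estimate_baseline(trace, min(20001L, length(trace$samples)))
  mad(trace$samples - baseline)
}
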
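#' A single translocation event
#'
#' Holds one detected (or stored) translocation: 0-based half-open sample
#' bounds in the source trace, the extracted samples, the local baseline
#' `I0_local`, and derived duration statistics. The normalized duration is
#' the event duration in ms divided by the local baseline current in nA
#' (ms/nA), which makes dwell times comparable across pores with different
#' open-pore currents.
#'
#' @param x_left,x_right 0-based half-open sample bounds; `x_right > x_left`
#'   and `x_right - x_left` must equal `length(samples)`.
#' @param samples extracted current samples (nA).
#' @param I0_local baseline current at the event (nA), > 0.
#' @param sampling_rate samples per second.
#' @param ... optional decode results carried with the event: `category`,
#'   `bits`, `orientation`, `class_id`, `ecd`, `bit_confidence`.
#' @return An object of class `event_record`.
#' @seealso [find_events()], [normalized_duration()]
#' @export
event_record <- function(x_left, x_right, samples, I0_local, sampling_rate, ...) {
  x_left <- as.integer(x_left); x_right <- as.integer(x_right)
  samples <- as.numeric(samples)
  if (x_right <= x_left) stop("x_right must exceed x_left", call. = FALSE)
  if (length(samples) != x_right - x_left)
    stop("samples length must equal x_right - x_left", call. = FALSE)
  if (!is.finite(I0_local) || I0_local <= 0)
    stop("I0_local must be a positive number", call. = FALSE)
  dur_s <- (x_right - x_left) / sampling_rate
  ev <- list(x_left = x_left, x_right = x_right, samples = samples,
             I0_local = as.numeric(I0_local),
             min_current = min(samples),
             sampling_rate = as.numeric(sampling_rate),
             duration_s = dur_s,
             duration_norm = dur_s * 1000 / I0_local)
  extra <- list(...)
  ev[names(extra)] <- extra
  structure(ev, class = "event_record")
}

#' @export
print.event_record <- function(x, ...) {
  cat(sprintf("<event_record> [%d, %d) %.3g ms, I0 %.3g nA, min %.3g nA",
              x$x_left, x$x_right, x$duration_s * 1000, x$I0_local,
              x$min_current))
  if (!is.null(x$category)) cat(" |", x$category)
  if (!is.null(x$bits)) cat(" bits", x$bits)
  cat("\n")
  invisible(x)
}

#' Normalized event duration (ms per nA of baseline)
#'
#' Dwell time normalized to the open-pore baseline current:
#' `((x_right - x_left) / sampling_rate * 1000) / I0`, in ms/nA. Because
#' different pores have different baselines, this is the duration statistic
#' compared across runs.
#'
#' @param event an [event_record()].
#' @return Normalized duration (ms/nA).
#' @examples
#' ev <- event_record(0, 1000, rep(5.6, 1000), I0_local = 5, sampling_rate = 1e6)
#' normalized_duration(ev)  # 1 ms / 5 nA = 0.2
#' @export
normalized_duration <- function(event) {
  stopifnot(inherits(event, "event_record"))
  if (!is.finite(event$I0_local) || event$I0_local <= 0)
    stop("I0_local must be > 0", call. = FALSE)
  ((event$x_right - event$x_left) / event$sampling_rate * 1000) / event$I0_local
}
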
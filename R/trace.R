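#' Sampled ionic-current trace
#'
#' A `trace_record` holds a sampled current time series in nA together with
#' its sampling rate and acquisition metadata (open-pore baseline `I0`,
#' applied voltage, pore diameter, buffer/acquisition labels). It is the raw
#' input to event detection.
#'
#' @param samples numeric vector of currents (nA); must be finite.
#' @param sampling_rate samples per second (Hz); must be positive.
#' @param metadata named list; if an `I0` entry is present it must be > 0.
#'
#' @return An object of class `trace_record`.
#' @examples
#' tr <- trace_record(rnorm(100, 6, 0.006), 1e6, list(I0 = 6))
#' tr
#' @export
trace_record <- function(samples, sampling_rate, metadata = list()) {
  samples <- as.numeric(samples)
  if (!all(is.finite(samples))) stop("trace samples must be finite", call. = FALSE)
  sampling_rate <- as.numeric(sampling_rate)
  if (length(sampling_rate) != 1L || !is.finite(sampling_rate) || sampling_rate <= 0)
    stop("sampling_rate must be a single positive number", call. = FALSE)
  if (!is.list(metadata)) stop("metadata must be a list", call. = FALSE)
  if (!is.null(metadata$I0) && !(is.numeric(metadata$I0) && metadata$I0 > 0))
    stop("metadata I0 must be > 0 when present", call. = FALSE)
  structure(list(samples = samples, sampling_rate = sampling_rate,
                 metadata = metadata),
            class = "trace_record")
}

#' @export
print.trace_record <- function(x, ...) {
  cat(sprintf("<trace_record> %d samples @ %g Hz (%.4g s)\n",
              length(x$samples), x$sampling_rate,
              length(x$samples) / x$sampling_rate))
  if (length(x$metadata)) {
    keys <- vapply(names(x$metadata), function(k)
      sprintf("%s=%s", k, format(x$metadata[[k]])), "")
    cat("  metadata:", paste(keys, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.trace_record <- function(x) length(x$samples)
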
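#' Barcode code-space helpers
#'
#' A carrier with `n_bits` spike/spacer positions encodes `2^n_bits`
#' distinct barcodes (32 for the 5-bit design used here; 56 bits would give
#' > 1e16). Because a carrier can enter the pore in either orientation, a
#' barcode read without an attached protein spike is only defined up to
#' time reversal; `canonical_code()` maps a bit string to the
#' lexicographic minimum of itself and its reverse, and
#' `barcode_classes()` enumerates the distinct reversal-equivalence
#' classes (20 for 5 bits: 8 palindromes plus 24/2 mirrored pairs).
#'
#' @param bits a bit string such as `"11011"` (or 0/1 vector).
#' @param n_bits number of bit positions.
#' @return `canonical_code()`: the canonical bit string; `barcode_codes()`:
#'   all `2^n_bits` bit strings; `barcode_classes()`: the canonical
#'   representatives; `code_space_size()`: `2^n_bits` as a double.
#' @examples
#' canonical_code("11101")       # same class as "10111"
#' length(barcode_classes(5))    # 20
#' code_space_size(56) > 1e16
#' @export
canonical_code <- function(bits) {
  b <- bits_to_string(parse_bits(bits))
  r <- paste(rev(strsplit(b, "")[[1]]), collapse = "")
  if (r < b) r else b
}

#' @rdname canonical_code
#' @export
barcode_codes <- function(n_bits) {
  n_bits <- as.integer(n_bits)
  stopifnot(n_bits >= 1L, n_bits <= 30L)
  vapply(0:(2L^n_bits - 1L), function(v)
    paste(rev(as.integer(intToBits(v))[seq_len(n_bits)]), collapse = ""), "")
}

#' @rdname canonical_code
#' @export
barcode_classes <- function(n_bits) {
  sort(unique(vapply(barcode_codes(n_bits), canonical_code, "",
                     USE.NAMES = FALSE)))
}

#' @rdname canonical_code
#' @export
code_space_size <- function(n_bits) 2^as.numeric(n_bits)

#' Decoder parameters
#'
#' Controls how events are decoded into barcode reads and oligomer-spike
#' calls. Spike thresholds default to multiples of the local noise sigma
#' (3x for bit spikes, 5x for oligomer spikes) with absolute floors that
#' guard near-noiseless recordings. Oligomer spikes are distinguished from
#' bit spikes positionally (they lie in the end margins, outside the bit
#' slots) and by amplitude; either criterion can be switched off.
#'
#' @param n_bits number of bit positions on the carrier.
#' @param margin_frac fraction of the event at each end that is outside the
#'   bit slots; must match the carrier design.
#' @param bit_threshold,oligomer_threshold absolute spike thresholds (nA,
#'   excess over the carrier level); `NULL` means derive from
#'   `noise_sigma`.
#' @param noise_sigma local noise sigma (nA); usually estimated from the
#'   trace by [estimate_noise_sigma()] and filled in by
#'   [classify_events()].
#' @param min_bit_threshold,min_oligomer_threshold floors for the derived
#'   thresholds (nA).
#' @param carrier_depth expected single-carrier blockade depth (nA), used
#'   by the folded-event filter.
#' @param folded_depth_factor,folded_frac_threshold an event is rejected as
#'   folded when its depth exceeds `folded_depth_factor * carrier_depth`
#'   over more than `folded_frac_threshold` of its samples.
#' @param min_spike_width minimum spike width (samples).
#' @param spike_pad padding (samples) added around a spike's threshold
#'   crossings before integrating its ECD, so the chord rests on the
#'   carrier level.
#' @param use_position,use_amplitude which criteria distinguish an oligomer
#'   spike from a bit spike.
#' @return An object of class `decoder_params`.
#' @export
decoder_params <- function(n_bits = 5L, margin_frac = 0.18,
                           bit_threshold = NULL, oligomer_threshold = NULL,
                           noise_sigma = NULL,
                           min_bit_threshold = 0.03,
                           min_oligomer_threshold = 0.05,
                           carrier_depth = 0.35,
                           folded_depth_factor = 1.6,
                           folded_frac_threshold = 0.15,
                           min_spike_width = 5L, spike_pad = 25L,
                           use_position = TRUE, use_amplitude = TRUE) {
  stopifnot(n_bits >= 1L, margin_frac > 0, margin_frac < 0.5,
            carrier_depth > 0, folded_depth_factor > 1,
            folded_frac_threshold > 0, folded_frac_threshold < 1,
            min_spike_width >= 1L, spike_pad >= 0L)
  structure(list(n_bits = as.integer(n_bits), margin_frac = margin_frac,
                 bit_threshold = bit_threshold,
                 oligomer_threshold = oligomer_threshold,
                 noise_sigma = noise_sigma,
                 min_bit_threshold = min_bit_threshold,
                 min_oligomer_threshold = min_oligomer_threshold,
                 carrier_depth = carrier_depth,
                 folded_depth_factor = folded_depth_factor,
                 folded_frac_threshold = folded_frac_threshold,
                 min_spike_width = as.integer(min_spike_width),
                 spike_pad = as.integer(spike_pad),
                 use_position = isTRUE(use_position),
                 use_amplitude = isTRUE(use_amplitude)),
            class = "decoder_params")
}

bit_thr <- function(params) {
  if (!is.null(params$bit_threshold)) return(params$bit_threshold)
  s <- if (is.null(params$noise_sigma)) 0 else params$noise_sigma
  max(3 * s, params$min_bit_threshold)
}

olig_thr <- function(params) {
  if (!is.null(params$oligomer_threshold)) return(params$oligomer_threshold)
  s <- if (is.null(params$noise_sigma)) 0 else params$noise_sigma
  max(5 * s, params$min_oligomer_threshold)
}

# depth excess over the estimated carrier level inside one event
event_excess <- function(event) {
  depth <- event$I0_local - event$samples
  n <- length(depth)
  k <- max(1L, as.integer(round(0.05 * n)))
  carrier <- median(depth[k:(n - k + 1L)])
  list(excess = depth - carrier, carrier = carrier, n = n)
}

#' Flag folded-carrier events
#'
#' A carrier that enters the pore doubled over blocks roughly twice the
#' single-carrier current over a contiguous part of the event. An event is
#' flagged when its depth stays above `folded_depth_factor * carrier_depth`
#' for a contiguous run longer than `folded_frac_threshold` of the event.
#' Narrow dumbbell or oligomer spikes also cross that depth but only over
#' short runs, so the run-length criterion separates the two. Flagged
#' events are excluded from barcode analysis.
#'
#' @param event an [event_record()].
#' @param params a [decoder_params()].
#' @return Logical flag.
#' @export
reject_folded <- function(event, params = decoder_params()) {
  stopifnot(inherits(event, "event_record"))
  depth <- event$I0_local - event$samples
  deep <- depth > params$folded_depth_factor * params$carrier_depth
  if (!any(deep)) return(FALSE)
  r <- rle(deep)
  max(r$lengths[r$values]) > params$folded_frac_threshold * length(depth)
}

#' Locate internal spikes within an event
#'
#' Finds excursions below the event's carrier level that exceed the bit
#' threshold for at least `min_spike_width` samples. Candidates are
#' returned with their threshold-crossing bounds (1-based, inclusive,
#' within the event), peak position and peak excess depth; an empty list is
#' a valid result (the all-zero barcode).
#'
#' @inheritParams reject_folded
#' @return List of spike candidates (`a`, `b`, `peak_idx`, `peak_excess`).
#' @export
detect_internal_spikes <- function(event, params = decoder_params()) {
  stopifnot(inherits(event, "event_record"))
  ex <- event_excess(event)
  thr <- bit_thr(params)
  mask <- ex$excess > thr
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- which(r$values & r$lengths >= params$min_spike_width)
  lapply(on, function(i) {
    a <- starts[i]; b <- ends[i]
    pk <- a - 1L + which.max(ex$excess[a:b])
    list(a = a, b = b, peak_idx = pk, peak_excess = ex$excess[pk])
  })
}

#' Detect a bound-oligomer spike in an event
#'
#' Searches the spike candidates for one attributable to a bound oligomer:
#' positioned in an end margin (outside the bit slots) and/or exceeding the
#' oligomer amplitude threshold, according to `use_position` /
#' `use_amplitude`. If several qualify, the largest-area spike wins. The
#' returned call carries the spike bounds `a`, `b` (padded by `spike_pad`
#' so the chord rests on the carrier shoulders) and its equivalent charge
#' deficit from [spike_ecd()].
#'
#' @inheritParams reject_folded
#' @param spikes optional precomputed candidates from
#'   [detect_internal_spikes()].
#' @return A spike call (`a`, `b`, `peak_idx`, `peak_extra_depth`,
#'   `ecd_nA_ms`) or `NULL` when no spike qualifies.
#' @export
detect_oligomer_spike <- function(event, params = decoder_params(),
                                  spikes = NULL) {
  stopifnot(inherits(event, "event_record"))
  if (is.null(spikes)) spikes <- detect_internal_spikes(event, params)
  if (!length(spikes)) return(NULL)
  n <- length(event$samples)
  lo <- params$margin_frac * n
  hi <- (1 - params$margin_frac) * n
  thr <- olig_thr(params)
  ok <- vapply(spikes, function(s) {
    pos_ok <- !params$use_position ||
      (s$peak_idx - 1L < lo || s$peak_idx - 1L >= hi)
    amp_ok <- !params$use_amplitude || s$peak_excess > thr
    pos_ok && amp_ok
  }, TRUE)
  if (!any(ok)) return(NULL)
  cand <- spikes[ok]
  calls <- lapply(cand, function(s) {
    a <- max(1L, s$a - params$spike_pad)
    b <- min(n, s$b + params$spike_pad)
    list(a = a, b = b, peak_idx = s$peak_idx,
         peak_extra_depth = s$peak_excess,
         ecd_nA_ms = spike_ecd(event$samples, a, b, event$sampling_rate))
  })
  calls[[which.max(vapply(calls, `[[`, 1.0, "ecd_nA_ms"))]]
}

#' Call the barcode bits of an event
#'
#' Partitions the central region of the event (between the end margins)
#' into `n_bits` equal temporal slots; a slot reads "1" iff it contains a
#' spike candidate's peak. When an oligomer spike is present its end
#' defines the protein end and hence the reading direction (the barcode is
#' read from the barcode-leading end toward the protein); without one the
#' orientation is `"ambiguous"` and the bits are reported as the canonical
#' (reversal-equivalence) form. Spike peaks that fall in a margin without
#' qualifying as the oligomer spike make the event undecodable — the
#' decoder refuses to guess.
#'
#' @inheritParams detect_oligomer_spike
#' @param spikes spike candidates from [detect_internal_spikes()].
#' @param oligomer the event's oligomer spike call (or `NULL`), used to
#'   exclude it from the bit slots and to resolve orientation.
#' @return An object of class `barcode_read`: `bits` (string, in reading
#'   order), `orientation` (`"forward"`, `"reversed"` or `"ambiguous"`),
#'   `class_id` (canonical code), `bit_confidence` (per-bit, in reading
#'   order), and `undecodable` flag with a `reason`.
#' @export
call_bits <- function(event, spikes, params = decoder_params(),
                      oligomer = NULL) {
  stopifnot(inherits(event, "event_record"))
  ex <- event_excess(event)
  n <- ex$n
  nb <- params$n_bits
  lo <- params$margin_frac * n
  hi <- (1 - params$margin_frac) * n
  if ((hi - lo) / nb < max(4, params$min_spike_width)) {
    return(undecodable_read("event too short for bit slots"))
  }
  bounds <- lo + (0:nb) * (hi - lo) / nb  # 0-based slot boundaries

  if (!is.null(oligomer)) {
    spikes <- Filter(function(s) s$peak_idx != oligomer$peak_idx, spikes)
  }
  peaks0 <- vapply(spikes, `[[`, 1L, "peak_idx") - 1L  # 0-based
  if (length(peaks0) && any(peaks0 < lo | peaks0 >= hi)) {
    return(undecodable_read("spike peak outside the bit slots"))
  }

  thr <- bit_thr(params)
  sig <- max(if (is.null(params$noise_sigma)) 0 else params$noise_sigma, 1e-9)
  bits_raw <- integer(nb)
  conf_raw <- numeric(nb)
  for (j in seq_len(nb)) {
    in_slot <- which(peaks0 >= bounds[j] & peaks0 < bounds[j + 1L])
    slot_idx <- (floor(bounds[j]) + 1L):ceiling(bounds[j + 1L])
    if (length(in_slot)) {
      bits_raw[j] <- 1L
      pk <- max(vapply(spikes[in_slot], `[[`, 1.0, "peak_excess"))
      conf_raw[j] <- pnorm((pk - thr) / sig)
    } else {
      conf_raw[j] <- pnorm((thr - max(ex$excess[slot_idx])) / sig)
    }
  }

  if (!is.null(oligomer)) {
    orientation <- if (oligomer$peak_idx - 1L >= n / 2) "forward" else "reversed"
    bits <- if (orientation == "forward") bits_raw else rev(bits_raw)
    conf <- if (orientation == "forward") conf_raw else rev(conf_raw)
  } else {
    orientation <- "ambiguous"
    fwd <- bits_to_string(bits_raw)
    if (canonical_code(fwd) == fwd) {
      bits <- bits_raw; conf <- conf_raw
    } else {
      bits <- rev(bits_raw); conf <- rev(conf_raw)
    }
  }
  structure(list(bits = bits_to_string(bits), orientation = orientation,
                 class_id = canonical_code(bits), bit_confidence = conf,
                 undecodable = FALSE, reason = NA_character_),
            class = "barcode_read")
}

undecodable_read <- function(reason) {
  structure(list(bits = NA_character_, orientation = "ambiguous",
                 class_id = NA_character_, bit_confidence = numeric(),
                 undecodable = TRUE, reason = reason),
            class = "barcode_read")
}

#' @export
print.barcode_read <- function(x, ...) {
  if (x$undecodable) {
    cat("<barcode_read> undecodable:", x$reason, "\n")
  } else {
    cat(sprintf("<barcode_read> %s (%s, class %s), min conf %.3f\n",
                x$bits, x$orientation, x$class_id,
                if (length(x$bit_confidence)) min(x$bit_confidence) else NA))
  }
  invisible(x)
}

#' Classify detected events into the screening categories
#'
#' Runs the full per-event decoding chain and assigns each event to one of
#' four categories: `barcode_only`, `barcode_plus_protein` (an oligomer
#' spike call is present if and only if the category says so),
#' `rejected_folded` or `rejected_undecodable`. This automates the manual
#' two-category sorting of the read-out (barcode without protein vs
#' barcode with protein), with explicit rejection classes.
#'
#' @param events list of [event_record()]s from [find_events()].
#' @param params a [decoder_params()]; if its `noise_sigma` is `NULL` and
#'   `trace` is supplied, the noise level is estimated from the trace.
#' @param trace optional source [trace_record()] for noise estimation.
#' @return A data frame with one row per event: sample bounds, duration
#'   statistics (including `duration_norm`, ms/nA), `category`, `bits`,
#'   `orientation`, `class_id`, oligomer spike fields (`ecd`, `spike_a`,
#'   `spike_b`, `peak_extra_depth`; `NA` when absent) and a
#'   `bit_confidence` list-column.
#' @examples
#' sim <- simulate_trace(sim_config(n_events = 20, fraction_folded = 0, seed = 3))
#' evs <- find_events(sim$trace)
#' cls <- classify_events(evs, trace = sim$trace)
#' table(cls$category)
#' @export
classify_events <- function(events, params = decoder_params(), trace = NULL) {
  stopifnot(inherits(params, "decoder_params"))
  if (is.null(params$noise_sigma) && !is.null(trace)) {
    params$noise_sigma <- estimate_noise_sigma(trace)
  }
  rows <- lapply(seq_along(events), function(i) {
    ev <- events[[i]]
    base <- list(event = i, x_left = ev$x_left, x_right = ev$x_right,
                 I0_local = ev$I0_local, duration_s = ev$duration_s,
                 duration_ms = ev$duration_s * 1000,
                 duration_norm = ev$duration_norm)
    if (reject_folded(ev, params)) {
      return(c(base, list(category = "rejected_folded", bits = NA_character_,
                          orientation = NA_character_, class_id = NA_character_,
                          ecd = NA_real_, spike_a = NA_integer_,
                          spike_b = NA_integer_, peak_extra_depth = NA_real_,
                          bit_confidence = list(numeric()))))
    }
    spikes <- detect_internal_spikes(ev, params)
    olig <- detect_oligomer_spike(ev, params, spikes)
    read <- call_bits(ev, spikes, params, oligomer = olig)
    if (read$undecodable) {
      return(c(base, list(category = "rejected_undecodable",
                          bits = NA_character_, orientation = NA_character_,
                          class_id = NA_character_, ecd = NA_real_,
                          spike_a = NA_integer_, spike_b = NA_integer_,
                          peak_extra_depth = NA_real_,
                          bit_confidence = list(numeric()))))
    }
    c(base, list(
      category = if (is.null(olig)) "barcode_only" else "barcode_plus_protein",
      bits = read$bits, orientation = read$orientation,
      class_id = read$class_id,
      ecd = if (is.null(olig)) NA_real_ else olig$ecd_nA_ms,
      spike_a = if (is.null(olig)) NA_integer_ else olig$a,
      spike_b = if (is.null(olig)) NA_integer_ else olig$b,
      peak_extra_depth = if (is.null(olig)) NA_real_ else olig$peak_extra_depth,
      bit_confidence = list(read$bit_confidence)))
  })
  df <- do.call(rbind, lapply(rows, function(r) {
    r$bit_confidence <- I(r$bit_confidence)
    as.data.frame(r, stringsAsFactors = FALSE)
  }))
  if (is.null(df)) df <- classified_prototype()
  rownames(df) <- NULL
  df
}

classified_prototype <- function() {
  data.frame(event = integer(), x_left = integer(), x_right = integer(),
             I0_local = numeric(), duration_s = numeric(),
             duration_ms = numeric(), duration_norm = numeric(),
             category = character(), bits = character(),
             orientation = character(), class_id = character(),
             ecd = numeric(), spike_a = integer(), spike_b = integer(),
             peak_extra_depth = numeric(),
             bit_confidence = I(list()), stringsAsFactors = FALSE)
}
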
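# shared fixture builders (everything is generated in code at test time)

# trace with a single rectangular blockade on a flat baseline
rect_trace <- function(drop_nA, duration_s, baseline = 5, fs = 1e6,
                       n_pad = 10000L) {
  n_ev <- as.integer(round(duration_s * fs))
  x <- c(rep(baseline, n_pad), rep(baseline - drop_nA, n_ev),
         rep(baseline, n_pad))
  trace_record(x, fs, list(I0 = baseline))
}

# count local maxima of the depth profile that rise above `thr` over the
# carrier level: an implementation-independent spike counter for rendered
# (noise-free) events
count_peaks <- function(delta, thr) {
  depth <- -delta
  carrier <- median(depth)
  ex <- depth - carrier
  above <- ex > thr
  sum(diff(c(FALSE, above)) == 1L)
}

# noise-free, unfiltered config: fast to assemble, exact to analyze
quiet_config <- function(...) {
  sim_config(noise_sigma = 0, lowpass_cutoff = NA, ...)
}

# map each classified event to the ground-truth event covering its midpoint
# (robust to the occasional merged or missed detection)
match_truth <- function(classified, truth) {
  mids <- (classified$x_left + classified$x_right) / 2
  vapply(mids, function(m) {
    hit <- which(truth$start <= m & m < truth$end)
    if (length(hit) == 1L) hit else NA_integer_
  }, 1L)
}
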
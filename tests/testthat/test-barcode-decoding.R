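test_that("code space arithmetic: 2^5 codes, reversal classes by brute force", {
  codes <- barcode_codes(5)
  expect_length(unique(codes), 32L)
  # independent enumeration of reversal-equivalence classes
  revstr <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
  oracle_classes <- unique(vapply(codes, function(s) min(s, revstr(s)), ""))
  expect_length(oracle_classes, 20L)  # 8 palindromes + 24/2 mirrored pairs
  expect_setequal(barcode_classes(5), oracle_classes)
  expect_gt(code_space_size(56), 1e16)
})

test_that("class ids are invariant under time reversal (exhaustive, n <= 8)", {
  for (nb in 2:8) {
    for (code in barcode_codes(nb)) {
      rev_code <- paste(rev(strsplit(code, "")[[1]]), collapse = "")
      expect_identical(canonical_code(code), canonical_code(rev_code))
    }
  }
})

test_that("folded carriers are flagged and unfolded ones are not", {
  cfg <- quiet_config()
  mk_event <- function(folded) {
    delta <- render_event("11011", folded = folded, folded_frac = 0.45,
                          config = cfg)
    event_record(0, length(delta), cfg$baseline_current + as.numeric(delta),
                 cfg$baseline_current, cfg$sampling_rate)
  }
  p <- decoder_params(carrier_depth = cfg$carrier_blockade_depth)
  expect_false(reject_folded(mk_event(FALSE), p))
  expect_true(reject_folded(mk_event(TRUE), p))
})

test_that("flagged fraction matches the injected folded fraction", {
  cfg <- quiet_config(n_events = 800L, event_rate = 150,
                      fraction_folded = 0.7, seed = 41)
  sim <- simulate_trace(cfg)
  evs <- find_events(sim$trace)
  expect_length(evs, 800L)
  p <- decoder_params(carrier_depth = cfg$carrier_blockade_depth,
                      noise_sigma = 0)
  flagged <- vapply(evs, reject_folded, TRUE, params = p)
  # exact agreement with truth, and binomial 99% band around 0.7
  expect_equal(which(flagged), which(sim$truth$folded))
  ci <- qbinom(c(0.005, 0.995), 800L, 0.7)
  expect_gte(sum(flagged), ci[1])
  expect_lte(sum(flagged), ci[2])
})

test_that("internal spike counts equal the popcount on clean events", {
  cfg <- quiet_config()
  as_event <- function(code) {
    delta <- render_event(code, config = cfg)
    event_record(0, length(delta), cfg$baseline_current + as.numeric(delta),
                 cfg$baseline_current, cfg$sampling_rate)
  }
  p <- decoder_params(noise_sigma = 0)
  expect_length(detect_internal_spikes(as_event("11111"), p), 5L)
  expect_length(detect_internal_spikes(as_event("00000"), p), 0L)
  expect_length(detect_internal_spikes(as_event("10010"), p), 2L)
})

test_that("noisy 11011 events yield candidates at the four 1-bit slots", {
  cfg <- sim_config(n_events = 30, fraction_folded = 0, seed = 51,
                    mixture = data.frame(bits = "11011", fraction_bound = 0,
                                         abundance = 1))
  sim <- simulate_trace(cfg)
  evs <- find_events(sim$trace)
  p <- decoder_params(carrier_depth = cfg$carrier_blockade_depth,
                      noise_sigma = estimate_noise_sigma(sim$trace))
  for (ev in evs) {
    spikes <- detect_internal_spikes(ev, p)
    expect_length(spikes, 4L)
    read <- call_bits(ev, spikes, p)
    expect_identical(read$class_id, canonical_code("11011"))
  }
})

test_that("orientation is resolved by the protein end and bits read exactly", {
  cfg <- quiet_config()
  p <- decoder_params(carrier_depth = cfg$carrier_blockade_depth,
                      noise_sigma = 0)
  for (code in c("11101", "10100", "11011")) {
    for (orient in c("forward", "reversed")) {
      delta <- render_event(code, bound = TRUE, orientation = orient,
                            config = cfg)
      ev <- event_record(0, length(delta),
                         cfg$baseline_current + as.numeric(delta),
                         cfg$baseline_current, cfg$sampling_rate)
      spikes <- detect_internal_spikes(ev, p)
      olig <- detect_oligomer_spike(ev, p, spikes)
      expect_false(is.null(olig))
      read <- call_bits(ev, spikes, p, oligomer = olig)
      expect_identical(read$orientation, orient)
      expect_identical(read$bits, code)
    }
  }
})

test_that("unbound reads are reported as reversal classes, not guesses", {
  cfg <- quiet_config()
  p <- decoder_params(noise_sigma = 0)
  delta <- render_event("11101", orientation = "reversed", config = cfg)
  ev <- event_record(0, length(delta),
                     cfg$baseline_current + as.numeric(delta),
                     cfg$baseline_current, cfg$sampling_rate)
  read <- call_bits(ev, detect_internal_spikes(ev, p), p)
  expect_identical(read$orientation, "ambiguous")
  expect_identical(read$class_id, canonical_code("11101"))
  expect_identical(read$class_id, canonical_code("10111"))
})

test_that("oligomer spikes are absent on unbound events and sound to threshold", {
  cfg <- quiet_config()
  p <- decoder_params(noise_sigma = 0)
  delta <- render_event("11011", bound = FALSE, config = cfg)
  ev <- event_record(0, length(delta),
                     cfg$baseline_current + as.numeric(delta),
                     cfg$baseline_current, cfg$sampling_rate)
  expect_null(detect_oligomer_spike(ev, p))
  # sub-threshold wiggles at the event ends stay undetected
  x <- cfg$baseline_current + as.numeric(delta)
  n <- length(x)
  x[10:20] <- x[10:20] - 0.04
  x[(n - 20):(n - 10)] <- x[(n - 20):(n - 10)] - 0.04
  ev2 <- event_record(0, n, x, cfg$baseline_current, cfg$sampling_rate)
  expect_null(detect_oligomer_spike(ev2, p))
})

test_that("recovered oligomer ECD matches the injected area at high SNR", {
  cfg <- sim_config()
  p <- decoder_params(carrier_depth = cfg$carrier_blockade_depth,
                      noise_sigma = 0.002)
  set.seed(61)
  for (rep in 1:10) {
    d <- runif(1, 0.4, 0.7); w <- runif(1, 1.2e-4, 2.4e-4)
    delta <- render_event("11011", bound = TRUE, config = cfg,
                          oligomer_depth = d, oligomer_width_s = w)
    truth_ecd <- attr(delta, "truth")$ecd_nA_ms
    x <- cfg$baseline_current + as.numeric(delta) +
      rnorm(length(delta), 0, 0.002)
    ev <- event_record(0, length(x), x, cfg$baseline_current,
                       cfg$sampling_rate)
    olig <- detect_oligomer_spike(ev, p)
    expect_false(is.null(olig))
    expect_lt(abs(olig$ecd_nA_ms - truth_ecd) / truth_ecd, 0.05)
  }
})

test_that("bit confidences increase with spike-to-noise ratio", {
  cfg <- quiet_config()
  delta <- render_event("11011", config = cfg)
  ev <- event_record(0, length(delta),
                     cfg$baseline_current + as.numeric(delta),
                     cfg$baseline_current, cfg$sampling_rate)
  confs <- vapply(c(0.08, 0.04, 0.02, 0.01), function(s) {
    p <- decoder_params(noise_sigma = s)
    min(call_bits(ev, detect_internal_spikes(ev, p), p)$bit_confidence)
  }, 1.0)
  expect_true(all(diff(confs) >= 0))
})

test_that("misassignment among the triplex codes stays below 1% at SNR >= 5", {
  cfg <- sim_config(n_events = 1000L, event_rate = 250, fraction_folded = 0,
                    noise_sigma = 30, seed = 71)
  sim <- simulate_trace(cfg)
  evs <- find_events(sim$trace)
  cls <- classify_events(evs, decoder_params(
    carrier_depth = cfg$carrier_blockade_depth), trace = sim$trace)
  dec <- cls$category %in% c("barcode_only", "barcode_plus_protein")
  expect_gt(mean(dec), 0.98)
  truth_class <- vapply(sim$truth$bits, canonical_code, "")
  idx <- match_truth(cls, sim$truth)
  keep <- dec & !is.na(idx)
  err <- cls$class_id[keep] != truth_class[idx[keep]]
  expect_lte(mean(err), 0.01)
})
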
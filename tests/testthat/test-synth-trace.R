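test_that("rendered events carry one spike per 1-bit and none for zeros", {
  cfg <- sim_config()
  thr <- cfg$bit_spike_depth / 2

  ev0 <- render_event("00000", config = cfg)
  expect_equal(count_peaks(ev0, thr), 0)
  # flat bottom at the carrier depth
  depth <- -ev0
  plateau <- depth[depth > 0.99 * cfg$carrier_blockade_depth]
  expect_true(all(abs(plateau - cfg$carrier_blockade_depth) < 1e-12))

  for (code in c("11111", "11011", "10001", "01010")) {
    ev <- render_event(code, config = cfg)
    expect_equal(count_peaks(ev, thr),
                 sum(as.integer(strsplit(code, "")[[1]])), info = code)
  }
})

test_that("render rejects a bit vector of the wrong length", {
  expect_error(render_event("1101", config = sim_config()), "length")
  expect_error(render_event(c(1, 0, 1), config = sim_config()), "length")
})

test_that("injected oligomer spike area matches the numeric-integration oracle", {
  cfg <- sim_config()
  d <- 0.6; w <- 2e-4
  bnd <- render_event("11011", bound = TRUE, config = cfg,
                      oligomer_depth = d, oligomer_width_s = w)
  unb <- render_event("11011", bound = FALSE, config = cfg)
  # oracle: trapezoidal integration of the isolated rendered spike
  spike <- -(as.numeric(bnd) - as.numeric(unb))
  oracle <- (sum(spike) - 0.5 * (spike[1] + spike[length(spike)])) /
    cfg$sampling_rate * 1000
  truth <- attr(bnd, "truth")$ecd_nA_ms
  one_sample <- d / cfg$sampling_rate * 1000
  expect_lt(abs(truth - oracle), one_sample)
  # raised-cosine bump: analytic area d*w/2 (nA.ms), same tolerance scale
  expect_lt(abs(truth - d * w / 2 * 1000), 2 * one_sample)
})

test_that("unbound events record zero true ECD", {
  ev <- render_event("10101", bound = FALSE, config = sim_config())
  expect_identical(attr(ev, "truth")$ecd_nA_ms, 0)
})

test_that("simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_events = 12, seed = 99)
  a <- simulate_trace(cfg)
  b <- simulate_trace(cfg)
  expect_identical(a$trace$samples, b$trace$samples)
  expect_identical(a$truth, b$truth)
})

test_that("zero event rate gives a pure noisy baseline and empty truth", {
  cfg <- sim_config(n_events = 0L, seed = 4)
  sim <- simulate_trace(cfg)
  expect_identical(nrow(sim$truth), 0L)
  expect_equal(length(sim$trace$samples),
               round(cfg$blank_duration * cfg$sampling_rate))
  expect_lt(abs(mean(sim$trace$samples) - cfg$baseline_current), 0.01)
})

test_that("infeasibly high event rates are rejected, not silently truncated", {
  expect_error(simulate_trace(sim_config(event_rate = 1000, n_events = 10)),
               "too high")
})

test_that("truth events are sorted and non-overlapping", {
  sim <- simulate_trace(quiet_config(n_events = 150, event_rate = 300,
                                     seed = 21))
  tr <- sim$truth
  expect_equal(nrow(tr), 150)
  expect_true(all(tr$end > tr$start))
  expect_true(!is.unsorted(tr$start, strictly = TRUE))
  expect_true(all(tr$start[-1] >= tr$end[-nrow(tr)]))
  expect_true(max(tr$end) <= length(sim$trace$samples))
})

test_that("bound counts follow the configured mixture (binomial oracle)", {
  cfg <- quiet_config(n_events = 2000L, event_rate = 400,
                      mixture = data.frame(bits = "11111",
                                           fraction_bound = 0.3,
                                           abundance = 1),
                      fraction_folded = 0, seed = 77)
  sim <- simulate_trace(cfg)
  k <- sum(sim$truth$bound)
  ci <- qbinom(c(0.005, 0.995), 2000L, 0.3)
  expect_gte(k, ci[1])
  expect_lte(k, ci[2])
})

test_that("per-barcode truth fractions converge to mixture probabilities", {
  cfg <- quiet_config(n_events = 1500L, event_rate = 400, seed = 31)
  sim <- simulate_trace(cfg)
  counts <- table(factor(sim$truth$bits, levels = cfg$mixture$bits))
  for (i in seq_len(nrow(cfg$mixture))) {
    ci <- qbinom(c(0.005, 0.995), 1500L, cfg$mixture$abundance[i])
    expect_gte(counts[[i]], ci[1])
    expect_lte(counts[[i]], ci[2])
  }
})

test_that("low-pass preserves DC and matches the analytic response", {
  fs <- 1e6; fc <- 5e4
  flat <- trace_record(rep(5, 5000), fs, list(I0 = 5))
  expect_equal(apply_lowpass(flat, fc)$samples, rep(5, 5000), tolerance = 1e-9)

  # analytic magnitude of the bilinear-designed order-4 Butterworth
  H <- function(f) 1 / sqrt(1 + (tan(pi * f / fs) / tan(pi * fc / fs))^8)
  measure <- function(f) {
    n <- 2e5
    x <- sin(2 * pi * f * (0:(n - 1)) / fs)
    y <- apply_lowpass(trace_record(x + 5, fs, list(I0 = 5)), fc)$samples - 5
    tail_idx <- (n / 2):n
    sqrt(mean(y[tail_idx]^2) / mean(x[tail_idx]^2))
  }
  expect_equal(measure(fc / 100), 1, tolerance = 0.01)       # passband
  expect_equal(measure(fc), 1 / sqrt(2), tolerance = 0.02)   # -3 dB point
  expect_equal(measure(2 * fc), H(2 * fc), tolerance = 0.05) # stopband
})

test_that("cutoffs at or above Nyquist are rejected", {
  tr <- trace_record(rep(5, 100), 1e6, list(I0 = 5))
  expect_error(apply_lowpass(tr, 5e5), "Nyquist|sampling_rate")
  expect_error(sim_config(lowpass_cutoff = 6e5), "lowpass_cutoff")
})

test_that("sim_config enforces its invariants", {
  expect_error(sim_config(carrier_blockade_depth = -1), "carrier")
  expect_error(sim_config(fraction_folded = 1.5), "fraction_folded")
  expect_error(sim_config(n_bits = 0), "n_bits")
  expect_error(sim_config(mixture = data.frame(bits = "111",
                                               fraction_bound = 0.5,
                                               abundance = 1)), "n_bits")
  m <- sim_config(mixture = data.frame(bits = c("11111", "00000"),
                                       fraction_bound = c(0.5, 0.5),
                                       abundance = c(3, 1)))$mixture
  expect_equal(sum(m$abundance), 1)
})
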
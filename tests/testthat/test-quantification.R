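# minimal classified-event table with the columns quantification reads
fake_classified <- function(class_id, n_only, n_spike, ecd = NULL,
                            n_rejected = 0) {
  n <- n_only + n_spike + n_rejected
  data.frame(
    event = seq_len(n),
    category = c(rep("barcode_only", n_only),
                 rep("barcode_plus_protein", n_spike),
                 rep("rejected_folded", n_rejected)),
    class_id = c(rep(class_id, n_only + n_spike),
                 rep(NA_character_, n_rejected)),
    ecd = c(rep(NA_real_, n_only),
            if (is.null(ecd)) rep(0.05, n_spike) else ecd,
            rep(NA_real_, n_rejected)),
    stringsAsFactors = FALSE
  )
}

test_that("fraction bound is a direct count ratio over decoded events", {
  expect_equal(fraction_bound(fake_classified("11111", 50, 0), "11111"), 0)
  expect_equal(fraction_bound(fake_classified("11111", 0, 50), "11111"), 1)
  tab <- fake_classified("11111", 80, 34, n_rejected = 25)
  expect_equal(fraction_bound(tab, "11111"), 34 / 114)
  # absent class is missing, never zero
  expect_identical(fraction_bound(tab, "11011"), NA_real_)
})

test_that("ECD closed forms: rectangle d*w and triangle d*w/2", {
  fs <- 1e6
  d <- 0.4; w_samp <- 500L  # 0.5 ms
  x <- c(rep(5, 100), rep(5 - d, w_samp), rep(5, 100))
  ecd <- spike_ecd(x, 50, length(x) - 50, fs)
  expect_equal(ecd, d * w_samp / fs * 1000, tolerance = d / fs * 1000 / ecd)

  tri <- c(rep(5, 100), 5 - d * seq(0, 1, length.out = 250),
           5 - d * seq(1, 0, length.out = 250), rep(5, 100))
  w_tri <- 500 / fs * 1000  # base width, ms
  ecd_tri <- spike_ecd(tri, 50, length(tri) - 50, fs)
  expect_equal(ecd_tri, d * w_tri / 2, tolerance = 2 * d / fs * 1000 / ecd_tri)

  expect_error(spike_ecd(x, 0, 100, fs), "bounds")
  expect_error(spike_ecd(x, 200, 100, fs), "bounds")
  expect_error(spike_ecd(x, 1, length(x) + 1, fs), "bounds")
})

test_that("estimated ECD scales linearly with injected spike depth", {
  cfg <- quiet_config()
  p <- decoder_params(carrier_depth = cfg$carrier_blockade_depth,
                      noise_sigma = 0)
  ecd_at <- function(d) {
    delta <- render_event("11111", bound = TRUE, config = cfg,
                          oligomer_depth = d, oligomer_width_s = 2e-4)
    ev <- event_record(0, length(delta),
                       cfg$baseline_current + as.numeric(delta),
                       cfg$baseline_current, cfg$sampling_rate)
    detect_oligomer_spike(ev, p)$ecd_nA_ms
  }
  base <- ecd_at(0.4)
  for (c_scale in c(1.5, 2, 3)) {
    expect_equal(ecd_at(0.4 * c_scale) / base, c_scale, tolerance = 0.02)
  }
})

test_that("bootstrap summaries behave like the analytic binomial SE", {
  tab <- fake_classified("11111", 80, 34)
  s <- bootstrap_summary(tab, "11111", n_boot = 2000, seed = 3)
  expect_equal(s$n_total, 114L)
  expect_equal(s$n_with_spike, 34L)
  expect_equal(s$fraction_bound, 34 / 114)
  analytic <- sqrt(s$fraction_bound * (1 - s$fraction_bound) / 114)
  expect_lt(abs(s$fraction_sd - analytic) / analytic, 0.2)
  expect_length(s$ecd_values, 34L)

  all_bound <- bootstrap_summary(fake_classified("11111", 0, 40), "11111",
                                 n_boot = 200, seed = 1)
  expect_identical(all_bound$fraction_sd, 0)

  s2 <- bootstrap_summary(tab, "11111", n_boot = 2000, seed = 3)
  expect_identical(s, s2)  # seeded reproducibility

  expect_error(bootstrap_summary(tab, "11111", n_boot = 50), "n_boot")
  small <- bootstrap_summary(fake_classified("11111", 4, 3), "11111",
                             n_boot = 100, seed = 1)
  expect_true(small$low_confidence)
})

test_that("ranking orders by fraction bound and reports ties", {
  mk <- function(label, n_only, n_spike) {
    s <- bootstrap_summary(fake_classified(label, n_only, n_spike), label,
                           label = label, n_boot = 500, seed = 7)
    s
  }
  # fractions 0.298, 0.419, 0.144: ordering low-to-high = strongest first
  r <- rank_samples(list(mk("11111", 80, 34), mk("10111", 25, 18),
                         mk("11011", 77, 13)))
  expect_identical(r$label, c("11011", "11111", "10111"))
  expect_identical(r$rank, c(1L, 2L, 3L))
  expect_false(any(r$tied))
  sig <- attr(r, "pairwise_significant")
  expect_true(is.matrix(sig) && isSymmetric(sig))
  expect_true(sig["11011", "10111"])  # 0.144 vs 0.419 clearly separated

  r2 <- rank_samples(list(mk("11111", 60, 40), mk("00000", 30, 20)))
  expect_true(all(r2$tied))
  expect_identical(r2$rank, c(1L, 1L))
  expect_error(rank_samples(list(mk("11111", 10, 5))), "at least 2")
})

test_that("per-class summaries are independent of other classes present", {
  a <- fake_classified("11111", 80, 34)
  b <- fake_classified("11011", 77, 13)
  b$event <- b$event + 200
  s_alone <- bootstrap_summary(a, "11111", n_boot = 300, seed = 5)
  s_mixed <- bootstrap_summary(rbind(a, b), "11111", n_boot = 300, seed = 5)
  expect_identical(s_alone, s_mixed)
})
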
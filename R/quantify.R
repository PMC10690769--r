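#' Fraction of carrier events with a bound oligomer
#'
#' The per-barcode screening read-out: among decoded events of a barcode
#' class, the proportion categorized `barcode_plus_protein`,
#' `N_with_spike(x) / N_total(x)` where `x` is the barcode. Rejected events
#' (folded or undecodable) appear in neither numerator nor denominator.
#' With zero decoded events the fraction is undefined and reported as `NA`,
#' never 0.
#'
#' @param classified classified-event data frame from [classify_events()].
#' @param class_id canonical barcode class (see [canonical_code()]).
#' @return Fraction in `[0, 1]`, or `NA_real_` if the class has no decoded
#'   events.
#' @export
fraction_bound <- function(classified, class_id) {
  dec <- classified$category %in% c("barcode_only", "barcode_plus_protein") &
    !is.na(classified$class_id) & classified$class_id == class_id
  if (!any(dec)) return(NA_real_)
  mean(classified$category[dec] == "barcode_plus_protein")
}

#' Equivalent charge deficit of a spike region
#'
#' Integrates the area between the measured current `f(x)` and the chord
#' `g(x)` joining the current at the region bounds `a` and `b`, by the
#' trapezoidal rule at the native sampling rate:
#' `ECD = integral over [a, b] of (g(x) - f(x)) dx`, in nA.ms. A downward
#' spike gives a positive ECD; the ECD is proportional to the excluded
#' volume of the bound particle, so larger values mean larger species.
#'
#' @param samples event current samples (nA).
#' @param a,b region bounds as 1-based inclusive indices into `samples`,
#'   `a < b`.
#' @param sampling_rate samples per second.
#' @return ECD in nA.ms.
#' @examples
#' # rectangular spike of depth 0.4 nA lasting 0.5 ms on a flat shoulder
#' x <- c(rep(5, 100), rep(4.6, 500), rep(5, 100))
#' spike_ecd(x, 50, 650, 1e6)  # ~ 0.4 * 0.5 = 0.2 nA.ms
#' @export
spike_ecd <- function(samples, a, b, sampling_rate) {
  a <- as.integer(a); b <- as.integer(b)
  if (a < 1L || b > length(samples) || a >= b)
    stop("spike bounds must satisfy 1 <= a < b <= length(samples)",
         call. = FALSE)
  if (!all(is.finite(samples[a:b]))) stop("samples must be finite", call. = FALSE)
  f <- samples[a:b]
  g <- seq(samples[a], samples[b], length.out = b - a + 1L)
  y <- g - f
  (sum(y) - 0.5 * (y[1] + y[length(y)])) / sampling_rate * 1000
}

#' Per-sample summary with bootstrap uncertainty
#'
#' Summarizes one barcode class of a classified-event table: decoded event
#' count, bound count, fraction bound, and the ECD distribution of the
#' bound events (median and interquartile range). Uncertainty on the
#' fraction comes from an event-level bootstrap: decoded events are
#' resampled with replacement `n_boot` times and `fraction_sd` is the
#' standard deviation of the fraction across replicates (the 2.5/97.5%
#' quantiles are kept for significance flags in [rank_samples()]).
#'
#' @param classified classified-event data frame from [classify_events()].
#' @param class_id canonical barcode class.
#' @param label sample label (e.g. the compound the barcode tags).
#' @param n_boot number of bootstrap replicates, >= 100.
#' @param seed optional seed for the bootstrap (local; does not disturb the
#'   global RNG).
#' @return An object of class `sample_summary`: `class_id`, `label`,
#'   `n_total`, `n_with_spike`, `fraction_bound`, `fraction_sd`,
#'   `fraction_ci`, `ecd_values`, `ecd_median`, `ecd_iqr`,
#'   `low_confidence` (flagged when fewer than 10 decoded events).
#' @export
bootstrap_summary <- function(classified, class_id, label = class_id,
                              n_boot = 1000L, seed = NULL) {
  if (n_boot < 100L) stop("n_boot must be >= 100", call. = FALSE)
  dec <- classified[classified$category %in%
                      c("barcode_only", "barcode_plus_protein") &
                      !is.na(classified$class_id) &
                      classified$class_id == class_id, , drop = FALSE]
  n <- nrow(dec)
  if (n == 0L) stop("no decoded events for class ", class_id, call. = FALSE)
  bound <- dec$category == "barcode_plus_protein"
  frac <- mean(bound)
  boots <- with_local_seed(seed, {
    vapply(seq_len(n_boot),
           function(i) mean(bound[sample.int(n, n, replace = TRUE)]), 1.0)
  })
  ecds <- dec$ecd[bound]
  structure(list(
    class_id = class_id, label = label,
    n_total = n, n_with_spike = sum(bound),
    fraction_bound = frac,
    fraction_sd = sd(boots),
    fraction_ci = unname(quantile(boots, c(0.025, 0.975))),
    ecd_values = ecds,
    ecd_median = if (length(ecds)) median(ecds) else NA_real_,
    ecd_iqr = if (length(ecds)) unname(diff(quantile(ecds, c(0.25, 0.75))))
              else NA_real_,
    low_confidence = n < 10L
  ), class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("<sample_summary> %s (class %s): %d/%d bound = %.3f +/- %.3f%s\n",
              x$label, x$class_id, x$n_with_spike, x$n_total,
              x$fraction_bound, x$fraction_sd,
              if (x$low_confidence) " [low confidence: < 10 events]" else ""))
  if (length(x$ecd_values))
    cat(sprintf("  ECD median %.3g nA.ms (IQR %.3g, n = %d)\n",
                x$ecd_median, x$ecd_iqr, length(x$ecd_values)))
  invisible(x)
}

#' Summarize every barcode class in a classified-event table
#'
#' @param classified classified-event data frame from [classify_events()].
#' @param labels optional named character vector mapping `class_id` to a
#'   sample label.
#' @param n_boot,seed passed to [bootstrap_summary()] (per-class seeds are
#'   derived from `seed`).
#' @return List of [bootstrap_summary()] objects, one per class with at
#'   least one decoded event.
#' @export
summarize_samples <- function(classified, labels = NULL, n_boot = 1000L,
                              seed = NULL) {
  ids <- sort(unique(classified$class_id[
    classified$category %in% c("barcode_only", "barcode_plus_protein") &
      !is.na(classified$class_id)]))
  out <- lapply(seq_along(ids), function(i) {
    lab <- if (!is.null(labels) && ids[i] %in% names(labels))
      labels[[ids[i]]] else ids[i]
    bootstrap_summary(classified, ids[i], label = lab, n_boot = n_boot,
                      seed = if (is.null(seed)) NULL else seed + i)
  })
  names(out) <- ids
  out
}

#' Rank samples by oligomer fraction bound
#'
#' Orders sample summaries by `fraction_bound` ascending: in an inhibitor
#' screen the lowest bound fraction marks the strongest inhibitor of
#' oligomer production. Equal fractions share a rank (ties are reported,
#' not broken arbitrarily). A pairwise difference is flagged significant
#' when the two bootstrap 95% intervals are disjoint; the logical matrix is
#' attached as attribute `"pairwise_significant"`.
#'
#' @param summaries list of [bootstrap_summary()] objects (>= 2).
#' @return Data frame ordered by `fraction_bound` with columns `label`,
#'   `class_id`, `n_total`, `n_with_spike`, `fraction_bound`,
#'   `fraction_sd`, `ecd_median`, `rank` and `tied`.
#' @examples
#' sim <- simulate_trace(sim_config(n_events = 120, fraction_folded = 0, seed = 9))
#' cls <- classify_events(find_events(sim$trace), trace = sim$trace)
#' rank_samples(summarize_samples(cls, n_boot = 200, seed = 1))
#' @export
rank_samples <- function(summaries) {
  if (length(summaries) < 2L) stop("need at least 2 summaries", call. = FALSE)
  fb <- vapply(summaries, `[[`, 1.0, "fraction_bound")
  df <- data.frame(
    label = vapply(summaries, `[[`, "", "label"),
    class_id = vapply(summaries, `[[`, "", "class_id"),
    n_total = vapply(summaries, `[[`, 1L, "n_total"),
    n_with_spike = vapply(summaries, `[[`, 1L, "n_with_spike"),
    fraction_bound = fb,
    fraction_sd = vapply(summaries, `[[`, 1.0, "fraction_sd"),
    ecd_median = vapply(summaries, `[[`, 1.0, "ecd_median"),
    stringsAsFactors = FALSE
  )
  df$rank <- rank(df$fraction_bound, ties.method = "min")
  df$tied <- duplicated(df$fraction_bound) |
    duplicated(df$fraction_bound, fromLast = TRUE)
  ord <- order(df$fraction_bound, df$label)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  cis <- lapply(summaries, `[[`, "fraction_ci")[ord]
  k <- nrow(df)
  sig <- matrix(FALSE, k, k, dimnames = list(df$label, df$label))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i != j)
      sig[i, j] <- cis[[i]][2] < cis[[j]][1] || cis[[j]][2] < cis[[i]][1]
  }
  attr(df, "pairwise_significant") <- sig
  df
}
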
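#' Specification for a synthetic arterial pressure waveform
#'
#' Describes a pulse train whose beat-to-beat (RR) intervals carry controlled
#' oscillatory power: RR_i = mean_rr_ms + sum of sinusoidal modulations
#' evaluated at the beat time, plus Gaussian jitter.  Each beat is a stylised
#' pulse rising from diastolic to systolic pressure, so per-beat SBP/DBP are
#' known by construction and spectral analysis of the extracted RR series can
#' be validated against the planted component power (a^2/2 for amplitude a).
#'
#' @param mean_rr_ms mean RR interval, ms (rat scale ~150 ms, i.e. ~400 bpm).
#' @param band_components list of \code{list(freq_hz =, amplitude_ms =)}
#'   sinusoidal RR modulations; each amplitude must be < mean_rr_ms / 2 and
#'   each frequency below the beat-rate Nyquist.
#' @param sbp_mmHg,dbp_mmHg systolic and diastolic pressures, mmHg.
#' @param jitter_sd_ms white RR jitter SD, ms.
#' @param duration_s record length, seconds.
#' @param sample_rate_hz waveform sampling rate, Hz.
#' @param seed integer seed.
#' @return an object of class \code{rr_sim_spec}.
#' @export
rr_sim_spec <- function(mean_rr_ms = 150, band_components = list(),
                        sbp_mmHg = 120, dbp_mmHg = 80, jitter_sd_ms = 0,
                        duration_s = 120, sample_rate_hz = 1000, seed = 1L) {
  stop_if_not(mean_rr_ms > 0, "mean_rr_ms must be > 0")
  stop_if_not(dbp_mmHg < sbp_mmHg, "dbp must be below sbp")
  nyq <- 1000 / mean_rr_ms / 2
  for (bc in band_components) {
    stop_if_not(bc$amplitude_ms < mean_rr_ms / 2,
                "component amplitude must be < mean_rr_ms / 2")
    stop_if_not(bc$freq_hz < nyq,
                sprintf("component frequency %.2f Hz is at or above the beat-rate Nyquist (%.2f Hz)",
                        bc$freq_hz, nyq))
  }
  structure(list(mean_rr_ms = mean_rr_ms, band_components = band_components,
                 sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
                 jitter_sd_ms = jitter_sd_ms, duration_s = duration_s,
                 sample_rate_hz = sample_rate_hz, seed = as.integer(seed)),
            class = "rr_sim_spec")
}

# planted RR sequence (ms) and beat onset times (s) for a spec
planted_rr_series <- function(spec) {
  set.seed(spec$seed)
  t <- 0
  rr <- numeric()
  onsets <- numeric()
  while (t < spec$duration_s) {
    r <- spec$mean_rr_ms
    for (bc in spec$band_components)
      r <- r + bc$amplitude_ms * sin(2 * pi * bc$freq_hz * t)
    if (spec$jitter_sd_ms > 0) r <- r + stats::rnorm(1, 0, spec$jitter_sd_ms)
    onsets <- c(onsets, t)
    rr <- c(rr, r)
    t <- t + r / 1000
  }
  list(onset_s = onsets, rr_ms = rr)
}

#' Simulate an arterial pressure waveform with planted RR structure
#'
#' @param spec an \code{\link{rr_sim_spec}}.
#' @param subject_id subject label.
#' @return an object of class \code{pressure_trace} (\code{samples} mmHg,
#'   \code{sample_rate_hz}, \code{subject_id}) with the planted RR series
#'   attached as attribute \code{"planted_rr"}.
#' @export
simulate_pressure_trace <- function(spec, subject_id = "S1") {
  stop_if_not(inherits(spec, "rr_sim_spec"), "spec must be an rr_sim_spec")
  fs <- spec$sample_rate_hz
  plan <- planted_rr_series(spec)
  n_total <- round(spec$duration_s * fs)
  p <- rep(spec$dbp_mmHg, n_total)
  for (i in seq_along(plan$rr_ms)) {
    n <- round(plan$rr_ms[i] / 1000 * fs)
    i0 <- round(plan$onset_s[i] * fs)
    n_up <- max(2L, round(0.3 * n))         # systolic upstroke + peak
    n_dn <- n - n_up                        # diastolic decay
    up <- spec$dbp_mmHg + (spec$sbp_mmHg - spec$dbp_mmHg) *
      sin(pi / 2 * seq_len(n_up) / n_up)
    # exponential decay rescaled to land exactly on DBP at the cycle end
    k <- seq_len(max(0L, n_dn)) / max(1L, n_dn)
    dn <- spec$dbp_mmHg + (spec$sbp_mmHg - spec$dbp_mmHg) *
      (exp(-3 * k) - exp(-3)) / (1 - exp(-3))
    beat <- c(up, dn)
    idx <- i0 + seq_along(beat)
    keep <- idx <= n_total
    p[idx[keep]] <- beat[keep]
  }
  structure(list(samples = p, sample_rate_hz = fs, subject_id = subject_id,
                 planted_rr = plan),
            class = "pressure_trace")
}

#' @export
print.pressure_trace <- function(x, ...) {
  cat(sprintf("<pressure_trace> subject %s: %.1f s at %g Hz, range %.0f-%.0f mmHg\n",
              x$subject_id, length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, min(x$samples), max(x$samples)))
  invisible(x)
}
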
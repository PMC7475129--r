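#' Extract beats from an arterial pressure waveform
#'
#' Cycles are delimited by upward crossings of the waveform's mid-level
#' (midpoint of the trace range); per cycle, SBP is the maximum, DBP the
#' minimum, MAP the time-average of the waveform over the cycle, and RR the
#' interval between successive systolic peaks (HR = 60000 / RR).
#'
#' @param trace a \code{pressure_trace}.
#' @return a \code{beat_table} data frame: \code{onset_s} (systolic peak
#'   time), \code{SBP}, \code{DBP}, \code{MAP} (mmHg), \code{RR} (ms),
#'   \code{HR} (beats/min).
#' @export
detect_beats <- function(trace) {
  stop_if_not(inherits(trace, "pressure_trace"), "trace must be a pressure_trace")
  fs <- trace$sample_rate_hz
  x <- trace$samples
  stop_if_not(length(x) >= 5 * fs, "need at least 5 s of signal")
  if (any(x < 0 | x > 300))
    warning("pressure outside 0-300 mmHg physiological range")
  mid <- (max(x) + min(x)) / 2
  if (max(x) - min(x) < 1)
    stop("no beats detected: flatline pressure signal", call. = FALSE)
  above <- x > mid
  ups <- which(above & !c(FALSE, above[-length(above)]))
  if (length(ups) < 3L)
    stop("no beats detected: fewer than three cycles", call. = FALSE)
  n_cyc <- length(ups) - 1L
  peak_i <- integer(n_cyc)
  sbp <- dbp <- map <- numeric(n_cyc)
  for (i in seq_len(n_cyc)) {
    seg <- ups[i]:(ups[i + 1L] - 1L)
    peak_i[i] <- seg[which.max(x[seg])]
    sbp[i] <- max(x[seg])
    dbp[i] <- min(x[seg])
    map[i] <- mean(x[seg])
  }
  rr <- diff(peak_i) / fs * 1000
  bt <- data.frame(onset_s = (peak_i[-n_cyc] - 1L) / fs,
                   SBP = sbp[-n_cyc], DBP = dbp[-n_cyc], MAP = map[-n_cyc],
                   RR = rr, HR = 60000 / rr)
  class(bt) <- c("beat_table", "data.frame")
  bt
}

#' Time-domain heart-rate-variability metrics
#'
#' SDRR (sample SD of RR), CVRR (SDRR / mean RR), SD rate (SD of
#' instantaneous heart rate), RMSSD (root mean square of successive RR
#' differences), SDSD (population SD of successive differences, so RMSSD and
#' SDSD coincide when the mean successive difference is zero), and Poincare
#' SD1/SD2 via \code{\link{poincare_sd}}.
#'
#' @param rr RR interval series, ms (>= 10 intervals).
#' @return named list of class \code{hrv_time}: \code{mean_RR_ms},
#'   \code{median_RR_ms}, \code{SDRR_ms}, \code{CVRR}, \code{SD_rate_bpm},
#'   \code{RMSSD_ms}, \code{SDSD_ms}, \code{SD1_ms}, \code{SD2_ms}.
#' @export
time_domain_hrv <- function(rr) {
  rr <- rr[is.finite(rr)]
  stop_if_not(length(rr) >= 10, "need at least 10 RR intervals")
  d <- diff(rr)
  sd12 <- poincare_sd(rr)
  structure(list(
    mean_RR_ms = mean(rr), median_RR_ms = stats::median(rr),
    SDRR_ms = stats::sd(rr), CVRR = stats::sd(rr) / mean(rr),
    SD_rate_bpm = stats::sd(60000 / rr),
    RMSSD_ms = sqrt(mean(d^2)), SDSD_ms = sqrt(pop_var(d)),
    SD1_ms = unname(sd12["SD1"]), SD2_ms = unname(sd12["SD2"])),
    class = "hrv_time")
}

# Welch power spectral density: one-sided, Hann window, 50% overlap.
# Returns freq (Hz) and psd (units^2 per Hz); a sinusoid of amplitude a
# integrates to a^2 / 2 across its spectral peak.
welch_psd <- function(x, fs, segment_s = 30, overlap = 0.5) {
  n <- length(x)
  nseg <- min(n, round(segment_s * fs))
  step <- max(1L, round(nseg * (1 - overlap)))
  starts <- seq(1L, n - nseg + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nseg) / (nseg + 1))  # Hann
  u <- sum(w^2)
  nfft <- nseg
  nf <- nfft %/% 2L
  acc <- numeric(nf)
  for (s0 in starts) {
    seg <- x[s0:(s0 + nseg - 1L)]
    seg <- seg - mean(seg)
    X <- stats::fft(seg * w)
    p <- (Mod(X[2:(nf + 1L)])^2) / (fs * u)
    p <- 2 * p                               # one-sided
    if (nfft %% 2L == 0L) p[nf] <- p[nf] / 2  # Nyquist bin not doubled
    acc <- acc + p
  }
  list(freq = (seq_len(nf)) * fs / nfft, psd = acc / length(starts))
}

#' Frequency-domain heart-rate-variability metrics
#'
#' The irregularly sampled RR series (intervals at their beat times) is
#' interpolated to a uniform grid with a cubic spline, linearly detrended and
#' its power spectral density estimated by Welch's method (Hann window, 50%
#' overlap, ~30 s segments, resolving the 0.2 Hz LF edge with >= 6 cycles per
#' segment).  Band powers are the PSD integrated over the rat-conventional
#' bands VLF < 0.2 Hz, LF 0.2-0.75 Hz, HF 0.75-3 Hz (configurable).
#' Normalised units: LF_nu = 100 LF / (LF + HF), HF_nu = 100 HF / (LF + HF).
#'
#' @param rr RR interval series, ms.
#' @param bands named list of \code{c(lo, hi)} Hz for VLF, LF, HF.
#' @param resample_hz uniform resampling rate, Hz.
#' @param segment_s Welch segment length, s.
#' @return named list of class \code{hrv_spectral}: \code{total_power_ms2},
#'   \code{VLF_ms2}, \code{LF_ms2}, \code{HF_ms2}, \code{VLF_pct},
#'   \code{LF_pct}, \code{HF_pct}, \code{LF_nu}, \code{HF_nu},
#'   \code{LF_HF_ratio}, plus the PSD (\code{freq}, \code{psd}).
#' @export
spectral_hrv <- function(rr, bands = list(VLF = c(0, 0.2), LF = c(0.2, 0.75),
                                          HF = c(0.75, 3.0)),
                         resample_hz = 20, segment_s = 30) {
  rr <- rr[is.finite(rr)]
  t_beat <- cumsum(rr) / 1000
  dur <- t_beat[length(t_beat)] - t_beat[1L]
  stop_if_not(dur >= 60, "need at least 60 s of RR data")
  stop_if_not(dur >= 3 / bands$LF[1L],
              "record shorter than 3 cycles of the lowest LF frequency")
  grid <- seq(t_beat[1L], t_beat[length(t_beat)], by = 1 / resample_hz)
  xi <- stats::spline(t_beat, rr, xout = grid, method = "natural")$y
  xi <- stats::lm.fit(cbind(1, seq_along(xi)), xi)$residuals  # linear detrend
  ps <- welch_psd(xi, resample_hz, segment_s = segment_s)
  df <- ps$freq[2L] - ps$freq[1L]
  band_power <- function(b)
    sum(ps$psd[ps$freq > b[1L] & ps$freq <= b[2L]]) * df
  vlf <- band_power(bands$VLF)
  lf <- band_power(bands$LF)
  hf <- band_power(bands$HF)
  total <- sum(ps$psd) * df
  pct <- function(p) if (total > 0) 100 * p / total else 0
  structure(list(
    total_power_ms2 = total, VLF_ms2 = vlf, LF_ms2 = lf, HF_ms2 = hf,
    VLF_pct = pct(vlf), LF_pct = pct(lf), HF_pct = pct(hf),
    LF_nu = if (lf + hf > 0) 100 * lf / (lf + hf) else NA_real_,
    HF_nu = if (lf + hf > 0) 100 * hf / (lf + hf) else NA_real_,
    LF_HF_ratio = if (hf > 0) lf / hf else NA_real_,
    freq = ps$freq, psd = ps$psd),
    class = "hrv_spectral")
}

#' Full heart-rate-variability metric suite for an RR series
#'
#' Combines \code{\link{time_domain_hrv}} and \code{\link{spectral_hrv}}.
#'
#' @param rr RR interval series, ms.
#' @param ... passed to \code{\link{spectral_hrv}}.
#' @return list of class \code{hrv_result} merging both metric sets.
#' @export
hrv_metrics <- function(rr, ...) {
  td <- time_domain_hrv(rr)
  sp <- spectral_hrv(rr, ...)
  structure(c(unclass(td), unclass(sp)), class = "hrv_result")
}

#' @export
print.hrv_result <- function(x, ...) {
  cat("<hrv_result>\n")
  cat(sprintf("  mean RR %.1f ms, SDRR %.2f ms, RMSSD %.2f ms, SD1 %.2f, SD2 %.2f\n",
              x$mean_RR_ms, x$SDRR_ms, x$RMSSD_ms, x$SD1_ms, x$SD2_ms))
  cat(sprintf("  total power %.2f ms^2; VLF %.2f, LF %.2f, HF %.2f ms^2; LF:HF %.3f\n",
              x$total_power_ms2, x$VLF_ms2, x$LF_ms2, x$HF_ms2, x$LF_HF_ratio))
  invisible(x)
}
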
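#' Segment a respiratory flow trace into breaths
#'
#' Breath-by-breath scoring of a plethysmography flow signal.  The trace is
#' smoothed with a short moving average (default 10 ms) and inspiratory onsets
#' are found as downward crossings of a hysteresis band (+/- a small fraction
#' of the epoch peak flow), which makes the segmentation robust to additive
#' noise without shifting timing by more than the smoothing window.
#' Inspiration is the negative-flow phase (plotting convention: downward
#' deflection = inspiration); set \code{invert = TRUE} for the opposite sign
#' convention.
#'
#' Per breath: T_i = duration of the inspiratory phase, T_e = remainder of the
#' inter-onset interval (so any expiratory pause is included in T_e, up to the
#' apnoea criterion applied later), V_T = |integrated flow| over inspiration,
#' V_T/T_i = mean inspiratory flow, inst_f_R = 60 / T_tot.  Cycles with T_i
#' below \code{min_ti_ms} or V_T below \code{min_vt_ml} are dropped as
#' sub-threshold (they are not apnoeas; pauses appear as long T_tot on the
#' preceding breath).
#'
#' @param trace a \code{flow_trace} (see \code{\link{simulate_flow_trace}} or
#'   \code{\link{read_trace}}).
#' @param min_ti_ms minimum inspiratory time, ms.
#' @param min_vt_ml minimum tidal volume, ml.
#' @param smooth_ms moving-average width, ms.
#' @param hysteresis_frac hysteresis half-band as a fraction of peak |flow|.
#' @param invert flip the sign convention (inspiration positive).
#' @return a \code{breath_table}: data frame with columns \code{onset_s},
#'   \code{T_i}, \code{T_e}, \code{T_tot} (ms), \code{V_T} (ml),
#'   \code{V_T_over_Ti} (ml/s), \code{inst_f_R} (breaths/min),
#'   \code{artifact_flag}; subject and body mass carried as attributes.
#' @export
segment_breaths <- function(trace, min_ti_ms = 30, min_vt_ml = 0.05,
                            smooth_ms = 10, hysteresis_frac = 0.02,
                            invert = FALSE) {
  stop_if_not(inherits(trace, "flow_trace"), "trace must be a flow_trace")
  fs <- trace$sample_rate_hz
  x <- trace$samples
  if (invert) x <- -x
  stop_if_not(all(is.finite(x)), "trace contains non-finite samples")
  if (length(x) < fs || max(x) == min(x))
    stop("no breaths detected: empty or constant trace", call. = FALSE)
  xs <- moving_average(x, max(1L, round(smooth_ms / 1000 * fs)))
  h <- hysteresis_frac * max(abs(xs))

  below <- xs < -h
  above <- xs > h
  # candidate inspiratory onsets: first sample of each below-band run
  starts <- which(below & !c(FALSE, below[-length(below)]))
  # depth guard: a genuine inspiration plunges well below the hysteresis band
  # within a few tens of ms, while noise excursions during an apnoeic pause do
  # not; candidates that never reach the dip threshold are discarded
  dip <- 0.15 * max(abs(xs))
  nw <- max(2L, round(0.1 * fs))
  deep <- vapply(starts, function(s)
    min(xs[s:min(length(xs), s + nw)]) <= -dip, logical(1))
  starts <- starts[deep]
  # hysteresis: keep a start only if the signal exceeded +h since the last one
  onsets <- integer()
  last <- 0L
  for (s in starts) {
    if (last == 0L || any(above[(last):(s - 1L)])) {
      # refine the onset back to the raw-signal zero crossing preceding the
      # -h crossing (raw, so noise sign flips stop the walk-back quickly)
      o <- s
      while (o > 1L && x[o - 1L] < 0) o <- o - 1L
      # an exact-zero boundary sample belongs to the new breath
      if (o > 1L && x[o - 1L] == 0) o <- o - 1L
      onsets <- c(onsets, o)
      last <- s
    }
  }
  if (length(onsets) < 2L)
    stop("no breaths detected: fewer than two inspiratory onsets",
         call. = FALSE)

  n_br <- length(onsets) - 1L
  onset_s <- (onsets[-length(onsets)] - 1L) / fs
  T_tot <- diff(onsets) / fs * 1000
  T_i <- numeric(n_br)
  V_T <- numeric(n_br)
  for (i in seq_len(n_br)) {
    # inspiratory phase ends at the first raw-signal zero up-crossing after
    # the (smoothed) trough: the raw crossing is not phase-shifted by the
    # smoothing window
    seg_s <- xs[onsets[i]:(onsets[i + 1L] - 1L)]
    seg <- x[onsets[i]:(onsets[i + 1L] - 1L)]
    imin <- which.min(seg_s)
    up <- which(seg >= 0)
    up <- up[up > imin]
    ti_n <- if (length(up)) up[1L] - 1L else length(seg)
    T_i[i] <- ti_n / fs * 1000
    raw <- x[onsets[i]:(onsets[i] + max(ti_n, 1L) - 1L)]
    V_T[i] <- abs(sum(raw)) / fs
  }
  keep <- T_i >= min_ti_ms & V_T >= min_vt_ml
  bt <- data.frame(onset_s = onset_s, T_i = T_i, T_e = T_tot - T_i,
                   T_tot = T_tot, V_T = V_T,
                   V_T_over_Ti = V_T / (T_i / 1000),
                   inst_f_R = 60000 / T_tot,
                   artifact_flag = FALSE)[keep, , drop = FALSE]
  if (!nrow(bt)) stop("no breaths detected above thresholds", call. = FALSE)
  # a dropped cycle leaves its time inside the preceding breath's interval
  bt$T_tot <- c(diff(bt$onset_s) * 1000, bt$T_tot[nrow(bt)])
  bt$T_e <- bt$T_tot - bt$T_i
  bt$inst_f_R <- 60000 / bt$T_tot
  rownames(bt) <- NULL
  structure(bt, class = c("breath_table", "data.frame"),
            subject_id = trace$subject_id, body_mass_g = trace$body_mass_g,
            sample_rate_hz = fs)
}

#' Flag artifact breaths
#'
#' Breaths overlapping declared artifact windows (animal movement, sniffing),
#' or with implausible timing or volume, are flagged; flagged breaths are
#' excluded from every downstream summary but retained in the table.  The
#' operation is idempotent.
#'
#' @param breaths a \code{breath_table}.
#' @param artifact_windows data frame with \code{onset_s}, \code{duration_s}
#'   (declared artifact intervals), or NULL.
#' @param t_tot_bounds_ms plausible total-breath-time range, ms.
#' @param vt_max_mult flag breaths whose V_T exceeds this multiple of the
#'   epoch median V_T.
#' @return the \code{breath_table} with updated \code{artifact_flag}.
#' @export
reject_artifacts <- function(breaths, artifact_windows = NULL,
                             t_tot_bounds_ms = c(100, 3000),
                             vt_max_mult = 5) {
  stop_if_not(inherits(breaths, "breath_table"), "breaths must be a breath_table")
  stop_if_not(nrow(breaths) > 0, "breath table is empty")
  # rules are recomputed from scratch each call (median over breaths not hit
  # by this call's window/timing rules), so flagging is idempotent
  new_flag <- rep(FALSE, nrow(breaths))
  if (!is.null(artifact_windows) && nrow(artifact_windows)) {
    for (i in seq_len(nrow(artifact_windows))) {
      a0 <- artifact_windows$onset_s[i]
      a1 <- a0 + artifact_windows$duration_s[i]
      b1 <- breaths$onset_s + breaths$T_tot / 1000
      new_flag <- new_flag | (breaths$onset_s < a1 & b1 > a0)
    }
  }
  new_flag <- new_flag |
    breaths$T_tot < t_tot_bounds_ms[1] |
    breaths$T_tot > t_tot_bounds_ms[2]
  med_vt <- stats::median(breaths$V_T[!new_flag])
  new_flag <- new_flag | breaths$V_T > vt_max_mult * med_vt
  breaths$artifact_flag <- breaths$artifact_flag | new_flag
  breaths
}

#' Epoch ventilation summary with per-100 g normalisation
#'
#' Means over the unflagged breaths in a time window; V_T, V_I and V_T/T_i
#' are normalised per 100 g body mass.  Minute ventilation is defined as
#' V_I = f_R x V_T from the window means, so the identity holds exactly in
#' the summary.
#'
#' @param breaths a \code{breath_table}.
#' @param window \code{c(start_s, end_s)}; breaths with onset in
#'   \code{[start_s, end_s)} are included.
#' @param body_mass_g body mass, g; default taken from the table attribute.
#' @return a one-row data frame of class \code{ventilation_summary}:
#'   \code{f_R} (brpm), \code{V_T} (ml/100 g), \code{V_I} (ml/min/100 g),
#'   \code{V_T_over_Ti} (ml/s/100 g), \code{T_i}, \code{T_e} (ms),
#'   \code{n_breaths}, \code{start_s}, \code{end_s}.
#' @export
summarize_epoch <- function(breaths, window = NULL, body_mass_g = NULL) {
  stop_if_not(inherits(breaths, "breath_table"), "breaths must be a breath_table")
  if (is.null(body_mass_g)) body_mass_g <- attr(breaths, "body_mass_g")
  stop_if_not(!is.null(body_mass_g) && body_mass_g > 0,
              "body_mass_g must be supplied and > 0")
  if (is.null(window))
    window <- c(min(breaths$onset_s), max(breaths$onset_s) + 1e-9)
  b <- breaths[!breaths$artifact_flag &
                 breaths$onset_s >= window[1] & breaths$onset_s < window[2], ]
  if (!nrow(b)) stop("no unflagged breaths in window", call. = FALSE)
  norm <- 100 / body_mass_g
  f_R <- mean(b$inst_f_R)
  V_T <- mean(b$V_T) * norm
  out <- data.frame(f_R = f_R, V_T = V_T, V_I = f_R * V_T,
                    V_T_over_Ti = mean(b$V_T_over_Ti) * norm,
                    T_i = mean(b$T_i), T_e = mean(b$T_e),
                    n_breaths = nrow(b),
                    start_s = window[1], end_s = window[2])
  class(out) <- c("ventilation_summary", "data.frame")
  out
}

#' Poincare short- and long-term variability of an interval series
#'
#' SD1/SD2 of the lag-1 Poincare plot (x_n against x_{n+1}) of an interval
#' series (breath-to-breath T_e or T_tot, or cardiac RR):
#' SD1 = sqrt(Var(x_n - x_{n+1}) / 2) measures dispersion perpendicular to
#' the identity line (short-term variability); SD2 = sqrt(Var(x_n + x_{n+1})
#' / 2) measures dispersion along it (long-term variability).  Population
#' (divide-by-n) variance over the lagged pairs, matching the
#' ellipse-fitting definition.
#'
#' @param series numeric interval series (ms).
#' @param lag lag between paired intervals (default 1).
#' @return named numeric vector \code{c(SD1 =, SD2 =)} in the series units.
#' @export
poincare_sd <- function(series, lag = 1L) {
  series <- series[is.finite(series)]
  stop_if_not(length(series) >= 3, "need at least 3 intervals")
  x <- series[seq_len(length(series) - lag)]
  y <- series[(1L + lag):length(series)]
  c(SD1 = sqrt(pop_var(x - y) / 2), SD2 = sqrt(pop_var(x + y) / 2))
}
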
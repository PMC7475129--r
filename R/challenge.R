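#' Metabolic rates from flow-through gas traces
#'
#' Steady-state open-flow respirometry: VO2 = flow x (mean inlet O2 fraction
#' - mean outlet O2 fraction), VCO2 = flow x (mean outlet CO2 fraction -
#' mean inlet CO2 fraction), both normalised per 100 g body mass.  The
#' ventilatory equivalent VE_eq = V_I / VCO2 is dimensionless when both are
#' per 100 g (the mass normalisation cancels).
#'
#' @param gas a \code{gas_traces} object.
#' @param window \code{c(start_s, end_s)} analysis window, or NULL for all.
#' @param body_mass_g body mass, g.
#' @param V_I minute ventilation, ml/min/100 g (optional; needed for VE_eq).
#' @param flow_ml_min chamber flow; default taken from the gas object.
#' @return one-row data frame of class \code{metabolic_result}: \code{VO2},
#'   \code{VCO2} (ml/min/100 g), \code{VE_eq}.
#' @export
compute_metabolism <- function(gas, window = NULL, body_mass_g = 100,
                               V_I = NA_real_, flow_ml_min = NULL) {
  stop_if_not(inherits(gas, "gas_traces"), "gas must be a gas_traces object")
  if (is.null(flow_ml_min)) flow_ml_min <- gas$flow_ml_min
  stop_if_not(flow_ml_min > 0, "flow must be > 0")
  idx <- seq_along(gas$o2_in)
  if (!is.null(window)) {
    t <- (idx - 1L) / gas$sample_rate_hz
    idx <- idx[t >= window[1] & t < window[2]]
    stop_if_not(length(idx) > 0, "window lies outside the gas traces")
  }
  vo2 <- flow_ml_min * (mean(gas$o2_in[idx]) - mean(gas$o2_out[idx]))
  vco2 <- flow_ml_min * (mean(gas$co2_out[idx]) - mean(gas$co2_in[idx]))
  if (vo2 < -1e-9 * flow_ml_min || vco2 < -1e-9 * flow_ml_min)
    stop("negative computed gas exchange; inlet/outlet sensor order suspected",
         call. = FALSE)
  norm <- 100 / body_mass_g
  out <- data.frame(VO2 = vo2 * norm, VCO2 = vco2 * norm,
                    VE_eq = V_I / (vco2 * norm))
  class(out) <- c("metabolic_result", "data.frame")
  out
}

#' Pooled baseline from repeated baseline epochs
#'
#' Resting steady state is determined by averaging the baseline recording
#' epochs: the unweighted mean of per-epoch means (epochs of unequal length
#' contribute equally, deliberately distinct from a pooled mean over all
#' samples).
#'
#' @param series data frame with \code{time_s} and \code{value}.
#' @param epochs data frame with \code{label}, \code{start_s}, \code{end_s};
#'   epochs whose label starts with "baseline" are used.
#' @return the baseline value (scalar).
#' @export
baseline_from_epochs <- function(series, epochs) {
  base <- epochs[grepl("^baseline", epochs$label), , drop = FALSE]
  stop_if_not(nrow(base) >= 1, "no baseline epoch present")
  m <- vapply(seq_len(nrow(base)), function(i) {
    v <- series$value[series$time_s >= base$start_s[i] &
                        series$time_s < base$end_s[i]]
    stop_if_not(length(v) > 0, sprintf("baseline epoch %d is empty", i))
    mean(v)
  }, numeric(1))
  mean(m)
}

#' Challenge response with the study windowing rules
#'
#' Two windowing conventions: in plethysmography mode (\code{mode = "pleth"})
#' the response is the mean over the final 5 min of the challenge epoch
#' (allowing chamber gas mixing) compared against the pooled baseline from
#' \code{\link{baseline_from_epochs}}, reported as absolute change; in
#' anaesthetised mode (\code{mode = "anaesth"}) the response is the mean over
#' the last 1 min of the challenge compared with the 1 min immediately
#' pre-challenge, reported as percent change.
#'
#' @param series data frame with \code{time_s}, \code{value}.
#' @param epochs epoch table (\code{label}, \code{start_s}, \code{end_s}).
#' @param challenge_label label of the challenge epoch to analyse.
#' @param mode "pleth" or "anaesth".
#' @param metric metric name carried into the result.
#' @return one-row data frame of class \code{challenge_response}:
#'   \code{metric}, \code{baseline_value}, \code{response_value},
#'   \code{delta}, \code{pct_change}, \code{pct_undefined} (TRUE when the
#'   baseline is zero).
#' @export
challenge_response <- function(series, epochs, challenge_label,
                               mode = c("pleth", "anaesth"),
                               metric = "metric") {
  mode <- match.arg(mode)
  ch <- epochs[epochs$label == challenge_label, , drop = FALSE]
  stop_if_not(nrow(ch) == 1, "challenge epoch not found (or duplicated)")
  need_s <- if (mode == "pleth") 300 else 60
  stop_if_not(ch$end_s - ch$start_s >= need_s,
              sprintf("challenge epoch shorter than required %d s window", need_s))
  resp_win <- c(ch$end_s - need_s, ch$end_s)
  v <- series$value[series$time_s >= resp_win[1] & series$time_s < resp_win[2]]
  stop_if_not(length(v) > 0, "no samples in response window")
  response <- mean(v)
  if (mode == "pleth") {
    baseline <- baseline_from_epochs(series, epochs)
  } else {
    b <- series$value[series$time_s >= ch$start_s - 60 &
                        series$time_s < ch$start_s]
    stop_if_not(length(b) > 0, "no samples in 1 min pre-challenge baseline")
    baseline <- mean(b)
  }
  delta <- response - baseline
  pct_undef <- baseline == 0
  out <- data.frame(metric = metric, baseline_value = baseline,
                    response_value = response, delta = delta,
                    pct_change = if (pct_undef) NA_real_ else
                      100 * delta / baseline,
                    pct_undefined = pct_undef)
  class(out) <- c("challenge_response", "data.frame")
  out
}

#' Peak response to a drug injection
#'
#' The series is averaged into \code{bin_s}-second bins after the injection;
#' the peak is the bin with the maximum absolute deviation from the 1 min
#' pre-injection baseline within the post-injection search window, so both
#' pressor and depressor responses fall out of the same rule with the correct
#' sign.  Reported as percent change from baseline.
#'
#' @param series data frame with \code{time_s}, \code{value}.
#' @param injection_time_s injection time, s.
#' @param bin_s bin width, s (3 or 5 in the anaesthetised protocols;
#'   per-drug choice).
#' @param baseline_s pre-injection baseline length, s.
#' @param search_s post-injection search window, s.
#' @param metric metric name carried into the result.
#' @return one-row \code{challenge_response} data frame (delta and percent
#'   change of the peak bin).
#' @export
drug_response <- function(series, injection_time_s, bin_s = 3,
                          baseline_s = 60, search_s = 60,
                          metric = "metric") {
  stop_if_not(injection_time_s - baseline_s >= min(series$time_s) - 1e-9,
              "need a full pre-injection baseline inside the record")
  stop_if_not(injection_time_s + search_s <= max(series$time_s) + 1e-9,
              "need the full post-injection search window inside the record")
  b <- series$value[series$time_s >= injection_time_s - baseline_s &
                      series$time_s < injection_time_s]
  stop_if_not(length(b) > 0, "empty baseline window")
  baseline <- mean(b)
  edges <- seq(injection_time_s, injection_time_s + search_s, by = bin_s)
  bins <- vapply(seq_len(length(edges) - 1L), function(i) {
    v <- series$value[series$time_s >= edges[i] & series$time_s < edges[i + 1L]]
    if (length(v)) mean(v) else NA_real_
  }, numeric(1))
  bins <- bins[is.finite(bins)]
  stop_if_not(length(bins) > 0, "no samples in post-injection window")
  peak <- bins[which.max(abs(bins - baseline))]
  delta <- peak - baseline
  out <- data.frame(metric = metric, baseline_value = baseline,
                    response_value = peak, delta = delta,
                    pct_change = if (baseline == 0) NA_real_ else
                      100 * delta / baseline,
                    pct_undefined = baseline == 0)
  class(out) <- c("challenge_response", "data.frame")
  out
}

#' PBG-evoked apnoea and tachypnoea in baseline cycle units
#'
#' The pulmonary chemoreflex (5-HT3 agonist phenylbiguanide) evokes an apnoea
#' followed by tachypnoea.  Both durations are normalised to the mean breath
#' cycle (T_tot) of the 30 s pre-injection baseline.  The apnoea is the first
#' post-injection breath whose inter-onset interval exceeds 3x the baseline
#' mean cycle; the tachypnoea is the subsequent contiguous run (>= 3 breaths)
#' with T_tot below the baseline mean minus 2 SD.
#'
#' @param breaths a \code{breath_table}.
#' @param injection_time_s injection time, s.
#' @param tachypnoea_min_run minimum run length defining tachypnoea.
#' @return list: \code{apnoea_cycles}, \code{tachypnoea_cycles},
#'   \code{found_apnoea} (FALSE when no apnoea occurred; both durations 0).
#' @export
pbg_apnoea_tachypnoea <- function(breaths, injection_time_s,
                                  tachypnoea_min_run = 3L) {
  base <- breaths[!breaths$artifact_flag &
                    breaths$onset_s >= injection_time_s - 30 &
                    breaths$onset_s < injection_time_s, ]
  stop_if_not(nrow(base) >= 3, "need at least 30 s of breaths pre-injection")
  mu <- mean(base$T_tot)
  sdv <- stats::sd(base$T_tot)
  post <- breaths[breaths$onset_s >= injection_time_s, , drop = FALSE]
  apn_i <- which(post$T_tot > 3 * mu)
  if (!length(apn_i))
    return(list(apnoea_cycles = 0, tachypnoea_cycles = 0, found_apnoea = FALSE))
  a <- apn_i[1L]
  apnoea_ms <- post$T_tot[a]
  fast <- post$T_tot < mu - 2 * sdv & !post$artifact_flag
  run_len <- 0L
  run_ms <- 0
  i <- a + 1L
  while (i <= nrow(post) && fast[i]) {
    run_len <- run_len + 1L
    run_ms <- run_ms + post$T_tot[i]
    i <- i + 1L
  }
  if (run_len < tachypnoea_min_run) run_ms <- 0
  list(apnoea_cycles = apnoea_ms / mu,
       tachypnoea_cycles = run_ms / mu,
       found_apnoea = TRUE)
}

#' Pulmonary oedema index
#'
#' Percent wet weight lost on air drying: 100 (wet - dry) / wet.
#'
#' @param wet_mg,dry_mg wet and dry tissue masses (same units).
#' @return oedema index, percent.
#' @export
oedema_index <- function(wet_mg, dry_mg) {
  stop_if_not(all(dry_mg > 0), "dry mass must be > 0")
  stop_if_not(all(dry_mg <= wet_mg), "dry mass exceeds wet mass")
  100 * (wet_mg - dry_mg) / wet_mg
}

#' Internal-standard ratio quantification
#'
#' Analyte concentration from chromatographic peak responses:
#' (analyte peak / internal-standard peak) x internal-standard amount x
#' calibration factor.
#'
#' @param analyte_peak,internal_standard_peak peak responses.
#' @param is_amount amount of internal standard added.
#' @param calibration relative response (calibration) factor.
#' @return concentration in the units of \code{is_amount}.
#' @export
ratio_quantify <- function(analyte_peak, internal_standard_peak, is_amount,
                           calibration = 1) {
  stop_if_not(all(internal_standard_peak > 0),
              "internal standard peak must be > 0")
  (analyte_peak / internal_standard_peak) * is_amount * calibration
}
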
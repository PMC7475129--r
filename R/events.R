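#' Detect sighs (augmented breaths)
#'
#' A sigh is an augmented breath whose tidal volume is at least
#' \code{gain_threshold} times the prevailing average V_T (default: double).
#' The prevailing average is a rolling mean over the surrounding
#' \code{baseline_window_breaths} unflagged breaths, computed in two passes so
#' that large sighs cannot inflate their own threshold: candidate sighs from
#' pass one are excluded from the baseline used in pass two.
#'
#' @param breaths a \code{breath_table}.
#' @param gain_threshold sigh criterion as a multiple of the average V_T.
#' @param baseline_window_breaths rolling-window width (breaths).
#' @param body_mass_g body mass (g) for per-100 g amplitude; defaults to the
#'   table attribute.
#' @return a \code{resp_events} data frame: \code{kind} ("sigh"),
#'   \code{onset_s}, \code{duration_s}, \code{amplitude_ml_per_100g},
#'   \code{breath_index}.
#' @export
detect_sighs <- function(breaths, gain_threshold = 2.0,
                         baseline_window_breaths = 50,
                         body_mass_g = NULL) {
  stop_if_not(inherits(breaths, "breath_table"), "breaths must be a breath_table")
  if (is.null(body_mass_g)) body_mass_g <- attr(breaths, "body_mass_g")
  ok <- !breaths$artifact_flag
  stop_if_not(sum(ok) >= baseline_window_breaths,
              sprintf("need at least %d unflagged breaths", baseline_window_breaths))
  vt <- breaths$V_T
  n <- nrow(breaths)
  half <- max(1L, baseline_window_breaths %/% 2L)
  rolling_base <- function(exclude) {
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - half)
      hi <- min(n, i + half)
      idx <- lo:hi
      idx <- idx[ok[idx] & !exclude[idx] & idx != i]
      if (!length(idx)) return(NA_real_)
      mean(vt[idx])
    }, numeric(1))
  }
  base1 <- rolling_base(exclude = rep(FALSE, n))
  cand <- ok & !is.na(base1) & vt >= gain_threshold * base1
  base2 <- rolling_base(exclude = cand)
  sigh <- ok & !is.na(base2) & vt >= gain_threshold * base2
  idx <- which(sigh)
  ev <- data.frame(kind = rep("sigh", length(idx)),
                   onset_s = breaths$onset_s[idx],
                   duration_s = breaths$T_tot[idx] / 1000,
                   amplitude_ml_per_100g = if (!is.null(body_mass_g))
                     vt[idx] * 100 / body_mass_g else NA_real_,
                   breath_index = idx)
  class(ev) <- c("resp_events", "data.frame")
  ev
}

#' Detect apnoeas (breathing pauses)
#'
#' The apnoea criterion is a pause in breathing greater than
#' \code{miss_multiple} consecutive missed breaths: a breath's inter-onset
#' interval (its T_tot, which includes any expiratory pause) qualifies iff it
#' exceeds \code{(1 + miss_multiple)} times the local mean T_tot, where the
#' local mean is taken over the preceding \code{local_window_breaths}
#' unflagged, non-sigh, non-apnoeic breaths.  With the default
#' \code{miss_multiple = 2} a gap of 3.5 local cycles is an apnoea and a gap
#' of 2.5 cycles is not (strict "greater than two missed breaths").  Breaths
#' before the first full local window are not scored.  Every breath is
#' assessed as a potential gap regardless of its own artifact flag (a pause
#' is by definition a long inter-onset interval, which timing rules may have
#' flagged); flagged breaths are only excluded from the local baseline.
#'
#' @param breaths a \code{breath_table}.
#' @param sighs optional \code{resp_events} from \code{\link{detect_sighs}};
#'   sigh breaths are excluded from local means.
#' @param miss_multiple number of missed breaths defining the criterion.
#' @param local_window_breaths width of the preceding local-mean window.
#' @return a \code{resp_events} data frame: \code{kind} ("apnoea", later
#'   classified), \code{onset_s} (start of the pause: breath onset plus the
#'   local mean cycle), \code{duration_s} (the full inter-onset interval, s),
#'   \code{breath_index}.
#' @export
detect_apnoeas <- function(breaths, sighs = NULL, miss_multiple = 2.0,
                           local_window_breaths = 10) {
  stop_if_not(inherits(breaths, "breath_table"), "breaths must be a breath_table")
  n <- nrow(breaths)
  is_sigh <- rep(FALSE, n)
  if (!is.null(sighs) && nrow(sighs)) is_sigh[sighs$breath_index] <- TRUE
  usable <- !breaths$artifact_flag & !is_sigh
  stop_if_not(sum(usable) >= local_window_breaths,
              sprintf("need at least %d unflagged breaths", local_window_breaths))
  is_apn <- rep(FALSE, n)
  out <- list()
  for (i in seq_len(n)) {
    prev <- which(usable[seq_len(i - 1L)] & !is_apn[seq_len(i - 1L)])
    if (length(prev) < local_window_breaths) next
    win <- utils::tail(prev, local_window_breaths)
    local_ttot <- mean(breaths$T_tot[win])
    if (breaths$T_tot[i] > (1 + miss_multiple) * local_ttot) {
      is_apn[i] <- TRUE
      out[[length(out) + 1L]] <- data.frame(
        kind = "apnoea",
        onset_s = breaths$onset_s[i] + local_ttot / 1000,
        duration_s = breaths$T_tot[i] / 1000,
        breath_index = i)
    }
  }
  ev <- if (length(out)) do.call(rbind, out) else
    data.frame(kind = character(), onset_s = numeric(),
               duration_s = numeric(), breath_index = integer())
  class(ev) <- c("resp_events", "data.frame")
  ev
}

#' Classify apnoeas as post-sigh or spontaneous
#'
#' An apnoea is post-sigh iff the breath opening the pause is within
#' \code{post_sigh_lag_breaths} breaths after (or is itself) a detected sigh;
#' otherwise spontaneous.  Every apnoea receives exactly one class.
#'
#' @param apnoeas \code{resp_events} from \code{\link{detect_apnoeas}}.
#' @param sighs \code{resp_events} from \code{\link{detect_sighs}}.
#' @param post_sigh_lag_breaths maximum breath lag from sigh to pause.
#' @return the apnoea events with \code{kind} set to "post_sigh_apnoea" or
#'   "spontaneous_apnoea".
#' @export
classify_apnoeas <- function(apnoeas, sighs, post_sigh_lag_breaths = 1L) {
  if (!nrow(apnoeas)) return(apnoeas)
  sigh_idx <- if (!is.null(sighs) && nrow(sighs)) sighs$breath_index else integer()
  kind <- vapply(apnoeas$breath_index, function(i) {
    if (length(sigh_idx) &&
        any(sigh_idx <= i & sigh_idx >= i - post_sigh_lag_breaths))
      "post_sigh_apnoea" else "spontaneous_apnoea"
  }, character(1))
  apnoeas$kind <- kind
  apnoeas
}

#' Event rate summary (apnoea index, sigh frequency)
#'
#' Rates are event counts divided by the analysed duration in hours (time
#' lost to artifacts should already be excluded from the duration by the
#' caller).  The apnoea index combines post-sigh and spontaneous apnoeas.
#'
#' @param events a \code{resp_events} table combining classified apnoeas and
#'   sighs.
#' @param analysed_duration_hr analysed recording time, hours (> 0).
#' @return one-row data frame of class \code{event_summary}:
#'   \code{apnoea_index}, \code{post_sigh_rate}, \code{spontaneous_rate},
#'   \code{sigh_frequency} (events/hr), \code{mean_sigh_amplitude}
#'   (ml/100 g), \code{analysed_duration_hr}.
#' @export
event_summary <- function(events, analysed_duration_hr) {
  stop_if_not(analysed_duration_hr > 0, "analysed duration must be > 0")
  n_ps <- sum(events$kind == "post_sigh_apnoea")
  n_sp <- sum(events$kind == "spontaneous_apnoea")
  n_sigh <- sum(events$kind == "sigh")
  amp <- if (n_sigh > 0 && "amplitude_ml_per_100g" %in% names(events))
    mean(events$amplitude_ml_per_100g[events$kind == "sigh"]) else NA_real_
  out <- data.frame(apnoea_index = (n_ps + n_sp) / analysed_duration_hr,
                    post_sigh_rate = n_ps / analysed_duration_hr,
                    spontaneous_rate = n_sp / analysed_duration_hr,
                    sigh_frequency = n_sigh / analysed_duration_hr,
                    mean_sigh_amplitude = amp,
                    analysed_duration_hr = analysed_duration_hr)
  class(out) <- c("event_summary", "data.frame")
  out
}

#' Score sighs and apnoeas and summarise their rates in one call
#'
#' Convenience wrapper chaining \code{\link{detect_sighs}},
#' \code{\link{detect_apnoeas}}, \code{\link{classify_apnoeas}} and
#' \code{\link{event_summary}}.
#'
#' @param breaths a \code{breath_table}.
#' @param analysed_duration_hr analysed time, hours; defaults to the breath
#'   table's time span.
#' @param ... passed on to the detectors.
#' @return list: \code{events} (combined \code{resp_events}),
#'   \code{summary} (an \code{event_summary}).
#' @export
score_events <- function(breaths, analysed_duration_hr = NULL, ...) {
  if (is.null(analysed_duration_hr))
    analysed_duration_hr <-
      (max(breaths$onset_s) - min(breaths$onset_s)) / 3600
  sighs <- detect_sighs(breaths, ...)
  apn <- classify_apnoeas(detect_apnoeas(breaths, sighs = sighs), sighs)
  apn$amplitude_ml_per_100g <- NA_real_
  ev <- rbind(sighs[, c("kind", "onset_s", "duration_s",
                        "amplitude_ml_per_100g", "breath_index")],
              apn[, c("kind", "onset_s", "duration_s",
                      "amplitude_ml_per_100g", "breath_index")])
  ev <- ev[order(ev$onset_s), ]
  rownames(ev) <- NULL
  class(ev) <- c("resp_events", "data.frame")
  list(events = ev, summary = event_summary(ev, analysed_duration_hr))
}
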
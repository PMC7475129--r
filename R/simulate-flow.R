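#' Simulation protocol for a respiratory flow trace
#'
#' Describes a synthetic whole-body plethysmography flow recording: a train of
#' stereotyped breaths at a set respiratory frequency, with optional planted
#' sighs (augmented breaths), apnoeas (zero-flow pauses) and movement
#' artifacts.  Inspiration is a negative deflection, matching the usual
#' plotting convention for rodent plethysmography; expiration is a positive
#' exponential-decay lobe so that inspired and expired volumes balance and the
#' breath is asymmetric (T_i < T_e).
#'
#' @param duration_s recording length in seconds.
#' @param sample_rate_hz sampling rate in Hz (>= 50).
#' @param f_R respiratory frequency, breaths per minute.
#' @param V_T tidal volume per breath, ml.
#' @param ti_fraction inspiratory fraction of the breath (T_i / T_tot).
#' @param noise_sd additive Gaussian noise SD, as a fraction of peak
#'   inspiratory flow.
#' @param sigh_times onsets (s) of planted sighs.
#' @param sigh_gain tidal-volume multiplier for sighs (>= 2 recommended so the
#'   planted events satisfy the "double the average V_T" definition).
#' @param apnoea_specs list of planted apnoeas, each
#'   \code{list(onset_s =, duration_ttot =, post_sigh =)}: the pause opens at
#'   the first scheduled breath at or after \code{onset_s} and the full
#'   inter-onset interval spans \code{duration_ttot} multiples of T_tot; if
#'   \code{post_sigh} the breath opening the pause is itself a sigh.
#' @param artifact_specs list of planted artifacts, each
#'   \code{list(onset_s =, duration_s =)}: high-amplitude broadband noise
#'   replacing the flow signal (movement/sniffing).
#' @param seed integer seed; identical seed and protocol give a bit-identical
#'   trace.
#' @return an object of class \code{sim_protocol}.
#' @export
sim_protocol <- function(duration_s = 600, sample_rate_hz = 200, f_R = 80,
                         V_T = 2.1, ti_fraction = 1 / 3, noise_sd = 0.02,
                         sigh_times = numeric(), sigh_gain = 2.5,
                         apnoea_specs = list(), artifact_specs = list(),
                         seed = 1L) {
  stop_if_not(duration_s > 0, "duration_s must be > 0")
  stop_if_not(sample_rate_hz >= 50, "sample_rate_hz must be >= 50")
  stop_if_not(f_R > 0 && V_T > 0, "f_R and V_T must be > 0")
  stop_if_not(ti_fraction > 0 && ti_fraction < 1,
              "ti_fraction must lie in (0, 1)")
  t_tot <- 60 / f_R
  ev <- data.frame(onset_s = numeric(), end_s = numeric(), kind = character())
  for (s in sigh_times)
    ev <- rbind(ev, data.frame(onset_s = s, end_s = s + t_tot, kind = "sigh"))
  for (a in apnoea_specs) {
    stop_if_not(a$duration_ttot > 1,
                "apnoea duration_ttot must exceed 1 (one breath is not a pause)")
    ev <- rbind(ev, data.frame(onset_s = a$onset_s,
                               end_s = a$onset_s + a$duration_ttot * t_tot,
                               kind = "apnoea"))
  }
  for (a in artifact_specs)
    ev <- rbind(ev, data.frame(onset_s = a$onset_s,
                               end_s = a$onset_s + a$duration_s,
                               kind = "artifact"))
  if (nrow(ev)) {
    stop_if_not(all(ev$onset_s >= 0 & ev$end_s <= duration_s),
                "planted events must lie inside [0, duration_s]")
    ev <- ev[order(ev$onset_s), ]
    if (nrow(ev) > 1L) {
      bad <- which(ev$onset_s[-1L] < ev$end_s[-nrow(ev)])
      if (length(bad))
        stop(sprintf("planted events overlap: %s at %.1f s and %s at %.1f s",
                     ev$kind[bad[1L]], ev$onset_s[bad[1L]],
                     ev$kind[bad[1L] + 1L], ev$onset_s[bad[1L] + 1L]),
             call. = FALSE)
    }
  }
  structure(list(duration_s = duration_s, sample_rate_hz = sample_rate_hz,
                 f_R = f_R, V_T = V_T, ti_fraction = ti_fraction,
                 noise_sd = noise_sd, sigh_times = sort(sigh_times),
                 sigh_gain = sigh_gain, apnoea_specs = apnoea_specs,
                 artifact_specs = artifact_specs, seed = as.integer(seed)),
            class = "sim_protocol")
}

# one breath: negative half-sine inspiration (area V_T) then positive
# exponential-decay expiration (same area); returns flow samples, ml/s
breath_samples <- function(t_tot, ti_fraction, v_t, fs, n = round(t_tot * fs)) {
  t <- (seq_len(n) - 1) / fs
  ti <- ti_fraction * t_tot
  te <- t_tot - ti
  insp <- t < ti
  flow <- numeric(n)
  flow[insp] <- -sin(pi * t[insp] / ti)
  tau <- te / 4
  # decay shifted to land exactly on zero at the cycle end (no discontinuity
  # at the next inspiratory onset)
  flow[!insp] <- exp(-(t[!insp] - ti) / tau) - exp(-te / tau)
  # normalise each lobe so its sampled integral is exactly V_T
  flow[insp] <- flow[insp] * v_t / (sum(-flow[insp]) / fs)
  flow[!insp] <- flow[!insp] * v_t / (sum(flow[!insp]) / fs)
  flow
}

#' Simulate a respiratory flow trace with planted ground truth
#'
#' Builds the breath train described by a \code{\link{sim_protocol}} and
#' returns both the trace and a log of every planted event, the ground truth
#' used by recovery tests of the breath scorer and event detectors.
#'
#' Apnoeas replace scheduled breaths with zero flow (plus the ambient noise
#' floor); no amplitude taper is applied, so the planted pause boundaries are
#' unambiguous.  The event log records, for each apnoea, the onset of the zero
#' flow (end of the breath opening the pause) and the full inter-onset
#' interval as its duration — the same convention \code{\link{detect_apnoeas}}
#' reports.
#'
#' @param spec a \code{\link{sim_protocol}}.
#' @param subject_id subject label stored on the trace.
#' @param body_mass_g body mass in grams stored on the trace (used downstream
#'   for per-100 g normalisation).
#' @return a list with \code{trace} (class \code{flow_trace}: \code{samples}
#'   ml/s, \code{sample_rate_hz}, \code{subject_id}, \code{body_mass_g}) and
#'   \code{log} (data frame \code{kind}, \code{onset_s}, \code{duration_s},
#'   \code{amplitude}).
#' @export
simulate_flow_trace <- function(spec, subject_id = "S1", body_mass_g = 300) {
  stop_if_not(inherits(spec, "sim_protocol"), "spec must be a sim_protocol")
  fs <- spec$sample_rate_hz
  t_tot <- 60 / spec$f_R
  n_total <- round(spec$duration_s * fs)
  normal <- breath_samples(t_tot, spec$ti_fraction, spec$V_T, fs)
  peak <- max(abs(normal))

  apn <- spec$apnoea_specs
  apn_onsets <- vapply(apn, function(a) a$onset_s, numeric(1))
  log <- list()
  flow <- numeric(n_total)
  cursor <- 0          # seconds; next breath onset
  used_sigh <- rep(FALSE, length(spec$sigh_times))
  used_apn <- rep(FALSE, length(apn))
  # segments are placed on the sample grid (boundaries rounded per event, not
  # accumulated) so long traces do not drift off the breath schedule
  place <- function(samples, at_s) {
    i0 <- round(at_s * fs)
    idx <- i0 + seq_along(samples)
    keep <- idx <= n_total
    flow[idx[keep]] <<- samples[keep]
  }
  n_of <- function(at_s, dur_s) round((at_s + dur_s) * fs) - round(at_s * fs)

  while (round((cursor + t_tot) * fs) <= n_total) {
    # does an apnoea open at this breath slot?
    ai <- which(!used_apn & apn_onsets <= cursor + t_tot / 2)
    si <- which(!used_sigh & spec$sigh_times <= cursor + t_tot / 2)
    is_sigh <- length(si) > 0
    if (length(ai)) {
      a <- apn[[ai[1L]]]
      used_apn[ai[1L]] <- TRUE
      post_sigh <- isTRUE(a$post_sigh)
      gap_s <- a$duration_ttot * t_tot
      # the breath opening the pause (a sigh if post_sigh), then zero flow
      vt <- if (post_sigh || is_sigh) spec$V_T * spec$sigh_gain else spec$V_T
      place(breath_samples(t_tot, spec$ti_fraction, vt, fs,
                           n = n_of(cursor, t_tot)), cursor)
      if (post_sigh || is_sigh) {
        log[[length(log) + 1L]] <- data.frame(
          kind = "sigh", onset_s = cursor, duration_s = t_tot, amplitude = vt)
        if (is_sigh) used_sigh[si[1L]] <- TRUE
      }
      log[[length(log) + 1L]] <- data.frame(
        kind = if (post_sigh) "post_sigh_apnoea" else "spontaneous_apnoea",
        onset_s = cursor + t_tot, duration_s = gap_s, amplitude = NA_real_)
      cursor <- cursor + gap_s
    } else if (is_sigh) {
      used_sigh[si[1L]] <- TRUE
      vt <- spec$V_T * spec$sigh_gain
      place(breath_samples(t_tot, spec$ti_fraction, vt, fs,
                           n = n_of(cursor, t_tot)), cursor)
      log[[length(log) + 1L]] <- data.frame(
        kind = "sigh", onset_s = cursor, duration_s = t_tot, amplitude = vt)
      cursor <- cursor + t_tot
    } else {
      place(breath_samples(t_tot, spec$ti_fraction, spec$V_T, fs,
                           n = n_of(cursor, t_tot)), cursor)
      cursor <- cursor + t_tot
    }
  }

  set.seed(spec$seed)
  if (spec$noise_sd > 0)
    flow <- flow + stats::rnorm(n_total, 0, spec$noise_sd * peak)
  for (a in spec$artifact_specs) {
    idx <- seq(round(a$onset_s * fs) + 1L,
               min(n_total, round((a$onset_s + a$duration_s) * fs)))
    flow[idx] <- stats::rnorm(length(idx), 0, 4 * peak)
    log[[length(log) + 1L]] <- data.frame(
      kind = "artifact", onset_s = a$onset_s, duration_s = a$duration_s,
      amplitude = NA_real_)
  }

  log <- if (length(log)) do.call(rbind, log) else
    data.frame(kind = character(), onset_s = numeric(),
               duration_s = numeric(), amplitude = numeric())
  log <- log[order(log$onset_s), , drop = FALSE]
  rownames(log) <- NULL

  trace <- structure(list(samples = flow, sample_rate_hz = fs,
                          subject_id = subject_id, body_mass_g = body_mass_g),
                     class = "flow_trace")
  list(trace = trace, log = log)
}

#' @export
print.flow_trace <- function(x, ...) {
  cat(sprintf("<flow_trace> subject %s: %.1f s at %g Hz (%d samples), body mass %g g\n",
              x$subject_id, length(x$samples) / x$sample_rate_hz,
              x$sample_rate_hz, length(x$samples), x$body_mass_g))
  invisible(x)
}
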
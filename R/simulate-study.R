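#' Design of a simulated 2x2 (exposure x diet) study
#'
#' @param n_per_group subjects per cell (>= 2).
#' @param body_mass_means named vector of group mean body masses (g) for the
#'   four cells; defaults mirror the scale typical of adult male rats after a
#'   chronic-intermittent-hypoxia / prebiotic protocol.
#' @param body_mass_sd body-mass SD (g) within each cell.
#' @param map_offset_cih planted blood-pressure offset (mmHg, added to SBP and
#'   DBP) in CIH-exposed subjects; 0 disables.
#' @param apnoea_rate_cih planted extra apnoeas per flow trace in CIH-exposed
#'   subjects (integer); 0 disables.
#' @param flow_duration_s,pressure_duration_s per-subject trace lengths.
#' @param count_spec a \code{\link{count_sim_spec}} template for the shared
#'   microbiome table (per-group n is overridden by \code{n_per_group}), or
#'   NULL to skip counts.
#' @param seed master seed; subject streams are derived with
#'   \code{\link{child_seed}}.
#' @return object of class \code{study_design}.
#' @export
study_design <- function(n_per_group = 12,
                         body_mass_means = c("Sham.VEH" = 368, "CIH.VEH" = 346,
                                             "Sham.PREB" = 308, "CIH.PREB" = 263),
                         body_mass_sd = 20, map_offset_cih = 0,
                         apnoea_rate_cih = 0L, flow_duration_s = 60,
                         pressure_duration_s = 120, count_spec = NULL,
                         seed = 1L) {
  stop_if_not(n_per_group >= 2, "n_per_group must be >= 2")
  structure(as.list(environment()), class = "study_design")
}

#' Simulate a complete study dataset
#'
#' Bundles per-subject flow, pressure and gas traces, body masses, a shared
#' microbiome count table and the planted ground truth for a 2x2
#' exposure-by-diet design.  With all planted effects at zero the dataset is a
#' global null for the statistical harness.
#'
#' @param design a \code{\link{study_design}}.
#' @return list of class \code{study_dataset}: \code{subjects} (data frame
#'   with subject_id, diet, exposure, body_mass_g, seed), \code{flow}
#'   (per-subject \code{simulate_flow_trace} results), \code{pressure}
#'   (per-subject \code{pressure_trace}s), \code{gas} (per-subject
#'   \code{gas_traces}), \code{counts}/\code{count_truth} (or NULL).
#' @export
simulate_study <- function(design) {
  stop_if_not(inherits(design, "study_design"), "design must be a study_design")
  cells <- expand.grid(diet = c("VEH", "PREB"), exposure = c("Sham", "CIH"),
                       stringsAsFactors = FALSE)
  subj <- list()
  flow <- list()
  pressure <- list()
  gas <- list()
  k <- 0L
  for (ci in seq_len(nrow(cells))) {
    key <- paste(cells$exposure[ci], cells$diet[ci], sep = ".")
    mu <- design$body_mass_means[[key]]
    for (s in seq_len(design$n_per_group)) {
      k <- k + 1L
      sid <- sprintf("%s_%s_%02d", cells$exposure[ci], cells$diet[ci], s)
      cs <- child_seed(design$seed, k)
      set.seed(cs)
      mass <- stats::rnorm(1, mu, design$body_mass_sd)
      is_cih <- cells$exposure[ci] == "CIH"
      apn <- list()
      n_apn <- if (is_cih) design$apnoea_rate_cih else 0L
      if (n_apn > 0) {
        t_tot <- 60 / 80
        onsets <- seq(10, design$flow_duration_s - 10, length.out = n_apn)
        apn <- lapply(onsets, function(o)
          list(onset_s = o, duration_ttot = 3.5, post_sigh = FALSE))
      }
      fspec <- sim_protocol(duration_s = design$flow_duration_s,
                            apnoea_specs = apn, seed = child_seed(cs, 1))
      flow[[sid]] <- simulate_flow_trace(fspec, subject_id = sid,
                                         body_mass_g = mass)
      off <- if (is_cih) design$map_offset_cih else 0
      pspec <- rr_sim_spec(mean_rr_ms = 150,
                           band_components = list(
                             list(freq_hz = 0.4, amplitude_ms = 2),
                             list(freq_hz = 1.5, amplitude_ms = 4)),
                           sbp_mmHg = 120 + off, dbp_mmHg = 80 + off,
                           jitter_sd_ms = 2,
                           duration_s = design$pressure_duration_s,
                           seed = child_seed(cs, 2))
      pressure[[sid]] <- simulate_pressure_trace(pspec, subject_id = sid)
      vo2 <- 2.7 / 100 * mass   # ml/min whole-animal at ~2.7 ml/min/100 g
      vco2 <- 1.9 / 100 * mass
      gas[[sid]] <- simulate_gas_traces(vo2, vco2, flow_ml_min = 3000)
      subj[[k]] <- data.frame(subject_id = sid, diet = cells$diet[ci],
                              exposure = cells$exposure[ci],
                              body_mass_g = mass, seed = cs)
    }
  }
  subjects <- do.call(rbind, subj)
  counts <- NULL
  count_truth <- NULL
  if (!is.null(design$count_spec)) {
    cspec <- design$count_spec
    cspec$n_samples_per_group <- design$n_per_group
    cspec$seed <- child_seed(design$seed, 99991L)
    sim <- simulate_count_table(cspec)
    counts <- sim$counts
    count_truth <- sim$truth
  }
  structure(list(subjects = subjects, flow = flow, pressure = pressure,
                 gas = gas, counts = counts, count_truth = count_truth,
                 design = design),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat(sprintf("<study_dataset> %d subjects (2x2 design, n = %d/cell)\n",
              nrow(x$subjects), x$design$n_per_group))
  print(table(x$subjects$exposure, x$subjects$diet))
  invisible(x)
}
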
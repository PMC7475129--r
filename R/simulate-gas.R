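#' Simulate steady-state flow-through gas fraction traces
#'
#' Produces inlet and outlet O2/CO2 fraction traces consistent with set
#' metabolic rates under the steady-state flow-through equations
#' VO2 = flow * (FiO2_in - FiO2_out) and VCO2 = flow * (FiCO2_out - FiCO2_in),
#' inverted algebraically for the outlet fractions.  The traces are constant
#' (steady state), so \code{\link{compute_metabolism}} recovers the planted
#' rates exactly.
#'
#' @param vo2_ml_min planted oxygen consumption, ml/min (whole animal).
#' @param vco2_ml_min planted CO2 production, ml/min.
#' @param flow_ml_min chamber flow, ml/min.
#' @param inlet_o2,inlet_co2 inlet gas fractions (0-1); room-air defaults.
#' @param duration_s trace length, seconds.
#' @param sample_rate_hz sampling rate, Hz.
#' @return an object of class \code{gas_traces}: constant traces
#'   \code{o2_in}, \code{o2_out}, \code{co2_in}, \code{co2_out} plus
#'   \code{flow_ml_min} and \code{sample_rate_hz}.
#' @export
simulate_gas_traces <- function(vo2_ml_min, vco2_ml_min, flow_ml_min,
                                inlet_o2 = 0.2093, inlet_co2 = 0.0004,
                                duration_s = 60, sample_rate_hz = 1) {
  stop_if_not(flow_ml_min > 0, "flow must be > 0")
  stop_if_not(inlet_o2 > 0 && inlet_o2 < 1 && inlet_co2 >= 0 && inlet_co2 < 1,
              "inlet fractions must lie in (0, 1)")
  o2_out <- inlet_o2 - vo2_ml_min / flow_ml_min
  co2_out <- inlet_co2 + vco2_ml_min / flow_ml_min
  stop_if_not(o2_out > 0 && o2_out < 1 && co2_out > 0 && co2_out < 1,
              "implied outlet fraction outside (0, 1); check flow and rates")
  n <- round(duration_s * sample_rate_hz)
  structure(list(o2_in = rep(inlet_o2, n), o2_out = rep(o2_out, n),
                 co2_in = rep(inlet_co2, n), co2_out = rep(co2_out, n),
                 flow_ml_min = flow_ml_min, sample_rate_hz = sample_rate_hz),
            class = "gas_traces")
}
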
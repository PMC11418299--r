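#' Intermittent-flow respirometry protocol
#'
#' Describes the flush/measure scheduling of an intermittent-flow
#' respirometry run: a first sealed measurement immediately after the
#' exhaustive chase (used for maximum metabolic rate), followed by automated
#' cycles each made of a flushing period that re-oxygenates the chamber and a
#' flush-off (sealed) period during which oxygen uptake is measured.
#'
#' Defaults follow the common field setup: 15-min cycles split into 9 min of
#' flushing and 6 min of measurement, a 5-min first measurement, 1 Hz optode
#' sampling, and roughly 20 h of overnight cycling. The automated cycles are
#' kept above a floor of 80% air saturation.
#'
#' @param cycle_min total cycle length in minutes (flush + measure).
#' @param flush_min flushing duration in minutes.
#' @param measure_min sealed measurement duration in minutes.
#' @param first_measure_min duration of the first post-chase measurement (min).
#' @param sample_rate optode sampling rate (Hz).
#' @param total_hours total trace duration (h), first measurement included.
#' @param o2_saturation dissolved O2 concentration at 100% air saturation
#'   (mg l-1); default 10.78, fresh water at 12 degrees C.
#' @param o2_saturation_floor floor for the automated cycles, in % air
#'   saturation.
#' @param flush_tau_s time constant (s) of the exponential re-approach to
#'   saturation during flushing.
#' @return an object of class `resp_protocol`.
#' @examples
#' respirometry_protocol()
#' respirometry_protocol(cycle_min = 10, flush_min = 6, measure_min = 4)
#' @export
respirometry_protocol <- function(cycle_min = 15, flush_min = 9,
                                  measure_min = 6, first_measure_min = 5,
                                  sample_rate = 1, total_hours = 20,
                                  o2_saturation = 10.78,
                                  o2_saturation_floor = 80,
                                  flush_tau_s = 60) {
  .assert_scalar(cycle_min, "cycle_min", 0, strict_lower = TRUE)
  .assert_scalar(flush_min, "flush_min", 0, strict_lower = TRUE)
  .assert_scalar(measure_min, "measure_min", 0, strict_lower = TRUE)
  .assert_scalar(first_measure_min, "first_measure_min", 0, strict_lower = TRUE)
  .assert_scalar(sample_rate, "sample_rate", 0, strict_lower = TRUE)
  .assert_scalar(total_hours, "total_hours", 0, strict_lower = TRUE)
  .assert_scalar(o2_saturation, "o2_saturation", 0, strict_lower = TRUE)
  .assert_scalar(o2_saturation_floor, "o2_saturation_floor", 0, 100,
                 strict_lower = TRUE, strict_upper = TRUE)
  .assert_scalar(flush_tau_s, "flush_tau_s", 0, strict_lower = TRUE)
  if (abs(flush_min + measure_min - cycle_min) > 1e-9) {
    stop("flush_min + measure_min must equal cycle_min", call. = FALSE)
  }
  structure(
    list(cycle_min = cycle_min, flush_min = flush_min,
         measure_min = measure_min, first_measure_min = first_measure_min,
         sample_rate = sample_rate, total_hours = total_hours,
         o2_saturation = o2_saturation,
         o2_saturation_floor = o2_saturation_floor,
         flush_tau_s = flush_tau_s),
    class = "resp_protocol"
  )
}

#' Ground-truth kinetics for a simulated respirometry trace
#'
#' Encodes what a simulated fish "really" does: its resting rate, its peak
#' rate immediately after exhaustion, and the exponential rate constant with
#' which the post-exercise excess decays back to rest, plus the sensor noise
#' and cycle-level biological variability layered on top.
#'
#' The resting rate is placed, by calibration of the cycle-level jitter, at
#' the 10% quantile of the overnight cycle distribution, so that `rmr_true`
#' is exactly the quantity the low-quantile resting-rate estimator targets
#' (see the methods vignette).
#'
#' @param rmr resting metabolic rate (mg O2 kg-1 min-1).
#' @param mmr maximum metabolic rate (mg O2 kg-1 min-1); must exceed `rmr`.
#' @param k_recovery exponential recovery rate constant (min-1).
#' @param noise_sd additive optode noise (mg l-1) per sample.
#' @param cv_cycle coefficient of variation of the lognormal cycle-level
#'   jitter on the resting component.
#' @param drift linear sensor drift (mg l-1 h-1).
#' @return an object of class `trace_truth`.
#' @examples
#' trace_truth(rmr = 3, mmr = 11, k_recovery = 0.05)
#' @export
trace_truth <- function(rmr, mmr, k_recovery = 0.05, noise_sd = 0.005,
                        cv_cycle = 0.05, drift = 0) {
  .assert_scalar(rmr, "rmr", 0, strict_lower = TRUE)
  .assert_scalar(mmr, "mmr", rmr, strict_lower = TRUE)
  .assert_scalar(k_recovery, "k_recovery", 0, strict_lower = TRUE)
  .assert_scalar(noise_sd, "noise_sd", 0)
  .assert_scalar(cv_cycle, "cv_cycle", 0)
  .assert_scalar(drift, "drift")
  structure(
    list(rmr = rmr, mmr = mmr, k_recovery = k_recovery,
         noise_sd = noise_sd, cv_cycle = cv_cycle, drift = drift),
    class = "trace_truth"
  )
}

#' Ground truth for a simulated acute thermal ramp
#'
#' @param ctmax_true temperature (degrees C) at which the fish loses
#'   equilibrium.
#' @param start_temp ramp starting temperature (degrees C).
#' @param ramp_rate warming rate (degrees C min-1); the study protocol is
#'   0.1 degrees C min-1.
#' @return an object of class `thermal_truth`.
#' @examples
#' thermal_truth(ctmax_true = 26.8)
#' @export
thermal_truth <- function(ctmax_true, start_temp = 12, ramp_rate = 0.1) {
  .assert_scalar(start_temp, "start_temp")
  .assert_scalar(ramp_rate, "ramp_rate", 0, strict_lower = TRUE)
  .assert_scalar(ctmax_true, "ctmax_true", start_temp, strict_lower = TRUE)
  structure(
    list(start_temp = start_temp, ramp_rate = ramp_rate,
         ctmax_true = ctmax_true),
    class = "thermal_truth"
  )
}

#' Per-fish identity, morphology and respirometer geometry
#'
#' Carries the quantities entering the mass-specific uptake equation: the
#' fish mass `m` (kg), the respirometer volume `v_R` (l) and the fish volume
#' `v_F` (l, assuming 1 kg = 1 l so that the effective water volume is
#' `v_R - v_F`).
#'
#' @param fish_id identifier string.
#' @param sex `"female"` or `"male"`.
#' @param treatment `"sham"` or `"ligated"`.
#' @param body_mass_kg body mass in kg.
#' @param fork_length_cm fork length in cm (optional).
#' @param respirometer_volume_l chamber volume in litres; default 54.5.
#' @param fish_volume_l fish volume in litres; defaults to the body mass.
#' @return an object of class `fish_record`.
#' @examples
#' fish_record("f01", "female", "sham", body_mass_kg = 2.5)
#' @export
fish_record <- function(fish_id, sex = c("female", "male"),
                        treatment = c("sham", "ligated"),
                        body_mass_kg, fork_length_cm = NA_real_,
                        respirometer_volume_l = 54.5,
                        fish_volume_l = body_mass_kg) {
  sex <- match.arg(sex)
  treatment <- match.arg(treatment)
  .assert_scalar(body_mass_kg, "body_mass_kg", 0, strict_lower = TRUE)
  .assert_scalar(fish_volume_l, "fish_volume_l", 0, strict_lower = TRUE)
  .assert_scalar(respirometer_volume_l, "respirometer_volume_l", 0,
                 strict_lower = TRUE)
  if (respirometer_volume_l <= fish_volume_l) {
    stop("invalid geometry: fish volume must be smaller than the ",
         "respirometer volume", call. = FALSE)
  }
  structure(
    list(fish_id = as.character(fish_id), sex = sex, treatment = treatment,
         body_mass_kg = body_mass_kg, fork_length_cm = fork_length_cm,
         respirometer_volume_l = respirometer_volume_l,
         fish_volume_l = fish_volume_l),
    class = "fish_record"
  )
}
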
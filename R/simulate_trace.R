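#' Post-exhaustion recovery curve of oxygen uptake
#'
#' Single-exponential decay from the maximum metabolic rate at the moment of
#' exhaustion toward the resting rate:
#' `mdot(t) = rmr + (mmr - rmr) * exp(-k * t)`. The simplest monotone
#' recovery model, chosen because its excess integral has the closed form
#' `(mmr - rmr) / k`, which serves as an analytic oracle for the
#' spline-based EPOC estimator.
#'
#' @param truth a [trace_truth()] object.
#' @param t_min time since exhaustion, in minutes (vectorised, all >= 0).
#' @return oxygen uptake rate(s), mg O2 kg-1 min-1.
#' @examples
#' tr <- trace_truth(rmr = 3, mmr = 11, k_recovery = 0.05)
#' simulate_recovery_mdot(tr, 0)    # = mmr
#' simulate_recovery_mdot(tr, 20)   # 3 + 8 * exp(-1)
#' @export
simulate_recovery_mdot <- function(truth, t_min) {
  stopifnot(inherits(truth, "trace_truth"))
  if (!is.numeric(t_min) || any(!is.finite(t_min)) || any(t_min < 0)) {
    stop("`t_min` must be non-negative", call. = FALSE)
  }
  truth$rmr + (truth$mmr - truth$rmr) * exp(-truth$k_recovery * t_min)
}

# Phase schedule for a protocol: one row per phase with [t0, t1) in seconds
# and the measurement cycle index (NA for flushes).
.phase_schedule <- function(protocol) {
  total_s <- protocol$total_hours * 3600
  first_s <- protocol$first_measure_min * 60
  flush_s <- protocol$flush_min * 60
  meas_s <- protocol$measure_min * 60
  t0 <- 0
  rows <- list(data.frame(phase = "measure", t0 = 0, t1 = min(first_s, total_s),
                          cycle = 1L))
  t0 <- first_s
  cyc <- 1L
  while (t0 < total_s) {
    f1 <- min(t0 + flush_s, total_s)
    rows[[length(rows) + 1L]] <-
      data.frame(phase = "flush", t0 = t0, t1 = f1, cycle = NA_integer_)
    t0 <- f1
    if (t0 >= total_s) break
    m1 <- min(t0 + meas_s, total_s)
    cyc <- cyc + 1L
    rows[[length(rows) + 1L]] <-
      data.frame(phase = "measure", t0 = t0, t1 = m1, cycle = cyc)
    t0 <- m1
  }
  do.call(rbind, rows)
}

#' Simulate a raw intermittent-flow respirometry trace
#'
#' Generates a tidy dissolved-O2 time series for one fish. During each sealed
#' measurement phase the expected O2 concentration declines linearly at the
#' rate implied by the programmed consumption through the mass-specific
#' uptake equation (`mdot * m / (v_R - v_F)`, converted to mg l-1 s-1);
#' flushing phases restore O2 exponentially toward air saturation.
#'
#' Consumption is held constant within each sealed phase at the recovery
#' curve's value at the seal time (the assay resolves a single rate per
#' cycle, so this cycle-level discretisation makes noiseless round-trips
#' exact). The first post-chase measurement is programmed at `truth$mmr`.
#' Subsequent cycles receive multiplicative lognormal jitter on the resting
#' component, calibrated so that its 10% quantile equals 1. The automated
#' cycles are clamped at the protocol's saturation floor (the first
#' measurement is exempt; see the methods vignette).
#'
#' @param fish a [fish_record()].
#' @param truth a [trace_truth()].
#' @param protocol a [respirometry_protocol()].
#' @param seed optional integer seed; a fixed seed yields an identical trace.
#' @return a data frame with columns `time_s`, `o2_mg_per_l`, `phase`
#'   (`"flush"`/`"measure"`), `temp_c`, plus an attribute `cycle_truth`
#'   giving the programmed consumption per measurement cycle.
#' @examples
#' fish <- fish_record("f01", "female", "sham", body_mass_kg = 2.5)
#' tr <- trace_truth(rmr = 3, mmr = 11, noise_sd = 0, cv_cycle = 0)
#' prot <- respirometry_protocol(total_hours = 1)
#' trace <- simulate_trace(fish, tr, prot, seed = 1)
#' head(trace)
#' @export
simulate_trace <- function(fish, truth, protocol = respirometry_protocol(),
                           seed = NULL) {
  stopifnot(inherits(fish, "fish_record"), inherits(truth, "trace_truth"),
            inherits(protocol, "resp_protocol"))
  with_seed(seed, {
    sched <- .phase_schedule(protocol)
    dt <- 1 / protocol$sample_rate
    sat <- protocol$o2_saturation
    floor_conc <- protocol$o2_saturation_floor / 100 * sat
    vol <- fish$respirometer_volume_l - fish$fish_volume_l
    m <- fish$body_mass_kg

    meas <- sched[sched$phase == "measure", , drop = FALSE]
    n_cyc <- nrow(meas)
    sigma <- sqrt(log(1 + truth$cv_cycle^2))
    # q10 of the jitter equals 1: meanlog = qnorm(0.9) * sdlog
    jitter <- exp(stats::rnorm(n_cyc, mean = stats::qnorm(0.9) * sigma,
                               sd = sigma))
    excess <- (truth$mmr - truth$rmr) * exp(-truth$k_recovery * meas$t0 / 60)
    consumption <- truth$rmr * jitter + excess

    time_list <- vector("list", nrow(sched))
    o2_list <- vector("list", nrow(sched))
    o2_prev <- sat  # chamber starts at saturation when sealed after the chase
    ci <- 0L
    for (i in seq_len(nrow(sched))) {
      tt <- seq(sched$t0[i], sched$t1[i] - dt / 2, by = dt)
      if (sched$phase[i] == "measure") {
        ci <- ci + 1L
        rate <- consumption[ci] * m / vol / 60  # mg l-1 s-1
        o2 <- o2_prev - rate * (tt - sched$t0[i])
        if (ci > 1L) o2 <- pmax(o2, floor_conc)
      } else {
        o2 <- sat - (sat - o2_prev) * exp(-(tt - sched$t0[i]) /
                                            protocol$flush_tau_s)
      }
      o2_prev <- if (length(o2)) o2[length(o2)] else o2_prev
      time_list[[i]] <- tt
      o2_list[[i]] <- o2
    }
    time_s <- unlist(time_list, use.names = FALSE)
    o2 <- unlist(o2_list, use.names = FALSE)
    phase <- rep(sched$phase, vapply(time_list, length, 1L))
    o2 <- o2 + truth$drift * time_s / 3600
    if (truth$noise_sd > 0) {
      o2 <- o2 + stats::rnorm(length(o2), sd = truth$noise_sd)
    }
    out <- data.frame(time_s = time_s, o2_mg_per_l = o2, phase = phase,
                      temp_c = 12, stringsAsFactors = FALSE)
    attr(out, "cycle_truth") <- data.frame(
      cycle_index = seq_len(n_cyc), t_start_s = meas$t0, t_end_s = meas$t1,
      consumption = consumption
    )
    out
  })
}

#' Simulate an acute thermal ramping trial
#'
#' Warms the water at a constant rate from the starting temperature until the
#' fish loses equilibrium at its true critical thermal maximum; the
#' loss-of-equilibrium time is the exact linear inversion
#' `t_LOE = (ctmax_true - start_temp) / ramp_rate`.
#'
#' @param truth a [thermal_truth()].
#' @param log_resolution_min spacing of the returned temperature log (min).
#' @return a list with `start_temp`, `ramp_rate`, `t_loe_min` and a
#'   `temperature_log` data frame (`time_min`, `temp_c`).
#' @examples
#' simulate_thermal_trial(thermal_truth(26.8))$t_loe_min  # 148
#' @export
simulate_thermal_trial <- function(truth, log_resolution_min = 1) {
  stopifnot(inherits(truth, "thermal_truth"))
  t_loe <- (truth$ctmax_true - truth$start_temp) / truth$ramp_rate
  tt <- unique(c(seq(0, t_loe, by = log_resolution_min), t_loe))
  list(start_temp = truth$start_temp, ramp_rate = truth$ramp_rate,
       t_loe_min = t_loe,
       temperature_log = data.frame(time_min = tt,
                                    temp_c = truth$start_temp +
                                      truth$ramp_rate * tt))
}

#' Simulate a sealed-chamber venous PO2 reading
#'
#' A blood aliquot injected into a sealed optode chamber equilibrates
#' exponentially toward the blood's oxygen tension; the reading is taken once
#' the signal plateaus at about 3 minutes.
#'
#' @param plateau_torr true venous PO2 (Torr).
#' @param tau_s equilibration time constant (s).
#' @param duration_s record length (s).
#' @param start_torr initial chamber reading (Torr).
#' @param noise_sd additive sensor noise (Torr).
#' @param sample_rate sampling rate (Hz).
#' @param seed optional integer seed.
#' @return data frame with columns `time_s`, `po2_torr`.
#' @export
simulate_pvo2_series <- function(plateau_torr, tau_s = 30, duration_s = 180,
                                 start_torr = max(0, plateau_torr - 20),
                                 noise_sd = 0.3, sample_rate = 1,
                                 seed = NULL) {
  .assert_scalar(plateau_torr, "plateau_torr", 0)
  .assert_scalar(tau_s, "tau_s", 0, strict_lower = TRUE)
  .assert_scalar(duration_s, "duration_s", 0, strict_lower = TRUE)
  with_seed(seed, {
    tt <- seq(0, duration_s, by = 1 / sample_rate)
    po2 <- plateau_torr + (start_torr - plateau_torr) * exp(-tt / tau_s)
    if (noise_sd > 0) po2 <- po2 + stats::rnorm(length(tt), sd = noise_sd)
    data.frame(time_s = tt, po2_torr = po2)
  })
}
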
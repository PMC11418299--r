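test_that("recovery curve follows the exponential decay and its limits", {
  tr <- trace_truth(rmr = 3, mmr = 11, k_recovery = 0.05)
  expect_equal(simulate_recovery_mdot(tr, 0), 11)
  expect_equal(simulate_recovery_mdot(tr, 1e9), 3, tolerance = 1e-12)
  expect_equal(simulate_recovery_mdot(tr, 20), 3 + 8 * exp(-1),
               tolerance = 1e-12)
  t <- seq(0, 500, by = 5)
  expect_true(all(diff(simulate_recovery_mdot(tr, t)) <= 0))
  expect_error(simulate_recovery_mdot(tr, -1), "non-negative")
})

test_that("truth and protocol constructors enforce their invariants", {
  expect_error(trace_truth(rmr = 3, mmr = 2), "mmr")
  expect_error(trace_truth(rmr = -1, mmr = 2), "rmr")
  expect_error(trace_truth(rmr = 3, mmr = 11, noise_sd = -0.1), "noise_sd")
  expect_error(respirometry_protocol(flush_min = 8), "must equal")
  expect_error(thermal_truth(ctmax_true = 11, start_temp = 12),
               "ctmax_true")
  expect_error(fish_record("x", "female", "sham", body_mass_kg = 2.5,
                           respirometer_volume_l = 2, fish_volume_l = 2.5),
               "geometry")
})

test_that("noiseless traces invert exactly to the programmed consumption", {
  fish <- std_fish()
  prot <- short_protocol()
  trc <- simulate_trace(fish, noiseless_truth(), prot, seed = 1)
  truth <- attr(trc, "cycle_truth")
  cyc <- process_trace(trc, fish)
  expect_equal(nrow(cyc), nrow(truth))
  expect_equal(cyc$mdot, truth$consumption, tolerance = 1e-10)
  expect_true(all(cyc$r2 > 0.999))
})

test_that("a fixed seed reproduces a trace byte for byte", {
  fish <- std_fish()
  prot <- short_protocol(1)
  tr <- trace_truth(rmr = 3, mmr = 11)
  a <- simulate_trace(fish, tr, prot, seed = 99)
  b <- simulate_trace(fish, tr, prot, seed = 99)
  expect_identical(serialize(a, NULL), serialize(b, NULL))
  c <- simulate_trace(fish, tr, prot, seed = 100)
  expect_false(identical(a$o2_mg_per_l, c$o2_mg_per_l))
})

test_that("first-cycle decline is steeper than every overnight cycle", {
  fish <- std_fish()
  trc <- simulate_trace(fish, trace_truth(rmr = 3, mmr = 11),
                        short_protocol(6), seed = 3)
  cyc <- process_trace(trc, fish)
  expect_true(all(cyc$slope[1] < cyc$slope[-1]))
})

test_that("phase bookkeeping is contiguous and alternating", {
  prot <- respirometry_protocol(total_hours = 3)
  trc <- simulate_trace(std_fish(), noiseless_truth(), prot, seed = 1)
  expect_true(all(diff(trc$time_s) > 0))
  r <- rle(trc$phase)
  expect_true(all(r$values == rep(c("measure", "flush"),
                                  length.out = length(r$values))))
  # every complete flush and measure run has its scheduled span
  # (the final run may be truncated by the total duration)
  flush_runs <- r$lengths[r$values == "flush"]
  meas_runs <- r$lengths[r$values == "measure"][-1L]  # first is the chase
  drop_last <- function(x) x[-length(x)]
  expect_true(all(drop_last(flush_runs) == prot$flush_min * 60 *
                    prot$sample_rate))
  expect_true(all(drop_last(meas_runs) == prot$measure_min * 60 *
                    prot$sample_rate))
})

test_that("slope scatter across seeds grows with sensor noise", {
  fish <- std_fish()
  prot <- respirometry_protocol(total_hours = 0.5)
  sd_of_first_slope <- function(noise) {
    slopes <- vapply(1:12, function(s) {
      tr <- trace_truth(rmr = 3, mmr = 11, noise_sd = noise, cv_cycle = 0)
      process_trace(simulate_trace(fish, tr, prot, seed = s), fish)$slope[1]
    }, 0)
    sd(slopes)
  }
  sds <- vapply(c(0, 0.01, 0.05), sd_of_first_slope, 0)
  expect_true(all(diff(sds) > 0))
})

test_that("thermal trials invert the ramp exactly", {
  tr <- simulate_thermal_trial(thermal_truth(26.8, start_temp = 12,
                                             ramp_rate = 0.1))
  expect_equal(tr$t_loe_min, 148)
  expect_equal(simulate_thermal_trial(thermal_truth(12.1))$t_loe_min, 1)
  # round trip through the CTmax calculator is the identity
  for (ct in c(24.3, 25.8, 26.9)) {
    trial <- simulate_thermal_trial(thermal_truth(ct))
    expect_equal(ctmax_from_ramp(trial$start_temp, trial$ramp_rate,
                                 trial$t_loe_min)$ctmax, ct)
  }
})

test_that("degenerate cohorts reproduce their cell means exactly", {
  cells <- default_cells()
  cells$n <- 1L
  cfg <- cohort_config(cells = cells,
                       protocol = respirometry_protocol(total_hours = 0.25),
                       rmr_between_sd = 0, mmr_between_sd = 0,
                       noise_sd = 0, cv_cycle = 0, seed = 5)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$fish), 4)
  expect_equal(coh$fish$rmr_true, cells$rmr_mean)
  expect_equal(coh$fish$mmr_true, cells$mmr_mean)
})

test_that("cohorts are seed-deterministic and differ across seeds", {
  cells <- transform(default_cells(), n = 2L)
  prot <- respirometry_protocol(total_hours = 0.25)
  a <- simulate_cohort(cohort_config(cells = cells, protocol = prot,
                                     seed = 1))
  b <- simulate_cohort(cohort_config(cells = cells, protocol = prot,
                                     seed = 1))
  c <- simulate_cohort(cohort_config(cells = cells, protocol = prot,
                                     seed = 2))
  expect_identical(serialize(a$fish, NULL), serialize(b$fish, NULL))
  expect_identical(serialize(a$traces, NULL), serialize(b$traces, NULL))
  expect_false(identical(a$fish$rmr_true, c$fish$rmr_true))
  expect_error(
    cohort_config(cells = transform(default_cells(), n = 0L)),
    "empty cell"
  )
})

test_that("every fish carries the full complement of endpoints", {
  cells <- transform(default_cells(), n = 1L)
  cfg <- cohort_config(cells = cells,
                       protocol = respirometry_protocol(total_hours = 0.25),
                       seed = 11)
  coh <- simulate_cohort(cfg)
  expect_length(coh$traces, nrow(coh$fish))
  expect_equal(sort(unique(coh$blood$time_point)),
               sort(c("0", "15", "60", "rest", "ctmax")))
  per_fish <- table(coh$blood$fish_id)
  expect_true(all(per_fish == per_fish[1]))
  expect_equal(nrow(coh$morpho), nrow(coh$fish))
  expect_true(all(coh$thermal$ctmax_true > coh$thermal$start_temp))
})
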
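test_that("sliding-window MMR matches brute-force enumeration", {
  fish <- std_fish()
  set.seed(101)
  for (r in 1:25) {
    sl <- random_mmr_slice()
    fast <- estimate_mmr(sl, fish)
    oracle <- brute_force_mmr(sl, fish)
    expect_equal(fast$determined, oracle$determined)
    if (fast$determined) {
      expect_equal(fast$window_start_s, oracle$window_start_s)
      expect_equal(fast$window_end_s, oracle$window_end_s)
      expect_equal(fast$slope, oracle$slope, tolerance = 1e-9)
    }
  }
})

test_that("a perfectly linear slice ties to the earliest minimum window", {
  fish <- std_fish()
  sl <- data.frame(time_s = 0:299, o2_mg_per_l = 10 - 0.004 * (0:299))
  res <- estimate_mmr(sl, fish)
  expect_equal(res$window_start_s, 0)
  expect_equal(res$window_end_s, 180)
  expect_equal(res$mmr, mdot_from_slope(-0.004, fish))
  expect_equal(res$r2, 1)
})

test_that("a steep embedded segment is found and noise is rejected", {
  fish <- std_fish()
  # piecewise: gentle decline, then a steep 200-s segment, then gentle
  t <- 0:599
  rate <- ifelse(t >= 200 & t < 400, 0.006, 0.001)
  y <- 10 - cumsum(rate)
  res <- estimate_mmr(data.frame(time_s = t, o2_mg_per_l = y), fish)
  expect_true(res$determined)
  expect_gte(res$window_start_s, 198)
  expect_lte(res$window_end_s, 402)
  # pure white noise: no admissible window reaches r2 > 0.95
  set.seed(33)
  for (r in 1:5) {
    noise <- data.frame(time_s = 0:249,
                        o2_mg_per_l = rnorm(250, 10, 0.01))
    expect_false(estimate_mmr(noise, fish)$determined)
  }
  expect_error(estimate_mmr(data.frame(time_s = 0:100,
                                       o2_mg_per_l = rnorm(101, 10)),
                            fish), "minimum window")
})

test_that("quantile RMR follows the linear-interpolation convention", {
  expect_equal(estimate_rmr(rep(4.2, 60))$rmr, 4.2)
  expect_equal(estimate_rmr(1:100)$rmr, 10.9)
  r <- estimate_rmr(rnorm(59, 3), min_cycles = 60)
  expect_false(r$determined)
  expect_equal(r$flag, "insufficient_cycles")
  expect_true(is.na(r$rmr))
  e <- estimate_rmr(numeric(0))
  expect_equal(e$flag, "no_cycles")
})

test_that("RMR is translation-equivariant and monotone", {
  set.seed(5)
  x <- rlnorm(80, log(3), 0.05)
  base <- estimate_rmr(x)$rmr
  expect_equal(estimate_rmr(x + 1.7)$rmr, base + 1.7, tolerance = 1e-12)
  for (r in 1:10) {
    y <- x
    i <- sample(80, 5)
    y[i] <- y[i] + runif(5, 0, 2)
    expect_gte(estimate_rmr(y)$rmr, base - 1e-12)
  }
})

test_that("aerobic scope identities and homogeneity hold", {
  sc <- aerobic_scope(11.94, 2.96)
  expect_equal(sc$aas, 8.98)
  expect_equal(sc$fas, 11.94 / 2.96)
  expect_equal(aerobic_scope(5, 5), list(aas = 0, fas = 1))
  sc2 <- aerobic_scope(2 * 11.94, 2 * 2.96)
  expect_equal(sc2$aas, 2 * sc$aas)
  expect_equal(sc2$fas, sc$fas)
  expect_error(aerobic_scope(10, 0), "positive")
})

test_that("spline EPOC matches the closed-form exponential integral", {
  # truth: excess integral = (mmr - rmr) / k = 8 / 0.05 = 160 mg O2 kg-1
  t10 <- seq(0, 1190, by = 10)
  ep10 <- estimate_epoc(t10, 3 + 8 * exp(-0.05 * t10), rmr = 3)
  expect_lt(abs(ep10$epoc - 160) / 160, 0.02)
  t1 <- seq(0, 1190, by = 1)
  ep1 <- estimate_epoc(t1, 3 + 8 * exp(-0.05 * t1), rmr = 3)
  expect_lt(abs(ep1$epoc - 160) / 160, 0.005)
})

test_that("EPOC handles flat, rectangular and censored recoveries", {
  t <- seq(0, 120, by = 10)
  flat <- estimate_epoc(t, rep(3, length(t)), rmr = 3)
  expect_equal(flat$epoc, 0)
  expect_equal(flat$epoc_duration_min, 0)
  # rectangular excess of height 5 held for 15 min, sampled densely
  tr <- c(0:15, seq(16, 60, by = 1))
  md <- ifelse(tr <= 15, 8, 3)
  rect <- estimate_epoc(tr, md, rmr = 3)
  expect_lt(abs(rect$epoc - 5 * 15) / (5 * 15), 0.05)
  # never reaching the resting rate censors at the record length
  tc <- seq(0, 100, by = 10)
  cen <- estimate_epoc(tc, 5 + 3 * exp(-0.01 * tc), rmr = 3)
  expect_true(cen$censored)
  expect_equal(cen$epoc_duration_min, 100)
  expect_gt(cen$epoc, 0)
})

test_that("EPOC is non-negative and additive over disjoint episodes", {
  t <- seq(0, 200, by = 5)
  bump <- function(c0, w) 4 * exp(-((t - c0) / w)^2)
  two <- 3 + bump(30, 8) + bump(150, 8)
  both <- estimate_epoc(t, two, rmr = 3)
  first_half <- estimate_epoc(t[t <= 100], two[t <= 100], rmr = 3)
  second_half <- estimate_epoc(t[t >= 100] - 100, two[t >= 100], rmr = 3)
  expect_gte(both$epoc, 0)
  expect_equal(both$epoc, first_half$epoc + second_half$epoc,
               tolerance = 0.05)
})

test_that("noiseless end-to-end recovery of rmr and mmr is discretisation-exact", {
  fish <- std_fish()
  prot <- respirometry_protocol(total_hours = 20)
  for (pars in list(c(3, 11), c(2.96, 11.94))) {
    trc <- simulate_trace(fish, noiseless_truth(pars[1], pars[2]), prot,
                          seed = 8)
    ms <- metabolic_summary(trc, fish, protocol = prot,
                            compute_epoc = FALSE)
    expect_lt(abs(ms$mmr - pars[2]) / pars[2], 0.005)
    expect_lt(abs(ms$rmr - pars[1]) / pars[1], 0.005)
    expect_equal(ms$aas, ms$mmr - ms$rmr)
    expect_equal(ms$fas, ms$mmr / ms$rmr)
  }
})

test_that("insufficient validated cycles flag the fish instead of guessing", {
  fish <- std_fish()
  trc <- simulate_trace(fish, noiseless_truth(), short_protocol(1),
                        seed = 2)
  ms <- metabolic_summary(trc, fish, min_cycles = 60)
  expect_true(is.na(ms$rmr))
  expect_match(ms$flags, "insufficient_cycles")
})
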
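# Shared fixtures: a standard fish, a short protocol for fast end-to-end
# runs, and an independent brute-force sliding-window oracle.

std_fish <- function(id = "f01", sex = "female", treatment = "sham",
                     mass = 2.5) {
  fish_record(id, sex, treatment, body_mass_kg = mass)
}

# Two-hour protocol: enough cycles for segmentation/EPOC tests while staying
# fast; RMR tests lower `min_cycles` accordingly.
short_protocol <- function(hours = 2) {
  respirometry_protocol(total_hours = hours)
}

noiseless_truth <- function(rmr = 3, mmr = 11, k = 0.05) {
  trace_truth(rmr = rmr, mmr = mmr, k_recovery = k, noise_sd = 0,
              cv_cycle = 0)
}

# Independent oracle: enumerate every admissible window with stats::cov/var
# fits, applying the same tie rule (minimum length first, strictly-steeper
# replacement, earliest window within a length).
brute_force_mmr <- function(slice, fish, window_min_s = 180, r2_min = 0.95) {
  tt <- slice$time_s
  yy <- slice$o2_mg_per_l
  n <- length(tt)
  dt <- stats::median(diff(tt))
  p_min <- as.integer(ceiling(window_min_s / dt - 1e-9)) + 1L
  best <- list(slope = Inf, i = NA_integer_, j = NA_integer_)
  for (p in p_min:n) {
    for (i in 1:(n - p + 1L)) {
      j <- i + p - 1L
      x <- tt[i:j]
      y <- yy[i:j]
      sxx <- stats::var(x)
      sxy <- stats::cov(x, y)
      syy <- stats::var(y)
      s <- sxy / sxx
      r2 <- if (syy <= 0) 0 else sxy^2 / (sxx * syy)
      if (r2 > r2_min && s < best$slope - 1e-12 * max(1, abs(s))) {
        best <- list(slope = s, i = i, j = j)
      }
    }
  }
  if (!is.finite(best$slope)) {
    return(list(determined = FALSE, slope = NA_real_,
                window_start_s = NA_real_, window_end_s = NA_real_))
  }
  list(determined = TRUE, slope = best$slope,
       window_start_s = tt[best$i], window_end_s = tt[best$j],
       mmr = mdot_from_slope(best$slope, fish))
}

# Random first-measurement-like slice: gently convex decline plus noise.
random_mmr_slice <- function(n = sample(185:230, 1), noise = 0.003) {
  t <- 0:(n - 1)
  a <- runif(1, 0.002, 0.008)
  b <- runif(1, 0, 3e-5)
  data.frame(time_s = t,
             o2_mg_per_l = 10 - a * t - b * t^2 / 2 +
               rnorm(n, 0, noise))
}
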
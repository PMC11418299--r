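#' Maximum metabolic rate by sliding-window steepest slope
#'
#' Scans the first post-chase measurement slice with windows of every
#' admissible length (at least `window_min_s`, in sample-spacing
#' increments up to the full slice), advancing window starts in `step_s`
#' increments. Each window is fitted by ordinary least squares; among
#' windows whose coefficient of determination exceeds `r2_min`, the steepest
#' (most negative) O2 slope defines MMR. Ties are broken reproducibly: the
#' minimum length is scanned first and longer windows only replace the
#' incumbent when strictly steeper; within a length the earliest window
#' wins.
#'
#' When no window passes the gate the result is flagged undetermined rather
#' than silently filled.
#'
#' @param slice data frame with `time_s`, `o2_mg_per_l` for the first
#'   measurement; must span at least `window_min_s`.
#' @param fish a [fish_record()].
#' @param window_min_s minimum window length in seconds (default 180).
#' @param step_s start-position increment in seconds (default 1).
#' @param r2_min minimum coefficient of determination (default 0.95).
#' @return list with `mmr` (mg O2 kg-1 min-1), `slope`, `r2`,
#'   `window_start_s`, `window_end_s` and `determined`.
#' @examples
#' fish <- fish_record("f01", "female", "sham", body_mass_kg = 2.5)
#' sl <- data.frame(time_s = 0:299, o2_mg_per_l = 10 - 0.004 * (0:299))
#' estimate_mmr(sl, fish)$mmr
#' @export
estimate_mmr <- function(slice, fish, window_min_s = 180, step_s = 1,
                         r2_min = 0.95) {
  stopifnot(is.data.frame(slice),
            all(c("time_s", "o2_mg_per_l") %in% names(slice)),
            inherits(fish, "fish_record"))
  tt <- slice$time_s - slice$time_s[1L]
  yy <- slice$o2_mg_per_l
  N <- length(tt)
  if (N < 3L || tt[N] < window_min_s) {
    stop("first measurement slice must span at least the minimum window",
         call. = FALSE)
  }
  dt <- stats::median(diff(tt))
  step_pts <- max(1L, as.integer(round(step_s / dt)))
  p_min <- as.integer(ceiling(window_min_s / dt - 1e-9)) + 1L

  # Zero-padded prefix sums give every window's OLS slope and r2 in O(1).
  c1 <- c(0, cumsum(tt))
  c2 <- c(0, cumsum(tt * tt))
  cy <- c(0, cumsum(yy))
  cyy <- c(0, cumsum(yy * yy))
  cty <- c(0, cumsum(tt * yy))
  win_sum <- function(cs, i, j) cs[j + 1L] - cs[i]

  best <- list(slope = Inf, i = NA_integer_, j = NA_integer_, r2 = NA_real_)
  for (p in seq.int(p_min, N)) {
    starts <- seq.int(1L, N - p + 1L, by = step_pts)
    ends <- starts + p - 1L
    n <- p
    st <- win_sum(c1, starts, ends)
    stt <- win_sum(c2, starts, ends)
    sy <- win_sum(cy, starts, ends)
    syy <- win_sum(cyy, starts, ends)
    sty <- win_sum(cty, starts, ends)
    sxx <- stt - st * st / n
    sxy <- sty - st * sy / n
    syy0 <- syy - sy * sy / n
    slope <- sxy / sxx
    r2 <- ifelse(syy0 <= 0, 0, (sxy * sxy) / (sxx * syy0))
    slope[r2 <= r2_min] <- Inf
    m <- min(slope)
    if (is.finite(m)) {
      tol <- 1e-12 * max(1, abs(m))  # float-level ties resolve to earliest
      k <- which(slope <= m + tol)[1L]
      if (slope[k] < best$slope - tol) {
        best <- list(slope = slope[k], i = starts[k], j = ends[k],
                     r2 = r2[k])
      }
    }
  }
  if (!is.finite(best$slope)) {
    return(list(mmr = NA_real_, slope = NA_real_, r2 = NA_real_,
                window_start_s = NA_real_, window_end_s = NA_real_,
                determined = FALSE))
  }
  list(mmr = mdot_from_slope(best$slope, fish), slope = best$slope,
       r2 = best$r2,
       window_start_s = slice$time_s[best$i],
       window_end_s = slice$time_s[best$j],
       determined = TRUE)
}

#' Resting metabolic rate as a low quantile of validated cycles
#'
#' The resting rate is the `prob` quantile (default 0.10) of all validated
#' per-cycle uptake values, computed with the linear-interpolation quantile
#' convention (R type 7). A fish with fewer than `min_cycles` validated
#' cycles is flagged and returns `NA` rather than an estimate.
#'
#' @param mdots validated per-cycle uptake values (mg O2 kg-1 min-1),
#'   already gated at r2 > 0.90.
#' @param prob quantile level (default 0.10).
#' @param min_cycles minimum number of validated cycles (default 60).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return list with `rmr`, `n`, `determined` and `flag`.
#' @examples
#' estimate_rmr(1:100, min_cycles = 60)$rmr  # 10.9
#' @export
estimate_rmr <- function(mdots, prob = 0.10, min_cycles = 60, type = 7) {
  mdots <- mdots[is.finite(mdots)]
  n <- length(mdots)
  if (n == 0L) {
    return(list(rmr = NA_real_, n = 0L, determined = FALSE,
                flag = "no_cycles"))
  }
  if (n < min_cycles) {
    return(list(rmr = NA_real_, n = n, determined = FALSE,
                flag = "insufficient_cycles"))
  }
  list(rmr = unname(stats::quantile(mdots, prob, type = type)), n = n,
       determined = TRUE, flag = NA_character_)
}

#' Absolute and factorial aerobic scope
#'
#' @param mmr maximum metabolic rate (mg O2 kg-1 min-1).
#' @param rmr resting metabolic rate (mg O2 kg-1 min-1); must be positive.
#' @return list with `aas = mmr - rmr` and `fas = mmr / rmr`.
#' @examples
#' aerobic_scope(11.94, 2.96)
#' @export
aerobic_scope <- function(mmr, rmr) {
  if (any(!is.finite(rmr)) || any(rmr <= 0)) {
    stop("`rmr` must be positive and finite", call. = FALSE)
  }
  list(aas = mmr - rmr, fas = mmr / rmr)
}

#' Excess post-exercise oxygen consumption by monotone-spline integration
#'
#' Interpolates the cycle-level recovery curve with a shape-preserving
#' (Fritsch-Carlson) cubic spline, locates the first down-crossing of the
#' resting rate that is sustained through the next cycle point, and
#' integrates the excess above the resting rate up to that time:
#' `epoc = integral of (mdot(t) - rmr) dt`, in mg O2 kg-1. If the spline
#' never sustainably reaches the resting rate within the record the result
#' is censored: the duration is the record length and the integral is a
#' lower bound.
#'
#' @param time_min cycle times in minutes, starting at the MMR measurement.
#' @param mdot uptake values at `time_min` (mg O2 kg-1 min-1).
#' @param rmr resting rate defining the baseline and the end-of-recovery
#'   threshold.
#' @param grid_dt_min resolution (min) of the crossing search and of the
#'   trapezoidal integration grid.
#' @return list with `epoc` (mg O2 kg-1), `epoc_duration_min` and
#'   `censored`.
#' @examples
#' t <- seq(0, 600, by = 10)
#' estimate_epoc(t, 3 + 8 * exp(-0.05 * t), rmr = 3)$epoc  # about 160
#' @export
estimate_epoc <- function(time_min, mdot, rmr, grid_dt_min = 1 / 60) {
  stopifnot(length(time_min) == length(mdot), length(time_min) >= 2L,
            all(diff(time_min) > 0))
  .assert_scalar(rmr, "rmr", 0, strict_lower = TRUE)
  f <- stats::splinefun(time_min, mdot, method = "monoH.FC")
  t0 <- time_min[1L]
  t_end <- time_min[length(time_min)]
  grid <- seq(t0, t_end, by = grid_dt_min)
  if (grid[length(grid)] < t_end) grid <- c(grid, t_end)
  vals <- f(grid)
  below <- vals <= rmr + 1e-9 * max(1, abs(rmr))

  duration <- NA_real_
  r <- rle(below)
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  for (k in which(r$values)) {
    tc <- grid[run_start[k]]
    nxt <- time_min[time_min > tc + 1e-12]
    t_need <- if (length(nxt)) nxt[1L] else t_end
    if (grid[run_end[k]] >= t_need - 1e-9) {
      duration <- tc - t0
      break
    }
  }
  censored <- is.na(duration)
  if (censored) duration <- t_end - t0

  gi <- grid[grid <= t0 + duration + 1e-12]
  if (length(gi) < 2L) {
    epoc <- 0
  } else {
    yv <- f(gi) - rmr
    epoc <- sum(diff(gi) * (utils::head(yv, -1L) + utils::tail(yv, -1L)) / 2)
  }
  list(epoc = max(0, epoc), epoc_duration_min = duration,
       censored = censored)
}

#' Per-fish metabolic summary from a raw trace
#'
#' Runs the whole per-fish chain: cycle segmentation and slope fitting,
#' validity gating, sliding-window MMR on the first measurement, quantile
#' RMR over all validated cycles, aerobic scope, and spline EPOC on the
#' recovery series (the MMR value at its window midpoint followed by the
#' validated overnight cycles at their midpoints).
#'
#' @param trace raw trace data frame.
#' @param fish a [fish_record()].
#' @param protocol optional [respirometry_protocol()] for label-free traces.
#' @param r2_rmr validity gate for resting cycles (default 0.90).
#' @param r2_mmr validity gate for MMR windows (default 0.95).
#' @param window_min_s minimum MMR window (s).
#' @param step_s MMR window start increment (s).
#' @param rmr_prob quantile level for the resting rate.
#' @param min_cycles minimum validated cycles for a resting estimate.
#' @param overnight_only if `TRUE`, restrict the resting quantile to cycles
#'   starting after `overnight_after_min` minutes.
#' @param overnight_after_min start of the overnight window (min).
#' @param compute_epoc set `FALSE` to skip the EPOC integration.
#' @return one-row data frame: identifiers, `rmr`, `mmr`, `aas`, `fas`,
#'   `epoc`, `epoc_duration_min`, `n_valid_cycles` and quality flags.
#' @examples
#' fish <- fish_record("f01", "female", "sham", body_mass_kg = 2.5)
#' tr <- trace_truth(rmr = 3, mmr = 11, noise_sd = 0, cv_cycle = 0)
#' prot <- respirometry_protocol(total_hours = 2)
#' metabolic_summary(simulate_trace(fish, tr, prot), fish,
#'                   min_cycles = 5)
#' @export
metabolic_summary <- function(trace, fish, protocol = NULL, r2_rmr = 0.90,
                              r2_mmr = 0.95, window_min_s = 180, step_s = 1,
                              rmr_prob = 0.10, min_cycles = 60,
                              overnight_only = FALSE,
                              overnight_after_min = 360,
                              compute_epoc = TRUE) {
  cycles <- process_trace(trace, fish, protocol, r2_min = r2_rmr)
  idx <- .measure_index(trace, protocol)
  first <- trace[idx$i0[1L]:idx$i1[1L], , drop = FALSE]
  mmr_res <- estimate_mmr(first, fish, window_min_s, step_s, r2_mmr)

  valid <- cycles[cycles$valid, , drop = FALSE]
  rmr_pool <- valid
  if (overnight_only) {
    rmr_pool <- rmr_pool[rmr_pool$t_start_s >= overnight_after_min * 60, ,
                         drop = FALSE]
  }
  rmr_res <- estimate_rmr(rmr_pool$mdot, rmr_prob, min_cycles)

  aas <- fas <- NA_real_
  if (mmr_res$determined && rmr_res$determined && rmr_res$rmr > 0) {
    sc <- aerobic_scope(mmr_res$mmr, rmr_res$rmr)
    aas <- sc$aas
    fas <- sc$fas
  }

  epoc <- dur <- NA_real_
  censored <- NA
  if (compute_epoc && mmr_res$determined && rmr_res$determined) {
    t_mmr <- (mmr_res$window_start_s + mmr_res$window_end_s) / 2 / 60
    rec <- valid[valid$cycle_index > 1L & valid$t_mid_s / 60 > t_mmr, ,
                 drop = FALSE]
    if (nrow(rec) >= 1L) {
      ep <- estimate_epoc(c(t_mmr, rec$t_mid_s / 60),
                          c(mmr_res$mmr, rec$mdot), rmr_res$rmr)
      epoc <- ep$epoc
      dur <- ep$epoc_duration_min
      censored <- ep$censored
    }
  }

  flags <- c(
    if (!mmr_res$determined) "mmr_undetermined",
    if (!rmr_res$determined) rmr_res$flag,
    if (isTRUE(censored)) "epoc_censored"
  )
  data.frame(
    fish_id = fish$fish_id, treatment = fish$treatment, sex = fish$sex,
    body_mass_kg = fish$body_mass_kg,
    rmr = if (rmr_res$determined) rmr_res$rmr else NA_real_,
    mmr = mmr_res$mmr, aas = aas, fas = fas,
    epoc = epoc, epoc_duration_min = dur,
    n_valid_cycles = nrow(valid),
    flags = paste(flags, collapse = ";"),
    stringsAsFactors = FALSE
  )
}

#' Metabolic summaries for every fish of a cohort
#'
#' @param cohort a `cohort` object from [simulate_cohort()].
#' @param ... passed on to [metabolic_summary()].
#' @return data frame with one row per fish.
#' @export
summarize_cohort <- function(cohort, ...) {
  stopifnot(inherits(cohort, "cohort"))
  fish <- cohort$fish
  rows <- lapply(seq_len(nrow(fish)), function(i) {
    fr <- fish_record(fish$fish_id[i], fish$sex[i], fish$treatment[i],
                      fish$body_mass_kg[i], fish$fork_length_cm[i],
                      fish$respirometer_volume_l[i], fish$fish_volume_l[i])
    metabolic_summary(cohort$traces[[fish$fish_id[i]]], fr,
                      protocol = cohort$config$protocol, ...)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
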
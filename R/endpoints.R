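#' Somatic organ index
#'
#' `organ_mass / body_mass * 100`, the percentage formulation used for
#' relative ventricular mass (RVM), gonadal (GSI), hepatosomatic (HSI) and
#' splenosomatic (SSI) indices. Scale-invariant and dimensionless.
#'
#' @param organ_mass organ mass (any unit, vectorised), non-negative.
#' @param body_mass body mass in the same unit, positive.
#' @return index in percent.
#' @examples
#' organ_index(2.4, 2400)  # RVM of 0.10%
#' @export
organ_index <- function(organ_mass, body_mass) {
  if (any(!is.finite(organ_mass)) || any(organ_mass < 0)) {
    stop("`organ_mass` must be non-negative", call. = FALSE)
  }
  if (any(!is.finite(body_mass)) || any(body_mass <= 0)) {
    stop("`body_mass` must be positive", call. = FALSE)
  }
  organ_mass / body_mass * 100
}

#' Percentage compact myocardium
#'
#' Compact dry mass as a percentage of total ventricular dry mass
#' (compact + spongy); bounded in `[0, 100]`.
#'
#' @param compact_dry_mass dried compact myocardium mass (vectorised).
#' @param spongy_dry_mass dried spongy myocardium mass.
#' @return percentage of compact myocardium.
#' @examples
#' percent_compact(30, 70)  # 30
#' @export
percent_compact <- function(compact_dry_mass, spongy_dry_mass) {
  if (any(!is.finite(compact_dry_mass)) || any(compact_dry_mass < 0) ||
      any(!is.finite(spongy_dry_mass)) || any(spongy_dry_mass < 0)) {
    stop("masses must be non-negative", call. = FALSE)
  }
  total <- compact_dry_mass + spongy_dry_mass
  if (any(total <= 0)) {
    stop("total ventricular dry mass must be positive", call. = FALSE)
  }
  compact_dry_mass / total * 100
}

#' All somatic indices for a morphometric table
#'
#' @param morpho data frame with `body_mass_g`, `ventricle_mass_g`,
#'   `liver_mass_g`, `spleen_mass_g`, `gonad_mass_g`,
#'   `compact_dry_mass_mg`, `spongy_dry_mass_mg` (as produced by
#'   [simulate_cohort()]).
#' @return the input with columns `rvm`, `gsi`, `hsi`, `ssi`,
#'   `percent_compact` appended (all in percent).
#' @export
somatic_indices <- function(morpho) {
  stopifnot(is.data.frame(morpho))
  morpho$rvm <- organ_index(morpho$ventricle_mass_g, morpho$body_mass_g)
  morpho$gsi <- organ_index(morpho$gonad_mass_g, morpho$body_mass_g)
  morpho$hsi <- organ_index(morpho$liver_mass_g, morpho$body_mass_g)
  morpho$ssi <- organ_index(morpho$spleen_mass_g, morpho$body_mass_g)
  morpho$percent_compact <- percent_compact(morpho$compact_dry_mass_mg,
                                            morpho$spongy_dry_mass_mg)
  morpho
}

#' Venous PO2 from a sealed-chamber plateau
#'
#' Estimates the blood oxygen tension as the mean of the final `tail_s`
#' seconds of the chamber record, provided the absolute slope over that tail
#' has fallen below `slope_tol` (Torr min-1). A record that is still rising
#' or falling faster than the tolerance is flagged non-plateaued; its tail
#' mean is still returned for inspection but should not be trusted.
#'
#' @param series data frame with `time_s` and `po2_torr`, spanning at least
#'   `tail_s` seconds (typically about 3 min).
#' @param tail_s length of the averaging tail (s).
#' @param slope_tol plateau criterion on the tail slope (Torr min-1).
#' @return list with `pvo2` (Torr), `plateaued`, `tail_slope_torr_min`.
#' @examples
#' s <- simulate_pvo2_series(23, noise_sd = 0, seed = 1)
#' pvo2_plateau(s)$pvo2
#' @export
pvo2_plateau <- function(series, tail_s = 30, slope_tol = 0.5) {
  stopifnot(is.data.frame(series),
            all(c("time_s", "po2_torr") %in% names(series)))
  span <- diff(range(series$time_s))
  if (span < tail_s) {
    stop("insufficient data: series shorter than the plateau tail window",
         call. = FALSE)
  }
  t_max <- max(series$time_s)
  tail <- series[series$time_s >= t_max - tail_s, , drop = FALSE]
  fit <- .ols_line(tail$time_s, tail$po2_torr)
  slope_min <- fit$slope * 60
  list(pvo2 = mean(tail$po2_torr), plateaued = abs(slope_min) < slope_tol,
       tail_slope_torr_min = slope_min)
}

#' Critical thermal maximum from a constant-rate ramp
#'
#' `ctmax = start_temp + ramp_rate * t_loe`. When a temperature log is
#' supplied, the logged temperature at the loss-of-equilibrium time takes
#' precedence, with a consistency flag raised if it deviates from the
#' computed value by more than `tol` degrees C. A missing
#' loss-of-equilibrium time yields a censored trial.
#'
#' @param start_temp ramp starting temperature (degrees C).
#' @param ramp_rate warming rate (degrees C min-1).
#' @param t_loe_min time to loss of equilibrium (min), or `NA` for a
#'   censored trial.
#' @param temperature_log optional data frame (`time_min`, `temp_c`).
#' @param tol consistency tolerance between logged and computed temperature.
#' @return list with `ctmax` (degrees C; `NA` when censored), `censored`,
#'   `source` (`"log"` or `"computed"`) and `flag`.
#' @examples
#' ctmax_from_ramp(12, 0.1, 149)$ctmax  # 26.9
#' @export
ctmax_from_ramp <- function(start_temp, ramp_rate, t_loe_min,
                            temperature_log = NULL, tol = 0.5) {
  .assert_scalar(start_temp, "start_temp")
  .assert_scalar(ramp_rate, "ramp_rate", 0, strict_lower = TRUE)
  if (is.na(t_loe_min)) {
    return(list(ctmax = NA_real_, censored = TRUE, source = NA_character_,
                flag = "censored_trial"))
  }
  .assert_scalar(t_loe_min, "t_loe_min", 0)
  computed <- start_temp + ramp_rate * t_loe_min
  if (!is.null(temperature_log)) {
    logged <- stats::approx(temperature_log$time_min, temperature_log$temp_c,
                            xout = t_loe_min, rule = 2)$y
    flag <- if (abs(logged - computed) > tol) "log_ramp_mismatch"
            else NA_character_
    return(list(ctmax = logged, censored = FALSE, source = "log",
                flag = flag))
  }
  list(ctmax = computed, censored = FALSE, source = "computed",
       flag = NA_character_)
}
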
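#' Default treatment-by-sex cell truths for the metabolic cohort
#'
#' Group means for resting and maximum metabolic rate per treatment-by-sex
#' cell, in mg O2 kg-1 min-1, together with the default cell sizes (the
#' number of fish completing the overnight record per cell). Pooled resting
#' rates are 2.96 (sham) and 2.92 (ligated); pooled maxima 11.94 (sham) and
#' 10.03 (ligated), a 16% reduction. Cells are anchored so that the pooled
#' means over the study's own cell compositions reproduce those pooled
#' values exactly; females sit 0.3 (RMR) and 1.0 (MMR) units below males.
#' See the methods vignette for how these values were assembled.
#'
#' @return data frame with columns `treatment`, `sex`, `n`, `rmr_mean`,
#'   `mmr_mean`.
#' @export
default_cells <- function() {
  data.frame(
    treatment = c("sham", "sham", "ligated", "ligated"),
    sex = c("female", "male", "female", "male"),
    n = c(5L, 4L, 7L, 7L),
    rmr_mean = c(2.96 - 0.3 * 4 / 9, 2.96 + 0.3 * 5 / 9,
                 2.92 - 0.15, 2.92 + 0.15),
    mmr_mean = c(11.94 - 1.0 * 5 / 13, 11.94 + 1.0 * 8 / 13,
                 10.03 - 1.0 * 10 / 19, 10.03 + 1.0 * 9 / 19),
    stringsAsFactors = FALSE
  )
}

#' Default thermal-trial truths per treatment
#'
#' Group-mean critical thermal maxima of 26.9 (sham) and 25.8 (ligated)
#' degrees C — a 1.1 degree reduction under coronary ligation — with a
#' between-fish standard deviation of 0.8 degrees C, ramped at
#' 0.1 degrees C min-1 from 12 degrees C. Cell sizes are the fish completing
#' the full ramp.
#'
#' @return data frame with columns `treatment`, `sex`, `n`, `ctmax_mean`,
#'   `ctmax_sd`, `start_temp`, `ramp_rate`.
#' @export
default_thermal_effects <- function() {
  data.frame(
    treatment = c("sham", "sham", "ligated", "ligated"),
    sex = c("female", "male", "female", "male"),
    n = c(7L, 2L, 6L, 7L),
    ctmax_mean = c(26.9, 26.9, 25.8, 25.8),
    ctmax_sd = 0.8, start_temp = 12, ramp_rate = 0.1,
    stringsAsFactors = FALSE
  )
}

#' Default blood-analyte means by treatment, sex and time point
#'
#' Long-format table of analyte means across the five sampling points
#' (0, 15 and 60 min post-exercise, overnight rest, and after the thermal
#' ramp). Venous PO2 and lactate means follow the recovery trajectories
#' reported for sham versus ligated fish (e.g. PO2 of 35.7 vs 23.0 Torr at
#' 15 min; peak lactate of 16.1 vs 19.5 mmol l-1 at 60 min); cortisol is
#' strongly female-elevated; glucose carries a male excursion at 60 min.
#' Cortisol and glucose are drawn on the log10 scale (`scale = "log10"`,
#' where `mean` is still on the natural scale), so that the inference
#' module's transform gate is exercised by construction.
#'
#' @return data frame with columns `analyte`, `treatment`, `sex` (`"all"`
#'   when the mean does not depend on sex), `time_point`, `mean`, `sd`,
#'   `scale`.
#' @export
default_blood_effects <- function() {
  tp <- c("0", "15", "60", "rest", "ctmax")
  row <- function(analyte, treatment, sex, means, sd, scale = "identity") {
    data.frame(analyte = analyte, treatment = treatment, sex = sex,
               time_point = tp, mean = means, sd = sd, scale = scale,
               stringsAsFactors = FALSE)
  }
  rbind(
    row("pvo2", "sham", "all", c(25.2, 35.7, 33.9, 33.9, 12.0), 5.0),
    row("pvo2", "ligated", "all", c(21.3, 23.0, 33.1, 31.0, 14.6), 5.0),
    row("lactate", "sham", "all", c(10, 13, 16.1, 0.9, 14.0), 2.0),
    row("lactate", "ligated", "all", c(10, 13, 19.5, 3.3, 12.9), 2.0),
    row("glucose", "sham", "female", c(5, 5.5, 6, 5, 5.2), 0.08, "log10"),
    row("glucose", "sham", "male", c(5, 5.5, 7, 5, 5.2), 0.08, "log10"),
    row("glucose", "ligated", "female", c(5, 5.5, 6, 5, 5.2), 0.08, "log10"),
    row("glucose", "ligated", "male", c(5, 5.5, 7, 5, 5.2), 0.08, "log10"),
    row("potassium", "sham", "all", c(3.2, 3.4, 3.6, 3.0, 5.0), 0.4),
    row("potassium", "ligated", "all", c(3.2, 3.4, 3.6, 3.0, 5.0), 0.4),
    row("sodium", "sham", "female", c(148, 147, 146, 150, 149), 3.0),
    row("sodium", "sham", "male", c(152, 151, 150, 153, 152), 3.0),
    row("sodium", "ligated", "female", c(147, 145, 142, 149, 148), 3.0),
    row("sodium", "ligated", "male", c(151, 150, 149, 152, 151), 3.0),
    row("cortisol", "sham", "female", c(220, 260, 300, 180, 320), 0.15,
        "log10"),
    row("cortisol", "sham", "male", c(90, 110, 130, 70, 150), 0.15, "log10"),
    row("cortisol", "ligated", "female", c(230, 270, 310, 190, 330), 0.15,
        "log10"),
    row("cortisol", "ligated", "male", c(95, 115, 135, 75, 155), 0.15,
        "log10"),
    row("haematocrit", "sham", "all", c(55, 50, 45, 35, 55), 5.0),
    row("haematocrit", "ligated", "all", c(55, 50, 45, 35, 55), 5.0)
  )
}

#' Default morphometric means
#'
#' Somatic-index means (percent of body mass) per treatment and sex, and the
#' split of ventricular dry mass into compact and spongy myocardium
#' (percent compact 29.0 sham vs 31.2 ligated). Relative ventricular mass is
#' male- and ligation-elevated, the gonadal index female-dominant, the
#' hepatosomatic index female- and ligation-elevated, and the splenosomatic
#' index male-elevated.
#'
#' @return list of data frames: `indices` (per treatment/sex means of RVM,
#'   GSI, HSI, SSI, percent compact) and `body` (mass and length moments).
#' @export
default_morpho_effects <- function() {
  list(
    indices = data.frame(
      treatment = rep(c("sham", "ligated"), each = 2),
      sex = rep(c("female", "male"), 2),
      rvm = c(0.090, 0.110, 0.100, 0.120),
      gsi = c(8.0, 3.0, 8.0, 3.0),
      hsi = c(1.60, 1.20, 1.80, 1.40),
      ssi = c(0.18, 0.25, 0.18, 0.25),
      percent_compact = c(29.0, 29.0, 31.2, 31.2),
      cv = 0.10,
      stringsAsFactors = FALSE
    ),
    body = data.frame(mass_mean_kg = 2.5, mass_sd_kg = 0.35,
                      fork_mean_cm = 55.7, fork_sd_cm = 5.3)
  )
}

#' Configuration of a synthetic cohort
#'
#' Bundles everything the generator needs: cell sizes and cell-mean truths,
#' the respirometry protocol, between-fish variability, recovery kinetics,
#' sensor noise, endpoint effect tables and the seed. All randomness in
#' [simulate_cohort()] flows from `seed`.
#'
#' @param cells data frame as [default_cells()]; one row per
#'   treatment-by-sex cell with `n >= 1`.
#' @param protocol a [respirometry_protocol()].
#' @param thermal data frame as [default_thermal_effects()], or `NULL` to
#'   skip thermal trials.
#' @param blood data frame as [default_blood_effects()], or `NULL`.
#' @param morpho list as [default_morpho_effects()], or `NULL`.
#' @param rmr_between_sd,mmr_between_sd between-fish standard deviations of
#'   the true resting and maximum rates (mg O2 kg-1 min-1).
#' @param k_recovery recovery rate constant (min-1).
#' @param noise_sd optode noise (mg l-1).
#' @param cv_cycle cycle-level jitter coefficient of variation.
#' @param drift sensor drift (mg l-1 h-1).
#' @param seed integer seed.
#' @return an object of class `cohort_config`.
#' @examples
#' cfg <- cohort_config(seed = 42)
#' @export
cohort_config <- function(cells = default_cells(),
                          protocol = respirometry_protocol(),
                          thermal = default_thermal_effects(),
                          blood = default_blood_effects(),
                          morpho = default_morpho_effects(),
                          rmr_between_sd = 0.30, mmr_between_sd = 1.2,
                          k_recovery = 0.05, noise_sd = 0.005,
                          cv_cycle = 0.05, drift = 0, seed = 1) {
  stopifnot(is.data.frame(cells), inherits(protocol, "resp_protocol"))
  need <- c("treatment", "sex", "n", "rmr_mean", "mmr_mean")
  if (!all(need %in% names(cells))) {
    stop("`cells` must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cells) == 0L || any(cells$n < 1L)) {
    stop("empty cell specification: every cell needs n >= 1", call. = FALSE)
  }
  if (any(cells$mmr_mean <= cells$rmr_mean)) {
    stop("every cell needs mmr_mean > rmr_mean", call. = FALSE)
  }
  .assert_scalar(rmr_between_sd, "rmr_between_sd", 0)
  .assert_scalar(mmr_between_sd, "mmr_between_sd", 0)
  .assert_scalar(seed, "seed")
  structure(
    list(cells = cells, protocol = protocol, thermal = thermal,
         blood = blood, morpho = morpho,
         rmr_between_sd = rmr_between_sd, mmr_between_sd = mmr_between_sd,
         k_recovery = k_recovery, noise_sd = noise_sd,
         cv_cycle = cv_cycle, drift = drift, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

# Draw per-fish truths for one cell, keeping mmr > rmr by construction.
.draw_cell_truths <- function(n, rmr_mean, mmr_mean, rmr_sd, mmr_sd) {
  rmr <- stats::rnorm(n, rmr_mean, rmr_sd)
  mmr <- stats::rnorm(n, mmr_mean, mmr_sd)
  rmr <- pmax(rmr, 0.2 * rmr_mean)
  mmr <- pmax(mmr, rmr * 1.5)
  data.frame(rmr_true = rmr, mmr_true = mmr)
}

#' Simulate a complete synthetic cohort
#'
#' Generates, for every fish of every treatment-by-sex cell: a fish record
#' (mass, length, respirometer geometry), a full overnight O2 trace, a
#' five-point blood panel, organ masses, and an acute thermal trial. All
#' ground truth is retained so downstream estimates can be compared against
#' it. The draw is fully determined by `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return an object of class `cohort`: a list with `fish` (data frame of
#'   identities, morphology and per-fish truths), `traces` (named list of
#'   trace data frames), `blood`, `morpho`, `thermal` (data frames) and
#'   `config`.
#' @examples
#' cfg <- cohort_config(
#'   cells = transform(default_cells(), n = 1),
#'   protocol = respirometry_protocol(total_hours = 0.5),
#'   seed = 7
#' )
#' coh <- simulate_cohort(cfg)
#' coh$fish[, c("fish_id", "treatment", "sex", "rmr_true", "mmr_true")]
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    cells <- config$cells
    body <- (config$morpho %||% default_morpho_effects())$body
    fish_rows <- list()
    idx <- 0L
    for (ci in seq_len(nrow(cells))) {
      n <- cells$n[ci]
      truths <- .draw_cell_truths(n, cells$rmr_mean[ci], cells$mmr_mean[ci],
                                  config$rmr_between_sd,
                                  config$mmr_between_sd)
      for (j in seq_len(n)) {
        idx <- idx + 1L
        fish_rows[[idx]] <- data.frame(
          fish_id = sprintf("fish_%02d", idx),
          treatment = cells$treatment[ci], sex = cells$sex[ci],
          body_mass_kg = max(1, stats::rnorm(1, body$mass_mean_kg,
                                             body$mass_sd_kg)),
          fork_length_cm = stats::rnorm(1, body$fork_mean_cm, body$fork_sd_cm),
          respirometer_volume_l = 54.5,
          rmr_true = truths$rmr_true[j], mmr_true = truths$mmr_true[j],
          stringsAsFactors = FALSE
        )
      }
    }
    fish <- do.call(rbind, fish_rows)
    fish$fish_volume_l <- fish$body_mass_kg

    traces <- vector("list", nrow(fish))
    names(traces) <- fish$fish_id
    for (i in seq_len(nrow(fish))) {
      fr <- fish_record(fish$fish_id[i], fish$sex[i], fish$treatment[i],
                        fish$body_mass_kg[i], fish$fork_length_cm[i],
                        fish$respirometer_volume_l[i], fish$fish_volume_l[i])
      tt <- trace_truth(fish$rmr_true[i], fish$mmr_true[i],
                        k_recovery = config$k_recovery,
                        noise_sd = config$noise_sd,
                        cv_cycle = config$cv_cycle, drift = config$drift)
      traces[[i]] <- simulate_trace(fr, tt, config$protocol)
    }

    blood <- if (!is.null(config$blood)) {
      .simulate_blood(fish, config$blood)
    }
    morpho <- if (!is.null(config$morpho)) {
      .simulate_morpho(fish, config$morpho)
    }
    thermal <- if (!is.null(config$thermal)) {
      .simulate_thermal(config$thermal)
    }

    structure(list(fish = fish, traces = traces, blood = blood,
                   morpho = morpho, thermal = thermal, config = config),
              class = "cohort")
  })
}

.simulate_blood <- function(fish, effects) {
  rows <- list()
  for (i in seq_len(nrow(fish))) {
    sel <- effects$treatment == fish$treatment[i] &
      (effects$sex == "all" | effects$sex == fish$sex[i])
    eff <- effects[sel, , drop = FALSE]
    value <- ifelse(
      eff$scale == "log10",
      10^(stats::rnorm(nrow(eff), log10(eff$mean), eff$sd)),
      stats::rnorm(nrow(eff), eff$mean, eff$sd)
    )
    rows[[i]] <- data.frame(
      fish_id = fish$fish_id[i], treatment = fish$treatment[i],
      sex = fish$sex[i], time_point = eff$time_point,
      analyte = eff$analyte, value = pmax(value, 0),
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.simulate_morpho <- function(fish, morpho) {
  ind <- morpho$indices
  rows <- list()
  for (i in seq_len(nrow(fish))) {
    e <- ind[ind$treatment == fish$treatment[i] & ind$sex == fish$sex[i], ]
    body_g <- fish$body_mass_kg[i] * 1000
    jit <- function(mu) max(0, stats::rnorm(1, mu, e$cv * mu))
    ventricle_g <- jit(e$rvm) / 100 * body_g
    dry_mg <- 0.15 * ventricle_g * 1000  # dry mass ~15% of wet ventricle
    pc <- min(100, max(0, stats::rnorm(1, e$percent_compact,
                                       e$cv * e$percent_compact)))
    rows[[i]] <- data.frame(
      fish_id = fish$fish_id[i], treatment = fish$treatment[i],
      sex = fish$sex[i], body_mass_g = body_g,
      ventricle_mass_g = ventricle_g,
      liver_mass_g = jit(e$hsi) / 100 * body_g,
      spleen_mass_g = jit(e$ssi) / 100 * body_g,
      gonad_mass_g = jit(e$gsi) / 100 * body_g,
      compact_dry_mass_mg = pc / 100 * dry_mg,
      spongy_dry_mass_mg = (1 - pc / 100) * dry_mg,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.simulate_thermal <- function(effects) {
  rows <- list()
  idx <- 0L
  for (ci in seq_len(nrow(effects))) {
    for (j in seq_len(effects$n[ci])) {
      idx <- idx + 1L
      ct <- stats::rnorm(1, effects$ctmax_mean[ci], effects$ctmax_sd[ci])
      ct <- max(ct, effects$start_temp[ci] + 1)
      trial <- simulate_thermal_trial(
        thermal_truth(ct, effects$start_temp[ci], effects$ramp_rate[ci])
      )
      rows[[idx]] <- data.frame(
        trial_id = sprintf("trial_%02d", idx),
        treatment = effects$treatment[ci], sex = effects$sex[ci],
        start_temp = trial$start_temp, ramp_rate = trial$ramp_rate,
        t_loe_min = trial$t_loe_min, ctmax_true = ct,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
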
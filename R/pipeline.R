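#' Build a pipeline run configuration
#'
#' Assembles everything a reproducible run needs: the cohort generator
#' configuration, the respirometry protocol, the analysis thresholds (all
#' defaulting to the workflow's standard values: 180-s minimum MMR window at
#' 1-s steps with r2 > 0.95, cycle validation at r2 > 0.90, the 0.10
#' quantile over at least 60 validated cycles, alpha = 0.05), and the seed.
#' A YAML file can override any threshold or generator scalar.
#'
#' @param file optional YAML file with fields among `seed`, `thresholds`
#'   (named list), `protocol` (arguments of [respirometry_protocol()]) and
#'   `cells` (data frame columns as in [default_cells()]).
#' @param cohort a [cohort_config()]; built from defaults (and the YAML
#'   overrides) when `NULL`.
#' @param thresholds named list overriding analysis thresholds.
#' @param seed integer seed; overrides the YAML value.
#' @return a list of class `run_config`.
#' @export
run_config <- function(file = NULL, cohort = NULL, thresholds = list(),
                       seed = NULL) {
  ycfg <- if (!is.null(file)) yaml::read_yaml(file) else list()
  thr <- list(r2_rmr = 0.90, r2_mmr = 0.95, window_min_s = 180, step_s = 1,
              rmr_prob = 0.10, min_cycles = 60, alpha = 0.05, min_cell = 5)
  thr[names(ycfg$thresholds %||% list())] <- ycfg$thresholds
  thr[names(thresholds)] <- thresholds
  seed <- seed %||% ycfg$seed %||% 1L
  if (is.null(cohort)) {
    prot <- do.call(respirometry_protocol, ycfg$protocol %||% list())
    cells <- if (!is.null(ycfg$cells)) {
      yc <- ycfg$cells
      if (is.null(names(yc))) {  # row-oriented (as written by reports)
        do.call(rbind, lapply(yc, as.data.frame,
                              stringsAsFactors = FALSE))
      } else {                   # column-oriented
        as.data.frame(lapply(yc, unlist), stringsAsFactors = FALSE)
      }
    } else {
      default_cells()
    }
    cohort <- cohort_config(cells = cells, protocol = prot, seed = seed)
  } else {
    cohort$seed <- as.integer(seed)
  }
  structure(list(cohort = cohort, thresholds = thr, seed = as.integer(seed)),
            class = "run_config")
}

#' Write a cohort to disk as tidy text files
#'
#' One trace CSV per fish (`time_s`, `o2_mg_per_l`, `phase`, `temp_c`),
#' plus cohort metadata, blood, morphometric and thermal CSVs and a YAML
#' sidecar holding the generator truth.
#'
#' @param cohort a `cohort` object.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cohort"))
  dir.create(file.path(dir, "traces"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$fish, file.path(dir, "fish_metadata.csv"),
                   row.names = FALSE)
  for (id in names(cohort$traces)) {
    utils::write.csv(cohort$traces[[id]],
                     file.path(dir, "traces", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  if (!is.null(cohort$blood)) {
    utils::write.csv(cohort$blood, file.path(dir, "blood_panels.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$morpho)) {
    utils::write.csv(cohort$morpho, file.path(dir, "morphometrics.csv"),
                     row.names = FALSE)
  }
  if (!is.null(cohort$thermal)) {
    utils::write.csv(cohort$thermal, file.path(dir, "thermal_trials.csv"),
                     row.names = FALSE)
  }
  truth <- list(
    seed = cohort$config$seed,
    k_recovery = cohort$config$k_recovery,
    noise_sd = cohort$config$noise_sd,
    cv_cycle = cohort$config$cv_cycle,
    cells = lapply(seq_len(nrow(cohort$config$cells)), function(i) {
      as.list(cohort$config$cells[i, ])
    }),
    fish_truth = stats::setNames(
      lapply(seq_len(nrow(cohort$fish)), function(i) {
        list(rmr_true = cohort$fish$rmr_true[i],
             mmr_true = cohort$fish$mmr_true[i])
      }),
      cohort$fish$fish_id
    )
  )
  yaml::write_yaml(truth, file.path(dir, "truth.yaml"))
  invisible(dir)
}

#' Read a previously written cohort directory
#'
#' @param dir directory produced by [write_cohort()].
#' @param protocol the [respirometry_protocol()] the traces were generated
#'   under (needed downstream for label-free segmentation; defaults to the
#'   standard protocol).
#' @return a `cohort` object (without generator truth columns if the
#'   sidecar is missing).
#' @export
read_cohort <- function(dir, protocol = respirometry_protocol()) {
  fish <- utils::read.csv(file.path(dir, "fish_metadata.csv"),
                          stringsAsFactors = FALSE)
  traces <- stats::setNames(
    lapply(fish$fish_id, function(id) {
      utils::read.csv(file.path(dir, "traces", paste0(id, ".csv")),
                      stringsAsFactors = FALSE)
    }),
    fish$fish_id
  )
  read_opt <- function(f) {
    p <- file.path(dir, f)
    if (file.exists(p)) utils::read.csv(p, stringsAsFactors = FALSE)
  }
  blood <- read_opt("blood_panels.csv")
  if (!is.null(blood)) blood$time_point <- as.character(blood$time_point)
  cfg <- cohort_config(cells = default_cells(), protocol = protocol,
                       seed = 0L)
  structure(list(fish = fish, traces = traces,
                 blood = blood,
                 morpho = read_opt("morphometrics.csv"),
                 thermal = read_opt("thermal_trials.csv"),
                 config = cfg),
            class = "cohort")
}

# Staged statistics over the standard endpoint set of a run. Degenerate
# designs (saturated fits, singular mixed models) are tolerated: warnings
# are muted and failures recorded as error stubs rather than aborting.
.run_inference <- function(metab, morpho_idx, thermal, blood, thr) {
  alpha <- thr$alpha
  quiet_try <- function(expr) {
    tryCatch(suppressMessages(suppressWarnings(expr)),
             error = function(e) list(error = conditionMessage(e)))
  }
  res <- list()
  for (ep in c("rmr", "mmr", "aas", "fas")) {
    res[[ep]] <- quiet_try(
      analyze_endpoint(metab, ep, c("treatment", "sex"), alpha,
                       min_cell = 1, type = "auto")
    )
  }
  for (ep in c("epoc", "epoc_duration_min")) {
    res[[ep]] <- quiet_try(
      analyze_endpoint(metab, ep, c("treatment", "sex"), alpha,
                       min_cell = thr$min_cell, type = "auto")
    )
  }
  if (!is.null(morpho_idx)) {
    for (ep in c("rvm", "gsi", "hsi", "ssi", "percent_compact")) {
      res[[ep]] <- quiet_try(
        analyze_endpoint(morpho_idx, ep, c("treatment", "sex"), alpha,
                         min_cell = 1, type = "II")
      )
    }
  }
  if (!is.null(thermal)) {
    res$ctmax <- quiet_try(
      analyze_endpoint(thermal, "ctmax", c("treatment", "sex"), alpha,
                       min_cell = thr$min_cell, type = "auto")
    )
  }
  if (!is.null(blood)) {
    for (an in unique(blood$analyte)) {
      d <- blood[blood$analyte == an, , drop = FALSE]
      gate <- assumption_gate(d$value, group = d$treatment, alpha = alpha)
      if (gate$transform == "log10") d$value <- log10(d$value)
      lmm <- quiet_try(repeated_measures_lmm(d, "value"))
      if (!is.null(lmm$anova)) lmm$gate <- gate
      res[[paste0("blood_", an)]] <- lmm
    }
  }
  res
}

# Serialisable digest of one aero_stat (or error stub) for the results JSON.
.stat_json <- function(x) {
  if (!is.null(x$error)) return(list(error = x$error))
  out <- list(anova_type = x$anova_type %||% "III", anova = x$anova)
  if (!is.null(x$gate)) {
    out$transform <- x$gate$transform
    out$shapiro_p_raw <- x$gate$shapiro_p_raw
    out$levene_p <- x$gate$levene_p
  }
  if (!is.null(x$factors_used)) out$factors <- x$factors_used
  if (!is.null(x$formula)) out$model <- x$formula
  if (!is.null(x$anova_f)) out$anova_satterthwaite <- x$anova_f
  if (!is.null(x$letters)) out$letters <- as.list(x$letters)
  if (!is.null(x$singular)) out$singular_random_effect <- x$singular
  out
}

#' Run the full simulate-process-summarise-infer pipeline
#'
#' `mode = "simulate"` writes a synthetic cohort to `outdir`;
#' `mode = "analyze"` reads a cohort directory and writes per-fish cycle
#' tables, the metabolic summary table, endpoint tables, a statistics JSON
#' and a text report; `mode = "full"` does both. Runs are deterministic
#' given the configuration (seed included), and the report carries a
#' provenance block (config hash, seed, versions).
#'
#' @param config a [run_config()].
#' @param outdir run directory.
#' @param mode `"full"`, `"simulate"` or `"analyze"`.
#' @return (invisibly) a list with the metabolic summary, endpoint tables
#'   and statistics results.
#' @export
run_pipeline <- function(config, outdir, mode = c("full", "simulate",
                                                  "analyze")) {
  mode <- match.arg(mode)
  stopifnot(inherits(config, "run_config"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  thr <- config$thresholds

  if (mode %in% c("full", "simulate")) {
    cohort <- simulate_cohort(config$cohort)
    write_cohort(cohort, outdir)
    if (mode == "simulate") return(invisible(list(cohort = cohort)))
  } else {
    need <- file.path(outdir, c("fish_metadata.csv", "traces"))
    missing <- need[!file.exists(need)]
    if (length(missing)) {
      stop("analyze mode is missing input artifacts: ",
           paste(basename(missing), collapse = ", "), call. = FALSE)
    }
    cohort <- read_cohort(outdir, protocol = config$cohort$protocol)
  }

  dir.create(file.path(outdir, "cycles"), showWarnings = FALSE)
  metab <- summarize_cohort(cohort, r2_rmr = thr$r2_rmr,
                            r2_mmr = thr$r2_mmr,
                            window_min_s = thr$window_min_s,
                            step_s = thr$step_s, rmr_prob = thr$rmr_prob,
                            min_cycles = thr$min_cycles)
  for (i in seq_len(nrow(cohort$fish))) {
    id <- cohort$fish$fish_id[i]
    fr <- fish_record(id, cohort$fish$sex[i], cohort$fish$treatment[i],
                      cohort$fish$body_mass_kg[i],
                      cohort$fish$fork_length_cm[i],
                      cohort$fish$respirometer_volume_l[i],
                      cohort$fish$fish_volume_l[i])
    cyc <- process_trace(cohort$traces[[id]], fr,
                         protocol = config$cohort$protocol,
                         r2_min = thr$r2_rmr)
    utils::write.csv(cyc, file.path(outdir, "cycles", paste0(id, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(metab, file.path(outdir, "metabolic_summary.csv"),
                   row.names = FALSE)

  morpho_idx <- if (!is.null(cohort$morpho)) somatic_indices(cohort$morpho)
  thermal <- cohort$thermal
  if (!is.null(thermal)) {
    thermal$ctmax <- vapply(seq_len(nrow(thermal)), function(i) {
      ctmax_from_ramp(thermal$start_temp[i], thermal$ramp_rate[i],
                      thermal$t_loe_min[i])$ctmax
    }, 0)
    utils::write.csv(thermal, file.path(outdir, "thermal_ctmax.csv"),
                     row.names = FALSE)
  }
  if (!is.null(morpho_idx)) {
    utils::write.csv(morpho_idx, file.path(outdir, "somatic_indices.csv"),
                     row.names = FALSE)
  }

  stats_res <- .run_inference(metab, morpho_idx, thermal, cohort$blood, thr)
  jsonlite::write_json(lapply(stats_res, .stat_json),
                       file.path(outdir, "stats_results.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows",
                       pretty = TRUE, force = TRUE)

  .write_report(config, outdir, metab, stats_res)
  invisible(list(metabolic_summary = metab, somatic_indices = morpho_idx,
                 thermal = thermal, stats = stats_res))
}

.write_report <- function(config, outdir, metab, stats_res) {
  cfg_file <- file.path(outdir, "run_config.yaml")
  yaml::write_yaml(list(seed = config$seed, thresholds = config$thresholds,
                        protocol = unclass(config$cohort$protocol),
                        cells = lapply(seq_len(nrow(config$cohort$cells)),
                                       function(i) {
                                         as.list(config$cohort$cells[i, ])
                                       })),
                   cfg_file)
  lines <- c(
    "# Respirometry pipeline report",
    "",
    "## Provenance",
    sprintf("config_md5: %s", unname(tools::md5sum(cfg_file))),
    sprintf("seed: %d", config$seed),
    sprintf("R: %s", as.character(getRversion())),
    sprintf("package: aeroscope %s",
            as.character(utils::packageVersion("aeroscope"))),
    "",
    "## Group summaries (mean ± s.e.m.)",
    ""
  )
  for (ep in c("rmr", "mmr", "aas", "fas", "epoc")) {
    if (!ep %in% names(metab)) next
    gs <- tryCatch(group_summary(metab, ep, "treatment"),
                   error = function(e) NULL)
    if (is.null(gs)) next
    lines <- c(lines, sprintf("%s: %s", ep,
                              paste(gs$treatment, gs$label,
                                    collapse = "; ")))
  }
  lines <- c(lines, "", "## Tests")
  for (nm in names(stats_res)) {
    x <- stats_res[[nm]]
    if (!is.null(x$error)) {
      lines <- c(lines, sprintf("%s: not fitted (%s)", nm, x$error))
      next
    }
    a <- x$anova
    stat_name <- if (!is.null(x$formula)) "chi2" else "F"
    for (i in seq_len(nrow(a))) {
      lines <- c(lines, sprintf("%s | %s: %s(%d) = %.3f, P = %.4g", nm,
                                a$term[i], stat_name, a$df[i],
                                a$statistic[i], a$p[i]))
    }
  }
  writeLines(lines, file.path(outdir, "report.txt"))
}
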
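# Internal: index ranges of measurement phases. Uses phase labels when
# present, otherwise infers them from protocol timing.
.measure_index <- function(trace, protocol = NULL) {
  stopifnot(is.data.frame(trace), all(c("time_s", "o2_mg_per_l") %in%
                                        names(trace)))
  if (nrow(trace) > 1L && any(diff(trace$time_s) <= 0)) {
    stop("trace time must be strictly increasing", call. = FALSE)
  }
  phase <- trace$phase
  if (is.null(phase) || anyNA(phase)) {
    if (is.null(protocol)) {
      stop("segmentation error: trace has no usable phase labels and no ",
           "protocol timing was supplied", call. = FALSE)
    }
    sched <- .phase_schedule(protocol)
    phase <- rep("flush", nrow(trace))
    meas <- sched[sched$phase == "measure", , drop = FALSE]
    for (i in seq_len(nrow(meas))) {
      phase[trace$time_s >= meas$t0[i] & trace$time_s < meas$t1[i]] <-
        "measure"
    }
  }
  if (!all(phase %in% c("flush", "measure"))) {
    stop("segmentation error: phase labels must be 'flush' or 'measure'",
         call. = FALSE)
  }
  r <- rle(phase)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values == "measure"
  data.frame(cycle_index = seq_len(sum(keep)),
             i0 = starts[keep], i1 = ends[keep])
}

#' Split a trace into measurement-phase slices
#'
#' Returns the flush-off (sealed) spans of an intermittent-flow trace, in
#' order, as a list of data frames. Phase labels in the trace are used when
#' present; otherwise phases are reconstructed from the protocol's timing.
#' Flush samples are never included.
#'
#' @param trace data frame with `time_s`, `o2_mg_per_l` and optionally
#'   `phase`.
#' @param protocol a [respirometry_protocol()], required when the trace
#'   carries no phase labels.
#' @return list of data frames, one per measurement cycle, each with an
#'   attribute `cycle_index`.
#' @examples
#' fish <- fish_record("f01", "female", "sham", body_mass_kg = 2.5)
#' tr <- trace_truth(rmr = 3, mmr = 11, noise_sd = 0, cv_cycle = 0)
#' prot <- respirometry_protocol(total_hours = 1)
#' slices <- segment_cycles(simulate_trace(fish, tr, prot), prot)
#' length(slices)
#' @export
segment_cycles <- function(trace, protocol = NULL) {
  idx <- .measure_index(trace, protocol)
  lapply(seq_len(nrow(idx)), function(i) {
    out <- trace[idx$i0[i]:idx$i1[i], , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "cycle_index") <- idx$cycle_index[i]
    out
  })
}

#' Fit the linear O2 decline of one measurement slice
#'
#' Ordinary least squares of O2 concentration on time. The coefficient of
#' determination of a zero-variance response is defined as 0 (the cycle then
#' fails validation) rather than 0/0.
#'
#' @param slice data frame with `time_s` and `o2_mg_per_l` (3 or more rows).
#' @return list with `slope` (mg l-1 s-1), `intercept`, `r2` and `n`.
#' @examples
#' sl <- data.frame(time_s = 0:299, o2_mg_per_l = 10 - 0.001 * (0:299))
#' fit_cycle_slope(sl)$slope  # -0.001
#' @export
fit_cycle_slope <- function(slice) {
  stopifnot(is.data.frame(slice),
            all(c("time_s", "o2_mg_per_l") %in% names(slice)))
  .ols_line(slice$time_s, slice$o2_mg_per_l)
}

#' Mass-specific oxygen uptake from a fitted slope
#'
#' Applies the uptake equation `mdot = dO2 * (v_R - v_F) / m`, where `dO2`
#' is the magnitude of the linear O2 decline, `v_R - v_F` the effective
#' water volume and `m` the fish mass, converting the per-second slope to
#' the package's canonical rate unit of mg O2 kg-1 min-1 (use
#' [mdot_to_hourly()] for mg O2 kg-1 h-1). A positive slope (O2 rising)
#' yields a negative value, which downstream validation rejects.
#'
#' @param slope fitted O2 slope, mg l-1 s-1 (vectorised).
#' @param fish a [fish_record()].
#' @return oxygen uptake, mg O2 kg-1 min-1.
#' @examples
#' fish <- fish_record("f01", "female", "sham", body_mass_kg = 2.5)
#' mdot_from_slope(-0.001, fish)  # 0.001 * 52 / 2.5 * 60 = 1.248
#' @export
mdot_from_slope <- function(slope, fish) {
  stopifnot(inherits(fish, "fish_record"))
  vol <- fish$respirometer_volume_l - fish$fish_volume_l
  -slope * vol / fish$body_mass_kg * 60
}

#' Convert a per-minute uptake rate to per-hour
#'
#' @param mdot rate(s) in mg O2 kg-1 min-1.
#' @return rate(s) in mg O2 kg-1 h-1.
#' @export
mdot_to_hourly <- function(mdot) mdot * 60

#' Keep only cycles that pass the linearity gate
#'
#' Retains cycles whose coefficient of determination exceeds `r2_min` and
#' whose O2 slope is negative (an automated stand-in for visual assessment
#' of negative linearity). Ordering is preserved; an empty result is allowed.
#'
#' @param cycles cycle table as returned by [process_trace()].
#' @param r2_min minimum coefficient of determination (default 0.90, the
#'   gate used for resting-rate cycles).
#' @return the validated subset of `cycles`.
#' @export
validate_cycles <- function(cycles, r2_min = 0.90) {
  stopifnot(is.data.frame(cycles),
            all(c("slope", "r2") %in% names(cycles)))
  cycles[cycles$r2 > r2_min & cycles$slope < 0, , drop = FALSE]
}

#' Turn a raw trace into a per-cycle uptake table
#'
#' Segments the trace into measurement cycles, fits each cycle's linear O2
#' decline, converts slopes to mass-specific uptake and flags validity
#' (`r2 > r2_min` and negative slope).
#'
#' @param trace trace data frame (see [simulate_trace()] for the schema).
#' @param fish a [fish_record()].
#' @param protocol optional [respirometry_protocol()] for label-free traces.
#' @param r2_min validity threshold on the coefficient of determination.
#' @param wait_s seconds discarded at the start of each measurement phase
#'   (mixing lag); default 0.
#' @param blank_slope optional background (blank) O2 slope, mg l-1 s-1,
#'   subtracted from every cycle slope before conversion; default `NULL`
#'   applies no background correction.
#' @return data frame with one row per measurement cycle: `cycle_index`,
#'   `t_start_s`, `t_end_s`, `t_mid_s`, `n`, `slope`, `r2`, `mdot`, `valid`.
#' @examples
#' fish <- fish_record("f01", "female", "sham", body_mass_kg = 2.5)
#' tr <- trace_truth(rmr = 3, mmr = 11, noise_sd = 0, cv_cycle = 0)
#' prot <- respirometry_protocol(total_hours = 1)
#' process_trace(simulate_trace(fish, tr, prot), fish)
#' @export
process_trace <- function(trace, fish, protocol = NULL, r2_min = 0.90,
                          wait_s = 0, blank_slope = NULL) {
  stopifnot(inherits(fish, "fish_record"))
  idx <- .measure_index(trace, protocol)
  tt <- trace$time_s
  o2 <- trace$o2_mg_per_l
  out <- vector("list", nrow(idx))
  for (i in seq_len(nrow(idx))) {
    sel <- idx$i0[i]:idx$i1[i]
    if (wait_s > 0) sel <- sel[tt[sel] >= tt[sel[1L]] + wait_s]
    if (length(sel) < 3L) {
      out[[i]] <- data.frame(cycle_index = idx$cycle_index[i],
                             t_start_s = tt[idx$i0[i]], t_end_s = tt[idx$i1[i]],
                             t_mid_s = mean(tt[c(idx$i0[i], idx$i1[i])]),
                             n = length(sel), slope = NA_real_, r2 = NA_real_,
                             mdot = NA_real_, valid = FALSE)
      next
    }
    fit <- .ols_line(tt[sel], o2[sel])
    slope <- fit$slope - (blank_slope %||% 0)
    out[[i]] <- data.frame(
      cycle_index = idx$cycle_index[i],
      t_start_s = tt[sel[1L]], t_end_s = tt[sel[length(sel)]],
      t_mid_s = (tt[sel[1L]] + tt[sel[length(sel)]]) / 2,
      n = fit$n, slope = slope, r2 = fit$r2,
      mdot = mdot_from_slope(slope, fish),
      valid = fit$r2 > r2_min && slope < 0
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
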
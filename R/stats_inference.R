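#' Normality and homoscedasticity gate with log10 fallback
#'
#' Applies the staged assumption check used throughout the analysis
#' workflow: a Shapiro-Wilk normality test (and, when a grouping factor is
#' supplied, Levene's test for heteroscedasticity); endpoints failing
#' normality at `alpha` are log10-transformed and retested. The gate is
#' applied per endpoint across all observations, so one transform decision
#' holds for the whole metric.
#'
#' @param values numeric endpoint values (n >= 3).
#' @param group optional grouping factor for Levene's test.
#' @param alpha significance level of the gate.
#' @return list with `transform` (`"none"` or `"log10"`), `values`
#'   (transformed when applicable), `shapiro_p_raw`, `shapiro_p_final`,
#'   `levene_p`, `degenerate` and `flag`.
#' @examples
#' assumption_gate(rlnorm(50))$transform
#' @export
assumption_gate <- function(values, group = NULL, alpha = 0.05) {
  values <- values[is.finite(values)]
  if (length(values) < 3L) {
    stop("need at least 3 finite values", call. = FALSE)
  }
  if (stats::sd(values) == 0) {
    return(list(transform = "none", values = values,
                shapiro_p_raw = NA_real_, shapiro_p_final = NA_real_,
                levene_p = NA_real_, degenerate = TRUE,
                flag = "zero_variance"))
  }
  sw_raw <- stats::shapiro.test(values)$p.value
  lev <- NA_real_
  if (!is.null(group)) {
    group <- factor(group)
    if (nlevels(group) >= 2L) {
      lev <- car::leveneTest(values ~ group)[1L, "Pr(>F)"]
    }
  }
  if (sw_raw > alpha) {
    return(list(transform = "none", values = values, shapiro_p_raw = sw_raw,
                shapiro_p_final = sw_raw, levene_p = lev, degenerate = FALSE,
                flag = NA_character_))
  }
  if (any(values <= 0)) {
    return(list(transform = "none", values = values, shapiro_p_raw = sw_raw,
                shapiro_p_final = sw_raw, levene_p = lev, degenerate = FALSE,
                flag = "transform_impossible"))
  }
  lv <- log10(values)
  sw_final <- stats::shapiro.test(lv)$p.value
  list(transform = "log10", values = lv, shapiro_p_raw = sw_raw,
       shapiro_p_final = sw_final, levene_p = lev, degenerate = FALSE,
       flag = if (sw_final <= alpha) "nonnormal_after_log10"
              else NA_character_)
}

# Tidy a car::Anova table into term/statistic/df/p rows.
.tidy_anova <- function(tab) {
  stat_col <- intersect(c("F value", "Chisq"), colnames(tab))[1L]
  keep <- !rownames(tab) %in% c("(Intercept)", "Residuals")
  data.frame(term = rownames(tab)[keep],
             statistic = tab[keep, stat_col],
             df = tab[keep, "Df"],
             p = tab[keep, grep("^Pr", colnames(tab))],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Factorial ANOVA with an automated interaction drop rule
#'
#' Fits the full treatment-by-sex interaction model with type III sums of
#' squares under sum-to-zero contrasts. When the interaction is not
#' significant at `alpha`, the model is refitted without it and type II
#' main-effect tests are reported instead — automating the staged rule used
#' for the metabolic endpoints. `type = "II"` skips the interaction stage
#' (the convention used for the morphometric endpoints), and a single
#' factor yields a one-way ANOVA.
#'
#' @param data data frame containing `response` and the factor columns.
#' @param response name of the response column.
#' @param factors character vector of one or two factor names.
#' @param alpha significance level for the interaction drop rule.
#' @param type `"auto"` (type III with drop rule) or `"II"`.
#' @return an object of class `aero_stat`: a list with the fitted `model`,
#'   a tidy `anova` table, `anova_type`, `interaction_p` (when staged) and
#'   `alpha`.
#' @examples
#' d <- expand.grid(treatment = c("sham", "ligated"),
#'                  sex = c("female", "male"), rep = 1:5)
#' d$y <- rnorm(nrow(d), 10)
#' factorial_anova(d, "y")$anova
#' @export
factorial_anova <- function(data, response, factors = c("treatment", "sex"),
                            alpha = 0.05, type = c("auto", "II")) {
  type <- match.arg(type)
  stopifnot(is.data.frame(data), response %in% names(data),
            all(factors %in% names(data)), length(factors) %in% 1:2)
  d <- data[is.finite(data[[response]]), c(response, factors)]
  for (f in factors) d[[f]] <- factor(d[[f]])
  ctr <- stats::setNames(rep(list("contr.sum"), length(factors)), factors)

  if (length(factors) == 1L) {
    fml <- stats::reformulate(factors, response)
    fit <- stats::lm(fml, data = d, contrasts = ctr)
    return(structure(list(model = fit,
                          anova = .tidy_anova(car::Anova(fit, type = 2)),
                          anova_type = "II", interaction_p = NA_real_,
                          alpha = alpha),
                     class = "aero_stat"))
  }

  cell_n <- table(d[[factors[1L]]], d[[factors[2L]]])
  if (any(cell_n == 0L)) {
    stop("empty design cell: type III analysis undefined", call. = FALSE)
  }
  if (type == "II") {
    fml <- stats::reformulate(paste(factors, collapse = " + "), response)
    fit <- stats::lm(fml, data = d, contrasts = ctr)
    return(structure(list(model = fit,
                          anova = .tidy_anova(car::Anova(fit, type = 2)),
                          anova_type = "II", interaction_p = NA_real_,
                          alpha = alpha),
                     class = "aero_stat"))
  }
  fml_full <- stats::reformulate(paste(factors, collapse = " * "), response)
  fit_full <- stats::lm(fml_full, data = d, contrasts = ctr)
  tab3 <- .tidy_anova(car::Anova(fit_full, type = 3))
  int_term <- paste(factors, collapse = ":")
  p_int <- tab3$p[tab3$term == int_term]
  if (length(p_int) == 1L && !is.na(p_int) && p_int < alpha) {
    return(structure(list(model = fit_full, anova = tab3, anova_type = "III",
                          interaction_p = p_int, alpha = alpha),
                     class = "aero_stat"))
  }
  fml_add <- stats::reformulate(paste(factors, collapse = " + "), response)
  fit_add <- stats::lm(fml_add, data = d, contrasts = ctr)
  structure(list(model = fit_add,
                 anova = .tidy_anova(car::Anova(fit_add, type = 2)),
                 anova_type = "II",
                 interaction_p = if (length(p_int)) p_int else NA_real_,
                 alpha = alpha),
            class = "aero_stat")
}

# Candidate fixed-effect structures: all main effects plus every subset of
# the two-way interactions, plus the full factorial.
.lmm_candidates <- function(fixed) {
  mains <- paste(fixed, collapse = " + ")
  if (length(fixed) < 2L) return(mains)
  twoway <- utils::combn(fixed, 2L, paste, collapse = ":")
  cands <- mains
  for (k in seq_along(twoway)) {
    sets <- utils::combn(twoway, k, simplify = FALSE)
    cands <- c(cands, vapply(sets, function(s) {
      paste(c(mains, s), collapse = " + ")
    }, ""))
  }
  if (length(fixed) >= 3L) {
    cands <- c(cands, paste(fixed, collapse = " * "))
  }
  unique(cands)
}

#' Repeated-measures linear mixed model with BIC selection
#'
#' For endpoints measured repeatedly on the same fish. Candidate
#' fixed-effect structures (all main effects, every subset of two-way
#' interactions, and the full factorial) are fitted by maximum likelihood
#' with a per-fish random intercept and compared by BIC; the winning model
#' is refitted by REML and summarised with type III Wald chi-square tests
#' (and Satterthwaite F tests alongside), plus Tukey-adjusted contrasts
#' across time points. A singular random-effect fit is flagged and refitted
#' as a fixed-effects model with a warning.
#'
#' @param data data frame in long format.
#' @param response response column name.
#' @param fixed character vector of fixed-effect factors (default
#'   `treatment`, `sex`, `time_point`).
#' @param random name of the grouping column for the random intercept.
#' @param alpha significance level.
#' @param contrast_margin factor over which Tukey contrasts are computed.
#' @return an object of class `aero_stat` with elements `model`, `anova`
#'   (Wald chi-square), `anova_f` (Satterthwaite), `bic` (per candidate),
#'   `formula`, `contrasts`, `letters`, `singular`, `alpha`.
#' @export
repeated_measures_lmm <- function(data, response,
                                  fixed = c("treatment", "sex", "time_point"),
                                  random = "fish_id", alpha = 0.05,
                                  contrast_margin = "time_point") {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(fixed %in% names(data)), random %in% names(data))
  d <- data[is.finite(data[[response]]),
            c(response, fixed, random), drop = FALSE]
  for (f in c(fixed, random)) d[[f]] <- factor(d[[f]])
  if (nlevels(d[[contrast_margin]]) < 2L ||
      anyDuplicated(d[[random]]) == 0L) {
    stop("repeated-measures model needs >= 2 time points and repeated fish",
         call. = FALSE)
  }
  old <- options(contrasts = c("contr.sum", "contr.poly"))
  on.exit(options(old), add = TRUE)

  cands <- .lmm_candidates(fixed)
  fmls <- sprintf("%s ~ %s + (1 | %s)", response, cands, random)
  bics <- vapply(fmls, function(f) {
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(stats::as.formula(f), data = d, REML = FALSE)
    ))
    stats::BIC(fit)
  }, 0)
  best <- which.min(bics)
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(stats::as.formula(fmls[best]), data = d, REML = TRUE)
  ))
  singular <- lme4::isSingular(fit)
  if (singular) {
    warning("random-intercept fit is singular; falling back to a ",
            "fixed-effects model", call. = FALSE)
    fit_fb <- stats::lm(stats::reformulate(cands[best], response), data = d)
    wald <- .tidy_anova(car::Anova(fit_fb, type = 3))
    anova_f <- wald
    model <- fit_fb
  } else {
    model <- fit
    wald <- .tidy_anova(car::Anova(fit, type = 3,
                                   test.statistic = "Chisq"))
    ftab <- stats::anova(fit, type = 3)
    anova_f <- data.frame(term = rownames(ftab),
                          statistic = ftab[, "F value"],
                          df = ftab[, "NumDF"], den_df = ftab[, "DenDF"],
                          p = ftab[, "Pr(>F)"],
                          stringsAsFactors = FALSE, row.names = NULL)
  }
  ctr <- tukey_contrasts(model, contrast_margin, alpha = alpha, data = d)
  structure(list(model = model, anova = wald, anova_f = anova_f,
                 bic = stats::setNames(bics, cands), formula = fmls[best],
                 contrasts = ctr$contrasts, letters = ctr$letters,
                 singular = singular, alpha = alpha),
            class = "aero_stat")
}

#' Tukey-adjusted pairwise contrasts with a letter display
#'
#' All pairwise differences between the levels of `margin`, family-wise
#' adjusted by the Tukey method on estimated marginal means, together with a
#' compact letter display (levels sharing no letter differ at `alpha`).
#'
#' @param model a fitted `lm` or `lmer` model.
#' @param margin name of the factor to compare.
#' @param alpha significance level for the letter display.
#' @param data the model frame (needed by emmeans for some fits).
#' @return list with `emmeans` (marginal means), `contrasts` (data frame)
#'   and `letters` (named character vector); both `NULL` when the margin
#'   has a single level.
#' @export
tukey_contrasts <- function(model, margin, alpha = 0.05, data = NULL) {
  emm <- if (is.null(data)) {
    emmeans::emmeans(model, specs = margin)
  } else {
    emmeans::emmeans(model, specs = margin, data = data)
  }
  emm_df <- as.data.frame(emm)
  if (nrow(emm_df) < 2L) {
    return(list(emmeans = emm_df, contrasts = NULL, letters = NULL))
  }
  prs <- as.data.frame(summary(emmeans::contrast(emm, method = "pairwise"),
                               adjust = "tukey"))
  lv <- as.character(emm_df[[margin]])
  sides <- do.call(rbind, strsplit(as.character(prs$contrast), " - "))
  # emmeans may wrap level names in parentheses inside contrast labels
  strip <- function(x) gsub("^\\(|\\)$", "", x)
  pairs_df <- data.frame(level1 = strip(sides[, 1L]),
                         level2 = strip(sides[, 2L]),
                         p = prs$p.value, stringsAsFactors = FALSE)
  list(emmeans = emm_df, contrasts = prs,
       letters = letter_display(lv, pairs_df, alpha = alpha))
}

#' Compact letter display from pairwise comparisons
#'
#' Insert-and-absorb algorithm: levels sharing a letter are not
#' significantly different; every significant pair shares no letter.
#'
#' @param levels character vector of level names, in display order.
#' @param pairs data frame with columns `level1`, `level2`, `p`.
#' @param alpha significance threshold.
#' @return named character vector of letter strings.
#' @examples
#' letter_display(c("a", "b", "c"),
#'                data.frame(level1 = c("a", "a", "b"),
#'                           level2 = c("b", "c", "c"),
#'                           p = c(0.01, 0.01, 0.9)))
#' @export
letter_display <- function(levels, pairs, alpha = 0.05) {
  stopifnot(all(pairs$level1 %in% levels), all(pairs$level2 %in% levels))
  sets <- list(levels)
  sig <- pairs[!is.na(pairs$p) & pairs$p < alpha, , drop = FALSE]
  for (i in seq_len(nrow(sig))) {
    a <- sig$level1[i]
    b <- sig$level2[i]
    new_sets <- list()
    for (s in sets) {
      if (a %in% s && b %in% s) {
        new_sets <- c(new_sets, list(setdiff(s, a)), list(setdiff(s, b)))
      } else {
        new_sets <- c(new_sets, list(s))
      }
    }
    # absorb: drop sets contained in another set
    keep <- rep(TRUE, length(new_sets))
    for (j in seq_along(new_sets)) {
      for (k in seq_along(new_sets)) {
        if (j != k && keep[k] &&
            all(new_sets[[j]] %in% new_sets[[k]]) &&
            (length(new_sets[[j]]) < length(new_sets[[k]]) || j > k)) {
          keep[j] <- FALSE
          break
        }
      }
    }
    sets <- unique(new_sets[keep])
    sets <- sets[vapply(sets, length, 1L) > 0L]
  }
  ord <- order(vapply(sets, function(s) min(match(s, levels)), 1L))
  sets <- sets[ord]
  out <- stats::setNames(rep("", length(levels)), levels)
  for (j in seq_along(sets)) {
    out[sets[[j]]] <- paste0(out[sets[[j]]], letters[j])
  }
  out
}

#' Cell means and standard errors
#'
#' @param data data frame.
#' @param response response column name.
#' @param by character vector of grouping columns.
#' @return data frame with `n`, `mean`, `sem` (`NA` with a flag when
#'   `n = 1`) and a formatted `label` ("mean +/- s.e.m.") per cell.
#' @examples
#' group_summary(data.frame(g = "x", y = c(2, 4)), "y", "g")
#' @export
group_summary <- function(data, response, by) {
  stopifnot(is.data.frame(data), response %in% names(data),
            all(by %in% names(data)))
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  if (nrow(d) == 0L) stop("no finite observations", call. = FALSE)
  agg <- stats::aggregate(d[[response]], d[, by, drop = FALSE], function(v) {
    c(n = length(v), mean = mean(v),
      sem = if (length(v) > 1L) stats::sd(v) / sqrt(length(v)) else NA_real_)
  })
  out <- cbind(agg[by], as.data.frame(agg$x))
  out$flag <- ifelse(out$n == 1L, "sem_undefined", NA_character_)
  out$label <- ifelse(is.na(out$sem),
                      sprintf("%.3g", out$mean),
                      sprintf("%.3g ± %.3g", out$mean, out$sem))
  out
}

#' Gate, guard and test one endpoint table
#'
#' Convenience wrapper running the full staged workflow on one endpoint:
#' the assumption gate (with log10 fallback), a minimum-cell-size guard that
#' drops sex from the design when any treatment-by-sex cell is smaller than
#' `min_cell` (the low-n rule used for EPOC and thermal-limit endpoints),
#' and the factorial ANOVA with the interaction drop rule.
#'
#' @param data data frame with the endpoint and factor columns.
#' @param response endpoint column name.
#' @param factors design factors (default treatment and sex).
#' @param alpha significance level.
#' @param min_cell minimum observations per cell before sex is dropped.
#' @param type passed to [factorial_anova()].
#' @return an `aero_stat` object with `gate` and `factors_used` attached.
#' @export
analyze_endpoint <- function(data, response,
                             factors = c("treatment", "sex"), alpha = 0.05,
                             min_cell = 5, type = "auto") {
  d <- data[is.finite(data[[response]]), , drop = FALSE]
  gate <- assumption_gate(d[[response]],
                          group = if ("treatment" %in% factors)
                            d$treatment,
                          alpha = alpha)
  if (gate$transform == "log10") d[[response]] <- log10(d[[response]])
  if (length(factors) == 2L) {
    cell_n <- table(d[[factors[1L]]], d[[factors[2L]]])
    if (any(cell_n < min_cell)) factors <- setdiff(factors, "sex")
  }
  res <- factorial_anova(d, response, factors, alpha = alpha, type = type)
  res$gate <- gate
  res$factors_used <- factors
  res
}

#' @export
print.aero_stat <- function(x, ...) {
  cat("ANOVA (type ", x$anova_type %||% "III", ")\n", sep = "")
  print(x$anova, digits = 4)
  invisible(x)
}
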
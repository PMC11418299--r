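test_that("the assumption gate is calibrated and transforms lognormal data", {
  set.seed(1)
  rejections <- vapply(1:300, function(i) {
    assumption_gate(rnorm(50, 10, 1))$transform != "none"
  }, TRUE)
  expect_gt(mean(rejections), 0.005)
  expect_lt(mean(rejections), 0.11)

  set.seed(4)
  g <- assumption_gate(rlnorm(50, 0, 1))
  expect_equal(g$transform, "log10")
  expect_lte(g$shapiro_p_raw, 0.05)
  expect_gt(g$shapiro_p_final, 0.05)

  d <- assumption_gate(rep(7, 10))
  expect_true(d$degenerate)
  expect_equal(d$flag, "zero_variance")

  set.seed(6)
  neg <- assumption_gate(c(rlnorm(49, 0, 1), -1))
  expect_equal(neg$flag, "transform_impossible")
})

test_that("factorial ANOVA reproduces hand-computed sums of squares", {
  # balanced 2x2, n = 3 per cell, integer data
  d <- data.frame(
    treatment = rep(c("sham", "ligated"), each = 6),
    sex = rep(rep(c("female", "male"), each = 3), 2),
    y = c(5, 6, 7, 8, 9, 10, 3, 4, 5, 4, 5, 6)
  )
  n <- 3
  cm <- with(d, tapply(y, list(treatment, sex), mean))
  gm <- mean(d$y)
  ss_a <- n * 2 * sum((rowMeans(cm) - gm)^2)
  ss_b <- n * 2 * sum((colMeans(cm) - gm)^2)
  ss_ab <- n * sum((cm - outer(rowMeans(cm), colMeans(cm), `+`) + gm)^2)
  ss_e <- sum((d$y - cm[cbind(d$treatment, d$sex)])^2)
  df_e <- nrow(d) - 4
  res <- factorial_anova(d, "y")
  tab <- res$anova
  f_of <- function(term) tab$statistic[tab$term == term]
  if (res$anova_type == "III") {
    expect_equal(f_of("treatment:sex"), (ss_ab / 1) / (ss_e / df_e))
    expect_equal(f_of("treatment"), (ss_a / 1) / (ss_e / df_e))
    expect_equal(f_of("sex"), (ss_b / 1) / (ss_e / df_e))
  } else {
    # additive refit: error now pools the interaction
    ss_e2 <- ss_e + ss_ab
    df_e2 <- df_e + 1
    expect_equal(f_of("treatment"), (ss_a / 1) / (ss_e2 / df_e2))
    expect_equal(f_of("sex"), (ss_b / 1) / (ss_e2 / df_e2))
  }
})

test_that("equal cell means with shared residuals give F = 0 exactly", {
  d <- expand.grid(treatment = c("sham", "ligated"),
                   sex = c("female", "male"), rep = 1:3)
  d$y <- 10 + c(-1, 0, 1)[d$rep]
  res <- factorial_anova(d, "y")
  expect_true(all(abs(res$anova$statistic) < 1e-20))
})

test_that("type II and type III coincide on balanced designs", {
  set.seed(9)
  d <- expand.grid(treatment = c("sham", "ligated"),
                   sex = c("female", "male"), rep = 1:6)
  d$y <- rnorm(nrow(d), 10, 1)
  for (f in c("treatment", "sex")) d[[f]] <- factor(d[[f]])
  ctr <- list(treatment = "contr.sum", sex = "contr.sum")
  fit <- lm(y ~ treatment * sex, d, contrasts = ctr)
  t2 <- car::Anova(fit, type = 2)
  t3 <- car::Anova(fit, type = 3)
  for (term in c("treatment", "sex", "treatment:sex")) {
    expect_equal(t2[term, "Sum Sq"], t3[term, "Sum Sq"], tolerance = 1e-10)
  }
})

test_that("the interaction drop rule is automated", {
  set.seed(10)
  d <- expand.grid(treatment = c("sham", "ligated"),
                   sex = c("female", "male"), rep = 1:8)
  # additive truth: interaction should be dropped, type II reported
  d$y <- 10 + 2 * (d$treatment == "ligated") + 1 * (d$sex == "male") +
    rnorm(nrow(d), 0, 0.8)
  res_add <- factorial_anova(d, "y")
  expect_equal(res_add$anova_type, "II")
  expect_false("treatment:sex" %in% res_add$anova$term)
  # strong crossover interaction: type III on the full model is kept
  d$y2 <- 10 + 3 * (d$treatment == "ligated") * (d$sex == "male") +
    rnorm(nrow(d), 0, 0.3)
  res_int <- factorial_anova(d, "y2")
  expect_equal(res_int$anova_type, "III")
  expect_true("treatment:sex" %in% res_int$anova$term)
  # empty cell: type III undefined
  d_empty <- d[!(d$treatment == "sham" & d$sex == "male"), ]
  expect_error(factorial_anova(d_empty, "y"), "empty design cell")
})

test_that("an additive truth rarely retains the interaction", {
  set.seed(12)
  kept <- vapply(1:40, function(i) {
    d <- expand.grid(treatment = c("sham", "ligated"),
                     sex = c("female", "male"), rep = 1:8)
    d$y <- 10 + 1.5 * (d$treatment == "ligated") + (d$sex == "male") +
      rnorm(nrow(d), 0, 1)
    factorial_anova(d, "y")$anova_type == "III"
  }, TRUE)
  expect_lte(mean(kept), 0.10 + 3 * sqrt(0.05 * 0.95 / 40))
})

make_repeated <- function(n_fish = 12, fish_sd = 2, resid_sd = 1,
                          treat_effect = 0, time_effect = c(0, 4, 2, 1)) {
  d <- expand.grid(fish_id = sprintf("f%02d", 1:n_fish),
                   time_point = c("0", "15", "60", "rest"))
  d$treatment <- ifelse(as.integer(factor(d$fish_id)) <= n_fish / 2,
                        "sham", "ligated")
  d$sex <- ifelse(as.integer(factor(d$fish_id)) %% 2 == 0, "female",
                  "male")
  fe <- rnorm(n_fish, 0, fish_sd)
  d$y <- 20 + time_effect[as.integer(factor(d$time_point))] +
    treat_effect * (d$treatment == "ligated") +
    fe[as.integer(factor(d$fish_id))] + rnorm(nrow(d), 0, resid_sd)
  d
}

test_that("zero between-fish variance falls back to a fixed-effects fit", {
  set.seed(15)
  d <- make_repeated(fish_sd = 0, resid_sd = 1, time_effect = c(0, 3, 1, 0))
  expect_warning(res <- repeated_measures_lmm(d, "y"), "singular")
  expect_true(res$singular)
  expect_s3_class(res$model, "lm")
  p_time <- res$anova$p[res$anova$term == "time_point"]
  expect_lt(p_time, 0.001)
})

test_that("the mixed model detects time and treatment structure", {
  set.seed(16)
  d <- make_repeated(n_fish = 30, fish_sd = 2, resid_sd = 1.5,
                     treat_effect = 5, time_effect = c(0, 8, 4, 1))
  res <- repeated_measures_lmm(d, "y")
  expect_false(res$singular)
  expect_lt(res$anova$p[res$anova$term == "time_point"], 1e-4)
  expect_lt(res$anova$p[res$anova$term == "treatment"], 0.01)
  # Satterthwaite table accompanies the Wald table
  expect_true(all(c("statistic", "den_df") %in% names(res$anova_f)))
  # Tukey letters cover every time point
  expect_setequal(names(res$letters), c("0", "15", "60", "rest"))
})

test_that("treatment detection power at study-scale effects is high", {
  set.seed(17)
  hits <- vapply(1:12, function(i) {
    d <- make_repeated(n_fish = 30, fish_sd = 2, resid_sd = 2,
                       treat_effect = 6, time_effect = c(0, 10, 6, 1))
    res <- suppressWarnings(repeated_measures_lmm(d, "y"))
    res$anova$p[res$anova$term == "treatment"] < 0.05
  }, TRUE)
  expect_gte(mean(hits), 0.8)
})

test_that("BIC model choice is invariant to response rescaling", {
  set.seed(18)
  d <- make_repeated(n_fish = 16, fish_sd = 1.5, resid_sd = 1,
                     treat_effect = 3)
  a <- suppressWarnings(repeated_measures_lmm(d, "y"))
  d$y <- d$y * 10
  b <- suppressWarnings(repeated_measures_lmm(d, "y"))
  expect_equal(sub(".*~", "", a$formula), sub(".*~", "", b$formula))
  # all candidates shift by the same additive constant 2 * n * log(c)
  shift <- b$bic - a$bic
  expect_lt(diff(range(shift)), 1e-6)
})

test_that("Tukey contrasts reduce to the unadjusted test for two levels", {
  set.seed(19)
  d <- data.frame(g = rep(c("a", "b"), each = 8),
                  y = rnorm(16, 10) + rep(c(0, 1), each = 8))
  fit <- lm(y ~ g, d)
  ctr <- tukey_contrasts(fit, "g")
  raw <- summary(emmeans::contrast(emmeans::emmeans(fit, "g"),
                                   method = "pairwise"), adjust = "none")
  expect_equal(ctr$contrasts$p.value, raw$p.value, tolerance = 1e-10)
})

test_that("identical means with tiny noise yield one shared letter", {
  set.seed(20)
  d <- data.frame(g = rep(letters[1:5], each = 6),
                  y = rnorm(30, 10, 1))
  fit <- lm(y ~ g, d)
  ctr <- tukey_contrasts(fit, "g")
  expect_true(all(ctr$contrasts$p.value > 0.05))
  expect_true(all(ctr$letters == ctr$letters[1]))
})

test_that("letter displays are consistent with the significance matrix", {
  hand <- letter_display(
    c("a", "b", "c"),
    data.frame(level1 = c("a", "a", "b"), level2 = c("b", "c", "c"),
               p = c(0.01, 0.01, 0.9))
  )
  expect_false(any(strsplit(hand[["a"]], "")[[1]] %in%
                     strsplit(hand[["b"]], "")[[1]]))
  expect_true(any(strsplit(hand[["b"]], "")[[1]] %in%
                    strsplit(hand[["c"]], "")[[1]]))
  # property: significant pairs never share a letter; non-significant do
  set.seed(21)
  for (r in 1:20) {
    lv <- letters[1:5]
    prs <- t(combn(lv, 2))
    p <- runif(nrow(prs))
    # enforce transitivity-compatible structure by thresholding a 1-D layout
    pos <- sort(runif(5, 0, 4))
    names(pos) <- lv
    p <- ifelse(abs(pos[prs[, 1]] - pos[prs[, 2]]) > 1.2, 0.01, 0.5)
    lets <- letter_display(lv, data.frame(level1 = prs[, 1],
                                          level2 = prs[, 2], p = p))
    share <- function(x, y) {
      any(strsplit(lets[[x]], "")[[1]] %in% strsplit(lets[[y]], "")[[1]])
    }
    for (i in seq_len(nrow(prs))) {
      if (p[i] < 0.05) expect_false(share(prs[i, 1], prs[i, 2]))
      else expect_true(share(prs[i, 1], prs[i, 2]))
    }
  }
})

test_that("letter displays agree with multcomp's on a worked example", {
  skip_if_not_installed("multcomp")
  set.seed(22)
  d <- data.frame(g = factor(rep(c("a", "b", "c"), each = 10)),
                  y = rnorm(30, rep(c(0, 0.3, 4), each = 10), 1))
  fit <- aov(y ~ g, d)
  glht <- multcomp::glht(fit, linfct = multcomp::mcp(g = "Tukey"))
  ref <- multcomp::cld(glht)$mcletters$Letters
  ours <- tukey_contrasts(fit, "g")$letters
  share <- function(lets, x, y) {
    any(strsplit(lets[[x]], "")[[1]] %in% strsplit(lets[[y]], "")[[1]])
  }
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    expect_equal(share(ours, pair[1], pair[2]),
                 share(as.list(ref), pair[1], pair[2]))
  }
})

test_that("group summaries report mean and s.e.m. with degenerate flags", {
  gs <- group_summary(data.frame(g = "x", y = c(2, 4)), "y", "g")
  expect_equal(gs$mean, 3)
  expect_equal(gs$sem, 1)
  expect_match(gs$label, "3 ± 1")
  one <- group_summary(data.frame(g = c("x", "x", "z"), y = c(1, 3, 5)),
                       "y", "g")
  expect_true(is.na(one$sem[one$g == "z"]))
  expect_equal(one$flag[one$g == "z"], "sem_undefined")
})

test_that("the endpoint wrapper applies the low-n guard and transform", {
  set.seed(23)
  d <- data.frame(
    treatment = rep(c("sham", "ligated"), c(10, 10)),
    sex = rep(c("female", "male"), 10),
    y = rlnorm(20, log(100), 0.6)
  )
  d$sex[d$treatment == "sham"][1:9] <- "female"  # starve one cell
  res <- analyze_endpoint(d, "y", min_cell = 5)
  expect_equal(res$factors_used, "treatment")
  expect_equal(res$gate$transform,
               assumption_gate(d$y)$transform)
})
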
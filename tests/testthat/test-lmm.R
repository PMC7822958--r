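spec2 <- lmm_spec_model2()

test_that("mixed-model fits are deterministic and recover a known direction effect", {
  tab <- make_lmm_table(n_participants = 16, direction_effect = 0.08, seed = 2)
  m1 <- fit_lmm(tab, spec2)
  m2 <- fit_lmm(tab, spec2)
  expect_identical(coef(m1), coef(m2))
  # direction effect within 2 SE of truth: difference of the two cell means
  em <- posthoc_contrasts(m1, specs = "direction")
  d <- em$estimates
  est <- d$emmean[d$direction == "rostro_caudal"] -
    d$emmean[d$direction == "caudo_rostral"]
  se <- sqrt(sum(d$SE^2))
  expect_lt(abs(est - 0.08), 2 * se)
})

test_that("zero between-participant variance yields near-zero random intercepts", {
  tab <- make_lmm_table(n_participants = 12, sd_participant_stream = 0,
                        sd_participant_level = 0, sd_noise = 0.05, seed = 4)
  m <- suppressWarnings(fit_lmm(tab, spec2))
  vc <- as.data.frame(lme4::VarCorr(m$fit))
  re <- vc$vcov[vc$grp != "Residual"]
  expect_lt(max(re), 1e-4)
})

test_that("Type III F on a balanced one-factor design equals classical ANOVA", {
  # balanced within-participant design: the REML fit with a participant
  # random intercept reproduces the classical blocked ANOVA F exactly
  set.seed(9)
  n <- 12; reps <- 6
  tab <- expand.grid(participant = sprintf("p%02d", 1:n),
                     direction = c("rostro_caudal", "caudo_rostral"),
                     rep = seq_len(reps), stringsAsFactors = FALSE)
  re <- rnorm(n, 0, 0.05)
  tab$dc <- 0.3 + 0.04 * (tab$direction == "rostro_caudal") +
    re[match(tab$participant, unique(tab$participant))] +
    rnorm(nrow(tab), 0, 0.08)
  tab$stream <- 1; tab$level_pair <- "1-2"
  m <- fit_lmm(tab, lmm_spec(factors = "direction",
                             covariates = character(0),
                             random = "participant", REML = TRUE))
  f_lmm <- m$anova$F[m$anova$term == "direction"]
  cl <- summary(aov(dc ~ direction + Error(participant), data = tab))
  f_aov <- cl[["Error: Within"]][[1]]["direction", "F value"]
  expect_equal(f_lmm, f_aov, tolerance = 1e-6)
})

test_that("top-down reduction removes only removable non-significant maximal terms", {
  # data with ONLY a direction main effect: all interactions with duration
  # should be removed, the main effect retained
  tab <- make_lmm_table(n_participants = 14, direction_effect = 0.1,
                        sd_noise = 0.04, seed = 11)
  m <- reduce_model(tab, spec2)
  expect_true("direction" %in% m$terms)
  expect_false("direction:state:duration_before_implant" %in% m$terms)
  expect_true(all(m$history$p_at_removal > 0.05))
  # marginality audit: replay the history; every removed term was maximal
  # (not contained in another term present) at its removal step
  all_terms <- attr(terms(~ direction * state * duration_before_implant),
                    "term.labels")
  current <- all_terms
  for (k in seq_len(nrow(m$history))) {
    t_rm <- m$history$term[k]
    vars <- strsplit(t_rm, ":")[[1]]
    contained <- vapply(setdiff(current, t_rm), function(tt) {
      all(vars %in% strsplit(tt, ":")[[1]])
    }, logical(1))
    expect_false(any(contained))
    expect_gte(length(vars), 2)  # main effects are never removed
    current <- setdiff(current, t_rm)
  }
  expect_setequal(current, m$terms)
  # an already parsimonious model comes back unchanged
  tab2 <- make_lmm_table(n_participants = 14, direction_effect = 0.1,
                         state_dir_dur_slope = -0.01, sd_noise = 0.02,
                         seed = 12)
  m2 <- reduce_model(tab2, spec2)
  expect_equal(nrow(m2$history), 0)
  expect_true("direction:state:duration_before_implant" %in% m2$terms)
})

test_that("variance inflation factors match the closed form and flag collinearity", {
  set.seed(5)
  n <- 400
  # orthogonal predictors -> VIF 1
  x1 <- rnorm(n); x2 <- rnorm(n)
  x2 <- residuals(lm(x2 ~ x1))
  d <- data.frame(x1 = x1, x2 = x2)
  v <- vif_check(d, c("x1", "x2"))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-10)
  # two correlated predictors: VIF = 1 / (1 - r^2)
  y <- 0.6 * x1 + sqrt(1 - 0.36) * rnorm(n)
  d2 <- data.frame(x1 = x1, y = y)
  r <- cor(x1, y)
  expect_equal(vif_check(d2, c("x1", "y"))$vif,
               rep(1 / (1 - r^2), 2), tolerance = 1e-8)
  # perfect collinearity reported as infinite and flagged
  d3 <- data.frame(x1 = x1, x1b = x1, x2 = x2)
  v3 <- vif_check(d3, c("x1", "x1b", "x2"))
  expect_true(all(is.infinite(v3$vif[1:2])))
  expect_true(all(v3$flagged[1:2]))
  expect_error(vif_check(d, "x1"), ">= 2 predictors")
})

test_that("VIF agrees with the car package on a multi-predictor design", {
  skip_if_not_installed("car")
  tab <- make_lmm_table(n_participants = 20, seed = 6)
  preds <- c("duration_before_implant", "time_since_implant", "ledd", "vat")
  mine <- vif_check(tab, preds)
  fit <- lm(dc ~ duration_before_implant + time_since_implant + ledd + vat,
            data = tab)
  expect_equal(mine$vif, unname(car::vif(fit)), tolerance = 1e-8)
})

test_that("post-hoc contrasts are Tukey-adjusted and null for identical groups", {
  tab <- make_lmm_table(n_participants = 14, direction_effect = 0,
                        sd_noise = 0.05, seed = 21)
  m <- fit_lmm(tab, lmm_spec(factors = c("direction", "state"),
                             covariates = character(0)))
  pc <- posthoc_contrasts(m, specs = c("direction", "state"))
  expect_true(all(abs(pc$contrasts$estimate) < 0.02))
  expect_true(all(pc$contrasts$p.value > 0.05))
  # adjusted p >= unadjusted p for every pair
  em <- emmeans::emmeans(m$fit, ~ direction * state, lmer.df = "satterthwaite")
  unadj <- summary(emmeans::contrast(em, "pairwise", adjust = "none"))$p.value
  expect_true(all(pc$contrasts$p.value >= unadj - 1e-12))
  # confidence bounds present at the 95% level
  expect_true(all(c("lower.CL", "upper.CL") %in% names(pc$estimates)))
})

test_that("simple-slope contrasts recover a state-dependent duration slope", {
  tab <- make_lmm_table(n_participants = 20, direction_effect = 0.08,
                        state_dir_dur_slope = -0.006, sd_noise = 0.04,
                        seed = 31)
  m <- reduce_model(tab, spec2)
  pc <- posthoc_contrasts(m, specs = c("direction", "state"),
                          var = "duration_before_implant")
  sl <- pc$estimates
  on_rc <- sl$duration_before_implant.trend[sl$direction == "rostro_caudal" &
                                              sl$state == "ON"]
  off_rc <- sl$duration_before_implant.trend[sl$direction == "rostro_caudal" &
                                               sl$state == "OFF"]
  expect_lt(on_rc, off_rc)
})

test_that("covariate substitution refits under derived time covariates", {
  tab <- make_lmm_table(n_participants = 16, direction_effect = 0.08,
                        state_dir_dur_slope = -0.006, sd_noise = 0.04,
                        seed = 41)
  spec1 <- lmm_spec(factors = c("direction", "state"),
                    covariates = c("age_at_onset", "duration_before_implant",
                                   "time_since_implant"))
  # chronological age is the exact sum of the three time covariates
  sub2 <- covariate_substitution_refit(tab, spec1, "chronological_age")
  expect_equal(sub2$data$chronological_age,
               tab$age_at_onset + tab$duration_before_implant +
                 tab$time_since_implant)
  expect_equal(sub2$control, "chronological_age")
  expect_true("chronological_age" %in% sub2$spec$covariates)
  expect_false("duration_before_implant" %in% sub2$spec$covariates)
  # substituting by a perfect copy: when time-since has zero spread the
  # overall duration is the original duration shifted by a constant, and
  # the moderator F is unchanged
  tabc <- tab
  tabc$time_since_implant <- 4
  m_orig <- reduce_model(tabc, lmm_spec(factors = c("direction", "state"),
                                        covariates = "duration_before_implant"))
  m_sub <- covariate_substitution_refit(
    tabc, lmm_spec(factors = c("direction", "state"),
                   covariates = c("duration_before_implant",
                                  "time_since_implant")),
    "overall_duration")
  f1 <- m_orig$anova
  f2 <- m_sub$anova
  key1 <- f1$F[f1$term == "direction:state:duration_before_implant"]
  key2 <- f2$F[f2$term == "direction:state:overall_duration"]
  if (length(key1) && length(key2)) {
    expect_equal(key1, key2, tolerance = 1e-6)
  } else {
    # both reductions must have made the same retention decision
    expect_equal(length(key1), length(key2))
  }
  # constant derived covariate is refused
  tab0 <- tab
  tab0$age_at_onset <- 50 - tab0$duration_before_implant - tab0$time_since_implant
  expect_error(covariate_substitution_refit(tab0, spec1, "chronological_age"),
               "constant")
})
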
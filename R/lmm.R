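#' Mixed-model specification for connection-table analyses
#'
#' Describes the initial (maximal) fixed-effects structure: every factor
#' interaction crossed with each covariate in its own block (all lower-order
#' terms included), plus the two random intercepts — stream within
#' participant and level pair within participant — which are never reduced.
#' The primary model crosses direction x hemisphere x stimulation state with
#' each of five covariates; the replication model uses
#' direction x stimulation state x pre-implant disease duration.
#'
#' @param factors Character vector of factor names in the connection table.
#' @param covariates Character vector of numeric covariate names (each gets
#'   its own full-interaction block with the factors).
#' @param random Right-hand sides of the random-intercept terms.
#' @param alpha Significance threshold for the top-down reduction.
#' @param center Center covariates before fitting (default `FALSE`:
#'   covariates enter untransformed).
#' @param REML Use restricted maximum likelihood instead of the default
#'   maximum-likelihood fit (ML is the analysis convention here; REML is
#'   useful when comparing balanced designs against classical ANOVA).
#' @return An object of class `lmm_spec`.
#' @export
lmm_spec <- function(factors = c("direction", "hemisphere_label", "state"),
                     covariates = c("age_at_onset", "duration_before_implant",
                                    "time_since_implant", "ledd", "vat"),
                     random = c("participant:stream", "participant:level_pair"),
                     alpha = 0.05, center = FALSE, REML = FALSE) {
  structure(list(factors = factors, covariates = covariates, random = random,
                 alpha = alpha, center = center, REML = REML),
            class = "lmm_spec")
}

#' Replication-model specification (direction x state x duration)
#' @inheritParams lmm_spec
#' @return An `lmm_spec` without the hemisphere factor and with the
#'   pre-implant disease duration as the only covariate.
#' @export
lmm_spec_model2 <- function(alpha = 0.05, center = FALSE) {
  lmm_spec(factors = c("direction", "state"),
           covariates = "duration_before_implant",
           alpha = alpha, center = center)
}

initial_terms <- function(spec) {
  fx <- paste(spec$factors, collapse = " * ")
  if (length(spec$covariates)) {
    paste(vapply(spec$covariates,
                 function(cv) paste0("(", fx, ") * ", cv), character(1)),
          collapse = " + ")
  } else {
    fx
  }
}

lmm_formula <- function(fixed, spec) {
  stats::as.formula(paste("dc ~", fixed, "+",
                          paste(sprintf("(1 | %s)", spec$random),
                                collapse = " + ")))
}

prepare_lmm_data <- function(table, spec) {
  dat <- as.data.frame(table)
  for (f in c(spec$factors, "participant", "stream", "level_pair")) {
    if (!f %in% names(dat)) stop("data error: column missing: ", f)
    dat[[f]] <- factor(dat[[f]])
  }
  for (cv in spec$covariates) {
    if (!cv %in% names(dat)) stop("data error: covariate missing: ", cv)
    if (!is.numeric(dat[[cv]])) stop("data error: covariate not numeric: ", cv)
    if (spec$center) dat[[cv]] <- dat[[cv]] - mean(dat[[cv]])
  }
  # sum-to-zero contrasts: required for meaningful Type III marginal tests
  for (f in spec$factors) stats::contrasts(dat[[f]]) <- stats::contr.sum(nlevels(dat[[f]]))
  dat
}

fit_one <- function(fixed, dat, spec) {
  form <- lmm_formula(fixed, spec)
  fit <- withCallingHandlers(
    suppressWarnings(lmerTest::lmer(form, data = dat,
                                    REML = isTRUE(spec$REML))),
    message = function(m) invokeRestart("muffleMessage"))
  if (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0) {
    stop("estimation error: optimizer did not converge: ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "))
  }
  msgs <- unlist(fit@optinfo$conv$lme4$messages)
  if (any(grepl("failed to converge", msgs))) {
    # lme4's post-hoc gradient check; surfaced, not fatal, on these fits
    warning("convergence check: ", paste(msgs, collapse = "; "))
  }
  fit
}

#' Fit a linear mixed-effects model to a connection table
#'
#' Maximum-likelihood fit of the directed-coherence values with the fixed
#' structure of `spec` and random intercepts for participant x stream and
#' participant x level pair. Unbalanced session structure (participants
#' missing OFF or ON2 measurements) is handled by row absence, without
#' imputation. Singular random-effects fits produce a recorded warning,
#' not an error.
#'
#' @param table A connection table (see [build_connection_table()]).
#' @param spec An [lmm_spec()].
#' @return An object of class `dc_lmm` wrapping the `lmerTest` fit, with
#'   the Type III F table, the model formula, and an (empty) reduction
#'   history.
#' @export
fit_lmm <- function(table, spec = lmm_spec()) {
  dat <- prepare_lmm_data(table, spec)
  fit <- fit_one(initial_terms(spec), dat, spec)
  singular <- lme4::isSingular(fit)
  if (singular) warning("singular random-effects fit")
  structure(list(fit = fit, spec = spec, data = dat,
                 terms = attr(stats::terms(lme4::nobars(stats::formula(fit))),
                              "term.labels"),
                 anova = type3_tests_fit(fit),
                 history = data.frame(step = integer(), term = character(),
                                      p_at_removal = numeric()),
                 singular = singular, reduced = FALSE),
            class = "dc_lmm")
}

type3_tests_fit <- function(fit) {
  tab <- tryCatch({
    a <- stats::anova(fit, type = 3)
    data.frame(term = rownames(a), F = a$`F value`, num_df = a$NumDF,
               den_df = a$DenDF, p = a$`Pr(>F)`, method = "satterthwaite",
               stringsAsFactors = FALSE, row.names = NULL)
  }, error = function(e) NULL)
  if (is.null(tab)) {
    # fallback: likelihood-ratio chi-square per marginal term, flagged
    d1 <- stats::drop1(fit, test = "Chisq")
    tab <- data.frame(term = rownames(d1)[-1], F = NA_real_,
                      num_df = d1$npar[-1], den_df = NA_real_,
                      p = d1$`Pr(Chi)`[-1], method = "LRT",
                      stringsAsFactors = FALSE, row.names = NULL)
  }
  tab
}

#' Type III F tests of the fixed effects
#'
#' One F row per fixed term, with Satterthwaite's approximation of the
#' denominator degrees of freedom. If the Satterthwaite computation fails,
#' likelihood-ratio chi-square tests are reported instead and flagged in
#' the `method` column.
#'
#' @param result A `dc_lmm` from [fit_lmm()] / [reduce_model()].
#' @return Data frame with columns `term`, `F`, `num_df`, `den_df`, `p`,
#'   `method`.
#' @export
type3_tests <- function(result) {
  stopifnot(inherits(result, "dc_lmm"))
  result$anova
}

term_vars <- function(term) strsplit(term, ":", fixed = TRUE)[[1]]

# maximal interaction terms: not contained in any other current term
removable_terms <- function(terms) {
  ord <- vapply(terms, function(t) length(term_vars(t)), integer(1))
  keep <- logical(length(terms))
  for (i in seq_along(terms)) {
    if (ord[i] < 2) next # main effects are protected
    vi <- term_vars(terms[i])
    contained <- any(vapply(seq_along(terms), function(j) {
      j != i && all(vi %in% term_vars(terms[j]))
    }, logical(1)))
    keep[i] <- !contained
  }
  terms[keep]
}

#' Top-down reduction of the fixed-effects structure
#'
#' Starting from the maximal model of `spec`, repeatedly inspects the
#' Type III table, identifies the currently highest-order (maximal)
#' interaction terms, and removes the least significant one with
#' `p > alpha` — one term per iteration, refitting before the next
#' decision. Lower-order terms are always retained with their interactions
#' (marginality), main effects are never removed, and the random structure
#' is never reduced. Stops when every maximal interaction is significant.
#'
#' @param table A connection table.
#' @param spec An [lmm_spec()].
#' @return A `dc_lmm` with `reduced = TRUE` and a `history` data frame
#'   recording each removed term and its p value at removal.
#' @export
reduce_model <- function(table, spec = lmm_spec()) {
  dat <- prepare_lmm_data(table, spec)
  terms <- attr(stats::terms(stats::as.formula(
    paste("~", initial_terms(spec)))), "term.labels")
  history <- data.frame(step = integer(), term = character(),
                        p_at_removal = numeric(), stringsAsFactors = FALSE)
  step <- 0L
  repeat {
    fit <- fit_one(paste(terms, collapse = " + "), dat, spec)
    tab <- type3_tests_fit(fit)
    cand <- removable_terms(terms)
    ct <- tab[tab$term %in% cand & tab$p > spec$alpha, , drop = FALSE]
    if (!nrow(ct)) break
    drop <- ct$term[which.max(ct$p)]
    step <- step + 1L
    history <- rbind(history, data.frame(step = step, term = drop,
                                         p_at_removal = ct$p[which.max(ct$p)],
                                         stringsAsFactors = FALSE))
    terms <- setdiff(terms, drop)
  }
  singular <- lme4::isSingular(fit)
  structure(list(fit = fit, spec = spec, data = dat, terms = terms,
                 anova = tab, history = history, singular = singular,
                 reduced = TRUE),
            class = "dc_lmm")
}

#' @export
print.dc_lmm <- function(x, ...) {
  cat("Linear mixed model of directed coherence",
      if (x$reduced) "(reduced)" else "(maximal)", "\n")
  cat("  fixed terms:", length(x$terms),
      "| random intercepts:", paste(x$spec$random, collapse = ", "), "\n")
  if (nrow(x$history)) {
    cat("  removed", nrow(x$history), "term(s):",
        paste(x$history$term, collapse = ", "), "\n")
  }
  cat("\nType III tests (", x$anova$method[1], " df):\n", sep = "")
  tab <- x$anova
  tab$F <- round(tab$F, 2); tab$den_df <- round(tab$den_df, 1)
  tab$p <- signif(tab$p, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' @export
summary.dc_lmm <- function(object, ...) summary(object$fit, ...)

#' @export
coef.dc_lmm <- function(object, ...) lme4::fixef(object$fit)

#' @export
residuals.dc_lmm <- function(object, ...) stats::residuals(object$fit, ...)

#' @export
anova.dc_lmm <- function(object, ...) object$anova

#' Variance inflation factors of the fixed-effect predictors
#'
#' Computes, for each predictor column of the fixed-effects design built
#' from `terms` (main effects), the variance inflation factor
#' `1 / (1 - R^2_j)` from regressing it on the remaining predictors.
#' Perfectly collinear predictors are reported as `Inf`.
#'
#' @param table A connection table (or any data frame).
#' @param terms Character vector of predictor names (>= 2).
#' @param flag_threshold VIFs at or above this are flagged (default 5).
#' @return Data frame `predictor`, `vif`, `flagged`.
#' @export
vif_check <- function(table, terms, flag_threshold = 5) {
  if (length(terms) < 2) stop("configuration error: need >= 2 predictors")
  X <- stats::model.matrix(
    stats::as.formula(paste("~", paste(terms, collapse = " + "))),
    data = as.data.frame(table))[, -1, drop = FALSE]
  vif <- vapply(seq_len(ncol(X)), function(j) {
    f <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(f$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(predictor = colnames(X), vif = vif,
             flagged = vif >= flag_threshold, row.names = NULL)
}

#' Post-hoc contrasts: least-squares means or simple slopes
#'
#' Least-squares (estimated marginal) means over factor cells, or simple
#' slopes of DC on a covariate within factor cells, with pairwise
#' comparisons adjusted by Tukey's method and 95% confidence bounds.
#'
#' @param result A `dc_lmm`.
#' @param specs Factor names defining the cells (e.g.
#'   `c("state", "direction")`).
#' @param var Covariate name: when given, simple slopes (trends of DC on
#'   `var` per cell) are computed instead of cell means.
#' @return An object of class `contrast_table`: list with `estimates`
#'   (means or slopes with 95% CIs) and `contrasts` (Tukey-adjusted
#'   pairwise comparisons).
#' @export
posthoc_contrasts <- function(result, specs = c("state", "direction"),
                              var = NULL) {
  stopifnot(inherits(result, "dc_lmm"))
  specs <- intersect(specs, names(result$data))
  form <- stats::as.formula(paste("~", paste(specs, collapse = " * ")))
  old <- emmeans::emm_options(lmerTest.limit = 1e6, pbkrtest.limit = 0)
  on.exit(emmeans::emm_options(old), add = TRUE)
  em <- if (is.null(var)) {
    emmeans::emmeans(result$fit, form, lmer.df = "satterthwaite")
  } else {
    emmeans::emtrends(result$fit, form, var = var, lmer.df = "satterthwaite")
  }
  est <- as.data.frame(summary(em, infer = c(TRUE, FALSE), level = 0.95))
  ctr <- as.data.frame(summary(emmeans::contrast(em, method = "pairwise",
                                                 adjust = "tukey")))
  structure(list(estimates = est, contrasts = ctr, var = var, specs = specs),
            class = "contrast_table")
}

#' @export
print.contrast_table <- function(x, ...) {
  cat(if (is.null(x$var)) "Least-squares means"
      else paste("Simple slopes of dc on", x$var),
      "by", paste(x$specs, collapse = " x "), "\n")
  print(x$estimates, row.names = FALSE)
  cat("\nTukey-adjusted pairwise comparisons:\n")
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}

#' Control refits with substituted time covariates
#'
#' Refits the reduced model with (I) pre-implant disease duration and time
#' since implantation substituted by their sum, the overall disease
#' duration, or (II) all three time covariates substituted by the
#' chronological age (their sum). Used to demonstrate that a moderator
#' effect is specific to the pre-implant duration rather than to overall
#' duration or age.
#'
#' @param table A connection table.
#' @param spec The [lmm_spec()] of the primary analysis.
#' @param substitution `"overall_duration"` or `"chronological_age"`.
#' @return A `dc_lmm` (reduced under the same procedure) with a `control`
#'   field naming the substitution.
#' @export
covariate_substitution_refit <- function(table, spec = lmm_spec(),
                                         substitution = c("overall_duration",
                                                          "chronological_age")) {
  substitution <- match.arg(substitution)
  dat <- as.data.frame(table)
  if (substitution == "overall_duration") {
    dat$overall_duration <- dat$duration_before_implant + dat$time_since_implant
    replaced <- c("duration_before_implant", "time_since_implant")
    new_cov <- "overall_duration"
  } else {
    dat$chronological_age <- dat$age_at_onset + dat$duration_before_implant +
      dat$time_since_implant
    replaced <- c("age_at_onset", "duration_before_implant",
                  "time_since_implant")
    new_cov <- "chronological_age"
  }
  if (stats::sd(dat[[new_cov]]) == 0) {
    stop("data error: derived covariate ", new_cov, " is constant")
  }
  covs <- c(setdiff(spec$covariates, replaced), new_cov)
  spec2 <- lmm_spec(factors = spec$factors, covariates = covs,
                    random = spec$random, alpha = spec$alpha,
                    center = spec$center, REML = spec$REML)
  out <- reduce_model(dat, spec2)
  out$control <- substitution
  out
}
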
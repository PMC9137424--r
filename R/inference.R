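#' Model specification for the accuracy analysis
#'
#' @param fixed One-sided or two-sided formula for the fixed effects on the
#'   RAU response (default `rau ~ mask * modality * group`).
#' @param random Name of the grouping factor carrying the random intercept
#'   (default `"subject_id"`).
#' @param alpha Significance level used by the interaction elimination.
#' @param reference Named list of reference levels, e.g.
#'   `list(mask = "none", modality = "AO", group = "CNH")`.
#' @return A `masksim_modelspec` object.
#' @export
model_spec <- function(fixed = rau ~ mask * modality * group,
                       random = "subject_id", alpha = 0.05,
                       reference = list(mask = "none", modality = "AO",
                                        group = "CNH")) {
  stopifnot(inherits(fixed, "formula"), alpha > 0, alpha < 1)
  structure(list(fixed = fixed, random = random, alpha = alpha,
                 reference = reference),
            class = "masksim_modelspec")
}

prepare_model_data <- function(scores, spec) {
  d <- as.data.frame(scores)
  vars <- all.vars(spec$fixed)
  for (v in c(setdiff(vars, "rau"), spec$random)) {
    if (!v %in% names(d)) next
    if (is.character(d[[v]])) d[[v]] <- factor(d[[v]])
    if (is.factor(d[[v]]) && !is.null(spec$reference[[v]]) &&
        spec$reference[[v]] %in% levels(d[[v]])) {
      d[[v]] <- stats::relevel(d[[v]], ref = spec$reference[[v]])
    }
  }
  d
}

interaction_terms <- function(formula) {
  tl <- attr(terms(formula), "term.labels")
  tl[grepl(":", tl, fixed = TRUE)]
}

#' Fit the mixed-effects accuracy model with interaction elimination
#'
#' Fits a linear mixed-effects model (REML) of RAU-transformed accuracy on
#' the specified fixed factors with a random intercept per subject, then
#' backward-eliminates non-significant interactions: at each step the
#' highest-order interactions are examined and the least significant one
#' with p above `alpha` is removed (main effects are never removed), until
#' every retained interaction is significant. F-tests use the Satterthwaite
#' approximation to the denominator degrees of freedom (via
#' \pkg{lmerTest}).
#'
#' @param scores A score table (e.g. from [score_trials()] or
#'   [simulate_rau_scores()]).
#' @param spec A [model_spec()].
#' @return A `masksim_fit`: list with the final `model`
#'   (`lmerModLmerTest`), `anova` (F-table of the final model),
#'   `elimination` (trace tibble), `spec`, and `data`.
#' @export
fit_accuracy_model <- function(scores, spec = model_spec()) {
  stopifnot(inherits(spec, "masksim_modelspec"))
  d <- prepare_model_data(scores, spec)
  if (!spec$random %in% names(d)) {
    abort(sprintf("Random-intercept factor '%s' not found in the score table.", spec$random))
  }
  fixed <- spec$fixed
  trace <- tibble(step = integer(), dropped = character(),
                  f_value = numeric(), p_value = numeric())
  step <- 0L
  repeat {
    fml <- as.formula(paste(deparse(fixed, width.cutoff = 500), "+ (1 |",
                            spec$random, ")"))
    fit <- lmerTest::lmer(fml, data = d, REML = TRUE)
    an <- as.data.frame(anova(fit))  # Type III, Satterthwaite ddf
    ints <- interaction_terms(fixed)
    if (length(ints) == 0) break
    # droppable = interactions not nested in a retained higher-order one
    parts <- strsplit(ints, ":", fixed = TRUE)
    droppable <- vapply(seq_along(ints), function(i) {
      !any(vapply(seq_along(ints), function(j) {
        j != i && all(parts[[i]] %in% parts[[j]])
      }, logical(1)))
    }, logical(1))
    cand <- ints[droppable]
    p <- an[cand, "Pr(>F)"]
    p[is.na(p)] <- Inf  # inestimable terms are removed first
    nonsig <- p > spec$alpha
    if (!any(nonsig)) break
    # highest-order non-significant candidates first, then largest p
    ord <- vapply(strsplit(cand, ":", fixed = TRUE), length, integer(1))
    pool <- which(nonsig & ord == max(ord[nonsig]))
    drop_term <- cand[pool[which.max(p[pool])]]
    step <- step + 1L
    trace <- bind_rows(trace, tibble(
      step = step, dropped = drop_term,
      f_value = an[drop_term, "F value"], p_value = an[drop_term, "Pr(>F)"]))
    fixed <- update(fixed, paste(". ~ . -", drop_term))
  }
  if (lme4::isSingular(fit, tol = 1e-4)) {
    warn("Final mixed-model fit is singular (random-intercept variance near zero); interpret the variance components with care.")
  }
  structure(list(model = fit, anova = an, elimination = trace,
                 spec = spec, fixed = fixed, data = d),
            class = "masksim_fit")
}

#' @export
print.masksim_fit <- function(x, ...) {
  cat("<masksim_fit> linear mixed-effects accuracy model\n")
  cat("Final fixed effects:", deparse(x$fixed), "\n")
  if (nrow(x$elimination) > 0) {
    cat("Eliminated interactions:",
        paste(x$elimination$dropped, collapse = ", "), "\n")
  } else {
    cat("Eliminated interactions: none\n")
  }
  cat("\nF-tests (Satterthwaite df):\n")
  print(round(x$anova, 4))
  invisible(x)
}

#' Tidy the fixed effects of a fitted accuracy model
#'
#' @param x A `masksim_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `std_error`, `df`,
#'   `statistic`, `p_value`.
#' @export
tidy.masksim_fit <- function(x, ...) {
  cf <- as.data.frame(summary(x$model)$coefficients)
  tibble(term = rownames(cf), estimate = cf[, "Estimate"],
         std_error = cf[, "Std. Error"], df = cf[, "df"],
         statistic = cf[, "t value"], p_value = cf[, "Pr(>|t|)"])
}

#' One-row summary of a fitted accuracy model
#'
#' @param x A `masksim_fit`.
#' @param ... Unused.
#' @return A tibble with `nobs`, `n_subjects`, `sigma`,
#'   `sd_subject` (random-intercept SD), `logLik`, `REML`,
#'   `n_eliminated`.
#' @export
glance.masksim_fit <- function(x, ...) {
  vc <- as.data.frame(lme4::VarCorr(x$model))
  tibble(
    nobs = stats::nobs(x$model),
    n_subjects = lme4::ngrps(x$model)[[1]],
    sigma = stats::sigma(x$model),
    sd_subject = vc$sdcor[vc$grp == x$spec$random][1],
    logLik = as.numeric(stats::logLik(x$model)),
    REML = TRUE,
    n_eliminated = nrow(x$elimination)
  )
}

#' Post hoc contrasts by reference re-leveling
#'
#' Refits the final model with the requested reference levels and returns
#' the re-leveled coefficient table, mirroring the practice of varying the
#' reference condition for post hoc comparisons. No multiplicity
#' correction is applied by default; set `p_adjust` to a
#' [stats::p.adjust()] method to correct the reported p-values.
#'
#' @param fit A `masksim_fit`.
#' @param reference Named list of reference levels to set (unnamed factors
#'   keep their current reference).
#' @param p_adjust `"none"` (default) or a [stats::p.adjust()] method.
#' @return A coefficient tibble as in [tidy.masksim_fit()], with the
#'   reference recorded in the attribute `"reference"`.
#' @export
posthoc_contrasts <- function(fit, reference = list(), p_adjust = "none") {
  stopifnot(inherits(fit, "masksim_fit"))
  d <- fit$data
  for (v in names(reference)) {
    if (!v %in% names(d)) abort(sprintf("Unknown factor '%s'.", v))
    if (!reference[[v]] %in% levels(d[[v]])) {
      abort(sprintf("Unknown level '%s' for factor '%s'.", reference[[v]], v))
    }
    d[[v]] <- stats::relevel(d[[v]], ref = reference[[v]])
  }
  fml <- as.formula(paste(deparse(fit$fixed, width.cutoff = 500), "+ (1 |",
                          fit$spec$random, ")"))
  m <- lmerTest::lmer(fml, data = d, REML = TRUE)
  cf <- as.data.frame(summary(m)$coefficients)
  out <- tibble(term = rownames(cf), estimate = cf[, "Estimate"],
                std_error = cf[, "Std. Error"], df = cf[, "df"],
                statistic = cf[, "t value"], p_value = cf[, "Pr(>|t|)"])
  if (p_adjust != "none") {
    out$p_value <- stats::p.adjust(out$p_value, method = p_adjust)
  }
  attr(out, "reference") <- reference
  out
}

#' Welch's unequal-variance t-test between two groups of scores
#'
#' @param a,b Numeric score vectors (at least 2 observations each).
#' @return A one-row tibble: `estimate` (mean difference a - b),
#'   `statistic` (t), `df` (Welch-Satterthwaite), `p_value`.
#' @export
welch_group_test <- function(a, b) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2 || length(b) < 2) abort("Each group needs at least 2 observations.")
  if (sd(a) == 0 && sd(b) == 0) abort("Both groups have zero variance; t is undefined.")
  tt <- t.test(a, b, var.equal = FALSE)
  tibble(estimate = unname(diff(rev(tt$estimate))),
         statistic = unname(tt$statistic),
         df = unname(tt$parameter),
         p_value = tt$p.value)
}
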
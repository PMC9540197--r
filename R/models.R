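#' Assemble a tidy subject-by-condition modeling table
#'
#' One row per subject and condition, with the ordinal vocoding level
#' (1 = clearest, increasing with degradation) and the recorded measures.
#' The level is centered before modeling (and before squaring) so linear
#' and quadratic terms are decorrelated.
#'
#' @param subject Subject identifiers.
#' @param condition Condition identifiers.
#' @param level Ordinal vocoding level (integer-valued, 1 = clearest).
#' @param response Measure value (hit rate, tracking, or alpha).
#' @param ... Further per-row columns (e.g. `tracking_norm`,
#'   `activation_norm`).
#' @return A `data.frame` of class `model_table`.
#' @export
model_table <- function(subject, condition, level, response, ...) {
  tab <- data.frame(subject = factor(subject), condition = condition,
                    level = as.numeric(level), response = response, ...)
  if (anyDuplicated(tab[, c("subject", "condition")])) {
    stop("one row per subject x condition required")
  }
  class(tab) <- c("model_table", "data.frame")
  tab
}

#' Random-intercept model of a measure across vocoding levels
#'
#' Fits `response ~ level (+ level^2) + (1 | subject)` by maximum
#' likelihood (ML, not REML, because fixed-effect structures are compared
#' by likelihood-ratio tests). The level covariate is centered before
#' squaring. A singular fit (zero between-subject variance) still
#' succeeds; the variance is reported as 0.
#'
#' @param table A data frame with columns `subject`, `level`, and the
#'   response.
#' @param form `"linear"` or `"quadratic"`.
#' @param response Name of the response column (default `"response"`).
#' @return An object of class `mixed_fit`: list with `fit` (the `lmerMod`
#'   object), `coefficients` (fixed effects), `ranef_var`, `sigma2`,
#'   `logLik`, `df` (number of parameters), `AIC`, `form`, `response`.
#' @export
fit_level_model <- function(table, form = c("linear", "quadratic"),
                            response = "response") {
  form <- match.arg(form)
  stopifnot(all(c("subject", "level", response) %in% names(table)))
  d <- as.data.frame(table)
  d$.y <- d[[response]]
  d$.lc <- d$level - mean(unique(d$level))
  if (form == "quadratic" && length(unique(d$level)) < 3L) {
    stop("quadratic model needs >= 3 distinct levels")
  }
  if (nlevels(factor(d$subject)) < 2L) stop("need >= 2 subjects")
  fml <- if (form == "linear") {
    .y ~ .lc + (1 | subject)
  } else {
    .y ~ .lc + I(.lc^2) + (1 | subject)
  }
  fit <- suppressMessages(lme4::lmer(fml, data = d, REML = FALSE))
  vc <- as.data.frame(lme4::VarCorr(fit))
  rv <- vc$vcov[vc$grp == "subject"]
  if (length(rv) && rv <= 1e-12) {
    warning("singular fit: between-subject variance estimated as 0")
  }
  ll <- stats::logLik(fit)
  structure(list(fit = fit,
                 coefficients = lme4::fixef(fit),
                 ranef_var = rv,
                 sigma2 = stats::sigma(fit)^2,
                 logLik = as.numeric(ll),
                 df = attr(ll, "df"),
                 AIC = stats::AIC(fit),
                 form = form, response = response),
            class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf("<mixed_fit> %s model of %s: logLik = %.3f, AIC = %.2f\n",
              x$form, x$response, x$logLik, x$AIC))
  print(round(x$coefficients, 5))
  invisible(x)
}

#' Likelihood-ratio test between nested ML fits
#'
#' `chi2 = 2 (logLik_complex - logLik_simple)`, degrees of freedom equal
#' to the parameter-count difference, p-value from the upper chi-squared
#' tail. This is the "ANOVA" comparison of a linear against a
#' linear-plus-quadratic mixed model.
#'
#' @param simple,complex `mixed_fit` objects, `simple` nested in
#'   `complex`, both fit by ML.
#' @return List with `chi2`, `df`, `p`.
#' @export
lrt <- function(simple, complex) {
  stopifnot(inherits(simple, "mixed_fit"), inherits(complex, "mixed_fit"))
  df <- complex$df - simple$df
  if (df < 0L) stop("simple model must be nested in complex")
  chi2 <- 2 * (complex$logLik - simple$logLik)
  if (chi2 < -1e-6) {
    stop("complex model has lower likelihood than nested simple model")
  }
  chi2 <- max(chi2, 0)
  p <- if (df == 0L) 1 else stats::pchisq(chi2, df, lower.tail = FALSE)
  list(chi2 = chi2, df = df, p = p)
}

#' Normalize measures by each subject's nonvocoded value
#'
#' Divides the named measure columns by the subject's value in the clear
#' (nonvocoded) condition and drops the clear rows, yielding the unitless
#' per-subject tracking and activation predictors used by the
#' intelligibility models. Subjects whose clear value is (near) zero in
#' any measure are excluded with a warning.
#'
#' @param table Data frame with `subject`, `condition`, and the measure
#'   columns.
#' @param measures Character vector of measure column names.
#' @param clear Condition identifier of the nonvocoded condition.
#' @param tol Relative tolerance below which a clear value counts as zero.
#' @return The table restricted to vocoded rows, measures normalized, with
#'   `<measure>_norm` columns appended.
#' @export
normalize_by_clear <- function(table, measures, clear = "orig",
                               tol = 1e-8) {
  stopifnot(all(c("subject", "condition") %in% names(table)),
            all(measures %in% names(table)))
  d <- as.data.frame(table)
  clear_rows <- d[d$condition == clear, , drop = FALSE]
  if (nrow(clear_rows) == 0L) stop("no rows for clear condition '", clear, "'")
  drop_subj <- character(0)
  for (m in measures) {
    ref <- clear_rows[[m]][match(d$subject, clear_rows$subject)]
    scale_ref <- stats::median(abs(clear_rows[[m]]))
    bad <- unique(as.character(clear_rows$subject[
      abs(clear_rows[[m]]) <= tol * max(scale_ref, 1e-300)]))
    drop_subj <- union(drop_subj, bad)
    d[[paste0(m, "_norm")]] <- d[[m]] / ref
  }
  if (length(drop_subj)) {
    warning("excluding subject(s) with (near-)zero clear-condition value: ",
            paste(drop_subj, collapse = ", "))
    d <- d[!(as.character(d$subject) %in% drop_subj), , drop = FALSE]
  }
  d <- d[d$condition != clear, , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Intelligibility models from neural measures
#'
#' Fits three random-intercept ML models of observed intelligibility (the
#' per-subject hit rate in the vocoded conditions): the combined model
#' `Intelligibility ~ Tracking / Activation`, the tracking-only model
#' `Intelligibility ~ Tracking`, and the activation-only model
#' `Intelligibility ~ Activation`, where tracking and activation are the
#' subject-normalized ([normalize_by_clear()]) coherence and alpha-power
#' measures. Each model is tested against the intercept-only null by
#' likelihood-ratio test; the three (non-nested) models are compared to
#' each other by log-likelihood and AIC.
#'
#' @param table Data frame with columns `subject`, `response` (hit rate),
#'   `tracking_norm`, `activation_norm`, restricted to vocoded conditions.
#' @return List with `fits` (named `mixed_fit`s incl. `null`) and
#'   `comparison`, a data frame with per-model `logLik`, `AIC`, and the
#'   LRT against the null (`chi2`, `df`, `p`).
#' @export
intelligibility_models <- function(table) {
  stopifnot(all(c("subject", "response", "tracking_norm",
                  "activation_norm") %in% names(table)))
  d <- as.data.frame(table)
  bad <- d$activation_norm <= 0
  if (any(bad)) {
    warning(sum(bad), " row(s) with activation <= 0 excluded from the ratio predictor")
    d <- d[!bad, , drop = FALSE]
  }
  d$ratio <- d$tracking_norm / d$activation_norm

  fit_one <- function(fml) {
    fit <- suppressMessages(lme4::lmer(fml, data = d, REML = FALSE))
    ll <- stats::logLik(fit)
    structure(list(fit = fit, coefficients = lme4::fixef(fit),
                   logLik = as.numeric(ll), df = attr(ll, "df"),
                   AIC = stats::AIC(fit), form = deparse(fml[[3L]]),
                   response = "response"),
              class = "mixed_fit")
  }
  fits <- list(
    null = fit_one(response ~ 1 + (1 | subject)),
    combined = fit_one(response ~ ratio + (1 | subject)),
    tracking = fit_one(response ~ tracking_norm + (1 | subject)),
    activation = fit_one(response ~ activation_norm + (1 | subject))
  )
  rows <- lapply(c("combined", "tracking", "activation"), function(nm) {
    lr <- lrt(fits$null, fits[[nm]])
    data.frame(model = nm, logLik = fits[[nm]]$logLik,
               AIC = fits[[nm]]$AIC, chi2_vs_null = lr$chi2,
               df = lr$df, p_vs_null = lr$p)
  })
  list(fits = fits, comparison = do.call(rbind, rows))
}
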
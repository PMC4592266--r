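# Model specification and fitting front-end for the four response families
# used in the pipeline: Poisson counts, Gaussian, logistic-exposure
# binomial, and ordinal cumulative-logit.  Mixed models are fitted by ML
# (never REML) so AICc comparisons across fixed structures are valid.

#' Declare a model specification
#'
#' A `dn_spec` records everything needed to fit one analysis: the response,
#' the likelihood family, the candidate fixed terms (main effects,
#' quadratics written `I(x^2)`, interactions written `a:b`), the terms
#' locked into every candidate model, optional random intercept groupings,
#' and, for exposure models, the exposure-days column.
#'
#' @param response Name of the response column (0/1 failure indicator for
#'   `"binomial-exposure"`).
#' @param family One of `"poisson"`, `"gaussian"`, `"binomial"`,
#'   `"binomial-exposure"`, `"ordinal"`.
#' @param terms Character vector of fixed terms.
#' @param locked Character vector of terms always included (subset of
#'   `terms`).
#' @param random `NULL`, or character vector of grouping columns (nested in
#'   the given order for (G)LMMs; a single grouping for ordinal fits).
#' @param exposure Exposure-days column for `"binomial-exposure"`.
#' @return An object of class `dn_spec`.
#' @export
model_spec <- function(response, family, terms, locked = character(),
                       random = NULL, exposure = NULL) {
  family <- match.arg(family, c("poisson", "gaussian", "binomial",
                                "binomial-exposure", "ordinal"))
  if (!all(locked %in% terms)) stop("locked terms must be a subset of terms")
  if (family == "binomial-exposure" && is.null(exposure))
    stop("binomial-exposure models need an exposure column")
  for (tm in terms) {
    par <- term_parents(tm)
    if (length(par) && !all(par %in% terms))
      stop(sprintf("term %s lacks its parent main effect(s) %s",
                   tm, paste(setdiff(par, terms), collapse = ", ")))
  }
  structure(list(response = response, family = family, terms = terms,
                 locked = locked, random = random, exposure = exposure),
            class = "dn_spec")
}

#' Parent main effects implied by a term
#'
#' An interaction `a:b` requires `a` and `b`; a quadratic `I(x^2)` requires
#' `x`; a main effect has no parents.  Used to enforce marginality during
#' all-subsets enumeration.
#'
#' @param term A single term label.
#' @return Character vector of parent terms (possibly empty).
#' @export
term_parents <- function(term) {
  if (grepl(":", term, fixed = TRUE))
    return(strsplit(term, ":", fixed = TRUE)[[1]])
  m <- regmatches(term,
                  regexec("^I\\(([A-Za-z._][A-Za-z0-9._]*)\\^2\\)$", term))[[1]]
  if (length(m) == 2) return(m[2])
  character(0)
}

.spec_formula <- function(spec, terms = spec$terms) {
  if (length(terms) == 0)
    as.formula(paste(spec$response, "~ 1"))
  else
    as.formula(paste(spec$response, "~", paste(terms, collapse = " + ")))
}

.re_string <- function(random) {
  if (length(random) > 1) paste0("(1 | ", paste(random, collapse = "/"), ")")
  else paste0("(1 | ", random, ")")
}

#' Fit a declared model specification
#'
#' Dispatches on `spec$family`:
#' Poisson (log link) and plain binomial (logit) use [glm()] or, with random
#' intercepts, `lme4::glmer` (Laplace, ML); Gaussian uses [lm()] (ML
#' log-likelihood) or `lme4::lmer` with `REML = FALSE`;
#' `"binomial-exposure"` uses [logexp_fit()]; `"ordinal"` uses [clm_fit()].
#' The returned `dn_fit` carries the coefficient table, ML log-likelihood,
#' parameter count `k` (fixed coefficients plus thresholds, random-intercept
#' variances and the Gaussian residual variance) and `n`.
#'
#' @param spec A `dn_spec`.
#' @param data Data frame.
#' @param terms Optional subset of `spec$terms` to fit (used by
#'   [dn_dredge()]); defaults to all terms.
#' @return A `dn_fit`.
#' @export
fit_model <- function(spec, data, terms = spec$terms) {
  stopifnot(inherits(spec, "dn_spec"))
  need <- unique(c(all.vars(.spec_formula(spec)), spec$exposure, spec$random))
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop(sprintf("analysis '%s': missing column(s) %s", spec$response,
                 paste(miss, collapse = ", ")))
  form <- .spec_formula(spec, terms)
  fam <- spec$family
  if (fam == "binomial-exposure")
    return(logexp_fit(form, data, exposure = spec$exposure,
                      random = spec$random))
  if (fam == "ordinal")
    return(clm_fit(form, data, random = spec$random[1]))

  d <- data[complete.cases(data[need]), , drop = FALSE]
  if (is.null(spec$random)) {
    m <- switch(fam,
      poisson  = glm(form, data = d, family = poisson()),
      binomial = glm(form, data = d, family = binomial()),
      gaussian = lm(form, data = d))
    if (fam != "gaussian" && !m$converged) stop("GLM failed to converge")
    alias <- is.na(coef(m))
    if (any(alias)) stop("aliased terms in design: ",
                         paste(names(coef(m))[alias], collapse = ", "))
    ll <- logLik(m)
    est <- coef(m)
    se <- sqrt(diag(vcov(m)))
    X <- model.matrix(m)
    new_dn_fit(estimate = est, se = se, logLik = as.numeric(ll),
               k = attr(ll, "df"), n = nrow(d), family = fam, terms = terms,
               varcomp = NULL, var_fixed = var(drop(X %*% est)), object = m,
               extra = list(mean_response = mean(d[[spec$response]]),
                            resid_var = if (fam == "gaussian") {
                              # n-1 denominator, matching var() in the
                              # fixed-predictor variance, so the partition
                              # reduces exactly to classical R-squared
                              r <- stats::residuals(m)
                              sum(r^2) / (length(r) - 1)
                            } else NULL))
  } else {
    full <- as.formula(paste(deparse(form[[2]]), "~",
                             paste(deparse(form[[3]]), collapse = " "),
                             "+", .re_string(spec$random)))
    m <- switch(fam,
      poisson  = lme4::glmer(full, data = d, family = poisson()),
      binomial = lme4::glmer(full, data = d, family = binomial()),
      gaussian = lme4::lmer(full, data = d, REML = FALSE))
    ll <- logLik(m)
    est <- lme4::fixef(m)
    se <- sqrt(diag(as.matrix(vcov(m))))
    vc <- as.data.frame(lme4::VarCorr(m))
    resid_row <- vc$grp == "Residual"
    varcomp <- setNames(vc$vcov[!resid_row], vc$grp[!resid_row])
    X <- model.matrix(m)
    new_dn_fit(estimate = est, se = setNames(se, names(est)),
               logLik = as.numeric(ll), k = attr(ll, "df"), n = nrow(d),
               family = fam, terms = terms, varcomp = varcomp,
               var_fixed = var(drop(X %*% est)), object = m,
               extra = list(resid_var = if (fam == "gaussian")
                 sigma(m)^2 else NULL, random = spec$random,
                 mean_response = mean(d[[spec$response]])))
  }
}
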
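# AICc ranking, all-subsets enumeration under marginality, top-set
# coefficient averaging with unconditional standard errors, and
# marginal/conditional R-squared.

#' Second-order Akaike Information Criterion
#'
#' \deqn{AICc = -2\ell + 2k + \frac{2k(k+1)}{n-k-1}}
#' where \eqn{\ell} is the maximized log-likelihood, `k` the number of
#' estimated parameters (including variance components and thresholds) and
#' `n` the number of observations.  Accepts either a fitted `dn_fit` or the
#' three quantities directly.
#'
#' @param object A `dn_fit`, or the log-likelihood as a number.
#' @param k,n Parameter and observation counts (when `object` is numeric).
#' @return The AICc value.
#' @examples
#' aicc(-10, k = 2, n = 10)  # 25.7143
#' @export
aicc <- function(object, k = NULL, n = NULL) {
  if (inherits(object, "dn_fit")) {
    ll <- object$logLik; k <- object$k; n <- object$n
  } else {
    ll <- object
    if (is.null(k) || is.null(n)) stop("supply k and n with a numeric logLik")
  }
  if (n <= k + 1) stop("AICc undefined: n must exceed k + 1")
  -2 * ll + 2 * k + 2 * k * (k + 1) / (n - k - 1)
}

.admissible_subsets <- function(free, locked) {
  m <- length(free)
  if (m > 20) stop("more than 20 free terms; override the guard explicitly")
  subsets <- list()
  for (mask in 0:(2^m - 1)) {
    inc <- free[bitwAnd(mask, 2^(seq_len(m) - 1)) > 0]
    all_terms <- c(locked, inc)
    ok <- all(vapply(all_terms, function(tm)
      all(term_parents(tm) %in% all_terms), logical(1)))
    if (ok) subsets[[length(subsets) + 1]] <- inc
  }
  subsets
}

#' All-subsets model enumeration and AICc ranking
#'
#' Enumerates every submodel of a global specification that contains all
#' locked terms and respects marginality (an interaction or quadratic enters
#' only when its parent main effects are present), fits each, and ranks the
#' set by AICc.  Akaike weights are
#' \eqn{w_i = \exp(-\Delta_i/2) / \sum_j \exp(-\Delta_j/2)}.
#'
#' @param spec A global `dn_spec`.
#' @param data Data frame.
#' @param max_free Guard against combinatorial explosion: more than
#'   `max_free` free (non-locked) terms is an error unless raised.
#' @return An object of class `dn_dredge`: a list with `table` (one row per
#'   model, sorted by AICc, with columns `model`, `terms`, `k`, `logLik`,
#'   `AICc`, `delta`, `weight`), `fits` (list of `dn_fit` in table order)
#'   and `spec`.
#' @export
dn_dredge <- function(spec, data, max_free = 20) {
  stopifnot(inherits(spec, "dn_spec"))
  free <- setdiff(spec$terms, spec$locked)
  if (length(free) > max_free)
    stop(sprintf("%d free terms exceeds the guard of %d", length(free),
                 max_free))
  subsets <- .admissible_subsets(free, spec$locked)
  fits <- lapply(subsets, function(inc)
    fit_model(spec, data, terms = c(spec$locked, inc)))
  tab <- data.frame(
    model = vapply(subsets, function(inc)
      if (length(c(spec$locked, inc)))
        paste(c(spec$locked, inc), collapse = " + ") else "1",
      character(1)),
    k = vapply(fits, function(f) f$k, numeric(1)),
    logLik = vapply(fits, function(f) f$logLik, numeric(1)))
  tab$AICc <- vapply(fits, aicc, numeric(1))
  ord <- order(tab$AICc)
  tab <- tab[ord, , drop = FALSE]
  fits <- fits[ord]
  tab$delta <- tab$AICc - tab$AICc[1]
  w <- exp(-tab$delta / 2)
  tab$weight <- w / sum(w)
  rownames(tab) <- NULL
  structure(list(table = tab, fits = fits, spec = spec),
            class = "dn_dredge")
}

#' @method print dn_dredge
#' @export
print.dn_dredge <- function(x, ...) {
  cat(sprintf("<dn_dredge> %d candidate models (response: %s)\n",
              nrow(x$table), x$spec$response))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Average the coefficients of the top model set
#'
#' Retains every model with \eqn{\Delta AICc <} `delta` (strict; the best
#' model always qualifies), renormalizes Akaike weights over that set, and
#' averages each design-matrix coefficient across the models in which it
#' appears.  The default `method = "conditional"` renormalizes weights over
#' the containing models (so a term's estimate is its average where it is
#' estimated, and `n_models` reports its retention count);
#' `method = "full"` substitutes zero where a term is absent.  Standard
#' errors use the unconditional form combining within- and between-model
#' variance, \eqn{SE = \sum_i \tilde w_i \sqrt{SE_i^2 + (\beta_i - \bar\beta)^2}},
#' and confidence intervals are Wald \eqn{\pm 1.96\,SE}.
#'
#' @param dredged A `dn_dredge`.
#' @param delta Top-set threshold on \eqn{\Delta AICc} (default 2, strict).
#' @param method `"conditional"` (default) or `"full"`.
#' @param conf_z Normal quantile for the intervals (default 1.96).
#' @return An object of class `dn_avg`: a data frame with columns `term`,
#'   `n_models`, `estimate`, `se`, `lower_ci`, `upper_ci`, `significant`
#'   (interval excludes zero), plus attributes `table` (the top-set model
#'   table with renormalized weights) and `delta`.
#' @export
average_top_set <- function(dredged, delta = 2,
                            method = c("conditional", "full"),
                            conf_z = 1.96) {
  stopifnot(inherits(dredged, "dn_dredge"))
  method <- match.arg(method)
  keep <- dredged$table$delta < delta
  tab <- dredged$table[keep, , drop = FALSE]
  fits <- dredged$fits[keep]
  w <- tab$weight / sum(tab$weight)
  coefs <- unique(unlist(lapply(fits, function(f) names(f$estimate))))
  rows <- lapply(coefs, function(cn) {
    has <- vapply(fits, function(f) cn %in% names(f$estimate), logical(1))
    if (method == "conditional") {
      b <- vapply(fits[has], function(f) unname(f$estimate[cn]), numeric(1))
      s <- vapply(fits[has], function(f) unname(f$se[cn]), numeric(1))
      wi <- w[has] / sum(w[has])
    } else {
      # full-model averaging: absent terms contribute 0 with SE 0
      b <- s <- numeric(length(fits))
      b[has] <- vapply(fits[has], function(f) unname(f$estimate[cn]),
                       numeric(1))
      s[has] <- vapply(fits[has], function(f) unname(f$se[cn]), numeric(1))
      wi <- w
    }
    est <- sum(wi * b)
    se <- sum(wi * sqrt(s^2 + (b - est)^2))
    data.frame(term = cn, n_models = sum(has), estimate = est, se = se,
               lower_ci = est - conf_z * se, upper_ci = est + conf_z * se)
  })
  out <- do.call(rbind, rows)
  out$significant <- out$lower_ci > 0 | out$upper_ci < 0
  tab$weight <- w
  structure(out, class = c("dn_avg", "data.frame"),
            table = tab, delta = delta, method = method)
}

#' Marginal and conditional R-squared for (mixed) models
#'
#' Variance-partition R-squared: the marginal value is the variance of the
#' fixed-effect linear predictor over the total of fixed, random-intercept
#' and residual variance; the conditional value adds the random-intercept
#' variance to the numerator.  The family-specific residual variance is the
#' ML residual variance for Gaussian models, the lognormal approximation
#' \eqn{\ln(1/\bar\lambda + 1)} for Poisson log-link models (with
#' \eqn{\bar\lambda} the mean response) and \eqn{\pi^2/3} for
#' binomial/logistic models (including logistic-exposure fits).  For a
#' fixed-effects Gaussian model both values reduce to the classical
#' R-squared.
#'
#' @param fit A `dn_fit` from [fit_model()] or [logexp_fit()].
#' @param data Optional data frame used to recompute the mean response for
#'   the Poisson residual-variance approximation; by default the value
#'   cached at fit time is used.
#' @return Named numeric vector `c(marginal = , conditional = )`.
#' @export
r2_nakagawa <- function(fit, data = NULL) {
  stopifnot(inherits(fit, "dn_fit"))
  var_f <- fit$var_fixed
  if (!is.finite(var_f)) var_f <- 0
  var_r <- if (is.null(fit$varcomp)) 0 else sum(fit$varcomp)
  var_e <- switch(fit$family,
    gaussian = {
      if (!is.null(fit$extra$resid_var)) fit$extra$resid_var
      else if (!is.null(fit$object) && inherits(fit$object, "lm")) {
        r <- stats::residuals(fit$object)
        sum(r^2) / length(r)           # ML residual variance
      } else stop("no residual variance available for Gaussian fit")
    },
    poisson = {
      lam <- fit$extra$mean_response
      if (is.null(lam)) stop("Poisson fit lacks a cached mean response")
      log(1 / lam + 1)
    },
    binomial = pi^2 / 3,
    `binomial-exposure` = pi^2 / 3,
    stop("unsupported family for r2_nakagawa: ", fit$family))
  tot <- var_f + var_r + var_e
  c(marginal = var_f / tot, conditional = (var_f + var_r) / tot)
}
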
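# Cumulative-link (proportional-odds) models for ordinal fledgling counts,
# with an optional single random intercept integrated out by a 1-d Laplace
# approximation per group.

.clm_nll_factory <- function(X, yi, K, n_re = 0, group = NULL) {
  # parameters: theta_1, log-diffs for theta_2..theta_{K-1}, beta, [log sigma]
  p <- ncol(X)
  unpack <- function(par) {
    th <- cumsum(c(par[1], exp(par[seq_len(K - 2) + 1])))
    beta <- if (p) par[(K - 1) + seq_len(p)] else numeric(0)
    sig <- if (n_re) exp(par[length(par)]) else NA_real_
    list(theta = th, beta = beta, sigma = sig)
  }
  cell_loglik <- function(eta, theta, yi) {
    upper <- ifelse(yi < length(theta) + 1, theta[pmin(yi, length(theta))], Inf)
    lower <- ifelse(yi > 1, theta[pmax(yi - 1, 1)], -Inf)
    log(pmax(plogis(upper - eta) - plogis(lower - eta), 1e-300))
  }
  if (!n_re) {
    function(par) {
      u <- unpack(par)
      eta <- if (p) drop(X %*% u$beta) else numeric(nrow(X))
      -sum(cell_loglik(eta, u$theta, yi))
    }
  } else {
    gidx <- split(seq_along(yi), group)
    function(par) {
      u <- unpack(par)
      eta0 <- if (p) drop(X %*% u$beta) else numeric(nrow(X))
      tot <- 0
      for (ix in gidx) {
        g <- function(b)
          sum(cell_loglik(eta0[ix] + b, u$theta, yi[ix])) -
            b^2 / (2 * u$sigma^2)
        bhat <- optimize(g, c(-6, 6) * max(u$sigma, 0.05),
                         maximum = TRUE)$maximum
        hstep <- 1e-4
        g2 <- (g(bhat + hstep) - 2 * g(bhat) + g(bhat - hstep)) / hstep^2
        if (!is.finite(g2) || g2 >= 0) g2 <- -1 / u$sigma^2
        tot <- tot + g(bhat) + 0.5 * log(2 * pi) - 0.5 * log(-g2) -
          0.5 * log(2 * pi * u$sigma^2)
      }
      -tot
    }
  }
}

#' Fit a cumulative-logit model for ordinal counts
#'
#' Proportional-odds model \eqn{P(Y \le k) = logit^{-1}(\theta_k - x'\beta)}
#' with ordered thresholds, fitted by maximum likelihood.  An optional
#' random intercept (one grouping factor, e.g. nest or farm) is integrated
#' out with a one-dimensional Laplace approximation per group, so AICc
#' comparisons across fixed structures remain on the ML scale.
#'
#' @param formula Model formula; the response is coerced to an ordered
#'   factor of its observed levels (at least 2 required).
#' @param data Data frame.
#' @param random Optional name of a single grouping column for a random
#'   intercept.
#' @return A `dn_fit` with thresholds named `"k|k+1"` followed by slope
#'   coefficients; `$extra$levels` records the response levels and
#'   `$extra$null_logLik` the intercept-only log-likelihood used for
#'   McFadden's pseudo R-squared.
#' @export
clm_fit <- function(formula, data, random = NULL) {
  need <- unique(c(all.vars(formula), random))
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data[complete.cases(data[need]), , drop = FALSE]
  y <- eval(formula[[2]], d)
  lev <- sort(unique(y))
  K <- length(lev)
  if (K < 2) stop("ordinal response must have at least 2 observed levels")
  yi <- match(y, lev)
  X <- model.matrix(formula, d)
  X <- X[, setdiff(colnames(X), "(Intercept)"), drop = FALSE]
  p <- ncol(X)
  if (p && qr(X)$rank < p) stop("design matrix is rank deficient")
  group <- if (!is.null(random)) factor(d[[random]]) else NULL
  n_re <- as.integer(!is.null(random))

  cum <- cumsum(tabulate(yi, K))[seq_len(K - 1)] / length(yi)
  cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
  th0 <- qlogis(cum)
  start <- c(th0[1], if (K > 2) log(pmax(diff(th0), 1e-3)),
             rep(0, p), if (n_re) log(0.5))
  nll <- .clm_nll_factory(X, yi, K, n_re, group)
  opt <- optim(start, nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-12))
  if (opt$convergence != 0)
    opt <- optim(opt$par, nll, method = "Nelder-Mead",
                 control = list(maxit = 5000))
  par <- opt$par
  theta <- cumsum(c(par[1], exp(par[seq_len(K - 2) + 1])))
  beta <- if (p) par[(K - 1) + seq_len(p)] else numeric(0)
  sigma2 <- if (n_re) exp(2 * par[length(par)]) else NULL

  # SEs on the natural (theta, beta) scale: the ordering constraint is
  # inactive at an interior optimum, so the direct Hessian is valid there
  direct_nll <- function(q) {
    th <- q[seq_len(K - 1)]
    if (is.unsorted(th)) return(1e10)
    b <- if (p) q[(K - 1) + seq_len(p)] else numeric(0)
    par2 <- c(th[1], if (K > 2) log(pmax(diff(th), 1e-12)), b,
              if (n_re) par[length(par)])
    nll(par2)
  }
  qhat <- c(theta, beta)
  Hn <- pracma::hessian(direct_nll, qhat)
  se <- tryCatch(sqrt(diag(solve(Hn))),
                 error = function(e) rep(NA_real_, length(qhat)))

  nm <- c(paste(lev[-K], lev[-1], sep = "|"), colnames(X))
  est <- setNames(qhat, nm)
  null_ll <- if (p || n_re) {
    nll0 <- .clm_nll_factory(X[, 0, drop = FALSE], yi, K, 0, NULL)
    -optim(c(th0[1], if (K > 2) log(pmax(diff(th0), 1e-3))), nll0,
           method = "BFGS", control = list(maxit = 1000))$value
  } else -opt$value
  vf <- if (p) var(drop(X %*% beta)) else 0
  new_dn_fit(estimate = est, se = setNames(se, nm), logLik = -opt$value,
             k = (K - 1) + p + n_re, n = length(yi),
             family = "ordinal-cumulative-logit",
             terms = attr(terms(formula), "term.labels"),
             varcomp = if (n_re) setNames(sigma2, random),
             var_fixed = vf,
             extra = list(levels = lev, null_logLik = null_ll,
                          random = random))
}

#' McFadden's pseudo R-squared for an ordinal fit
#'
#' \eqn{1 - \ell(model) / \ell(intercept-only)}, using the intercept-only
#' (thresholds-only, no random effect) log-likelihood stored with the fit.
#'
#' @param fit A `dn_fit` from [clm_fit()].
#' @return A single number in \[0, 1\] for non-degenerate fits.
#' @export
r2_mcfadden <- function(fit) {
  stopifnot(inherits(fit, "dn_fit"),
            fit$family == "ordinal-cumulative-logit")
  1 - fit$logLik / fit$extra$null_logLik
}
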
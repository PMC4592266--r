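test_that("intercept-only fits recover closed-form maximum likelihood", {
  d <- data.frame(y = c(1.2, 3.4, 2.0, 5.1, 0.3))
  spec <- model_spec("y", "gaussian", terms = character())
  fit <- fit_model(spec, d)
  expect_equal(unname(coef(fit)), mean(d$y))
  n <- nrow(d); s2 <- sum((d$y - mean(d$y))^2) / n
  expect_equal(fit$logLik, -n / 2 * (log(2 * pi * s2) + 1), tolerance = 1e-10)

  dp <- data.frame(y = c(2, 3, 4))
  pfit <- fit_model(model_spec("y", "poisson", terms = character()), dp)
  expect_equal(unname(exp(coef(pfit))), 3, tolerance = 1e-8)

  dor <- data.frame(y = rep(c(1, 2, 3), times = c(20, 50, 30)))
  ofit <- fit_model(model_spec("y", "ordinal", terms = character()), dor)
  expect_equal(unname(plogis(coef(ofit))), c(0.2, 0.7), tolerance = 1e-4)
})

test_that("cumulative-logit fits agree with an independent implementation", {
  set.seed(31)
  n <- 300
  x <- rnorm(n); g <- rnorm(n)
  y <- cut(0.9 * x - 0.5 * g + rlogis(n), c(-Inf, -1, 0.4, 1.5, Inf),
           labels = FALSE)
  d <- data.frame(y = y, x = x, g = g)
  mine <- clm_fit(y ~ x + g, d)
  ref <- MASS::polr(factor(y, ordered = TRUE) ~ x + g, data = d, Hess = TRUE)
  expect_equal(mine$logLik, as.numeric(logLik(ref)), tolerance = 1e-6)
  expect_equal(unname(coef(mine)[c("x", "g")]), unname(coef(ref)),
               tolerance = 1e-4)
  expect_equal(unname(coef(mine)[1:3]), unname(ref$zeta), tolerance = 1e-4)
  expect_equal(unname(mine$se[c("x", "g")]),
               unname(sqrt(diag(vcov(ref))[1:2])), tolerance = 1e-3)
})

test_that("AICc matches its closed form and limits", {
  expect_equal(aicc(-10, k = 2, n = 10), 25.7143, tolerance = 1e-4)
  expect_equal(aicc(-10, k = 0, n = 10), 20)                 # k = 0: AIC
  expect_equal(aicc(-50, k = 3, n = 1e6), -2 * -50 + 6, tolerance = 1e-3)
  expect_error(aicc(-10, k = 9, n = 10), "undefined")
})

test_that("dredge enumerates admissible submodels under marginality", {
  set.seed(17)
  n <- 50
  d <- data.frame(A = rnorm(n), B = rnorm(n))
  d$y <- 1 + 0.5 * d$A + rnorm(n)

  spec <- model_spec("y", "gaussian", terms = c("A", "B", "A:B"))
  dd <- dn_dredge(spec, d)
  expect_equal(nrow(dd$table), 5)  # {}, A, B, AB, AB+A:B

  spec2 <- model_spec("y", "gaussian", terms = c("A", "B"))
  expect_equal(nrow(dn_dredge(spec2, d)$table), 4)

  spec3 <- model_spec("y", "gaussian", terms = c("A", "B"), locked = "A")
  dd3 <- dn_dredge(spec3, d)
  expect_equal(nrow(dd3$table), 2)
  expect_true(all(grepl("A", dd3$table$model)))

  expect_equal(sum(dd$table$weight), 1, tolerance = 1e-12)
  expect_true(all(diff(dd$table$AICc) >= 0))
  # combinatorial guard
  wide <- as.data.frame(matrix(rnorm(n * 21), n))
  names(wide) <- paste0("V", 1:21)
  wide$y <- rnorm(n)
  expect_error(dn_dredge(model_spec("y", "gaussian", terms = names(wide)[1:21]),
                         wide), "guard")
})

test_that("model rankings match the brute-force enumerator on random structures", {
  set.seed(23)
  for (rep in 1:10) {
    n <- 60
    d <- data.frame(A = rnorm(n), B = rnorm(n), C = rnorm(n), D = rnorm(n))
    free <- random_structure()
    d$y <- rnorm(n) + 0.7 * d$A
    spec <- model_spec("y", "gaussian", terms = free)
    got <- dn_dredge(spec, d)$table
    want <- oracle_dredge_gaussian("y", free, character(), d)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$AICc, want$aicc, tolerance = 1e-8)
  }
})

test_that("top-set averaging follows the conditional and full conventions", {
  mk <- function(est, se, ll, k = 2) densnest:::new_dn_fit(
    estimate = est, se = se, logLik = ll, k = k, n = 30,
    family = "gaussian", terms = names(est))
  # deltas 0 and 2*log(3/2) give renormalized weights 0.6 / 0.4
  d2 <- 2 * log(0.6 / 0.4)
  f1 <- mk(c("(Intercept)" = 0.2, A = 1.0), c("(Intercept)" = 0.1, A = 0.3),
           ll = 0)
  f2 <- mk(c("(Intercept)" = 0.1), c("(Intercept)" = 0.1), ll = -d2 / 2,
           k = 1)
  tab <- data.frame(model = c("A", "1"), k = c(2, 1), logLik = c(0, -d2 / 2),
                    AICc = c(10, 10 + d2), delta = c(0, d2))
  w <- exp(-tab$delta / 2); tab$weight <- w / sum(w)
  dd <- structure(list(table = tab, fits = list(f1, f2),
                       spec = model_spec("y", "gaussian", "A")),
                  class = "dn_dredge")
  avg <- average_top_set(dd, delta = 3)
  arow <- avg[avg$term == "A", ]
  expect_equal(arow$estimate, 1.0)          # conditional: only model 1 has A
  expect_equal(arow$n_models, 1)
  expect_equal(arow$se, 0.3)
  full <- average_top_set(dd, delta = 3, method = "full")
  expect_equal(full[full$term == "A", "estimate"], 0.6, tolerance = 1e-12)

  # identical estimates and SEs across models leave the SE unchanged
  g1 <- mk(c("(Intercept)" = 0.5), c("(Intercept)" = 0.2), ll = 0, k = 1)
  g2 <- mk(c("(Intercept)" = 0.5), c("(Intercept)" = 0.2), ll = -0.3, k = 1)
  tg <- data.frame(model = c("1", "1b"), k = 1, logLik = c(0, -0.3),
                   AICc = c(5, 5.6), delta = c(0, 0.6))
  wg <- exp(-tg$delta / 2); tg$weight <- wg / sum(wg)
  ddg <- structure(list(table = tg, fits = list(g1, g2),
                        spec = model_spec("y", "gaussian", character())),
                   class = "dn_dredge")
  expect_equal(average_top_set(ddg)$se, 0.2, tolerance = 1e-12)
})

test_that("the delta threshold is strict and a singleton set averages to itself", {
  set.seed(29)
  d <- data.frame(A = rnorm(40))
  d$y <- 2 + rnorm(40)
  dd <- dn_dredge(model_spec("y", "gaussian", terms = "A"), d)
  # force an exact boundary: second model at delta exactly 2 is excluded
  dd$table$delta <- c(0, 2)
  avg <- average_top_set(dd)
  expect_equal(nrow(attr(avg, "table")), 1)
  best <- dd$fits[[1]]
  expect_equal(avg$estimate, unname(best$estimate))
  expect_equal(avg$se, unname(best$se))
})

test_that("variance-partition R2 reduces to classical R2 and handles null fits", {
  set.seed(37)
  n <- 120
  d <- data.frame(x = rnorm(n))
  d$y <- 1 + 0.8 * d$x + rnorm(n)
  fit <- fit_model(model_spec("y", "gaussian", terms = "x"), d)
  r2 <- r2_nakagawa(fit)
  classical <- summary(lm(y ~ x, d))$r.squared
  expect_equal(unname(r2["marginal"]), classical, tolerance = 1e-10)
  expect_equal(unname(r2["marginal"]), unname(r2["conditional"]))

  null <- fit_model(model_spec("y", "gaussian", terms = character()), d)
  expect_equal(unname(r2_nakagawa(null)["marginal"]), 0)
})

test_that("R2 is ordered and bounded across supported families", {
  set.seed(41)
  n <- 200
  d <- data.frame(x = rnorm(n), g = rep(sprintf("g%d", 1:20), each = 10))
  d$y <- rpois(n, exp(0.5 + 0.3 * d$x + rep(rnorm(20, 0, 0.4), each = 10)))
  fit <- fit_model(model_spec("y", "poisson", terms = "x", random = "g"), d)
  r2 <- r2_nakagawa(fit)
  expect_true(r2["marginal"] >= 0 && r2["marginal"] <= r2["conditional"])
  expect_true(r2["conditional"] <= 1)
})

test_that("adding a pure-noise covariate never decreases the log-likelihood", {
  set.seed(43)
  n <- 80
  d <- data.frame(x = rnorm(n), junk = rnorm(n))
  d$y <- 1 + 0.5 * d$x + rnorm(n)
  d$cnt <- rpois(n, exp(0.3 + 0.2 * d$x))
  d$failed <- rbinom(n, 1, 0.3)
  d$expo <- runif(n, 1, 20)
  for (fam in c("gaussian", "poisson")) {
    resp <- if (fam == "gaussian") "y" else "cnt"
    small <- fit_model(model_spec(resp, fam, terms = "x"), d)
    big <- fit_model(model_spec(resp, fam, terms = c("x", "junk")), d)
    expect_gte(big$logLik, small$logLik - 1e-8)
  }
  small <- logexp_fit(failed ~ x, d, exposure = "expo")
  big <- logexp_fit(failed ~ x + junk, d, exposure = "expo")
  expect_gte(big$logLik, small$logLik - 1e-8)
})
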
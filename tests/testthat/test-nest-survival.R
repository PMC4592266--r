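test_that("exposure days follow the last-active / first-inactive midpoint rule", {
  failed <- visits_df(c(10, 13, 16, 20, 24),
                      c(rep("active-eggs", 4), "depredated"))
  expect_equal(exposure_days(failed), (20 + 24) / 2 - 10)  # 12

  censored <- visits_df(c(10, 13, 16, 19), rep("active-eggs", 4))
  expect_equal(exposure_days(censored), 9)

  halfday <- visits_df(c(10, 14, 17, 20, 21),
                       c(rep("active-eggs", 4), "damaged"))
  expect_equal(exposure_days(halfday), 10.5)

  expect_error(exposure_days(visits_df(5, "active-eggs")), "two visits")
  expect_error(exposure_days(visits_df(c(5, 3), rep("active-eggs", 2))),
               "strictly increasing")
})

test_that("exposure splits additively at the hatch day", {
  # found day 0, hatch day 6, fails with midpoint day 10
  v <- visits_df(c(0, 3, 6, 8, 12),
                 c("active-eggs", "active-eggs", "active-nestlings",
                   "active-nestlings", "depredated"))
  sp <- split_exposure(v, hatch_day = 6)
  expect_equal(unname(sp), c(6, 4))

  # egg-stage failure before the projected hatch day
  v2 <- visits_df(c(0, 3, 5), c("active-eggs", "active-eggs", "depredated"))
  sp2 <- split_exposure(v2, hatch_day = 6)
  expect_equal(unname(sp2), c(4, 0))

  # found at the nestling stage: zero egg exposure
  v3 <- visits_df(c(0, 3, 6), rep("active-nestlings", 3))
  sp3 <- split_exposure(v3, hatch_day = 0)
  expect_equal(unname(sp3), c(0, 6))

  expect_error(split_exposure(v, hatch_day = 200), "monitored window")
})

test_that("the fledging rule classifies outcomes from visit histories", {
  fledged <- visits_df(c(0, 7, 10),
                       c("active-nestlings", "active-nestlings",
                         "empty-intact"),
                       n_nestlings = c(3L, 3L, NA))
  out <- classify_outcome(fledged, hatch_day = 0)
  expect_equal(out$outcome, "fledged")
  expect_equal(out$n_fledged, 3L)

  damaged <- visits_df(c(0, 7, 10),
                       c("active-nestlings", "active-nestlings", "damaged"),
                       n_nestlings = c(3L, 3L, NA))
  expect_equal(classify_outcome(damaged, hatch_day = 0)$outcome, "failed")

  # empty before the nestlings could have reached fledging age
  early <- visits_df(c(0, 3, 6),
                     c("active-nestlings", "active-nestlings",
                       "empty-intact"),
                     n_nestlings = c(4L, 4L, NA))
  expect_equal(classify_outcome(early, hatch_day = 0)$outcome, "failed")

  # brood reduction: hatched 4, fledged 3
  reduced <- visits_df(c(0, 4, 7, 10),
                       c(rep("active-nestlings", 3), "empty-intact"),
                       n_nestlings = c(4L, 3L, 3L, NA))
  out2 <- classify_outcome(reduced, hatch_day = 0)
  expect_equal(out2$outcome, "fledged")
  expect_equal(out2$n_fledged, 3L)
  expect_equal(out2$brood_reduced, 1L)

  # no hatch day: emptying from the nestling stage cannot be aged
  expect_equal(classify_outcome(fledged)$outcome, "unknown")
})

test_that("egg and nestling exposure always sum to the total", {
  sim <- simulate_dataset(sim_config(seed = 21, n_farms = 8))
  es <- summarize_exposure(sim$visits, sim$nests)
  for (i in seq_len(nrow(es))) {
    v <- sim$visits[sim$visits$nest_id == es$nest_id[i], ]
    hd <- es$hatch_day[i]
    tot <- exposure_days(v, failed = es$outcome[i] == "failed",
                         hatch_day = if (is.na(hd)) NULL else hd)
    expect_equal(es$egg_exposure[i] + es$nestling_exposure[i], tot)
  }
  expect_true(all(es$egg_exposure >= 0 & es$nestling_exposure >= 0))
  expect_true(all(es$nestling_failed[es$fledged == 1] == 0))
})

test_that("the Mayfield estimator and its boundary cases are exact", {
  m <- mayfield_dsr(1, 50, period = 21)
  expect_equal(m$dsr, 0.98)
  expect_equal(m$period_survival, 0.98^21)
  expect_equal(mayfield_dsr(0, 30)$se, 0)
  expect_equal(mayfield_dsr(0, 30)$dsr, 1)
  expect_equal(mayfield_dsr(5, 100)$daily_failure, 0.05)
  expect_error(mayfield_dsr(1, 0), "positive")
  # period survival decreases with horizon and with failure rate
  expect_true(mayfield_dsr(2, 100, period = 30)$period_survival <
              mayfield_dsr(2, 100, period = 10)$period_survival)
})

test_that("intercept-only logistic-exposure fit is the Mayfield estimator", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(20:100, 1)
    d <- data.frame(failed = rbinom(n, 1, 0.3),
                    exposure = runif(n, 0.5, 25))
    if (sum(d$failed) %in% c(0, n)) next
    fit <- logexp_fit(failed ~ 1, d, exposure = "exposure")
    expect_equal(unname(plogis(coef(fit))),
                 sum(d$failed) / sum(d$exposure), tolerance = 1e-12)
  }
})

test_that("covariate fits agree with binomial GLM on integer exposures", {
  set.seed(5)
  d <- simulate_logexp(400)
  mine <- logexp_fit(failed ~ z, d, exposure = "exposure")
  ref <- glm(cbind(failed, exposure - failed) ~ z, data = d,
             family = binomial())
  expect_equal(unname(coef(mine)), unname(coef(ref)), tolerance = 1e-8)
  expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
               tolerance = 1e-4)
})

test_that("likelihood at the MLE matches a generic numeric optimizer", {
  set.seed(9)
  d <- simulate_logexp(200)
  d$w <- rnorm(200)
  fit <- logexp_fit(failed ~ z + w, d, exposure = "exposure")
  nll <- function(b) {
    h <- plogis(b[1] + b[2] * d$z + b[3] * d$w)
    -sum(d$failed * log(h) + (d$exposure - d$failed) * log(1 - h))
  }
  opt <- optim(c(-3, 0, 0), nll, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  expect_equal(fit$logLik, -opt$value, tolerance = 1e-6)
  expect_equal(unname(coef(fit)), opt$par, tolerance = 1e-4)
})

test_that("all-success data raises a separation warning", {
  d <- data.frame(failed = rep(0, 30), exposure = runif(30, 2, 20))
  expect_warning(fit <- logexp_fit(failed ~ 1, d, exposure = "exposure"),
                 "separation")
  expect_true(fit$extra$separation)
})

test_that("interval likelihood and random-intercept variants fit", {
  set.seed(13)
  d <- simulate_logexp(300)
  d$farm <- rep(sprintf("f%02d", 1:15), each = 20)
  iv0 <- logexp_fit(failed ~ 1, d, exposure = "exposure",
                    method = "interval")
  # oracle: direct 1-d maximization of the interval likelihood
  nll <- function(b) {
    h <- plogis(b)
    -sum(ifelse(d$failed == 1, log(1 - (1 - h)^d$exposure),
                d$exposure * log(1 - h)))
  }
  oracle <- optimize(nll, c(-8, 0))$minimum
  expect_equal(unname(coef(iv0)), oracle, tolerance = 1e-4)
  iv <- logexp_fit(failed ~ z, d, exposure = "exposure",
                   method = "interval")
  expect_true(all(is.finite(coef(iv))))
  mm <- logexp_fit(failed ~ z, d, exposure = "exposure", random = "farm")
  expect_true(all(is.finite(coef(mm))))
  expect_equal(mm$k, 3)       # intercept, slope, farm variance
  expect_named(mm$varcomp, "farm")
})
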
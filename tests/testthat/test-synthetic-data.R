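zero_slopes <- c(hedge = 0, hedge_10_50 = 0, hedge_gt50 = 0,
                 fence_veg = 0, gappy = 0, fence_wall = 0)

test_that("identical seed and config give identical tables", {
  cfg <- sim_config(seed = 101, n_farms = 6)
  s1 <- simulate_dataset(cfg)
  s2 <- simulate_dataset(cfg)
  for (tb in c("farms", "boundaries", "territories", "nests", "visits",
               "watches", "masses"))
    expect_identical(s1[[tb]], s2[[tb]])
})

test_that("farm generation honours ranges and covers all habitat classes", {
  rng <- list(hedge = c(500, 500), hedge_10_50 = c(100, 900),
              hedge_gt50 = c(100, 900), fence_veg = c(100, 900),
              gappy = c(50, 800), fence_wall = c(200, 900))
  cfg <- sim_config(seed = 3, n_farms = 10, habitat_length_ranges = rng)
  fa <- gen_farms(cfg)
  tot <- boundary_lengths(fa$boundaries)
  expect_equal(tot$hedge, rep(500, 10), tolerance = 1e-9)  # degenerate range
  expect_setequal(unique(fa$boundaries$habitat), unname(habitat_classes))
  expect_length(unique(fa$boundaries$habitat), 6)
  expect_setequal(unique(fa$farms$management), c("organic", "conventional"))

  bad <- rng; bad$hedge <- c(900, 100)
  expect_error(sim_config(habitat_length_ranges = bad), "configuration error")
})

test_that("territory counts are Poisson with the configured log-linear mean", {
  cfg <- sim_config(n_farms = 800, seed = 5,
                    territory_intensity = list(
                      intercept = log(3), slopes = zero_slopes,
                      year_2008 = 0, landscape_organic = 0))
  fa <- gen_farms(cfg)
  te <- gen_territories(fa, cfg, years = 2007)
  m <- mean(te$counts$n_territories)
  expect_lt(abs(m - 3), 3 * sqrt(3 / 800))
  # zero-territory farms appear in the count table but place no points
  zero_farms <- te$counts$farm_id[te$counts$n_territories == 0]
  expect_gt(length(zero_farms), 0)
  expect_false(any(te$territories$farm_id %in% zero_farms))
})

test_that("counts increase with hedgerow length when its slope is positive", {
  slopes <- zero_slopes; slopes["hedge"] <- 0.5
  cfg <- sim_config(n_farms = 500, seed = 8,
                    territory_intensity = list(
                      intercept = -1, slopes = slopes,
                      year_2008 = 0, landscape_organic = 0))
  fa <- gen_farms(cfg)
  te <- gen_territories(fa, cfg, years = 2007)
  tot <- boundary_lengths(fa$boundaries)
  merged <- merge(te$counts, tot, by = "farm_id")
  expect_gt(cor(merged$hedge, merged$n_territories, method = "spearman"), 0)
})

test_that("an overflowing linear predictor is a configuration error", {
  cfg <- sim_config(n_farms = 2, seed = 1,
                    territory_intensity = list(
                      intercept = 40, slopes = zero_slopes,
                      year_2008 = 0, landscape_organic = 0))
  fa <- gen_farms(cfg)
  expect_error(gen_territories(fa, cfg), "overflow")
})

test_that("hazard limits: zero hazard fledges everything, certain failure nothing", {
  mk <- function(egg, nst) sim_config(
    seed = 12, n_farms = 6, nest_prob = 1,
    daily_failure = list(egg = egg, nestling = nst, egg_coefs = c(nnd = 0),
                         nestling_coefs = c(nnd = 0), nnd_center = 300))
  safe <- simulate_dataset(mk(0, 0))
  expect_true(all(safe$nests$true_fate == "fledged"))
  last_status <- tapply(safe$visits$status, safe$visits$nest_id,
                        function(s) s[length(s)])
  expect_true(all(last_status == "empty-intact"))
  es <- summarize_exposure(safe$visits, safe$nests)
  expect_true(all(es$fledged == 1))

  doomed <- simulate_dataset(mk(0, 1))
  expect_true(all(doomed$nests$true_fate != "fledged"))
  expect_true(all(doomed$nests$n_fledged_true == 0))
})

test_that("observed egg-stage failure rate matches the configured hazard", {
  cfg <- sim_config(n_farms = 80, nest_prob = 1, seed = 6,
                    daily_failure = list(egg = 0.03, nestling = 0.03,
                                         egg_coefs = c(nnd = 0),
                                         nestling_coefs = c(nnd = 0),
                                         nnd_center = 300))
  sim <- simulate_dataset(cfg)
  es <- summarize_exposure(sim$visits, sim$nests)
  expo <- sum(es$egg_exposure)
  expect_gt(expo, 5000)
  rate <- sum(es$egg_failed) / expo
  expect_lt(abs(rate - 0.03), 3 * sqrt(0.03 * 0.97 / expo))
})

test_that("noiseless watches equal the configured linear predictor", {
  cfg <- sim_config(seed = 14, n_farms = 10)
  cfg$provisioning$noise_sd <- 0
  sim <- simulate_dataset(cfg)
  w <- sim$watches
  cf <- attr(w, "true_coefs")
  ce <- cfg$provisioning$center
  nndc <- w$nnd - ce[["nnd"]]
  lp <- cf[["intercept"]] + cf[["nestling_age"]] * w$nestling_age +
    cf[["brood"]] * (w$brood_size - ce[["brood"]]) +
    cf[["corvid"]] * w$corvid_activity + cf[["nnd"]] * nndc +
    cf[["management_organic"]] * (w$management == "organic") +
    cf[["year_2008"]] * (w$year == 2008) +
    cf[["temperature"]] * (w$temperature - ce[["temperature"]]) +
    cf[["nnd:corvid"]] * nndc * w$corvid_activity +
    cf[["nnd:brood"]] * nndc * (w$brood_size - ce[["brood"]])
  expect_equal(w$trips_per_hour, lp, tolerance = 1e-12)

  # and a regression on the noiseless data recovers the interactions exactly
  w$nndc <- nndc; w$broodc <- w$brood_size - ce[["brood"]]
  w$tempc <- w$temperature - ce[["temperature"]]
  fit <- lm(trips_per_hour ~ nestling_age + broodc + corvid_activity + nndc +
              management + factor(year) + tempc + nndc:corvid_activity +
              nndc:broodc, data = w)
  expect_equal(unname(coef(fit)["corvid_activity:nndc"]),
               cf[["nnd:corvid"]], tolerance = 1e-10)
  expect_equal(unname(coef(fit)["broodc:nndc"]), cf[["nnd:brood"]],
               tolerance = 1e-10)
  # negative interaction: at high corvid activity provisioning declines
  # with territory spacing
  slope_high <- cf[["nnd"]] + cf[["nnd:corvid"]] * 59
  expect_lt(slope_high, 0)
})

test_that("a zero mass-gain slope on NND is recovered as no effect", {
  cfg <- sim_config(seed = 15, n_farms = 20, nest_prob = 1)
  cfg$mass$coefs[["nnd_per100"]] <- 0
  sim <- simulate_dataset(cfg)
  m <- sim$masses
  expect_gt(nrow(m), 100)
  fit <- summary(lm(mass_second ~ mass_first + hours_elapsed + age_second +
                      nnd, data = m))
  expect_lt(abs(fit$coefficients["nnd", "t value"]), 2)
})

test_that("the configured mass NND slope is recovered within its CI", {
  cfg <- sim_config(seed = 16, n_farms = 25, nest_prob = 1)
  sim <- simulate_dataset(cfg)
  m <- sim$masses
  m$nnd100 <- m$nnd / 100
  fit <- summary(lm(mass_second ~ mass_first + hours_elapsed + age_second +
                      nnd100, data = m))
  est <- fit$coefficients["nnd100", "Estimate"]
  se <- fit$coefficients["nnd100", "Std. Error"]
  truth <- attr(m, "true_coefs")[["nnd_per100"]]
  expect_lt(abs(est - truth), 1.96 * se)
})

test_that("referential integrity: nests on territories, watches on live nests", {
  sim <- simulate_dataset(sim_config(seed = 18, n_farms = 10))
  expect_true(all(sim$nests$territory_id %in% sim$territories$territory_id))
  expect_true(all(sim$visits$nest_id %in% sim$nests$nest_id))
  w <- merge(sim$watches, sim$nests, by = "nest_id")
  age <- w$day - w$true_hatch_day
  expect_true(all(age >= 2 & age <= 7))
  alive <- is.na(w$true_fail_day) | w$day < w$true_fail_day
  expect_true(all(alive))
})

test_that("tables round-trip through CSV with a seed header", {
  sim <- simulate_dataset(sim_config(seed = 19, n_farms = 4))
  dir <- withr::local_tempdir()
  paths <- write_sim_tables(sim, dir)
  expect_true(all(file.exists(file.path(dir, c("nests.csv", "visits.csv")))))
  first <- readLines(file.path(dir, "nests.csv"), n = 1)
  expect_equal(first, "# seed: 19")
  back <- read.csv(file.path(dir, "nests.csv"), comment.char = "#")
  expect_equal(nrow(back), nrow(sim$nests))
})
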
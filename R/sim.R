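# Synthetic-data generator: farms with classified boundary habitats,
# Poisson territory counts driven by log(length + 1) habitat covariates,
# a constant-hazard daily nest-failure process observed through a visit
# schedule, provisioning watches with density-by-predation and
# density-by-brood interactions, and linear nestling mass gain increasing
# with territory spacing.  Every stage draws from its own deterministic
# seed offset so individual generators and full runs are both reproducible.

#' Simulation configuration
#'
#' Builds and validates the configuration driving [simulate_dataset()] and
#' the individual `gen_*` generators.  Defaults emulate a two-year study of
#' paired organic/conventional farms: territory-count coefficients are the
#' published farmland values (hedgerow 0.394 and vegetated-fence 0.065 per
#' log-metre, fewer territories in the second year, more in organic
#' landscapes), baseline daily failure ~0.03 at both stages (consistent
#' with a ~45% per-nest success rate over a ~24-day nesting period), a
#' 3-day maximum visit interval, clutches of 3--4 eggs, and provisioning /
#' mass-gain structures carrying the density-by-corvid, density-by-brood
#' and density-on-growth effects the downstream models estimate.
#'
#' @param n_farms Number of farms (paired organic/conventional).
#' @param farm_extent Side of each (non-overlapping) square farm, metres.
#' @param habitat_length_ranges Named list (keys of [habitat_classes]) of
#'   `c(min, max)` total metres per class per farm.
#' @param territory_intensity List with `intercept`, named `slopes` per
#'   habitat class (per log(length+1) metre), `year_2008` and
#'   `landscape_organic` effects, all on the log scale.
#' @param daily_failure List with baseline `egg` and `nestling` daily
#'   failure probabilities in \[0,1\], named `egg_coefs` / `nestling_coefs`
#'   on the logit scale (currently `nnd`), and `nnd_center` (metres) at
#'   which the baselines apply.
#' @param visit_interval_max Maximum days between monitoring visits (>= 1).
#' @param nest_prob Probability a territory holds a monitored nest (at most
#'   one per territory).
#' @param clutch_probs Named probabilities over clutch sizes.
#' @param concealment_probs Probabilities over concealment scores 1--5.
#' @param brood_reduction_prob Probability a brood loses one nestling.
#' @param hatch_fail_prob Probability one egg fails to hatch.
#' @param incubation_days Days from clutch completion to hatching.
#' @param fledge_age Nestling age (days) at fledging.
#' @param provisioning List: `coefs` (trips/hour linear predictor, with
#'   `nnd:corvid` and `nnd:brood` interactions), `noise_sd`,
#'   `watches_per_nest`, covariate distributions (`corvid_mean`,
#'   `invert_meanlog`, `invert_sdlog`, `temp_mean`, `temp_sd`) and
#'   `center` values for nnd/brood/temperature.
#' @param mass List: `coefs` for second mass as a function of first mass,
#'   hours elapsed, age and NND (`nnd_per100`, grams per 100 m), `noise_sd`,
#'   and the first-mass model (`mass1_base`, `mass1_per_day`, `mass1_sd`).
#' @param seed Integer seed; identical seed and config give byte-identical
#'   tables.
#' @return Object of class `dn_sim_config`.
#' @export
sim_config <- function(
    n_farms = 18,
    farm_extent = 1000,
    habitat_length_ranges = list(
      hedge = c(500, 3000), hedge_10_50 = c(100, 1500),
      hedge_gt50 = c(100, 1500), fence_veg = c(100, 1500),
      gappy = c(50, 1000), fence_wall = c(200, 2000)),
    territory_intensity = list(
      intercept = -1.231,
      slopes = c(hedge = 0.394, hedge_10_50 = 0.043, hedge_gt50 = -0.056,
                 fence_veg = 0.065, gappy = 0, fence_wall = 0),
      year_2008 = -0.748,
      landscape_organic = 0.364),
    daily_failure = list(egg = 0.03, nestling = 0.03,
                         egg_coefs = c(nnd = 0),
                         nestling_coefs = c(nnd = -0.002),
                         nnd_center = 300),
    visit_interval_max = 3,
    nest_prob = 0.5,
    clutch_probs = c("3" = 0.68, "4" = 0.32),
    concealment_probs = c(0.05, 0.10, 0.20, 0.35, 0.30),
    brood_reduction_prob = 0.24,
    hatch_fail_prob = 0.2,
    incubation_days = 12,
    fledge_age = 9,
    provisioning = list(
      coefs = c(intercept = 8, nestling_age = 0.3, brood = 0.5,
                corvid = -0.05, nnd = 0.004, management_organic = -1,
                year_2008 = 0.5, temperature = 0.05,
                "nnd:corvid" = -0.0008, "nnd:brood" = -0.001),
      noise_sd = 2, watches_per_nest = 2,
      corvid_mean = 3, invert_meanlog = 1, invert_sdlog = 0.6,
      temp_mean = 15, temp_sd = 3,
      center = c(nnd = 300, brood = 3, temperature = 15)),
    mass = list(
      coefs = c(intercept = 1.0, mass1 = 0.8, hours = 0.05, age = 0.4,
                nnd_per100 = 0.3),
      noise_sd = 0.5, mass1_base = 5.5, mass1_per_day = 1.3, mass1_sd = 0.7),
    seed = 1L) {
  cfg <- list(n_farms = n_farms, farm_extent = farm_extent,
              habitat_length_ranges = habitat_length_ranges,
              territory_intensity = territory_intensity,
              daily_failure = daily_failure,
              visit_interval_max = visit_interval_max,
              nest_prob = nest_prob, clutch_probs = clutch_probs,
              concealment_probs = concealment_probs,
              brood_reduction_prob = brood_reduction_prob,
              hatch_fail_prob = hatch_fail_prob,
              incubation_days = incubation_days, fledge_age = fledge_age,
              provisioning = provisioning, mass = mass,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "dn_sim_config")
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$daily_failure$egg, cfg$daily_failure$nestling,
             cfg$nest_prob, cfg$brood_reduction_prob, cfg$hatch_fail_prob,
             cfg$clutch_probs, cfg$concealment_probs)
  if (any(probs < 0 | probs > 1))
    stop("configuration error: probabilities must lie in [0, 1]")
  if (cfg$farm_extent <= 0 || cfg$n_farms < 1)
    stop("configuration error: extents and counts must be positive")
  if (cfg$visit_interval_max < 1)
    stop("configuration error: visit_interval_max must be >= 1")
  if (!setequal(names(cfg$habitat_length_ranges), names(habitat_classes)))
    stop("configuration error: habitat_length_ranges must cover all classes")
  for (k in names(cfg$habitat_length_ranges)) {
    r <- cfg$habitat_length_ranges[[k]]
    if (length(r) != 2 || r[1] > r[2] || r[1] < 0)
      stop(sprintf("configuration error: invalid length range for %s", k))
  }
  invisible(cfg)
}

.stage_seed <- function(cfg, offset)
  set.seed((cfg$seed + offset) %% .Machine$integer.max)

#' Generate farms and boundary segments
#'
#' Farms come in organic/conventional pairs, each pair inside a landscape
#' that alternates between organic and conventional; farms occupy
#' non-overlapping squares.  Each habitat class gets a per-farm total length
#' drawn from its configured range, split into 1--3 segments whose lengths
#' sum exactly to the total.  Segments carry a synthetic planar geometry
#' (start point and bearing within the farm square) used to place
#' territories.
#'
#' @param config A `dn_sim_config`.
#' @return List with `farms` (farm_id, management, landscape, origin_x,
#'   origin_y) and `boundaries` (farm_id, segment_id, habitat, length_m,
#'   x0, y0, bearing).
#' @export
gen_farms <- function(config) {
  validate_sim_config(config)
  .stage_seed(config, 0L)
  n <- config$n_farms
  ext <- config$farm_extent
  farm_id <- sprintf("F%02d", seq_len(n))
  management <- rep(c("organic", "conventional"), length.out = n)
  landscape <- rep(rep(c("organic", "conventional"), each = 2),
                   length.out = n)
  farms <- data.frame(farm_id = farm_id, management = management,
                      landscape = landscape,
                      origin_x = (seq_len(n) - 1) * ext * 1.5,
                      origin_y = 0)
  rows <- list()
  for (i in seq_len(n)) {
    for (key in names(habitat_classes)) {
      r <- config$habitat_length_ranges[[key]]
      total <- runif(1, r[1], r[2])
      n_seg <- sample(1:3, 1)
      wts <- runif(n_seg)
      lens <- total * wts / sum(wts)
      lens[n_seg] <- total - sum(lens[-n_seg])   # exact total
      for (s in seq_len(n_seg)) {
        rows[[length(rows) + 1]] <- data.frame(
          farm_id = farm_id[i],
          segment_id = sprintf("%s_%s_%d", farm_id[i], key, s),
          habitat = habitat_classes[[key]],
          length_m = lens[s],
          x0 = farms$origin_x[i] + runif(1, 0, ext),
          y0 = farms$origin_y[i] + runif(1, 0, ext),
          bearing = runif(1, 0, 2 * pi))
      }
    }
  }
  boundaries <- do.call(rbind, rows)
  rownames(boundaries) <- NULL
  list(farms = farms, boundaries = boundaries)
}

#' Generate territory points from farm habitat
#'
#' Per farm-year the territory count is Poisson with log mean
#' `intercept + sum(slope_k * log(length_k + 1)) + year + landscape` terms;
#' points are placed uniformly along boundary segments chosen with
#' probability proportional to length, re-drawn on exact coordinate
#' duplicates so nearest-neighbour distances are never zero.
#'
#' @param farms Output of [gen_farms()] (the full list).
#' @param config A `dn_sim_config`.
#' @param years Years simulated (default 2007--2008; the year effect applies
#'   to 2008).
#' @return List with `territories` (territory_id, farm_id, year,
#'   management, landscape, x, y) and `counts` (farm_id, year,
#'   n_territories) — farms with zero territories appear in `counts` only.
#' @export
gen_territories <- function(farms, config, years = c(2007, 2008)) {
  validate_sim_config(config)
  .stage_seed(config, 1L)
  totals <- boundary_lengths(farms$boundaries)
  ti <- config$territory_intensity
  counts <- list(); pts <- list()
  for (yr in years) {
    for (i in seq_len(nrow(farms$farms))) {
      f <- farms$farms[i, ]
      tot <- totals[totals$farm_id == f$farm_id, ]
      eta <- ti$intercept +
        sum(vapply(names(ti$slopes), function(k)
          ti$slopes[[k]] * log(tot[[k]] + 1), numeric(1))) +
        ti$year_2008 * (yr == 2008) +
        ti$landscape_organic * (f$landscape == "organic")
      if (abs(eta) > 30)
        stop("configuration error: territory linear predictor overflow")
      n_t <- rpois(1, exp(eta))
      counts[[length(counts) + 1]] <- data.frame(
        farm_id = f$farm_id, year = yr, n_territories = n_t)
      if (n_t == 0) next
      segs <- farms$boundaries[farms$boundaries$farm_id == f$farm_id, ]
      placed <- matrix(NA_real_, 0, 2)
      for (j in seq_len(n_t)) {
        repeat {
          s <- segs[sample(nrow(segs), 1, prob = segs$length_m), ]
          u <- runif(1)
          xy <- c(s$x0 + u * s$length_m * cos(s$bearing),
                  s$y0 + u * s$length_m * sin(s$bearing))
          if (!any(placed[, 1] == xy[1] & placed[, 2] == xy[2])) break
        }
        placed <- rbind(placed, xy)
        pts[[length(pts) + 1]] <- data.frame(
          territory_id = sprintf("%s_%d_T%02d", f$farm_id, yr, j),
          farm_id = f$farm_id, year = yr,
          management = f$management, landscape = f$landscape,
          x = xy[1], y = xy[2])
      }
    }
  }
  territories <- if (length(pts)) do.call(rbind, pts) else
    data.frame(territory_id = character(), farm_id = character(),
               year = numeric(), management = character(),
               landscape = character(), x = numeric(), y = numeric())
  rownames(territories) <- NULL
  list(territories = territories, counts = do.call(rbind, counts))
}

.hazard <- function(base, coefs, nnd, center) {
  eta <- qlogis(base)
  if (!is.null(coefs) && "nnd" %in% names(coefs))
    eta <- eta + coefs[["nnd"]] * (nnd - center)
  plogis(eta)
}

#' Generate nests and visit histories
#'
#' At most one nest per territory (with probability `nest_prob`).  The true
#' fate follows a daily Bernoulli failure process at stage-specific hazards
#' (logit-linear in NND around `nnd_center`), starting at nest discovery;
#' surviving broods fledge at `fledge_age` days.  Visits run from discovery
#' at the configured maximum interval with mandated checks at nestling ages
#' 7 and 10 (no visits between, mimicking field practice near fledging);
#' failure is observed only as an interval-censored status (depredated,
#' damaged or empty-intact) at the first visit after the latent failure
#' day.  True fates, hazards and fail days are stored alongside for
#' recovery tests.
#'
#' @param territories Output of [gen_territories()] (the full list) or its
#'   `territories` data frame.
#' @param config A `dn_sim_config`.
#' @return List with `nests` (one row per nest incl. `nnd`, `concealment`,
#'   `clutch`, observed `hatch_day` — `NA` when the nest failed before
#'   hatching — and `true_*` columns) and `visits` (nest_id, day, status,
#'   n_eggs, n_nestlings).
#' @export
gen_nests <- function(territories, config) {
  validate_sim_config(config)
  .stage_seed(config, 2L)
  terr <- if (is.list(territories) && !is.data.frame(territories))
    territories$territories else territories
  if (nrow(terr) == 0)
    return(list(nests = data.frame(), visits = data.frame()))
  dens <- territory_density(terr)
  df <- config$daily_failure
  nests <- list(); visits <- list()
  for (i in seq_len(nrow(terr))) {
    if (runif(1) > config$nest_prob) next
    tr <- terr[i, ]
    nnd_i <- dens$nnd[i]
    h_egg <- .hazard(df$egg, df$egg_coefs, nnd_i, df$nnd_center)
    h_nst <- .hazard(df$nestling, df$nestling_coefs, nnd_i, df$nnd_center)
    clutch <- as.integer(sample(names(config$clutch_probs), 1,
                                prob = config$clutch_probs))
    concealment <- sample(1:5, 1, prob = config$concealment_probs)
    start_day <- sample(1:50, 1)
    hatch <- start_day + config$incubation_days
    found_day <- start_day + sample(0:(config$incubation_days + 2), 1)
    fledge_day <- hatch + config$fledge_age
    brood <- clutch - rbinom(1, 1, config$hatch_fail_prob)
    brood <- max(brood, 1L)
    reduce_day <- if (runif(1) < config$brood_reduction_prob && brood > 1)
      hatch + sample(1:6, 1) else NA_integer_

    # latent daily failure process from discovery
    fail_day <- NA_integer_
    d <- found_day
    while (d < fledge_day) {
      d <- d + 1
      h <- if (d <= hatch) h_egg else h_nst
      if (runif(1) < h) { fail_day <- d; break }
    }
    fate <- if (is.na(fail_day)) "fledged"
            else if (fail_day <= hatch) "failed_egg" else "failed_nestling"

    # visit schedule: discovery, then every visit_interval_max days, with
    # mandated age-7 and age-10 checks and a gap in between
    sched <- seq(found_day, fledge_day + 1 + config$visit_interval_max,
                 by = config$visit_interval_max)
    sched <- sort(unique(c(sched, hatch + 7, hatch + 10)))
    sched <- sched[sched >= found_day &
                     !(sched > hatch + 7 & sched < hatch + 10)]
    vrows <- list()
    for (day in sched) {
      if (!is.na(fail_day) && day >= fail_day) {
        status <- sample(c("depredated", "damaged", "empty-intact"), 1,
                         prob = c(0.5, 0.2, 0.3))
        vrows[[length(vrows) + 1]] <- data.frame(
          day = day, status = status, n_eggs = NA_integer_,
          n_nestlings = NA_integer_)
        break
      }
      if (day <= hatch) {
        vrows[[length(vrows) + 1]] <- data.frame(
          day = day, status = "active-eggs", n_eggs = clutch,
          n_nestlings = NA_integer_)
      } else if (day < fledge_day) {
        cnt <- if (!is.na(reduce_day) && day >= reduce_day)
          brood - 1L else brood
        vrows[[length(vrows) + 1]] <- data.frame(
          day = day, status = "active-nestlings", n_eggs = NA_integer_,
          n_nestlings = cnt)
      } else {
        vrows[[length(vrows) + 1]] <- data.frame(
          day = day, status = "empty-intact", n_eggs = NA_integer_,
          n_nestlings = NA_integer_)
        break
      }
    }
    if (length(vrows) < 2) next   # discovered essentially at its end
    nest_id <- paste0("N_", tr$territory_id)
    v <- do.call(rbind, vrows)
    v <- data.frame(nest_id = nest_id, v)
    visits[[length(visits) + 1]] <- v
    n_fledged_true <- if (fate == "fledged") {
      if (!is.na(reduce_day)) brood - 1L else brood
    } else 0L
    observed_hatch <- if (fate == "failed_egg") NA_real_ else hatch
    nests[[length(nests) + 1]] <- data.frame(
      nest_id = nest_id, territory_id = tr$territory_id,
      farm_id = tr$farm_id, year = tr$year,
      management = tr$management, landscape = tr$landscape,
      nnd = nnd_i, ntnd = dens$ntnd[i], concealment = concealment,
      clutch = clutch, found_day = found_day, hatch_day = observed_hatch,
      brood_hatched = brood,
      true_hatch_day = hatch, true_fate = fate,
      true_fail_day = if (is.na(fail_day)) NA_real_ else fail_day,
      true_h_egg = h_egg, true_h_nestling = h_nst,
      n_fledged_true = n_fledged_true)
  }
  if (!length(nests))
    return(list(nests = data.frame(), visits = data.frame()))
  out_n <- do.call(rbind, nests); rownames(out_n) <- NULL
  out_v <- do.call(rbind, visits); rownames(out_v) <- NULL
  list(nests = out_n, visits = out_v)
}

#' Generate provisioning watches
#'
#' One row per watch for nests whose nestlings were alive at ages 2--7,
#' with Gaussian noise around the configured linear predictor, which
#' includes NND-by-corvid-activity and NND-by-brood-size interactions
#' (covariates centred as configured).  True coefficients are attached as
#' the `true_coefs` attribute for recovery tests.
#'
#' @param nests Output of [gen_nests()] (the full list) or its `nests`
#'   data frame.
#' @param config A `dn_sim_config`.
#' @return Data frame with nest_id, watch day/age, covariates and
#'   `trips_per_hour`; empty (with a warning) when no nest is eligible.
#' @export
gen_watches <- function(nests, config) {
  validate_sim_config(config)
  .stage_seed(config, 3L)
  nd <- if (is.list(nests) && !is.data.frame(nests)) nests$nests else nests
  pv <- config$provisioning
  cf <- pv$coefs; ce <- pv$center
  rows <- list()
  for (i in seq_len(nrow(nd))) {
    ns <- nd[i, ]
    if (ns$true_fate == "failed_egg") next
    last_age <- if (ns$true_fate == "fledged") config$fledge_age
                else ns$true_fail_day - ns$true_hatch_day - 1
    if (last_age < 2) next
    ages_ok <- seq(2, min(7, last_age))
    ages <- sort(ages_ok[sample.int(length(ages_ok),
                                    min(pv$watches_per_nest,
                                        length(ages_ok)))])
    for (a in ages) {
      corvid <- rpois(1, pv$corvid_mean)
      invert <- rlnorm(1, pv$invert_meanlog, pv$invert_sdlog)
      temp <- rnorm(1, pv$temp_mean, pv$temp_sd)
      tod <- runif(1, 6, 20)
      brood <- ns$brood_hatched
      nndc <- ns$nnd - ce[["nnd"]]
      lp <- cf[["intercept"]] + cf[["nestling_age"]] * a +
        cf[["brood"]] * (brood - ce[["brood"]]) +
        cf[["corvid"]] * corvid + cf[["nnd"]] * nndc +
        cf[["management_organic"]] * (ns$management == "organic") +
        cf[["year_2008"]] * (ns$year == 2008) +
        cf[["temperature"]] * (temp - ce[["temperature"]]) +
        cf[["nnd:corvid"]] * nndc * corvid +
        cf[["nnd:brood"]] * nndc * (brood - ce[["brood"]])
      rows[[length(rows) + 1]] <- data.frame(
        nest_id = ns$nest_id, farm_id = ns$farm_id, year = ns$year,
        management = ns$management, day = ns$true_hatch_day + a,
        nestling_age = a, brood_size = brood, nnd = ns$nnd, ntnd = ns$ntnd,
        corvid_activity = corvid, invert_abundance = invert,
        temperature = temp, time_of_day = tod,
        trips_per_hour = lp + rnorm(1, 0, pv$noise_sd))
    }
  }
  if (!length(rows)) {
    warning("no nests eligible for provisioning watches")
    return(structure(data.frame(), true_coefs = cf))
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  structure(out, true_coefs = cf)
}

#' Generate paired nestling mass measurements
#'
#' Two timed mass measurements per nestling for nests whose brood survived
#' long enough: the first mass follows linear early growth, the second is
#' the configured linear function of first mass, hours elapsed, age at
#' second measurement and NND (grams per 100 m), plus Gaussian noise.  True
#' coefficients are attached as the `true_coefs` attribute.
#'
#' @inheritParams gen_watches
#' @return Data frame with one row per nestling; empty (with a warning)
#'   when no nest is eligible.
#' @export
gen_masses <- function(nests, config) {
  validate_sim_config(config)
  .stage_seed(config, 4L)
  nd <- if (is.list(nests) && !is.data.frame(nests)) nests$nests else nests
  mc <- config$mass
  cf <- mc$coefs
  rows <- list()
  for (i in seq_len(nrow(nd))) {
    ns <- nd[i, ]
    if (ns$true_fate == "failed_egg") next
    last_age <- if (ns$true_fate == "fledged") config$fledge_age
                else ns$true_fail_day - ns$true_hatch_day - 1
    if (last_age < 5) next
    age1 <- sample(2:3, 1)
    hours <- runif(1, 42, 54)
    age2 <- age1 + hours / 24
    if (age2 > min(7, last_age)) next
    for (j in seq_len(ns$brood_hatched)) {
      mass1 <- mc$mass1_base + mc$mass1_per_day * age1 +
        rnorm(1, 0, mc$mass1_sd)
      mass2 <- cf[["intercept"]] + cf[["mass1"]] * mass1 +
        cf[["hours"]] * hours + cf[["age"]] * age2 +
        cf[["nnd_per100"]] * ns$nnd / 100 + rnorm(1, 0, mc$noise_sd)
      rows[[length(rows) + 1]] <- data.frame(
        nest_id = ns$nest_id, nestling_id = sprintf("%s_c%d", ns$nest_id, j),
        farm_id = ns$farm_id, year = ns$year, nnd = ns$nnd, ntnd = ns$ntnd,
        age_first = age1, age_second = age2, hours_elapsed = hours,
        time_second = runif(1, 8, 18),
        mass_first = mass1, mass_second = mass2)
    }
  }
  if (!length(rows)) {
    warning("no nests eligible for mass measurements")
    return(structure(data.frame(), true_coefs = cf))
  }
  out <- do.call(rbind, rows); rownames(out) <- NULL
  structure(out, true_coefs = cf)
}

#' Run the full synthetic-data generator
#'
#' Chains [gen_farms()], [gen_territories()], [gen_nests()],
#' [gen_watches()] and [gen_masses()] under the configured seed.
#'
#' @param config A `dn_sim_config`.
#' @return List with `farms`, `boundaries`, `territories`,
#'   `territory_counts`, `nests`, `visits`, `watches`, `masses` and the
#'   `config` used.
#' @export
simulate_dataset <- function(config = sim_config()) {
  fa <- gen_farms(config)
  te <- gen_territories(fa, config)
  nv <- gen_nests(te, config)
  wa <- suppressWarnings(gen_watches(nv, config))
  ma <- suppressWarnings(gen_masses(nv, config))
  list(farms = fa$farms, boundaries = fa$boundaries,
       territories = te$territories, territory_counts = te$counts,
       nests = nv$nests, visits = nv$visits, watches = wa, masses = ma,
       config = config)
}

#' Write simulation tables as CSV
#'
#' Writes each table with a `# seed: <seed>` comment header line so runs
#' are traceable; read back with `read.csv(..., comment.char = "#")`.
#'
#' @param sim Output of [simulate_dataset()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_sim_tables <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("farms", "boundaries", "territories", "territory_counts",
              "nests", "visits", "watches", "masses")
  paths <- character()
  for (tb in tables) {
    path <- file.path(dir, paste0(tb, ".csv"))
    con <- file(path, "w")
    writeLines(sprintf("# seed: %d", sim$config$seed), con)
    write.csv(sim[[tb]], con, row.names = FALSE)
    close(con)
    paths <- c(paths, path)
  }
  invisible(paths)
}

#' Simulate nest failure histories directly from a logistic-exposure model
#'
#' Lightweight generator for parameter-recovery studies: each nest draws a
#' standard-normal covariate `z`, a daily failure probability
#' `plogis(beta[1] + beta[2] * z)`, and a geometric time to failure
#' truncated at `max_days`, yielding the exposure days and 0/1 failure
#' indicator the logistic-exposure likelihood models.
#'
#' @param n Number of nests.
#' @param beta Length-2 coefficient vector (intercept, slope) on the logit
#'   daily-failure scale.
#' @param max_days Monitoring horizon in days.
#' @return Data frame with `z`, `failed`, `exposure`.
#' @export
simulate_logexp <- function(n, beta = c(-3.5, 0.8), max_days = 20) {
  z <- rnorm(n)
  h <- plogis(beta[1] + beta[2] * z)
  days_to_fail <- rgeom(n, h) + 1   # day of failure
  failed <- as.integer(days_to_fail <= max_days)
  exposure <- pmin(days_to_fail, max_days)
  data.frame(z = z, failed = failed, exposure = exposure)
}
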
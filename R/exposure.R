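# Reduction of nest-visit histories to Mayfield exposure days and outcomes.
#
# Visit statuses: "active-eggs", "active-nestlings", "empty-intact",
# "damaged", "depredated".  A nest is monitored at intervals of at most a
# few days; failure is interval-censored between the last active and first
# inactive visit.

.active_statuses <- c("active-eggs", "active-nestlings")
.visit_statuses <- c(.active_statuses, "empty-intact", "damaged", "depredated")

.check_visits <- function(visits) {
  stopifnot(all(c("day", "status") %in% names(visits)))
  if (nrow(visits) < 2) stop("at least two visits are required")
  if (is.unsorted(visits$day, strictly = TRUE))
    stop("visit days must be strictly increasing")
  bad <- setdiff(visits$status, .visit_statuses)
  if (length(bad)) stop("unknown visit status: ", bad[1])
  invisible(visits)
}

#' Classify the outcome of a monitored nest
#'
#' Applies the fledging rule: a nest whose nestlings were present at age 7
#' days or older and whose nest was found empty but intact at the following
#' check is deemed to have fledged; an empty-intact nest whose nestlings were
#' younger (or that still held eggs) has failed, as has any nest found
#' damaged or depredated.  The number fledged is the last nestling count
#' observed before the nest emptied, and partial brood reduction is flagged
#' when that count is below the initial brood size.
#'
#' @param visits Data frame of visits for one nest with columns `day`,
#'   `status` and (optionally) `n_eggs`, `n_nestlings`.
#' @param hatch_day Study day of hatching (observed or estimated); needed to
#'   age nestlings for the fledging rule.  When `NULL` and the nest emptied
#'   from the nestling stage the outcome is `"unknown"`.
#' @return List with elements `outcome` (`"fledged"`, `"failed"` or
#'   `"unknown"`), `n_fledged`, `brood_reduced` (0/1 or `NA`),
#'   `last_active_day` and `first_inactive_day` (`NA` if never inactive).
#' @export
classify_outcome <- function(visits, hatch_day = NULL) {
  .check_visits(visits)
  act <- visits$status %in% .active_statuses
  if (!any(act))
    return(list(outcome = "unknown", n_fledged = NA_integer_,
                brood_reduced = NA_integer_, last_active_day = NA_real_,
                first_inactive_day = NA_real_))
  last_active_i <- max(which(act))
  inactive_after <- which(!act & seq_len(nrow(visits)) > last_active_i)
  first_inactive_day <- if (length(inactive_after))
    visits$day[inactive_after[1]] else NA_real_
  first_inactive_status <- if (length(inactive_after))
    visits$status[inactive_after[1]] else NA_character_

  counts <- if ("n_nestlings" %in% names(visits)) visits$n_nestlings else
    rep(NA_integer_, nrow(visits))
  nestling_i <- which(visits$status == "active-nestlings" & !is.na(counts))
  initial_brood <- if (length(nestling_i)) counts[nestling_i[1]] else NA_integer_
  last_count <- if (length(nestling_i)) counts[max(nestling_i)] else NA_integer_

  if (is.na(first_inactive_day)) {           # censored: still active at end
    outcome <- "unknown"
    n_fledged <- NA_integer_
  } else if (first_inactive_status %in% c("damaged", "depredated")) {
    outcome <- "failed"
    n_fledged <- 0L
  } else {                                   # empty-intact
    prev_status <- visits$status[last_active_i]
    if (prev_status == "active-nestlings") {
      if (is.null(hatch_day)) {
        outcome <- "unknown"; n_fledged <- NA_integer_
      } else if (visits$day[last_active_i] - hatch_day >= 7) {
        outcome <- "fledged"
        n_fledged <- if (is.na(last_count)) NA_integer_ else last_count
      } else {
        outcome <- "failed"; n_fledged <- 0L
      }
    } else {
      outcome <- "failed"; n_fledged <- 0L   # emptied from the egg stage
    }
  }
  brood_reduced <- if (outcome == "fledged" && !is.na(initial_brood) &&
                       !is.na(last_count))
    as.integer(last_count < initial_brood) else NA_integer_
  list(outcome = outcome, n_fledged = n_fledged,
       brood_reduced = brood_reduced,
       last_active_day = visits$day[last_active_i],
       first_inactive_day = first_inactive_day)
}

#' Exposure days for one nest ("Last Active-B" rule)
#'
#' For a failed nest, exposure runs from the first visit to the midpoint of
#' the last-active and first-inactive visit days; for a successful or
#' censored nest it runs from the first visit to the last day the nest was
#' observed active.  Midpoints may yield half-day exposures, which are kept
#' as fractional values.
#'
#' @inheritParams classify_outcome
#' @param failed Logical; did the nest fail?  When `NULL`, inferred from the
#'   visit history via [classify_outcome()] (a nest of unknown outcome is
#'   treated as censored).
#' @return Total exposure in days (possibly fractional).
#' @examples
#' v <- data.frame(day = c(10, 14, 17, 20, 24),
#'                 status = c(rep("active-eggs", 4), "depredated"))
#' exposure_days(v)  # (20 + 24)/2 - 10 = 12
#' @export
exposure_days <- function(visits, failed = NULL, hatch_day = NULL) {
  .check_visits(visits)
  cls <- classify_outcome(visits, hatch_day = hatch_day)
  if (is.null(failed)) failed <- identical(cls$outcome, "failed")
  if (is.na(cls$last_active_day))
    stop("nest was never observed active; exposure undefined")
  first_day <- visits$day[1]
  if (failed) {
    if (is.na(cls$first_inactive_day))
      stop("nest marked failed but no inactive visit present")
    (cls$last_active_day + cls$first_inactive_day) / 2 - first_day
  } else {
    cls$last_active_day - first_day
  }
}

#' Split total exposure into egg- and nestling-stage exposure
#'
#' Exposure accrued before the hatch day is egg-stage exposure; exposure
#' after it is nestling-stage.  A nest that failed before its (projected)
#' hatch day therefore has zero nestling exposure, and a nest found at the
#' nestling stage (hatch day equal to the first visit) has zero egg
#' exposure.
#'
#' @inheritParams classify_outcome
#' @param hatch_day Study day of hatching.  May precede the first visit
#'   (nest found at the nestling stage, egg exposure 0) but must lie within
#'   30 days of the monitored window.
#' @param failed Passed to [exposure_days()].
#' @return Named numeric vector `c(egg = , nestling = )`; the two components
#'   always sum to the total exposure.
#' @export
split_exposure <- function(visits, hatch_day, failed = NULL) {
  .check_visits(visits)
  first_day <- visits$day[1]
  last_day <- visits$day[nrow(visits)]
  if (hatch_day < first_day - 30 || hatch_day > last_day + 30)
    stop("hatch_day lies outside the monitored window")
  total <- exposure_days(visits, failed = failed, hatch_day = hatch_day)
  end_day <- first_day + total
  egg <- max(0, min(end_day, hatch_day) - first_day)
  c(egg = egg, nestling = total - egg)
}

#' Summarize visit histories into per-nest exposure and outcome rows
#'
#' Runs [classify_outcome()], [exposure_days()] and [split_exposure()] over
#' every nest in a visit table and returns one row per nest, the input
#' expected by the stage-specific survival models.  Nests whose outcome
#' cannot be determined under the fledging rule are retained with outcome
#' `"unknown"` so the caller can decide to drop them (they are excluded from
#' failure models by convention).
#'
#' @param visits Data frame of visits for many nests: columns `nest_id`,
#'   `day`, `status`, optionally `n_eggs`, `n_nestlings`.
#' @param nests Optional data frame with `nest_id` and `hatch_day` (observed
#'   or estimated).  Nests without a hatch day that failed at the egg stage
#'   accrue all exposure to the egg stage; a hatch day at or before the
#'   first visit means the nest was found at the nestling stage (zero egg
#'   exposure).
#' @return Data frame with columns `nest_id`, `egg_exposure`,
#'   `nestling_exposure`, `egg_failed`, `nestling_failed`, `fledged`,
#'   `n_fledged`, `brood_reduced`, `hatch_day`, `outcome`.
#' @export
summarize_exposure <- function(visits, nests = NULL) {
  stopifnot(all(c("nest_id", "day", "status") %in% names(visits)))
  ids <- unique(visits$nest_id)
  hatch_lookup <- if (!is.null(nests))
    setNames(nests$hatch_day, nests$nest_id) else NULL
  rows <- lapply(ids, function(id) {
    v <- visits[visits$nest_id == id, , drop = FALSE]
    v <- v[order(v$day), , drop = FALSE]
    hd <- if (!is.null(hatch_lookup) && as.character(id) %in% names(hatch_lookup))
      unname(hatch_lookup[[as.character(id)]]) else NA_real_
    cls <- classify_outcome(v, hatch_day = if (is.na(hd)) NULL else hd)
    failed <- identical(cls$outcome, "failed")
    total <- exposure_days(v, failed = failed,
                           hatch_day = if (is.na(hd)) NULL else hd)
    if (is.na(hd)) {
      # never aged: all exposure accrues to the egg stage
      egg <- total; nst <- 0
    } else {
      sp <- split_exposure(v, hd, failed = failed)
      egg <- sp[["egg"]]; nst <- sp[["nestling"]]
    }
    egg_failed <- as.integer(failed && nst == 0)
    nestling_failed <- as.integer(failed && nst > 0)
    data.frame(nest_id = id, egg_exposure = egg, nestling_exposure = nst,
               egg_failed = egg_failed, nestling_failed = nestling_failed,
               fledged = as.integer(identical(cls$outcome, "fledged")),
               n_fledged = cls$n_fledged, brood_reduced = cls$brood_reduced,
               hatch_day = hd, outcome = cls$outcome)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Mayfield daily survival rate
#'
#' The classic exposure-day estimator: daily survival rate
#' \eqn{DSR = 1 - failures / exposure}, with a binomial standard error on the
#' daily failure proportion, and period survival \eqn{DSR^t}.
#'
#' @param failures Total number of nest failures.
#' @param exposure Total exposure in nest-days (> 0).
#' @param period Optional number of days over which to report period
#'   survival (e.g. the full nesting period).
#' @return List with `dsr`, `se`, `daily_failure` and, if `period` is given,
#'   `period_survival`.
#' @examples
#' mayfield_dsr(1, 50, period = 21)  # DSR 0.98, 21-day survival ~0.654
#' @export
mayfield_dsr <- function(failures, exposure, period = NULL) {
  if (exposure <= 0) stop("exposure must be positive")
  if (failures < 0 || failures > exposure)
    stop("failures must lie in [0, exposure]")
  p <- failures / exposure
  out <- list(dsr = 1 - p, daily_failure = p,
              se = sqrt(p * (1 - p) / exposure))
  if (!is.null(period)) out$period_survival <- (1 - p)^period
  out
}
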
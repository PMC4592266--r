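#' Territory density metrics (NND and NTND)
#'
#' Computes, for every territory centre, the nearest-neighbour distance
#' (NND) and the mean distance to the `k` nearest neighbours (NTND, `k = 3`
#' by default).  Distances are planar Euclidean in metres.  Neighbours are
#' sought only among territories of the same farm and year; each
#' neighbour distance is capped at `cap` metres (1 km by default), and when
#' fewer than `k` neighbours exist the missing neighbours contribute the cap
#' (so an isolated territory has NND = NTND = `cap` exactly).  Setting
#' `partial_average = TRUE` instead averages over however many neighbours
#' exist (still capped), falling back to `cap` only when there are none.
#'
#' @param points Data frame with columns `territory_id`, `farm_id`, `year`,
#'   `x`, `y` (coordinates in metres).
#' @param k Number of nearest neighbours for NTND (default 3).
#' @param cap Distance cap in metres (default 1000).
#' @param partial_average Logical; see Details.
#' @return Data frame with `territory_id`, `farm_id`, `year`, `nnd`, `ntnd`
#'   and `n_neighbours_used` (actual neighbours contributing, at most `k`).
#' @examples
#' pts <- data.frame(territory_id = 1:3, farm_id = "A", year = 2007,
#'                   x = c(0, 100, 300), y = 0)
#' territory_density(pts)$nnd  # 100 100 200
#' @export
territory_density <- function(points, k = 3, cap = 1000,
                              partial_average = FALSE) {
  req <- c("territory_id", "farm_id", "year", "x", "y")
  stopifnot(all(req %in% names(points)), cap > 0, k >= 1)
  if (any(!is.finite(points$x)) || any(!is.finite(points$y)))
    stop("coordinates must be finite")
  grp <- interaction(points$farm_id, points$year, drop = TRUE)
  out <- points[, c("territory_id", "farm_id", "year")]
  out$nnd <- out$ntnd <- NA_real_
  out$n_neighbours_used <- NA_integer_
  for (g in levels(grp)) {
    idx <- which(grp == g)
    xy <- cbind(points$x[idx], points$y[idx])
    if (anyDuplicated(xy))
      stop(sprintf("duplicate coordinates within farm-year group %s", g))
    n <- length(idx)
    if (n == 1) {
      out$nnd[idx] <- cap
      out$ntnd[idx] <- cap
      out$n_neighbours_used[idx] <- 0L
      next
    }
    for (j in seq_len(n)) {
      d <- sqrt((xy[, 1] - xy[j, 1])^2 + (xy[, 2] - xy[j, 2])^2)[-j]
      d <- pmin(d, cap)
      d <- sort(d)
      out$nnd[idx[j]] <- d[1]
      avail <- min(k, length(d))
      if (partial_average) {
        out$ntnd[idx[j]] <- mean(d[seq_len(avail)])
      } else {
        dk <- c(d[seq_len(avail)], rep(cap, k - avail))
        out$ntnd[idx[j]] <- mean(dk)
      }
      out$n_neighbours_used[idx[j]] <- avail
    }
  }
  rownames(out) <- NULL
  out
}

#' Nearest-neighbour distance only
#'
#' Convenience wrapper around [territory_density()] returning just the NND
#' column.
#' @inheritParams territory_density
#' @return Numeric vector of NND values in `points` row order.
#' @export
nnd <- function(points, cap = 1000) territory_density(points, cap = cap)$nnd

#' Mean distance to the k nearest neighbours
#'
#' Convenience wrapper around [territory_density()] returning just the NTND
#' column.
#' @inheritParams territory_density
#' @return Numeric vector of NTND values in `points` row order.
#' @export
ntnd <- function(points, k = 3, cap = 1000, partial_average = FALSE)
  territory_density(points, k = k, cap = cap,
                    partial_average = partial_average)$ntnd
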
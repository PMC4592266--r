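#' Boundary habitat classes
#'
#' The six boundary habitat classes used to describe field-boundary
#' vegetation.  Names are short column-safe keys; values are the descriptive
#' labels used in boundary tables.
#'
#' @format Named character vector of length 6.
#' @export
habitat_classes <- c(
  hedge       = "Hedge",
  hedge_10_50 = "Hedge with 10-50% trees",
  hedge_gt50  = "Hedge with >50% trees",
  fence_veg   = "Fence with vegetation",
  gappy       = "Gappy hedge",
  fence_wall  = "Fence or wall"
)

#' Classify a field boundary into a habitat class
#'
#' Applies the boundary-vegetation classification rules: for hedgerows the
#' gap check comes first (>20% gaps along the length makes a "Gappy hedge"),
#' then canopy-cover bands from trees over 3 m (<10% cover is plain "Hedge",
#' 10--50% inclusive is "Hedge with 10-50% trees", >50% is "Hedge with >50%
#' trees").  Non-hedgerow boundaries with >50% tree canopy are tree lines and
#' also fall in the ">50% trees" class; the remainder split on the width of
#' adjoining dense herbaceous vegetation at 1 m ("Fence with vegetation"
#' above 1 m, "Fence or wall" at or below it).
#'
#' Boundary values: exactly 10% and exactly 50% canopy fall in the middle
#' band; exactly 20% gaps is not gappy; exactly 1 m of herbaceous vegetation
#' is "Fence or wall" (the printed rules use strict inequalities).
#'
#' @param height Boundary vegetation height in metres (recorded but not used
#'   by the printed rules once `is_hedgerow` is known; kept for table
#'   completeness).
#' @param canopy_pct Percent canopy cover from trees over 3 m, in \[0, 100\].
#' @param gap_pct Percent gaps along the boundary length, in \[0, 100\].
#' @param herb_width Width in metres of adjoining dense herbaceous
#'   vegetation.
#' @param is_hedgerow Logical; is the boundary a hedgerow?
#' @return Character vector of habitat class labels (values of
#'   [habitat_classes]).
#' @examples
#' classify_boundary(2.5, canopy_pct = 5, gap_pct = 0, herb_width = 0,
#'                   is_hedgerow = TRUE)   # "Hedge"
#' classify_boundary(1.2, canopy_pct = 0, gap_pct = 0, herb_width = 1.5,
#'                   is_hedgerow = FALSE)  # "Fence with vegetation"
#' @export
classify_boundary <- function(height, canopy_pct, gap_pct, herb_width,
                              is_hedgerow) {
  n <- max(length(height), length(canopy_pct), length(gap_pct),
           length(herb_width), length(is_hedgerow))
  height <- rep_len(height, n); canopy_pct <- rep_len(canopy_pct, n)
  gap_pct <- rep_len(gap_pct, n); herb_width <- rep_len(herb_width, n)
  is_hedgerow <- rep_len(is_hedgerow, n)
  if (any(canopy_pct < 0 | canopy_pct > 100, na.rm = TRUE) ||
      any(gap_pct < 0 | gap_pct > 100, na.rm = TRUE))
    stop("percent covers must lie in [0, 100]")
  out <- character(n)
  for (i in seq_len(n)) {
    out[i] <- if (isTRUE(is_hedgerow[i])) {
      if (gap_pct[i] > 20) habitat_classes[["gappy"]]
      else if (canopy_pct[i] < 10) habitat_classes[["hedge"]]
      else if (canopy_pct[i] <= 50) habitat_classes[["hedge_10_50"]]
      else habitat_classes[["hedge_gt50"]]
    } else {
      if (canopy_pct[i] > 50) habitat_classes[["hedge_gt50"]] # tree line
      else if (herb_width[i] > 1) habitat_classes[["fence_veg"]]
      else habitat_classes[["fence_wall"]]
    }
  }
  out
}

#' Total boundary length per farm and habitat class
#'
#' Sums segment lengths by farm and habitat class, returning one row per farm
#' with one column per habitat class (zero where a class is absent).  Column
#' names are the keys of [habitat_classes].
#'
#' @param segments Data frame with columns `farm_id`, `habitat` (labels from
#'   [habitat_classes]) and `length_m` (metres).
#' @return Data frame with `farm_id` and six numeric length columns.
#' @export
boundary_lengths <- function(segments) {
  stopifnot(all(c("farm_id", "habitat", "length_m") %in% names(segments)))
  bad <- which(!segments$habitat %in% habitat_classes)
  if (length(bad))
    stop(sprintf("unknown habitat class %s in segment row %d",
                 dQuote(segments$habitat[bad[1]]), bad[1]))
  if (any(segments$length_m < 0)) stop("segment lengths must be >= 0")
  farms <- unique(segments$farm_id)
  out <- data.frame(farm_id = farms)
  for (key in names(habitat_classes)) {
    sub <- segments[segments$habitat == habitat_classes[[key]], ]
    tot <- tapply(sub$length_m, factor(sub$farm_id, levels = farms), sum)
    tot[is.na(tot)] <- 0
    out[[key]] <- as.numeric(tot)
  }
  out
}
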
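#' Total tablet mass from the component mass balance
#'
#' A tablet contains fixed masses of drug and cetyl alcohol while the
#' gel-forming polymer (HPMC K15M) and the lubricant (magnesium stearate)
#' are dosed as percentages of the *total* tablet mass, so the total solves
#' `total * (1 - hpmc/100 - mgst/100) = drug + cetyl`:
#' \deqn{total = \frac{drug + cetyl}{1 - hpmc/100 - mgst/100}}
#'
#' @param drug_mg Drug (e.g. metformin HCl) mass per tablet (mg).
#' @param cetyl_mg Cetyl alcohol (or other fixed excipient) mass (mg).
#' @param hpmc_pct HPMC as % of total tablet mass.
#' @param mgst_pct Magnesium stearate as % of total tablet mass.
#' @return Total tablet mass (mg), full precision (round at report time).
#'   All arguments are vectorized.
#' @export
#' @examples
#' tablet_mass(500, 200, 25, 5) # 1000
#' round(tablet_mass(500, 150, 5, 5), 1) # 722.2
tablet_mass <- function(drug_mg, cetyl_mg, hpmc_pct, mgst_pct) {
  if (any(drug_mg <= 0) || any(cetyl_mg <= 0)) {
    stop_validation("component masses must be positive")
  }
  if (any(hpmc_pct < 0) || any(mgst_pct < 0)) {
    stop_validation("percentage components must be non-negative")
  }
  denom <- 1 - hpmc_pct / 100 - mgst_pct / 100
  if (any(denom <= 0)) {
    stop_validation("percentage components must sum to less than 100% of the tablet")
  }
  (drug_mg + cetyl_mg) / denom
}

#' Tablet swelling percentage
#'
#' Weight gain of the hydrated tablet relative to its initial weight:
#' `(swollen - initial) / initial * 100`. A swollen weight below the
#' initial weight yields a negative value, which is returned with a
#' warning rather than rejected (blotting losses can produce it).
#'
#' @param initial_mg Initial (dry) tablet weight (mg).
#' @param swollen_mg Swollen tablet weight (mg) after blotting.
#' @return Swelling (%), vectorized.
#' @export
swelling_percent <- function(initial_mg, swollen_mg) {
  if (any(initial_mg <= 0) || any(swollen_mg <= 0)) {
    stop_validation("tablet weights must be positive")
  }
  out <- (swollen_mg - initial_mg) / initial_mg * 100
  if (any(out < 0)) warn("swollen weight below initial weight: negative swelling returned")
  out
}

#' Matrix erosion percentage
#'
#' Dry-matrix weight loss relative to the initial weight:
#' `(initial - dried) / initial * 100`. A dried weight above the initial
#' weight yields a negative value, returned with a warning.
#'
#' @param initial_mg Initial tablet weight (mg).
#' @param dried_mg Weight (mg) of the tablet after drying.
#' @return Matrix erosion (%), vectorized.
#' @export
erosion_percent <- function(initial_mg, dried_mg) {
  if (any(initial_mg <= 0) || any(dried_mg <= 0)) {
    stop_validation("tablet weights must be positive")
  }
  out <- (initial_mg - dried_mg) / initial_mg * 100
  if (any(out < 0)) warn("dried weight above initial weight: negative erosion returned")
  out
}

#' Swelling and erosion summary of a weight series
#'
#' Applies [swelling_percent()] and [erosion_percent()] across a
#' `swelling_series` (see [simulate_swelling()]) or any tibble with
#' columns `time_h`, `swollen_mg`, `dried_mg`.
#'
#' @param series A `swelling_series` tibble.
#' @param initial_mg Initial weight; defaults to the series attribute.
#' @return The series with `swelling_pct` and `erosion_pct` columns added.
#' @export
swelling_erosion <- function(series, initial_mg = attr(series, "initial_mg")) {
  if (is.null(initial_mg)) stop_validation("initial_mg is required")
  series$swelling_pct <- swelling_percent(initial_mg, series$swollen_mg)
  series$erosion_pct <- erosion_percent(initial_mg, series$dried_mg)
  series
}
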
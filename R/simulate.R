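#' Default dissolution sampling grid
#'
#' The 10-point sampling schedule (minutes) used throughout the package for
#' sustained-release dissolution runs.
#'
#' @return Numeric vector `c(15, 30, 45, 60, 120, 240, 480, 720, 1080, 1440)`.
#' @export
default_time_grid <- function() {
  c(15, 30, 45, 60, 120, 240, 480, 720, 1080, 1440)
}

#' Solve power-law release parameters from two target points
#'
#' Given two (time, release) anchors, solves the Korsmeyer-Peppas curve
#' Q(t) = k * t^n that passes through both (log-log two-equation system).
#' The package default reproduces a reference product releasing about
#' 30/60/80% at 60/240/480 min: anchoring at (60, 30) and (480, 80) gives
#' n = log(80/30)/log(480/60) and k = 30/60^n.
#'
#' @param times Two times (min).
#' @param targets Two cumulative release values (%) at those times.
#' @return A list with `k` (% per min^n) and `n_exp`.
#' @export
#' @examples
#' p <- kp_solve_targets(c(60, 480), c(30, 80))
#' p$k * c(60, 240, 480)^p$n_exp # approx (30, 58, 80)
kp_solve_targets <- function(times = c(60, 480), targets = c(30, 80)) {
  if (length(times) != 2 || length(targets) != 2) {
    stop_validation("kp_solve_targets needs exactly two (time, release) anchors")
  }
  if (any(times <= 0) || any(targets <= 0) || times[1] == times[2]) {
    stop_validation("anchor times and targets must be positive and times distinct")
  }
  n_exp <- log(targets[2] / targets[1]) / log(times[2] / times[1])
  k <- targets[1] / times[1]^n_exp
  list(k = k, n_exp = n_exp)
}

validate_curve <- function(k, n_exp, cap) {
  if (!is.numeric(k) || length(k) != 1 || !is.finite(k) || k <= 0) {
    stop_validation("k must be a single positive number (% per min^n)")
  }
  if (!is.numeric(n_exp) || length(n_exp) != 1 || n_exp <= 0 || n_exp >= 1.5) {
    stop_validation("n_exp must lie in (0, 1.5)")
  }
  if (!is.numeric(cap) || length(cap) != 1 || cap <= 0 || cap > 120) {
    stop_validation("cap must lie in (0, 120]")
  }
  invisible(TRUE)
}

#' Simulate a 12-unit dissolution run
#'
#' Generates per-unit cumulative release curves around a Korsmeyer-Peppas
#' mean curve `min(cap, k * t^n_exp)`. Each unit receives independent
#' additive Gaussian noise (SD `unit_sd` percentage points) at every time
#' point; each unit's series is then made non-decreasing by a running
#' maximum and clipped to `[0, cap]`. With `unit_sd = 0` all units equal the
#' mean curve exactly, and a fixed `seed` makes the output reproducible.
#'
#' @param k Power-law rate constant (% per min^n). Default is the reference
#'   curve through (60 min, 30%) and (480 min, 80%).
#' @param n_exp Release exponent.
#' @param times Sampling times (min); default [default_time_grid()].
#' @param n_units Number of tablet units (default 12, the usual bootstrap
#'   f2 sample size).
#' @param unit_sd Between-tablet additive noise SD in percentage points
#'   (default 2).
#' @param cap Maximum cumulative release % (default 100).
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @param product_id Product label for the resulting profile.
#' @return A [dissolution_profile()].
#' @export
simulate_profiles <- function(k = 4.34915, n_exp = 0.4716792,
                              times = default_time_grid(), n_units = 12,
                              unit_sd = 2, cap = 100, seed = NULL,
                              product_id = "SIM") {
  validate_curve(k, n_exp, cap)
  if (!is.numeric(n_units) || n_units < 1) stop_validation("n_units must be >= 1")
  if (!is.numeric(unit_sd) || unit_sd < 0) stop_validation("unit_sd must be >= 0")
  if (any(times <= 0) || is.unsorted(times, strictly = TRUE)) {
    stop_validation("times must be positive and strictly increasing")
  }
  if (!is.null(seed)) set.seed(seed)

  mean_curve <- pmin(cap, k * times^n_exp)
  p <- length(times)
  units <- vapply(seq_len(n_units), function(i) {
    y <- mean_curve + rnorm(p, 0, unit_sd)
    pmin(cap, pmax(0, cummax(y)))
  }, numeric(p))

  dissolution_profile(tibble::tibble(
    product = product_id,
    unit = rep(seq_len(n_units), each = p),
    time_min = rep(times, n_units),
    release_pct = as.vector(units)
  ))
}

#' Published linear response-surface coefficients
#'
#' Actual-scale (physical units) coefficients of the linear models relating
#' cumulative release at 60, 240 and 480 min (responses R1-R3, %) to cetyl
#' alcohol mass A (mg) and HPMC K15M proportion B (% of tablet mass), as
#' obtained from a face-centered response-surface study of a floating
#' metformin tablet. They serve as the package's worked default for
#' response simulation, prediction and threshold solving.
#'
#' @return Named list of coefficient vectors `c(intercept, A, B)` for
#'   responses `R1`, `R2`, `R3`.
#' @export
reference_response_coeffs <- function() {
  list(
    R1 = c(intercept = 53.73, A = -0.03, B = -0.59),
    R2 = c(intercept = 94.48, A = -0.06, B = -0.83),
    R3 = c(intercept = 111.17, A = -0.06, B = -0.78)
  )
}

eval_actual_equation <- function(coeffs, A, B) {
  full <- c(intercept = 0, A = 0, B = 0, AB = 0, A2 = 0, B2 = 0)
  unknown <- setdiff(names(coeffs), names(full))
  if (length(unknown) > 0 || is.null(names(coeffs)) || !("intercept" %in% names(coeffs))) {
    stop_validation(paste0(
      "coefficients must be named among intercept, A, B, AB, A2, B2",
      if (length(unknown) > 0) paste0("; unknown: ", paste(unknown, collapse = ", "))
    ))
  }
  full[names(coeffs)] <- coeffs
  full[["intercept"]] + full[["A"]] * A + full[["B"]] * B +
    full[["AB"]] * A * B + full[["A2"]] * A^2 + full[["B2"]] * B^2
}

#' Fill a DoE design with simulated responses
#'
#' Evaluates actual-scale response equations at every design point and adds
#' independent Gaussian noise. With `noise_sd = 0` the responses reproduce
#' the equations exactly, which is how the noiseless model-recovery tests
#' are built.
#'
#' @param design A design tibble from [build_ffd_design()] or
#'   [build_ccf_design()] (needs columns `A_mg`, `B_pct`).
#' @param coeffs Named list of actual-equation coefficient vectors, one per
#'   response; names among `intercept`, `A`, `B`, `AB`, `A2`, `B2`.
#'   Default [reference_response_coeffs()].
#' @param noise_sd Gaussian noise SD added to every response value.
#' @param seed Integer seed; `NULL` leaves the RNG state alone.
#' @return The design with one numeric column appended per response.
#' @export
simulate_doe_responses <- function(design, coeffs = reference_response_coeffs(),
                                   noise_sd = 0, seed = NULL) {
  if (!all(c("A_mg", "B_pct") %in% names(design))) {
    stop_validation("design must have columns A_mg and B_pct")
  }
  if (is.null(names(coeffs)) || any(names(coeffs) == "")) {
    stop_validation("coeffs must be a named list, one element per response")
  }
  if (!is.null(seed)) set.seed(seed)
  for (resp in names(coeffs)) {
    mu <- eval_actual_equation(coeffs[[resp]], design$A_mg, design$B_pct)
    design[[resp]] <- mu + if (noise_sd > 0) rnorm(nrow(design), 0, noise_sd) else 0
  }
  design
}

#' Simulate a tablet swelling / erosion weight series
#'
#' Emulates the weight trajectory of a gel-forming matrix tablet during
#' dissolution: water uptake follows a saturating exponential (rapid early
#' swelling, plateau within about a day), while the dry matrix erodes
#' linearly with time.
#'
#' @param initial_mg Initial tablet weight (mg).
#' @param swell_frac Plateau water uptake as a fraction of the initial
#'   weight (e.g. 0.8 means the swollen weight saturates at 1.8x initial).
#' @param swell_rate Swelling rate constant (per hour); the curve is
#'   `initial * (1 + swell_frac * (1 - exp(-swell_rate * t)))`.
#' @param erosion_rate Linear matrix erosion rate (% of initial weight per
#'   hour), so the dried weight at time t is `initial * (1 - erosion_rate * t / 100)`.
#' @param times_h Sampling times (hours).
#' @param noise_sd Additive Gaussian weighing noise SD (mg) on the swollen
#'   weights; the dried weights are noise-free by construction.
#' @param seed Integer seed.
#' @return A tibble of class `swelling_series` with columns `time_h`,
#'   `swollen_mg`, `dried_mg`, and attribute `initial_mg`.
#' @export
simulate_swelling <- function(initial_mg, swell_frac = 0.8, swell_rate = 0.5,
                              erosion_rate = 2, times_h = c(0.5, 1, 2, 4, 6, 12, 24),
                              noise_sd = 0, seed = NULL) {
  if (!is.numeric(initial_mg) || initial_mg <= 0) {
    stop_validation("initial_mg must be positive")
  }
  if (swell_frac < 0 || swell_rate < 0 || erosion_rate < 0 || noise_sd < 0) {
    stop_validation("swelling/erosion rates and noise_sd must be non-negative")
  }
  if (erosion_rate * max(times_h) >= 100) {
    stop_validation("linear erosion would consume the whole tablet within the sampling window")
  }
  if (!is.null(seed)) set.seed(seed)
  swollen <- initial_mg * (1 + swell_frac * (1 - exp(-swell_rate * times_h)))
  if (noise_sd > 0) swollen <- swollen + rnorm(length(times_h), 0, noise_sd)
  dried <- initial_mg * (1 - erosion_rate * times_h / 100)
  out <- tibble::tibble(time_h = times_h, swollen_mg = swollen, dried_mg = dried)
  attr(out, "initial_mg") <- initial_mg
  class(out) <- c("swelling_series", class(out))
  out
}
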
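#' Fit the four classical release-kinetics models
#'
#' Fits, by least squares on each model's conventional linearized scale,
#' the four standard models of cumulative drug release Q(t) (%):
#'
#' * zero-order: `Q = k t` (through the origin);
#' * first-order: `ln(100 - Q) = ln(100) - k t` (intercept fixed at
#'   `ln(100)`, i.e. 100% load);
#' * Higuchi: `Q = k sqrt(t)` (through the origin);
#' * Korsmeyer-Peppas: `log10(Q/100) = log10(k) + n log10(t)`, fitted only
#'   on early points with `0 < Q <= kp_max_release` (default 60%), the
#'   range over which the power law is valid.
#'
#' R-squared is reported on each model's own fitting scale (uncentered for
#' the through-origin models, as `lm()` reports it). Points with
#' `Q >= 100` are excluded from the first-order transform with a warning;
#' a model with fewer than 2 usable points is marked unfit.
#'
#' @param times Sampling times (min).
#' @param release Mean cumulative release (%) across units at those times
#'   (fits are on the mean profile, not per unit).
#' @param kp_max_release Upper release bound (%) for points entering the
#'   Korsmeyer-Peppas fit.
#' @return A tibble of class `release_fits` with one row per model:
#'   `model`, `k`, `n` (exponent, Korsmeyer-Peppas only), `r_squared`,
#'   `n_points`, `n_params`, `ok`. The zero-order and Higuchi `k` are on
#'   the percent scale (%/min, %/sqrt(min)); the first-order `k` is per
#'   min; the Korsmeyer-Peppas `k` is on the Mt/Minf fractional scale
#'   (per min^n).
#' @export
#' @examples
#' t <- c(15, 30, 60, 120, 240, 480)
#' q <- 100 * 0.04 * t^0.4
#' fit_release_models(t, q) # Korsmeyer-Peppas recovers n = 0.4, k = 0.04
fit_release_models <- function(times, release, kp_max_release = 60) {
  if (length(times) != length(release)) {
    stop_validation("times and release must have equal length")
  }
  keep <- release > 0
  if (sum(keep) < 3) {
    stop_validation("need at least 3 time points with positive release")
  }
  ord <- order(times)
  times <- times[ord]
  release <- release[ord]

  unfit <- function(model, n_params) tibble::tibble(
    model = model, k = NA_real_, n = NA_real_, r_squared = NA_real_,
    n_points = 0L, n_params = n_params, ok = FALSE
  )
  # R^2 on the fitting scale; uncentered total SS for through-origin models
  # (the same convention summary.lm uses), computed directly so that exact
  # fits do not trip lm's perfect-fit notice
  r2_of <- function(fit) {
    y <- fit$model[[1]]
    ss_res <- sum(fit$residuals^2)
    ss_tot <- if (attr(fit$terms, "intercept") == 1) sum((y - mean(y))^2) else sum(y^2)
    1 - ss_res / ss_tot
  }
  from_lm <- function(model, fit, k, n = NA_real_, n_params = 1L) {
    tibble::tibble(
      model = model, k = k, n = n,
      r_squared = r2_of(fit),
      n_points = length(fit$residuals), n_params = n_params, ok = TRUE
    )
  }

  t0 <- times[keep]
  q0 <- release[keep]

  fit_zero <- lm(q0 ~ 0 + t0)
  zero <- from_lm("zero_order", fit_zero, coef(fit_zero)[[1]])

  s <- sqrt(t0)
  fit_higu <- lm(q0 ~ 0 + s)
  higu <- from_lm("higuchi", fit_higu, coef(fit_higu)[[1]])

  fo_keep <- q0 < 100
  if (any(!fo_keep)) {
    warn("first-order fit: points with Q >= 100% excluded from the log transform")
  }
  first <- if (sum(fo_keep) >= 2) {
    tf <- t0[fo_keep]
    y <- log(100 - q0[fo_keep]) - log(100)
    fit_fo <- lm(y ~ 0 + tf)
    from_lm("first_order", fit_fo, -coef(fit_fo)[[1]])
  } else {
    unfit("first_order", 1L)
  }

  kp_keep <- q0 <= kp_max_release
  kp <- if (sum(kp_keep) >= 2) {
    lt <- log10(t0[kp_keep])
    ly <- log10(q0[kp_keep] / 100)
    fit <- lm(ly ~ lt)
    tibble::tibble(
      model = "korsmeyer_peppas",
      k = 10^coef(fit)[[1]], n = coef(fit)[[2]],
      r_squared = r2_of(fit),
      n_points = length(fit$residuals), n_params = 2L, ok = TRUE
    )
  } else {
    unfit("korsmeyer_peppas", 2L)
  }

  out <- dplyr::bind_rows(zero, first, higu, kp)
  class(out) <- c("release_fits", class(out))
  out
}

#' Classify the drug-release mechanism from the power-law exponent
#'
#' For the tablet geometry considered, a Korsmeyer-Peppas exponent below
#' 0.45 indicates Fickian diffusion, 0.45-0.89 anomalous (coupled
#' diffusion/relaxation) transport, and above 0.89 case-II (relaxation
#' controlled) transport. Boundary values are assigned to the anomalous
#' class.
#'
#' @param n_exp Release exponent(s); must be positive.
#' @return Character vector of mechanism labels.
#' @export
#' @examples
#' classify_mechanism(c(0.37, 0.45, 1.0))
classify_mechanism <- function(n_exp) {
  if (any(!is.finite(n_exp)) || any(n_exp <= 0)) {
    stop_validation("release exponent must be positive")
  }
  dplyr::case_when(
    n_exp < 0.45 ~ "Fickian diffusion",
    n_exp <= 0.89 ~ "anomalous transport",
    TRUE ~ "case-II transport"
  )
}

#' Select the best-fitting release model
#'
#' Picks the fit with the largest R-squared; exact ties are broken in
#' favour of the model with fewer parameters.
#'
#' @param fits A `release_fits` tibble from [fit_release_models()].
#' @return The winning one-row fit.
#' @export
select_best_model <- function(fits) {
  fits <- dplyr::filter(fits, .data$ok)
  if (nrow(fits) == 0) stop_validation("no successful fits to select from")
  fits |>
    dplyr::arrange(dplyr::desc(.data$r_squared), .data$n_params) |>
    dplyr::slice(1)
}

#' @export
#' @rdname fit_release_models
#' @param object A `release_fits` tibble.
#' @param ... Unused.
#' @method glance release_fits
glance.release_fits <- function(object, ...) {
  best <- select_best_model(object)
  kp_n <- object$n[object$model == "korsmeyer_peppas"]
  kp_k <- object$k[object$model == "korsmeyer_peppas"]
  tibble::tibble(
    best_model = best$model,
    best_r_squared = best$r_squared,
    kp_n = kp_n,
    kp_k = kp_k,
    mechanism = if (length(kp_n) == 1 && is.finite(kp_n)) {
      classify_mechanism(kp_n)
    } else {
      NA_character_
    }
  )
}
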
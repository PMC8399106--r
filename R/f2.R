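#' Similarity factor f2 of two mean dissolution profiles
#'
#' The Moore-Flanner similarity factor
#' \deqn{f_2 = 50 \log_{10}\left\{\left[1 + \frac{1}{P}\sum_{i=1}^{P}
#'   (\mu_{ti} - \mu_{ri})^2\right]^{-0.5} \times 100\right\}}
#' where \eqn{\mu_{ti}} and \eqn{\mu_{ri}} are the mean cumulative release
#' (%) of the test and reference products at the i-th of P time points.
#' Identical profiles give exactly 100; a uniform offset of
#' \eqn{\sqrt{99} \approx 9.95} percentage points at every time gives
#' exactly 50, the conventional similarity cutoff.
#'
#' @param test_means,ref_means Equal-length numeric vectors of mean release
#'   (%) at matching time points.
#' @return The similarity factor (dimensionless, at most 100).
#' @export
#' @examples
#' f2_mean(c(40, 70, 90), c(30, 60, 80)) # 100 - 25*log10(101) = 49.89
f2_mean <- function(test_means, ref_means) {
  if (length(test_means) == 0 || length(ref_means) == 0) {
    stop_validation("mean vectors must be non-empty")
  }
  if (length(test_means) != length(ref_means)) {
    stop_validation("test and reference mean vectors must have equal length")
  }
  msd <- mean((test_means - ref_means)^2)
  50 * log10(100 / sqrt(1 + msd))
}

#' Variance-penalized expected similarity factor E(f2)
#'
#' Asymptotically unbiased estimate of the population f2 that corrects the
#' downward-biasing effect of between-unit sampling noise on the observed
#' mean squared difference:
#' \deqn{E(f_2) = 50 \log_{10}\left\{\left[1 + \frac{1}{P}\sum_{i=1}^{P}
#'   \left((\chi_{ti} - \chi_{ri})^2 + \frac{s_{ti}^2 + s_{ri}^2}{n}\right)
#'   \right]^{-0.5} \times 100\right\}}
#' with \eqn{\chi} the per-time sample means, \eqn{s^2} the unbiased sample
#' variances and n the units per product. It equals [f2_mean()] when all
#' variances are zero and is strictly smaller otherwise.
#'
#' @param test,ref `profile_summary` tibbles from [summarize_profile()]
#'   at matching time points (columns `time_min`, `mean_release`,
#'   `var_release`, `n`).
#' @param pool_p If `TRUE` (default) the 1/P factor divides the variance sum
#'   as well as the squared-difference sum, matching the per-time-point
#'   expectation \eqn{E[(\chi_t-\chi_r)^2] = (\mu_t-\mu_r)^2 +
#'   (\sigma_t^2+\sigma_r^2)/n}; `FALSE` applies 1/P to the squared
#'   differences only.
#' @return The E(f2) value.
#' @export
f2_expected <- function(test, ref, pool_p = TRUE) {
  need <- c("time_min", "mean_release", "var_release", "n")
  if (!all(need %in% names(test)) || !all(need %in% names(ref))) {
    stop_validation("test and ref must be profile summaries (see summarize_profile)")
  }
  if (nrow(test) != nrow(ref) || !isTRUE(all.equal(test$time_min, ref$time_min))) {
    stop_validation("test and reference summaries must share the same time points")
  }
  p <- nrow(test)
  d2 <- (test$mean_release - ref$mean_release)^2
  vterm <- (test$var_release + ref$var_release) / test$n
  inner <- if (pool_p) sum(d2 + vterm) / p else sum(d2) / p + sum(vterm)
  50 * log10(100 / sqrt(1 + inner))
}

# type-1 (empirical-CDF) quantile of a sorted vector at probability p:
# the ceiling(B*p)-th order statistic, clamped into [1, B].
quantile_type1 <- function(sorted_values, p) {
  b <- length(sorted_values)
  idx <- pmin(b, pmax(1L, ceiling(b * p)))
  sorted_values[idx]
}

#' Bootstrap distribution and 90% intervals for f2
#'
#' Nonparametric bootstrap of the similarity factor: whole tablet units
#' (entire time vectors) are resampled with replacement independently
#' within the test and within the reference product, preserving each
#' product's unit count, and f2 is computed from the replicate means. This
#' preserves within-tablet correlation across time points. Both the
#' percentile interval (PI) and Efron's bias-corrected and accelerated
#' (BCa) interval are reported.
#'
#' @details Per replicate, `n_t` test unit indices are drawn first, then
#' `n_r` reference indices (each a single `sample.int(n, n, replace = TRUE)`
#' call), so a fixed `seed` pins down the whole resampling stream.
#' Percentile bounds use the empirical-CDF (type-1) quantile, i.e. the
#' order statistics at ranks `ceiling(B * alpha/2)` and
#' `ceiling(B * (1 - alpha/2))`. The bias-correction constant z0 is the
#' normal quantile of the fraction of replicates below the sample f2
#' (replicates exactly equal count one half); the acceleration a comes from
#' a delete-one jackknife over the combined unit list (deleting one test OR
#' one reference unit per jackknife replicate),
#' \eqn{a = \sum(\bar\theta-\theta_i)^3 / [6 (\sum(\bar\theta-\theta_i)^2)^{1.5}]}.
#' When every replicate is identical the PI collapses to that constant and
#' the BCa interval is flagged degenerate (z0 undefined) and reported equal
#' to the PI.
#'
#' @param test,ref [dissolution_profile()]s with at least 2 units each.
#' @param time_points Times (min) entering f2; default `c(60, 240, 480)`.
#' @param B Number of bootstrap replicates (default 500; below 100 a
#'   warning is raised).
#' @param seed Integer seed for the resampling stream.
#' @param alpha Two-sided level (default 0.10 for 90% intervals).
#' @param cutoff Similarity cutoff for the equivalence decision (default 50).
#' @return An object of class `f2_boot`: a list with `f2_sample`,
#'   `f2_expected`, `boot_values`, `boot_mean`, `pi_lower`, `pi_upper`,
#'   `bca_lower`, `bca_upper`, `z0`, `accel`, `B`, `alpha`, `cutoff`,
#'   `degenerate`, `n_test`, `n_ref`, `time_points`, and `equivalent` (see
#'   [assess_equivalence()]). Has [tidy()], [glance()] and [autoplot()]
#'   methods.
#' @export
bootstrap_f2 <- function(test, ref, time_points = c(60, 240, 480), B = 500,
                         seed = NULL, alpha = 0.10, cutoff = 50) {
  if (!is.numeric(B) || B < 1) stop_validation("B must be >= 1")
  if (B < 100) warn("B < 100 bootstrap replicates: intervals will be unstable")
  if (alpha <= 0 || alpha >= 1) stop_validation("alpha must lie in (0, 1)")

  mt <- profile_matrix(dissolution_profile(test))
  mr <- profile_matrix(dissolution_profile(ref))
  sel_t <- match(as.character(time_points), colnames(mt))
  sel_r <- match(as.character(time_points), colnames(mr))
  if (anyNA(sel_t) || anyNA(sel_r)) {
    stop_validation("every requested time point must be sampled in both profiles")
  }
  mt <- mt[, sel_t, drop = FALSE]
  mr <- mr[, sel_r, drop = FALSE]
  n_t <- nrow(mt)
  n_r <- nrow(mr)
  if (n_t < 2 || n_r < 2) stop_validation("bootstrap needs >= 2 units per product")

  f2_sample <- f2_mean(colMeans(mt), colMeans(mr))
  ef2 <- f2_expected(
    summarize_profile(test, time_points),
    summarize_profile(ref, time_points)
  )

  if (!is.null(seed)) set.seed(seed)
  boot_values <- vapply(seq_len(B), function(b) {
    it <- sample.int(n_t, n_t, replace = TRUE)
    ir <- sample.int(n_r, n_r, replace = TRUE)
    f2_mean(colMeans(mt[it, , drop = FALSE]), colMeans(mr[ir, , drop = FALSE]))
  }, numeric(1))

  sorted <- sort(boot_values)
  pi_lower <- quantile_type1(sorted, alpha / 2)
  pi_upper <- quantile_type1(sorted, 1 - alpha / 2)

  degenerate <- diff(range(boot_values)) == 0
  if (degenerate) {
    z0 <- NA_real_
    accel <- NA_real_
    bca_lower <- pi_lower
    bca_upper <- pi_upper
  } else {
    frac <- (sum(boot_values < f2_sample) + 0.5 * sum(boot_values == f2_sample)) / B
    frac <- min(max(frac, 0.5 / B), 1 - 0.5 / B) # keep qnorm finite
    z0 <- qnorm(frac)

    # delete-one jackknife over the combined unit list
    theta <- c(
      vapply(seq_len(n_t), function(i) {
        f2_mean(colMeans(mt[-i, , drop = FALSE]), colMeans(mr))
      }, numeric(1)),
      vapply(seq_len(n_r), function(j) {
        f2_mean(colMeans(mt), colMeans(mr[-j, , drop = FALSE]))
      }, numeric(1))
    )
    dev <- mean(theta) - theta
    denom <- 6 * sum(dev^2)^1.5
    accel <- if (denom == 0) 0 else sum(dev^3) / denom

    zlo <- qnorm(alpha / 2)
    zhi <- qnorm(1 - alpha / 2)
    a_lo <- pnorm(z0 + (z0 + zlo) / (1 - accel * (z0 + zlo)))
    a_hi <- pnorm(z0 + (z0 + zhi) / (1 - accel * (z0 + zhi)))
    bca_lower <- quantile_type1(sorted, a_lo)
    bca_upper <- quantile_type1(sorted, a_hi)
  }

  res <- structure(
    list(
      f2_sample = f2_sample, f2_expected = ef2,
      boot_values = boot_values, boot_mean = mean(boot_values),
      pi_lower = pi_lower, pi_upper = pi_upper,
      bca_lower = bca_lower, bca_upper = bca_upper,
      z0 = z0, accel = accel, B = B, alpha = alpha, cutoff = cutoff,
      degenerate = degenerate, n_test = n_t, n_ref = n_r,
      time_points = time_points
    ),
    class = "f2_boot"
  )
  res$equivalent <- assess_equivalence(res, cutoff)$equivalent
  res
}

#' Assemble an f2 result from pre-computed quantities
#'
#' Builds a minimal object that [assess_equivalence()] accepts, for use
#' when the similarity factor and its interval bounds come from elsewhere
#' (e.g. a published table) rather than from [bootstrap_f2()].
#'
#' @param f2_sample Sample similarity factor.
#' @param pi_lower,pi_upper Percentile interval bounds.
#' @param bca_lower,bca_upper BCa interval bounds (default to the PI bounds).
#' @param cutoff Similarity cutoff (default 50).
#' @return An object of class `f2_result`.
#' @export
f2_result <- function(f2_sample, pi_lower, pi_upper = 100,
                      bca_lower = pi_lower, bca_upper = pi_upper,
                      cutoff = 50) {
  if (pi_lower > pi_upper || bca_lower > bca_upper) {
    stop_validation("interval lower bounds must not exceed upper bounds")
  }
  structure(
    list(
      f2_sample = f2_sample, pi_lower = pi_lower, pi_upper = pi_upper,
      bca_lower = bca_lower, bca_upper = bca_upper, cutoff = cutoff
    ),
    class = "f2_result"
  )
}

#' Equivalence decision from an f2 result
#'
#' Declares the dissolution profiles equivalent only when the sample f2 and
#' the lower limits of both the percentile and the BCa interval all exceed
#' the cutoff (strictly). This is the conservative rule that eliminates
#' borderline formulations whose mean f2 exceeds 50 but whose interval
#' lower bound does not.
#'
#' @param result An [f2_result()] or `f2_boot` object.
#' @param cutoff Similarity cutoff (default: the cutoff stored in `result`,
#'   or 50).
#' @return A one-row tibble with logical columns `pass_f2`, `pass_pi`,
#'   `pass_bca`, `equivalent`, and `failed` (comma-separated names of the
#'   failed criteria, or `NA` when equivalent).
#' @export
assess_equivalence <- function(result, cutoff = NULL) {
  cutoff <- cutoff %||% result$cutoff %||% 50
  checks <- c(
    f2_sample = result$f2_sample > cutoff,
    pi_lower = result$pi_lower > cutoff,
    bca_lower = result$bca_lower > cutoff
  )
  tibble::tibble(
    f2_sample = result$f2_sample,
    pi_lower = result$pi_lower,
    bca_lower = result$bca_lower,
    cutoff = cutoff,
    pass_f2 = checks[["f2_sample"]],
    pass_pi = checks[["pi_lower"]],
    pass_bca = checks[["bca_lower"]],
    equivalent = all(checks),
    failed = if (all(checks)) NA_character_ else paste(names(checks)[!checks], collapse = ", ")
  )
}

#' @export
print.f2_boot <- function(x, ...) {
  cat(sprintf(
    paste0(
      "Bootstrap f2 (B = %d, %d+%d units, %.0f%% intervals)\n",
      "  f2 = %.2f   E(f2) = %.2f   bootstrap mean = %.2f\n",
      "  PI  = (%.2f, %.2f)\n  BCa = (%.2f, %.2f)%s\n",
      "  equivalent at cutoff %.0f: %s\n"
    ),
    x$B, x$n_test, x$n_ref, 100 * (1 - x$alpha),
    x$f2_sample, x$f2_expected, x$boot_mean,
    x$pi_lower, x$pi_upper, x$bca_lower, x$bca_upper,
    if (x$degenerate) "  [degenerate]" else "",
    x$cutoff, x$equivalent
  ))
  invisible(x)
}

#' @rdname bootstrap_f2
#' @param x An `f2_boot` object.
#' @param ... Unused.
#' @method tidy f2_boot
#' @export
tidy.f2_boot <- function(x, ...) {
  tibble::tibble(
    statistic = c("f2_sample", "f2_expected", "boot_mean", "pi_lower",
                  "pi_upper", "bca_lower", "bca_upper"),
    value = c(x$f2_sample, x$f2_expected, x$boot_mean, x$pi_lower,
              x$pi_upper, x$bca_lower, x$bca_upper)
  )
}

#' @rdname bootstrap_f2
#' @method glance f2_boot
#' @export
glance.f2_boot <- function(x, ...) {
  tibble::tibble(
    f2_sample = x$f2_sample, f2_expected = x$f2_expected,
    boot_mean = x$boot_mean, pi_lower = x$pi_lower, pi_upper = x$pi_upper,
    bca_lower = x$bca_lower, bca_upper = x$bca_upper,
    B = x$B, alpha = x$alpha, cutoff = x$cutoff,
    degenerate = x$degenerate, equivalent = x$equivalent
  )
}

#' @rdname bootstrap_f2
#' @param object An `f2_boot` object.
#' @method autoplot f2_boot
#' @export
autoplot.f2_boot <- function(object, ...) {
  df <- tibble::tibble(f2 = object$boot_values)
  bounds <- tibble::tibble(
    bound = c("PI lower", "PI upper", "BCa lower", "BCa upper"),
    value = c(object$pi_lower, object$pi_upper, object$bca_lower, object$bca_upper)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$f2)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(
      data = bounds,
      ggplot2::aes(xintercept = .data$value, linetype = .data$bound)
    ) +
    ggplot2::geom_vline(xintercept = object$cutoff, colour = "red") +
    ggplot2::labs(
      x = "bootstrap f2 replicate", y = "count",
      title = sprintf("Bootstrap f2 distribution (B = %d)", object$B),
      subtitle = sprintf(
        "f2 = %.2f, PI (%.2f, %.2f), BCa (%.2f, %.2f); red line = cutoff",
        object$f2_sample, object$pi_lower, object$pi_upper,
        object$bca_lower, object$bca_upper
      )
    ) +
    ggplot2::theme_minimal()
}
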
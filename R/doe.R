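code_level <- function(x, range) (x - mean(range)) / (diff(range) / 2)
decode_level <- function(a, range) mean(range) + a * diff(range) / 2

check_ranges <- function(a_range, b_range) {
  if (length(a_range) != 2 || length(b_range) != 2 ||
      diff(a_range) <= 0 || diff(b_range) <= 0) {
    stop_validation("factor ranges must be length-2 with low < high")
  }
  invisible(TRUE)
}

new_design <- function(coded, a_range, b_range, seed) {
  n <- nrow(coded)
  run_order <- if (is.null(seed)) seq_len(n) else {
    set.seed(seed)
    sample.int(n)
  }
  out <- tibble::tibble(
    std_order = seq_len(n),
    run_order = run_order,
    A_mg = decode_level(coded$a, a_range),
    B_pct = decode_level(coded$b, b_range),
    a = coded$a,
    b = coded$b,
    replicate = coded$replicate,
    is_center = coded$a == 0 & coded$b == 0
  )
  attr(out, "a_range") <- a_range
  attr(out, "b_range") <- b_range
  class(out) <- c("doe_design", class(out))
  out
}

#' Two-level full factorial screening design
#'
#' Builds the 2x2 full factorial design in cetyl alcohol mass A (mg) and
#' HPMC proportion B (% of tablet mass): `4 * replicates` corner runs at
#' the coded levels (+/-1, +/-1) plus `center_points` runs at the coded
#' center (0, 0). The run order is randomized when a seed is given; the
#' randomization is stored for provenance and does not affect fitting.
#'
#' @param a_range,b_range Length-2 low/high ranges for A (mg) and B (%).
#'   Defaults 50-250 mg and 5-25%.
#' @param replicates Corner replicates (default 2).
#' @param center_points Center-point runs (default 2).
#' @param seed Integer seed for run-order randomization; `NULL` keeps
#'   standard order.
#' @return A tibble of class `doe_design` with columns `std_order`,
#'   `run_order`, `A_mg`, `B_pct`, coded `a`, `b`, `replicate`,
#'   `is_center`, and the factor ranges as attributes.
#' @export
build_ffd_design <- function(a_range = c(50, 250), b_range = c(5, 25),
                             replicates = 2, center_points = 2, seed = NULL) {
  check_ranges(a_range, b_range)
  if (replicates < 1) stop_validation("replicates must be >= 1")
  if (center_points < 0) stop_validation("center_points must be >= 0")
  corners <- expand.grid(a = c(-1, 1), b = c(-1, 1))
  coded <- do.call(rbind, lapply(seq_len(replicates), function(r) {
    cbind(corners, replicate = r)
  }))
  if (center_points > 0) {
    coded <- rbind(coded, data.frame(a = 0, b = 0, replicate = seq_len(center_points)))
  }
  new_design(coded, a_range, b_range, seed)
}

#' Face-centered central composite (CCF) design
#'
#' Builds the face-centered central composite design used for response
#' surface optimization: the 4 factorial corners, 4 axial points on the
#' face centers (coded (+/-1, 0) and (0, +/-1)), and `center_points`
#' center runs — 10 points with the default two centers.
#'
#' @inheritParams build_ffd_design
#' @return A `doe_design` tibble (see [build_ffd_design()]).
#' @export
build_ccf_design <- function(a_range = c(150, 250), b_range = c(15, 25),
                             center_points = 2, seed = NULL) {
  check_ranges(a_range, b_range)
  if (center_points < 0) stop_validation("center_points must be >= 0")
  coded <- data.frame(
    a = c(-1, 1, -1, 1, -1, 1, 0, 0),
    b = c(-1, -1, 1, 1, 0, 0, -1, 1),
    replicate = 1
  )
  if (center_points > 0) {
    coded <- rbind(coded, data.frame(a = 0, b = 0, replicate = seq_len(center_points)))
  }
  new_design(coded, a_range, b_range, seed)
}

# expand a polynomial in coded units into actual (physical) units.
# coded: named vector over (intercept, a, b, ab, a2, b2);
# a = (A - cA)/hA, b = (B - cB)/hB.
coded_to_actual <- function(cc, a_range, b_range) {
  cA <- mean(a_range); hA <- diff(a_range) / 2
  cB <- mean(b_range); hB <- diff(b_range) / 2
  g <- function(nm) if (nm %in% names(cc)) cc[[nm]] else 0
  out <- c(
    intercept = g("intercept") - g("a") * cA / hA - g("b") * cB / hB +
      g("ab") * cA * cB / (hA * hB) + g("a2") * cA^2 / hA^2 + g("b2") * cB^2 / hB^2,
    A = g("a") / hA - g("ab") * cB / (hA * hB) - 2 * g("a2") * cA / hA^2,
    B = g("b") / hB - g("ab") * cA / (hA * hB) - 2 * g("b2") * cB / hB^2,
    AB = g("ab") / (hA * hB),
    A2 = g("a2") / hA^2,
    B2 = g("b2") / hB^2
  )
  if (!any(c("ab", "a2", "b2") %in% names(cc))) out <- out[c("intercept", "A", "B")]
  out
}

#' Fit a coded response-surface model with ANOVA
#'
#' Ordinary least squares of one dissolution response on the coded factor
#' levels, either linear (`intercept + a + b`) or quadratic
#' (`+ ab + a^2 + b^2`). Reports per-term t-test p-values, the whole-model
#' F-test p-value, R-squared and adjusted R-squared (as percentages), and
#' both the coded and the actual (physical units) coefficient vectors; the
#' actual form is obtained by exact algebraic substitution of the coding
#' transform, so the two forms agree at every design point to machine
#' precision.
#'
#' @param design A `doe_design` tibble.
#' @param response A numeric vector of per-run response values in standard
#'   order, or the name of a column of `design`.
#' @param model_type `"linear"` or `"quadratic"`.
#' @param response_id Optional label (e.g. `"R1"`).
#' @return An object of class `response_model`: list with `response_id`,
#'   `model_type`, `coded_coeffs`, `actual_coeffs`, `p_values` (`$terms`,
#'   `$model`), `r_squared`, `adj_r_squared` (percent), `a_range`,
#'   `b_range`, and the underlying `lm` fit. Has [tidy()] and [glance()]
#'   methods.
#' @export
fit_response_model <- function(design, response,
                               model_type = c("linear", "quadratic"),
                               response_id = NULL) {
  model_type <- match.arg(model_type)
  if (is.character(response) && length(response) == 1) {
    response_id <- response_id %||% response
    if (!response %in% names(design)) {
      stop_validation(paste0("response column '", response, "' not in design"))
    }
    response <- design[[response]]
  }
  if (length(response) != nrow(design)) {
    stop_validation("response must have one value per design run")
  }

  df <- data.frame(y = response, a = design$a, b = design$b)
  form <- if (model_type == "linear") {
    y ~ a + b
  } else {
    y ~ a + b + I(a * b) + I(a^2) + I(b^2)
  }
  n_terms <- if (model_type == "linear") 3L else 6L
  if (nrow(df) < n_terms + 1) {
    stop_validation("not enough runs for the requested model type")
  }
  fit <- lm(form, data = df)
  cf <- coef(fit)
  if (anyNA(cf)) {
    bad <- names(cf)[is.na(cf)]
    stop_validation(paste0(
      "design is rank-deficient for a ", model_type, " model: cannot estimate ",
      paste(bad, collapse = ", ")
    ))
  }
  term_map <- c(
    "(Intercept)" = "intercept", "a" = "a", "b" = "b",
    "I(a * b)" = "ab", "I(a^2)" = "a2", "I(b^2)" = "b2"
  )
  names(cf) <- term_map[names(cf)]

  # exact (noiseless) fits are legitimate inputs here; muffle only lm's
  # perfect-fit notice, everything else propagates
  sm <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  term_p <- sm$coefficients[, "Pr(>|t|)"]
  names(term_p) <- term_map[rownames(sm$coefficients)]
  fstat <- sm$fstatistic
  model_p <- if (var(df$y) == 0 || is.null(fstat) || !is.finite(fstat[1])) {
    warn("whole-model F statistic undefined (constant response or saturated fit)")
    NA_real_
  } else {
    unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE))
  }

  a_range <- attr(design, "a_range")
  b_range <- attr(design, "b_range")
  structure(
    list(
      response_id = response_id,
      model_type = model_type,
      coded_coeffs = cf,
      actual_coeffs = coded_to_actual(cf, a_range, b_range),
      p_values = list(terms = term_p, model = model_p),
      r_squared = 100 * sm$r.squared,
      adj_r_squared = 100 * sm$adj.r.squared,
      a_range = a_range,
      b_range = b_range,
      fit = fit
    ),
    class = "response_model"
  )
}

#' Build response models directly from actual-equation coefficients
#'
#' Wraps known actual-scale coefficients (e.g. a published equation) into
#' `response_model` objects usable by [predict_dissolution()],
#' [predict_f2()] and [solve_hpmc_threshold()] without refitting.
#'
#' @param coeffs Named list of actual coefficient vectors as in
#'   [simulate_doe_responses()]; default [reference_response_coeffs()].
#' @param a_range,b_range Factor ranges the models are valid over.
#' @return Named list of `response_model` objects.
#' @export
response_models_from_coeffs <- function(coeffs = reference_response_coeffs(),
                                        a_range = c(150, 250),
                                        b_range = c(15, 25)) {
  purrr::imap(coeffs, function(cc, id) {
    eval_actual_equation(cc, mean(a_range), mean(b_range)) # validates names
    structure(
      list(
        response_id = id,
        model_type = if (any(c("AB", "A2", "B2") %in% names(cc))) "quadratic" else "linear",
        coded_coeffs = NULL,
        actual_coeffs = cc,
        p_values = NULL,
        r_squared = NA_real_, adj_r_squared = NA_real_,
        a_range = a_range, b_range = b_range, fit = NULL
      ),
      class = "response_model"
    )
  })
}

#' Predict the dissolution responses at a candidate composition
#'
#' Evaluates the actual-scale equations of three response models (release %
#' at 60, 240 and 480 min) at cetyl alcohol mass `A` (mg) and HPMC
#' proportion `B` (%). Predictions are clipped to \[0, 100\] with a flag;
#' compositions outside the models' factor ranges are still computed but
#' flagged (with a warning) as extrapolations.
#'
#' @param models Named list of three `response_model`s (R1, R2, R3 order).
#' @param A Cetyl alcohol mass (mg).
#' @param B HPMC proportion (% of tablet mass).
#' @return A tibble with columns `response`, `predicted` (clipped),
#'   `raw` (unclipped), `clipped`, `extrapolated`.
#' @export
#' @examples
#' m <- response_models_from_coeffs()
#' predict_dissolution(m, A = 150, B = 17)
predict_dissolution <- function(models, A, B) {
  if (length(models) != 3) stop_validation("need models for all three responses")
  extrap <- vapply(models, function(m) {
    A < m$a_range[1] || A > m$a_range[2] || B < m$b_range[1] || B > m$b_range[2]
  }, logical(1))
  if (any(extrap)) {
    warn(sprintf("composition (A = %g, B = %g) is outside the model factor ranges", A, B))
  }
  raw <- vapply(models, function(m) eval_actual_equation(m$actual_coeffs, A, B), numeric(1))
  pred <- pmin(100, pmax(0, raw))
  tibble::tibble(
    response = names(models) %||% paste0("R", seq_along(models)),
    predicted = unname(pred),
    raw = unname(raw),
    clipped = unname(pred != raw),
    extrapolated = unname(extrap)
  )
}

#' Predicted similarity factor for a candidate composition
#'
#' Applies [f2_mean()] to the three model-predicted release values against
#' a reference mean profile at the same time points.
#'
#' @inheritParams predict_dissolution
#' @param ref_means Reference mean release (%) at the three comparison
#'   times (default target (30, 60, 80) at 60/240/480 min).
#' @return The predicted f2.
#' @export
predict_f2 <- function(models, A, B, ref_means = c(30, 60, 80)) {
  if (length(ref_means) != 3) {
    stop_validation("ref_means must give the reference release at the three comparison times")
  }
  pred <- predict_dissolution(models, A, B)
  f2_mean(pred$predicted, ref_means)
}

#' Minimum HPMC proportion meeting the similarity cutoff
#'
#' Solves, by bisection at fixed cetyl alcohol mass, for the HPMC
#' proportion B at which the model-predicted f2 against the reference
#' equals the cutoff. Because the predicted f2 is monotone in B over the
#' modelled range, this is the threshold above which the predicted profile
#' is similar to the reference.
#'
#' @inheritParams predict_f2
#' @param cutoff Similarity cutoff (default 50).
#' @param b_range Bisection bracket for B (%); defaults to the models'
#'   B factor range.
#' @param tol Bisection tolerance on B (default 1e-4 percentage points).
#' @return The threshold B (%).
#' @export
#' @examples
#' m <- response_models_from_coeffs()
#' solve_hpmc_threshold(m, A = 150) # about 16.92% HPMC
solve_hpmc_threshold <- function(models, A, ref_means = c(30, 60, 80),
                                 cutoff = 50, b_range = NULL, tol = 1e-4) {
  b_range <- b_range %||% models[[1]]$b_range
  g <- function(B) {
    suppressWarnings(predict_f2(models, A, B, ref_means)) - cutoff
  }
  g_lo <- g(b_range[1])
  g_hi <- g(b_range[2])
  if (is.na(g_lo) || is.na(g_hi) || g_lo * g_hi > 0) {
    abort(sprintf(
      "predicted f2 does not cross the cutoff %g in B = [%g, %g]: f2 - cutoff = %.4f and %.4f at the brackets",
      cutoff, b_range[1], b_range[2], g_lo, g_hi
    ), class = "floatdoe_validation_error")
  }
  lo <- b_range[1]
  hi <- b_range[2]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(lo) * g(mid) <= 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

#' Root mean squared error of prediction
#'
#' RMSEP over an external validation set:
#' \eqn{\sqrt{(1/n)\sum_i (y_i - \hat y_i)^2}}, the criterion used to
#' choose between competing (e.g. linear vs quadratic) response models.
#'
#' @param observed Reference values of the validation set.
#' @param predicted Model predictions for the same runs.
#' @return The RMSEP (same units as the response).
#' @export
#' @examples
#' rmsep(c(1, 2, 3), c(2, 2, 2)) # sqrt(2/3)
rmsep <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 1) {
    stop_validation("observed and predicted must be equal-length, non-empty")
  }
  sqrt(mean((observed - predicted)^2))
}

#' @export
print.response_model <- function(x, ...) {
  terms <- names(x$actual_coeffs)
  eq <- paste0(
    sprintf("%.4g", x$actual_coeffs[1]),
    paste0(sprintf(" %+.4g*%s", x$actual_coeffs[-1], terms[-1]), collapse = "")
  )
  cat(sprintf(
    "<response_model %s> %s: %s = %s\n",
    x$response_id %||% "?", x$model_type, x$response_id %||% "y", eq
  ))
  if (!is.na(x$r_squared)) {
    cat(sprintf(
      "  R2 = %.2f%%  adj R2 = %.2f%%  model p = %s\n",
      x$r_squared, x$adj_r_squared,
      format.pval(x$p_values$model, digits = 3)
    ))
  }
  invisible(x)
}

#' @rdname fit_response_model
#' @param x,object A `response_model`.
#' @param ... Unused.
#' @method tidy response_model
#' @export
tidy.response_model <- function(x, ...) {
  if (is.null(x$coded_coeffs)) {
    return(tibble::tibble(
      term = names(x$actual_coeffs),
      actual_estimate = unname(x$actual_coeffs)
    ))
  }
  actual_map <- c(intercept = "intercept", a = "A", b = "B",
                  ab = "AB", a2 = "A2", b2 = "B2")
  tibble::tibble(
    term = names(x$coded_coeffs),
    coded_estimate = unname(x$coded_coeffs),
    actual_estimate = unname(x$actual_coeffs[actual_map[names(x$coded_coeffs)]]),
    p.value = unname(x$p_values$terms[names(x$coded_coeffs)])
  )
}

#' @rdname fit_response_model
#' @method glance response_model
#' @export
glance.response_model <- function(x, ...) {
  tibble::tibble(
    response_id = x$response_id %||% NA_character_,
    model_type = x$model_type,
    r_squared = x$r_squared,
    adj_r_squared = x$adj_r_squared,
    p_model = if (is.null(x$p_values)) NA_real_ else x$p_values$model
  )
}
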
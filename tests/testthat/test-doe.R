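test_that("full factorial screening design has the right geometry", {
  d <- build_ffd_design(c(50, 250), c(5, 25), replicates = 2, center_points = 2)
  expect_equal(nrow(d), 10)
  corners <- dplyr::filter(d, !is_center)
  expect_equal(nrow(dplyr::distinct(corners, A_mg, B_pct)), 4)
  expect_true(all(corners$a %in% c(-1, 1) & corners$b %in% c(-1, 1)))

  d1 <- build_ffd_design(replicates = 1, center_points = 0)
  expect_equal(nrow(d1), 4)
  expect_true(all(!d1$is_center))

  # coding transform: a = (A - midrange) / (half-range)
  expect_equal(d$a, (d$A_mg - 150) / 100)
  expect_equal(d$b, (d$B_pct - 15) / 10)

  expect_error(build_ffd_design(c(100, 100), c(5, 25)),
               class = "floatdoe_validation_error")
})

test_that("face-centered composite design has 10 points with face axials", {
  d <- build_ccf_design(c(150, 250), c(15, 25), center_points = 2)
  expect_equal(nrow(d), 10)
  axial <- dplyr::filter(d, (a == 0) != (b == 0))
  expect_equal(nrow(axial), 4)
  expect_true(all(rowSums(cbind(axial$a == 0, axial$b == 0)) == 1))
  # axial (0, -1) decodes to the B face center (200, 15)
  lo_b <- dplyr::filter(d, a == 0, b == -1)
  expect_equal(c(lo_b$A_mg, lo_b$B_pct), c(200, 15))
  # randomized run order is a permutation and does not change the points
  ds <- build_ccf_design(seed = 99)
  expect_setequal(ds$run_order, 1:10)
})

test_that("noiseless responses from the published equations are recovered to 1e-9", {
  design <- build_ccf_design(c(150, 250), c(15, 25))
  filled <- simulate_doe_responses(design, noise_sd = 0)
  expected <- list(
    R1 = c(intercept = 53.73, A = -0.03, B = -0.59),
    R2 = c(intercept = 94.48, A = -0.06, B = -0.83),
    R3 = c(intercept = 111.17, A = -0.06, B = -0.78)
  )
  for (r in names(expected)) {
    m <- fit_response_model(filled, r, "linear")
    expect_equal(unname(m$actual_coeffs), unname(expected[[r]]), tolerance = 1e-9)
    expect_equal(m$r_squared, 100, tolerance = 1e-9)
  }
})

test_that("quadratic generators need the quadratic model; linear fits lose R^2", {
  design <- build_ccf_design(c(150, 250), c(15, 25))
  quad <- list(R = c(intercept = 40, A = -0.05, B = -0.4, AB = 0.002, A2 = -4e-4, B2 = 0.03))
  filled <- simulate_doe_responses(design, quad, noise_sd = 0)
  mq <- fit_response_model(filled, "R", "quadratic")
  expect_equal(unname(mq$actual_coeffs), unname(quad$R), tolerance = 1e-8)
  ml <- fit_response_model(filled, "R", "linear")
  expect_lt(ml$r_squared, mq$r_squared)
})

test_that("coded and actual model forms agree at every design point", {
  design <- build_ccf_design(c(150, 250), c(15, 25))
  filled <- simulate_doe_responses(design, noise_sd = 1.2, seed = 5)
  for (type in c("linear", "quadratic")) {
    m <- fit_response_model(filled, "R1", type)
    coded_val <- m$coded_coeffs[["intercept"]] +
      m$coded_coeffs[["a"]] * design$a + m$coded_coeffs[["b"]] * design$b
    if (type == "quadratic") {
      coded_val <- coded_val + m$coded_coeffs[["ab"]] * design$a * design$b +
        m$coded_coeffs[["a2"]] * design$a^2 + m$coded_coeffs[["b2"]] * design$b^2
    }
    actual_val <- vapply(
      seq_len(nrow(design)),
      function(i) {
        cc <- m$actual_coeffs
        g <- function(nm) if (nm %in% names(cc)) cc[[nm]] else 0
        g("intercept") + g("A") * design$A_mg[i] + g("B") * design$B_pct[i] +
          g("AB") * design$A_mg[i] * design$B_pct[i] +
          g("A2") * design$A_mg[i]^2 + g("B2") * design$B_pct[i]^2
      },
      numeric(1)
    )
    expect_lt(max(abs(coded_val - actual_val)), 1e-9)
  }
})

test_that("coded OLS coefficients match a brute-force normal-equations solve", {
  design <- build_ccf_design(c(150, 250), c(15, 25))
  filled <- simulate_doe_responses(design, noise_sd = 2, seed = 8)
  m <- fit_response_model(filled, "R2", "quadratic")
  X <- cbind(1, design$a, design$b, design$a * design$b, design$a^2, design$b^2)
  beta <- solve(t(X) %*% X, t(X) %*% filled$R2)
  expect_equal(unname(m$coded_coeffs), as.vector(beta), tolerance = 1e-9)
})

test_that("rank-deficient and degenerate fits fail informatively", {
  d4 <- build_ffd_design(replicates = 1, center_points = 0)
  filled <- simulate_doe_responses(d4, noise_sd = 0)
  expect_error(fit_response_model(filled, "R1", "quadratic"),
               class = "floatdoe_validation_error")

  d <- build_ccf_design()
  d$Rconst <- rep(5, nrow(d))
  expect_warning(m <- fit_response_model(d, "Rconst", "linear"), "undefined")
  expect_equal(unname(m$coded_coeffs[c("a", "b")]), c(0, 0), tolerance = 1e-12)
  expect_true(is.na(m$p_values$model))
})

test_that("noisy refits recover the generating coefficients within 3 SE almost always", {
  design <- build_ccf_design(c(150, 250), c(15, 25))
  gen <- reference_response_coeffs()$R1
  hits <- logical(200)
  for (i in 1:200) {
    filled <- simulate_doe_responses(design, list(R1 = gen), noise_sd = 1, seed = 5000 + i)
    m <- fit_response_model(filled, "R1", "linear")
    se_coded <- sqrt(diag(stats::vcov(m$fit)))
    # linear coding: actual slope SE = coded SE / half-range
    se_actual <- c(NA, se_coded[2] / 50, se_coded[3] / 5)
    hits[i] <- all(abs(m$actual_coeffs[2:3] - gen[2:3]) <= 3 * se_actual[2:3])
  }
  expect_gte(mean(hits), 0.95)
})

test_that("predicted dissolution at a candidate composition evaluates the actual equations", {
  models <- response_models_from_coeffs()
  pred <- predict_dissolution(models, A = 150, B = 17)
  expect_equal(pred$predicted, c(39.20, 71.37, 88.91), tolerance = 1e-9)
  expect_true(all(!pred$clipped))

  # out-of-range predictions are clipped and flagged
  hot <- response_models_from_coeffs(list(R1 = c(intercept = 120, A = 0, B = 0),
                                          R2 = c(intercept = -5, A = 0, B = 0),
                                          R3 = c(intercept = 50, A = 0, B = 0)))
  p2 <- predict_dissolution(hot, 200, 20)
  expect_equal(p2$predicted, c(100, 0, 50))
  expect_equal(p2$clipped, c(TRUE, TRUE, FALSE))

  expect_warning(predict_dissolution(models, A = 300, B = 17), "outside")
})

test_that("predicted f2 behaves and increases with HPMC against the reference targets", {
  models <- response_models_from_coeffs()
  pred <- predict_dissolution(models, 150, 17)
  expect_equal(predict_f2(models, 150, 17, ref_means = pred$predicted), 100)
  expect_equal(predict_f2(models, 150, 17), 50.13456, tolerance = 1e-4)
  expect_gt(predict_f2(models, 150, 25), predict_f2(models, 150, 15))
})

test_that("the HPMC threshold solver brackets the similarity cutoff", {
  models <- response_models_from_coeffs()
  thr <- solve_hpmc_threshold(models, A = 150)
  expect_equal(thr, 16.91558, tolerance = 1e-3)
  # cross-check with an independent root finder on the same objective
  oracle <- stats::uniroot(
    function(B) predict_f2(models, 150, B) - 50,
    c(15, 25), tol = 1e-10
  )$root
  expect_equal(thr, oracle, tolerance = 2e-4)
  # invariant to the starting bracket as long as it straddles the root
  expect_equal(solve_hpmc_threshold(models, 150, b_range = c(16, 18)), thr,
               tolerance = 2e-4)
  # a cutoff the model can never reach reports the bracket values
  expect_error(solve_hpmc_threshold(models, 150, cutoff = 100),
               class = "floatdoe_validation_error", regexp = "bracket")
})

test_that("rmsep matches hand computation and is order invariant", {
  expect_equal(rmsep(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmsep(c(1, 2, 3), c(2, 2, 2)), sqrt(2 / 3), tolerance = 1e-12)
  o <- c(4, 9, 1, 7)
  p <- c(5, 7, 2, 6)
  idx <- c(3, 1, 4, 2)
  expect_equal(rmsep(o[idx], p[idx]), rmsep(o, p))
  expect_error(rmsep(1:3, 1:2), class = "floatdoe_validation_error")
})

test_that("external validation prefers the linear model for linear truth plus noise", {
  design <- build_ccf_design(c(150, 250), c(15, 25))
  truth <- reference_response_coeffs()["R3"]
  grid <- expand.grid(A = seq(150, 250, 25), B = seq(15, 25, 2.5))
  true_val <- 111.17 - 0.06 * grid$A - 0.78 * grid$B
  wins <- logical(100)
  for (i in 1:100) {
    filled <- simulate_doe_responses(design, truth, noise_sd = 1, seed = 9000 + i)
    ml <- fit_response_model(filled, "R3", "linear")
    mq <- fit_response_model(filled, "R3", "quadratic")
    pred_of <- function(m) {
      vapply(seq_len(nrow(grid)), function(j) {
        cc <- m$actual_coeffs
        g <- function(nm) if (nm %in% names(cc)) cc[[nm]] else 0
        g("intercept") + g("A") * grid$A[j] + g("B") * grid$B[j] +
          g("AB") * grid$A[j] * grid$B[j] + g("A2") * grid$A[j]^2 + g("B2") * grid$B[j]^2
      }, numeric(1))
    }
    wins[i] <- rmsep(true_val, pred_of(ml)) < rmsep(true_val, pred_of(mq))
  }
  expect_gte(mean(wins), 0.90)
})

test_that("tidy and glance expose coded/actual coefficients and fit quality", {
  design <- build_ccf_design()
  filled <- simulate_doe_responses(design, noise_sd = 0.5, seed = 2)
  m <- fit_response_model(filled, "R1", "linear")
  td <- generics::tidy(m)
  expect_equal(td$term, c("intercept", "a", "b"))
  expect_equal(td$coded_estimate, unname(m$coded_coeffs))
  expect_equal(td$actual_estimate, unname(m$actual_coeffs))
  gl <- generics::glance(m)
  expect_equal(gl$model_type, "linear")
  expect_lte(gl$adj_r_squared, gl$r_squared)
})
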
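# global refinement tests run on a reduced two- or four-curve synthetic
# series so the whole file stays fast

series4 <- generate_saxs_series(saxs_series_spec(seed = 42))

test_that("noiseless data initialized at truth is a fixed point with zero chi2", {
  series0 <- generate_saxs_series(saxs_series_spec(noise = 0))
  prob <- global_fit_problem(series0, init = truth_par())
  fit <- fit_global(prob, n_starts = 1)
  expect_true(fit$converged)
  expect_lt(fit$chi2_red, 1e-12)
  expect_equal(fit$par[["L_t"]], 14.3, tolerance = 1e-6)
  expect_equal(fit$par[["L_h"]], 6.65, tolerance = 1e-6)
  expect_equal(fit$par[["R"]], 5.37, tolerance = 1e-6)
  expect_equal(fit$par[["x_4"]], 0.030, tolerance = 1e-6)
})

test_that("rescaling one dataset leaves chi2 and non-scale parameters unchanged", {
  fit_a <- fit_global(global_fit_problem(series4), n_starts = 2, seed = 1)
  scaled <- series4
  scaled[[2]]$I <- 1000 * scaled[[2]]$I
  scaled[[2]]$sigma <- 1000 * scaled[[2]]$sigma
  fit_b <- fit_global(global_fit_problem(scaled), n_starts = 2, seed = 1)
  expect_equal(fit_b$chi2_red, fit_a$chi2_red, tolerance = 1e-6)
  for (nm in c("L_t", "L_h", "R"))
    expect_equal(fit_b$par[[nm]], fit_a$par[[nm]], tolerance = 1e-4)
  for (nm in sprintf("x_%d", 1:4))  # absolute: x sits near zero
    expect_lt(abs(fit_b$par[[nm]] - fit_a$par[[nm]]), 1e-4)
  expect_equal(fit_b$par[["C1_2"]] / fit_a$par[["C1_2"]], 1000,
               tolerance = 1e-3)
})

test_that("dataset order does not move the shared parameters", {
  fit_a <- fit_global(global_fit_problem(series4), n_starts = 2, seed = 1)
  fit_b <- fit_global(global_fit_problem(rev(series4)), n_starts = 2,
                      seed = 1)
  for (nm in c("L_t", "L_h", "R"))
    expect_equal(fit_b$par[[nm]], fit_a$par[[nm]], tolerance = 1e-3)
  expect_equal(fit_b$par[["x_1"]], fit_a$par[["x_4"]], tolerance = 1e-3)
  expect_equal(fit_b$chi2_red, fit_a$chi2_red, tolerance = 1e-5)
})

test_that("constraining all protein fractions to zero cannot improve the fit", {
  free_fit <- fit_global(global_fit_problem(series4), n_starts = 2, seed = 1)
  fixed_names <- sprintf("x_%d", 1:4)
  prob0 <- global_fit_problem(series4,
                              init = stats::setNames(rep(0, 4), fixed_names),
                              fixed = fixed_names)
  fixed_fit <- fit_global(prob0, n_starts = 2, seed = 1)
  expect_gte(fixed_fit$ssr, free_fit$ssr - 1e-6 * free_fit$ssr)
})

test_that("q-window restriction drops points from the objective", {
  prob_full <- global_fit_problem(series4)
  prob_win <- global_fit_problem(series4, q_window = c(0.02, 0.35))
  fit_win <- fit_global(prob_win, n_starts = 1)
  expect_lt(fit_win$n_points, fit_global(prob_full, n_starts = 1)$n_points)
})

test_that("profile interval on a linear parameter matches the closed form", {
  # with the shape parameters fixed the model is exactly linear in the
  # scales and background, so chi2 is quadratic and the profile interval
  # must equal the analytic +/- sqrt(Delta) * SE of weighted least squares
  series1 <- generate_saxs_series(saxs_series_spec(seed = 9))[1]
  shape_fix <- c("L_t", "L_h", "R", "x_1")
  prob <- global_fit_problem(series1, init = truth_par(1)[shape_fix],
                             fixed = shape_fix)
  fit <- fit_global(prob, n_starts = 1)
  expect_true(fit$converged)

  d <- series1[[1]]
  X <- vesiquant:::.basis_curves(d$q, 14.3, 6.65, 5.37, 0, sld_set())
  Xw <- X / d$sigma
  # closed-form weighted-least-squares covariance via equilibrated QR
  # (the raw normal equations span ~20 orders of magnitude)
  cn <- sqrt(colSums(Xw^2))
  cov <- chol2inv(qr.R(qr(sweep(Xw, 2, cn, "/")))) / tcrossprod(cn)
  delta <- qchisq(0.638, 1)
  for (par in c("C1_1", "B_1")) {
    k <- match(c(C1_1 = "lam", C2_1 = "mic", B_1 = "bg")[[par]],
               colnames(X))
    se <- sqrt(cov[k, k])
    ci <- profile_confidence_interval(prob, fit, par)
    expect_equal(unname(ci["upper"] - ci["lower"]), 2 * sqrt(delta) * se,
                 tolerance = 0.01)
    expect_true(ci["lower"] < fit$par[[par]] && fit$par[[par]] < ci["upper"])
  }

  # level -> 0 collapses the interval onto the estimate
  ci0 <- profile_confidence_interval(prob, fit, "C1_1", level = 0)
  expect_equal(as.numeric(ci0), rep(fit$par[["C1_1"]], 2))

  # doubling sigma widens the interval by a factor of two (linear regime)
  wide <- series1
  wide[[1]]$sigma <- 2 * wide[[1]]$sigma
  prob2 <- global_fit_problem(wide, init = truth_par(1)[shape_fix],
                              fixed = shape_fix)
  fit2 <- fit_global(prob2, n_starts = 1)
  ci1 <- profile_confidence_interval(prob, fit, "C1_1")
  ci2 <- profile_confidence_interval(prob2, fit2, "C1_1")
  expect_equal(unname(ci2["upper"] - ci2["lower"]) /
                 unname(ci1["upper"] - ci1["lower"]), 2, tolerance = 0.01)
})

test_that("profile endpoints at a parameter bound are flagged censored", {
  # two-curve problem keeps the re-minimizations quick; x_1 is generated at
  # its lower bound 0, so the lower profile endpoint must censor at 0
  series2 <- generate_saxs_series(saxs_series_spec(seed = 3))[1:2]
  prob <- global_fit_problem(series2, init = truth_par(2))
  fit <- fit_global(prob, n_starts = 1)
  ci <- profile_confidence_interval(prob, fit, "x_1")
  expect_equal(unname(ci["lower"]), 0)
  expect_true(attr(ci, "censored")[1])
  expect_false(attr(ci, "censored")[2])
  expect_gt(ci["upper"], fit$par[["x_1"]])
  expect_error(profile_confidence_interval(prob, fit, "L_q"),
               "not a refinable")
})

test_that("problem construction validates bounds and names", {
  expect_error(global_fit_problem(list()), "at least one")
  expect_error(global_fit_problem(series4, init = c(L_t = 40)), "bounds")
  expect_error(global_fit_problem(series4, init = c(bogus = 1)), "unknown")
  expect_error(global_fit_problem(series4, fixed = "nope"), "unknown")
})
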
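test_that("constant clock exposure gives an exactly logarithmic time", {
  u <- seq(1, exp(1), length.out = 3000)
  tc <- time_arbitrary(u, rep(1, length(u)))
  expect_equal(max(tc$t_au), 1, tolerance = 1e-6)
  expect_equal(tc$t_au[1], 0)
  expect_true(all(diff(tc$t_au) >= 0))

  u2 <- seq(2, 8, length.out = 3000)
  tc2 <- time_arbitrary(u2, rep(1, 3000))
  expect_equal(max(tc2$t_au), log(4), tolerance = 1e-6)

  # linear in the exposure scale
  tc3 <- time_arbitrary(u2, rep(2.5, 3000))
  expect_equal(tc3$t_au, 2.5 * tc2$t_au, tolerance = 1e-12)

  expect_warning(tz <- time_arbitrary(u2, rep(0, 3000)), "no clock")
  expect_true(all(tz$t_au == 0))
  expect_error(time_arbitrary(rev(u2), rep(1, 3000)), "ascending")
})

test_that("calibration rescales to the known duration", {
  tc <- time_arbitrary(seq(1, 10, length.out = 50),
                       rep(1, 50))
  tc$t_au <- tc$t_au * 4 / max(tc$t_au) # max(t_au) = 4
  cal <- calibrate_recurrence(tc, 12)
  expect_equal(max(cal$t_real), 12)
  expect_equal(cal$t_real[which.min(abs(cal$t_au - 2))], 6,
               tolerance = 0.05)
  same <- calibrate_recurrence(tc, max(tc$t_au))
  expect_equal(same$t_real, same$t_au)
  expect_true(all(diff(cal$t_real) >= 0))
})

test_that("boundary windows measure flux and mean inverse frequency", {
  tc <- structure(
    data.frame(u = seq(1, 100, length.out = 100),
               t_au = seq(0, 40, length.out = 100),
               t_real = seq(0, 40, length.out = 100)),
    class = c("time_course", "data.frame")
  )
  # last 5% of time points span 2 months and hold 100 mutations
  u_var <- rep(97, 100)
  bf <- boundary_flux(tc, u_var, "primary-end")
  expect_equal(bf$dM, 100)
  expect_equal(bf$dt, 40 * 4 / 99, tolerance = 1e-9)
  expect_equal(bf$u_mean, 97)
  bf2 <- boundary_flux(tc, c(rep(2, 60), rep(50, 40)), "recurrence-start")
  expect_equal(bf2$dM, 60)
  expect_equal(bf2$u_mean, 2)
})

test_that("time propagation matches the closed-form substitution", {
  # grid chosen so the terminal window holds 100 mutations at u = 98
  tc <- structure(
    data.frame(u = seq(1, 100, length.out = 100),
               t_au = seq(0, 10, length.out = 100)),
    class = c("time_course", "data.frame")
  )
  u_var <- rep(98, 100)
  prop <- propagate_primary(tc, u_var, dMdt_R = 50, uR = 49,
                            gamma_PR = 1 / 300)
  # dt_P = 100 / ((98/49) * (1/300) * 50) = 300
  expect_equal(prop$dt_P, 300)
  expect_equal(prop$dM_P, 100)
  expect_equal(prop$uP, 98)
  # the propagated timeline spans dt_P over the terminal window
  bf <- boundary_flux(prop$tc, u_var, "primary-end")
  expect_equal(bf$dt, 300)
  expect_error(propagate_primary(tc, u_var, dMdt_R = 0, uR = 49), "zero")
})

test_that("the survival ratio follows its defining identity", {
  expect_equal(survival_ratio(10, uR = 2, uP = 5, dMdt_P = 1), 25)
  expect_equal(survival_ratio(3, uR = 4, uP = 4, dMdt_P = 3), 1)
  expect_error(survival_ratio(-1, 2, 2, 1), "positive")
})

test_that("propagation followed by the ratio returns the assumption exactly", {
  tc <- structure(
    data.frame(u = exp(seq(0, 5, length.out = 200)),
               t_au = seq(0, 7, length.out = 200)^1.3),
    class = c("time_course", "data.frame")
  )
  set.seed(13)
  u_var <- exp(runif(3000, 0, 5))
  for (gpr in c(1 / 300, 1 / 30, 0.5)) {
    prop <- propagate_primary(tc, u_var, dMdt_R = 17.3, uR = 3.7,
                              gamma_PR = gpr)
    bf <- boundary_flux(prop$tc, u_var, "primary-end")
    est <- survival_ratio(17.3, uR = 3.7, uP = bf$u_mean, dMdt_P = bf$dMdt)
    expect_equal(est, 1 / gpr, tolerance = 1e-12)
  }
})

test_that("expansion profiles differentiate u against time", {
  # linear u(t): constant profile
  tc <- structure(data.frame(u = 1 + 2 * (0:50), t_au = 0:50),
                  class = c("time_course", "data.frame"))
  prof <- expansion_profile(tc, smooth = FALSE)
  expect_equal(unique(round(prof$wgn, 9)), 2)
  # u = t^2: profile ~ 2t
  t <- seq(1, 10, length.out = 100)
  tc2 <- structure(data.frame(u = t^2, t_au = t),
                   class = c("time_course", "data.frame"))
  prof2 <- expansion_profile(tc2, smooth = FALSE)
  interior <- 2:99
  expect_lt(max(abs(prof2$wgn[interior] - 2 * t[interior]) /
                  (2 * t[interior])), 0.02)
  bad <- structure(data.frame(u = 1:5, t_au = c(0, 1, 1, 0.5, 2)),
                   class = c("time_course", "data.frame"))
  expect_error(expansion_profile(bad), "nonmonotone")
})

test_that("recurrence-time regression recovers known coefficients", {
  set.seed(14)
  r <- 10^runif(24, 0.5, 2.5)
  t <- 19.5 - 5.8 * log10(r) + rnorm(24, 0, 1)
  fit <- recurrence_time_regression(r, t)
  expect_lt(abs(fit$fit1$slope - (-5.8)), 2 * fit$fit1$se_slope)
  expect_lt(fit$fit1$p_adj, 0.05)
  expect_false(is.null(fit$fit2))

  # perfectly collinear data: exact coefficients, zero standard error
  r2 <- c(10, 100, 1000)
  t2 <- 20 - 4 * log10(r2)
  fit2 <- suppressWarnings(recurrence_time_regression(r2, t2))
  expect_equal(fit2$fit1$slope, -4, tolerance = 1e-9)
  expect_lt(fit2$fit1$se_slope, 1e-9)

  expect_error(recurrence_time_regression(c(2, 3), c(1, 2)), "at least 3")
  expect_warning(recurrence_time_regression(c(0.5, 2, 3, 4), 1:4),
                 "excluded")
})
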
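test_that("noiseless 4PL data are recovered to high precision", {
  p <- list(bottom = 0, top = 1, ic50 = 10, hill = 1)
  dr <- simulate_dose_response(p, log_spaced_doses(10), cv = 0, seed = 1)
  f <- fit_4pl(dr)
  expect_true(f$converged)
  expect_lt(abs(f$ic50 - 10) / 10, 1e-6)
  expect_lt(abs(f$hill) - 1, 1e-6)
  expect_equal(f$bottom, 0, tolerance = 1e-6)
  expect_equal(f$top, 1, tolerance = 1e-6)
  # canonical orientation and the midpoint property
  expect_lte(f$bottom, f$top)
  expect_equal(predict(f, data.frame(dose = f$ic50)),
               (f$top + f$bottom) / 2, tolerance = 1e-8)
})

test_that("rising curves (negative slope parameterization) fit equally well", {
  p <- list(bottom = 0, top = 1, ic50 = 4, hill = -1.5)
  dr <- simulate_dose_response(p, log_spaced_doses(4), cv = 0, seed = 1)
  f <- fit_4pl(dr)
  expect_lt(abs(f$ic50 - 4) / 4, 1e-6)
  expect_equal(f$hill, -1.5, tolerance = 1e-5)
})

test_that("fitting rejects thin or broken inputs honestly", {
  expect_error(fit_4pl(data.frame(dose = c(1, 2, 4), response = 1:3)),
               "4 distinct")
  expect_error(fit_4pl(data.frame(dose = c(-1, 1, 2, 4, 8),
                                  response = 1:5)),
               "strictly positive")
  expect_error(fit_4pl(data.frame(dose = c(1, 2, 4, 8),
                                  response = c(1, NA, 2, 3))),
               "finite")
})

test_that("fitted IC50 is equivariant under dose rescaling", {
  p <- list(bottom = 5, top = 95, ic50 = 2, hill = 1.3)
  dr <- simulate_dose_response(p, log_spaced_doses(2), cv = 0.05, seed = 6)
  f1 <- fit_4pl(dr)
  dr2 <- dr; dr2$dose <- dr$dose * 1000
  f2 <- fit_4pl(dr2)
  expect_equal(f2$ic50 / f1$ic50, 1000, tolerance = 1e-6)
  expect_equal(f2$hill, f1$hill, tolerance = 1e-6)
  expect_equal(f2$top, f1$top, tolerance = 1e-6)
  expect_equal(f2$bottom, f1$bottom, tolerance = 1e-6)
})

test_that("IC50 recovery under realistic noise stays tight over many curves", {
  set.seed(55)
  errs <- vapply(1:100, function(i) {
    ic50 <- 10^runif(1, -1, 2)
    p <- list(bottom = 0, top = 1, ic50 = ic50, hill = 1)
    dr <- simulate_dose_response(p, log_spaced_doses(ic50), cv = 0.05,
                                 n_replicates = 3, seed = 1000 + i)
    abs(log(fit_4pl(dr)$ic50 / ic50))
  }, numeric(1))
  expect_lt(median(errs), 0.07)
})

test_that("a noisy fenticonazole-like binding curve recovers its IC50", {
  # rising displacement curve, 0 -> 100 %
  p <- list(bottom = 0, top = 100, ic50 = 14, hill = -1)
  dr <- simulate_dose_response(p, log_spaced_doses(14), cv = 0.05,
                               n_replicates = 3, seed = 7)
  f <- fit_4pl(dr)
  expect_lt(abs(f$ic50 - 14) / 14, 0.15)
})

test_that("bootstrap interval is degenerate without noise and grows with it", {
  p <- list(bottom = 0, top = 1, ic50 = 10, hill = 1)
  doses <- log_spaced_doses(10)
  dr0 <- simulate_dose_response(p, doses, cv = 0, seed = 1)
  f0 <- fit_4pl(dr0)
  ci0 <- bootstrap_ci(dr0, f0, n_boot = 100, seed = 2)
  expect_equal(ci0$ci_low, f0$ic50, tolerance = 1e-6)
  expect_equal(ci0$ci_high, f0$ic50, tolerance = 1e-6)

  widths <- vapply(c(0.02, 0.1), function(cv) {
    dr <- simulate_dose_response(p, doses, cv = cv, seed = 5)
    f <- fit_4pl(dr)
    ci <- bootstrap_ci(dr, f, n_boot = 150, seed = 3)
    ci$ci_high - ci$ci_low
  }, numeric(1))
  expect_lt(widths[1], widths[2])

  dr <- simulate_dose_response(p, doses, cv = 0.05, seed = 8)
  f <- fit_4pl(dr)
  expect_identical(bootstrap_ci(dr, f, n_boot = 120, seed = 4),
                   bootstrap_ci(dr, f, n_boot = 120, seed = 4))
  ci_small <- bootstrap_ci(dr, f, n_boot = 50, seed = 4)
  expect_match(ci_small$warning, "below 100")
  expect_true(ci_small$ci_low <= f$ic50 && f$ic50 <= ci_small$ci_high)
})

test_that("Cheng-Prusoff conversion bounds and arithmetic hold", {
  expect_equal(cheng_prusoff_ki(10, 1e-9, 1), 10, tolerance = 1e-6)
  expect_equal(cheng_prusoff_ki(10, 2, 2), 5)
  expect_equal(cheng_prusoff_ki(28, 3, 3), 14)
  expect_error(cheng_prusoff_ki(10, 0, 1), "positive")
  # always <= IC50 and monotone decreasing in tracer concentration
  kis <- vapply(c(0.1, 1, 10), function(conc)
    cheng_prusoff_ki(10, conc, 2), numeric(1))
  expect_true(all(kis <= 10))
  expect_true(all(diff(kis) < 0))
})

test_that("endpoint growth inhibition normalizes to treatment time", {
  times <- seq(0, 144, by = 24)
  growth <- function(rate) 1 * exp(rate * times / 24)
  curves <- rbind(
    data.frame(time_h = times, dose = 0, cell_index = growth(0.4)),
    data.frame(time_h = times, dose = 1, cell_index = growth(0.4)),
    data.frame(time_h = times, dose = 10,
               cell_index = growth(0.4) * c(1, 1, rep(0.5, 5))),
    data.frame(time_h = times, dose = 100,
               cell_index = c(growth(0.4)[1:2], rep(1e-9, 5))))
  res <- growth_endpoint_inhibition(curves, t_treat = 24, t_end = 144)
  out <- res$data
  expect_equal(out$response[out$dose == 1], 0)          # same as vehicle
  expect_equal(out$response[out$dose == 10], 0.5)       # half the vehicle NCI
  expect_equal(out$response[out$dose == 100], 1, tolerance = 1e-6)
  expect_error(growth_endpoint_inhibition(curves[curves$dose > 0, ],
                                          24, 144), "vehicle")
  bad <- curves; bad$cell_index[bad$dose == 1 & bad$time_h == 24] <- 0
  expect_error(growth_endpoint_inhibition(bad, 24, 144), "positive")
})
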
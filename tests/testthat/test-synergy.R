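# shared noiseless fixture: two rising single-agent effect curves
make_null_grid <- function(model = "bliss", cv = 0, seed = 1,
                           interaction = "null") {
  pa <- list(bottom = 0, top = 1, ic50 = 5, hill = -1)
  pb <- list(bottom = 0, top = 1, ic50 = 2, hill = -1.3)
  da <- c(0, 5 * c(1/9, 1/3, 1, 3, 9))
  db <- c(0, 2 * c(1/9, 1/3, 1, 3, 9))
  simulate_combination_grid(pa, pb, da, db, interaction = interaction,
                            model = model, cv = cv, seed = seed)
}

test_that("Bliss expected-effect arithmetic and bounds hold", {
  expect_equal(bliss_expected(0.5, 0.5), 0.75)
  expect_equal(bliss_expected(0.3, 0), 0.3) # margin identity
  expect_error(bliss_expected(1.2, 0.5), "\\[0, 1\\]")
  set.seed(14)
  ea <- runif(200); eb <- runif(200)
  e <- bliss_expected(ea, eb)
  expect_true(all(e >= pmax(ea, eb) - 1e-12))
  expect_true(all(e <= pmin(1, ea + eb) + 1e-12))
})

test_that("expected surfaces equal the observed single-agent margins", {
  g <- make_null_grid(cv = 0)
  fits <- fit_single_agents(g)
  for (m in c("loewe", "bliss", "hsa")) {
    s <- expected_surface(g, fits, m)
    expect_equal(s$expected[1, ], g$observed[1, ])
    expect_equal(s$expected[, 1], g$observed[, 1])
    expect_true(all(s$flags[1, ] == "margin"))
  }
})

test_that("HSA never exceeds Bliss on the fraction scale", {
  g <- make_null_grid(cv = 0.03, seed = 4)
  fits <- fit_single_agents(g)
  hsa <- expected_surface(g, fits, "hsa")$expected[-1, -1]
  bliss <- expected_surface(g, fits, "bliss")$expected[-1, -1]
  expect_true(all(hsa <= bliss + 1e-12))
})

test_that("Loewe passes the sham-combination test", {
  p <- list(bottom = 0, top = 1, ic50 = 5, hill = -1)
  d <- c(0, 5 * c(1/9, 1/3, 1, 3, 9))
  g <- simulate_combination_grid(p, p, d, d, cv = 0, seed = 1)
  fits <- fit_single_agents(g)
  s <- expected_surface(g, fits, "loewe")
  for (i in 2:6) {
    # a drug sham-combined with itself: (d, d) behaves like 2d alone
    expect_equal(s$expected[i, i], fourpl(2 * d[i], 0, 1, 5, -1),
                 tolerance = 1e-6)
  }
})

test_that("Loewe flags cells beyond both drugs' achievable effects", {
  # drug A plateaus at 0.3 while B reaches 0.9: the shared effect range
  # is capped at A's ceiling, which high doses of B alone exceed
  pa <- list(bottom = 0, top = 0.3, ic50 = 5, hill = -1)
  pb <- list(bottom = 0, top = 0.9, ic50 = 2, hill = -1)
  da <- c(0, 5 * c(1/9, 1/3, 1, 3, 9))
  db <- c(0, 2 * c(1/9, 1/3, 1, 3, 9))
  g <- simulate_combination_grid(pa, pb, da, db, cv = 0, seed = 1)
  fits <- fit_single_agents(g)
  s <- expected_surface(g, fits, "loewe")
  expect_equal(s$flags[6, 6], "out_of_range")
  expect_true(is.na(s$expected[6, 6]))
  expect_equal(s$flags[2, 2], "ok")
})

test_that("synergy deltas vanish for self-consistent null grids", {
  g <- make_null_grid(model = "bliss", cv = 0)
  fits <- fit_single_agents(g)
  s <- synergy_matrix(g, expected_surface(g, fits, "bliss"))
  expect_equal(s$summary_score, 0, tolerance = 1e-8)
  expect_true(all(abs(s$delta) < 1e-8))
})

test_that("a planted interior delta is recovered and averaged correctly", {
  delta <- matrix(0, 6, 6); delta[4, 4] <- 0.2
  g <- make_null_grid(interaction = delta, cv = 0)
  fits <- fit_single_agents(g)
  s <- synergy_matrix(g, expected_surface(g, fits, "bliss"))
  expect_equal(s$delta[4, 4], 0.2, tolerance = 1e-7)
  # mean over the 25 interior cells of the 6x6 grid
  expect_equal(s$summary_score, 0.2 / 25, tolerance = 1e-7)
})

test_that("summary score averages a 5x5 grid's planted delta over 16 cells", {
  pa <- list(bottom = 0, top = 1, ic50 = 5, hill = -1)
  pb <- list(bottom = 0, top = 1, ic50 = 2, hill = -1)
  da <- c(0, 5 * c(1/6, 1/2, 2, 6)); db <- c(0, 2 * c(1/6, 1/2, 2, 6))
  delta <- matrix(0, 5, 5); delta[3, 3] <- 0.2
  g <- simulate_combination_grid(pa, pb, da, db, interaction = delta,
                                 cv = 0, seed = 1)
  s <- synergy_matrix(g, expected_surface(g, fit_single_agents(g), "bliss"))
  expect_equal(s$summary_score, 0.2 / 16, tolerance = 1e-7)
})

test_that("margin fits recover a planted palbociclib-like potency", {
  pa <- list(bottom = 0, top = 1, ic50 = 28, hill = -1)
  pb <- list(bottom = 0, top = 1, ic50 = 2.45, hill = -1)
  da <- c(0, 10^seq(log10(28 / 30), log10(28 * 30), length.out = 8))
  db <- c(0, 10^seq(log10(2.45 / 30), log10(2.45 * 30), length.out = 8))
  g <- simulate_combination_grid(pa, pb, da, db, cv = 0.05, seed = 31)
  fits <- fit_single_agents(g)
  expect_lt(abs(fits$fit_b$ic50 - 2.45) / 2.45, 0.15)
})

test_that("grid construction enforces margins and shape", {
  expect_error(combination_grid(c(1, 2, 3), c(0, 1), matrix(0, 3, 2)),
               "start at 0")
  expect_error(combination_grid(c(0, 2, 1), c(0, 1), matrix(0, 3, 2)),
               "increasing")
  expect_error(combination_grid(c(0, 1), c(0, 1), matrix(0, 3, 2)),
               "dimensions")
  expect_error(fit_single_agents(
    combination_grid(c(0, 1, 2, 3), c(0, 1, 2, 3, 4, 5),
                     matrix(0, 4, 6))), "4 nonzero")
})
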
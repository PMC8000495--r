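test_that("screen simulation plants the requested binders and is seed-stable", {
  cfg <- screen_sim_config(n_compounds = 200, n_planted_binders = 10,
                           seed = 3)
  sim <- simulate_fp_screen(cfg)
  expect_equal(sum(sim$truth$is_binder), 10)
  expect_true(all(sim$truth$true_displacement[sim$truth$is_binder] >= 0.8))
  expect_equal(sim$truth$true_displacement[!sim$truth$is_binder],
               rep(0, 190))
  # one truth entry per simulated compound
  expect_setequal(sim$truth$compound_id,
                  stats::na.omit(sim$plates$compound_id))
  sim2 <- simulate_fp_screen(cfg)
  expect_identical(sim, sim2)
  expect_false(identical(
    sim, simulate_fp_screen(screen_sim_config(n_compounds = 200,
                                              n_planted_binders = 10,
                                              seed = 4))))
})

test_that("plate layout arithmetic fills the minimum number of plates", {
  cfg <- screen_sim_config(n_compounds = 20, n_planted_binders = 2, seed = 1)
  sim <- simulate_fp_screen(cfg)
  expect_equal(length(unique(sim$plates$plate_id)), 1)
  expect_equal(sum(sim$plates$role == "compound"), 20)
  expect_equal(sum(sim$plates$role == "pos_ctrl"), 16)
  expect_equal(sum(sim$plates$role == "neg_ctrl"), 16)
  # 353 compounds exceed one 384-well plate's 352 compound wells
  expect_equal(screen_sim_config(n_compounds = 353, seed = 1)$n_plates, 2)
  expect_error(screen_sim_config(n_compounds = 1018, n_plates = 2),
               "does not fit")
})

test_that("degenerate screen configs are rejected or warned about", {
  expect_error(screen_sim_config(n_pos_ctrl_wells = 0), "control")
  expect_error(screen_sim_config(n_compounds = 10, n_planted_binders = 11),
               "n_planted_binders")
  expect_error(screen_sim_config(ctrl_mP_bound = 50, ctrl_mP_free = 50),
               "exceed")
  # noise beyond window/6 implies an expected Z' below zero
  expect_warning(screen_sim_config(noise_sd = 30), "Z'")
})

test_that("dose-response simulation sits on the true curve at cv 0", {
  p <- list(bottom = 0, top = 100, ic50 = 10, hill = 1)
  doses <- log_spaced_doses(10)
  dr <- simulate_dose_response(p, doses, cv = 0, n_replicates = 2, seed = 1)
  expect_equal(dr$response,
               fourpl(dr$dose, 0, 100, 10, 1))
  # 4PL midpoint at the IC50
  mid <- simulate_dose_response(p, c(10, 1, 100, 0.1), cv = 0, seed = 1)
  expect_equal(mid$response[mid$dose == 10], rep(50, 3))
  expect_identical(simulate_dose_response(p, doses, cv = 0.05, seed = 9),
                   simulate_dose_response(p, doses, cv = 0.05, seed = 9))
  expect_error(simulate_dose_response(p, doses, cv = -0.1), "cv")
  expect_error(simulate_dose_response(p, c(1, 10, 100), cv = 0),
               "4 distinct")
})

test_that("combination grids honor margins, planted deltas and the Bliss scale", {
  pa <- list(bottom = 0, top = 1, ic50 = 5, hill = -1)
  pb <- list(bottom = 0, top = 1, ic50 = 2, hill = -1)
  da <- c(0, 5 * c(1/9, 1/3, 1, 3, 9)); db <- c(0, 2 * c(1/9, 1/3, 1, 3, 9))
  g <- simulate_combination_grid(pa, pb, da, db, cv = 0, seed = 1)
  # dose_b = 0 column equals drug A's single-agent curve
  expect_equal(g$observed[-1, 1], fourpl(da[-1], 0, 1, 5, -1))
  expect_equal(g$observed[1, ], c(0, fourpl(db[-1], 0, 1, 2, -1)))
  delta <- matrix(0, 6, 6); delta[3, 4] <- 0.2
  g2 <- simulate_combination_grid(pa, pb, da, db, interaction = delta,
                                  cv = 0, seed = 1)
  expect_equal(g2$observed - g$observed, delta)
  expect_error(simulate_combination_grid(pa, pb, da[-1], db),
               "include 0")
  big <- list(bottom = 0, top = 2, ic50 = 5, hill = -1)
  expect_error(simulate_combination_grid(big, pb, da, db, model = "bliss"),
               "\\[0, 1\\]")
})

test_that("in-cell simulation plants effects that drive the consensus", {
  labs <- estroscreen:::incell_dataset_specs()$label
  planted <- list(hit4 = labs[1:4], hit3 = labs[1:3])
  d <- simulate_incell_datasets(c("hit4", "hit3", "inert"), planted,
                                cell_lines = "MCF-7", noise_sd = 1,
                                seed = 11)
  hm <- build_hit_matrix(d, "MCF-7")
  cons <- consensus_call(hm, k = 4)
  expect_true(cons[["hit4"]])
  expect_false(cons[["hit3"]])
  expect_false(cons[["inert"]])
  expect_identical(d, simulate_incell_datasets(c("hit4", "hit3", "inert"),
                                               planted,
                                               cell_lines = "MCF-7",
                                               noise_sd = 1, seed = 11))
  expect_error(simulate_incell_datasets("a", vehicle_n = 2), "vehicle")
})

test_that("with no planted effects the in-cell hit rate stays near null", {
  d <- simulate_incell_datasets(sprintf("c%03d", 1:100),
                                cell_lines = "MCF-7", seed = 21)
  hm <- build_hit_matrix(d, "MCF-7")
  # 600 compound-dataset scores at a -3 robust-Z rule: expect only a
  # small handful of false positives (n = 3 replicate means are noisy)
  expect_lt(mean(hm), 0.05)
})

test_that("qPCR simulation encodes folds in Ct space", {
  ct <- simulate_qpcr_panel(c(a = 1, b = 0.5, c = 2), noise_sd = 0,
                            seed = 1)
  expect_equal(ct$ct_target_treated - ct$ct_target_control,
               -log2(c(1, 0.5, 2)))
  # fold 0.5: treated target amplifies exactly one cycle later
  expect_equal(ct$ct_target_treated[2] - ct$ct_target_control[2], 1)
  expect_equal(ct$ct_ref_treated, ct$ct_ref_control)
  expect_identical(simulate_qpcr_panel(c(1, 2), seed = 5),
                   simulate_qpcr_panel(c(1, 2), seed = 5))
  expect_error(simulate_qpcr_panel(numeric(0)), "at least one gene")
  expect_error(simulate_qpcr_panel(c(1, -2)), "positive")
})
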
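#' Pipeline configuration
#'
#' Assembles every tunable of the end-to-end demonstration pipeline with
#' explicit seeds for each stochastic stage (derived from `seed` when not
#' given), so re-running a config is bit-identical.
#'
#' @param seed Master integer seed; stage seeds default to fixed offsets
#'   of it.
#' @param n_compounds,n_planted_binders,n_plates Primary-screen scale
#'   (defaults: 1018-compound library, 61 planted binders, 12 plates of
#'   384 wells).
#' @param noise_sd Screen well noise in mP.
#' @param z_star_threshold Primary hit threshold on the robust Z score.
#' @param n_anticancer,n_endocrine,n_manual Triage flag counts planted in
#'   the synthetic annotation table (defaults 14, 12, 14).
#' @param consensus_k Minimum supporting datasets for a consensus call
#'   (default 4 of the 6).
#' @param incell_threshold Per-dataset robust-effect hit threshold
#'   (default -3).
#' @param binding_ki True binding IC50s (µM) used for the validation
#'   dose-response stage.
#' @param n_boot Bootstrap refits for IC50 confidence intervals.
#' @param modulation_threshold Gene-panel modulation threshold.
#' @param out_dir Directory for CSV/JSON artifacts, or `NULL` to skip
#'   writing.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, n_compounds = 1018,
                            n_planted_binders = 61, n_plates = 12,
                            noise_sd = 5, z_star_threshold = 3,
                            n_anticancer = 14, n_endocrine = 12,
                            n_manual = 14, consensus_k = 4,
                            incell_threshold = -3,
                            binding_ki = c(clotrimazole = 28,
                                           fenticonazole = 14),
                            n_boot = 200, modulation_threshold = 0.5,
                            out_dir = NULL) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full synthetic screen-to-validation pipeline
#'
#' Orchestrates simulate -> screen -> triage -> consensus -> dose-response
#' -> synergy -> gene panel on fully synthetic data with planted ground
#' truth, and returns a machine-readable run report of per-stage counts
#' and results. With `out_dir` set, writes the per-stage CSV/JSON
#' artifacts. Deterministic: the same config yields an identical report.
#'
#' @param config A [pipeline_config()].
#' @return List of class `run_report`; see the `funnel` element for the
#'   stage-by-stage compound counts.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- config$seed

  ## 1. primary screen -------------------------------------------------
  scfg <- screen_sim_config(n_compounds = config$n_compounds,
                            n_planted_binders = config$n_planted_binders,
                            n_plates = config$n_plates,
                            noise_sd = config$noise_sd, seed = seed)
  sim <- simulate_fp_screen(scfg)
  screen <- score_fp_screen(sim$plates,
                            z_star_threshold = config$z_star_threshold)
  hits <- call_binding_hits(screen$scores, config$z_star_threshold)

  ## 2. annotation triage ----------------------------------------------
  binder_ids <- sim$truth$compound_id[sim$truth$is_binder]
  ann <- simulate_annotations(sim$truth$compound_id,
                              flag_ids = binder_ids,
                              n_anticancer = config$n_anticancer,
                              n_endocrine = config$n_endocrine,
                              n_manual = config$n_manual)
  triage <- filter_hits(hits$compound_id, ann)
  candidates <- triage$stages$final

  ## 3. in-cell consensus across two cell lines ------------------------
  # plant a shared-active pair plus one line-specific active per line,
  # mirroring a screen where two drugs act in both models
  all6 <- incell_dataset_specs()$label
  pick <- function(i) candidates[min(i, length(candidates))]
  planted_mcf7 <- stats::setNames(
    list(all6[1:5], all6[1:4], all6[1:4]),
    c(pick(1), pick(2), pick(3)))
  planted_y537s <- stats::setNames(
    list(all6[1:5], all6[1:4], all6[2:5]),
    c(pick(1), pick(2), pick(4)))
  incell <- rbind(
    simulate_incell_datasets(candidates, planted_mcf7,
                             cell_lines = "MCF-7", seed = seed + 101),
    simulate_incell_datasets(candidates, planted_y537s,
                             cell_lines = "Y537S", seed = seed + 102))
  hm_mcf7 <- build_hit_matrix(incell, "MCF-7", config$incell_threshold)
  hm_y537s <- build_hit_matrix(incell, "Y537S", config$incell_threshold)
  cons_mcf7 <- names(which(consensus_call(hm_mcf7, config$consensus_k)))
  cons_y537s <- names(which(consensus_call(hm_y537s, config$consensus_k)))
  lines <- intersect_lines(cons_mcf7, cons_y537s,
                           labels = c("mcf7", "y537s"))

  ## 4. binding dose-response validation of shared candidates ----------
  fits <- lapply(seq_along(config$binding_ki), function(i) {
    ki <- config$binding_ki[[i]]
    doses <- 10^seq(log10(ki / 30), log10(ki * 30), length.out = 8)
    dr <- simulate_dose_response(list(bottom = 0, top = 100, ic50 = ki,
                                      hill = -1), # rising displacement
                                 doses, cv = 0.05, n_replicates = 3,
                                 seed = seed + 200 + i)
    fit <- fit_4pl(dr)
    ci <- bootstrap_ci(dr, fit, n_boot = config$n_boot,
                       seed = seed + 300 + i)
    data.frame(compound = names(config$binding_ki)[i],
               true_ic50 = ki, ic50 = fit$ic50, hill = fit$hill,
               bottom = fit$bottom, top = fit$top,
               ci_low = ci$ci_low, ci_high = ci$ci_high,
               converged = fit$converged)
  })
  fits <- do.call(rbind, fits)

  ## 5. combination synergy demo ---------------------------------------
  pa <- list(bottom = 0, top = 1, ic50 = 28, hill = -1)   # rising effect
  pb <- list(bottom = 0, top = 1, ic50 = 2.45, hill = -1)
  doses_a <- c(0, 28 * c(1/9, 1/3, 1, 3, 9))
  doses_b <- c(0, 2.45 * c(1/9, 1/3, 1, 3, 9))
  delta <- matrix(0, 6, 6); delta[3:5, 3:5] <- 0.1
  grid <- simulate_combination_grid(pa, pb, doses_a, doses_b,
                                    interaction = delta, model = "bliss",
                                    cv = 0.02, seed = seed + 400)
  sfits <- fit_single_agents(grid)
  synergy <- lapply(c("loewe", "bliss", "hsa"), function(m) {
    s <- synergy_matrix(grid, expected_surface(grid, sfits, m))
    s$summary_score
  })
  names(synergy) <- c("loewe", "bliss", "hsa")

  ## 6. gene-panel modulation demo -------------------------------------
  folds <- withr::with_seed(seed + 500, {
    n <- 88
    mod <- sample(c(TRUE, FALSE), n, replace = TRUE, prob = c(0.55, 0.45))
    f <- stats::runif(n, 0.7, 1.4)
    f[mod] <- ifelse(stats::runif(sum(mod)) < 0.65,
                     stats::runif(sum(mod), 0.05, 0.45),
                     stats::runif(sum(mod), 1.6, 4))
    f
  })
  panel <- analyze_gene_panel(
    simulate_qpcr_panel(folds, noise_sd = 0.05, seed = seed + 501),
    threshold = config$modulation_threshold)

  report <- structure(list(
    config = config,
    funnel = c(library = config$n_compounds,
               plates = nrow(screen$qc),
               plates_passed = sum(screen$qc$passed),
               scored = nrow(screen$scores),
               qc_excluded = length(screen$excluded),
               hits = nrow(hits),
               after_anticancer = length(triage$stages$after_anticancer),
               after_endocrine = length(triage$stages$after_endocrine),
               final_candidates = length(candidates)),
    planted_binders_recovered = sum(hits$compound_id %in% binder_ids),
    qc = screen$qc,
    scores = screen$scores,
    hits = hits,
    triage = triage,
    hit_matrices = list(`MCF-7` = hm_mcf7, Y537S = hm_y537s),
    consensus = list(`MCF-7` = cons_mcf7, Y537S = cons_y537s,
                     lines = lines),
    fits = fits,
    synergy_scores = synergy,
    panel = panel$summary),
    class = "run_report")

  if (!is.null(config$out_dir)) write_report(report, config$out_dir)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("Screen-to-validation run report\n")
  cat("  funnel: ",
      paste(sprintf("%s=%d", names(x$funnel), x$funnel), collapse = " "),
      "\n", sep = "")
  cat("  planted binders recovered:", x$planted_binders_recovered, "\n")
  cat("  consensus: MCF-7 {", paste(x$consensus$`MCF-7`, collapse = ", "),
      "}; Y537S {", paste(x$consensus$Y537S, collapse = ", "), "}\n")
  cat("  shared candidates:",
      paste(x$consensus$lines$shared, collapse = ", "), "\n")
  cat(sprintf("  fitted binding IC50s: %s\n",
              paste(sprintf("%s %.3g uM (true %.3g)", x$fits$compound,
                            x$fits$ic50, x$fits$true_ic50),
                    collapse = "; ")))
  cat(sprintf("  synergy summary scores: loewe %.3g, bliss %.3g, hsa %.3g\n",
              x$synergy_scores$loewe, x$synergy_scores$bliss,
              x$synergy_scores$hsa))
  cat(sprintf("  gene panel: %.1f%% modulated, %.1f%% of modulated reduced\n",
              x$panel$pct_modulated, x$panel$pct_reduced_of_modulated))
  invisible(x)
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, f) utils::write.csv(df, file.path(out_dir, f),
                                        row.names = FALSE)
  w(report$qc, "plate_qc.csv")
  w(report$scores, "screen_scores.csv")
  w(report$hits, "hits.csv")
  w(report$triage$ledger, "triage_ledger.csv")
  w(report$fits, "dose_response_fits.csv")
  json <- list(funnel = as.list(report$funnel),
               planted_binders_recovered = report$planted_binders_recovered,
               consensus = report$consensus,
               synergy_scores = report$synergy_scores,
               panel = report$panel)
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
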
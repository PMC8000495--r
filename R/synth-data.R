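#' Configuration for a synthetic fluorescence-polarization screen
#'
#' Describes a primary competitive-binding screen of a compound library in
#' multi-well plates with vehicle (DMSO, tracer fully bound, high mP) and
#' competitor (estradiol, tracer displaced, low mP) control wells, plus a
#' set of planted true binders. Defaults emulate a 1018-compound
#' FDA-approved-drug library screened in 384-well format with 61 strong
#' binders among the compounds.
#'
#' @param n_compounds Library size (default 1018).
#' @param n_planted_binders Number of true binders planted (default 61).
#' @param plate_format Wells per plate, 96 or 384 (default 384).
#' @param n_plates Number of plates; `NULL` (default) uses the minimum
#'   needed for the library at this plate format. Control columns are
#'   present on every plate.
#' @param n_pos_ctrl_wells,n_neg_ctrl_wells Control wells per plate
#'   (default: one full column each, 16 in 384-well format).
#' @param ctrl_mP_bound Expected mP of vehicle (bound-tracer) wells
#'   (default 200).
#' @param ctrl_mP_free Expected mP of competitor (free-tracer) wells
#'   (default 50); must be below `ctrl_mP_bound`.
#' @param noise_sd Gaussian well noise in mP (default 5). A warning is
#'   issued when the requested noise implies an expected plate Z' below 0.
#' @param planted_displacement_range Range of displacement fractions for
#'   planted binders, drawn uniformly (default \[0.8, 1\] so all planted
#'   binders are strong).
#' @param seed Integer seed; all generators take explicit seeds.
#' @return A `screen_sim_config` list.
#' @export
screen_sim_config <- function(n_compounds = 1018, n_planted_binders = 61,
                              plate_format = 384, n_plates = NULL,
                              n_pos_ctrl_wells = NULL, n_neg_ctrl_wells = NULL,
                              ctrl_mP_bound = 200, ctrl_mP_free = 50,
                              noise_sd = 5,
                              planted_displacement_range = c(0.8, 1.0),
                              seed = 1) {
  dims <- plate_dims(plate_format)
  if (is.null(n_pos_ctrl_wells)) n_pos_ctrl_wells <- dims$nrow
  if (is.null(n_neg_ctrl_wells)) n_neg_ctrl_wells <- dims$nrow
  if (n_pos_ctrl_wells < 1 || n_neg_ctrl_wells < 1)
    stop("each plate needs at least one positive and one negative control ",
         "well (Z' is undefined otherwise)")
  if (n_planted_binders > n_compounds)
    stop("n_planted_binders must not exceed n_compounds")
  if (ctrl_mP_bound <= ctrl_mP_free)
    stop("ctrl_mP_bound must exceed ctrl_mP_free")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  stopifnot(length(planted_displacement_range) == 2,
            planted_displacement_range[1] > 0,
            planted_displacement_range[2] <= 1)
  capacity <- dims$nrow * (dims$ncol - 2) # last two columns host controls
  if (is.null(n_plates)) n_plates <- max(1L, ceiling(n_compounds / capacity))
  if (n_plates * capacity < n_compounds)
    stop("library does not fit: ", n_plates, " plate(s) hold at most ",
         n_plates * capacity, " compounds")
  if (noise_sd > (ctrl_mP_bound - ctrl_mP_free) / 6)
    warning("noise_sd implies an expected plate Z' below 0; ",
            "plates will likely fail QC")
  structure(list(n_compounds = n_compounds,
                 n_planted_binders = n_planted_binders,
                 plate_format = plate_format, n_plates = n_plates,
                 n_pos_ctrl_wells = n_pos_ctrl_wells,
                 n_neg_ctrl_wells = n_neg_ctrl_wells,
                 ctrl_mP_bound = ctrl_mP_bound, ctrl_mP_free = ctrl_mP_free,
                 noise_sd = noise_sd,
                 planted_displacement_range = planted_displacement_range,
                 seed = seed),
            class = "screen_sim_config")
}

plate_dims <- function(plate_format) {
  switch(as.character(plate_format),
         "96" = list(nrow = 8L, ncol = 12L),
         "384" = list(nrow = 16L, ncol = 24L),
         stop("unsupported plate format: ", plate_format))
}

# Map an mP value to a parallel/perpendicular intensity pair at fixed
# total intensity, so compute_polarization() recovers it exactly.
mp_to_intensities <- function(mP, total = 5e4, g_factor = 1) {
  p <- mP / 1000
  data.frame(i_parallel = total * (1 + p) / 2,
             i_perpendicular = total * (1 - p) / (2 * g_factor))
}

#' Simulate a fluorescence-polarization primary screen
#'
#' Lays the library out across plates (compound wells in all but the last
#' two columns; the penultimate column holds competitor/positive controls,
#' the last column vehicle/negative controls), plants strong binders whose
#' expected mP is `ctrl_mP_free + (1 - displacement) * (bound - free)`,
#' leaves the remaining compounds at the bound-tracer baseline, and adds
#' Gaussian mP noise to every well before converting to channel
#' intensities. Identical seeds give bit-identical output.
#'
#' @param config A [screen_sim_config()].
#' @return List with `plates` (long-format well table: `plate_id`, `well`,
#'   `role`, `compound_id`, `i_parallel`, `i_perpendicular`, `g_factor`)
#'   and `truth` (`compound_id`, `is_binder`, `true_displacement`).
#' @export
simulate_fp_screen <- function(config) {
  stopifnot(inherits(config, "screen_sim_config"))
  dims <- plate_dims(config$plate_format)
  withr::with_seed(config$seed, {
    ids <- sprintf("CPD%04d", seq_len(config$n_compounds))
    binders <- sort(sample.int(config$n_compounds, config$n_planted_binders))
    disp <- numeric(config$n_compounds)
    disp[binders] <- stats::runif(config$n_planted_binders,
                                  config$planted_displacement_range[1],
                                  config$planted_displacement_range[2])
    truth <- data.frame(compound_id = ids,
                        is_binder = seq_along(ids) %in% binders,
                        true_displacement = disp,
                        stringsAsFactors = FALSE)

    plate_of <- rep(seq_len(config$n_plates), length.out = 0)
    # near-even consecutive chunks across plates
    sizes <- diff(round(seq(0, config$n_compounds,
                            length.out = config$n_plates + 1)))
    plate_of <- rep(seq_len(config$n_plates), times = sizes)

    window <- config$ctrl_mP_bound - config$ctrl_mP_free
    rows <- LETTERS[seq_len(dims$nrow)]
    plates <- vector("list", config$n_plates)
    for (p in seq_len(config$n_plates)) {
      idx <- which(plate_of == p)
      n_cpd <- length(idx)
      well_r <- rows[((seq_len(n_cpd) - 1) %% dims$nrow) + 1]
      well_c <- ((seq_len(n_cpd) - 1) %/% dims$nrow) + 1
      cpd_mu <- config$ctrl_mP_free + (1 - disp[idx]) * window
      pos_r <- rows[seq_len(config$n_pos_ctrl_wells)]
      neg_r <- rows[seq_len(config$n_neg_ctrl_wells)]
      df <- data.frame(
        plate_id = sprintf("P%02d", p),
        well = c(paste0(well_r, well_c),
                 paste0(pos_r, dims$ncol - 1),
                 paste0(neg_r, dims$ncol)),
        role = c(rep("compound", n_cpd),
                 rep("pos_ctrl", config$n_pos_ctrl_wells),
                 rep("neg_ctrl", config$n_neg_ctrl_wells)),
        compound_id = c(ids[idx], rep(NA_character_,
                                      config$n_pos_ctrl_wells +
                                        config$n_neg_ctrl_wells)),
        stringsAsFactors = FALSE)
      mu <- c(cpd_mu,
              rep(config$ctrl_mP_free, config$n_pos_ctrl_wells),
              rep(config$ctrl_mP_bound, config$n_neg_ctrl_wells))
      mp <- stats::rnorm(length(mu), mu, config$noise_sd)
      plates[[p]] <- cbind(df, mp_to_intensities(mp), g_factor = 1)
    }
    plates <- do.call(rbind, plates)
    rownames(plates) <- NULL
    list(plates = plates, truth = truth)
  })
}

#' Simulate replicated dose-response data from a known 4PL curve
#'
#' Responses are the true curve value times `(1 + e)` with
#' `e ~ Normal(0, cv)` independently per replicate (multiplicative
#' measurement noise, the usual model for optical readouts).
#'
#' @param true_params List with `bottom`, `top`, `ic50`, `hill`.
#' @param doses Strictly positive doses, at least 4 distinct.
#' @param cv Coefficient of variation of the noise (>= 0).
#' @param n_replicates Replicates per dose.
#' @param seed Integer seed.
#' @return data.frame with `dose`, `replicate`, `response`.
#' @export
simulate_dose_response <- function(true_params, doses, cv = 0.05,
                                   n_replicates = 3, seed = 1) {
  if (cv < 0) stop("cv must be non-negative")
  if (any(doses <= 0)) stop("doses must be strictly positive")
  if (length(unique(doses)) < 4) stop("need at least 4 distinct doses")
  d <- rep(doses, each = n_replicates)
  mu <- fourpl(d, true_params$bottom, true_params$top,
               true_params$ic50, true_params$hill)
  resp <- withr::with_seed(seed, mu * (1 + stats::rnorm(length(mu), 0, cv)))
  data.frame(dose = d, replicate = rep(seq_len(n_replicates), length(doses)),
             response = resp)
}

#' Simulate a two-drug combination grid
#'
#' Single-agent effects come from the supplied 4PL parameters (effect
#' scale: fraction of control inhibited, 0 at dose 0); interior cells are
#' generated from a null reference model (Bliss independence by default,
#' or highest single agent), optionally plus a planted deviation matrix,
#' then multiplied by `(1 + e)`, `e ~ Normal(0, cv)`.
#'
#' @param params_a,params_b 4PL parameter lists for the two agents, on a
#'   \[0, 1\] effect-fraction scale for the Bliss null.
#' @param doses_a,doses_b Dose axes; both must include 0 (single-agent
#'   margins).
#' @param interaction `"null"` or a `length(doses_a) x length(doses_b)`
#'   matrix of planted effect deviations added to the null surface.
#' @param model Reference model generating the null surface (`"bliss"` or
#'   `"hsa"`).
#' @param cv Coefficient of variation of multiplicative noise.
#' @param n_replicates Replicate wells per grid cell; the stored observed
#'   matrix is the per-cell replicate mean (default 3).
#' @param seed Integer seed.
#' @return A `combination_grid` (see [combination_grid()]) with the true
#'   delta matrix attached as attribute `"true_delta"` and the replicate
#'   count as `"n_replicates"`.
#' @export
simulate_combination_grid <- function(params_a, params_b, doses_a, doses_b,
                                      interaction = "null", model = "bliss",
                                      cv = 0, n_replicates = 3, seed = 1) {
  if (!0 %in% doses_a || !0 %in% doses_b)
    stop("both dose axes must include 0 for the single-agent margins")
  if (cv < 0) stop("cv must be non-negative")
  model <- match.arg(model, c("bliss", "hsa"))
  ea <- ifelse(doses_a == 0, 0,
               fourpl(doses_a, params_a$bottom, params_a$top,
                      params_a$ic50, params_a$hill))
  eb <- ifelse(doses_b == 0, 0,
               fourpl(doses_b, params_b$bottom, params_b$top,
                      params_b$ic50, params_b$hill))
  if (model == "bliss" && (any(ea < 0 | ea > 1) || any(eb < 0 | eb > 1)))
    stop("Bliss null requires single-agent effects on a [0, 1] fraction scale")
  expected <- switch(model,
                     bliss = outer(ea, eb, function(a, b) a + b - a * b),
                     hsa = outer(ea, eb, pmax))
  delta <- matrix(0, length(doses_a), length(doses_b))
  if (is.matrix(interaction)) {
    stopifnot(all(dim(interaction) == dim(delta)))
    delta <- interaction
  } else if (!identical(interaction, "null")) {
    stop("interaction must be \"null\" or a planted delta matrix")
  }
  mu <- expected + delta
  obs <- withr::with_seed(seed, {
    reps <- vapply(seq_len(n_replicates),
                   function(r) mu * (1 + stats::rnorm(length(mu), 0, cv)),
                   matrix(0, nrow(mu), ncol(mu)))
    apply(reps, c(1, 2), mean)
  })
  g <- combination_grid(doses_a, doses_b, obs)
  attr(g, "true_delta") <- delta
  attr(g, "n_replicates") <- n_replicates
  g
}

#' Simulate the six in-cell validation datasets per cell line
#'
#' Emulates the validation cascade: receptor levels and proliferation
#' read at 3 and 7 days, transcriptional-reporter activity at 1 and
#' 3 days, for each cell line. Vehicle wells are drawn around a common
#' baseline; compounds with a planted effect are shifted downward
#' (all three assays are read as reductions) by the planted fraction of
#' baseline.
#'
#' @param compounds Character vector of compound ids.
#' @param planted Named list: `planted[[compound]]` is a character vector
#'   of dataset labels (`"<assay>_d<timepoint>"`, e.g. `"er_level_d3"`)
#'   in which that compound has a real effect.
#' @param effect_size Planted fractional reduction of baseline (default
#'   0.5).
#' @param cell_lines Cell lines to simulate (default MCF-7 and Y537S).
#' @param vehicle_n Vehicle replicates per dataset (default 8, >= 3).
#' @param n_replicates Compound replicates per dataset (default 3).
#' @param baseline Mean vehicle signal (default 100).
#' @param noise_sd Gaussian noise SD in signal units (default 3).
#' @param seed Integer seed.
#' @return Tidy data.frame: `cell_line`, `assay`, `timepoint_days`,
#'   `compound_id` (`"VEHICLE"` for vehicle wells), `replicate`,
#'   `readout`.
#' @export
simulate_incell_datasets <- function(compounds, planted = list(),
                                     effect_size = 0.5,
                                     cell_lines = c("MCF-7", "Y537S"),
                                     vehicle_n = 8, n_replicates = 3,
                                     baseline = 100, noise_sd = 3, seed = 1) {
  if (vehicle_n < 3) stop("need at least 3 vehicle replicates per dataset")
  specs <- incell_dataset_specs()
  withr::with_seed(seed, {
    out <- list()
    for (cl in cell_lines) for (k in seq_len(nrow(specs))) {
      lab <- specs$label[k]
      veh <- data.frame(cell_line = cl, assay = specs$assay[k],
                        timepoint_days = specs$timepoint_days[k],
                        compound_id = "VEHICLE",
                        replicate = seq_len(vehicle_n),
                        readout = stats::rnorm(vehicle_n, baseline, noise_sd),
                        stringsAsFactors = FALSE)
      cpd <- lapply(compounds, function(id) {
        eff <- if (lab %in% (planted[[id]] %||% character())) effect_size else 0
        data.frame(cell_line = cl, assay = specs$assay[k],
                   timepoint_days = specs$timepoint_days[k],
                   compound_id = id, replicate = seq_len(n_replicates),
                   readout = stats::rnorm(n_replicates,
                                          baseline * (1 - eff), noise_sd),
                   stringsAsFactors = FALSE)
      })
      out[[paste(cl, lab)]] <- rbind(veh, do.call(rbind, cpd))
    }
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
  })
}

incell_dataset_specs <- function() {
  data.frame(assay = c("er_level", "er_level", "proliferation",
                       "proliferation", "transcription", "transcription"),
             timepoint_days = c(3, 7, 3, 7, 1, 3),
             label = c("er_level_d3", "er_level_d7", "proliferation_d3",
                       "proliferation_d7", "transcription_d1",
                       "transcription_d3"),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate a qPCR Ct table with planted fold changes
#'
#' The treated target Ct is the control Ct minus `log2(fold)` (a gene
#' induced 2-fold amplifies one cycle earlier); reference-gene Cts are
#' constant up to noise. Noise is additive Gaussian in Ct (cycle) space
#' on every measured Ct.
#'
#' @param planted_folds Positive fold changes (treated/control), one per
#'   gene; names become gene symbols (default `gene_001`, ...).
#' @param ct_ref Reference-gene Ct (default 18 cycles).
#' @param ct_target_base Control target Ct (default 26 cycles); recycled.
#' @param noise_sd Ct noise SD in cycles (default 0.1).
#' @param seed Integer seed.
#' @return data.frame with `gene`, `ct_target_treated`,
#'   `ct_target_control`, `ct_ref_treated`, `ct_ref_control`.
#' @export
simulate_qpcr_panel <- function(planted_folds, ct_ref = 18,
                                ct_target_base = 26, noise_sd = 0.1,
                                seed = 1) {
  n <- length(planted_folds)
  if (n == 0) stop("need at least one gene")
  if (any(planted_folds <= 0)) stop("planted folds must be positive")
  genes <- names(planted_folds) %||% sprintf("gene_%03d", seq_len(n))
  if (is.null(names(planted_folds))) names(planted_folds) <- genes
  ctc <- rep_len(ct_target_base, n)
  withr::with_seed(seed, {
    noise <- function() stats::rnorm(n, 0, noise_sd)
    data.frame(gene = genes,
               ct_target_treated = ctc - log2(planted_folds) + noise(),
               ct_target_control = ctc + noise(),
               ct_ref_treated = ct_ref + noise(),
               ct_ref_control = ct_ref + noise(),
               stringsAsFactors = FALSE)
  })
}

#' Synthetic compound annotations reproducing the triage funnel
#'
#' Assigns disjoint anti-cancer, endocrine-indication and manual-exclusion
#' flags to a chosen subset of compounds (by default the planted binders,
#' so the staged triage of a recovered hit list reproduces the
#' 61 - 14 - 12 - 14 = 21 funnel). Purely synthetic: real drug-class
#' annotations are a user-supplied table.
#'
#' @param compound_ids Full library of compound ids.
#' @param flag_ids Ids eligible for flags, in flag-assignment order.
#' @param n_anticancer,n_endocrine,n_manual Flag counts (defaults 14, 12,
#'   14), assigned disjointly from the head of `flag_ids`.
#' @return Annotation data.frame: `compound_id`, `name`, `is_anticancer`,
#'   `is_endocrine_indication`, `manual_exclusion_class`.
#' @export
simulate_annotations <- function(compound_ids, flag_ids = compound_ids,
                                 n_anticancer = 14, n_endocrine = 12,
                                 n_manual = 14) {
  if (n_anticancer + n_endocrine + n_manual > length(flag_ids))
    stop("not enough flag_ids for the requested flag counts")
  ann <- data.frame(compound_id = compound_ids,
                    name = paste0("drug_", compound_ids),
                    is_anticancer = FALSE,
                    is_endocrine_indication = FALSE,
                    manual_exclusion_class = "none",
                    stringsAsFactors = FALSE)
  grp <- rep(c("ac", "endo", "man"), c(n_anticancer, n_endocrine, n_manual))
  tgt <- flag_ids[seq_along(grp)]
  ann$is_anticancer[ann$compound_id %in% tgt[grp == "ac"]] <- TRUE
  ann$is_endocrine_indication[ann$compound_id %in% tgt[grp == "endo"]] <- TRUE
  man <- tgt[grp == "man"]
  cls <- rep_len(c("xenoestrogen", "progestin", "hormone"), length(man))
  ann$manual_exclusion_class[match(man, ann$compound_id)] <- cls
  ann
}
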
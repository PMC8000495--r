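# Printed reference potencies (µM) used as planted ground truth throughout
# the simulation-recovery tests.
reference_potencies <- function() {
  list(binding = c(clotrimazole = 28, fenticonazole = 14),
       proliferation = c(fenti_mcf7 = 9.94, fenti_y537s = 10.64,
                         clo_mcf7 = 14.14, clo_y537s = 25.17),
       cdk46 = c(palbociclib = 2.45, abemaciclib = 0.73,
                 ribociclib = 18.29))
}

log_spaced_doses <- function(ic50, span = 30, n = 8) {
  10^seq(log10(ic50 / span), log10(ic50 * span), length.out = n)
}

# Build a long-format plate table directly from target mP values
# (total intensity 1000, g = 1, so mP round-trips exactly).
plate_from_mp <- function(plate_id, compound_mp, pos_mp, neg_mp) {
  mp <- c(compound_mp, pos_mp, neg_mp)
  n_c <- length(compound_mp)
  data.frame(
    plate_id = plate_id,
    well = paste0("W", seq_along(mp)),
    role = rep(c("compound", "pos_ctrl", "neg_ctrl"),
               c(n_c, length(pos_mp), length(neg_mp))),
    compound_id = c(sprintf("%s_C%03d", plate_id, seq_len(n_c)),
                    rep(NA_character_, length(pos_mp) + length(neg_mp))),
    i_parallel = (1000 + mp) / 2,
    i_perpendicular = (1000 - mp) / 2,
    g_factor = 1,
    stringsAsFactors = FALSE)
}

# Tidy single-dataset in-cell table from vehicle readouts and named
# per-compound readout vectors.
incell_dataset <- function(vehicle, compounds,
                           assay = "er_level", timepoint = 3,
                           cell_line = "MCF-7") {
  rows <- list(data.frame(cell_line = cell_line, assay = assay,
                          timepoint_days = timepoint,
                          compound_id = "VEHICLE",
                          replicate = seq_along(vehicle),
                          readout = vehicle, stringsAsFactors = FALSE))
  for (id in names(compounds)) {
    v <- compounds[[id]]
    rows[[id]] <- data.frame(cell_line = cell_line, assay = assay,
                             timepoint_days = timepoint, compound_id = id,
                             replicate = seq_along(v), readout = v,
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}
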
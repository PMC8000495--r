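#' Convert fluorescence intensities to millipolarization
#'
#' Fluorescence polarization is computed from the parallel and perpendicular
#' emission channels as \eqn{1000 (I_\parallel - G I_\perp) / (I_\parallel +
#' G I_\perp)}, where the G factor corrects for instrument bias between the
#' two channels. Bound tracer tumbles slowly and keeps its polarization
#' (high mP); tracer displaced from the receptor by a competitor tumbles
#' freely (low mP).
#'
#' @param i_parallel,i_perpendicular Non-negative fluorescence intensities
#'   (arbitrary units), vectorized.
#' @param g_factor Dimensionless instrument G factor (default 1).
#' @param well Optional well labels used in error messages.
#' @return Polarization in millipolarization units, in \[-1000, 1000\].
#' @examples
#' compute_polarization(300, 100) # 500 mP
#' @export
compute_polarization <- function(i_parallel, i_perpendicular, g_factor = 1,
                                 well = NULL) {
  stopifnot(length(i_parallel) == length(i_perpendicular))
  if (any(i_parallel < 0, na.rm = TRUE) || any(i_perpendicular < 0, na.rm = TRUE))
    stop("fluorescence intensities must be non-negative")
  total <- i_parallel + g_factor * i_perpendicular
  bad <- which(!is.na(total) & total <= 0)
  if (length(bad)) {
    lab <- if (is.null(well)) paste(bad, collapse = ", ") else
      paste(well[bad], collapse = ", ")
    stop("zero total intensity in well(s): ", lab)
  }
  1000 * (i_parallel - g_factor * i_perpendicular) / total
}

#' Plate quality: the Z' factor
#'
#' \eqn{Z' = 1 - 3(\sigma_+ + \sigma_-)/|\mu_+ - \mu_-|} with sample
#' (n-1) standard deviations over the positive and negative control wells.
#' Z' = 1 means perfect separation of the control distributions; Z' < 0
#' means the 3-sigma envelopes overlap and the plate carries no usable
#' assay window.
#'
#' @param pos_values,neg_values Control readouts (mP), at least 2 each.
#' @return Dimensionless Z', always <= 1.
#' @examples
#' z_prime(c(90, 100, 110), c(-10, 0, 10)) # 0.4
#' @export
z_prime <- function(pos_values, neg_values) {
  if (length(pos_values) < 2 || length(neg_values) < 2)
    stop("need at least 2 control wells per group to compute Z'")
  window <- abs(mean(pos_values) - mean(neg_values))
  if (window == 0)
    stop("positive and negative control means are equal: no assay window")
  1 - 3 * (stats::sd(pos_values) + stats::sd(neg_values)) / window
}

#' Percent displacement relative to plate controls
#'
#' Linear rescaling of a well's polarization onto the control window:
#' 0 at the negative (vehicle, tracer fully bound) control mean and 100 at
#' the positive (competitor, tracer fully displaced) control mean. Values
#' outside \[0, 100\] can occur through noise and are retained.
#'
#' @param mP Well polarization (mP), vectorized.
#' @param neg_ctrl_mean,pos_ctrl_mean Control means (mP).
#' @return Percent displacement.
#' @export
normalize_displacement <- function(mP, neg_ctrl_mean, pos_ctrl_mean) {
  if (neg_ctrl_mean == pos_ctrl_mean)
    stop("control means are equal: displacement is undefined")
  100 * (neg_ctrl_mean - mP) / (neg_ctrl_mean - pos_ctrl_mean)
}

#' Robust Z scores
#'
#' Standardizes values against the median and the median absolute
#' deviation scaled by 1.4826 (the consistency factor making the MAD
#' estimate the standard deviation under normality), so scores are
#' comparable to classical Z scores but resistant to the very outliers
#' (true actives) a screen is trying to find.
#'
#' @param values Numeric vector, length >= 5.
#' @return Vector of robust Z scores.
#' @examples
#' robust_z_scores(c(1, 2, 3, 4, 100))[5] # 97 / 1.4826 = 65.43
#' @export
robust_z_scores <- function(values) {
  if (length(values) < 5)
    stop("need at least 5 values for a robust Z score")
  s <- stats::mad(values) # constant = 1.4826 by default
  if (s == 0)
    stop("MAD is zero (constant values): robust Z undefined; ",
         "report and skip this plate")
  (values - stats::median(values)) / s
}

#' Plate-level quality control
#'
#' Computes Z' per plate from its control wells and flags plates with
#' Z' < 0 as failed (the boundary Z' = 0 is kept). Plates whose Z' cannot
#' be computed (degenerate controls) are marked failed with the reason.
#'
#' @param plates Long-format plate table with columns `plate_id`, `well`,
#'   `role` (one of compound/pos_ctrl/neg_ctrl/empty), `compound_id`,
#'   `i_parallel`, `i_perpendicular`, `g_factor`.
#' @return data.frame with `plate_id`, `z_prime`, `n_pos`, `n_neg`,
#'   `passed`, `reason`.
#' @export
qc_plates <- function(plates) {
  check_plate_table(plates)
  out <- lapply(split(plates, plates$plate_id), function(p) {
    mp <- compute_polarization(p$i_parallel, p$i_perpendicular, p$g_factor,
                               well = p$well)
    pos <- mp[p$role == "pos_ctrl"]
    neg <- mp[p$role == "neg_ctrl"]
    zp <- tryCatch(z_prime(pos, neg), error = function(e) conditionMessage(e))
    if (is.character(zp)) {
      data.frame(plate_id = p$plate_id[1], z_prime = NA_real_,
                 n_pos = length(pos), n_neg = length(neg),
                 passed = FALSE, reason = zp, stringsAsFactors = FALSE)
    } else {
      data.frame(plate_id = p$plate_id[1], z_prime = zp,
                 n_pos = length(pos), n_neg = length(neg),
                 passed = zp >= 0,
                 reason = if (zp >= 0) "" else "Z' < 0",
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

check_plate_table <- function(plates) {
  need <- c("plate_id", "well", "role", "compound_id",
            "i_parallel", "i_perpendicular", "g_factor")
  miss <- setdiff(need, names(plates))
  if (length(miss))
    stop("plate table is missing column(s): ", paste(miss, collapse = ", "))
  if (!all(plates$role %in% c("compound", "pos_ctrl", "neg_ctrl", "empty")))
    stop("unknown well role in plate table")
  bad <- plates$role == "compound" & (is.na(plates$compound_id) |
                                        plates$compound_id == "")
  if (any(bad))
    stop("compound wells without a compound_id: ",
         paste(plates$well[bad], collapse = ", "))
  invisible(plates)
}

#' Score a fluorescence-polarization screen
#'
#' Full primary-screen scoring: per-well polarization, plate QC by Z'
#' (failed plates contribute no compounds to scoring), percent
#' displacement against each plate's own controls, robust Z scores over
#' each plate's compound wells on the displacement scale (binders score
#' positive), and hit calling at a strict `z_star > threshold`.
#'
#' @param plates Long-format plate table (see [qc_plates()]).
#' @param z_star_threshold Hit threshold on the robust Z score (default 3;
#'   hits are strictly above it).
#' @return List with `scores` (compound_id, plate_id, mP, displacement_pct,
#'   z_star, is_hit for compounds on passing plates), `qc` (per-plate QC
#'   table), and `excluded` (compound ids on failed plates).
#' @export
score_fp_screen <- function(plates, z_star_threshold = 3) {
  check_plate_table(plates)
  qc <- qc_plates(plates)
  scores <- lapply(split(plates, plates$plate_id), function(p) {
    pid <- p$plate_id[1]
    if (!qc$passed[qc$plate_id == pid]) return(NULL)
    mp <- compute_polarization(p$i_parallel, p$i_perpendicular, p$g_factor,
                               well = p$well)
    pos_mean <- mean(mp[p$role == "pos_ctrl"])
    neg_mean <- mean(mp[p$role == "neg_ctrl"])
    cmp <- p$role == "compound"
    disp <- normalize_displacement(mp[cmp], neg_mean, pos_mean)
    z <- robust_z_scores(disp)
    data.frame(compound_id = p$compound_id[cmp], plate_id = pid,
               mP = mp[cmp], displacement_pct = disp, z_star = z,
               is_hit = z > z_star_threshold, stringsAsFactors = FALSE)
  })
  scores <- do.call(rbind, scores)
  rownames(scores) <- NULL
  failed <- qc$plate_id[!qc$passed]
  excluded <- unique(plates$compound_id[plates$role == "compound" &
                                          plates$plate_id %in% failed])
  list(scores = scores, qc = qc, excluded = excluded)
}

#' Call binding hits from screen scores
#'
#' @param scores Score table from [score_fp_screen()].
#' @param z_star_threshold Strict lower bound on the robust Z score.
#' @return Scores of hit compounds, sorted by decreasing `z_star`.
#' @export
call_binding_hits <- function(scores, z_star_threshold = 3) {
  hits <- scores[scores$z_star > z_star_threshold, , drop = FALSE]
  hits <- hits[order(-hits$z_star), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}
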
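#' Relative expression by the delta-delta-Ct method
#'
#' Fold change of a target gene (treated / control) after normalization
#' to a reference gene measured in the same samples:
#' \eqn{fold = 2^{-[(Ct^{tgt}_{trt} - Ct^{ref}_{trt}) - (Ct^{tgt}_{ctl} -
#' Ct^{ref}_{ctl})]}}. Any global Ct offset (machine drift) cancels.
#' Measurements with a missing Ct or any Ct above `max_ct` are marked
#' invalid and excluded from downstream denominators.
#'
#' @param ct data.frame with columns `gene`, `ct_target_treated`,
#'   `ct_target_control`, `ct_ref_treated`, `ct_ref_control` (cycles).
#' @param max_ct Validity ceiling in cycles (default 40).
#' @return The input with `fold` and `valid` columns added (`fold` is
#'   `NA` for invalid rows).
#' @export
delta_delta_ct <- function(ct, max_ct = 40) {
  need <- c("gene", "ct_target_treated", "ct_target_control",
            "ct_ref_treated", "ct_ref_control")
  miss <- setdiff(need, names(ct))
  if (length(miss))
    stop("Ct table is missing column(s): ", paste(miss, collapse = ", "))
  cts <- as.matrix(ct[, need[-1]])
  valid <- apply(cts, 1, function(r) all(is.finite(r)) && all(r > 0) &&
                   all(r <= max_ct))
  ddct <- (ct$ct_target_treated - ct$ct_ref_treated) -
    (ct$ct_target_control - ct$ct_ref_control)
  ct$fold <- ifelse(valid, 2^(-ddct), NA_real_)
  ct$valid <- valid
  ct
}

#' Classify gene modulation from fold change
#'
#' A gene is modulated when its fold change deviates from 1 by strictly
#' more than `threshold` on the linear fold scale (default 0.5, i.e. a
#' >50% variation versus untreated; fold 0.4 and fold 1.6 both qualify,
#' fold 1.5 does not). Direction is read off the fold: `down` below 1,
#' `up` above.
#'
#' @param fold Positive fold changes (`NA` allowed: classified
#'   `invalid`).
#' @param threshold Strict deviation threshold (default 0.5).
#' @return Character vector: `"up"`, `"down"`, `"unmodulated"`,
#'   `"invalid"`.
#' @export
classify_modulation <- function(fold, threshold = 0.5) {
  if (any(fold[!is.na(fold)] <= 0)) stop("fold changes must be positive")
  ifelse(is.na(fold), "invalid",
         ifelse(abs(fold - 1) > threshold,
                ifelse(fold < 1, "down", "up"),
                "unmodulated"))
}

#' Panel-level modulation summary
#'
#' The pie-chart numbers for a gene panel: the percentage of valid genes
#' modulated, and of those, the percentage reduced (down-modulated).
#'
#' @param modulation Classification vector from [classify_modulation()].
#' @return List with `n_genes`, `n_valid`, `n_modulated`,
#'   `pct_modulated` (of valid genes) and `pct_reduced_of_modulated`
#'   (`NA` when no gene is modulated).
#' @export
panel_summary <- function(modulation) {
  n_valid <- sum(modulation != "invalid")
  if (n_valid == 0) stop("no valid genes in panel")
  n_mod <- sum(modulation %in% c("up", "down"))
  n_down <- sum(modulation == "down")
  list(n_genes = length(modulation), n_valid = n_valid,
       n_modulated = n_mod,
       pct_modulated = 100 * n_mod / n_valid,
       pct_reduced_of_modulated = if (n_mod == 0) NA_real_
       else 100 * n_down / n_mod)
}

#' Full qPCR panel analysis
#'
#' Convenience wrapper: delta-delta-Ct fold changes, modulation
#' classification and the panel summary in one call.
#'
#' @inheritParams delta_delta_ct
#' @inheritParams classify_modulation
#' @return List with `genes` (per-gene table incl. `fold`, `modulation`)
#'   and `summary` (see [panel_summary()]).
#' @export
analyze_gene_panel <- function(ct, threshold = 0.5, max_ct = 40) {
  genes <- delta_delta_ct(ct, max_ct = max_ct)
  genes$modulation <- classify_modulation(genes$fold, threshold = threshold)
  list(genes = genes, summary = panel_summary(genes$modulation))
}
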
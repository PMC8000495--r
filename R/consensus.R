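#' Score one in-cell validation dataset against its vehicle wells
#'
#' Each compound's mean readout is standardized against the vehicle
#' distribution with a robust Z: \eqn{(\bar{x}_{cpd} -
#' median_{veh}) / (1.4826\, MAD_{veh})}. A compound is a hit when its
#' effect is at or below the (negative) threshold — one-sided, because
#' every assay in the cascade (receptor level, proliferation, reporter
#' transcription) reads an active compound as a reduction.
#'
#' @param dataset Tidy data.frame for one dataset: columns `compound_id`
#'   (`"VEHICLE"` marks vehicle wells), `replicate`, `readout`.
#' @param threshold Hit threshold on the robust effect size (default -3);
#'   hits satisfy `effect_size <= threshold`.
#' @return data.frame with `compound_id`, `effect_size`, `is_hit`.
#' @export
score_incell_assay <- function(dataset, threshold = -3) {
  veh <- dataset$readout[dataset$compound_id == "VEHICLE"]
  if (length(veh) < 3) stop("dataset needs at least 3 vehicle replicates")
  s <- stats::mad(veh)
  if (s == 0) stop("vehicle MAD is zero: effect size undefined")
  ctr <- stats::median(veh)
  cpd <- dataset[dataset$compound_id != "VEHICLE", , drop = FALSE]
  means <- tapply(cpd$readout, cpd$compound_id, mean)
  eff <- (as.numeric(means) - ctr) / s
  data.frame(compound_id = names(means), effect_size = eff,
             is_hit = eff <= threshold, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Build the compounds-by-datasets hit matrix for one cell line
#'
#' Scores each of the six (assay, timepoint) datasets of a cell line with
#' [score_incell_assay()] and assembles the boolean hit matrix feeding
#' the consensus vote.
#'
#' @param assay_data Tidy data.frame with columns `cell_line`, `assay`,
#'   `timepoint_days`, `compound_id`, `replicate`, `readout`.
#' @param cell_line Cell line to extract.
#' @param threshold Passed to [score_incell_assay()].
#' @return Logical matrix, compounds x datasets (labelled
#'   `<assay>_d<timepoint>`).
#' @export
build_hit_matrix <- function(assay_data, cell_line, threshold = -3) {
  d <- assay_data[assay_data$cell_line == cell_line, , drop = FALSE]
  if (nrow(d) == 0) stop("no data for cell line ", cell_line)
  specs <- incell_dataset_specs()
  cols <- lapply(seq_len(nrow(specs)), function(k) {
    ds <- d[d$assay == specs$assay[k] &
              d$timepoint_days == specs$timepoint_days[k], , drop = FALSE]
    if (nrow(ds) == 0)
      stop("missing dataset ", specs$label[k], " for cell line ", cell_line)
    sc <- score_incell_assay(ds, threshold)
    stats::setNames(sc$is_hit, sc$compound_id)
  })
  ids <- sort(unique(unlist(lapply(cols, names))))
  m <- vapply(cols, function(v) v[ids], logical(length(ids)))
  dimnames(m) <- list(ids, specs$label)
  m
}

#' Consensus vote over the per-dataset hit matrix
#'
#' A compound passes when it is a hit in at least `k` of the `n` datasets
#' of a cell line (default: at least 4 of 6). Monotone by construction:
#' adding a hit never clears a consensus flag.
#'
#' @param hit_matrix Logical compounds x datasets matrix, no missing
#'   entries.
#' @param k Minimum number of supporting datasets (default 4).
#' @return Named logical vector of consensus flags.
#' @export
consensus_call <- function(hit_matrix, k = 4) {
  if (anyNA(hit_matrix))
    stop("hit matrix has missing entries; every dataset must be scored")
  rowSums(hit_matrix) >= k
}

#' Intersect consensus sets across cell lines
#'
#' @param consensus_a,consensus_b Character vectors of consensus compound
#'   ids from two cell lines.
#' @param labels Names for the two lines (for the output list).
#' @return List with `shared`, `<a>_only`, `<b>_only`.
#' @export
intersect_lines <- function(consensus_a, consensus_b,
                            labels = c("a", "b")) {
  out <- list(shared = sort(intersect(consensus_a, consensus_b)),
              sort(setdiff(consensus_a, consensus_b)),
              sort(setdiff(consensus_b, consensus_a)))
  names(out)[2:3] <- paste0(labels, "_only")
  out
}
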
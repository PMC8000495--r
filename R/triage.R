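#' Staged annotation triage of primary hits
#'
#' Applies the hit-list depuration stages in order: (1) remove anti-cancer
#' drugs, (2) remove drugs already used for endocrine-system indications,
#' (3) remove manually flagged compounds (xenoestrogens, progestins,
#' hormones). A compound matching several flags is removed at — and
#' attributed to — its first matching stage, so every input hit appears
#' exactly once in the survivors or the removal ledger.
#'
#' @param hits Character vector of hit compound ids (or a data.frame with
#'   a `compound_id` column).
#' @param annotations Annotation table with columns `compound_id`,
#'   `is_anticancer`, `is_endocrine_indication`,
#'   `manual_exclusion_class` (`"none"` when not manually excluded).
#' @return List of class `triage_result`: `stages` (named list of
#'   surviving id vectors: `input`, `after_anticancer`, `after_endocrine`,
#'   `final`), `ledger` (data.frame `compound_id`, `stage`), and `counts`.
#' @export
filter_hits <- function(hits, annotations) {
  if (is.data.frame(hits)) hits <- hits$compound_id
  hits <- as.character(hits)
  if (anyDuplicated(hits)) stop("duplicate compound ids in hit list")
  missing <- setdiff(hits, annotations$compound_id)
  if (length(missing))
    stop("hits without an annotation record: ",
         paste(missing, collapse = ", "))
  ann <- annotations[match(hits, annotations$compound_id), , drop = FALSE]

  stage_flags <- list(
    anticancer = ann$is_anticancer,
    endocrine = ann$is_endocrine_indication,
    manual = ann$manual_exclusion_class != "none")

  surviving <- hits
  stages <- list(input = hits)
  ledger <- data.frame(compound_id = character(), stage = character(),
                       stringsAsFactors = FALSE)
  for (st in names(stage_flags)) {
    flagged <- hits[stage_flags[[st]]]
    removed <- intersect(surviving, flagged)
    if (length(removed))
      ledger <- rbind(ledger, data.frame(compound_id = removed, stage = st,
                                         stringsAsFactors = FALSE))
    surviving <- setdiff(surviving, flagged)
    stages[[paste0("after_", st)]] <- surviving
  }
  names(stages)[names(stages) == "after_manual"] <- "final"
  structure(list(stages = stages, ledger = ledger,
                 counts = vapply(stages, length, integer(1))),
            class = "triage_result")
}

#' @export
print.triage_result <- function(x, ...) {
  cat("Hit triage funnel:",
      paste(sprintf("%s = %d", names(x$counts), x$counts), collapse = " -> "),
      "\n")
  invisible(x)
}

#' Set-overlap (Venn) summary of the triage flags
#'
#' Counts the eight regions of the three flag sets (anti-cancer,
#' endocrine indication, manual exclusion) restricted to the input hit
#' list. The exclusive regions partition the hits, so their sum equals
#' the number of hits (inclusion-exclusion holds by construction).
#'
#' @param hits Hit compound ids (vector or data.frame).
#' @param annotations Annotation table (see [filter_hits()]).
#' @return List with `region_counts` (named by membership pattern such as
#'   `"anticancer"`, `"anticancer+manual"`, `"none"`), and `set_sizes`.
#' @export
venn_summary <- function(hits, annotations) {
  if (is.data.frame(hits)) hits <- hits$compound_id
  ann <- annotations[match(hits, annotations$compound_id), , drop = FALSE]
  if (anyNA(ann$compound_id))
    stop("hits without an annotation record")
  m <- cbind(anticancer = ann$is_anticancer,
             endocrine = ann$is_endocrine_indication,
             manual = ann$manual_exclusion_class != "none")
  pattern <- apply(m, 1, function(r) {
    on <- colnames(m)[r]
    if (length(on) == 0) "none" else paste(on, collapse = "+")
  })
  list(region_counts = table(factor(pattern)),
       set_sizes = colSums(m),
       n_hits = length(hits))
}
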
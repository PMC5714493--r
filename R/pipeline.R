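#' Compare discovered junctions with a simulation truth table
#'
#' Left-joins the truth table to the call set on (seq_id, start, end,
#' strand) and reports, per planted intron, whether it was recovered and
#' with which donor class.
#'
#' @param calls data.frame from [discover_junctions()]; flagged
#'   (`pass_filter = FALSE`) calls are ignored.
#' @param truth Truth table from [emit_genome()].
#' @return List with `table` (truth plus `recovered`, `called_donor`,
#'   `class_match`, `support`), `n_truth`, `n_recovered`,
#'   `n_class_match`, `n_spurious` (passing calls not in the truth set).
#' @export
compare_to_truth <- function(calls, truth) {
  if ("pass_filter" %in% names(calls)) {
    calls <- calls[calls$pass_filter, , drop = FALSE]
  }
  key <- function(d) paste(d$seq_id, d$start, d$end, d$strand, sep = "\r")
  idx <- match(key(truth), key(calls))
  tab <- truth
  tab$recovered <- !is.na(idx)
  tab$called_donor <- ifelse(tab$recovered, calls$donor[idx], NA_character_)
  tab$support <- ifelse(tab$recovered, calls$support[idx], 0L)
  tab$class_match <- !is.na(tab$called_donor) &
    tab$called_donor == tab$donor_class
  list(table = tab,
       n_truth = nrow(truth),
       n_recovered = sum(tab$recovered),
       n_class_match = sum(tab$class_match),
       n_spurious = sum(!key(calls) %in% key(truth)))
}

#' Run the simulate-discover-classify pipeline
#'
#' Simulates a dataset (unless one is supplied), discovers junctions under
#' the requested donor-acceptance mode, classifies the recovered introns,
#' tabulates donor classes per gene, and scores recovery against the
#' planted truth.
#'
#' @param config A [sim_config()] (used when `dataset` is `NULL`).
#' @param mode Donor-acceptance mode for discovery (see
#'   [donor_mode_set()]).
#' @param dataset Optional pre-simulated dataset from
#'   [simulate_dataset()].
#' @param k,min_anchor,min_support,mismatch_budget Discovery parameters,
#'   see [discover_junctions()].
#' @return List with `dataset`, `calls`, `classified`, `summary` (a
#'   `donor_summary`), and `recovery` (from [compare_to_truth()]).
#' @export
splice_pipeline <- function(config = sim_config(), mode = "g",
                            dataset = NULL, k = 16L, min_anchor = 8L,
                            min_support = 2L, mismatch_budget = 0L) {
  if (is.null(dataset)) dataset <- simulate_dataset(config)
  calls <- discover_junctions(dataset$reads, dataset$genome, mode = mode,
                              k = k, min_anchor = min_anchor,
                              min_support = min_support,
                              mismatch_budget = mismatch_budget)
  classified <- classify_junctions(calls, dataset$genome, dataset$models)
  summary <- tabulate_donors(classified)
  recovery <- compare_to_truth(calls, dataset$truth)
  list(dataset = dataset, calls = calls, classified = classified,
       summary = summary, recovery = recovery)
}
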
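## Benchmarks for correct-fold detection: how close the selected decoy is to
## the native compared with the rest of its set (Criterion-1) and how often
## a method beats the energy-only baseline (Criterion-2).

#' Distances of every decoy to the native structure
#'
#' Evaluation-only helper (not charged to any selection budget).
#'
#' @param set a [decoy_set] with a native structure.
#' @param metric `"ca_rmsd"` or `"gdt_ts_distance"`.
#' @return named numeric vector keyed by decoy id.
#' @export
native_distances <- function(set, metric = c("ca_rmsd", "gdt_ts_distance")) {
  metric <- match.arg(metric)
  if (is.null(set$native)) stop("decoy set '", set$id, "' has no native")
  fn <- if (metric == "ca_rmsd") ca_rmsd else gdt_ts_distance
  vapply(set$structures, fn, numeric(1), y = set$native)
}

#' Build an evaluation record for one set and one selection
#'
#' @param set a [decoy_set] with native.
#' @param selected_id id of the decoy a method selected.
#' @param baseline_id optional id of the baseline (energy-only) selection.
#' @param metric distance metric.
#' @param nat_d optional precomputed [native_distances()] for `set`.
#' @return one-row data.frame: `set_id`, `selected_id`, `dist_to_native`,
#'   `baseline_id`, `baseline_dist`.
#' @export
eval_record <- function(set, selected_id, baseline_id = NA_character_,
                        metric = "ca_rmsd", nat_d = NULL) {
  if (is.null(nat_d)) nat_d <- native_distances(set, metric)
  stopifnot(selected_id %in% names(nat_d))
  data.frame(set_id = set$id,
             selected_id = selected_id,
             dist_to_native = unname(nat_d[[selected_id]]),
             baseline_id = baseline_id,
             baseline_dist = if (is.na(baseline_id)) NA_real_
                             else unname(nat_d[[baseline_id]]),
             stringsAsFactors = FALSE)
}

#' Criterion-1: mean percentage of decoys outperformed
#'
#' For each decoy set, the percentage of decoys whose distance to the native
#' is strictly greater than the selected decoy's, out of the full set size
#' (the selected decoy does not outperform itself and ties count for
#' neither side); the per-set percentages are averaged over all sets.
#' Measures how close to the native the selection is relative to the rest
#' of its set; 100 means the selection is uniquely closest in every set.
#'
#' @param records data.frame of [eval_record()] rows.
#' @param sets list of the corresponding [decoy_set]s (matched by `id`).
#' @param metric distance metric.
#' @param nat_d optional named list of precomputed [native_distances()]
#'   keyed by set id (avoids recomputation across runs).
#' @return percentage in `[0, 100]`.
#' @export
criterion1 <- function(records, sets, metric = "ca_rmsd", nat_d = NULL) {
  set_ids <- vapply(sets, `[[`, "", "id")
  per_set <- vapply(seq_len(nrow(records)), function(i) {
    sid <- records$set_id[i]
    k <- match(sid, set_ids)
    if (is.na(k)) stop("no decoy set with id '", sid, "'")
    d <- if (!is.null(nat_d)) nat_d[[sid]]
         else native_distances(sets[[k]], metric)
    100 * sum(d > records$dist_to_native[i]) / length(d)
  }, numeric(1))
  mean(per_set)
}

#' Criterion-2: sets where a method beats the energy-only baseline
#'
#' The number of decoy sets in which the method's selected decoy is strictly
#' closer to the native than the baseline's.  For stochastic methods this
#' count is typically averaged over repeated runs; see [criterion2_runs()].
#'
#' @param records data.frame of [eval_record()] rows with `baseline_dist`
#'   present.
#' @return integer count in `[0, nrow(records)]`.
#' @export
criterion2 <- function(records) {
  if (anyNA(records$baseline_dist))
    stop("baseline distance missing for set(s): ",
         paste(records$set_id[is.na(records$baseline_dist)], collapse = ", "))
  sum(records$dist_to_native < records$baseline_dist)
}

#' Summarize Criterion-2 counts over repeated runs
#'
#' @param counts numeric vector of per-run [criterion2()] counts.
#' @return list with `mean` and `sd` (sample standard deviation; `NA` for a
#'   single run).
#' @export
criterion2_runs <- function(counts) {
  list(mean = mean(counts),
       sd = if (length(counts) >= 2L) stats::sd(counts) else NA_real_)
}

#' Run-to-run spread of the selected decoy's distance to native
#'
#' Sample standard deviation of the distance-to-native values a stochastic
#' selector produced over repeated runs on one decoy set.
#'
#' @param dists numeric vector of per-run distances (length >= 2).
#' @return standard deviation, in the metric's units.
#' @export
run_std <- function(dists) {
  if (length(dists) < 2L) stop("need at least 2 runs")
  stats::sd(dists)
}
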
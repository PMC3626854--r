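## Full selection pipeline: pivots -> hash functions -> T randomized trees
## -> per-tree candidates -> consensus decoy, plus the pivot-based
## "consensus" pseudo-energy used when no energy table is available.

#' Parameters of a selection run
#'
#' Defaults are the recommended operating point: `P = 40` pivots, `T = 30`
#' trees, `S = 30` clusters ranked per tree, `E = 10` lowest-energy
#' reference decoys, and height bound `h_max = P / 2` so that different
#' trees draw partially different hash-function subsets.
#'
#' @param P number of pivots.
#' @param T number of trees.
#' @param S number of largest cluster nodes ranked per tree.
#' @param E number of lowest-energy reference decoys.
#' @param h_max tree height bound; defaults to `P / 2` and must not exceed
#'   `P`.
#' @param seed integer seed governing every random draw of the run.
#' @param metric distance metric, `"ca_rmsd"` (Angstroms) or
#'   `"gdt_ts_distance"`.
#' @param energy_source `"table"` to use supplied decoy energies (falling
#'   back automatically when none are present), `"consensus"` to force the
#'   pivot-based pseudo-energy.
#' @return a list of class `hs_forest_params`.
#' @export
hs_forest_params <- function(P = 40L, T = 30L, S = 30L, E = 10L,
                             h_max = max(1L, floor(P / 2)), seed = 1L,
                             metric = c("ca_rmsd", "gdt_ts_distance"),
                             energy_source = c("table", "consensus")) {
  metric <- match.arg(metric)
  energy_source <- match.arg(energy_source)
  stopifnot(P >= 1, T >= 1, S >= 1, E >= 1, h_max >= 1)
  if (h_max > P) stop("h_max must not exceed the number of pivots P")
  structure(list(P = as.integer(P), T = as.integer(T), S = as.integer(S),
                 E = as.integer(E), h_max = as.integer(h_max),
                 seed = as.integer(seed), metric = metric,
                 energy_source = energy_source),
            class = "hs_forest_params")
}

#' Pivot-based consensus pseudo-energy
#'
#' Ranks decoys by their total distance to the pivot structures (lower is
#' better).  The column sums of the pivot distance matrix provide this for
#' free, so no extra distance evaluation is charged.
#'
#' @param set a [decoy_set].
#' @param pivots a [pivot_index] over `set`.
#' @return named numeric vector of pseudo-energies keyed by decoy id.
#' @export
consensus_energy <- function(set, pivots) {
  stats::setNames(pivots$column_sums, decoy_ids(set))
}

#' Consensus over tree candidates
#'
#' Returns the candidate with the smallest total distance to all candidate
#' occurrences (multiplicity counted; occurrences of a candidate contribute
#' 0 to its own total).  Ties go to the lowest decoy index.  Charges at most
#' `choose(U, 2)` evaluations for `U` distinct candidates.
#'
#' @param candidates integer vector of decoy indices, one per tree, with
#'   multiplicity.
#' @param tracker the run's [distance_tracker].
#' @return decoy index.
#' @export
consensus_select <- function(candidates, tracker) {
  stopifnot(length(candidates) >= 1L)
  uniq <- sort(unique(candidates))
  mult <- vapply(uniq, function(u) sum(candidates == u), integer(1))
  totals <- vapply(seq_along(uniq), function(i)
    sum(vapply(seq_along(uniq), function(j)
      if (i == j) 0 else mult[j] * tracker$eval(uniq[i], uniq[j]),
      numeric(1))),
    numeric(1))
  uniq[order(totals, uniq)][1L]
}

## indices of the E lowest-energy decoys (ascending energy, ties by index)
low_energy_indices <- function(energy, E) {
  ok <- which(!is.na(energy))
  ok[order(energy[ok], ok)][seq_len(min(E, length(ok)))]
}

#' Run the full selection pipeline
#'
#' Selects `P` pivots, builds their hashing functions once, grows `T`
#' randomized hash trees, extracts each tree's candidate decoy, and returns
#' the consensus candidate.  Deterministic given the inputs and
#' `params$seed`.  The unique-pair distance-evaluation count is tracked and
#' always bounded by `P*N + T*S*E + choose(T, 2)`; no pairwise distance
#' matrix is ever materialized.
#'
#' @param set a [decoy_set] of at least 2 decoys.
#' @param params an [hs_forest_params()] list.
#' @param energies optional named numeric vector of decoy energies keyed by
#'   id (overrides energies stored in `set`).  When no energies are
#'   available, or `params$energy_source == "consensus"`, the pivot-based
#'   [consensus_energy()] is used instead.
#' @return object of class `hs_selection`: `consensus_id`/`consensus_index`,
#'   `candidate_ids`/`candidate_indices` (one per tree), `tree_summaries`
#'   (cluster count and sizes per tree), `eval_count`, `eval_budget`,
#'   `energy_source_used`, and the `params` echo.
#' @export
run_hs_forest <- function(set, params = hs_forest_params(), energies = NULL) {
  stopifnot(inherits(set, "decoy_set"), inherits(params, "hs_forest_params"))
  n <- length(set$structures)
  if (n < 2L) stop("need at least 2 decoys")
  if (params$P > n) stop("P = ", params$P, " exceeds decoy count N = ", n)
  ids <- decoy_ids(set)
  with_seed(params$seed, {
    tracker <- distance_tracker(set, params$metric)
    pivots <- select_pivots(set, params$P, tracker)
    hash_pool <- lapply(seq_len(params$P), build_hash_function,
                        pivots = pivots)
    en <- energies
    if (is.null(en)) en <- decoy_energies(set)
    en <- en[match(ids, names(en))]
    use_consensus <- params$energy_source == "consensus" || all(is.na(en))
    if (use_consensus) en <- consensus_energy(set, pivots)
    low_e <- low_energy_indices(unname(en), params$E)

    cands <- integer(params$T)
    summaries <- vector("list", params$T)
    for (t in seq_len(params$T)) {
      tree <- build_tree(set, pivots, hash_pool, h_max = params$h_max)
      cands[t] <- tree_candidate(tree, pivots, low_e, tracker, params$S)
      sizes <- vapply(tree$cluster_nodes, function(x) length(x$members),
                      integer(1))
      summaries[[t]] <- list(cluster_count = length(sizes),
                             cluster_sizes = sizes,
                             height = tree$height,
                             candidate = ids[[cands[t]]])
    }
    consensus <- consensus_select(cands, tracker)
    budget <- params$P * n + params$T * params$S * params$E +
      choose(params$T, 2)
    structure(list(
      consensus_id = ids[[consensus]],
      consensus_index = consensus,
      candidate_ids = ids[cands],
      candidate_indices = cands,
      tree_summaries = summaries,
      low_energy_ids = ids[low_e],
      energy_source_used = if (use_consensus) "consensus" else "table",
      eval_count = tracker$count(),
      eval_budget = budget,
      params = unclass(params)),
      class = "hs_selection")
  })
}

#' @export
print.hs_selection <- function(x, ...) {
  p <- x$params
  cat("HS-Forest selection\n")
  cat("  selected decoy : ", x$consensus_id, "\n", sep = "")
  cat("  parameters     : P=", p$P, " T=", p$T, " S=", p$S, " E=", p$E,
      " h_max=", p$h_max, " metric=", p$metric, " seed=", p$seed, "\n",
      sep = "")
  cat("  energy source  : ", x$energy_source_used, "\n", sep = "")
  tab <- table(x$candidate_ids)
  cat("  tree votes     : ",
      paste0(names(tab), " x", as.integer(tab), collapse = ", "), "\n",
      sep = "")
  ccounts <- vapply(x$tree_summaries, `[[`, integer(1), "cluster_count")
  cat("  cluster nodes  : ", min(ccounts), "-", max(ccounts),
      " per tree\n", sep = "")
  cat("  distance evals : ", x$eval_count, " (budget ", x$eval_budget,
      ")\n", sep = "")
  invisible(x)
}
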
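## Pivot selection and median-split hashing functions.  Each randomly chosen
## pivot decoy induces one locality-sensitive hash: decoys fall in bin 0 or
## bin 1 according to whether their distance to the pivot is below the
## pivot's median distance over the whole set.  Similar decoys have similar
## distances to any third structure, so they tend to co-hash.

#' Select pivots and compute the pivot distance matrix
#'
#' Samples `P` distinct decoys uniformly without replacement and evaluates
#' the distance from every pivot to every decoy with the tracker's metric.
#' Self-distances are 0 by definition and symmetric pivot-pivot pairs are
#' memoized, so at most `P*N` unique evaluations are charged.
#'
#' @param set a [decoy_set] of `N` decoys.
#' @param P number of pivots, `1 <= P <= N`.
#' @param tracker a [distance_tracker] bound to `set`.
#' @return object of class `pivot_index`: `pivot_ids` (decoy indices),
#'   `dist_matrix` (`P x N`), and `column_sums` (total distance of each
#'   decoy to all pivots; the free "consensus" pseudo-energy).
#' @export
select_pivots <- function(set, P, tracker) {
  n <- length(set$structures)
  if (P < 1L || P > n) stop("P must be between 1 and N = ", n)
  ids <- sample.int(n, P)
  m <- matrix(0, nrow = P, ncol = n)
  for (r in seq_len(P)) {
    p <- ids[[r]]
    for (j in seq_len(n)) if (j != p) m[r, j] <- tracker$eval(p, j)
  }
  structure(list(pivot_ids = ids, dist_matrix = m,
                 column_sums = colSums(m)),
            class = "pivot_index")
}

#' Build one median-split hashing function
#'
#' The threshold is the lower-upper median of the pivot's distance row: the
#' order statistic at 0-based index `floor(N/2)` of the sorted distances.
#' With the strict `<` split this divides distinct distances into bins of
#' `floor(N/2)` and `ceiling(N/2)`.
#'
#' @param pivots a [pivot_index].
#' @param row which pivot row (1..P).
#' @return object of class `hash_function` with `pivot_row` and `threshold`.
#' @export
build_hash_function <- function(pivots, row) {
  d <- pivots$dist_matrix[row, ]
  n <- length(d)
  thr <- sort(d)[floor(n / 2) + 1L]
  structure(list(pivot_row = row, threshold = thr), class = "hash_function")
}

#' Assign members to the two bins of a hashing function
#'
#' Bin 0 holds members whose distance to the pivot is strictly below the
#' threshold; bin 1 holds the rest (ties go to bin 1).  Input order is
#' preserved within each bin.  An all-tied row yields an empty bin 0, which
#' tree construction treats as an unsplittable node.
#'
#' @param h a [build_hash_function()] result.
#' @param pivots the [pivot_index] the function was built from.
#' @param members integer vector of decoy indices.
#' @return list with `bin0` and `bin1` index vectors (disjoint cover of
#'   `members`).
#' @export
hash_assign <- function(h, pivots, members) {
  stopifnot(length(members) > 0L)
  d <- pivots$dist_matrix[h$pivot_row, members]
  low <- d < h$threshold
  list(bin0 = members[low], bin1 = members[!low])
}
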
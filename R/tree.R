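## One randomized hash tree ("HS-Tree": Height and Size).  Each level splits
## the surviving nodes with one randomly chosen hashing function; descent
## stops at "cluster nodes" whose height/size balance marks a dense region.

#' Cluster-node test
#'
#' A node of height `h` and size `z` in a tree over `Z` decoys with height
#' bound `h_max` is a cluster node when `h / h_max >= log(z) / log(Z)`:
#' node size decays roughly exponentially with depth, so the log-scaled size
#' ratio is comparable to the height ratio, and a node satisfying the
#' inequality is at least as deep (dense) as its size warrants.  During
#' construction the maximal height `h_max` stands in for the realized tree
#' height, which lets the tree stop splitting at the first satisfying node
#' and build only a fraction of its nodes.
#'
#' @param h node height (splits from the root; root is 0).
#' @param z node size (number of member decoys), `1 <= z <= Z`.
#' @param h_max height bound (`>= 1`).
#' @param Z decoy-set size (`>= 2`).
#' @return logical.
#' @examples
#' is_cluster_node(0, 1000, 20, 1000)  # root: FALSE
#' is_cluster_node(10, 30, 20, 1000)   # 0.5 >= 0.492: TRUE
#' @export
is_cluster_node <- function(h, z, h_max, Z) {
  if (Z < 2) stop("decoy-set size Z must be >= 2")
  stopifnot(h_max >= 1, h >= 0, z >= 1, z <= Z)
  h / h_max >= log(z) / log(Z)
}

#' Build one HS-Tree
#'
#' Splits the decoy set level by level, each level using one hashing
#' function sampled without replacement from `hash_pool`.  A node becomes a
#' leaf when (a) it satisfies [is_cluster_node()] (flagged as a cluster
#' node), (b) it reaches the height bound, (c) it is a singleton, or (d) its
#' split is degenerate (all members tie on one side of the threshold).
#' Only nodes on not-yet-stopped paths are ever constructed.
#'
#' With `exact_height = TRUE` the tree is instead built to full depth
#' (stopping only at singletons/degenerate splits, using up to
#' `length(hash_pool)` levels), and cluster nodes are then determined with
#' the realized tree height in place of the bound -- the setting in which at
#' least one cluster node is guaranteed to exist whenever the realized
#' height is at least 1.
#'
#' @param set a [decoy_set].
#' @param pivots a [pivot_index] over `set`.
#' @param hash_pool list of `P` [build_hash_function()] results.
#' @param h_max height bound, `1 <= h_max <= length(hash_pool)`; ignored
#'   when `exact_height = TRUE`.
#' @param exact_height build the full tree and use its realized height in
#'   the cluster-node rule (analysis mode).
#' @return object of class `hs_tree`: `root` (nested nodes with `members`,
#'   `h`, `is_cluster`, `children`), `cluster_nodes` (list of
#'   `list(members, h)` in depth-first, bin0-first discovery order),
#'   `height` (maximal leaf height reached), `h_max`, `level_rows` (pivot
#'   rows used per level).
#' @export
build_tree <- function(set, pivots, hash_pool, h_max = NULL,
                       exact_height = FALSE) {
  Z <- length(set$structures)
  if (Z < 2L) stop("need at least 2 decoys")
  P <- length(hash_pool)
  if (exact_height) {
    levels <- sample.int(P, P)
  } else {
    if (is.null(h_max)) stop("h_max required unless exact_height = TRUE")
    if (h_max < 1L || h_max > P)
      stop("h_max must be between 1 and the hash-pool size ", P)
    levels <- sample.int(P, h_max)
  }
  level_fns <- hash_pool[levels]
  nlev <- length(level_fns)
  acc <- new.env(parent = emptyenv())
  acc$clusters <- list()
  acc$height <- 0L

  grow <- function(members, h) {
    z <- length(members)
    if (h > acc$height) acc$height <- h
    node <- list(members = members, h = h, is_cluster = FALSE,
                 children = NULL)
    if (!exact_height && is_cluster_node(h, z, nlev, Z)) {
      node$is_cluster <- TRUE
      acc$clusters[[length(acc$clusters) + 1L]] <-
        list(members = members, h = h)
      return(node)
    }
    if (h == nlev || z == 1L) return(node)
    bins <- hash_assign(level_fns[[h + 1L]], pivots, members)
    if (length(bins$bin0) == 0L || length(bins$bin1) == 0L) return(node)
    node$children <- list(grow(bins$bin0, h + 1L),
                          grow(bins$bin1, h + 1L))
    node
  }
  root <- grow(seq_len(Z), 0L)

  if (exact_height) {
    H <- acc$height
    if (H >= 1L) {
      mark <- function(node) {
        if (is_cluster_node(node$h, length(node$members), H, Z)) {
          node$is_cluster <- TRUE
          node$children <- NULL  # descent conceptually stops here
          acc$clusters[[length(acc$clusters) + 1L]] <-
            list(members = node$members, h = node$h)
        } else if (!is.null(node$children)) {
          node$children <- lapply(node$children, mark)
        }
        node
      }
      root <- mark(root)
    }
  }

  if (length(acc$clusters) == 0L)
    stop_hsf(paste0("tree produced no cluster nodes (height bound ", nlev,
                    "); reduce h_max and re-run"),
             "hsforest_empty_result")
  structure(list(root = root, cluster_nodes = acc$clusters,
                 height = acc$height, h_max = nlev,
                 level_rows = levels),
            class = "hs_tree")
}

#' Cluster representative
#'
#' The member with the smallest total distance to the pivot set, read off
#' the precomputed pivot column sums -- no new distance evaluation.  Ties go
#' to the lowest decoy index.
#'
#' @param node a cluster node (`list(members, h)`).
#' @param pivots the [pivot_index].
#' @return decoy index.
#' @export
select_representative <- function(node, pivots) {
  m <- node$members
  stopifnot(length(m) > 0L)
  m[order(pivots$column_sums[m], m)][1L]
}

#' Candidate decoy of one tree
#'
#' Takes the `S` largest cluster nodes (ties broken by discovery order),
#' extracts each one's representative, and ranks representatives by total
#' distance to the `E` lowest-energy decoys; the smallest total wins (ties
#' to the lowest decoy index).  Charges at most `S * E` distance
#' evaluations.
#'
#' @param tree an [build_tree()] result.
#' @param pivots the [pivot_index].
#' @param low_energy integer indices of the `E` lowest-energy decoys.
#' @param tracker the run's [distance_tracker].
#' @param S number of largest cluster nodes to consider.
#' @return decoy index (the tree's candidate).
#' @export
tree_candidate <- function(tree, pivots, low_energy, tracker, S) {
  cl <- tree$cluster_nodes
  sizes <- vapply(cl, function(x) length(x$members), integer(1))
  keep <- order(-sizes)[seq_len(min(S, length(cl)))]  # stable: ties by discovery
  reps <- vapply(cl[keep], select_representative, integer(1), pivots = pivots)
  reps <- unique(reps)
  totals <- vapply(reps, function(r)
    sum(vapply(low_energy, function(e) tracker$eval(r, e), numeric(1))),
    numeric(1))
  reps[order(totals, reps)][1L]
}
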
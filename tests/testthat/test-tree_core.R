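# walk a tree: cluster nodes disjoint, at most one per root-to-leaf path,
# children partition parents, heights increment
check_tree_invariants <- function(tree, n) {
  seen <- integer(0)
  walk <- function(node, clusters_above) {
    expect_false(clusters_above && node$is_cluster)
    if (node$is_cluster) {
      expect_length(intersect(node$members, seen), 0L)
      seen <<- c(seen, node$members)
      expect_null(node$children)
    }
    if (!is.null(node$children)) {
      expect_length(node$children, 2L)
      kids <- c(node$children[[1]]$members, node$children[[2]]$members)
      expect_setequal(kids, node$members)
      for (ch in node$children) {
        expect_equal(ch$h, node$h + 1L)
        walk(ch, clusters_above || node$is_cluster)
      }
    }
  }
  walk(tree$root, FALSE)
  expect_true(all(seen %in% seq_len(n)))  # partial cover is permitted
  seen
}

test_that("the cluster-node inequality follows the height/size balance", {
  expect_false(is_cluster_node(0, 1000, 20, 1000))  # root never qualifies
  expect_true(is_cluster_node(1, 1, 20, 1000))      # singleton below root
  # log(30)/log(1000) = 0.4924 against h/h_max
  expect_true(is_cluster_node(10, 30, 20, 1000))
  expect_false(is_cluster_node(9, 30, 20, 1000))
  expect_error(is_cluster_node(1, 1, 20, 1), "Z must be >= 2")
})

test_that("two distinct decoys at h_max = 1 split into two singleton clusters", {
  set.seed(6)
  structs <- list(random_structure("a", 6), random_structure("b", 6))
  set <- decoy_set(structs, id = "pair")
  tr <- distance_tracker(set, "ca_rmsd")
  pv <- select_pivots(set, 2, tr)
  pool <- lapply(1:2, function(r) build_hash_function(pv, r))
  tree <- build_tree(set, pv, pool, h_max = 1)
  expect_length(tree$cluster_nodes, 2L)
  expect_true(all(vapply(tree$cluster_nodes,
                         function(x) length(x$members), integer(1)) == 1L))
})

test_that("tree construction is deterministic under a fixed seed", {
  gen <- dominant_cluster_set(seed = 2)
  tr <- distance_tracker(gen$set, "ca_rmsd")
  set.seed(10)
  pv <- select_pivots(gen$set, 8, tr)
  pool <- lapply(1:8, function(r) build_hash_function(pv, r))
  set.seed(33); t1 <- build_tree(gen$set, pv, pool, h_max = 4)
  set.seed(33); t2 <- build_tree(gen$set, pv, pool, h_max = 4)
  expect_identical(t1, t2)
})

test_that("tree invariants hold and identical decoy sets raise EmptyResult", {
  gen <- dominant_cluster_set(seed = 4)
  n <- length(gen$set)
  tr <- distance_tracker(gen$set, "ca_rmsd")
  set.seed(8)
  pv <- select_pivots(gen$set, 10, tr)
  pool <- lapply(1:10, function(r) build_hash_function(pv, r))
  for (s in 1:5) {
    set.seed(s)
    tree <- build_tree(gen$set, pv, pool, h_max = 5)
    check_tree_invariants(tree, n)
  }

  # all-identical decoys: every hash row is constant, the root cannot split,
  # and no cluster node exists
  one <- random_structure("x", 6)
  dup <- decoy_set(lapply(1:4, function(i) {
    s <- one; s$id <- paste0("x", i); s
  }), id = "dups")
  trd <- distance_tracker(dup, "ca_rmsd")
  set.seed(1)
  pvd <- select_pivots(dup, 2, trd)
  poold <- lapply(1:2, function(r) build_hash_function(pvd, r))
  expect_error(build_tree(dup, pvd, poold, h_max = 2),
               class = "hsforest_empty_result")
})

test_that("cluster nodes are pure on well-separated synthetic clusters", {
  gen <- two_cluster_set(sizes = c(120, 80), centers = c(2, 9),
                         sigma = 0.5, seed = 19)
  tr <- distance_tracker(gen$set, "ca_rmsd")
  set.seed(50)
  pv <- select_pivots(gen$set, 10, tr)
  pool <- lapply(1:10, function(r) build_hash_function(pv, r))
  pure_runs <- 0L
  for (s in 1:50) {
    set.seed(s)
    tree <- build_tree(gen$set, pv, pool, h_max = 5)
    pure <- all(vapply(tree$cluster_nodes, function(nd)
      length(unique(gen$labels[nd$members])) == 1L, logical(1)))
    pure_runs <- pure_runs + pure
  }
  expect_gte(pure_runs, 48L)  # >= 95% of 50 seeded runs
})

test_that("exact-height trees always contain a cluster node (fuzz)", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(c(4, 7, 12, 30), 1)
    set <- random_decoy_set(n = n, n_res = 6, seed = 1000 + rep)
    tr <- distance_tracker(set, "ca_rmsd")
    P <- min(n, 8)
    pv <- select_pivots(set, P, tr)
    pool <- lapply(seq_len(P), function(r) build_hash_function(pv, r))
    tree <- build_tree(set, pv, pool, exact_height = TRUE)
    expect_gte(tree$height, 1L)
    expect_gte(length(tree$cluster_nodes), 1L)
    check_tree_invariants(tree, n)
  }
})

test_that("representatives minimize total distance to the pivots", {
  fake <- structure(
    list(pivot_ids = 1L, dist_matrix = matrix(0, 1, 3),
         column_sums = c(7.1, 5.0, 9.2)), class = "pivot_index")
  expect_equal(select_representative(list(members = 1:3, h = 1), fake), 2L)
  expect_equal(select_representative(list(members = 2L, h = 1), fake), 2L)
  tie <- structure(
    list(pivot_ids = 1L, dist_matrix = matrix(0, 1, 3),
         column_sums = c(5.0, 5.0, 9.2)), class = "pivot_index")
  expect_equal(select_representative(list(members = c(2L, 1L), h = 1), tie),
               1L)
})

test_that("tree candidates are ranked by distance to low-energy decoys", {
  gen <- dominant_cluster_set(seed = 9)
  set <- gen$set
  tr <- distance_tracker(set, "ca_rmsd")
  set.seed(12)
  pv <- select_pivots(set, 10, tr)
  pool <- lapply(1:10, function(r) build_hash_function(pv, r))
  set.seed(13)
  tree <- build_tree(set, pv, pool, h_max = 5)
  en <- decoy_energies(set)
  low_e <- order(en, seq_along(en))[1:3]

  # independent recomputation of the winner
  sizes <- vapply(tree$cluster_nodes, function(x) length(x$members),
                  integer(1))
  keep <- order(-sizes)[seq_len(min(5, length(sizes)))]
  reps <- unique(vapply(tree$cluster_nodes[keep], select_representative,
                        integer(1), pivots = pv))
  totals <- vapply(reps, function(r) sum(vapply(low_e, function(e)
    if (r == e) 0 else ca_rmsd(set$structures[[r]], set$structures[[e]]),
    numeric(1))), numeric(1))
  expected <- reps[order(totals, reps)][1]

  got <- tree_candidate(tree, pv, low_e, tr, S = 5)
  expect_identical(got, expected)

  # a single cluster node wins regardless of S and E
  single <- tree
  single$cluster_nodes <- tree$cluster_nodes[1]
  expect_identical(tree_candidate(single, pv, low_e, tr, S = 30),
                   select_representative(tree$cluster_nodes[[1]], pv))
})
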
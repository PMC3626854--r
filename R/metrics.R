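## Pairwise structure distances: C-alpha RMSD under optimal rigid
## superposition (Kabsch) and a GDT-TS based distance, plus the evaluation
## tracker that the selection pipeline uses to enforce its distance budget.

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Finds the proper rotation `R` and translation `t` minimizing
#' `sqrt(mean(rowSums((A %*% t(R) + t - B)^2)))`, i.e. the RMSD of `A` onto
#' `B` over all rigid transforms.  Uses the SVD of the cross-covariance
#' matrix with a determinant-sign correction so reflections are never
#' returned; collinear/degenerate point sets still yield a minimizing
#' (non-unique) transform.
#'
#' @param A,B numeric `N x 3` coordinate matrices (Angstroms), same `N >= 3`.
#' @return list with `rotation` (3x3, det +1), `translation` (length 3) and
#'   `rmsd` (Angstroms); the transform maps `A` onto `B` as
#'   `A %*% t(rotation)` then adding `translation` row-wise.
#' @examples
#' a <- matrix(rnorm(12), ncol = 3)
#' kabsch_superpose(a, a)$rmsd  # 0
#' @export
kabsch_superpose <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (!is.numeric(A) || !is.numeric(B) || ncol(A) != 3L || ncol(B) != 3L)
    stop("coordinates must be numeric N x 3 matrices")
  if (nrow(A) != nrow(B))
    stop("coordinate sets differ in length (", nrow(A), " vs ", nrow(B), ")")
  if (nrow(A) < 3L) stop("need at least 3 points to superpose")
  if (!all(is.finite(A)) || !all(is.finite(B)))
    stop("non-finite coordinates")
  ca <- colMeans(A); cb <- colMeans(B)
  Ac <- sweep(A, 2L, ca); Bc <- sweep(B, 2L, cb)
  H <- crossprod(Ac, Bc)
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1  # rank-deficient H: either sign attains the optimum
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  tr <- s$d[1L] + s$d[2L] + d * s$d[3L]
  msd <- (sum(Ac * Ac) + sum(Bc * Bc) - 2 * tr) / nrow(A)
  list(rotation = R,
       translation = as.numeric(cb - R %*% ca),
       rmsd = sqrt(max(0, msd)))
}

## rmsd only, on pre-centered coordinate matrices with cached squared norms;
## the hot path for pivot-matrix construction.
rmsd_centered <- function(Ac, Bc, qa, qb) {
  s <- svd(crossprod(Ac, Bc))
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) d <- 1
  tr <- s$d[1L] + s$d[2L] + d * s$d[3L]
  sqrt(max(0, (qa + qb - 2 * tr) / nrow(Ac)))
}

coords_of <- function(x) {
  if (inherits(x, "decoy_structure")) x$coords else as.matrix(x)
}

#' C-alpha RMSD between two structures
#'
#' Root-mean-square deviation of corresponding C-alpha atoms after optimal
#' rigid superposition.  Symmetric, non-negative, zero iff the structures are
#' rigid-motion equivalent.
#'
#' @param x,y `decoy_structure` objects or `N x 3` coordinate matrices of
#'   equal length.
#' @return distance in Angstroms.
#' @export
ca_rmsd <- function(x, y) {
  kabsch_superpose(coords_of(x), coords_of(y))$rmsd
}

gdt_cutoffs <- c(1, 2, 4, 8)

## fraction of residues of A placeable within each cutoff of B, refined from
## one seed transform: re-superpose on the currently-within set until stable.
gdt_refine <- function(A, B, fit, max_iter = 10L) {
  n <- nrow(A)
  best <- numeric(length(gdt_cutoffs))
  for (k in seq_along(gdt_cutoffs)) {
    cut <- gdt_cutoffs[k]
    rot <- fit$rotation; trans <- fit$translation
    prev <- integer(0)
    for (it in seq_len(max_iter)) {
      moved <- A %*% t(rot)
      moved <- sweep(moved, 2L, trans, `+`)
      dev <- sqrt(rowSums((moved - B)^2))
      sel <- which(dev <= cut)
      if (length(sel) > best[k]) best[k] <- length(sel)
      if (length(sel) < 3L || identical(sel, prev)) break
      prev <- sel
      f2 <- kabsch_superpose(A[sel, , drop = FALSE], B[sel, , drop = FALSE])
      rot <- f2$rotation; trans <- f2$translation
    }
  }
  best / n
}

#' GDT-TS similarity score
#'
#' Global Distance Test Total Score: the mean over distance cutoffs 1, 2, 4
#' and 8 Angstroms of the maximal fraction of residues that can be placed
#' within the cutoff of their counterparts under some rigid superposition.
#' The maximum is approximated by seeding superpositions from the global
#' Kabsch fit and from every contiguous window of lengths 3, 5 and `N/2`
#' along the chain, each seed iteratively refined by re-superposing on the
#' residues currently within the cutoff (at most 10 iterations).  This is
#' the standard heuristic search; an exhaustive search could in principle
#' score slightly higher in rare cases.
#'
#' @inheritParams ca_rmsd
#' @return score in `[0, 1]`; 1 for identical structures.
#' @export
gdt_ts <- function(x, y) {
  A <- coords_of(x); B <- coords_of(y)
  if (nrow(A) != nrow(B))
    stop("structures differ in length (", nrow(A), " vs ", nrow(B), ")")
  n <- nrow(A)
  best <- gdt_refine(A, B, kabsch_superpose(A, B))
  wins <- unique(pmin(c(3L, 5L, as.integer(floor(n / 2))), n))
  wins <- wins[wins >= 3L]
  for (L in wins) {
    for (st in seq_len(n - L + 1L)) {
      idx <- st:(st + L - 1L)
      fit <- kabsch_superpose(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
      best <- pmax(best, gdt_refine(A, B, fit))
    }
  }
  mean(best)
}

#' GDT-TS distance
#'
#' `1 - gdt_ts(x, y)`, so that the selection pipeline can use GDT-TS in
#' place of C-alpha RMSD wherever a dissimilarity is required.
#'
#' @inheritParams ca_rmsd
#' @return distance in `[0, 1]`.
#' @export
gdt_ts_distance <- function(x, y) 1 - gdt_ts(x, y)

#' Distance tracker for a decoy set
#'
#' Binds a distance metric to a [decoy_set] and counts *unique* pairwise
#' evaluations: distances are memoized per unordered index pair within the
#' tracker's lifetime, and memo hits are free.  The selection pipeline's
#' sub-quadratic distance budget (`P*N + T*S*E + choose(T, 2)`) is asserted
#' against this counter.
#'
#' @param set a [decoy_set].
#' @param metric `"ca_rmsd"` or `"gdt_ts_distance"`.
#' @return object of class `distance_tracker` with elements `eval(i, j)`
#'   (distance between decoys `i` and `j` by index), `eval_native(i)`
#'   (uncounted distance of decoy `i` to the native, evaluation only),
#'   `count()` and `reset()`.
#' @export
distance_tracker <- function(set, metric = c("ca_rmsd", "gdt_ts_distance")) {
  metric <- match.arg(metric)
  stopifnot(inherits(set, "decoy_set"))
  n <- length(set$structures)
  memo <- new.env(hash = TRUE, parent = emptyenv(), size = 1024L)
  count <- 0L
  ## pre-center once; RMSD of centered sets needs no further translation
  cen <- lapply(set$structures, function(s) {
    m <- s$coords
    sweep(m, 2L, colMeans(m))
  })
  qq <- vapply(cen, function(m) sum(m * m), numeric(1))
  raw <- switch(metric,
    ca_rmsd = function(i, j) rmsd_centered(cen[[i]], cen[[j]], qq[i], qq[j]),
    gdt_ts_distance = function(i, j)
      gdt_ts_distance(set$structures[[i]], set$structures[[j]]))
  eval_fun <- function(i, j) {
    if (i == j) return(0)
    key <- if (i < j) paste0(i, ".", j) else paste0(j, ".", i)
    hit <- get0(key, envir = memo, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    d <- raw(i, j)
    assign(key, d, envir = memo)
    count <<- count + 1L
    d
  }
  obj <- list(
    metric = metric,
    n = n,
    eval = eval_fun,
    eval_native = function(i) {
      if (is.null(set$native)) stop("decoy set has no native structure")
      fn <- if (metric == "ca_rmsd") ca_rmsd else gdt_ts_distance
      fn(set$structures[[i]], set$native)
    },
    count = function() count,
    reset = function() {
      count <<- 0L
      rm(list = ls(memo), envir = memo)
      invisible(NULL)
    })
  class(obj) <- "distance_tracker"
  obj
}
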
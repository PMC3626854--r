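# Independent oracles used to validate the superposition and GDT code.
# The RMSD oracle never touches the SVD path: it scans a dense grid of
# Euler-angle rotations (exact optimal translation comes from centering both
# point sets) and polishes the best grid point with Nelder-Mead.

euler_rotation <- function(a, b, c) {
  ca <- cos(a); sa <- sin(a); cb <- cos(b); sb <- sin(b)
  cc <- cos(c); sc <- sin(c)
  matrix(c(ca * cb * cc - sa * sc, sa * cb * cc + ca * sc, -sb * cc,
           -ca * cb * sc - sa * cc, -sa * cb * sc + ca * cc, sb * sc,
           ca * sb, sa * sb, cb),
         nrow = 3)
}

.oracle_env <- new.env()

# 372,600 rotations at 4-degree resolution, rows = column-major vec(R)
rotation_grid <- function() {
  if (!is.null(.oracle_env$G)) return(.oracle_env$G)
  step <- 4 * pi / 180
  a <- seq(0, 2 * pi - step, by = step)
  b <- seq(0, pi, by = step)
  g <- expand.grid(a = a, b = b, c = a)
  ca <- cos(g$a); sa <- sin(g$a); cb <- cos(g$b); sb <- sin(g$b)
  cc <- cos(g$c); sc <- sin(g$c)
  G <- cbind(ca * cb * cc - sa * sc,   # R11
             sa * cb * cc + ca * sc,   # R21
             -sb * cc,                 # R31
             -ca * cb * sc - sa * cc,  # R12
             -sa * cb * sc + ca * cc,  # R22
             sb * sc,                  # R32
             ca * sb,                  # R13
             sa * sb,                  # R23
             cb)                       # R33
  .oracle_env$G <- G
  .oracle_env$angles <- g
  G
}

# minimal RMSD over rigid transforms, by exhaustive rotation grid + polish
rmsd_grid_oracle <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  Ac <- sweep(A, 2, colMeans(A)); Bc <- sweep(B, 2, colMeans(B))
  H <- crossprod(Ac, Bc)
  qa <- sum(Ac^2); qb <- sum(Bc^2); n <- nrow(A)
  G <- rotation_grid()
  tr_all <- as.numeric(G %*% as.vector(t(H)))
  best <- which.max(tr_all)
  ang <- as.numeric(.oracle_env$angles[best, ])
  neg_tr <- function(p) -sum(euler_rotation(p[1], p[2], p[3]) * t(H))
  op <- stats::optim(ang, neg_tr, method = "Nelder-Mead",
                     control = list(reltol = 1e-15, maxit = 5000))
  sqrt(max(0, (qa + qb - 2 * -op$value) / n))
}

# GDT-TS by exhaustive enumeration of superposition seeds: every residue
# subset of size >= 3 (feasible for n <= 8 only)
gdt_subset_oracle <- function(A, B, cutoffs = c(1, 2, 4, 8)) {
  n <- nrow(A)
  stopifnot(n <= 10)
  best <- numeric(length(cutoffs))
  for (k in 3:n) {
    combs <- utils::combn(n, k)
    for (ci in seq_len(ncol(combs))) {
      idx <- combs[, ci]
      fit <- kabsch_superpose(A[idx, , drop = FALSE], B[idx, , drop = FALSE])
      moved <- sweep(A %*% t(fit$rotation), 2, fit$translation, `+`)
      dev <- sqrt(rowSums((moved - B)^2))
      for (j in seq_along(cutoffs))
        best[j] <- max(best[j], sum(dev <= cutoffs[j]))
    }
  }
  list(fractions = best / n, score = mean(best / n))
}

random_rigid_motion <- function(coords) {
  p <- stats::runif(3, -pi, pi)
  R <- euler_rotation(p[1], p[2], p[3])
  sweep(coords %*% t(R), 2, stats::runif(3, -20, 20), `+`)
}
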
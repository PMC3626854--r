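## Synthetic decoy sets with known ground truth.  Emulates the statistical
## shape of ab initio decoy collections: several structural clusters of
## differing size and tightness centered on perturbations of a native
## backbone, a diffuse far-from-native outlier fraction, and pseudo-energies
## that track distance-to-native up to noise (optionally inverted, to mimic
## a badly misleading energy function).

deg2rad <- function(x) x * pi / 180

## place the next C-alpha given the previous three, a bond length, a bond
## angle theta at the last atom and a torsion phi (NeRF construction)
place_next <- function(A, B, C, bond, theta, phi) {
  bc <- C - B; bc <- bc / sqrt(sum(bc^2))
  ab <- B - A; ab <- ab / sqrt(sum(ab^2))
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  nn <- sqrt(sum(n^2))
  if (nn < 1e-8) n <- c(0, 0, 1) else n <- n / nn
  m <- c(n[2] * bc[3] - n[3] * bc[2],
         n[3] * bc[1] - n[1] * bc[3],
         n[1] * bc[2] - n[2] * bc[1])
  d <- c(-bond * cos(theta),
         bond * cos(phi) * sin(theta),
         bond * sin(phi) * sin(theta))
  C + d[1] * bc + d[2] * m + d[3] * n
}

#' Generate a protein-like random C-alpha backbone
#'
#' Self-avoiding random chain with consecutive C-alpha distances of exactly
#' 3.8 Angstroms, pseudo-bond angles drawn uniformly from 80-150 degrees
#' (the range seen in real C-alpha traces), uniform pseudo-torsions, and no
#' two non-adjacent C-alphas closer than 3.0 Angstroms (rejection sampling;
#' the chain restarts if an atom cannot be placed).
#'
#' @param n_res number of residues, `>= 3`.
#' @param id identifier for the resulting structure.
#' @param max_restarts chain restarts before giving up.
#' @return a [decoy_structure].
#' @export
generate_native <- function(n_res, id = "native", max_restarts = 50L) {
  stopifnot(n_res >= 3L)
  bond <- 3.8
  for (attempt in seq_len(max_restarts)) {
    xyz <- matrix(NA_real_, nrow = n_res, ncol = 3L)
    xyz[1L, ] <- c(0, 0, 0)
    xyz[2L, ] <- c(bond, 0, 0)
    th0 <- deg2rad(stats::runif(1, 80, 150))
    xyz[3L, ] <- xyz[2L, ] + bond * c(-cos(th0), sin(th0), 0)
    ok <- TRUE
    for (i in seq(4L, length.out = max(0L, n_res - 3L))) {
      placed <- FALSE
      for (try in seq_len(50L)) {
        theta <- deg2rad(stats::runif(1, 80, 150))
        phi <- deg2rad(stats::runif(1, -180, 180))
        cand <- place_next(xyz[i - 3L, ], xyz[i - 2L, ], xyz[i - 1L, ],
                           bond, theta, phi)
        prev <- xyz[seq_len(i - 2L), , drop = FALSE]
        if (min(sqrt(rowSums(sweep(prev, 2L, cand)^2))) >= 3.0) {
          xyz[i, ] <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(decoy_structure(id, xyz))
  }
  stop("failed to generate a self-avoiding backbone after ",
       max_restarts, " restarts")
}

#' Specification of a synthetic decoy set
#'
#' Defaults describe a desk-scale decoy collection: three clusters of
#' decreasing size at increasing distance from the native (the largest and
#' tightest nearest the native, per the clustering hypothesis that decoys
#' accumulate near the correct fold), a 10 percent diffuse outlier
#' fraction, and energies equal to the distance-to-native plus Gaussian
#' noise.  The default near-native cluster center at 2.5 Angstroms
#' guarantees at least one decoy below the 4-Angstrom inclusion threshold
#' used for benchmark decoy sets.
#'
#' @param n_res residues per structure.
#' @param cluster_sizes integer vector: members per cluster.
#' @param cluster_center_rmsd numeric vector, same length: target C-alpha
#'   RMSD (Angstroms) of each cluster center from the native.
#' @param within_cluster_sigma per-coordinate Gaussian spread of members
#'   around their cluster center (Angstroms).
#' @param outlier_fraction fraction (of the clustered count) of additional
#'   far-from-native decoys, each 8-14 Angstroms from the native.
#' @param energy_slope energy units per Angstrom of distance-to-native.
#' @param energy_noise_sigma Gaussian noise on energies (energy units).
#' @param invert_energies adversarial mode: energies *decrease* with
#'   distance-to-native, emulating an energy function that favours wrong
#'   folds.
#' @param seed integer seed.
#' @param id set identifier.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_res = 60L,
                           cluster_sizes = c(200L, 100L, 50L),
                           cluster_center_rmsd = c(2.5, 6, 9),
                           within_cluster_sigma = 0.8,
                           outlier_fraction = 0.1,
                           energy_slope = 1,
                           energy_noise_sigma = 0.5,
                           invert_energies = FALSE,
                           seed = 1L,
                           id = "synthetic") {
  stopifnot(length(cluster_sizes) == length(cluster_center_rmsd),
            all(cluster_sizes >= 1), all(cluster_center_rmsd > 0),
            within_cluster_sigma >= 0, outlier_fraction >= 0,
            outlier_fraction <= 1, energy_noise_sigma >= 0, n_res >= 3)
  structure(list(n_res = as.integer(n_res),
                 K = length(cluster_sizes),
                 cluster_sizes = as.integer(cluster_sizes),
                 cluster_center_rmsd = as.numeric(cluster_center_rmsd),
                 within_cluster_sigma = within_cluster_sigma,
                 outlier_fraction = outlier_fraction,
                 energy_slope = energy_slope,
                 energy_noise_sigma = energy_noise_sigma,
                 invert_energies = isTRUE(invert_energies),
                 seed = as.integer(seed), id = id),
            class = "synthetic_spec")
}

## scale a fixed Gaussian displacement field so the perturbed structure sits
## at the target RMSD from the reference (bisection; RMSD is monotone in the
## scale for a fixed field)
calibrate_offset <- function(ref, D, target, tol = 0.05, max_iter = 80L) {
  f <- function(s) ca_rmsd(ref, ref + s * D)
  hi <- target / sqrt(3)  # per-coordinate sigma ~ rmsd/sqrt(3) before fitting
  while (f(hi) < target) hi <- hi * 2
  lo <- 0
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    v <- f(mid)
    if (abs(v - target) <= tol) return(mid)
    if (v < target) lo <- mid else hi <- mid
  }
  if (abs(f((lo + hi) / 2) - target) > 0.2)
    stop("offset calibration did not converge to ", target, " Angstroms")
  (lo + hi) / 2
}

#' Generate a synthetic decoy set with ground truth
#'
#' Each cluster center is the native backbone deformed by a scaled Gaussian
#' coordinate field, the scale calibrated by bisection so the center's
#' superposed RMSD to the native hits its target; members add isotropic
#' Gaussian noise around the center; outliers are independent large
#' deformations of the native (8-14 Angstroms).  Energies are
#' `energy_slope * RMSD-to-native + N(0, energy_noise_sigma)`, optionally
#' inverted.
#'
#' @param spec a [synthetic_spec()].
#' @return list of class `synthetic_decoy_set`: `set` (a [decoy_set] with
#'   energies and native), `labels` (integer per decoy: cluster 1..K, 0 for
#'   outliers), `rmsd_to_native` (realized distances), `centers` (cluster
#'   center coordinate matrices), `center_rmsd` (their realized RMSD to the
#'   native), `spec`.
#' @export
generate_decoy_set <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    native <- generate_native(spec$n_res)
    ref <- native$coords
    coords <- list()
    labels <- integer(0)
    centers <- vector("list", spec$K)
    for (k in seq_len(spec$K)) {
      D <- matrix(stats::rnorm(spec$n_res * 3L), ncol = 3L)
      s <- calibrate_offset(ref, D, spec$cluster_center_rmsd[k])
      center <- ref + s * D
      centers[[k]] <- center
      for (m in seq_len(spec$cluster_sizes[k])) {
        coords[[length(coords) + 1L]] <- center +
          spec$within_cluster_sigma *
            matrix(stats::rnorm(spec$n_res * 3L), ncol = 3L)
        labels <- c(labels, k)
      }
    }
    n_out <- round(spec$outlier_fraction * sum(spec$cluster_sizes))
    for (o in seq_len(n_out)) {
      D <- matrix(stats::rnorm(spec$n_res * 3L), ncol = 3L)
      s <- calibrate_offset(ref, D, stats::runif(1, 8, 14))
      coords[[length(coords) + 1L]] <- ref + s * D
      labels <- c(labels, 0L)
    }
    n <- length(coords)
    rmsd_nat <- vapply(coords, function(m) ca_rmsd(m, ref), numeric(1))
    energy <- spec$energy_slope * rmsd_nat +
      stats::rnorm(n, 0, spec$energy_noise_sigma)
    if (spec$invert_energies)
      energy <- spec$energy_slope * (max(rmsd_nat) + min(rmsd_nat) - rmsd_nat) +
        stats::rnorm(n, 0, spec$energy_noise_sigma)
    ids <- sprintf("d%04d", seq_len(n))
    structs <- lapply(seq_len(n), function(i)
      decoy_structure(ids[i], coords[[i]], energy[i]))
    set <- decoy_set(structs, native = native, id = spec$id)
    if (any(spec$cluster_center_rmsd < 4) && min(rmsd_nat) >= 4)
      stop("inclusion rule violated: no decoy below 4 Angstroms ",
           "despite a sub-4 cluster center target")
    structure(list(set = set, labels = labels, rmsd_to_native = rmsd_nat,
                   centers = centers,
                   center_rmsd = vapply(centers, ca_rmsd, numeric(1), y = ref),
                   spec = spec),
              class = "synthetic_decoy_set")
  })
}

#' Write a synthetic decoy set as an on-disk fixture
#'
#' One PDB per decoy, `native.pdb`, an `energies.tsv` table and a
#' `labels.tsv` ground-truth table, laid out so that
#' [read_decoy_set()]`(dir, "energies.tsv", "native.pdb")` round-trips it.
#'
#' @param gen a [generate_decoy_set()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(gen, dir) {
  stopifnot(inherits(gen, "synthetic_decoy_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (s in gen$set$structures)
    write_pdb_calpha(s, file.path(dir, paste0(s$id, ".pdb")))
  write_pdb_calpha(gen$set$native, file.path(dir, "native.pdb"))
  ids <- decoy_ids(gen$set)
  en <- decoy_energies(gen$set)
  writeLines(c("# decoy-id energy",
               paste(ids, format(en, digits = 17, trim = TRUE))),
             file.path(dir, "energies.tsv"))
  writeLines(c("# decoy-id cluster-label (0 = outlier)",
               paste(ids, gen$labels)),
             file.path(dir, "labels.tsv"))
  invisible(dir)
}
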
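# Programmatic fixtures: every structure and decoy set used by the tests is
# built in code under a fixed seed.

random_structure <- function(id, n_res, scale = 5) {
  decoy_structure(id, matrix(stats::rnorm(n_res * 3, sd = scale), ncol = 3))
}

# a small unstructured decoy set (no clusters)
random_decoy_set <- function(n = 6, n_res = 8, seed = 42, native = FALSE) {
  set.seed(seed)
  structs <- lapply(seq_len(n), function(i)
    random_structure(sprintf("r%02d", i), n_res))
  nat <- if (native) random_structure("nat", n_res)
  decoy_set(structs, native = nat, id = paste0("rand", seed))
}

# two tight, well-separated clusters around perturbations of one backbone
two_cluster_set <- function(sizes = c(120, 80), centers = c(2, 9),
                            sigma = 0.5, n_res = 30, seed = 7) {
  generate_decoy_set(synthetic_spec(
    n_res = n_res, cluster_sizes = sizes, cluster_center_rmsd = centers,
    within_cluster_sigma = sigma, outlier_fraction = 0,
    energy_noise_sigma = 0.3, seed = seed, id = paste0("twoclust", seed)))
}

# the standing study condition for selection tests: one dominant tight
# near-native cluster, smaller far clusters, diffuse outliers, mildly noisy
# energies
dominant_cluster_set <- function(seed = 1, n_res = 30,
                                 invert_energies = FALSE,
                                 id = paste0("dom", seed)) {
  generate_decoy_set(synthetic_spec(
    n_res = n_res, cluster_sizes = c(100L, 40L, 25L),
    cluster_center_rmsd = c(2.5, 6, 9), within_cluster_sigma = 0.8,
    outlier_fraction = 0.1, energy_slope = 1, energy_noise_sigma = 0.5,
    invert_energies = invert_energies, seed = seed, id = id))
}

write_lines_pdb <- function(lines) {
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  path
}

pdb_atom_line <- function(serial, resno, x, y, z, elety = "CA", alt = " ") {
  sprintf("ATOM  %5d  %-3s%s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
          serial, elety, alt, "ALA", "A", resno, x, y, z)
}
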
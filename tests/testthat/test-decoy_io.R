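test_that("read_pdb_calpha extracts one C-alpha per residue in file order", {
  path <- write_lines_pdb(c(
    pdb_atom_line(1, 1, 0, 0, 0),
    pdb_atom_line(2, 2, 3.8, 0, 0),
    pdb_atom_line(3, 3, 7.6, 0, 0),
    "END"))
  s <- read_pdb_calpha(path)
  expect_s3_class(s, "decoy_structure")
  expect_equal(s$coords,
               matrix(c(0, 0, 0, 3.8, 0, 0, 7.6, 0, 0), byrow = TRUE,
                      ncol = 3))
  expect_identical(s$id, tools::file_path_sans_ext(basename(path)))
})

test_that("read_pdb_calpha keeps the first alternate location only", {
  path <- write_lines_pdb(c(
    pdb_atom_line(1, 1, 0, 0, 0),
    pdb_atom_line(2, 2, 3.8, 0, 0, alt = "A"),
    pdb_atom_line(3, 2, 9.9, 9.9, 9.9, alt = "B"),
    pdb_atom_line(4, 3, 7.6, 0, 0),
    "END"))
  s <- read_pdb_calpha(path)
  expect_equal(nrow(s$coords), 3L)
  expect_equal(s$coords[2, ], c(3.8, 0, 0))
})

test_that("read_pdb_calpha takes the first model of multi-model files", {
  path <- write_lines_pdb(c(
    "MODEL        1",
    pdb_atom_line(1, 1, 0, 0, 0),
    pdb_atom_line(2, 2, 3.8, 0, 0),
    pdb_atom_line(3, 3, 7.6, 0, 0),
    "ENDMDL",
    "MODEL        2",
    pdb_atom_line(1, 1, 1, 1, 1),
    pdb_atom_line(2, 2, 4.8, 1, 1),
    pdb_atom_line(3, 3, 8.6, 1, 1),
    "ENDMDL",
    "END"))
  s <- read_pdb_calpha(path)
  expect_equal(s$coords[1, ], c(0, 0, 0))
})

test_that("read_pdb_calpha rejects malformed inputs", {
  # residue 2 has no C-alpha
  p1 <- write_lines_pdb(c(
    pdb_atom_line(1, 1, 0, 0, 0),
    pdb_atom_line(2, 2, 3.8, 0, 0, elety = "CB"),
    pdb_atom_line(3, 3, 7.6, 0, 0),
    "END"))
  expect_error(read_pdb_calpha(p1), "without a C-alpha")

  # no ATOM records at all
  p2 <- write_lines_pdb(c("HEADER    EMPTY", "END"))
  expect_error(read_pdb_calpha(p2))

  # two residues violate N >= 3
  p3 <- write_lines_pdb(c(
    pdb_atom_line(1, 1, 0, 0, 0),
    pdb_atom_line(2, 2, 3.8, 0, 0),
    "END"))
  expect_error(read_pdb_calpha(p3), "fewer than 3")

  expect_error(read_pdb_calpha(tempfile()), "no such file")
})

test_that("PDB round-trip preserves coordinates to file precision", {
  set.seed(4)
  s <- random_structure("rt", 12)
  path <- tempfile(fileext = ".pdb")
  write_pdb_calpha(s, path)
  back <- read_pdb_calpha(path, id = "rt")
  expect_equal(back$coords, s$coords, tolerance = 1e-3)
})

test_that("read_energy_table parses, comments, duplicates and errors", {
  p <- tempfile()
  writeLines(c("d1 -12.5", "d2\t-10.0"), p)
  expect_equal(read_energy_table(p), c(d1 = -12.5, d2 = -10.0))

  writeLines(c("# header", "d1 3.0"), p)
  expect_equal(read_energy_table(p), c(d1 = 3.0))

  writeLines(c("d1 1.0", "d1 2.5"), p)
  expect_warning(en <- read_energy_table(p), "duplicate id 'd1' at line 2")
  expect_equal(en, c(d1 = 2.5))

  writeLines("d1 abc", p)
  expect_error(read_energy_table(p), "line 1.*non-numeric")
})

test_that("read_decoy_set loads, filters strays and joins energies", {
  set.seed(11)
  dir <- tempfile()
  dir.create(dir)
  for (i in 1:5)
    write_pdb_calpha(random_structure(sprintf("d%d", i), 10),
                     file.path(dir, sprintf("d%d.pdb", i)))

  s <- read_decoy_set(dir)
  expect_s3_class(s, "decoy_set")
  expect_length(s, 5L)
  expect_true(all(is.na(decoy_energies(s))))
  expect_false(anyDuplicated(decoy_ids(s)) > 0)

  # one decoy of a different length gets excluded with a warning
  write_pdb_calpha(random_structure("stray", 7),
                   file.path(dir, "stray.pdb"))
  expect_warning(s2 <- read_decoy_set(dir), "stray")
  expect_length(s2, 5L)
  expect_equal(s2$n_res, 10L)

  # energies joined by id; table ids covering 4 of 5 decoys
  etab <- tempfile()
  writeLines(paste(c("d1", "d2", "d3", "d4"), c(-1, -2, -3, -4)), etab)
  suppressWarnings(s3 <- read_decoy_set(dir, energy_table = etab))
  en <- decoy_energies(s3)
  expect_equal(sum(!is.na(en)), 4L)
  expect_equal(unname(en["d2"]), -2)

  # a table id matching no decoy warns
  writeLines(c("d1 -1", "ghost 0"), etab)
  w <- capture_warnings(read_decoy_set(dir, energy_table = etab))
  expect_true(any(grepl("ghost", w)))

  # fewer than 2 decoys is an error
  d2 <- tempfile(); dir.create(d2)
  write_pdb_calpha(random_structure("only", 10), file.path(d2, "only.pdb"))
  expect_error(read_decoy_set(d2), "at least 2")
})

test_that("decoy_set enforces id uniqueness and length homogeneity", {
  set.seed(2)
  a <- random_structure("a", 8); b <- random_structure("b", 8)
  expect_error(decoy_set(list(a, a)), "duplicate")
  expect_error(decoy_set(list(a, random_structure("c", 9))),
               "differ in residue count")
  expect_error(decoy_set(list(a, b), native = random_structure("n", 9)),
               "native length")
})

test_that("selection reports are complete and byte-identical across reruns", {
  gen <- dominant_cluster_set(seed = 5)
  p <- hs_forest_params(P = 8, T = 5, S = 5, E = 3, seed = 2)
  res <- run_hs_forest(gen$set, p)

  path <- tempfile(fileext = ".json")
  write_selection_report(res, path)
  json <- jsonlite::fromJSON(path)
  expect_identical(json$selected, res$consensus_id)
  expect_length(json$tree_candidates, 5L)
  expect_true(file.exists(sub("\\.json$", ".txt", path)))
  txt <- readLines(sub("\\.json$", ".txt", path))
  expect_true(any(grepl(res$consensus_id, txt, fixed = TRUE)))

  res2 <- run_hs_forest(gen$set, p)
  path2 <- tempfile(fileext = ".json")
  write_selection_report(res2, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))
})
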
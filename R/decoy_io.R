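## Reading decoy structures (C-alpha traces from PDB files) and per-decoy
## energy tables; writing PDB fixtures and selection reports.

#' Construct a decoy structure
#'
#' A decoy is one candidate fold: an ordered C-alpha trace plus an identifier
#' and an optional energy (arbitrary units, lower is better).
#'
#' @param id character identifier (typically the filename stem).
#' @param coords numeric `N x 3` matrix of C-alpha coordinates in Angstroms,
#'   residue order; `N >= 3`, all finite.
#' @param energy numeric scalar or `NA`.
#' @return object of class `decoy_structure`.
#' @export
decoy_structure <- function(id, coords, energy = NA_real_) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (ncol(coords) != 3L) stop("coords must have 3 columns")
  if (nrow(coords) < 3L)
    stop("structure '", id, "' has fewer than 3 residues")
  if (!all(is.finite(coords)))
    stop("structure '", id, "' has non-finite coordinates")
  dimnames(coords) <- NULL
  structure(list(id = as.character(id), coords = coords,
                 energy = as.numeric(energy)[1L]),
            class = "decoy_structure")
}

#' @export
print.decoy_structure <- function(x, ...) {
  cat("<decoy_structure> ", x$id, ": ", nrow(x$coords), " residues",
      if (!is.na(x$energy)) paste0(", energy ", signif(x$energy, 6)), "\n",
      sep = "")
  invisible(x)
}

#' Read the C-alpha trace of a PDB file
#'
#' Parses a PDB file (via \pkg{bio3d}) and returns one C-alpha per residue:
#' first MODEL only, first alternate location only, chain/residue order as in
#' the file.  All non-C-alpha atoms are discarded at parse time.
#'
#' @param path path to a PDB file.
#' @param id identifier; defaults to the filename stem.
#' @return a [decoy_structure] (energy absent).
#' @export
read_pdb_calpha <- function(path, id = tools::file_path_sans_ext(basename(path))) {
  if (!file.exists(path)) stop("no such file: ", path)
  utils::capture.output(  # bio3d chats about ALT records on stdout
    pdb <- suppressWarnings(
      bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE)))
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (nrow(atoms) == 0L) stop("no ATOM records in ", path)
  ## residues in file order, keyed by chain/resno/insert
  rkey <- paste(atoms$chain, atoms$resno, ifelse(is.na(atoms$insert), "", atoms$insert))
  res_order <- unique(rkey)
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(paste(ca$chain, ca$resno,
                             ifelse(is.na(ca$insert), "", ca$insert))), ,
           drop = FALSE]
  ca_key <- paste(ca$chain, ca$resno, ifelse(is.na(ca$insert), "", ca$insert))
  missing <- setdiff(res_order, ca_key)
  if (length(missing) > 0L)
    stop("residue(s) without a C-alpha atom in ", path, ": ",
         paste(utils::head(missing, 5L), collapse = ", "))
  ca <- ca[match(res_order, ca_key), , drop = FALSE]
  decoy_structure(id, cbind(ca$x, ca$y, ca$z))
}

#' Write a C-alpha trace as a PDB file
#'
#' Minimal PDB writer (via \pkg{bio3d}) used for synthetic fixtures; one
#' CA/ALA atom per residue, chain A.
#'
#' @param x a [decoy_structure].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_calpha <- function(x, path) {
  stopifnot(inherits(x, "decoy_structure"))
  n <- nrow(x$coords)
  bio3d::write.pdb(file = path, xyz = as.vector(t(x$coords)),
                   resno = seq_len(n), resid = rep("ALA", n),
                   elety = rep("CA", n), chain = rep("A", n),
                   o = rep(1, n), b = rep(0, n))
  invisible(path)
}

#' Read a two-column energy table
#'
#' Whitespace- or tab-delimited text with one `decoy-id energy` pair per
#' line; lines starting with `#` are comments.  A duplicated id keeps the
#' last value (with a warning).
#'
#' @param path path to the table.
#' @return named numeric vector of energies keyed by decoy id.
#' @export
read_energy_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- numeric(0)
  for (ln in seq_along(lines)) {
    s <- trimws(lines[[ln]])
    if (s == "" || startsWith(s, "#")) next
    parts <- strsplit(s, "[ \t]+")[[1L]]
    if (length(parts) != 2L)
      stop("line ", ln, ": expected 'id energy', got: ", s)
    e <- suppressWarnings(as.numeric(parts[2L]))
    if (is.na(e))
      stop("line ", ln, ": non-numeric energy '", parts[2L], "'")
    id <- parts[1L]
    if (id %in% names(out))
      warning("duplicate id '", id, "' at line ", ln, "; last value wins")
    out[id] <- e
  }
  out
}

#' Construct a decoy set
#'
#' @param structures list of [decoy_structure]s of a common length with
#'   unique ids.
#' @param native optional [decoy_structure] of the same length, used for
#'   evaluation only (never a member of the set).
#' @param id optional set identifier (e.g. target name).
#' @return object of class `decoy_set` with elements `structures` (named by
#'   id), `native`, `n_res` and `id`.
#' @export
decoy_set <- function(structures, native = NULL, id = NA_character_) {
  stopifnot(length(structures) >= 2L)
  lens <- vapply(structures, function(s) nrow(s$coords), integer(1))
  if (length(unique(lens)) != 1L)
    stop("structures differ in residue count: ",
         paste(unique(lens), collapse = ", "))
  ids <- vapply(structures, `[[`, "", "id")
  if (anyDuplicated(ids))
    stop("duplicate decoy ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(structures) <- ids
  if (!is.null(native)) {
    stopifnot(inherits(native, "decoy_structure"))
    if (nrow(native$coords) != lens[1L])
      stop("native length ", nrow(native$coords),
           " does not match set length ", lens[1L])
  }
  structure(list(structures = structures, native = native,
                 n_res = lens[[1L]], id = as.character(id)),
            class = "decoy_set")
}

#' @export
print.decoy_set <- function(x, ...) {
  ne <- sum(!is.na(decoy_energies(x)))
  cat("<decoy_set> ", length(x$structures), " decoys x ", x$n_res,
      " residues; energies for ", ne, "; native ",
      if (is.null(x$native)) "absent" else "present", "\n", sep = "")
  invisible(x)
}

#' @export
length.decoy_set <- function(x) length(x$structures)

#' Decoy ids / energies of a set
#' @param set a [decoy_set].
#' @return character vector of ids, or named numeric vector of energies
#'   (`NA` where absent).
#' @export
decoy_ids <- function(set) names(set$structures)

#' @rdname decoy_ids
#' @export
decoy_energies <- function(set) {
  vapply(set$structures, `[[`, numeric(1), "energy")
}

#' Read a directory of decoys
#'
#' Loads every `*.pdb` file in `dir` as a C-alpha trace.  The set length is
#' the modal residue count; decoys of any other length are excluded with a
#' warning.  Energies, if a table is given, are joined by decoy id
#' (filename stem).
#'
#' @param dir directory containing decoy PDB files.
#' @param energy_table optional path to a table for [read_energy_table()].
#' @param native optional path to the native structure's PDB file
#'   (evaluation only).
#' @param id set identifier; defaults to the directory name.
#' @return a [decoy_set].
#' @export
read_decoy_set <- function(dir, energy_table = NULL, native = NULL,
                           id = basename(normalizePath(dir))) {
  files <- list.files(dir, pattern = "\\.pdb$", full.names = TRUE)
  files <- files[basename(files) != "native.pdb"]
  if (length(files) < 2L)
    stop("need at least 2 decoy PDB files in ", dir)
  structs <- lapply(files, read_pdb_calpha)
  lens <- vapply(structs, function(s) nrow(s$coords), integer(1))
  modal <- as.integer(names(which.max(table(lens))))
  drop <- lens != modal
  if (any(drop)) {
    warning("excluding ", sum(drop), " decoy(s) not matching modal length ",
            modal, ": ",
            paste(vapply(structs[drop], `[[`, "", "id"), collapse = ", "))
    structs <- structs[!drop]
  }
  if (length(structs) < 2L)
    stop("fewer than 2 decoys remain after length filtering in ", dir)
  if (!is.null(energy_table)) {
    en <- read_energy_table(energy_table)
    ids <- vapply(structs, `[[`, "", "id")
    unmatched <- setdiff(names(en), ids)
    if (length(unmatched) > 0L)
      warning("energy table ids with no matching decoy: ",
              paste(unmatched, collapse = ", "))
    structs <- lapply(structs, function(s) {
      if (s$id %in% names(en)) s$energy <- unname(en[[s$id]])
      s
    })
  }
  nat <- if (!is.null(native)) read_pdb_calpha(native, id = "native")
  decoy_set(structs, native = nat, id = id)
}

#' Write a selection report
#'
#' Writes the result of [run_hs_forest()] as a machine-readable JSON file
#' plus a human-readable text summary alongside it.  The JSON payload is a
#' pure function of the inputs and seed (no timestamps), so re-running with
#' the same seed reproduces it byte for byte.
#'
#' @param result a `hs_selection` from [run_hs_forest()].
#' @param path output path for the JSON report; the text summary goes to the
#'   same path with extension `.txt`.
#' @return `path`, invisibly.
#' @export
write_selection_report <- function(result, path) {
  stopifnot(inherits(result, "hs_selection"))
  payload <- list(
    selected = result$consensus_id,
    tree_candidates = result$candidate_ids,
    trees = lapply(result$tree_summaries, function(s)
      list(cluster_count = s$cluster_count, cluster_sizes = s$cluster_sizes,
           candidate = s$candidate)),
    eval_count = result$eval_count,
    eval_budget = result$eval_budget,
    params = result$params[c("P", "T", "S", "E", "h_max", "metric",
                             "energy_source")],
    seed = result$params$seed)
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE)
  writeLines(json, path)
  txt <- sub("\\.json$", "", path)
  writeLines(utils::capture.output(print(result)), paste0(txt, ".txt"))
  invisible(path)
}
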
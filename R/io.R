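#' Load an ensemble from a topology plus trajectory files
#'
#' Reads a topology (PDB) for atom metadata and one or more trajectory files,
#' concatenating frames in the listed order. Supported trajectory formats:
#' multi-model PDB, DCD (via bio3d) and XTC (via the MDAnalysis engine,
#' invoked through a `python` subprocess; XTC stores nanometres, converted to
#' Angstrom on read). DCD coordinates are assumed to be Angstrom already.
#'
#' @param topology path to a PDB topology file.
#' @param trajectories character vector of trajectory file paths, read and
#'   concatenated in the given order.
#' @return a [structure_ensemble()] with `source_kind = "trajectory"`.
#' @export
read_trajectory_ensemble <- function(topology, trajectories) {
  if (missing(topology) || !length(topology)) {
    stop("a topology path is required", call. = FALSE)
  }
  if (missing(trajectories) || !length(trajectories)) {
    stop("at least one trajectory path is required", call. = FALSE)
  }
  for (p in c(topology, trajectories)) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  top <- bio3d::read.pdb(topology, multi = FALSE, verbose = FALSE)
  atoms <- atoms_from_bio3d(top)
  n_at <- nrow(atoms)
  xyz_list <- list()
  labels <- character(0)
  for (p in trajectories) {
    ext <- tolower(tools::file_ext(p))
    xyz <- switch(ext,
      pdb = bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)$xyz,
      dcd = unclass(bio3d::read.dcd(p, verbose = FALSE)),
      xtc = read_xtc_frames(topology, p),
      stop("unknown trajectory format '.", ext, "' for file ", p,
           call. = FALSE)
    )
    xyz <- matrix(as.numeric(xyz), nrow = nrow(xyz))
    if (ncol(xyz) != 3L * n_at) {
      stop("structural mismatch: trajectory ", p, " has ",
           ncol(xyz) %/% 3L, " atoms but the topology has ", n_at,
           call. = FALSE)
    }
    xyz_list[[length(xyz_list) + 1L]] <- xyz
    labels <- c(labels, paste0(basename(p), ":", seq_len(nrow(xyz))))
  }
  structure_ensemble(do.call(rbind, xyz_list), atoms,
                     frame_labels = labels, source_kind = "trajectory",
                     provenance = list(topology = topology,
                                       trajectories = trajectories))
}

# XTC has no native R reader; delegate to the MDAnalysis trajectory engine
# in a python subprocess, dumping Angstrom coordinates as plain text
read_xtc_frames <- function(topology, xtc) {
  python <- Sys.which("python")
  if (!nzchar(python)) python <- Sys.which("python3")
  if (!nzchar(python)) {
    stop("reading XTC requires a python interpreter with MDAnalysis ",
         "on the PATH", call. = FALSE)
  }
  out <- tempfile(fileext = ".txt")
  on.exit(unlink(out))
  script <- paste(
    "import sys, numpy as np, MDAnalysis as mda",
    "u = mda.Universe(sys.argv[1], sys.argv[2])",
    "arr = np.vstack([ts.positions.copy().ravel() for ts in u.trajectory])",
    "np.savetxt(sys.argv[3], arr, fmt='%.5f')",
    sep = "; ")
  status <- system2(python, c("-c", shQuote(script), shQuote(topology),
                              shQuote(xtc), shQuote(out)),
                    stdout = TRUE, stderr = TRUE)
  if (!is.null(attr(status, "status")) || !file.exists(out) ||
      !file.size(out)) {
    stop("failed to read XTC file ", xtc, " via MDAnalysis: ",
         paste(status, collapse = " "), call. = FALSE)
  }
  as.matrix(utils::read.table(out))
}

#' Load an ensemble from a set of PDB model files
#'
#' Builds an ensemble from separate PDB files (each contributing one frame
#' per `MODEL` record, single-model files contributing one frame), ordered by
#' (file order, model order). Frame labels are `filename` or
#' `filename:model`. Such model sets need not share temporal order;
#' `source_kind` is set to `"model_set"`.
#'
#' @param paths character vector of PDB file paths.
#' @param atom_matching `"strict_order"` (default): every file must present
#'   the same atoms in the same order as the first frame, otherwise a
#'   structural-mismatch error names the first offending file.
#'   `"name_resid_match"`: atoms are matched across files by the key
#'   (chain, resid, atom name); the intersection common to all files is
#'   kept, in first-file order, and the number of dropped atoms per file is
#'   recorded in the provenance.
#' @return a [structure_ensemble()] with `source_kind = "model_set"`.
#' @export
read_model_set <- function(paths,
                           atom_matching = c("strict_order",
                                             "name_resid_match")) {
  atom_matching <- match.arg(atom_matching)
  if (!length(paths)) stop("no model files given", call. = FALSE)
  for (p in paths) {
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
  }
  models <- lapply(paths, function(p) {
    pdb <- bio3d::read.pdb(p, multi = TRUE, verbose = FALSE)
    list(path = p, atoms = atoms_from_bio3d(pdb),
         xyz = matrix(as.numeric(pdb$xyz), nrow = nrow(pdb$xyz)))
  })
  total_frames <- sum(vapply(models, function(m) nrow(m$xyz), integer(1)))
  if (!total_frames) stop("no frames found in the model files", call. = FALSE)

  if (atom_matching == "strict_order") {
    ref <- models[[1]]
    ref_key <- atom_match_keys(ref$atoms)
    for (m in models[-1]) {
      if (nrow(m$atoms) != nrow(ref$atoms) ||
          !identical(atom_match_keys(m$atoms), ref_key)) {
        stop("structural mismatch under strict_order: file ", m$path,
             " has ", nrow(m$atoms), " atoms vs ", nrow(ref$atoms),
             " in ", ref$path,
             "; use atom_matching = 'name_resid_match' to intersect",
             call. = FALSE)
      }
    }
    atoms <- ref$atoms
    xyz <- do.call(rbind, lapply(models, `[[`, "xyz"))
    dropped <- NULL
  } else {
    keys <- lapply(models, function(m) atom_match_keys(m$atoms))
    common <- Reduce(intersect, keys)
    if (!length(common)) {
      stop("no atoms shared by all model files under name_resid_match",
           call. = FALSE)
    }
    keep1 <- keys[[1]][keys[[1]] %in% common]   # first-file order
    atoms <- models[[1]]$atoms[match(keep1, keys[[1]]), , drop = FALSE]
    xyz <- do.call(rbind, lapply(models, function(m) {
      idx <- match(keep1, atom_match_keys(m$atoms))
      m$xyz[, xyz_cols(idx), drop = FALSE]
    }))
    dropped <- stats::setNames(
      vapply(models, function(m) nrow(m$atoms) - length(common), integer(1)),
      basename(paths))
  }
  labels <- unlist(lapply(models, function(m) {
    nf <- nrow(m$xyz)
    if (nf == 1L) basename(m$path) else paste0(basename(m$path), ":",
                                               seq_len(nf))
  }))
  structure_ensemble(xyz, atoms, frame_labels = labels,
                     source_kind = "model_set",
                     provenance = list(model_paths = paths,
                                       atom_matching = atom_matching,
                                       dropped_atoms = dropped))
}

atom_match_keys <- function(atoms) {
  paste(atoms$chain, atoms$resid, toupper(trimws(atoms$elety)), sep = "|")
}

atoms_from_bio3d <- function(pdb) {
  a <- pdb$atom
  tibble::tibble(
    elety = as.character(a$elety),
    resid = as.integer(a$resno),
    resname = as.character(a$resid),
    chain = ifelse(is.na(a$chain), "A", as.character(a$chain)),
    segid = ifelse(is.na(a$segid), "", as.character(a$segid)),
    elesy = if (!is.null(a$elesy)) {
      ifelse(is.na(a$elesy) | !nzchar(trimws(a$elesy)),
             guess_element(a$elety), trimws(a$elesy))
    } else {
      guess_element(a$elety)
    },
    insert = ifelse(is.na(a$insert), "", as.character(a$insert))
  )
}

## ---- PDB writing (wwPDB v3.3 fixed columns) -------------------------------

format_pdb_atom_name <- function(elety, elesy) {
  nm <- trimws(elety)
  # names of <4 chars start in column 14 when the element symbol is 1 char
  if (nchar(nm) >= 4L) {
    substr(nm, 1, 4)
  } else if (nchar(trimws(elesy)) >= 2L) {
    formatC(nm, width = -4)
  } else {
    paste0(" ", formatC(nm, width = -3))
  }
}

pdb_atom_lines <- function(atoms, coords, b = NULL, occ = 1) {
  n <- nrow(atoms)
  if (is.null(b)) b <- rep(0, n)
  b <- pmin(pmax(b, 0), 999.99)
  names4 <- vapply(seq_len(n), function(i) {
    format_pdb_atom_name(atoms$elety[i], atoms$elesy[i])
  }, character(1))
  sprintf("ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          ((seq_len(n) - 1L) %% 99999L) + 1L,
          names4, " ", substr(atoms$resname, 1, 3),
          substr(paste0(atoms$chain, " "), 1, 1),
          atoms$resid %% 10000L,
          substr(paste0(atoms$insert, " "), 1, 1),
          coords[, 1], coords[, 2], coords[, 3],
          occ, b, formatC(substr(atoms$elesy, 1, 2), width = 2))
}

#' Write an ensemble as a multi-model PDB file
#'
#' Writes every frame as one `MODEL`/`ENDMDL` block in wwPDB v3.3 fixed
#' columns (coordinates to 0.001 Angstrom). Reloading with
#' [read_model_set()] reproduces the coordinates to PDB precision.
#'
#' @param ensemble a [structure_ensemble()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ensemble_pdb <- function(ensemble, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_len(n_frames(ensemble))) {
    writeLines(sprintf("MODEL %8d", f), con)
    writeLines(pdb_atom_lines(ensemble$atoms, frame_coords(ensemble, f)),
               con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Write a structure colored by per-atom values in the B-factor column
#'
#' Writes a single-model PDB of the chosen frame with the temperature-factor
#' column carrying `values` (fixed format `%6.2f`, clamped to
#' `[0, 999.99]`), the standard vehicle for coloring a structure by
#' fluctuation in molecular viewers. Atoms outside the analysis selection
#' should be given 0.
#'
#' @param ensemble a [structure_ensemble()].
#' @param values numeric vector, one finite value >= 0 per atom, Angstrom.
#' @param path output file path.
#' @param frame 1-based frame index to write (default 1).
#' @return `path`, invisibly.
#' @seealso [bfactor_values()] to expand an [run_ermsf()] profile to a
#'   per-atom vector.
#' @export
write_bfactor_pdb <- function(ensemble, values, path, frame = 1L) {
  if (length(values) != n_atoms(ensemble)) {
    stop("values length (", length(values), ") does not match the atom ",
         "count (", n_atoms(ensemble), ")", call. = FALSE)
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("values must be finite and >= 0", call. = FALSE)
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(pdb_atom_lines(ensemble$atoms, frame_coords(ensemble, frame),
                            b = values), con)
  writeLines("END", con)
  invisible(path)
}

#' Expand a result's average profile to a per-atom B-factor vector
#'
#' Maps each group's average fluctuation back onto its member atoms; atoms
#' outside the analysis selection receive 0.
#'
#' @param result an [run_ermsf()] result.
#' @param ensemble the ensemble the analysis was run on.
#' @return numeric vector of length `n_atoms(ensemble)`.
#' @export
bfactor_values <- function(result, ensemble) {
  sel <- select_atoms(ensemble, result$provenance$selection)
  values <- rep(0, n_atoms(ensemble))
  atoms_sel <- ensemble$atoms[sel$indices, , drop = FALSE]
  group_of_atom <- switch(result$provenance$group_level,
    atom = seq_len(nrow(atoms_sel)),
    residue = match(residue_keys(atoms_sel),
                    paste0(result$groups$chain, ":", result$groups$resid)),
    region = stop("bfactor_values() supports atom and residue grouping",
                  call. = FALSE)
  )
  mapped <- result$average_profile[group_of_atom]
  mapped[is.na(mapped)] <- 0
  values[sel$indices] <- mapped
  values
}

## ---- result tables --------------------------------------------------------

#' Write / read an eRMSF result matrix as delimited text
#'
#' `wide` layout: one row per group, one column per segment, a header row of
#' segment indices and a leading column of group labels. `long` layout:
#' columns `group_label`, `segment_index`, `ermsf_angstrom`. Values are
#' written with enough significant digits (8) that a round trip reproduces
#' the matrix well within 1e-6 Angstrom.
#'
#' @param result an [run_ermsf()] result.
#' @param path output path.
#' @param layout `"wide"` (default) or `"long"`.
#' @param sep field separator (default tab).
#' @return `path`, invisibly (`write_result_table`); for
#'   `read_result_table`, a numeric groups x segments matrix with group
#'   labels as row names.
#' @export
write_result_table <- function(result, path, layout = c("wide", "long"),
                               sep = "\t") {
  layout <- match.arg(layout)
  m <- result$matrix
  if (layout == "wide") {
    df <- data.frame(group_label = rownames(m),
                     signif(m, 8), check.names = FALSE,
                     stringsAsFactors = FALSE)
    names(df) <- c("group_label", colnames(m))
    utils::write.table(df, path, sep = sep, quote = FALSE,
                       row.names = FALSE)
  } else {
    long <- tidy(result)
    long$ermsf_angstrom <- signif(long$ermsf, 8)
    utils::write.table(long[, c("group", "segment", "ermsf_angstrom")],
                       path, sep = sep, quote = FALSE, row.names = FALSE,
                       col.names = c("group_label", "segment_index",
                                     "ermsf_angstrom"))
  }
  invisible(path)
}

#' @rdname write_result_table
#' @export
read_result_table <- function(path, layout = c("wide", "long"),
                              sep = "\t") {
  layout <- match.arg(layout)
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (layout == "wide") {
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1]]
  } else {
    groups <- unique(df$group_label)
    segs <- sort(unique(df$segment_index))
    m <- matrix(NA_real_, length(groups), length(segs),
                dimnames = list(groups, paste0("segment_", segs)))
    m[cbind(match(df$group_label, groups),
            match(df$segment_index, segs))] <- df$ermsf_angstrom
  }
  m
}
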
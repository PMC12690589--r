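#' Ensemble-average structure
#'
#' Arithmetic mean of every atom's position over the analyzed frames — the
#' reference point of the conventional RMSF.
#'
#' @param ensemble a [structure_ensemble()].
#' @param selection optional selection expression or [select_atoms()] result;
#'   default: all atoms.
#' @return numeric matrix, selected atoms x 3, Angstrom.
#' @export
mean_structure <- function(ensemble, selection = NULL) {
  m <- colMeans(ensemble$xyz)
  coords <- matrix(m, ncol = 3L, byrow = TRUE)
  if (!is.null(selection)) {
    sel <- as_atom_selection(ensemble, selection)
    coords <- coords[sel$indices, , drop = FALSE]
  }
  coords
}

# frames x atoms matrix of squared distances to per-atom reference positions
# ref: atoms x 3 (same atom subset/order as the xyz columns)
sq_dev_to_ref <- function(xyz, ref) {
  dev2 <- sweep(xyz, 2L, coords_to_row(ref))^2
  na <- ncol(xyz) %/% 3L
  dev2[, seq(1L, 3L * na, by = 3L), drop = FALSE] +
    dev2[, seq(2L, 3L * na, by = 3L), drop = FALSE] +
    dev2[, seq(3L, 3L * na, by = 3L), drop = FALSE]
}

#' Conventional per-atom RMSF
#'
#' For each selected atom, the square root of the mean (over all analyzed
#' frames, denominator N — the population form) of the squared Euclidean
#' distance between the atom's position and its own ensemble-average
#' position. The ensemble should be superposed first (see [align_ensemble()])
#' unless it is already free of global rigid-body motion.
#'
#' @inheritParams mean_structure
#' @return named numeric vector, one RMSF value in Angstrom per selected
#'   atom.
#' @export
#' @examples
#' ref <- make_reference_peptide(5)
#' ens <- make_gaussian_ensemble(ref, sigma = 0.5, n_frames = 500, seed = 2)
#' rmsf_classic(ens)   # approaches 0.5 * sqrt(3) for every atom
rmsf_classic <- function(ensemble, selection = NULL) {
  sel_idx <- if (is.null(selection)) {
    seq_len(n_atoms(ensemble))
  } else {
    as_atom_selection(ensemble, selection)$indices
  }
  xyz_sel <- ensemble$xyz[, xyz_cols(sel_idx), drop = FALSE]
  mu <- matrix(colMeans(xyz_sel), ncol = 3L, byrow = TRUE)
  sq <- sq_dev_to_ref(xyz_sel, mu)
  stats::setNames(sqrt(colMeans(sq)), atom_labels(ensemble$atoms[sel_idx, ]))
}

# xyz column indices for a set of atom indices
xyz_cols <- function(atom_idx) {
  as.vector(rbind(3L * atom_idx - 2L, 3L * atom_idx - 1L, 3L * atom_idx))
}

atom_labels <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resname, atoms$resid, atoms$insert,
         ":", trimws(atoms$elety))
}

residue_keys <- function(atoms) {
  paste0(atoms$chain, ":", atoms$resid, atoms$insert)
}

#' Segment-resolved eRMSF matrix at atom level
#'
#' The core fixed-reference statistic: entry (i, s) is the square root of the
#' mean, over the frames of segment s, of the squared Euclidean distance
#' between atom i's position and its position in the fixed reference
#' structure. Each segment is evaluated independently and normalized by its
#' own frame count (a partial final segment uses its own length).
#'
#' With `skip = 1` each entry collapses to the plain Euclidean distance
#' between the atom in that frame and the reference. With a single segment
#' covering all frames and the mean structure as reference, the statistic
#' collapses to the conventional RMSF.
#'
#' @param ensemble a [structure_ensemble()], already superposed if global
#'   motion should be removed.
#' @param selection selection expression or [select_atoms()] result;
#'   default all atoms.
#' @param reference reference specification (see [ref_frame()]); a frame
#'   index, `"mean"`, a matrix, or a PDB path are also accepted. Default:
#'   frame 1 of the analyzed frames.
#' @param segmentation a [segment_frames()] result, or a single integer taken
#'   as `skip` with `keep_partial` remainder handling. Default: `skip = 1`.
#' @return list with `ermsf` (selected atoms x segments matrix, Angstrom),
#'   `sq_means` (the per-atom per-segment mean squared deviations, Angstrom^2,
#'   used for residue/region pooling), `selection`, `reference`,
#'   `segmentation`.
#' @export
ermsf_atoms <- function(ensemble, selection = NULL,
                        reference = ref_frame(1L), segmentation = 1L) {
  sel <- if (is.null(selection)) {
    structure(list(expression = "all",
                   indices = seq_len(n_atoms(ensemble))),
              class = "atom_selection")
  } else {
    as_atom_selection(ensemble, selection)
  }
  if (!inherits(segmentation, "segmentation")) {
    segmentation <- segment_frames(n_frames(ensemble), segmentation)
  }
  if (max(segmentation$boundaries$last) > n_frames(ensemble)) {
    stop("segmentation covers ", max(segmentation$boundaries$last),
         " frames but the ensemble has ", n_frames(ensemble), call. = FALSE)
  }
  reference <- materialize_reference(reference, ensemble)
  ref_sel <- reference$coords[sel$indices, , drop = FALSE]
  xyz_sel <- ensemble$xyz[, xyz_cols(sel$indices), drop = FALSE]
  sq <- sq_dev_to_ref(xyz_sel, ref_sel)          # frames x atoms
  seg_idx <- segment_frame_indices(segmentation)
  sq_means <- vapply(seg_idx, function(rows) {
    colMeans(sq[rows, , drop = FALSE])
  }, numeric(ncol(sq)))
  sq_means <- matrix(sq_means, ncol = length(seg_idx),
                     dimnames = list(
                       atom_labels(ensemble$atoms[sel$indices, ]),
                       paste0("segment_", seq_along(seg_idx))))
  list(ermsf = sqrt(sq_means), sq_means = sq_means, selection = sel,
       reference = reference, segmentation = segmentation)
}

#' Grouping specification for fluctuation profiles
#'
#' Fluctuations can be reported per atom, pooled per residue, or pooled over
#' named regions. Pooling takes the root of the unweighted mean of the
#' per-atom mean squared deviations over the member atoms (squared deviations
#' are pooled before the root, preserving the RMS character of the statistic;
#' at atom level the reduction is the identity).
#'
#' @param level `"atom"`, `"residue"` or `"region"`.
#' @param regions named list of selection expressions (or [select_atoms()]
#'   results), required for `level = "region"`; names must be unique.
#' @return object of class `grouping_spec`.
#' @export
#' @examples
#' grouping_spec("residue")
#' grouping_spec("region", regions = list(lid = "resid 30-45"))
grouping_spec <- function(level = c("residue", "atom", "region"),
                          regions = NULL) {
  level <- match.arg(level)
  if (level == "region") {
    if (is.null(regions) || !length(regions)) {
      stop("level = 'region' requires a non-empty named `regions` list",
           call. = FALSE)
    }
    if (is.null(names(regions)) || any(!nzchar(names(regions))) ||
        anyDuplicated(names(regions))) {
      stop("region names must be present and unique", call. = FALSE)
    }
  } else if (!is.null(regions)) {
    stop("`regions` is only meaningful for level = 'region'", call. = FALSE)
  }
  structure(list(level = level, regions = regions), class = "grouping_spec")
}

# pool per-atom mean squared deviations (atoms x segments) to groups.
# Returns list(matrix = groups x segments eRMSF (sqrt applied),
#              sq_means = groups x segments pooled squared means,
#              labels, groups tibble)
group_reduce <- function(sq_means, grouping, atoms, sel) {
  atoms_sel <- atoms[sel$indices, , drop = FALSE]
  if (grouping$level == "atom") {
    labels <- atom_labels(atoms_sel)
    groups <- tibble::tibble(group = labels,
                             chain = atoms_sel$chain,
                             resid = atoms_sel$resid,
                             resname = atoms_sel$resname,
                             n_atoms = 1L)
    out <- sq_means
    rownames(out) <- labels
    return(list(matrix = sqrt(out), sq_means = out, labels = labels,
                groups = groups))
  }
  if (grouping$level == "residue") {
    key <- residue_keys(atoms_sel)
    ord <- unique(key)                    # order of first appearance
    member <- split(seq_len(nrow(atoms_sel)), factor(key, levels = ord))
    firsts <- vapply(member, `[`, integer(1), 1L)
    labels <- paste0(atoms_sel$chain[firsts], ":",
                     atoms_sel$resname[firsts], atoms_sel$resid[firsts],
                     atoms_sel$insert[firsts])
    groups <- tibble::tibble(group = labels,
                             chain = atoms_sel$chain[firsts],
                             resid = atoms_sel$resid[firsts],
                             resname = atoms_sel$resname[firsts],
                             n_atoms = lengths(member))
  } else {
    member <- lapply(names(grouping$regions), function(nm) {
      rsel <- as_atom_selection(
        structure(list(xyz = matrix(0, 1, 3 * nrow(atoms)), atoms = atoms),
                  class = "structure_ensemble"),
        grouping$regions[[nm]])
      outside <- setdiff(rsel$indices, sel$indices)
      if (length(outside)) {
        stop("region '", nm, "' references atom(s) outside the analysis ",
             "selection: ",
             paste(utils::head(atom_labels(atoms[outside, ]), 5),
                   collapse = ", "),
             if (length(outside) > 5) ", ...", call. = FALSE)
      }
      match(rsel$indices, sel$indices)
    })
    names(member) <- names(grouping$regions)
    labels <- names(grouping$regions)
    groups <- tibble::tibble(group = labels,
                             chain = NA_character_, resid = NA_integer_,
                             resname = NA_character_,
                             n_atoms = lengths(member))
  }
  pooled <- t(vapply(member, function(rows) {
    colMeans(sq_means[rows, , drop = FALSE])
  }, numeric(ncol(sq_means))))
  pooled <- matrix(pooled, nrow = length(member),
                   dimnames = list(labels, colnames(sq_means)))
  list(matrix = sqrt(pooled), sq_means = pooled, labels = labels,
       groups = groups)
}

#' Run the full segment-resolved eRMSF analysis
#'
#' Orchestrates the complete workflow: slice the frames, superpose them onto
#' the reference (optional but on by default), partition into segments,
#' compute the fixed-reference per-atom eRMSF, pool to the requested grouping
#' level, and attach an average per-group profile. All provenance (selection,
#' slice, alignment, reference, segmentation) is recorded on the result.
#'
#' @param ensemble a [structure_ensemble()].
#' @param selection atom selection expression (default `"protein"`) or a
#'   [select_atoms()] result.
#' @param reference reference specification: a 1-based frame index into the
#'   analyzed frames (default `1`), `"mean"`, a coordinate matrix, a PDB
#'   path, or a `reference_spec`.
#' @param skip frames per segment (default `1`: every frame is its own
#'   segment).
#' @param start,stop,step frame slicing (1-based, inclusive) applied before
#'   everything else; `skip` counts post-stride frames.
#' @param group_by `"residue"` (default), `"atom"`, `"region"`, or a
#'   [grouping_spec()].
#' @param regions named list of region selections when `group_by = "region"`.
#' @param align superpose each frame onto the reference before measuring
#'   fluctuations (default `TRUE`). Disable for pre-aligned ensembles or
#'   model sets in a common frame.
#' @param remainder_policy what to do with trailing frames when the frame
#'   count is not divisible by `skip`: keep them as a shorter final segment
#'   (`"keep_partial"`, default) or drop them (`"drop_partial"`).
#' @param average_mode how the average per-group profile is computed:
#'   `"mean_of_segments"` (arithmetic mean across the matrix columns) or
#'   `"classic_rmsf"` (conventional RMSF about the ensemble mean over all analyzed
#'   frames, pooled with the same rule). Default: `"classic_rmsf"` when the
#'   reference is the mean structure (the two coincide exactly for a single
#'   segment), otherwise `"mean_of_segments"`.
#' @return An object of class `ermsf_result`; see [tidy.ermsf_result()],
#'   [glance.ermsf_result()], [autoplot.ermsf_result()]. Fields: `matrix`
#'   (groups x segments, Angstrom), `groups` (tibble of group metadata),
#'   `average_profile`, `average_mode`, `segmentation`, `reference`,
#'   `provenance`.
#' @export
#' @examples
#' ref <- make_reference_peptide(10)
#' ens <- make_gaussian_ensemble(ref, sigma = 0.4, n_frames = 100, seed = 3)
#' res <- run_ermsf(ens, selection = "name CA", skip = 10, align = FALSE)
#' res
#' dim(res$matrix)
run_ermsf <- function(ensemble, selection = "protein",
                      reference = 1L, skip = 1L,
                      start = 1L, stop = NULL, step = 1L,
                      group_by = c("residue", "atom", "region"),
                      regions = NULL,
                      align = TRUE,
                      remainder_policy = c("keep_partial", "drop_partial"),
                      average_mode = NULL) {
  remainder_policy <- match.arg(remainder_policy)
  grouping <- if (inherits(group_by, "grouping_spec")) {
    group_by
  } else {
    grouping_spec(match.arg(group_by), regions = regions)
  }
  ens <- with_stage("slice", slice_frames(ensemble, start, stop, step))
  sel <- with_stage("selection", as_atom_selection(ens, selection))
  reference <- as_reference_spec(reference)
  if (align) {
    ens <- with_stage("alignment",
                      align_ensemble(ens, fit_selection = sel,
                                     reference = reference))
  }
  seg <- with_stage("segmentation",
                    segment_frames(n_frames(ens), skip, remainder_policy))
  core <- with_stage("ermsf", ermsf_atoms(ens, sel, reference, seg))
  red <- with_stage("grouping",
                    group_reduce(core$sq_means, grouping, ens$atoms, sel))
  if (is.null(average_mode)) {
    average_mode <- if (core$reference$mode == "mean_structure") {
      "classic_rmsf"
    } else {
      "mean_of_segments"
    }
  }
  average_mode <- match.arg(average_mode, c("mean_of_segments", "classic_rmsf"))
  avg <- with_stage("average_profile",
    if (average_mode == "mean_of_segments") {
      rowMeans(red$matrix)
    } else {
      xyz_sel <- ens$xyz[, xyz_cols(sel$indices), drop = FALSE]
      mu <- matrix(colMeans(xyz_sel), ncol = 3L, byrow = TRUE)
      sq_all <- matrix(colMeans(sq_dev_to_ref(xyz_sel, mu)), ncol = 1L,
                       dimnames = list(NULL, "all_frames"))
      drop(group_reduce(sq_all, grouping, ens$atoms, sel)$matrix[, 1L])
    })
  avg <- stats::setNames(as.numeric(avg), red$labels)
  structure(
    list(matrix = red$matrix,
         groups = red$groups,
         average_profile = avg,
         average_mode = average_mode,
         segmentation = seg,
         reference = list(mode = core$reference$mode,
                          frame_index = core$reference$frame_index),
         provenance = list(
           selection = sel$expression,
           n_atoms_selected = length(sel$indices),
           slice = list(start = start,
                        stop = if (is.null(stop)) NA_integer_ else stop,
                        step = step),
           n_frames_analyzed = n_frames(ens),
           align = align,
           group_level = grouping$level,
           source_kind = ensemble$source_kind,
           skip = seg$skip,
           remainder_policy = remainder_policy,
           frame_labels = ens$frame_labels)),
    class = "ermsf_result"
  )
}

#' @export
print.ermsf_result <- function(x, ...) {
  cat("<ermsf_result> ", nrow(x$matrix), " ", x$provenance$group_level,
      " group(s) x ", ncol(x$matrix), " segment(s)\n", sep = "")
  cat("  frames analyzed: ", x$provenance$n_frames_analyzed,
      " (skip = ", x$provenance$skip, "), selection: '",
      x$provenance$selection, "' (", x$provenance$n_atoms_selected,
      " atoms)\n", sep = "")
  cat("  reference: ", x$reference$mode,
      if (x$reference$mode == "frame_index") {
        paste0(" (frame ", x$reference$frame_index, ")")
      },
      ", alignment: ", if (x$provenance$align) "on" else "off", "\n",
      sep = "")
  cat("  eRMSF range: [", format(min(x$matrix), digits = 4), ", ",
      format(max(x$matrix), digits = 4), "] Angstrom; average profile mode: ",
      x$average_mode, "\n", sep = "")
  invisible(x)
}
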
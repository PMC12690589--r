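#' Construct a structure ensemble
#'
#' A `structure_ensemble` is an ordered set of conformations (frames) of the
#' same molecule. Coordinates are stored as a frames x 3N matrix in Angstrom
#' (the bio3d `xyz` layout: columns x1, y1, z1, x2, ...), together with a
#' per-atom metadata table. Frames may come from a time-ordered trajectory or
#' from an unordered set of structure models; `source_kind` records which.
#'
#' @param xyz numeric matrix, frames x (3 * n_atoms), coordinates in Angstrom.
#'   A single frame may be given as a numeric vector of length `3 * n_atoms`.
#' @param atoms data frame with one row per atom. Must contain columns
#'   `elety` (atom name), `resid` (residue sequence number), `resname`
#'   (residue name), `chain` (chain identifier). Optional columns: `segid`,
#'   `elesy` (element symbol), `insert` (insertion code).
#' @param frame_labels character vector of unique labels, one per frame.
#'   Defaults to `"frame_1"`, `"frame_2"`, ...
#' @param source_kind `"trajectory"` (time-ordered frames) or `"model_set"`
#'   (unordered structure models).
#' @param provenance optional list of free-form provenance records.
#'
#' @return An object of class `structure_ensemble`: a list with elements
#'   `xyz`, `atoms` (tibble), `frame_labels`, `source_kind`, `provenance`.
#' @export
#' @examples
#' ref <- make_reference_peptide(5)
#' ens <- make_gaussian_ensemble(ref, sigma = 0.3, n_frames = 10, seed = 1)
#' n_frames(ens)
#' n_atoms(ens)
structure_ensemble <- function(xyz, atoms,
                               frame_labels = NULL,
                               source_kind = c("trajectory", "model_set"),
                               provenance = list()) {
  source_kind <- match.arg(source_kind)
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (nrow(xyz) < 1L) {
    stop("ensemble must contain at least one frame", call. = FALSE)
  }
  if (ncol(xyz) < 3L || ncol(xyz) %% 3L != 0L) {
    stop("coordinate matrix must have 3 columns per atom (got ",
         ncol(xyz), " columns)", call. = FALSE)
  }
  if (any(!is.finite(xyz))) {
    stop("coordinates contain non-finite values", call. = FALSE)
  }
  n_at <- ncol(xyz) %/% 3L
  atoms <- tibble::as_tibble(atoms)
  required <- c("elety", "resid", "resname", "chain")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop("atom table lacks required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (nrow(atoms) != n_at) {
    stop("atom table has ", nrow(atoms), " rows but coordinates describe ",
         n_at, " atoms", call. = FALSE)
  }
  if (!"segid" %in% names(atoms)) atoms$segid <- ""
  if (!"elesy" %in% names(atoms)) atoms$elesy <- guess_element(atoms$elety)
  if (!"insert" %in% names(atoms)) atoms$insert <- ""
  atoms$resid <- as.integer(atoms$resid)
  if (is.null(frame_labels)) {
    frame_labels <- paste0("frame_", seq_len(nrow(xyz)))
  }
  frame_labels <- as.character(frame_labels)
  if (length(frame_labels) != nrow(xyz)) {
    stop("frame_labels length (", length(frame_labels),
         ") does not match frame count (", nrow(xyz), ")", call. = FALSE)
  }
  if (anyDuplicated(frame_labels)) {
    stop("frame_labels must be unique", call. = FALSE)
  }
  structure(
    list(xyz = xyz, atoms = atoms, frame_labels = frame_labels,
         source_kind = source_kind, provenance = provenance),
    class = "structure_ensemble"
  )
}

# crude element guess from the atom name (first alphabetic character,
# two-letter cases handled for common hetero elements)
guess_element <- function(elety) {
  nm <- toupper(trimws(as.character(elety)))
  two <- c("FE", "ZN", "MG", "MN", "CL", "BR", "NA", "CA2", "SE")
  vapply(nm, function(x) {
    stripped <- gsub("[^A-Z]", "", x)
    if (nchar(stripped) >= 2 && substr(stripped, 1, 2) %in% two &&
        !grepl("^CA$|^CB$|^CD|^CE|^CG|^CZ|^CH", stripped)) {
      return(substr(stripped, 1, 2))
    }
    substr(stripped, 1, 1)
  }, character(1), USE.NAMES = FALSE)
}

#' @export
print.structure_ensemble <- function(x, ...) {
  cat("<structure_ensemble> ", n_frames(x), " frame(s) x ", n_atoms(x),
      " atoms [", x$source_kind, "]\n", sep = "")
  res <- unique(paste(x$atoms$chain, x$atoms$resid))
  cat("  residues: ", length(res), ", chains: ",
      paste(unique(x$atoms$chain), collapse = ","), "\n", sep = "")
  cat("  frames: ", paste(utils::head(x$frame_labels, 3), collapse = ", "),
      if (n_frames(x) > 3) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' Ensemble dimensions
#'
#' @param ensemble a [structure_ensemble()].
#' @return `n_frames()`/`n_atoms()` return an integer count.
#' @export
n_frames <- function(ensemble) nrow(ensemble$xyz)

#' @rdname n_frames
#' @export
n_atoms <- function(ensemble) ncol(ensemble$xyz) %/% 3L

#' Extract one frame as an atoms x 3 coordinate matrix
#'
#' @param ensemble a [structure_ensemble()].
#' @param frame 1-based frame index.
#' @return numeric matrix, `n_atoms(ensemble)` x 3, Angstrom.
#' @export
frame_coords <- function(ensemble, frame) {
  if (frame < 1L || frame > n_frames(ensemble)) {
    stop("frame index ", frame, " out of range [1, ", n_frames(ensemble), "]",
         call. = FALSE)
  }
  matrix(ensemble$xyz[frame, ], ncol = 3L, byrow = TRUE)
}

# atoms x 3 matrix -> one xyz row (x1,y1,z1,x2,...)
coords_to_row <- function(coords) as.vector(t(coords))

#' Subset frames of an ensemble
#'
#' Returns the frames `seq(start, stop, by = step)` of the ensemble, order
#' preserved, atom table unchanged. Indexing is 1-based and `start`/`stop`
#' are inclusive, following R convention.
#'
#' @inheritParams frame_coords
#' @param start first frame to keep (1-based, inclusive). Default 1.
#' @param stop last frame to keep (inclusive). `NULL` (default) means the
#'   last frame.
#' @param step positive stride.
#' @return a [structure_ensemble()] with the selected frames.
#' @export
#' @examples
#' ref <- make_reference_peptide(4)
#' ens <- make_gaussian_ensemble(ref, sigma = 0.2, n_frames = 10, seed = 1)
#' n_frames(slice_frames(ens, start = 1, stop = 10, step = 2))
slice_frames <- function(ensemble, start = 1L, stop = NULL, step = 1L) {
  nf <- n_frames(ensemble)
  if (is.null(stop)) stop <- nf
  start <- as.integer(start); stop <- as.integer(stop); step <- as.integer(step)
  if (is.na(start) || start < 1L) {
    stop("start must be a positive frame index (got ", start, ")",
         call. = FALSE)
  }
  if (is.na(step) || step < 1L) {
    stop("step must be a positive integer (got ", step, ")", call. = FALSE)
  }
  if (is.na(stop)) stop("stop must be an integer or NULL", call. = FALSE)
  if (stop > nf) stop <- nf
  if (start > stop) {
    stop("frame slice resolves to zero frames (start = ", start,
         ", stop = ", stop, ", step = ", step, ", available frames = ",
         nf, ")", call. = FALSE)
  }
  idx <- seq.int(start, stop, by = step)
  structure_ensemble(
    xyz = ensemble$xyz[idx, , drop = FALSE],
    atoms = ensemble$atoms,
    frame_labels = ensemble$frame_labels[idx],
    source_kind = ensemble$source_kind,
    provenance = ensemble$provenance
  )
}
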
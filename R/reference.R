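#' Reference structure specification
#'
#' The eRMSF statistic measures every positional deviation against one fixed
#' global reference structure. The reference may be a frame of the analyzed
#' ensemble (`ref_frame()`, default frame 1), the ensemble-average structure
#' (`ref_mean()`), or an external structure (`ref_structure()`).
#'
#' @param frame_index 1-based index into the analyzed (post-slice) frame list.
#' @return An object of class `reference_spec`.
#' @export
#' @examples
#' ref_frame(1)
#' ref_mean()
ref_frame <- function(frame_index = 1L) {
  frame_index <- as.integer(frame_index)
  if (is.na(frame_index) || frame_index < 1L) {
    stop("reference frame_index must be a positive integer", call. = FALSE)
  }
  structure(list(mode = "frame_index", frame_index = frame_index,
                 coords = NULL),
            class = "reference_spec")
}

#' @rdname ref_frame
#' @export
ref_mean <- function() {
  structure(list(mode = "mean_structure", frame_index = NA_integer_,
                 coords = NULL),
            class = "reference_spec")
}

#' @rdname ref_frame
#' @param x external reference coordinates: an atoms x 3 numeric matrix, a
#'   one-frame [structure_ensemble()], or a path to a PDB file (first model
#'   used).
#' @export
ref_structure <- function(x) {
  coords <- if (is.matrix(x)) {
    x
  } else if (inherits(x, "structure_ensemble")) {
    frame_coords(x, 1L)
  } else if (is.character(x) && length(x) == 1L) {
    pdb <- bio3d::read.pdb(x, verbose = FALSE)
    matrix(pdb$xyz[1, ], ncol = 3L, byrow = TRUE)
  } else {
    stop("ref_structure() expects a matrix, a structure_ensemble, ",
         "or a PDB file path", call. = FALSE)
  }
  if (ncol(coords) != 3L || any(!is.finite(coords))) {
    stop("reference coordinates must be a finite atoms x 3 matrix",
         call. = FALSE)
  }
  structure(list(mode = "external_structure", frame_index = NA_integer_,
                 coords = coords),
            class = "reference_spec")
}

#' @export
print.reference_spec <- function(x, ...) {
  cat("<reference_spec> mode = ", x$mode,
      if (x$mode == "frame_index") paste0(" (frame ", x$frame_index, ")"),
      if (!is.null(x$coords)) paste0(" [", nrow(x$coords), " atoms]"),
      "\n", sep = "")
  invisible(x)
}

# accepts a reference_spec, a 1-based frame index, the string "mean",
# a matrix, or a PDB path
as_reference_spec <- function(reference) {
  if (inherits(reference, "reference_spec")) return(reference)
  if (is.numeric(reference) && length(reference) == 1L) {
    return(ref_frame(reference))
  }
  if (identical(reference, "mean")) return(ref_mean())
  ref_structure(reference)
}

# resolve a reference_spec to full-atom coordinates (n_atoms x 3) against a
# (post-slice, post-alignment) ensemble
materialize_reference <- function(reference, ensemble) {
  reference <- as_reference_spec(reference)
  coords <- switch(reference$mode,
    frame_index = {
      if (reference$frame_index > n_frames(ensemble)) {
        stop("reference frame_index ", reference$frame_index,
             " exceeds the analyzed frame count (", n_frames(ensemble), ")",
             call. = FALSE)
      }
      frame_coords(ensemble, reference$frame_index)
    },
    mean_structure = mean_structure(ensemble),
    external_structure = reference$coords
  )
  if (nrow(coords) != n_atoms(ensemble)) {
    stop("structural mismatch: reference has ", nrow(coords),
         " atoms but the ensemble has ", n_atoms(ensemble), call. = FALSE)
  }
  reference$coords <- coords
  reference
}
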
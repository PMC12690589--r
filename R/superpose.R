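#' Kabsch least-squares superposition of two coordinate sets
#'
#' Computes the proper rotation and translation that superpose `mobile` onto
#' `target` with minimal root-mean-square deviation, via singular value
#' decomposition of the cross-covariance matrix with the usual determinant
#' sign correction so that reflections are never returned.
#'
#' The transform maps a mobile coordinate row-vector `x` to
#' `R %*% (x - centroid(mobile)) + centroid(target)`, i.e.
#' `x %*% t(R) + translation` with `translation = centroid(target) -
#' centroid(mobile) %*% t(R)`.
#'
#' @param mobile,target numeric atoms x 3 matrices (same shape, >= 3 rows,
#'   finite, non-collinear).
#' @return list with `rotation` (3 x 3, `det = +1`), `translation`
#'   (length-3 vector, Angstrom), and `rmsd` (minimized RMSD, Angstrom).
#' @export
#' @examples
#' set.seed(1)
#' target <- matrix(rnorm(30), ncol = 3)
#' fit <- kabsch_fit(target + rep(c(5, -2, 1), each = 10), target)
#' fit$rmsd          # 0: pure translation is exactly removable
#' fit$translation   # recovers -(5, -2, 1)
kabsch_fit <- function(mobile, target) {
  mobile <- as.matrix(mobile); target <- as.matrix(target)
  if (!identical(dim(mobile), dim(target))) {
    stop("mobile and target must have identical dimensions", call. = FALSE)
  }
  if (ncol(mobile) != 3L) {
    stop("coordinate matrices must have 3 columns", call. = FALSE)
  }
  if (nrow(mobile) < 3L) {
    stop("degenerate fit: at least 3 atoms are required (got ",
         nrow(mobile), ")", call. = FALSE)
  }
  if (any(!is.finite(mobile)) || any(!is.finite(target))) {
    stop("coordinates contain non-finite values", call. = FALSE)
  }
  cm <- colMeans(mobile)
  ct <- colMeans(target)
  P <- sweep(mobile, 2L, cm)
  Q <- sweep(target, 2L, ct)
  check_not_collinear(P)
  H <- crossprod(P, Q)                     # 3x3 cross-covariance
  s <- svd(H)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  translation <- as.vector(ct - R %*% cm)
  fitted <- P %*% t(R)
  rmsd <- sqrt(mean(rowSums((fitted - Q)^2)))
  list(rotation = R, translation = translation, rmsd = rmsd)
}

# centered coordinates of rank < 2 (all atoms on a line or a point) leave the
# rotation about that axis undetermined
check_not_collinear <- function(centered) {
  sv <- svd(centered, nu = 0, nv = 0)$d
  if (sv[2] <= max(sv[1], 1) * 1e-10) {
    stop("degenerate fit: fit atoms are collinear (rank < 2)", call. = FALSE)
  }
  invisible(TRUE)
}

# apply a kabsch_fit result to an atoms x 3 matrix
apply_fit <- function(coords, fit) {
  sweep(coords %*% t(fit$rotation), 2L, fit$translation, "+")
}

#' Superpose every frame of an ensemble onto a reference
#'
#' Removes global rigid-body (translational and rotational) motion: each frame
#' is least-squares fitted onto the reference coordinates using the atoms of
#' `fit_selection`, and the resulting transform is applied to all atoms of the
#' frame. Fits are unweighted. If the reference is a member frame, that frame
#' has fit-RMSD 0 after alignment; aligning an already-aligned ensemble is a
#' no-op (within numerical precision).
#'
#' @param ensemble a [structure_ensemble()].
#' @param fit_selection atoms used to compute the fit: a selection expression
#'   or an [select_atoms()] result. Default `"all"`. Must resolve to >= 3
#'   non-collinear atoms.
#' @param reference a `reference_spec` (see [ref_frame()]), a frame index,
#'   `"mean"`, a coordinate matrix, or a PDB path. Default: frame 1.
#'   With `reference = ref_mean()` a two-pass scheme is used (align onto
#'   frame 1, compute the mean, realign onto that mean) since the mean
#'   structure itself depends on the alignment.
#' @return the aligned [structure_ensemble()].
#' @export
#' @examples
#' ref <- make_reference_peptide(6)
#' ens <- make_gaussian_ensemble(ref, sigma = 0.3, n_frames = 5, seed = 7)
#' aligned <- align_ensemble(ens, fit_selection = "name CA")
align_ensemble <- function(ensemble, fit_selection = "all",
                           reference = ref_frame(1L)) {
  sel <- as_atom_selection(ensemble, fit_selection)
  reference <- as_reference_spec(reference)
  if (reference$mode == "mean_structure") {
    pass1 <- align_onto(ensemble, sel, frame_coords(ensemble, 1L))
    return(align_onto(pass1, sel, mean_structure(pass1)))
  }
  ref <- materialize_reference(reference, ensemble)
  align_onto(ensemble, sel, ref$coords)
}

align_onto <- function(ensemble, sel, ref_coords) {
  idx <- sel$indices
  ref_sub <- ref_coords[idx, , drop = FALSE]
  xyz <- ensemble$xyz
  out <- xyz
  for (f in seq_len(nrow(xyz))) {
    fc <- matrix(xyz[f, ], ncol = 3L, byrow = TRUE)
    fit <- kabsch_fit(fc[idx, , drop = FALSE], ref_sub)
    out[f, ] <- coords_to_row(apply_fit(fc, fit))
  }
  structure_ensemble(out, ensemble$atoms, ensemble$frame_labels,
                     ensemble$source_kind,
                     c(ensemble$provenance,
                       list(aligned = list(fit_selection = sel$expression))))
}
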
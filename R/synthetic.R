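#' Build a reference peptide structure
#'
#' Deterministically constructs a geometrically plausible extended chain:
#' consecutive alpha carbons exactly 3.8 Angstrom apart, zigzagging in the
#' x-y plane as extended backbones do (so the chain is never collinear and
#' can serve as a superposition fit target), with a well-formed atom table
#' (residues numbered 1..n, single chain A, alanine residue names). The
#' synthetic generators perturb this reference to produce ensembles with
#' known fluctuation structure.
#'
#' @param n_residues number of residues (>= 1).
#' @param atoms_per_residue `"ca_only"` (one CA atom per residue, default) or
#'   `"backbone"` (N, CA, C, O per residue).
#' @return a one-frame [structure_ensemble()].
#' @export
#' @examples
#' make_reference_peptide(3)$atoms
make_reference_peptide <- function(n_residues,
                                   atoms_per_residue = c("ca_only",
                                                         "backbone")) {
  atoms_per_residue <- match.arg(atoms_per_residue)
  n_residues <- as.integer(n_residues)
  if (is.na(n_residues) || n_residues < 1L) {
    stop("n_residues must be a positive integer", call. = FALSE)
  }
  # zigzag of amplitude 0.95 A; x advance chosen so |CA(i+1)-CA(i)| = 3.8
  ca_y <- 0.95 * (-1)^(seq_len(n_residues) - 1L)
  ca_x <- sqrt(3.8^2 - 1.9^2) * (seq_len(n_residues) - 1L)
  if (atoms_per_residue == "ca_only") {
    coords <- cbind(ca_x, ca_y, 0)
    atoms <- tibble::tibble(
      elety = rep("CA", n_residues),
      resid = seq_len(n_residues),
      resname = "ALA", chain = "A", elesy = "C")
  } else {
    # offsets relative to each CA; rough but non-collinear backbone geometry
    offsets <- rbind(N = c(-1.46, 0.52, 0.00),
                     CA = c(0.00, 0.00, 0.00),
                     C = c(1.52, 0.45, 0.35),
                     O = c(1.70, 1.65, 0.55))
    coords <- do.call(rbind, lapply(seq_len(n_residues), function(i) {
      sweep(offsets, 2L, c(ca_x[i], ca_y[i], 0), "+")
    }))
    atoms <- tibble::tibble(
      elety = rep(rownames(offsets), n_residues),
      resid = rep(seq_len(n_residues), each = 4L),
      resname = "ALA", chain = "A",
      elesy = rep(c("N", "C", "C", "O"), n_residues))
  }
  structure_ensemble(coords_to_row(coords), atoms,
                     frame_labels = "reference",
                     source_kind = "model_set",
                     provenance = list(generator = "reference_peptide"))
}

# map a per-residue value vector onto atoms via their resid
per_atom_from_residue <- function(values, atoms) {
  res_levels <- unique(atoms$resid)
  if (length(values) == 1L) values <- rep(values, length(res_levels))
  if (length(values) != length(res_levels)) {
    stop("per-residue vector has length ", length(values), " but the ",
         "reference has ", length(res_levels), " residues", call. = FALSE)
  }
  values[match(atoms$resid, res_levels)]
}

#' Generate a Gaussian-jitter ensemble around a reference structure
#'
#' Every frame is the reference plus independent isotropic Gaussian noise,
#' with a per-residue per-coordinate scale `sigma` (Angstrom). Jitter is
#' uncorrelated across atoms, coordinates and frames, so the expected
#' fixed-reference eRMSF of a residue converges to `sigma * sqrt(3)` as the
#' segment size grows. All frames are jittered — the noiseless reference is
#' not a member frame. Fully deterministic for a given `seed`.
#'
#' @param reference a one-frame [structure_ensemble()] (see
#'   [make_reference_peptide()]).
#' @param sigma per-residue, per-coordinate noise scale in Angstrom: a single
#'   value (recycled) or one value per residue, all >= 0.
#' @param n_frames number of frames to generate.
#' @param seed integer RNG seed; the caller's RNG state is left untouched.
#' @return a [structure_ensemble()] with `source_kind = "trajectory"`.
#' @export
#' @examples
#' ref <- make_reference_peptide(4)
#' ens <- make_gaussian_ensemble(ref, sigma = 0.5, n_frames = 100, seed = 42)
make_gaussian_ensemble <- function(reference, sigma, n_frames, seed) {
  stopifnot(inherits(reference, "structure_ensemble"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 1L) {
    stop("n_frames must be a positive integer", call. = FALSE)
  }
  if (any(!is.finite(sigma)) || any(sigma < 0)) {
    stop("sigma must be finite and >= 0", call. = FALSE)
  }
  atom_sigma <- per_atom_from_residue(sigma, reference$atoms)
  col_sigma <- rep(atom_sigma, each = 3L)
  ref_row <- reference$xyz[1L, ]
  xyz <- with_preserved_seed(seed, {
    noise <- matrix(stats::rnorm(n_frames * length(ref_row)),
                    nrow = n_frames)
    sweep(noise, 2L, col_sigma, "*") +
      matrix(ref_row, n_frames, length(ref_row), byrow = TRUE)
  })
  structure_ensemble(xyz, reference$atoms,
                     source_kind = "trajectory",
                     provenance = list(generator = "gaussian",
                                       sigma = sigma, seed = seed))
}

#' Generate a two-state transition ensemble
#'
#' Emulates a trajectory containing a conformational transition: the first
#' `round(switch_fraction * n_frames)` frames sample state A (the reference
#' plus noise); the remaining frames sample state B, in which the atoms of
#' `displaced_residues` are shifted by `displacement` before noise is added.
#' Rounding is half-up. The 1-based index of the first state-B frame is
#' recorded in the provenance (`switch_frame`) so tests can assert on the
#' true transition location.
#'
#' @inheritParams make_gaussian_ensemble
#' @param displaced_residues residue numbers receiving the displacement.
#' @param displacement either a length-3 vector (Angstrom) applied to every
#'   displaced atom, or a single magnitude applied along x.
#' @param switch_fraction fraction of frames in state A, strictly in (0, 1).
#' @param noise_sigma isotropic per-coordinate noise scale, Angstrom (>= 0).
#' @return a [structure_ensemble()]; `provenance$switch_frame` holds the
#'   first state-B frame index, `provenance$n_state_a` the state-A frame
#'   count.
#' @export
#' @examples
#' ref <- make_reference_peptide(60)
#' ens <- make_transition_ensemble(ref, displaced_residues = 30:45,
#'                                 displacement = 8, switch_fraction = 0.4,
#'                                 noise_sigma = 0.3, n_frames = 100,
#'                                 seed = 11)
#' ens$provenance$switch_frame   # 41: frames 1-40 are state A
make_transition_ensemble <- function(reference, displaced_residues,
                                     displacement, switch_fraction,
                                     noise_sigma, n_frames, seed) {
  stopifnot(inherits(reference, "structure_ensemble"))
  n_frames <- as.integer(n_frames)
  if (is.na(n_frames) || n_frames < 2L) {
    stop("n_frames must be an integer >= 2", call. = FALSE)
  }
  if (!is.numeric(switch_fraction) || switch_fraction <= 0 ||
      switch_fraction >= 1) {
    stop("switch_fraction must lie strictly in (0, 1)", call. = FALSE)
  }
  if (!is.finite(noise_sigma) || noise_sigma < 0) {
    stop("noise_sigma must be finite and >= 0", call. = FALSE)
  }
  if (length(displacement) == 1L) displacement <- c(displacement, 0, 0)
  if (length(displacement) != 3L || any(!is.finite(displacement))) {
    stop("displacement must be a finite length-3 vector or a single ",
         "magnitude", call. = FALSE)
  }
  n_a <- as.integer(floor(switch_fraction * n_frames + 0.5))  # half-up
  n_a <- min(max(n_a, 1L), n_frames - 1L)
  mask <- reference$atoms$resid %in% displaced_residues
  if (!any(mask)) {
    stop("displaced_residues match no residues of the reference",
         call. = FALSE)
  }
  ref_row <- reference$xyz[1L, ]
  disp_row <- rep(0, length(ref_row))
  disp_row[xyz_cols(which(mask))] <- rep(displacement, times = sum(mask))
  xyz <- with_preserved_seed(seed, {
    noise <- matrix(stats::rnorm(n_frames * length(ref_row),
                                 sd = max(noise_sigma, .Machine$double.xmin)),
                    nrow = n_frames)
    if (noise_sigma == 0) noise[] <- 0
    base <- matrix(ref_row, n_frames, length(ref_row), byrow = TRUE)
    base[(n_a + 1L):n_frames, ] <-
      sweep(base[(n_a + 1L):n_frames, , drop = FALSE], 2L, disp_row, "+")
    base + noise
  })
  structure_ensemble(xyz, reference$atoms,
                     source_kind = "trajectory",
                     provenance = list(generator = "transition",
                                       switch_frame = n_a + 1L,
                                       n_state_a = n_a,
                                       displaced_residues = displaced_residues,
                                       displacement = displacement,
                                       noise_sigma = noise_sigma,
                                       seed = seed))
}
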
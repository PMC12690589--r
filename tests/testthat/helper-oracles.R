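# Independent oracles and fixture builders. Everything here recomputes the
# statistics straight from their definitions (plain loops, no shared code
# with the package internals) so tests compare two independent routes.

# random CA-chain ensemble: n_atoms single-CA residues, iid normal coords
random_ensemble <- function(n_atoms, n_frames, seed, sd = 1) {
  set.seed(seed)
  atoms <- tibble::tibble(
    elety = "CA", resid = seq_len(n_atoms), resname = "ALA",
    chain = "A", elesy = "C")
  structure_ensemble(matrix(rnorm(n_frames * 3 * n_atoms, sd = sd),
                            nrow = n_frames),
                     atoms)
}

# uniform random proper rotation from a normalized quaternion
random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - z * w), 2 * (x * z + y * w),
           2 * (x * y + z * w), 1 - 2 * (x^2 + z^2), 2 * (y * z - x * w),
           2 * (x * z - y * w), 2 * (y * z + x * w), 1 - 2 * (x^2 + y^2)),
         nrow = 3, byrow = TRUE)
}

# apply an independent random proper rigid transform to every frame
apply_random_rigid <- function(ensemble, seed, translation_sd = 10) {
  set.seed(seed)
  xyz <- ensemble$xyz
  for (f in seq_len(nrow(xyz))) {
    R <- random_rotation()
    tr <- rnorm(3, sd = translation_sd)
    fc <- matrix(xyz[f, ], ncol = 3, byrow = TRUE) %*% t(R)
    xyz[f, ] <- as.vector(t(sweep(fc, 2, tr, "+")))
  }
  structure_ensemble(xyz, ensemble$atoms, ensemble$frame_labels,
                     ensemble$source_kind)
}

# quaternion characteristic-polynomial superposition: minimal RMSD of
# mobile onto target via the largest eigenvalue of the Kearsley/Horn 4x4
# key matrix; independent of the SVD route used by the package
quaternion_superpose_rmsd <- function(mobile, target) {
  P <- sweep(mobile, 2, colMeans(mobile))
  Q <- sweep(target, 2, colMeans(target))
  S <- t(P) %*% Q
  Sxx <- S[1, 1]; Sxy <- S[1, 2]; Sxz <- S[1, 3]
  Syx <- S[2, 1]; Syy <- S[2, 2]; Syz <- S[2, 3]
  Szx <- S[3, 1]; Szy <- S[3, 2]; Szz <- S[3, 3]
  K <- matrix(c(
    Sxx + Syy + Szz, Syz - Szy,        Szx - Sxz,        Sxy - Syx,
    Syz - Szy,       Sxx - Syy - Szz,  Sxy + Syx,        Szx + Sxz,
    Szx - Sxz,       Sxy + Syx,       -Sxx + Syy - Szz,  Syz + Szy,
    Sxy - Syx,       Szx + Sxz,        Syz + Szy,       -Sxx - Syy + Szz),
    nrow = 4, byrow = TRUE)
  lambda_max <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(P^2) + sum(Q^2) - 2 * lambda_max) / nrow(P)
  sqrt(max(msd, 0))
}

# conventional RMSF by explicit double loop over atoms and frames
rmsf_loop_oracle <- function(ensemble, atom_idx = seq_len(n_atoms(ensemble))) {
  nf <- n_frames(ensemble)
  vapply(atom_idx, function(i) {
    pos <- t(vapply(seq_len(nf),
                    function(f) frame_coords(ensemble, f)[i, ],
                    numeric(3)))
    mu <- colMeans(pos)
    sqrt(mean(rowSums(sweep(pos, 2, mu)^2)))
  }, numeric(1))
}

# segment-resolved fixed-reference RMSF by explicit triple loop
ermsf_loop_oracle <- function(ensemble, ref_coords, segment_list,
                              atom_idx = seq_len(n_atoms(ensemble))) {
  out <- matrix(0, length(atom_idx), length(segment_list))
  for (ai in seq_along(atom_idx)) {
    i <- atom_idx[ai]
    for (s in seq_along(segment_list)) {
      frames <- segment_list[[s]]
      acc <- 0
      for (f in frames) {
        d <- frame_coords(ensemble, f)[i, ] - ref_coords[i, ]
        acc <- acc + sum(d^2)
      }
      out[ai, s] <- sqrt(acc / length(frames))
    }
  }
  out
}

# residue pooling recomputed from raw squared deviations, bypassing the
# package's per-atom intermediate
pooled_residue_oracle <- function(ensemble, ref_coords, segment_list,
                                  atom_idx) {
  resid_sel <- ensemble$atoms$resid[atom_idx]
  residues <- unique(resid_sel)
  out <- matrix(0, length(residues), length(segment_list))
  for (ri in seq_along(residues)) {
    members <- atom_idx[resid_sel == residues[ri]]
    for (s in seq_along(segment_list)) {
      frames <- segment_list[[s]]
      acc <- 0; cnt <- 0
      for (i in members) {
        for (f in frames) {
          d <- frame_coords(ensemble, f)[i, ] - ref_coords[i, ]
          acc <- acc + sum(d^2)
        }
        cnt <- cnt + length(frames)
      }
      out[ri, s] <- sqrt(acc / cnt)
    }
  }
  out
}
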
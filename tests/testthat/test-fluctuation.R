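test_that("mean_structure is the per-coordinate arithmetic mean", {
  ens <- random_ensemble(5, 100, seed = 1)
  mu <- mean_structure(ens)
  # naive double-loop oracle
  oracle <- matrix(0, 5, 3)
  for (i in 1:5) {
    for (f in 1:100) oracle[i, ] <- oracle[i, ] + frame_coords(ens, f)[i, ]
  }
  oracle <- oracle / 100
  expect_equal(mu, oracle, tolerance = 1e-12)

  # symmetry: one atom at +d and -d averages to the origin
  atoms <- tibble::tibble(elety = "CA", resid = 1L, resname = "ALA",
                          chain = "A")
  two <- structure_ensemble(rbind(c(2.5, 0, 0), c(-2.5, 0, 0)), atoms)
  expect_equal(mean_structure(two), matrix(0, 1, 3))
})

test_that("classic RMSF matches its definition", {
  # constant ensemble: zero everywhere
  atoms <- tibble::tibble(elety = "CA", resid = 1:3, resname = "ALA",
                          chain = "A")
  const <- structure_ensemble(matrix(rep(rnorm(9), each = 4), nrow = 4),
                              atoms)
  expect_equal(unname(rmsf_classic(const)), rep(0, 3))

  # one atom alternating between (d,0,0) and (-d,0,0): RMSF = d
  d <- 1.7
  alt <- structure_ensemble(
    matrix(c(d, 0, 0, -d, 0, 0, d, 0, 0, -d, 0, 0), nrow = 4, byrow = TRUE),
    atoms[1, ])
  expect_equal(unname(rmsf_classic(alt)), d)

  # random ensemble vs the explicit per-atom loop oracle
  ens <- random_ensemble(20, 50, seed = 3)
  expect_equal(unname(rmsf_classic(ens)), rmsf_loop_oracle(ens),
               tolerance = 1e-10)
})

test_that("eRMSF with skip 1 is the plain distance to the reference", {
  ens <- random_ensemble(6, 15, seed = 4)
  ref_coords <- frame_coords(ens, 1)
  core <- ermsf_atoms(ens, reference = ref_frame(1), segmentation = 1L)
  expect_equal(ncol(core$ermsf), 15L)
  for (s in c(1, 7, 15)) {
    dist <- sqrt(rowSums((frame_coords(ens, s) - ref_coords)^2))
    expect_equal(unname(core$ermsf[, s]), dist, tolerance = 1e-12)
  }
})

test_that("a 100-frame ensemble with skip 10 yields a 10-column matrix", {
  ens <- random_ensemble(4, 100, seed = 5)
  core <- ermsf_atoms(ens, segmentation = 10L)
  expect_equal(dim(core$ermsf), c(4L, 10L))
})

test_that("eRMSF matches the straight-from-definition triple loop", {
  for (seed in 1:5) {
    set.seed(seed)
    na <- sample(2:8, 1); nf <- sample(10:30, 1); skip <- sample(1:7, 1)
    ens <- random_ensemble(na, nf, seed = seed + 50)
    seg <- segment_frames(nf, skip)
    ref_coords <- frame_coords(ens, 1)
    core <- ermsf_atoms(ens, reference = ref_frame(1), segmentation = seg)
    oracle <- ermsf_loop_oracle(ens, ref_coords,
                                segrmsf:::segment_frame_indices(seg))
    expect_equal(unname(core$ermsf), oracle, tolerance = 1e-10)
  }
})

test_that("reference atom-count mismatch is a structural error", {
  ens <- random_ensemble(5, 10, seed = 6)
  expect_error(ermsf_atoms(ens, reference = matrix(0, 4, 3)),
               "structural mismatch")
})

test_that("residue pooling is the root mean of member squared deviations", {
  # two atoms in one residue with per-atom squared means a and b
  atoms <- tibble::tibble(elety = c("CA", "CB"), resid = 1L,
                          resname = "ALA", chain = "A", insert = "")
  sq <- matrix(c(1.2, 3.4), nrow = 2,
               dimnames = list(NULL, "segment_1"))
  sel <- structure(list(expression = "all", indices = 1:2),
                   class = "atom_selection")
  red <- segrmsf:::group_reduce(sq, grouping_spec("residue"), atoms, sel)
  expect_equal(unname(drop(red$matrix)), sqrt((1.2 + 3.4) / 2))

  # single-atom residues reduce to the identity
  ens <- random_ensemble(4, 12, seed = 7)
  res_atom <- run_ermsf(ens, selection = "all", skip = 4, align = FALSE,
                        group_by = "atom")
  res_res <- run_ermsf(ens, selection = "all", skip = 4, align = FALSE,
                       group_by = "residue")
  expect_equal(unname(res_res$matrix), unname(res_atom$matrix))
})

test_that("pooling matches a flat recomputation from raw deviations", {
  ref <- make_reference_peptide(5, atoms_per_residue = "backbone")
  ens <- make_gaussian_ensemble(ref, sigma = c(0.2, 0.5, 0.8, 0.4, 1.1),
                                n_frames = 24, seed = 8)
  seg <- segment_frames(24, 6)
  res <- run_ermsf(ens, selection = "all", skip = 6, align = FALSE,
                   group_by = "residue")
  oracle <- pooled_residue_oracle(ens, frame_coords(ens, 1),
                                  segrmsf:::segment_frame_indices(seg),
                                  seq_len(n_atoms(ens)))
  expect_equal(unname(res$matrix), oracle, tolerance = 1e-12)
})

test_that("region grouping pools its members and rejects outside atoms", {
  ref <- make_reference_peptide(10)
  ens <- make_gaussian_ensemble(ref, sigma = 0.5, n_frames = 20, seed = 9)
  res <- run_ermsf(ens, selection = "name CA", skip = 20, align = FALSE,
                   group_by = "region",
                   regions = list(head = "resid 1-3", tail = "resid 8-10"))
  expect_equal(rownames(res$matrix), c("head", "tail"))
  atom_res <- run_ermsf(ens, selection = "name CA", skip = 20,
                        align = FALSE, group_by = "atom")
  expect_equal(res$matrix["head", 1],
               sqrt(mean(atom_res$matrix[1:3, 1]^2)), tolerance = 1e-12)

  expect_error(
    run_ermsf(ens, selection = "resid 1-5", skip = 20, align = FALSE,
              group_by = "region", regions = list(bad = "resid 6-7")),
    "outside the analysis selection")
})

test_that("average profile modes behave as documented", {
  ens <- random_ensemble(3, 30, seed = 10)
  # single segment: mean_of_segments equals the only column
  one <- run_ermsf(ens, selection = "all", skip = 30, align = FALSE,
                   group_by = "atom", average_mode = "mean_of_segments")
  expect_equal(unname(one$average_profile), unname(one$matrix[, 1]))

  # hand-checkable arithmetic on a 2x2 matrix
  fake <- one
  fake$matrix <- matrix(c(1, 2, 3, 2), nrow = 2)
  expect_equal(unname(rowMeans(fake$matrix)), c(2, 2))

  # default mode: classic_rmsf when the reference is the mean structure
  mres <- run_ermsf(ens, selection = "all", reference = "mean", skip = 30,
                    align = FALSE, group_by = "atom")
  expect_equal(mres$average_mode, "classic_rmsf")
  expect_equal(unname(mres$average_profile), unname(rmsf_classic(ens)),
               tolerance = 1e-12)
  fres <- run_ermsf(ens, selection = "all", reference = 1, skip = 30,
                    align = FALSE, group_by = "atom")
  expect_equal(fres$average_mode, "mean_of_segments")
})

test_that("collapse identity: one segment about the mean equals classic RMSF", {
  ens <- random_ensemble(10, 30, seed = 11)
  res <- run_ermsf(ens, selection = "all", reference = "mean", skip = 30,
                   align = FALSE, group_by = "atom")
  expect_equal(unname(drop(res$matrix)), unname(rmsf_classic(ens)),
               tolerance = 1e-12)
})

test_that("eRMSF is non-negative, zero only for zero deviations", {
  ref <- make_reference_peptide(6)
  const <- make_gaussian_ensemble(ref, sigma = 0, n_frames = 100, seed = 12)
  res <- run_ermsf(const, selection = "name CA", skip = 10, align = FALSE)
  expect_true(all(res$matrix == 0))

  noisy <- make_gaussian_ensemble(ref, sigma = 0.3, n_frames = 100,
                                  seed = 13)
  res2 <- run_ermsf(noisy, selection = "name CA", skip = 10, align = FALSE)
  expect_true(all(res2$matrix > 0))
})

test_that("rigid transforms of one structure give zeros after alignment", {
  ref <- make_reference_peptide(8)
  base <- make_gaussian_ensemble(ref, sigma = 0, n_frames = 10, seed = 14)
  moved <- apply_random_rigid(base, seed = 15)
  res <- run_ermsf(moved, selection = "name CA", skip = 2, align = TRUE)
  expect_lt(max(res$matrix), 1e-8)
})

test_that("permuting frames within a segment leaves its column unchanged", {
  ens <- random_ensemble(5, 40, seed = 16)
  res <- run_ermsf(ens, selection = "all", skip = 10, align = FALSE,
                   group_by = "atom")
  set.seed(17)
  perm <- c(sample(1:10), 11:40)          # shuffle only segment 1
  shuffled <- structure_ensemble(ens$xyz[perm, ], ens$atoms,
                                 ens$frame_labels[perm])
  # keep the same reference coordinates (frame 1 may move under the permutation)
  res2 <- run_ermsf(shuffled, selection = "all",
                    reference = frame_coords(ens, 1), skip = 10,
                    align = FALSE, group_by = "atom")
  res1 <- run_ermsf(ens, selection = "all",
                    reference = frame_coords(ens, 1), skip = 10,
                    align = FALSE, group_by = "atom")
  expect_equal(res2$matrix[, 1], res1$matrix[, 1], tolerance = 1e-12)
})

test_that("added zero-mean jitter does not decrease eRMSF on average", {
  ref <- make_reference_peptide(6)
  base <- make_gaussian_ensemble(ref, sigma = 0.3, n_frames = 300, seed = 18)
  mean_base <- mean(run_ermsf(base, selection = "name CA", skip = 50,
                              align = FALSE)$matrix)
  extra <- vapply(1:5, function(s) {
    set.seed(100 + s)
    noisy <- structure_ensemble(
      base$xyz + matrix(rnorm(length(base$xyz), sd = 0.3),
                        nrow = nrow(base$xyz)),
      base$atoms, base$frame_labels)
    mean(run_ermsf(noisy, selection = "name CA",
                   reference = frame_coords(base, 1), skip = 50,
                   align = FALSE)$matrix)
  }, numeric(1))
  expect_true(all(extra > mean_base))
})

test_that("pipeline errors are tagged with their stage", {
  ens <- random_ensemble(5, 10, seed = 19)
  expect_error(run_ermsf(ens, start = 20), "^slice: ")
  expect_error(run_ermsf(ens, selection = "name XX"), "^selection: ")
  expect_error(run_ermsf(ens, selection = "all", reference = 99,
                         align = FALSE), "^ermsf: ")
})

test_that("two-state ensembles separate pre- and post-switch segments", {
  ref <- make_reference_peptide(60)
  ens <- make_transition_ensemble(ref, displaced_residues = 30:45,
                                  displacement = 8, switch_fraction = 0.4,
                                  noise_sigma = 0.3, n_frames = 100,
                                  seed = 20)
  res <- run_ermsf(ens, selection = "name CA", reference = 1, skip = 10)
  region <- res$groups$resid %in% 30:45
  col_means <- colMeans(res$matrix[region, ])
  switch_seg <- ceiling(ens$provenance$switch_frame / 10)
  pre <- col_means[seq_len(switch_seg - 1)]
  post <- col_means[switch_seg:length(col_means)]
  expect_true(max(pre) < min(post))

  # oracle route: direct fixed-reference loop on the generating coordinates
  seg <- segment_frames(100, 10)
  idx_ca <- select_atoms(ens, "name CA")$indices
  aligned <- align_ensemble(ens, fit_selection = "name CA")
  oracle <- ermsf_loop_oracle(aligned, frame_coords(aligned, 1),
                              segrmsf:::segment_frame_indices(seg),
                              atom_idx = idx_ca)
  expect_equal(unname(res$matrix), oracle, tolerance = 1e-10)
})
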
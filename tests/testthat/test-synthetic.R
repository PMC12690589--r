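test_that("reference peptide geometry is exact and deterministic", {
  pep <- make_reference_peptide(3)
  expect_equal(n_atoms(pep), 3L)
  expect_equal(pep$atoms$resid, 1:3)
  ca <- frame_coords(pep, 1)
  expect_equal(sqrt(rowSums(diff(ca)^2)), rep(3.8, 2))

  bb <- make_reference_peptide(2, atoms_per_residue = "backbone")
  expect_equal(n_atoms(bb), 8L)
  expect_equal(trimws(bb$atoms$elety), rep(c("N", "CA", "C", "O"), 2))
  expect_identical(make_reference_peptide(5)$xyz,
                   make_reference_peptide(5)$xyz)
})

test_that("gaussian generator is seed-deterministic and sigma-faithful", {
  ref <- make_reference_peptide(5)
  a <- make_gaussian_ensemble(ref, sigma = 0.5, n_frames = 50, seed = 7)
  b <- make_gaussian_ensemble(ref, sigma = 0.5, n_frames = 50, seed = 7)
  expect_identical(a$xyz, b$xyz)
  c_ <- make_gaussian_ensemble(ref, sigma = 0.5, n_frames = 50, seed = 8)
  expect_false(identical(a$xyz, c_$xyz))

  zero <- make_gaussian_ensemble(ref, sigma = 0, n_frames = 20, seed = 1)
  expect_true(all(zero$xyz == matrix(ref$xyz[1, ], 20, ncol(ref$xyz),
                                     byrow = TRUE)))

  # sample per-coordinate standard deviation close to sigma per residue
  big <- make_gaussian_ensemble(ref, sigma = 0.5, n_frames = 10000,
                                seed = 2)
  dev <- big$xyz - matrix(ref$xyz[1, ], 10000, ncol(ref$xyz), byrow = TRUE)
  for (atom in 1:5) {
    sds <- apply(dev[, segrmsf:::xyz_cols(atom)], 2,
                 function(x) sqrt(mean(x^2)))
    expect_true(all(abs(sds - 0.5) / 0.5 < 0.02))
  }

  # per-residue sigma vector maps onto the right atoms
  shaped <- make_gaussian_ensemble(ref, sigma = c(0, 1, 0, 1, 0),
                                   n_frames = 200, seed = 3)
  dev2 <- shaped$xyz - matrix(ref$xyz[1, ], 200, ncol(ref$xyz),
                              byrow = TRUE)
  expect_true(all(dev2[, segrmsf:::xyz_cols(1)] == 0))
  expect_gt(stats::sd(dev2[, segrmsf:::xyz_cols(2)[1]]), 0.8)
})

test_that("generator RNG use does not disturb the caller's stream", {
  ref <- make_reference_peptide(3)
  set.seed(99)
  before <- rnorm(3)
  set.seed(99)
  invisible(make_gaussian_ensemble(ref, 0.5, 10, seed = 1))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("transition generator places the switch by half-up rounding", {
  ref <- make_reference_peptide(10)
  ens <- make_transition_ensemble(ref, displaced_residues = 4:6,
                                  displacement = 5, switch_fraction = 0.4,
                                  noise_sigma = 0, n_frames = 100, seed = 4)
  expect_equal(ens$provenance$n_state_a, 40L)
  expect_equal(ens$provenance$switch_frame, 41L)
  # noiseless: frames 1-40 equal the reference, 41-100 are displaced
  ref_row <- matrix(ref$xyz[1, ], 100, ncol(ref$xyz), byrow = TRUE)
  delta <- ens$xyz - ref_row
  expect_true(all(delta[1:40, ] == 0))
  moved_cols <- segrmsf:::xyz_cols(which(ref$atoms$resid %in% 4:6))
  expect_true(all(delta[41:100, moved_cols[seq(1, length(moved_cols),
                                               by = 3)]] == 5))
  expect_true(all(delta[41:100, -moved_cols] == 0))

  # half-up: 0.45 of 10 frames -> 5 state-A frames (banker's would give 4)
  ens2 <- make_transition_ensemble(ref, 4:6, 5, switch_fraction = 0.45,
                                   noise_sigma = 0, n_frames = 10, seed = 5)
  expect_equal(ens2$provenance$n_state_a, 5L)
})

test_that("zero displacement gives statistically indistinguishable halves", {
  ref <- make_reference_peptide(8)
  ens <- make_transition_ensemble(ref, displaced_residues = 3:5,
                                  displacement = 0, switch_fraction = 0.4,
                                  noise_sigma = 0.4, n_frames = 400,
                                  seed = 6)
  res <- run_ermsf(ens, selection = "name CA",
                   reference = frame_coords(ref, 1), skip = 40,
                   align = FALSE)
  col_means <- colMeans(res$matrix)
  # all columns estimate sigma*sqrt(3); spread stays within sampling error
  expect_lt(diff(range(col_means)) / mean(col_means), 0.15)
})

test_that("written fixtures reload to near-identical fluctuations", {
  ref <- make_reference_peptide(12)
  ens <- make_transition_ensemble(ref, displaced_residues = 5:8,
                                  displacement = 6, switch_fraction = 0.5,
                                  noise_sigma = 0.3, n_frames = 40,
                                  seed = 7)
  path <- withr::local_tempfile(fileext = ".pdb")
  write_ensemble_pdb(ens, path)
  back <- read_model_set(path)
  a <- run_ermsf(ens, selection = "name CA", skip = 10, align = FALSE)
  b <- run_ermsf(back, selection = "name CA", skip = 10, align = FALSE)
  expect_lt(max(abs(a$matrix - b$matrix)), 2e-3)
})
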
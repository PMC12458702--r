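test_that("PDB round trip preserves atoms and coordinates", {
  sp <- synthetic_spec(seed = 3, domain_sizes = c(8, 6))
  toy <- make_toy_protein(sp)
  path <- tempfile(fileext = ".pdb")
  write_structure(toy, path)
  back <- read_structure(path)
  expect_equal(nrow(back$atoms), nrow(toy$atoms))
  expect_equal(n_frames(back), 1L)
  # PDB stores 3 decimals
  expect_lt(max(abs(get_frame(back) - get_frame(toy))), 1e-3)

  sp2 <- synthetic_spec(seed = 3, n_frames = 2, domain_sizes = c(8, 6),
                        domain_sigma = 0.5)
  ens2 <- make_ensemble(sp2)
  path2 <- tempfile(fileext = ".pdb")
  write_structure(ens2, path2)
  expect_equal(n_frames(read_structure(path2)), 2L)
})

test_that("malformed multi-model PDB with mismatched atom counts errors", {
  lines <- c(
    "MODEL        1",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  ALA A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ENDMDL",
    "END")
  path <- tempfile(fileext = ".pdb")
  writeLines(lines, path)
  expect_error(read_structure(path))
  expect_error(read_structure(tempfile(fileext = ".pdb")), "no such file")
})

test_that("superposition removes rigid motion and minimises RMSD", {
  set.seed(11)
  X <- matrix(rnorm(30), 10, 3)
  expect_equal(superpose(X, X)$rmsd, 0, tolerance = 1e-12)
  expect_equal(superpose(sweep(X, 2L, c(10, 0, 0), `+`), X)$rmsd, 0,
               tolerance = 1e-9)
  R <- random_rotation(5)
  expect_equal(superpose(apply_rigid(X, R, c(3, -2, 7)), X)$rmsd, 0,
               tolerance = 1e-9)
  expect_error(superpose(X[1:2, ], X[1:2, ]), ">= 3")
  line <- cbind(0:3, 0, 0)
  expect_error(superpose(line, line), "collinear")
})

test_that("Kabsch RMSD agrees with a rotation-grid-search oracle", {
  # two 4-point configurations, one point displaced off the reference
  P <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1.5, 0), c(0, 0, 2))
  Q <- P; Q[4, ] <- Q[4, ] + c(0.8, -0.5, 1.1)
  fitted <- superpose(P, Q)$rmsd
  # oracle: minimise RMSD over rotations (Euler angles) and translations
  # by direct numerical optimisation, independent of the SVD route
  obj <- function(par) {
    ca <- cos(par[1:3]); sa <- sin(par[1:3])
    Rx <- rbind(c(1, 0, 0), c(0, ca[1], -sa[1]), c(0, sa[1], ca[1]))
    Ry <- rbind(c(ca[2], 0, sa[2]), c(0, 1, 0), c(-sa[2], 0, ca[2]))
    Rz <- rbind(c(ca[3], -sa[3], 0), c(sa[3], ca[3], 0), c(0, 0, 1))
    M <- sweep(P %*% t(Rz %*% Ry %*% Rx), 2L, par[4:6], `+`)
    sqrt(mean(rowSums((M - Q)^2)))
  }
  best <- Inf
  for (s in 1:20) {
    set.seed(s)
    o <- stats::optim(c(runif(3, -pi, pi), rnorm(3)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(fitted, best, tolerance = 1e-3)
  expect_lte(fitted, best + 1e-9)   # Kabsch is the true minimum
})

test_that("RMSD is symmetric on random frames", {
  for (s in 1:5) {
    set.seed(s)
    A <- matrix(rnorm(60), 20, 3)
    B <- matrix(rnorm(60), 20, 3)
    expect_equal(frame_rmsd(A, B), frame_rmsd(B, A), tolerance = 1e-9)
  }
})

test_that("RMSF matches hand computation and rigid-motion invariance", {
  # static ensemble
  X <- matrix(rnorm(15), 5, 3)
  ens <- ca_ensemble(list(X, X, X))
  expect_true(all(rmsf(ens, fit = FALSE) == 0))
  # one atom alternating between (0,0,0) and (2,0,0): RMSF = 1
  f1 <- matrix(c(0, 0, 0), 1, 3); f2 <- matrix(c(2, 0, 0), 1, 3)
  ens1 <- ca_ensemble(list(f1, f2))
  expect_equal(unname(rmsf(ens1, fit = FALSE)), 1.0)
  # rigid-body translated frames with fitting: zero
  ens2 <- ca_ensemble(list(X, sweep(X, 2L, c(5, 5, 5), `+`)))
  expect_lt(max(rmsf(ens2, fit = TRUE)), 1e-9)
  # rotation+translation invariance of the profile
  set.seed(4)
  frames <- lapply(1:6, function(k) X + matrix(rnorm(15, sd = 0.3), 5, 3))
  base_prof <- rmsf(ca_ensemble(frames), fit = TRUE)
  R <- random_rotation(9)
  moved <- lapply(frames, function(f) apply_rigid(f, R, c(1, 2, 3)))
  expect_equal(rmsf(ca_ensemble(moved), fit = TRUE), base_prof,
               tolerance = 1e-6)
  expect_error(rmsf(ca_ensemble(X)), ">= 2 frames")
})

test_that("radius of gyration matches closed forms", {
  expect_equal(as.numeric(radius_of_gyration(matrix(c(1, 2, 3), 1, 3))), 0)
  two <- rbind(c(0, 0, 0), c(2, 0, 0))
  expect_equal(as.numeric(radius_of_gyration(two)), 1.0)
  cube <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  expect_equal(as.numeric(radius_of_gyration(cube)), sqrt(3))
  R <- random_rotation(2)
  expect_equal(as.numeric(radius_of_gyration(apply_rigid(cube, R, c(9, 9, 9)))),
               sqrt(3), tolerance = 1e-9)
  expect_error(radius_of_gyration(cube, sel = integer()), "empty")
})

test_that("frame clustering recovers planted conformers and populations", {
  # conformer A: compact helix-ish shape; conformer B: displaced subset
  set.seed(21)
  base <- matrix(rnorm(30), 10, 3) * 2
  confB <- base; confB[1:5, ] <- confB[1:5, ] + 12   # ~8 A+ RMSD apart
  frames <- c(lapply(1:6, function(i) base + matrix(rnorm(30, sd = 0.1), 10, 3)),
              lapply(1:4, function(i) confB + matrix(rnorm(30, sd = 0.1), 10, 3)))
  ens <- ca_ensemble(frames)
  cl <- cluster_frames(ens, epsilon = 3.0)
  expect_equal(nrow(cl$representatives), 2L)
  expect_equal(cl$representatives$population, c(0.6, 0.4))
  expect_true(all(cl$assignments[1:6] == 1L))
  expect_true(all(cl$assignments[7:10] == 2L))
  # representative belongs to its cluster
  for (i in seq_len(nrow(cl$representatives))) {
    expect_equal(cl$assignments[cl$representatives$frame[i]],
                 cl$representatives$cluster[i])
  }
  # identical frames: one cluster
  same <- ca_ensemble(rep(list(base), 10))
  cl1 <- cluster_frames(same, epsilon = 3.0)
  expect_equal(nrow(cl1$representatives), 1L)
  expect_equal(cl1$representatives$population, 1.0)
  # epsilon above any distance: one cluster
  expect_equal(nrow(cluster_frames(ens, epsilon = 100)$representatives), 1L)
  expect_error(cluster_frames(ens, epsilon = 0), "epsilon")
})

test_that("cluster assignments are stable under frame permutation", {
  set.seed(33)
  base <- matrix(rnorm(24), 8, 3) * 2
  confB <- base + 10
  frames <- c(lapply(1:5, function(i) base + matrix(rnorm(24, sd = 0.2), 8, 3)),
              lapply(1:5, function(i) confB + matrix(rnorm(24, sd = 0.2), 8, 3)))
  perm <- sample(10)
  cl_a <- cluster_frames(ca_ensemble(frames), epsilon = 3)
  cl_b <- cluster_frames(ca_ensemble(frames[perm]), epsilon = 3)
  # same partition of frames up to relabelling
  part_a <- split(seq_len(10), cl_a$assignments)
  part_b <- split(perm, cl_b$assignments)
  norm <- function(p) unname(lapply(p, sort))
  expect_setequal(sapply(norm(part_a), paste, collapse = ","),
                  sapply(norm(part_b), paste, collapse = ","))
})

test_that("domain partitions validate overlaps and unknown residues", {
  expect_error(domain_partition(A = 0:4, B = 3:8), "overlap")
  expect_error(domain_partition(A = 0:4, A = 5:8), "unique")
  p <- domain_partition(A = 0:4, B = 5:8)
  at <- data.frame(atom_id = 1:5, name = "CA", element = "C",
                   residue_index = 0:4, residue_name = "ALA", chain_id = "A")
  expect_error(ensemble(at, matrix(0, 5, 3), partition = p), "absent")
})
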
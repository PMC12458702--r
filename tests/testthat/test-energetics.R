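# two point charges in residues 0 and 2 (sequence separation 2, so the
# pair enters the energy matrix)
charged_pair <- function(q1, q2, r, sigma = 0, eps = 0) {
  tab <- data.frame(name = c("Q1", "CA", "Q2"), element = "C",
                    residue_index = c(0L, 1L, 2L),
                    residue_name = "GLY", stringsAsFactors = FALSE)
  fr <- rbind(c(0, 0, 0), c(500, 500, 500), c(r, 0, 0))
  ens <- atom_ensemble(tab, fr)
  ens$atoms$charge <- c(q1, 0, q2)
  ens$atoms$sigma <- c(sigma, 0, sigma)
  ens$atoms$epsilon <- c(eps, 0, eps)
  ens
}

test_that("Coulomb term reproduces the closed form", {
  ens <- charged_pair(1, -1, 3.32)
  pe <- pairwise_energy(ens, cutoff = 10)
  expect_equal(pe$total["0", "2"], -332.0637 / 3.32, tolerance = 1e-9)
  expect_equal(pe$total["0", "2"], -100.0, tolerance = 0.1)
  expect_equal(pe$total, t(pe$total))
  # linear scaling in each charge
  pe2 <- pairwise_energy(charged_pair(2, -1, 3.32), cutoff = 10)
  expect_equal(pe2$electrostatic["0", "2"],
               2 * pe$electrostatic["0", "2"], tolerance = 1e-9)
  # distance-dependent dielectric divides by an extra r
  ped <- pairwise_energy(ens, cutoff = 10, solvation = "ddd")
  expect_equal(ped$electrostatic["0", "2"],
               pe$electrostatic["0", "2"] / 3.32, tolerance = 1e-9)
})

test_that("zero parameters and cutoff behave per contract", {
  ens <- charged_pair(0, 0, 3.0)
  expect_equal(sum(abs(pairwise_energy(ens)$total)), 0)
  # pair beyond cutoff contributes exactly zero
  far <- charged_pair(1, -1, 12)
  expect_equal(sum(abs(pairwise_energy(far, cutoff = 10)$total)), 0)
  expect_error(pairwise_energy(ens, cutoff = -1), "cutoff")
  noq <- ens; noq$atoms$charge <- NULL
  expect_error(pairwise_energy(noq), "parameters")
})

test_that("Lennard-Jones minimum is -epsilon at 2^(1/6) sigma", {
  sig <- 3.4; eps <- 0.25
  r_min <- 2^(1 / 6) * sig
  ens <- charged_pair(0, 0, r_min, sigma = sig, eps = eps)
  pe <- pairwise_energy(ens, cutoff = 10)
  expect_equal(pe$vdw["0", "2"], -eps, tolerance = 1e-9)
})

test_that("sequence-adjacent residues are excluded from the matrix", {
  tab <- data.frame(name = c("Q1", "Q2"), element = "C",
                    residue_index = c(0L, 1L), residue_name = "GLY")
  ens <- atom_ensemble(tab, rbind(c(0, 0, 0), c(3, 0, 0)))
  ens$atoms$charge <- c(1, -1); ens$atoms$sigma <- 0; ens$atoms$epsilon <- 0
  expect_equal(sum(abs(pairwise_energy(ens)$total)), 0)
})

test_that("eigen analysis recovers planted structure", {
  # rank-1 planted matrix -5 v v^T
  set.seed(6)
  v <- abs(rnorm(12)); v <- v / sqrt(sum(v^2))
  M <- -5 * tcrossprod(v)
  ed <- edm_eigen(M)
  expect_gt(abs(sum(ed$first_eigenvector * v)), 0.999)
  expect_equal(abs(ed$eigenvalues[1]), 5, tolerance = 1e-9)
  expect_gte(sum(ed$first_eigenvector), 0)
  expect_equal(sqrt(sum(ed$first_eigenvector^2)), 1, tolerance = 1e-12)
  # zero matrix: degenerate flag, zero profile
  edz <- edm_eigen(matrix(0, 5, 5))
  expect_true(edz$degenerate)
  expect_equal(sum(edz$profile), 0)
  # two planted blocks: profile concentrates on the deep block
  sp <- synthetic_spec(seed = 4, domain_sizes = c(30),
                       energy_blocks = list(list(residues = 0:7, depth = -5),
                                            list(residues = 10:17, depth = -1)),
                       energy_noise = 0.01)
  M2 <- make_energy_matrix(sp, n = 30)
  ed2 <- edm_eigen(M2)
  top8 <- order(-ed2$profile)[1:8]
  expect_setequal(as.integer(names(ed2$profile)[top8]), 0:7)
  expect_error(edm_eigen(matrix(1:9, 3, 3)), "symmetric")
})

test_that("nuclei threshold is inclusive and counts interacting pairs", {
  prof <- c(0.004, 0.005, 0.006)
  M <- matrix(0.1, 3, 3); diag(M) <- 0
  dimnames(M) <- list(0:2, 0:2)
  fake <- structure(list(matrix = M, profile = stats::setNames(prof, 0:2)),
                    class = "edm")
  part <- domain_partition(D = 0:2)
  nuc <- electrostatic_nuclei(fake, part)
  expect_setequal(nuc$residues, c(1L, 2L))
  expect_equal(unname(nuc$intradomain_counts["D"]), 1L)  # pair (1,2)
  expect_error(electrostatic_nuclei(fake, part, threshold = -1), "threshold")
  # zero matrix: empty set
  edz <- edm_eigen(matrix(0, 3, 3))
  expect_length(electrostatic_nuclei(edz, part, threshold = 0.005)$residues, 0)
  # planted deep block: counts verified against brute-force enumeration
  sp <- synthetic_spec(seed = 4, domain_sizes = c(20),
                       energy_blocks = list(list(residues = 0:7, depth = -5)))
  M2 <- make_energy_matrix(sp, n = 20)
  dimnames(M2) <- list(0:19, 0:19)
  ed2 <- edm_eigen(M2)
  part2 <- domain_partition(A = 0:9, B = 10:19)
  nuc2 <- electrostatic_nuclei(ed2, part2, threshold = 0.005)
  brute <- 0L
  keep <- nuc2$residues[nuc2$residues %in% 0:9]
  for (i in seq_along(keep)) for (j in seq_along(keep)) {
    if (i < j && abs(M2[keep[i] + 1, keep[j] + 1]) > 0) brute <- brute + 1L
  }
  expect_equal(unname(nuc2$intradomain_counts["A"]), brute)
  expect_gt(brute, 0L)
})

test_that("interdomain energies average over frames", {
  tab <- data.frame(name = c("Q1", "CA", "Q2"), element = "C",
                    residue_index = c(0L, 1L, 2L), residue_name = "GLY")
  f1 <- rbind(c(0, 0, 0), c(500, 500, 500), c(4, 0, 0))
  f2 <- rbind(c(0, 0, 0), c(500, 500, 500), c(4 / 3, 0, 0))  # E scales by 3
  ens <- atom_ensemble(tab, list(f1, f2))
  ens$atoms$charge <- c(1, 0, -1); ens$atoms$sigma <- 0; ens$atoms$epsilon <- 0
  ens$partition <- domain_partition(A = 0:1, B = 2L)
  e1 <- -332.0637 / 4
  tbl <- interdomain_energy(ens)
  expect_equal(nrow(tbl), 1L)
  expect_equal(tbl$total, 2 * e1, tolerance = 1e-9)
  expect_equal(tbl$total, tbl$electrostatic + tbl$vdw, tolerance = 1e-9)
  # single frame equals the direct aggregation
  tbl1 <- interdomain_energy(ens, frames = 1L)
  expect_equal(tbl1$total, e1, tolerance = 1e-9)
  # fully separated domains: no entries
  farens <- ens
  farens$coords[3, 1, ] <- 500
  expect_equal(nrow(interdomain_energy(farens)), 0L)
})

test_that("protein-RNA interface counts contacts and signs energies", {
  tab <- data.frame(name = c("Q1", "Q2", "Q3", "P1", "P2"),
                    element = c("C", "C", "C", "P", "P"),
                    residue_index = c(0L, 0L, 1L, 2L, 2L),
                    residue_name = c("GLY", "GLY", "GLY", "U", "U"))
  fr <- rbind(c(0, 0, 0), c(1.5, 0, 0), c(10, 10, 10),
              c(3, 0, 0), c(20, 20, 20))
  ens <- atom_ensemble(tab, fr, chain = c("A", "A", "A", "R", "R"),
                       rna_chain = "R")
  ens$atoms$charge <- c(1, 0, 0, -1, 0)
  ens$atoms$sigma <- 0; ens$atoms$epsilon <- 0
  ens$partition <- domain_partition(PIWI = 0:1)
  out <- protein_rna_interface(ens)
  # heavy-atom pairs within 4.5: Q1-P1 (3.0), Q2-P1 (1.5) -> 2 contacts
  expect_equal(out$contacts, 2L)
  expect_lt(out$energies$electrostatic[1], 0)   # opposite charges stabilise
  # RNA moved far away: no contacts, no energy
  far <- ens
  far$coords[4:5, , 1] <- far$coords[4:5, , 1] + 500
  out2 <- protein_rna_interface(far)
  expect_equal(out2$contacts, 0L)
  expect_equal(nrow(out2$energies), 0L)
  noRNA <- ens; noRNA$rna_chain <- NULL
  expect_error(protein_rna_interface(noRNA), "RNA")
})
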
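test_that("COM distances and angles match elementary geometry", {
  # groups A and B are single atoms; C balances the global COM at the origin
  ps <- list(list(name = "d_A_B", type = "distance", groups = c("A", "B")),
             list(name = "a_A_B", type = "angle", groups = c("A", "B")))
  mk <- function(pa, pb, extra) {
    part <- domain_partition(A = 0L, B = 1L,
                             C = 2:(1L + nrow(extra)))
    ca_ensemble(rbind(pa, pb, extra), partition = part)
  }
  # distance 5 (3-4-5)
  e1 <- mk(c(0, 0, 0), c(3, 4, 0), rbind(c(0, -2, 0), c(-3, -2, 0)))
  v1 <- compute_descriptors(e1, pair_spec = ps[1])$values
  expect_equal(unname(v1[1, "d_A_B"]), 5.0)
  # angle undefined when a group COM sits on the vertex (the global COM)
  expect_error(compute_descriptors(e1, pair_spec = ps), "degenerate")
  e2 <- mk(c(5, 0, 0), c(-5, 0, 0), rbind(c(1, 1, 0), c(-1, -1, 0)))
  v2 <- compute_descriptors(e2, pair_spec = ps)$values
  expect_equal(unname(v2[1, "a_A_B"]), 180)
  # perpendicular: 90 degrees
  e3 <- mk(c(1, 0, 0), c(0, 1, 0), rbind(c(-1, 0, 0), c(0, -1, 0)))
  v3 <- compute_descriptors(e3, pair_spec = ps)$values
  expect_equal(unname(v3[1, "a_A_B"]), 90)
})

test_that("descriptors are invariant under global rigid motion", {
  sp <- synthetic_spec(seed = 8, n_frames = 5, domain_sigma = 0.5)
  ens <- make_ensemble(sp)
  v0 <- compute_descriptors(ens)$values
  R <- random_rotation(3)
  moved <- ens
  for (k in 1:5) moved$coords[, , k] <-
    apply_rigid(ens$coords[, , k], R, c(11, -4, 2))
  expect_equal(compute_descriptors(moved)$values, v0, tolerance = 1e-9)
})

test_that("standardised PCA satisfies its algebraic identities", {
  sp <- synthetic_spec(seed = 3, n_frames = 120, domain_sigma = 0.5,
                       breathing = list(list(pair = c("PAZ", "MID"),
                                             amplitude = 5, period = 12)))
  m1 <- compute_descriptors(make_ensemble(sp, label = "a"))
  m2 <- compute_descriptors(make_ensemble(sp, seed = 99, label = "b"))
  p <- fit_pca(list(m1, m2))
  # variance fractions sum to 1; correlation-matrix trace identity
  expect_equal(sum(p$explained_variance), 1, tolerance = 1e-9)
  # reconstruction round-trip: scores %*% t(coefficients) = standardised data
  X <- rbind(m1$values, m2$values)
  Z <- scale(X)
  expect_equal(unname(p$scores %*% t(p$coefficients)), unname(Z),
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_equal(max(abs(colMeans(Z))), 0, tolerance = 1e-9)
  # sign convention: largest-|loading| coefficient positive
  for (j in seq_len(ncol(p$coefficients))) {
    expect_gte(p$coefficients[which.max(abs(p$coefficients[, j])), j], 0)
  }
  # planted 1-D structure dominates PC1
  set.seed(5)
  v <- rnorm(13); v <- v / sqrt(sum(v^2))
  latent <- rnorm(400, sd = 10)
  Xp <- outer(latent, v) + matrix(rnorm(400 * 13, sd = 0.1), 400, 13)
  colnames(Xp) <- descriptor_names()
  mk <- function(rows, lab) structure(
    list(values = Xp[rows, ], labels = rep(lab, length(rows)),
         descriptor_names = colnames(Xp)), class = "descriptor_matrix")
  p1 <- fit_pca(list(mk(1:200, "a"), mk(201:400, "b")))
  expect_gt(p1$explained_variance[1], 0.9)
  # zero-variance column rejected by name
  Xz <- Xp; Xz[, 2] <- 1
  mkz <- function(rows, lab) structure(
    list(values = Xz[rows, ], labels = rep(lab, length(rows)),
         descriptor_names = colnames(Xz)), class = "descriptor_matrix")
  expect_error(fit_pca(list(mkz(1:200, "a"), mkz(201:400, "b"))), "d_PAZ_N")
})

test_that("Calinski-Harabasz matches its definition and limits", {
  # W = 0 with distinct means: infinity sentinel
  pts <- rbind(c(0, 0), c(0, 0), c(5, 5), c(5, 5))
  expect_identical(calinski_harabasz(pts, c("a", "a", "b", "b")), Inf)
  expect_error(calinski_harabasz(pts, rep("a", 4)), ">= 2")
  # hand-evaluated small case
  pts2 <- rbind(c(0, 0), c(1, 0), c(4, 0), c(5, 0))
  lab2 <- c("a", "a", "b", "b")
  # means: a=(0.5,0), b=(4.5,0), overall (2.5,0)
  B <- 2 * (0.5 - 2.5)^2 + 2 * (4.5 - 2.5)^2
  W <- 4 * 0.25
  expect_equal(calinski_harabasz(pts2, lab2), (B / 1) / (W / 2))
  # null expectation ~1 for random labels on one cloud
  ch_null <- vapply(1:100, function(s) {
    set.seed(s)
    calinski_harabasz(matrix(rnorm(800), 400, 2),
                      sample(rep(c("a", "b"), 200)))
  }, 1.0)
  # E[CH] is ~1 under the null (individual draws are chi-square spread)
  expect_gt(mean(ch_null), 0.5); expect_lt(mean(ch_null), 2)
  expect_gt(stats::median(ch_null), 0.3); expect_lt(stats::median(ch_null), 2)
  # two clouds 10 SD apart: large score
  set.seed(1)
  far <- rbind(matrix(rnorm(400), 200, 2),
               matrix(rnorm(400, mean = 10), 200, 2))
  expect_gt(calinski_harabasz(far, rep(c("a", "b"), each = 200)), 100)
  # invariance: rotation of the projection and group relabelling
  R2 <- matrix(c(cos(1), sin(1), -sin(1), cos(1)), 2, 2)
  expect_equal(calinski_harabasz(far %*% R2, rep(c("a", "b"), each = 200)),
               calinski_harabasz(far, rep(c("a", "b"), each = 200)),
               tolerance = 1e-9)
  expect_equal(calinski_harabasz(far, rep(c("b", "a"), each = 200)),
               calinski_harabasz(far, rep(c("a", "b"), each = 200)))
})

test_that("discriminative selection recovers a planted label effect", {
  for (s in 1:3) {
    eff <- list(A = stats::setNames(numeric(0), character(0)),
                B = c(d_L1_L2 = 3.54),
                C = stats::setNames(numeric(0), character(0)),
                D = stats::setNames(numeric(0), character(0)))
    sp <- synthetic_spec(seed = 1000 + s, n_frames = 300,
                         domain_sigma = 0.5,
                         breathing = list(
                           list(pair = c("PAZ", "MID"), amplitude = 6,
                                period = 37),
                           list(pair = c("N", "PIWI"), amplitude = 4,
                                period = 23)),
                         label_effects = eff)
    dm <- lapply(make_labeled_set(sp, c("A", "B", "C", "D")),
                 compute_descriptors)
    sel <- select_discriminative(fit_pca(dm))
    expect_false(isTRUE(sel$no_qualifying_pair))
    expect_true(all(sel$top_pair >= 3))
    expect_true(all(sel$candidate_pairs$variance >= 0.15))
    expect_equal(sel$top_descriptors$descriptor[1], "d_L1_L2")
  }
})

test_that("selection reports no qualifying pair explicitly", {
  # one dominant direction: PCs beyond 2 carry almost no variance
  set.seed(2)
  v <- rnorm(13); v <- v / sqrt(sum(v^2))
  X <- outer(rnorm(300, sd = 50), v) + matrix(rnorm(300 * 13, sd = 1e-3),
                                              300, 13)
  colnames(X) <- descriptor_names()
  mk <- function(rows, lab) structure(
    list(values = X[rows, ], labels = rep(lab, length(rows)),
         descriptor_names = colnames(X)), class = "descriptor_matrix")
  sel <- select_discriminative(fit_pca(list(mk(1:150, "a"), mk(151:300, "b"))))
  expect_true(sel$no_qualifying_pair)
  expect_null(sel$top_pair)
  expect_equal(nrow(sel$candidate_pairs), 0L)
})
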
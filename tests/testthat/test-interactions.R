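# donor residue (backbone N-H) and acceptor residue (carbonyl O) with the
# donor at the origin, acceptor placed along +x at distance d, hydrogen on
# the N-O axis (angle 180) unless displaced
hb_fixture <- function(d_no, h_pos = c(1, 0, 0),
                       res_names = c("GLY", "GLY")) {
  tab <- data.frame(name = c("N", "H", "O"),
                    element = c("N", "H", "O"),
                    residue_index = c(0L, 0L, 1L),
                    residue_name = c(res_names[1], res_names[1], res_names[2]))
  atom_ensemble(tab, rbind(c(0, 0, 0), h_pos, c(d_no, 0, 0)))
}

test_that("hydrogen-bond criteria follow distance and angle cutoffs", {
  ev <- detect_hbonds(hb_fixture(2.9))
  expect_length(ev, 1L)
  expect_equal(ev[[1]]$persistence, 1.0)
  expect_equal(ev[[1]]$kind, "hbond")
  # distance failure at 3.5
  expect_length(detect_hbonds(hb_fixture(3.5)), 0L)
  # angle failure: H well off the axis (D-H...A = 120 deg), distance 2.8
  h <- c(cos(pi / 3), sin(pi / 3), 0)
  ang_fix <- hb_fixture(2.8, h_pos = h)
  fr <- get_frame(ang_fix)
  u <- fr[1, ] - fr[2, ]; v <- fr[3, ] - fr[2, ]
  ang <- acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
  expect_lt(ang, 160)
  expect_length(detect_hbonds(ang_fix), 0L)
  # no explicit hydrogens: instructive error
  tab <- data.frame(name = c("N", "O"), element = c("N", "O"),
                    residue_index = c(0L, 1L), residue_name = "GLY")
  bare <- atom_ensemble(tab, rbind(c(0, 0, 0), c(2.9, 0, 0)))
  expect_error(detect_hbonds(bare), "explicit hydrogens")
})

test_that("salt-bridge distance cutoff is inclusive", {
  sb_fixture <- function(d) {
    tab <- data.frame(name = c("NZ", "OD1"), element = c("N", "O"),
                      residue_index = c(0L, 1L),
                      residue_name = c("LYS", "ASP"))
    atom_ensemble(tab, rbind(c(0, 0, 0), c(d, 0, 0)))
  }
  expect_length(detect_saltbridges(sb_fixture(3.5)), 1L)
  expect_length(detect_saltbridges(sb_fixture(4.0)), 1L)   # boundary: <=
  expect_length(detect_saltbridges(sb_fixture(4.1)), 0L)
})

test_that("detection is invariant under global rigid motion", {
  fix <- hb_fixture(2.9)
  R <- random_rotation(17)
  moved <- fix
  moved$coords[, , 1] <- apply_rigid(fix$coords[, , 1], R, c(7, -3, 2))
  expect_length(detect_hbonds(moved), 1L)
})

test_that("persistence filtering applies exact retain/flag rules", {
  sp <- synthetic_spec(seed = 1, n_frames = 20,
                       bond_traces = list(list(occupancy = 0.30),
                                          list(occupancy = 0.05),
                                          list(occupancy = 0.00)))
  bsys <- make_bonded_system(sp)
  ev <- detect_hbonds(bsys)
  pt <- persistence_filter(ev, retain = 0.05, flag = 0.20, ens = bsys)
  expect_equal(nrow(pt$bonds), 2L)   # the 0-occupancy trace never appears
  expect_equal(sort(pt$bonds$persistence), c(0.05, 0.30))
  expect_identical(pt$bonds$flagged[pt$bonds$persistence == 0.30], TRUE)
  expect_identical(pt$bonds$flagged[pt$bonds$persistence == 0.05], FALSE)
  # persistence equals the mean of the trace and survives frame permutation
  expect_equal(ev[[1]]$persistence, mean(ev[[1]]$trace))
  perm <- sample(20)
  bsys_p <- bsys; bsys_p$coords <- bsys$coords[, , perm, drop = FALSE]
  ev_p <- detect_hbonds(bsys_p)
  expect_equal(sort(vapply(ev_p, `[[`, 1.0, "persistence")),
               sort(vapply(ev, `[[`, 1.0, "persistence")))
  expect_error(persistence_filter(list(list(kind = "hbond", res_a = 0L,
    atom_a = "N", res_b = 1L, atom_b = "O", trace = logical(0),
    persistence = NaN))), "empty")
})

test_that("equivalent-atom averaging merges persistences correctly", {
  tab <- data.frame(name = c("CB", "OD1", "OD2", "NH1"),
                    element = c("C", "O", "O", "N"),
                    residue_index = c(0L, 0L, 0L, 1L),
                    residue_name = c("ASP", "ASP", "ASP", "ARG"))
  ens <- atom_ensemble(tab, matrix(0, 4, 3))
  mk_ev <- function(atom, trace) list(kind = "saltbridge", res_a = 0L,
    atom_a = atom, res_b = 1L, atom_b = "NH1", trace = trace,
    persistence = mean(trace))
  t10 <- c(rep(TRUE, 2), rep(FALSE, 18))   # 0.10
  t20 <- c(rep(TRUE, 4), rep(FALSE, 16))   # 0.20
  merged <- average_equivalent(list(mk_ev("OD1", t10), mk_ev("OD2", t20)), ens)
  expect_length(merged, 1L)
  expect_equal(merged[[1]]$persistence, 0.15)
  expect_equal(merged[[1]]$atom_a, "ODx")
  # merged trace is the frame-wise OR
  expect_equal(sum(merged[[1]]$trace), 4L)
  # idempotent
  again <- average_equivalent(merged, ens)
  expect_equal(again[[1]]$persistence, 0.15)
  expect_length(again, 1L)
  # mean of equal persistences is unchanged
  m2 <- average_equivalent(list(mk_ev("OD1", t20), mk_ev("OD2", t20)), ens)
  expect_equal(m2[[1]]$persistence, 0.20)
  # atom without an equivalence class passes through untouched
  solo <- list(list(kind = "hbond", res_a = 0L, atom_a = "CB", res_b = 1L,
                    atom_b = "NH1", trace = t10, persistence = 0.10))
  expect_equal(average_equivalent(solo, ens)[[1]]$atom_a, "CB")
})

test_that("bond classification distinguishes intra- and inter-domain", {
  sp <- synthetic_spec(seed = 1, n_frames = 10,
                       bond_traces = list(list(occupancy = 1),
                                          list(occupancy = 1)))
  bsys <- make_bonded_system(sp)
  # trace 1 joins residues 0-1, trace 2 residues 2-3
  part <- domain_partition(A = 0:1, B = 2:3)
  pt <- persistence_filter(detect_hbonds(bsys), ens = bsys, partition = part)
  expect_true(all(pt$bonds$classification == "intra"))
  part2 <- domain_partition(A = c(0L, 2L), B = c(1L, 3L))
  pt2 <- persistence_filter(detect_hbonds(bsys), ens = bsys, partition = part2)
  expect_true(all(pt2$bonds$classification == "inter"))
})

test_that("intradomain hydrogen-bond counts report mean and spread", {
  # 4 permanent bonds inside domain A
  sp <- synthetic_spec(seed = 1, n_frames = 6,
                       bond_traces = rep(list(list(occupancy = 1)), 4))
  bsys <- make_bonded_system(sp)
  part <- domain_partition(A = 0:7, B = 8:9)
  # extend partition to cover all residues
  part <- domain_partition(A = 0:(max(bsys$atoms$residue_index)))
  tab <- count_intradomain_hbonds(bsys, part)
  expect_equal(tab$mean, 4)
  expect_equal(tab$sd, 0)
  # alternating 3/5 bonds: mean 4, population SD 1
  sp2 <- synthetic_spec(seed = 1, n_frames = 2,
                        bond_traces = list(list(occupancy = 1),
                                           list(occupancy = 1),
                                           list(occupancy = 1),
                                           list(occupancy = 0.5),
                                           list(occupancy = 0.5)))
  bsys2 <- make_bonded_system(sp2)
  part2 <- domain_partition(A = 0:(max(bsys2$atoms$residue_index)))
  tab2 <- count_intradomain_hbonds(bsys2, part2)
  expect_equal(tab2$mean, 4)
  expect_equal(tab2$sd, 1)
})
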
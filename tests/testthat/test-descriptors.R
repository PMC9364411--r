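test_that("kabsch recovers rigid transforms and matches bio3d", {
  set.seed(2)
  a <- matrix(rnorm(30, sd = 4), 10, 3)
  expect_equal(kabsch(a, a)$rmsd, 0, tolerance = 1e-10)
  expect_equal(kabsch(a, a)$rotation, diag(3), tolerance = 1e-8)
  rot <- random_rotation(); shift <- c(3, -2, 7)
  b <- sweep(a %*% t(rot), 2, shift, "+")
  sp <- kabsch(a, b)
  expect_equal(sp$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
  # one displaced atom: cross-check against the bio3d superposition
  b2 <- a; b2[4, ] <- b2[4, ] + c(1, 0, 0)
  got <- kabsch(a, b2)$rmsd
  ref <- bio3d::rmsd(as.vector(t(a)), as.vector(t(b2)), fit = TRUE)
  expect_equal(got, ref, tolerance = 1e-3)
  expect_error(kabsch(a[1:2, ], b[1:2, ]), "3 atoms")
})

test_that("kabsch rmsd is symmetric and zero iff congruent", {
  set.seed(3)
  for (i in 1:5) {
    a <- matrix(rnorm(24, sd = 3), 8, 3)
    b <- a + matrix(rnorm(24, sd = 0.5), 8, 3)
    expect_equal(kabsch(a, b)$rmsd, kabsch(b, a)$rmsd, tolerance = 1e-8)
    expect_gt(kabsch(a, b)$rmsd, 0)
  }
})

test_that("ligand RMSD reports motion relative to the fitted receptor", {
  b <- build_bundle(2, 10)
  cx <- plant_complex(b, list(list(kind = "salt_bridge", residue = "A:5",
                                   distance = 3.0)))
  tr <- jitter_trajectory(cx, 0, 4, seed = 1)
  expect_equal(ligand_rmsd(tr, "backbone", "hetero"), rep(0, 4))
  # translate the ligand 2 A in one frame, receptor untouched
  li <- which(cx$atoms$hetero)
  tr$coords[li, 1, 3] <- tr$coords[li, 1, 3] + 2
  out <- ligand_rmsd(tr, "backbone", "hetero")
  expect_equal(out[3], 2, tolerance = 1e-6)
  expect_equal(out[-3], rep(0, 3), tolerance = 1e-6)
  expect_error(ligand_rmsd(tr, "backbone", "hetero", ref_frame = 9), "range")
})

test_that("jittered ligand RMSD approaches the sqrt(3) sigma expectation", {
  b <- build_bundle(2, 12)
  cx <- plant_complex(b, list(list(kind = "pi_stack", residue = "A:6",
                                   distance = 3.8)))
  sig <- 0.25
  tr <- jitter_trajectory(cx, sig, 2000, seed = 8)
  tr$coords[, , 1] <- coords(cx)          # clean reference frame
  out <- ligand_rmsd(tr, "backbone", "hetero", ref_frame = 1)
  expect_lt(abs(mean(out[-1]) - sqrt(3) * sig) / (sqrt(3) * sig), 0.1)
})

test_that("RMSF recovers planted fluctuation and scales into B-factors", {
  b <- build_bundle(7, 20)
  sig <- 0.2
  tr <- jitter_trajectory(b, sig, 1500, seed = 5)
  prof <- rmsf_bfactor(tr)
  target <- sqrt(3) * sig
  expect_lt(abs(mean(prof$rmsf) - target) / target, 0.05)
  expect_equal(prof$bfactor, (8 * pi^2 / 3) * prof$rmsf^2)
  # static trajectory: zero everywhere
  tr0 <- jitter_trajectory(b, 0, 3, seed = 1)
  expect_equal(max(rmsf_bfactor(tr0)$rmsf), 0, tolerance = 1e-9)
  # doubling sigma quadruples B (stochastically, within 5%)
  tr2 <- jitter_trajectory(b, 2 * sig, 1500, seed = 5)
  ratio <- mean(rmsf_bfactor(tr2)$bfactor) / mean(prof$bfactor)
  expect_lt(abs(ratio - 4) / 4, 0.05)
})

test_that("SASA matches the analytic sphere and is additive when separated", {
  s1 <- mk_atoms(matrix(0, 1, 3), element = "S")   # Bondi r = 1.8
  a1 <- sasa(s1, probe = 1.4)
  expect_lt(abs(a1$total - 4 * pi * 3.2^2) / (4 * pi * 3.2^2), 0.01)
  s2 <- mk_atoms(rbind(c(0, 0, 0), c(100, 0, 0)), element = "S")
  expect_lt(abs(sasa(s2)$total - 2 * a1$total) / (2 * a1$total), 0.01)
  expect_error(sasa(mk_atoms(matrix(0, 1, 3), element = "XX")), "XX")
})

test_that("overlapping spheres follow the spherical-cap closed form", {
  R <- 1.8 + 1.4
  for (d in c(1.5, 2.5, 4.0, 5.5)) {
    s <- mk_atoms(rbind(c(0, 0, 0), c(d, 0, 0)), element = "S")
    got <- sasa(s)$total
    want <- two_sphere_sasa(R, R, d)
    expect_lt(abs(got - want) / want, 0.02)
  }
})

test_that("SASA shrinks monotonically as two bodies approach", {
  vals <- vapply(c(8, 6, 4, 3, 2), function(d)
    sasa(mk_atoms(rbind(c(0, 0, 0), c(d, 0, 0)), element = "C"))$total, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("cavity SASA sums the right atoms and tracks cavity opening", {
  b <- build_bundle(2, 8, ring_radius = 5)
  tr <- jitter_trajectory(b, 0, 1, seed = 1)
  all_res <- residues(b)$uid
  expect_equal(cavity_sasa(tr, all_res)[1], sasa(b)$total, tolerance = 1e-9)
  expect_equal(cavity_sasa(tr, character(0)), 0)
  expect_error(cavity_sasa(tr, "A:999"), "unresolvable")
  # clamshell: moving the second helix 5 A away opens the facing surface
  tr2 <- jitter_trajectory(b, 0, 2, seed = 1)
  h2 <- which(b$atoms$resno > 100)
  tr2$coords[h2, 1, 2] <- tr2$coords[h2, 1, 2] - 5   # helix 2 sits at -x
  facing <- all_res
  sa <- cavity_sasa(tr2, facing)
  expect_gt(sa[2], sa[1])
})

test_that("helix-helix distances are geometric and rigid-invariant", {
  b <- build_bundle(2, 20, ring_radius = 6)
  tr <- jitter_trajectory(b, 0, 3, seed = 1)
  hd <- helix_distance(tr, "label TM1", "label TM2")
  expect_equal(hd$mean, 12, tolerance = 1e-6)
  expect_equal(helix_distance(tr, "label TM1", "label TM1")$mean, 0)
  tr2 <- tr
  tr2$coords <- tr2$coords + 17.3
  expect_equal(helix_distance(tr2, "label TM1", "label TM2")$values,
               hd$values, tolerance = 1e-9)
})

test_that("secondary structure separates helix from extended chain", {
  h <- build_helix(20)
  expect_gte(mean(assign_ss(h)$ss == "H"), 0.8)
  ext <- build_helix(20, phi = 180, psi = 180)
  expect_equal(mean(assign_ss(ext)$ss == "H"), 0)
  # alternating helix/extended frames average to half the helix fraction
  hc <- coords(h); ec <- coords(ext)
  arr <- array(0, dim = c(nrow(hc), 3, 10))
  for (i in 1:10) arr[, , i] <- if (i %% 2) hc else ec
  tr <- new_trajectory(h, arr)
  f_helix <- helix_fraction(jitter_trajectory(h, 0, 1), "all")
  f_mix <- helix_fraction(tr, "all")
  expect_lt(abs(f_mix - 0.5 * f_helix), 0.02)
})
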
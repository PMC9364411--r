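# Constructed-geometry fixtures: a guanidinium-like N trio facing a
# carboxylate O pair, benzene rings, and apolar carbon pairs.

lig_chem <- synthetic_ligand_template()

mk_saltbridge_fixture <- function(gap) {
  # ARG guanidinium atoms around origin; ligand carboxylate at +gap in x
  rec <- data.frame(
    serial = 1:4, name = c("CA", "NE", "NH1", "NH2"),
    element = c("C", "N", "N", "N"), chain = "A", resno = 1, icode = "",
    resname = "ARG",
    x = c(-4, -1.33, 0.665, 0.665), y = c(0, 0, 1.152, -1.152), z = 0,
    bfactor = 0, hetero = FALSE, stringsAsFactors = FALSE)
  # N centroid at (0,0,0); O centroid at (gap, 0, 0)
  lig <- data.frame(
    serial = 5:7, name = c("C1", "O1", "O2"), element = c("C", "O", "O"),
    chain = "L", resno = 1, icode = "", resname = "LIG",
    x = c(gap + 0.625, gap, gap), y = c(0, 1.0125, -1.0125), z = 0,
    bfactor = 0, hetero = TRUE, stringsAsFactors = FALSE)
  lig$x[2:3] <- gap - 0  # O pair centroid exactly at gap
  s <- new_structure(rbind(rec, lig))
  attr(s, "ligand_chem") <- lig_chem
  s
}

mk_ring_fixture <- function(dist, angle_deg = 0, offset = 0) {
  hexagon <- function(center, normal_angle) {
    rot <- matrix(c(cos(normal_angle), 0, sin(normal_angle),
                    0, 1, 0,
                    -sin(normal_angle), 0, cos(normal_angle)), 3, 3, byrow = TRUE)
    t(vapply(0:5, function(i) {
      a <- i * pi / 3
      center + as.numeric(rot %*% c(1.39 * cos(a), 1.39 * sin(a), 0))
    }, numeric(3)))
  }
  ring1 <- hexagon(c(0, 0, 0), 0)                     # plane z = 0
  ring2 <- hexagon(c(offset, 0, dist), angle_deg * pi / 180)
  rec <- mk_atoms(ring1, element = "C",
                  name = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
                  resno = 1, resname = "PHE")$atoms
  lig <- mk_atoms(ring2, element = "C", name = paste0("C", 2:7),
                  chain = "L", resno = 1, resname = "LIG",
                  hetero = TRUE)$atoms
  lig$serial <- lig$serial + 10
  rec$uid <- lig$uid <- NULL
  s <- new_structure(rbind(rec, lig))
  attr(s, "ligand_chem") <- lig_chem
  s
}

test_that("salt bridges are detected inside and not outside the cutoff", {
  s <- mk_saltbridge_fixture(3.0)
  det <- detect_interactions(s, "chain L", kinds = "salt_bridge")
  expect_equal(det$kind, "salt_bridge")
  expect_equal(det$dist, 3.0, tolerance = 1e-9)
  far <- mk_saltbridge_fixture(6.0)
  expect_equal(nrow(detect_interactions(far, "chain L", kinds = "salt_bridge")), 0L)
})

test_that("pi stacking obeys distance, plane-angle and offset windows", {
  hit <- detect_interactions(mk_ring_fixture(3.8), "chain L", kinds = "pi_stack")
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$dist, 3.8, tolerance = 1e-9)
  expect_lt(hit$angle, 1)
  expect_equal(nrow(detect_interactions(mk_ring_fixture(8.0), "chain L",
                                        kinds = "pi_stack")), 0L)
  # 45-degree tilt falls between the parallel and T-shaped windows
  expect_equal(nrow(detect_interactions(mk_ring_fixture(3.8, angle_deg = 45),
                                        "chain L", kinds = "pi_stack")), 0L)
  tsh <- detect_interactions(mk_ring_fixture(4.6, angle_deg = 85),
                             "chain L", kinds = "pi_stack")
  expect_equal(nrow(tsh), 1L)
})

test_that("detection is invariant under rigid-body transforms", {
  set.seed(11)
  s <- mk_saltbridge_fixture(3.4)
  base <- detect_interactions(s, "chain L", kinds = "salt_bridge")
  for (i in 1:5) {
    s2 <- rigid_transform(s)
    attr(s2, "ligand_chem") <- lig_chem
    d2 <- detect_interactions(s2, "chain L", kinds = "salt_bridge")
    expect_equal(d2$dist, base$dist, tolerance = 1e-8)
  }
})

test_that("occupancies count frames and tighten monotonically with cutoffs", {
  s <- mk_saltbridge_fixture(3.0)
  # planted in all frames
  tr <- jitter_trajectory(s, 0, 10, seed = 1)
  attr(tr$topology, "ligand_chem") <- lig_chem
  fp <- fingerprint(tr, "chain L", kinds = "salt_bridge")
  expect_equal(fp$occupancy, 1.0)
  # planted in half of 10 frames: push the ligand away in frames 6..10
  tr2 <- tr
  tr2$coords[5:7, 1, 6:10] <- tr2$coords[5:7, 1, 6:10] + 50
  fp2 <- fingerprint(tr2, "chain L", kinds = "salt_bridge")
  expect_equal(fp2$occupancy, 0.5)
  # jittered pose inside the cutoff keeps high occupancy
  trj <- jitter_trajectory(s, 0.1, 200, seed = 7)
  attr(trj$topology, "ligand_chem") <- lig_chem
  fpj <- fingerprint(trj, "chain L", kinds = "salt_bridge")
  expect_gte(fpj$occupancy[1], 0.9)
  # tightening the cutoff can only lower occupancy
  fpt <- fingerprint(trj, "chain L", kinds = "salt_bridge",
                     params = contact_params(salt_bridge = 3.05))
  occ_loose <- fpj$occupancy[1]
  occ_tight <- if (nrow(fpt)) fpt$occupancy[1] else 0
  expect_lte(occ_tight, occ_loose)
})

test_that("salt-bridge series takes the per-frame pair minimum", {
  # one O against two N at 3 and 6 Angstrom
  xyz <- rbind(c(0, 0, 0), c(3, 0, 0), c(-6, 0, 0))
  s <- mk_atoms(xyz, element = c("O", "N", "N"), name = c("O1", "N1", "N2"),
                resno = c(1, 2, 3), resname = c("LIG", "ARG", "ARG"))
  tr <- jitter_trajectory(s, 0, 5, seed = 1)
  ser <- saltbridge_series(tr, "resid 1", "resid 2-3")
  expect_equal(ser$values, rep(3, 5))
  expect_equal(ser$sd, 0)
  expect_error(saltbridge_series(tr, "resid 2", "resid 3"), "no oxygen")
})

test_that("jittered pair-distance spread matches the Gaussian prediction", {
  xyz <- rbind(c(0, 0, 0), c(5, 0, 0))
  s <- mk_atoms(xyz, element = c("O", "N"), name = c("O1", "N1"),
                resno = c(1, 2), resname = c("LIG", "ARG"))
  sig <- 0.15
  tr <- jitter_trajectory(s, sig, 1000, seed = 3)
  ser <- saltbridge_series(tr, "resid 1", "resid 2")
  predicted_sd <- sqrt(2) * sig      # difference of two iid jitters, projected
  expect_lt(abs(ser$sd - predicted_sd) / predicted_sd, 0.2)
})
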
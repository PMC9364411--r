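test_that("schedule validation enforces monotone unit-interval legs", {
  rep0 <- validate_schedule(lambda_schedule(c(0, 0.5, 1), c(0, 0.5, 1),
                                            c(0, 0.5, 1)))
  expect_equal(unname(rep0$counts), c(3, 3, 3))
  expect_error(lambda_schedule(c(0, 1, 0.5), c(0, 1), c(0, 1)),
               "strictly increasing")
  expect_error(lambda_schedule(c(0.1, 1), c(0, 1), c(0, 1)), "start at 0")
  ref <- validate_schedule(reference_schedule())
  expect_equal(unname(ref$counts), c(11, 5, 16))
  expect_equal(ref$total, 32)
})

test_that("identical states give exactly zero free-energy difference", {
  set.seed(1)
  u1 <- matrix(rnorm(200)^2 / 2, nrow = 1)
  u <- rbind(u1, u1)
  fit <- mbar_solve(u, counts = c(100, 100), uncertainty = "none")
  expect_equal(fit$f[2], 0, tolerance = 1e-12)
})

test_that("MBAR reduces to BAR on two states", {
  g <- gen_ensemble(kappa = c(1, 3), n = c(800, 1200), seed = 21)
  fit <- mbar_solve(g$ensemble, uncertainty = "none", tol = 1e-10)
  bar <- bar_oracle(g$ensemble$u, g$ensemble$counts)
  expect_lt(abs((fit$f[2] - fit$f[1]) - bar), 1e-6)
})

test_that("MBAR recovers harmonic closed forms and gauge invariance", {
  g <- gen_ensemble(kappa = c(1, 4), n = 2000, seed = 12)
  fit <- mbar_solve(g$ensemble, n_boot = 100, seed = 2)
  df <- fit$f[2] - fit$f[1]
  expect_lt(abs(df - 0.5 * log(4)), 3 * fit$se_kT)
  # adding a constant to one state's reduced potentials shifts only its f
  u2 <- g$ensemble$u
  u2[2, ] <- u2[2, ] + 2.5
  fit2 <- mbar_solve(u2, counts = g$ensemble$counts, uncertainty = "none")
  expect_equal(fit2$f[2] - fit$f[2], 2.5, tolerance = 1e-6)
  expect_error(mbar_solve(matrix(c(0, NA, 0, 0), 2), counts = c(1, 1)), "NaN")
})

test_that("five-state ladder matches closed form with exact telescoping", {
  g <- gen_ensemble(kappa = c(1, 2, 4, 8, 16), mu = seq(0, 0.8, 0.2),
                    n = 1500, seed = 33)
  fit <- mbar_solve(g$ensemble, n_boot = 60, seed = 3)
  se <- max(fit$se_kT, 0.02)
  for (k in 2:5)
    expect_lt(abs(fit$f[k] - g$f_true[k]), 3 * se * sqrt(k))
  jump <- sum(diff(fit$f))
  expect_lt(abs(jump - (fit$f[5] - fit$f[1])), 1e-10)
})

test_that("ensemble TSV round trips and feeds the estimator", {
  g <- gen_ensemble(kappa = c(2, 5), n = c(2, 2), temperature = 310, seed = 4)
  f <- tempfile(fileext = ".tsv")
  write_ensemble(g$ensemble, f)
  e2 <- read_ensemble(f)
  expect_equal(dim(e2$u), c(2L, 4L))
  expect_equal(e2$counts, c(2L, 2L))
  expect_equal(e2$temperature, 310)
  expect_equal(e2$u, g$ensemble$u, tolerance = 1e-8)
  # ragged rows are rejected
  lines <- readLines(f)
  writeLines(c(lines, "1\t0.5"), f)
  expect_error(read_ensemble(f), "ragged")
  # end-to-end: generated file reproduces the planted free energy
  g2 <- gen_ensemble(kappa = c(1, 4), n = 3000, seed = 9)
  f2 <- tempfile(fileext = ".tsv")
  write_ensemble(g2$ensemble, f2)
  fit <- mbar_solve(read_ensemble(f2), n_boot = 80, seed = 5)
  expect_lt(abs(fit$f[2] - log(2)), 3 * fit$se_kT)
})

test_that("Boresch correction scales as ln sqrt(prod k) and flags width", {
  r1 <- boresch_restraint(d = 8, theta_A = 80, theta_B = 100, phi_A = 30,
                          phi_B = -60, phi_C = 150)
  r2 <- boresch_restraint(d = 8, theta_A = 80, theta_B = 100, phi_A = 30,
                          phi_B = -60, phi_C = 150,
                          K_d = 20, K_theta = 20, K_phi = 20)
  kT <- 0.0019872041 * 300
  expect_equal(as.numeric(boresch_dg_on(r2)) - as.numeric(boresch_dg_on(r1)),
               3 * kT * log(2), tolerance = 1e-10)
  # half vs full convention differ by the same 3 kT ln 2
  r2f <- boresch_restraint(d = 8, theta_A = 80, theta_B = 100, phi_A = 30,
                           phi_B = -60, phi_C = 150, convention = "full")
  expect_equal(as.numeric(boresch_dg_on(r2f)) - as.numeric(boresch_dg_on(r1)),
               3 * kT * log(2), tolerance = 1e-10)
  soft <- boresch_restraint(d = 5, theta_A = 90, theta_B = 90, phi_A = 0,
                            phi_B = 0, phi_C = 0, K_theta = 0.5, K_phi = 0.5)
  expect_false(attr(boresch_dg_on(soft), "reliable"))
  expect_error(boresch_restraint(d = 5, theta_A = 0, theta_B = 90,
                                 phi_A = 0, phi_B = 0, phi_C = 0), "angles")
})

test_that("study-stiffness restraints sit near quadrature at the kT sigma^2 scale", {
  r <- boresch_restraint(d = 5, theta_A = 90, theta_B = 90, phi_A = 0,
                         phi_B = 120, phi_C = -120,
                         K_d = 20, K_theta = 20, K_phi = 20)
  gap <- abs(as.numeric(boresch_dg_on(r)) - boresch_quadrature(r))
  # harmonic (stiff-spring) truncation error, not a solver defect
  expect_lt(gap, 0.05)
  expect_gt(gap, 1e-4)
})

test_that("Boresch temperature trend matches the quadrature oracle", {
  # restraining is entropically costlier at higher T: dG_on rises with T,
  # and the closed form must trend exactly as the numerical integral does
  r <- boresch_restraint(d = 6, theta_A = 70, theta_B = 110, phi_A = 10,
                         phi_B = 100, phi_C = -150,
                         K_d = 600, K_theta = 600, K_phi = 600)
  dg <- vapply(c(280, 300, 320), function(Tk)
    as.numeric(boresch_dg_on(r, temperature = Tk)), 0)
  qq <- vapply(c(280, 300, 320), function(Tk)
    boresch_quadrature(r, temperature = Tk), 0)
  expect_true(all(diff(dg) > 0))
  expect_identical(sign(diff(dg)), sign(diff(qq)))
  expect_lt(max(abs(dg - qq)), 1e-3)
})

test_that("cycle composition is exact arithmetic with quadrature errors", {
  cy <- compose_cycle(-121.602, 103.941, 6.559, se = c(0.524, 0.254, 0))
  expect_equal(cy$dG_bind, -11.102, tolerance = 1e-12)
  expect_equal(cy$se_bind, sqrt(0.524^2 + 0.254^2), tolerance = 1e-12)
  expect_equal(compose_cycle(-123.153, 103.996, 6.7)$dG_bind, -12.457,
               tolerance = 1e-12)
  expect_equal(compose_cycle(0, 0, 0)$dG_bind, 0)
})

test_that("statistical inefficiency detects correlation and not noise", {
  set.seed(6)
  white <- rnorm(4000)
  expect_lt(statistical_inefficiency(white), 1.3)
  ar <- as.numeric(stats::arima.sim(list(ar = 0.9), 4000))
  expect_gt(statistical_inefficiency(ar), 5)
})
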
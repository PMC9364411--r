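# Absolute binding free energy machinery: lambda schedules, MBAR,
# the analytical Boresch restraint correction, thermodynamic-cycle
# composition, and a TSV ensemble format.

.KB_KCAL <- 0.0019872041   # Boltzmann constant, kcal mol-1 K-1

#' Construct an alchemical lambda schedule
#'
#' Three legs of coupling-parameter values: restraint switching
#' (`restr`), charge decoupling (`coul`) and Lennard-Jones decoupling
#' (`vdw`). Each leg must increase strictly from 0 to 1.
#'
#' @param restr,coul,vdw numeric vectors in [0, 1]
#' @export
lambda_schedule <- function(restr, coul, vdw) {
  s <- structure(list(restr = restr, coul = coul, vdw = vdw),
                 class = "lambda_schedule")
  validate_schedule(s)
  s
}

#' The published FFAR1 ABFE lambda schedule
#'
#' Restraint, charge and Lennard-Jones legs with 11, 5 and 16 windows
#' respectively, as used for the complex leg of the AM-8596/FFAR1
#' calculations (the solution leg reuses the charge and LJ lists).
#' @export
reference_schedule <- function() {
  lambda_schedule(
    restr = c(0, 0.01, 0.025, 0.05, 0.075, 0.10, 0.20, 0.35, 0.50, 0.75, 1),
    coul = c(0, 0.25, 0.50, 0.75, 1),
    vdw = c(0, 0.05, 0.10, 0.20, 0.30, 0.40, 0.50, 0.60, 0.65, 0.70,
            0.75, 0.80, 0.85, 0.90, 0.95, 1))
}

#' Validate a lambda schedule and report window counts
#'
#' Checks that every leg is strictly increasing with endpoints 0 and 1,
#' and reports the number of windows per leg and in total.
#'
#' @param s a [lambda_schedule()] (or a bare list with restr/coul/vdw)
#' @return list(counts, total) invisibly-printable report
#' @export
validate_schedule <- function(s) {
  for (leg in c("restr", "coul", "vdw")) {
    v <- s[[leg]]
    if (is.null(v) || length(v) < 2)
      stop("schedule leg '", leg, "' missing or too short")
    if (any(diff(v) <= 0))
      stop("schedule leg '", leg, "' is not strictly increasing")
    if (abs(v[1]) > 0 || abs(v[length(v)] - 1) > 0)
      stop("schedule leg '", leg, "' must start at 0.00 and end at 1.00")
    if (any(v < 0 | v > 1)) stop("schedule leg '", leg, "' outside [0, 1]")
  }
  counts <- c(restr = length(s$restr), coul = length(s$coul),
              vdw = length(s$vdw))
  list(counts = counts, total = sum(counts))
}

#' @export
print.lambda_schedule <- function(x, ...) {
  rep <- validate_schedule(x)
  cat(sprintf("<lambda_schedule> windows: restr %d, coul %d, vdw %d (total %d)\n",
              rep$counts["restr"], rep$counts["coul"], rep$counts["vdw"],
              rep$total))
  invisible(x)
}

# ---- ensembles ----------------------------------------------------------

#' Construct an alchemical ensemble
#'
#' Holds the reduced-potential matrix u[k, n]: the dimensionless energy
#' (units of kT) of sample n evaluated in every thermodynamic state k,
#' together with the per-state sample counts N_k.
#'
#' @param u K x N matrix of reduced potentials
#' @param counts integer vector N_k, summing to ncol(u)
#' @param temperature Kelvin
#' @export
new_ensemble <- function(u, counts, temperature = 300) {
  u <- as.matrix(u)
  if (any(!is.finite(u))) stop("non-finite reduced potentials")
  if (sum(counts) != ncol(u)) stop("sum(N_k) != number of samples")
  if (length(counts) != nrow(u)) stop("length(N_k) != number of states")
  structure(list(u = u, counts = as.integer(counts),
                 temperature = temperature), class = "alch_ensemble")
}

#' @export
print.alch_ensemble <- function(x, ...) {
  cat(sprintf("<alch_ensemble> %d states, %d samples, T = %g K\n",
              nrow(x$u), ncol(x$u), x$temperature))
  invisible(x)
}

#' Write an ensemble as TSV
#'
#' Format: a metadata line `#T_kelvin=<T>`, a header
#' `state<TAB>u_1<TAB>...<TAB>u_K`, then one row per sample whose first
#' column is the 1-based origin state.
#'
#' @param e a [new_ensemble()]
#' @param file output path
#' @export
write_ensemble <- function(e, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("#T_kelvin=%g", e$temperature), con)
  k <- nrow(e$u)
  writeLines(paste(c("state", paste0("u_", seq_len(k))), collapse = "\t"), con)
  origin <- rep(seq_len(k), e$counts)
  for (n in seq_len(ncol(e$u)))
    writeLines(paste(c(origin[n], sprintf("%.10g", e$u[, n])), collapse = "\t"),
               con)
  invisible(file)
}

#' Read an ensemble TSV
#' @param path file written by [write_ensemble()]
#' @export
read_ensemble <- function(path) {
  lines <- readLines(path, warn = FALSE)
  meta <- grep("^#", lines, value = TRUE)
  temperature <- 300
  tm <- grep("^#T_kelvin=", meta, value = TRUE)
  if (length(tm)) temperature <- as.numeric(sub("^#T_kelvin=", "", tm[1]))
  body <- lines[!grepl("^#", lines)]
  hdr <- strsplit(body[1], "\t", fixed = TRUE)[[1]]
  k <- length(hdr) - 1L
  rows <- strsplit(body[-1], "\t", fixed = TRUE)
  len <- lengths(rows)
  if (any(len != k + 1L))
    stop("ragged ensemble file: row ", which(len != k + 1L)[1] + 1L,
         " has ", len[len != k + 1L][1], " fields, expected ", k + 1L)
  m <- matrix(as.numeric(unlist(rows)), ncol = k + 1L, byrow = TRUE)
  origin <- as.integer(m[, 1])
  counts <- tabulate(origin, nbins = k)
  ord <- order(origin)
  new_ensemble(t(m[ord, -1, drop = FALSE]), counts, temperature)
}

# ---- MBAR ---------------------------------------------------------------

# column-wise log-sum-exp of a K x N matrix (K small, N large)
.logsumexp_cols <- function(m) {
  k <- nrow(m)
  mx <- m[1, ]
  if (k > 1) for (i in 2:k) mx <- pmax(mx, m[i, ])
  mx + log(colSums(exp(m - rep(mx, each = k))))
}

# MBAR self-consistent update; f anchored afterwards at f[1] = 0
.mbar_update <- function(u, logN, f) {
  logd <- .logsumexp_cols((f + logN) - u)    # length N
  a <- -u - rep(logd, each = nrow(u))
  mxr <- apply(a, 1, max)                    # K max() calls, cheap
  fn <- -(mxr + log(rowSums(exp(a - mxr))))
  fn - fn[1]
}

.mbar_core <- function(u, counts, tol = 1e-8, max_iter = 20000L,
                       f_init = NULL) {
  k <- nrow(u)
  logN <- log(counts)
  f <- if (is.null(f_init)) numeric(k) else f_init - f_init[1]
  if (is.null(f_init) && k > 1) {
    # convex objective minimised over f[-1] (gauge fixed at f[1] = 0)
    obj <- function(fr) {
      f <- c(0, fr)
      sum(.logsumexp_cols((f + logN) - u)) - sum(counts * f)
    }
    grad <- function(fr) {
      f <- c(0, fr)
      logd <- .logsumexp_cols((f + logN) - u)
      w <- exp((f + logN) - u - rep(logd, each = k))  # rows sum to N_k at optimum
      (rowSums(w) - counts)[-1]
    }
    opt <- stats::optim(f[-1], obj, grad, method = "BFGS",
                        control = list(maxit = 500, reltol = 1e-12))
    f <- c(0, opt$par)
  }
  conv <- FALSE
  for (it in seq_len(max_iter)) {            # self-consistent polish to tol
    fn <- .mbar_update(u, logN, f)
    if (max(abs(fn - f)) < tol) { f <- fn; conv <- TRUE; break }
    f <- fn
  }
  if (!conv && max(abs(.mbar_update(u, logN, f) - f)) > tol * 100)
    stop("MBAR failed to converge: poor overlap between states?")
  f
}

# overlap matrix O[i, j] = sum_n N_j W_ni W_nj, rows sum to 1;
# small off-diagonal mass flags poor phase-space overlap
mbar_overlap <- function(u, counts, f) {
  logd <- .logsumexp_cols(f + log(counts) - u)
  w <- exp(sweep(f - u, 2, logd))            # W[k, n]
  w %*% t(sweep(w, 1, counts, "*"))
}

#' Solve the MBAR equations for multistate free energies
#'
#' Computes the per-state reduced free energies f_k (units of kT, anchored
#' at f_1 = 0) satisfying the multistate Bennett acceptance ratio
#' self-consistent equations, by minimising the equivalent convex
#' objective (BFGS with analytic gradient) followed by self-consistent
#' polishing to `tol`. Endpoint uncertainty is estimated by block
#' bootstrap over samples within each state.
#'
#' @param e a [new_ensemble()] (or matrix u with `counts` given)
#' @param counts per-state sample counts when `e` is a bare matrix
#' @param temperature Kelvin (taken from the ensemble when available)
#' @param tol self-consistency tolerance in kT
#' @param uncertainty "bootstrap" or "none"
#' @param n_boot bootstrap resamples
#' @param block_length bootstrap block length (1 = ordinary bootstrap;
#'   raise for correlated samples)
#' @param seed RNG seed for the bootstrap
#' @return object of class `mbar_fit`: f (kT), delta_f matrix (kT),
#'   dG endpoint in kcal/mol, se, overlap matrix
#' @export
mbar_solve <- function(e, counts = NULL, temperature = NULL, tol = 1e-8,
                       uncertainty = c("bootstrap", "none"), n_boot = 200,
                       block_length = 1L, seed = 1L) {
  uncertainty <- match.arg(uncertainty)
  if (inherits(e, "alch_ensemble")) {
    u <- e$u; counts <- e$counts
    if (is.null(temperature)) temperature <- e$temperature
  } else { u <- as.matrix(e) }
  if (is.null(temperature)) temperature <- 300
  if (is.null(counts)) stop("per-state sample counts required")
  if (any(!is.finite(u))) stop("NaN/Inf in reduced potentials")
  if (nrow(u) < 2 || any(counts <= 0))
    stop("need >= 2 states with samples in each")
  f <- .mbar_core(u, counts, tol = tol)
  kT <- .KB_KCAL * temperature
  delta_f <- outer(f, f, function(a, b) b - a)  # delta_f[i, j] = f_j - f_i
  se_kT <- NA_real_
  if (uncertainty == "bootstrap") {
    k <- nrow(u)
    idx_by_state <- split(seq_len(ncol(u)), rep(seq_len(k), counts))
    set.seed(seed)
    boot_df <- numeric(n_boot)
    for (b in seq_len(n_boot)) {
      cols <- unlist(lapply(idx_by_state, function(ix) {
        n <- length(ix)
        if (block_length <= 1L) ix[sample.int(n, n, replace = TRUE)]
        else {
          nb <- ceiling(n / block_length)
          starts <- sample.int(n, nb, replace = TRUE)
          out <- unlist(lapply(starts, function(s0)
            ix[((s0 - 1 + seq_len(block_length) - 1) %% n) + 1]))
          out[seq_len(n)]
        }
      }))
      fb <- .mbar_core(u[, cols, drop = FALSE], counts, tol = 1e-6,
                       f_init = f)
      boot_df[b] <- fb[k] - fb[1]
    }
    se_kT <- stats::sd(boot_df)
  }
  res <- list(f = f, delta_f = delta_f,
              dG_kcal = (f[length(f)] - f[1]) * kT,
              se_kcal = se_kT * kT, se_kT = se_kT,
              temperature = temperature, counts = counts)
  class(res) <- "mbar_fit"
  res
}

#' @export
print.mbar_fit <- function(x, ...) {
  cat(sprintf("<mbar_fit> %d states, T = %g K\n", length(x$f), x$temperature))
  cat("  f_k (kT):", paste(sprintf("%.4f", x$f), collapse = " "), "\n")
  cat(sprintf("  endpoint dG = %.4f kcal/mol", x$dG_kcal))
  if (is.finite(x$se_kcal)) cat(sprintf(" +/- %.4f", x$se_kcal))
  cat("\n")
  invisible(x)
}

# ---- Boresch restraint correction --------------------------------------

#' Construct a six-degree-of-freedom Boresch restraint
#'
#' One distance, two angles and three dihedrals fixing the ligand's
#' position and orientation relative to the receptor during decoupling.
#' Force constants default to 10 kcal/mol per squared Angstrom/radian in
#' the stated convention: "half" means U = (k/2)(xi - xi0)^2, "full" means
#' U = K(xi - xi0)^2 (equivalent to half-convention k = 2K).
#'
#' @param d reference distance, Angstrom
#' @param theta_A,theta_B reference angles, degrees (0 < theta < 180)
#' @param phi_A,phi_B,phi_C reference dihedrals, degrees
#' @param K_d distance force constant, kcal mol-1 A-2
#' @param K_theta angle force constants (length 2 recycled), kcal mol-1 rad-2
#' @param K_phi dihedral force constants (length 3 recycled), kcal mol-1 rad-2
#' @param convention "half" or "full"
#' @export
boresch_restraint <- function(d, theta_A, theta_B, phi_A, phi_B, phi_C,
                              K_d = 10, K_theta = 10, K_phi = 10,
                              convention = c("half", "full")) {
  convention <- match.arg(convention)
  if (d <= 0) stop("reference distance must be positive")
  if (theta_A <= 0 || theta_A >= 180 || theta_B <= 0 || theta_B >= 180)
    stop("reference angles must lie strictly inside (0, 180) degrees")
  K_theta <- rep(K_theta, length.out = 2)
  K_phi <- rep(K_phi, length.out = 3)
  if (any(c(K_d, K_theta, K_phi) <= 0)) stop("force constants must be positive")
  structure(list(d = d, theta_A = theta_A, theta_B = theta_B,
                 phi_A = phi_A, phi_B = phi_B, phi_C = phi_C,
                 K_d = K_d, K_theta = K_theta, K_phi = K_phi,
                 convention = convention), class = "boresch_restraint")
}

#' Analytical free energy of imposing Boresch restraints
#'
#' Closed-form (stiff-spring) free energy of restraining the six relative
#' degrees of freedom of a decoupled ligand at standard concentration:
#'
#'   dG_on = kT ln( 8 pi^2 V0 sqrt(prod k_i) /
#'                  ( d^2 sin(theta_A) sin(theta_B) (2 pi kT)^3 ) )
#'
#' with half-convention force constants k_i. The result carries a
#' `reliable` attribute set FALSE when any angular width sqrt(kT/k)
#' exceeds 30 degrees, where the harmonic approximation degrades.
#'
#' @param r a [boresch_restraint()]
#' @param temperature Kelvin
#' @param v0 standard-state volume, Angstrom^3 (1660 A^3 = 1 M)
#' @return dG_on in kcal/mol with attributes `reliable` and `widths_deg`
#' @export
boresch_dg_on <- function(r, temperature = 300, v0 = 1660) {
  stopifnot(inherits(r, "boresch_restraint"))
  kT <- .KB_KCAL * temperature
  k <- c(r$K_d, r$K_theta, r$K_phi)
  if (r$convention == "full") k <- 2 * k
  tA <- r$theta_A * pi / 180; tB <- r$theta_B * pi / 180
  if (sin(tA) <= 0 || sin(tB) <= 0) stop("sin(theta) must be positive")
  dg <- kT * log(8 * pi^2 * v0 * sqrt(prod(k)) /
                 (r$d^2 * sin(tA) * sin(tB) * (2 * pi * kT)^3))
  widths <- sqrt(kT / k[-1]) * 180 / pi     # angular widths, degrees
  structure(dg, reliable = all(widths <= 30), widths_deg = widths)
}

# ---- thermodynamic cycle ------------------------------------------------

#' Compose the absolute-binding-free-energy thermodynamic cycle
#'
#' The binding free energy is the exact arithmetic sum of the three legs:
#' the complex-decoupling term (carried with its printed sign as
#' -dG_elec+vdw in complex), the solution-decoupling term, and the free
#' energy of imposing the Boresch restraints on the decoupled ligand.
#' Uncertainties combine in quadrature.
#'
#' @param minus_dG_complex complex-decoupling component, kcal/mol
#' @param dG_water solution-decoupling component, kcal/mol
#' @param dG_restr_on restraint component, kcal/mol
#' @param se standard errors of the three components (recycled)
#' @return object of class `cycle_result`
#' @export
compose_cycle <- function(minus_dG_complex, dG_water, dG_restr_on,
                          se = c(0, 0, 0)) {
  se <- rep(se, length.out = 3)
  res <- list(minus_dG_complex = minus_dG_complex, dG_water = dG_water,
              dG_restr_on = dG_restr_on,
              dG_bind = minus_dG_complex + dG_water + dG_restr_on,
              se_bind = sqrt(sum(se^2)), se = se)
  class(res) <- "cycle_result"
  res
}

#' @export
print.cycle_result <- function(x, ...) {
  cat("<cycle_result> (kcal/mol)\n")
  cat(sprintf("  -dG_complex  %10.3f\n", x$minus_dG_complex))
  cat(sprintf("   dG_water    %10.3f\n", x$dG_water))
  cat(sprintf("   dG_restr_on %10.3f\n", x$dG_restr_on))
  cat(sprintf("   dG_bind     %10.3f", x$dG_bind))
  if (x$se_bind > 0) cat(sprintf(" +/- %.3f", x$se_bind))
  cat("\n")
  invisible(x)
}

#' Statistical inefficiency of a sample series
#'
#' g = 1 + 2 sum of the normalised autocorrelation (truncated at the first
#' non-positive value); every g-th sample is approximately independent.
#' Provided for optional decorrelation of ensemble samples; off by
#' default in [mbar_solve()] (samples are assumed decorrelated).
#'
#' @param x numeric series
#' @return g >= 1
#' @export
statistical_inefficiency <- function(x) {
  n <- length(x)
  if (n < 3 || stats::sd(x) == 0) return(1)
  ac <- stats::acf(x, lag.max = min(n - 2, 1000), plot = FALSE)$acf[-1]
  pos <- which(ac <= 0)
  if (length(pos)) ac <- ac[seq_len(pos[1] - 1)]
  max(1, 1 + 2 * sum(ac * (1 - seq_along(ac) / n)))
}
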
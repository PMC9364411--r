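# Trajectory geometry descriptors.

#' Kabsch least-squares rigid superposition
#'
#' Finds the proper rotation R and translation t minimising
#' ||b R + t - a|| over all atoms (row vectors), via SVD of the covariance
#' with a determinant sign correction so det(R) = +1.
#'
#' @param a target coordinates, n x 3
#' @param b mobile coordinates, n x 3
#' @return object of class `superposition`: list(rotation, translation,
#'   rmsd); `b %*% rotation + translation` superposes b onto a.
#' @export
kabsch <- function(a, b) {
  a <- as.matrix(a); b <- as.matrix(b)
  if (!all(dim(a) == dim(b))) stop("coordinate sets differ in size")
  n <- nrow(a)
  if (n < 3) stop("need >= 3 atoms for superposition")
  ca <- colMeans(a); cb <- colMeans(b)
  a0 <- sweep(a, 2, ca); b0 <- sweep(b, 2, cb)
  h <- crossprod(b0, a0)                    # 3x3 covariance
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  if (any(abs(sv$d[1:2]) < 1e-12)) stop("degenerate (collinear) geometry")
  r <- sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
  fit <- b0 %*% r
  rmsd <- sqrt(mean(rowSums((fit - a0)^2)))
  structure(list(rotation = r, translation = ca - cb %*% r, rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> rmsd %.4f A\n", x$rmsd))
  invisible(x)
}

.apply_fit <- function(m, fit) sweep(m %*% fit$rotation, 2, -as.numeric(fit$translation))

#' Ligand RMSD series after receptor superposition
#'
#' Per frame: superpose the frame onto a reference frame using the `fit`
#' selection (typically the receptor backbone), then report the RMSD over
#' the `measure` selection (typically the ligand) without refitting --
#' the standard measure of ligand positional stability in a binding site.
#'
#' @param t a `mol_trajectory`
#' @param fit selection used for superposition
#' @param measure selection whose RMSD is reported
#' @param ref_frame reference frame index
#' @return numeric series, Angstrom
#' @export
ligand_rmsd <- function(t, fit = "backbone", measure, ref_frame = 1L) {
  if (ref_frame < 1 || ref_frame > n_frames(t)) stop("ref_frame out of range")
  fi <- if (is.numeric(fit)) as.integer(fit) else select_atoms(t$topology, fit)
  mi <- if (is.numeric(measure)) as.integer(measure) else select_atoms(t$topology, measure)
  if (!length(fi) || !length(mi)) stop("empty selection")
  ref_fit <- t$coords[fi, , ref_frame]
  ref_meas <- t$coords[mi, , ref_frame]
  out <- numeric(n_frames(t))
  for (f in seq_len(n_frames(t))) {
    sp <- kabsch(ref_fit, t$coords[fi, , f])
    moved <- .apply_fit(t$coords[mi, , f, drop = TRUE], sp)
    out[f] <- sqrt(mean(rowSums((moved - ref_meas)^2)))
  }
  out
}

#' Per-residue RMSF and B-factors
#'
#' Frames are superposed (on the selection) onto the mean structure in two
#' passes; the per-atom RMSF about the mean is averaged within residues and
#' converted to crystallographic B-factors via B = (8 pi^2 / 3) RMSF^2.
#'
#' @param t a `mol_trajectory` with >= 2 frames
#' @param selection atoms analysed (default C-alpha)
#' @return data.frame residue uid, rmsf (A), bfactor (A^2)
#'   (class `flexibility_profile`)
#' @export
rmsf_bfactor <- function(t, selection = "calpha") {
  idx <- if (is.numeric(selection)) as.integer(selection)
         else select_atoms(t$topology, selection)
  if (!length(idx)) stop("empty selection")
  nf <- n_frames(t)
  uid <- t$topology$atoms$uid[idx]
  if (nf < 2) {
    warning("single frame: RMSF is identically zero")
    prof <- data.frame(residue = unique(uid), rmsf = 0, bfactor = 0)
    class(prof) <- c("flexibility_profile", "data.frame")
    return(prof)
  }
  sub <- t$coords[idx, , , drop = FALSE]
  aligned <- sub
  ref <- sub[, , 1]
  for (pass in 1:2) {
    for (f in seq_len(nf)) {
      sp <- kabsch(ref, sub[, , f])
      aligned[, , f] <- .apply_fit(sub[, , f], sp)
    }
    ref <- apply(aligned, c(1, 2), mean)
  }
  mu <- ref
  dev2 <- sapply(seq_len(nf), function(f) rowSums((aligned[, , f] - mu)^2))
  rmsf_atom <- sqrt(rowMeans(dev2))
  rmsf <- tapply(rmsf_atom, uid, mean)[unique(uid)]
  prof <- data.frame(residue = names(rmsf), rmsf = as.numeric(rmsf),
                     bfactor = (8 * pi^2 / 3) * as.numeric(rmsf)^2,
                     stringsAsFactors = FALSE)
  rownames(prof) <- NULL
  class(prof) <- c("flexibility_profile", "data.frame")
  prof
}

# ---- SASA ---------------------------------------------------------------

# deterministic quasi-uniform sphere points (golden-section spiral)
.sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  th <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(th), sin(phi) * sin(th), cos(phi))
}

#' Shrake-Rupley solvent accessible surface area
#'
#' Classic rolling-probe SASA: for each atom, test points on a sphere of
#' radius r_atom + probe; the accessible fraction (points not buried inside
#' any neighbour's expanded sphere) times the sphere area gives the
#' per-atom SASA.
#'
#' @param s a `mol_structure`
#' @param probe probe radius, Angstrom (water = 1.4)
#' @param npoints test points per atom
#' @param radii_table optional van der Waals radius override
#'   (see [vdw_radii()])
#' @return object of class `sasa_result`: list(atom_area, total, probe,
#'   npoints)
#' @export
sasa <- function(s, probe = 1.4, npoints = 960, radii_table = NULL) {
  xyz <- coords(s)
  r <- vdw_radii(s$atoms$element, radii_table) + probe
  n <- nrow(xyz)
  pts <- .sphere_points(npoints)
  area <- numeric(n)
  # neighbour lists from one distance matrix (desk-scale structures)
  dm <- cross_dist(xyz, xyz)
  for (i in seq_len(n)) {
    nb <- which(dm[i, ] < r[i] + r & seq_len(n) != i)
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")
    if (length(nb)) {
      free <- rep(TRUE, npoints)
      for (j in nb) {
        if (!any(free)) break
        d2 <- rowSums(sweep(p[free, , drop = FALSE], 2, xyz[j, ])^2)
        buried <- d2 < r[j]^2
        free[free][buried] <- FALSE
      }
      frac <- sum(free) / npoints
    } else frac <- 1
    area[i] <- frac * 4 * pi * r[i]^2
  }
  structure(list(atom_area = area, total = sum(area), probe = probe,
                 npoints = npoints), class = "sasa_result")
}

#' @export
print.sasa_result <- function(x, ...) {
  cat(sprintf("<sasa_result> total %.1f A^2 over %d atoms (probe %.2f A)\n",
              x$total, length(x$atom_area), x$probe))
  invisible(x)
}

#' Cavity SASA series over a trajectory
#'
#' Per frame, the summed per-atom SASA of the listed residues computed in
#' the context of the full structure -- used to quantify the openness of
#' the intracellular G-protein binding cavity from a fixed residue list.
#'
#' @param t a `mol_trajectory`
#' @param cavity_residues residue uids or generic labels
#' @param ... passed to [sasa()]
#' @return numeric series, Angstrom^2
#' @export
cavity_sasa <- function(t, cavity_residues, ...) {
  s <- t$topology
  uids <- unique(s$atoms$uid)
  res <- character(0)
  for (cr in cavity_residues) {
    if (cr %in% uids) res <- c(res, cr)
    else if (!is.null(s$numbering) && cr %in% s$numbering$label)
      res <- c(res, s$numbering$uid[s$numbering$label == cr])
    else stop("unresolvable cavity residue: ", cr)
  }
  idx <- which(s$atoms$uid %in% res)
  out <- numeric(n_frames(t))
  for (f in seq_len(n_frames(t))) {
    sa <- sasa(frame_structure(t, f), ...)
    out[f] <- sum(sa$atom_area[idx])
  }
  out
}

#' Helix-helix distance series
#'
#' Per frame, the distance between the centres of mass of the C-alpha
#' atoms of two residue ranges (e.g. the intracellular ends of TM helices).
#'
#' @param t a `mol_trajectory`
#' @param range_a,range_b selection expressions (C-alpha atoms are used)
#' @return object of class `distance_series` with a histogram in
#'   `$histogram`
#' @export
helix_distance <- function(t, range_a, range_b) {
  s <- t$topology
  ai <- select_atoms(s, range_a); bi <- select_atoms(s, range_b)
  ai <- ai[s$atoms$name[ai] == "CA"]; bi <- bi[s$atoms$name[bi] == "CA"]
  if (!length(ai) || !length(bi)) stop("range contains no C-alpha atoms")
  nf <- n_frames(t)
  v <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- t$coords[, , f]
    v[f] <- vnorm(colMeans(m[ai, , drop = FALSE]) -
                  colMeans(m[bi, , drop = FALSE]))
  }
  structure(list(values = v, mean = mean(v), sd = stats::sd(v),
                 histogram = graphics::hist(v, plot = FALSE)),
            class = "distance_series")
}

# ---- secondary structure ------------------------------------------------

# Rebuild the amide H when absent: 1.01 A from N, opposite the bisector of
# C(i-1)-N-CA. Needed because trajectory dialects often strip hydrogens.
.amide_h <- function(n_xyz, cprev_xyz, ca_xyz) {
  u <- -(unitv(cprev_xyz - n_xyz) + unitv(ca_xyz - n_xyz))
  n_xyz + 1.01 * unitv(u)
}

.backbone_table <- function(s) {
  a <- s$atoms
  rs <- residues(s)
  rs <- rs[!rs$uid %in% a$uid[a$hetero], , drop = FALSE]
  get1 <- function(uid, nm) {
    i <- which(a$uid == uid & a$name == nm)
    if (length(i)) i[1] else NA_integer_
  }
  bb <- data.frame(uid = rs$uid,
                   N = vapply(rs$uid, get1, 0L, nm = "N"),
                   CA = vapply(rs$uid, get1, 0L, nm = "CA"),
                   C = vapply(rs$uid, get1, 0L, nm = "C"),
                   O = vapply(rs$uid, get1, 0L, nm = "O"),
                   H = vapply(rs$uid, get1, 0L, nm = "H"),
                   chain = rs$chain, resno = rs$resno,
                   stringsAsFactors = FALSE)
  rownames(bb) <- NULL
  bb
}

#' Kabsch-Sander secondary structure assignment (H/E/C)
#'
#' Backbone hydrogen bonds are scored with the Kabsch-Sander electrostatic
#' model, E = 0.084 * 332 * (1/d_ON + 1/d_CH - 1/d_OH - 1/d_CN) kcal/mol,
#' a bond existing when E < -0.5 kcal/mol. A residue is labelled H when it
#' lies within two consecutive i -> i+4 turns; strand (E) is assigned from
#' parallel/antiparallel bridge patterns; everything else is coil. The
#' amide H is reconstructed geometrically when missing.
#'
#' @param s a `mol_structure` with backbone N, CA, C, O atoms
#' @return data.frame residue uid, ss in {H, E, C} (class `ss_assignment`)
#' @export
assign_ss <- function(s) {
  bb <- .backbone_table(s)
  n <- nrow(bb)
  xyz <- coords(s)
  ok <- !is.na(bb$N) & !is.na(bb$CA) & !is.na(bb$C) & !is.na(bb$O)
  if (any(!ok)) warning("residues lacking backbone atoms skipped: ",
                        paste(bb$uid[!ok], collapse = ", "))
  # H coordinates (explicit or reconstructed; first residue of a chain has none)
  hxyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    if (!ok[i]) next
    if (!is.na(bb$H[i])) { hxyz[i, ] <- xyz[bb$H[i], ]; next }
    if (i > 1 && ok[i - 1] && bb$chain[i - 1] == bb$chain[i] &&
        bb$resno[i] - bb$resno[i - 1] == 1L)
      hxyz[i, ] <- .amide_h(xyz[bb$N[i], ], xyz[bb$C[i - 1], ], xyz[bb$CA[i], ])
  }
  # hb[i, j]: N-H of residue i donates to C=O of residue j
  hb <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    if (!ok[i] || any(is.na(hxyz[i, ]))) next
    for (j in seq_len(n)) {
      if (!ok[j] || abs(i - j) < 2) next
      dON <- vnorm(xyz[bb$O[j], ] - xyz[bb$N[i], ])
      if (dON > 5.5) next
      dCH <- vnorm(xyz[bb$C[j], ] - hxyz[i, ])
      dOH <- vnorm(xyz[bb$O[j], ] - hxyz[i, ])
      dCN <- vnorm(xyz[bb$C[j], ] - xyz[bb$N[i], ])
      e <- 0.084 * 332 * (1 / dON + 1 / dCH - 1 / dOH - 1 / dCN)
      hb[i, j] <- e < -0.5
    }
  }
  ss <- rep("C", n)
  # alpha helix: two consecutive i -> i+4 turns cover residues i+1 .. i+5
  turn <- vapply(seq_len(n), function(i)
    i + 4 <= n && hb[i + 4, i], logical(1))
  for (i in seq_len(n - 1)) if (turn[i] && turn[i + 1])
    ss[(i + 1):min(n, i + 5)] <- "H"
  # minimal bridge logic for strand
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (abs(i - j) < 3 || ss[i] == "H" || ss[j] == "H") next
    par <- (i > 1 && j < n && hb[i, j - 1] && hb[j + 1, i]) ||
           (j > 1 && i < n && hb[j, i - 1] && hb[i + 1, j])
    anti <- (hb[i, j] && hb[j, i]) ||
            (i > 1 && j < n && i < n && j > 1 &&
             hb[i + 1, j - 1] && hb[j + 1, i - 1])
    if (par || anti) { ss[i] <- "E"; ss[j] <- "E" }
  }
  out <- data.frame(residue = bb$uid, ss = ss, stringsAsFactors = FALSE)
  class(out) <- c("ss_assignment", "data.frame")
  out
}

#' Helix fraction of a region over a trajectory
#'
#' Mean over frames of (residues assigned H within the region) / (region
#' size); the standard way to quantify, e.g., helix formation in the ICL2
#' loop.
#'
#' @param t a `mol_trajectory`
#' @param region selection expression or residue uids
#' @param frames frame indices (default all)
#' @return scalar in [0, 1]
#' @export
helix_fraction <- function(t, region, frames = NULL) {
  if (is.null(frames)) frames <- seq_len(n_frames(t))
  s0 <- t$topology
  uids <- if (length(region) == 1L && !region[1] %in% s0$atoms$uid)
    select_residues(s0, region) else region
  if (!length(uids)) stop("empty region")
  fr <- vapply(frames, function(f) {
    ssa <- assign_ss(frame_structure(t, f))
    mean(ssa$ss[match(uids, ssa$residue)] == "H", na.rm = TRUE)
  }, 0)
  mean(fr)
}
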
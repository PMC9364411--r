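# Synthetic-structure and synthetic-ensemble generators.
#
# Everything the analysis pipeline consumes can be generated here with
# known ground truth: ideal helices and helix bundles standing in for a
# TM-bundle receptor, complexes with planted noncovalent interactions,
# harmonically jittered trajectories emulating equilibrium fluctuations,
# and multi-state Gaussian ensembles whose free-energy differences are
# known in closed form. All generators are deterministic given their seed.

# standard backbone internal coordinates
.BL <- c(N_CA = 1.458, CA_C = 1.525, C_N = 1.329, C_O = 1.231)
.BA <- c(N_CA_C = 111.2, CA_C_N = 116.2, C_N_CA = 121.7, CA_C_O = 120.8)

# place a point at (bond, angle, torsion) internal coordinates from c-b-a
.nerf <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- angle_deg * pi / 180; tor <- torsion_deg * pi / 180
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d <- c(-bond * cos(ang), bond * sin(ang) * cos(tor), bond * sin(ang) * sin(tor))
  c + d[1] * bc + d[2] * m + d[3] * n
}

#' Build an ideal polypeptide helix (or arbitrary phi/psi chain)
#'
#' Constructs backbone N, CA, C, O (plus amide H and a CB stub except for
#' Gly) from standard bond lengths/angles and the given backbone dihedrals.
#' Defaults (phi = -57, psi = -47) give an ideal alpha helix with a
#' C-alpha rise of about 1.5 Angstrom per residue.
#'
#' @param n_residues >= 4
#' @param sequence 1-letter amino acid string (recycled; default poly-Ala)
#' @param phi,psi backbone dihedrals, degrees
#' @param chain chain identifier
#' @param start_resno first residue number
#' @return a `mol_structure`
#' @export
build_helix <- function(n_residues, sequence = "A", phi = -57, psi = -47,
                        chain = "A", start_resno = 1L) {
  if (n_residues < 4) stop("need >= 4 residues")
  aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
           E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
           M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
           Y = "TYR", V = "VAL")
  seq1 <- strsplit(sequence, "")[[1]]
  seq1 <- rep(seq1, length.out = n_residues)
  resn <- aa3[seq1]
  if (any(is.na(resn))) stop("unknown residue letter in sequence")
  phi <- rep(phi, length.out = n_residues)
  psi <- rep(psi, length.out = n_residues)

  N <- matrix(NA_real_, n_residues, 3)
  CA <- N; C <- N; O <- N
  # seed residue along x
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(.BL["N_CA"], 0, 0)
  ang <- .BA["N_CA_C"] * pi / 180
  C[1, ] <- CA[1, ] + .BL["CA_C"] * c(-cos(ang), sin(ang), 0)
  for (i in seq_len(n_residues - 1)) {
    N[i + 1, ] <- .nerf(N[i, ], CA[i, ], C[i, ], .BL["C_N"], .BA["CA_C_N"], psi[i])
    CA[i + 1, ] <- .nerf(CA[i, ], C[i, ], N[i + 1, ], .BL["N_CA"], .BA["C_N_CA"], 180)
    C[i + 1, ] <- .nerf(C[i, ], N[i + 1, ], CA[i + 1, ], .BL["CA_C"], .BA["N_CA_C"], phi[i + 1])
  }
  for (i in seq_len(n_residues)) {
    O[i, ] <- .nerf(N[i, ], CA[i, ], C[i, ], .BL["C_O"], .BA["CA_C_O"], psi[i] + 180)
  }
  rows <- list(); serial <- 0L
  push <- function(nm, el, i, xyz) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = nm, element = el, chain = chain,
      resno = start_resno + i - 1L, icode = "", resname = resn[i],
      x = xyz[1], y = xyz[2], z = xyz[3], bfactor = 0, hetero = FALSE,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_residues)) {
    push("N", "N", i, N[i, ])
    if (i > 1) push("H", "H", i, .amide_h(N[i, ], C[i - 1, ], CA[i, ]))
    push("CA", "C", i, CA[i, ])
    if (resn[i] != "GLY") {
      # tetrahedral CB from N, C neighbours
      u1 <- unitv(N[i, ] - CA[i, ]); u2 <- unitv(C[i, ] - CA[i, ])
      bis <- unitv(u1 + u2); perp <- unitv(pracma_cross(u1, u2))
      cb <- CA[i, ] + 1.521 * (-bis * cos(0.9128) + perp * sin(0.9128))
      push("CB", "C", i, cb)
    }
    push("C", "C", i, C[i, ])
    push("O", "O", i, O[i, ])
  }
  new_structure(do.call(rbind, rows))
}

# helix axis by least-squares line through the C-alphas
.helix_axis <- function(s) {
  ca <- coords(s, select_atoms(s, "calpha"))
  c0 <- colMeans(ca)
  sv <- svd(sweep(ca, 2, c0))
  ax <- sv$v[, 1]
  if (sum(ax * (ca[nrow(ca), ] - ca[1, ])) < 0) ax <- -ax
  list(center = c0, axis = unitv(ax))
}

# rigid-transform a structure: rotate with R (rows = new basis) then shift
.transform <- function(s, rot, shift) {
  set_coords(s, sweep(coords(s) %*% t(rot), 2, shift, "+"))
}

# rotation taking unit vector a onto unit vector b
.rot_between <- function(a, b) {
  v <- pracma_cross(a, b); s <- vnorm(v); c <- sum(a * b)
  if (s < 1e-12) {
    if (c > 0) return(diag(3))
    p <- if (abs(a[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    v <- unitv(pracma_cross(a, p))
    return(2 * outer(v, v) - diag(3))
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c) / s^2)
}

#' Build a helix bundle
#'
#' Places copies of ideal helices with their axes vertical on a circle of
#' the given radius -- a minimal stand-in for the transmembrane bundle of
#' a GPCR. All helices share chain "A" with residue numbers offset by 100
#' per helix, and every residue is labelled TM1..TMn through the numbering
#' map. Structures with inter-helix atom clashes under `clash` error out.
#'
#' @param n_helices number of helices (>= 2), or a list of prebuilt helix
#'   `mol_structure`s
#' @param n_residues residues per helix (ignored when structures given)
#' @param ring_radius circle radius, Angstrom
#' @param sequence per-helix sequence string, recycled
#' @param clash minimum tolerated inter-helix atom distance, Angstrom
#' @return a `mol_structure` labelled TM1..TMn
#' @export
build_bundle <- function(n_helices, n_residues = 20, ring_radius = 9,
                         sequence = "A", clash = 2.0) {
  hel <- if (is.list(n_helices)) n_helices
         else lapply(seq_len(n_helices), function(k)
           build_helix(n_residues, sequence))
  nh <- length(hel)
  if (nh < 2) stop("need >= 2 helices")
  placed <- list()
  for (k in seq_len(nh)) {
    h <- hel[[k]]
    ax <- .helix_axis(h)
    rot <- .rot_between(ax$axis, c(0, 0, 1))
    h <- .transform(h, rot, c(0, 0, 0))
    c0 <- colMeans(coords(h, select_atoms(h, "calpha")))
    angle <- 2 * pi * (k - 1) / nh
    target <- c(ring_radius * cos(angle), ring_radius * sin(angle), 0)
    h <- .transform(h, diag(3), target - c0)
    h$atoms$resno <- h$atoms$resno + 100L * (k - 1L)
    h$atoms$serial <- h$atoms$serial + 10000L * (k - 1L)
    placed[[k]] <- h
  }
  atoms <- do.call(rbind, lapply(placed, function(h) h$atoms))
  atoms$uid <- NULL
  s <- new_structure(atoms)
  # clash check between different helices
  for (i in seq_len(nh - 1)) for (j in (i + 1):nh) {
    d <- min(cross_dist(coords(placed[[i]]), coords(placed[[j]])))
    if (d < clash)
      stop(sprintf("helix %d and helix %d clash: min distance %.2f A < %.2f A",
                   i, j, d, clash))
  }
  rs <- residues(s)
  tm <- paste0("TM", findInterval(rs$resno, seq(1, by = 100, length.out = nh)))
  s <- apply_numbering(s, data.frame(chain = rs$chain, resno = rs$resno,
                                     icode = rs$icode, label = tm))
  s
}

#' Default synthetic ligand chemistry template
#'
#' A small carboxylate ligand in the spirit of a fatty-acid-receptor
#' agonist: one carboxylate (acid_C + two acid_O), one benzene ring, one
#' H-bond-capable nitrogen and two apolar carbons.
#' @export
synthetic_ligand_template <- function() {
  data.frame(
    atom = c("C1", "O1", "O2", paste0("C", 2:7), "N1", "C8", "C9"),
    element = c("C", "O", "O", rep("C", 6), "N", "C", "C"),
    role = c("acid_C", "acid_O", "acid_O", rep("ring", 6), "donor",
             "apolar", "apolar"),
    ring = c("", "", "", rep("R1", 6), "", "", ""),
    stringsAsFactors = FALSE)
}

# place a single atom at distance d from `anchor`, choosing among
# deterministic candidate directions (locally emptiest first, then the
# radial direction and tilted variants) the first that keeps the new atom
# `clash`-free from every existing atom
.place_single <- function(s, anchor, d, radial, clash) {
  xyz <- coords(s)
  dd <- cross_dist(matrix(anchor, 1), xyz)[1, ]
  nb <- xyz[dd < 8 & dd > 1e-6, , drop = FALSE]
  void <- if (nrow(nb)) anchor - colMeans(nb) else radial
  cands <- list(void, radial, void + radial)
  for (base in list(void, radial)) {
    if (vnorm(base) < 1e-6) next
    fr <- .frame_of(base)
    for (th in c(30, 60) * pi / 180) for (sv in list(fr$v, -fr$v, fr$w, -fr$w))
      cands[[length(cands) + 1L]] <- cos(th) * fr$u + sin(th) * sv
  }
  for (u in cands) {
    if (vnorm(u) < 1e-6) next
    p <- anchor + d * unitv(u)
    if (min(cross_dist(matrix(p, 1), xyz)) >= clash) return(p)
  }
  stop(sprintf("unsatisfiable plan: no clash-free placement %.1f A from anchor",
               d))
}

# candidate outward directions for a residue: away from its own helix
# axis first (local C-alpha neighbourhood), then away from the bundle
# centre, then tilted variants -- tried in order until clash-free
.candidate_dirs <- function(s, uid, bundle_c) {
  a <- s$atoms
  ca <- as.numeric(coords(s, which(a$uid == uid & a$name == "CA")[1]))
  rn <- a$resno[a$uid == uid][1]; ch <- a$chain[a$uid == uid][1]
  nb <- which(a$name == "CA" & a$chain == ch & abs(a$resno - rn) <= 4 &
              a$uid != uid)
  loc <- if (length(nb)) ca - colMeans(coords(s, nb)) else ca - bundle_c
  rad <- ca - bundle_c
  out <- list()
  for (b in list(loc, rad, loc + rad)) {
    if (vnorm(b) < 1e-6) next
    out[[length(out) + 1L]] <- unitv(b)
    fr <- .frame_of(b)
    for (th in c(25, 50, 75) * pi / 180)
      for (sv in list(fr$v, -fr$v, fr$w, -fr$w))
        out[[length(out) + 1L]] <- cos(th) * fr$u + sin(th) * sv
  }
  out
}

# orthonormal frame with first axis u
.frame_of <- function(u) {
  u <- unitv(u)
  p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  v <- unitv(pracma_cross(u, p))
  w <- pracma_cross(u, v)
  list(u = u, v = v, w = w)
}

# minimal side-chain stubs: idealised charged / aromatic groups extended
# along the outward direction u from CA (geometry only needs to satisfy
# the detectors, not a force field)
.sidechain_stub <- function(resname, ca, fr) {
  u <- fr$u; v <- fr$v
  switch(resname,
    ARG = {
      cz <- ca + 4.0 * u
      list(names = c("CB", "CD", "CZ", "NE", "NH1", "NH2"),
           elements = c("C", "C", "C", "N", "N", "N"),
           xyz = rbind(ca + 1.52 * u, ca + 2.8 * u, cz,
                       cz - 1.33 * u,
                       cz + 1.33 * (0.5 * u + 0.866 * v),
                       cz + 1.33 * (0.5 * u - 0.866 * v)))
    },
    LYS = list(names = c("CB", "NZ"), elements = c("C", "N"),
               xyz = rbind(ca + 1.52 * u, ca + 4.0 * u)),
    ASP = {
      cg <- ca + 2.5 * u
      list(names = c("CB", "CG", "OD1", "OD2"),
           elements = c("C", "C", "O", "O"),
           xyz = rbind(ca + 1.52 * u, cg,
                       cg + 1.25 * (0.5 * u + 0.81 * v),
                       cg + 1.25 * (0.5 * u - 0.81 * v)))
    },
    GLU = {
      cd <- ca + 3.2 * u
      list(names = c("CB", "CD", "OE1", "OE2"),
           elements = c("C", "C", "O", "O"),
           xyz = rbind(ca + 1.52 * u, cd,
                       cd + 1.25 * (0.5 * u + 0.81 * v),
                       cd + 1.25 * (0.5 * u - 0.81 * v)))
    },
    PHE = {
      cen <- ca + 3.3 * u
      hex <- t(vapply(0:5, function(i) {
        a <- i * pi / 3
        cen + 1.39 * (cos(a) * fr$v + sin(a) * fr$w)
      }, numeric(3)))
      list(names = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
           elements = rep("C", 7),
           xyz = rbind(ca + 1.52 * u, hex))
    },
    stop("no side-chain stub for ", resname))
}

# replace a residue's side chain (and name) with an idealised stub
mutate_residue <- function(s, uid, resname, direction = NULL) {
  a <- s$atoms
  ri <- which(a$uid == uid)
  if (!length(ri)) stop("unknown residue: ", uid)
  ca <- which(a$uid == uid & a$name == "CA")
  if (!length(ca)) stop("residue has no CA: ", uid)
  ca_xyz <- as.numeric(coords(s, ca))
  if (is.null(direction)) {
    cas <- coords(s, select_atoms(s, "calpha"))
    direction <- ca_xyz - colMeans(cas)
    if (vnorm(direction) < 1e-6) direction <- c(1, 0, 0)
  }
  fr <- .frame_of(direction)
  stub <- .sidechain_stub(resname, ca_xyz, fr)
  keep <- !(a$uid == uid & !a$name %in% c("N", "H", "CA", "C", "O"))
  a <- a[keep, , drop = FALSE]
  a$resname[a$uid == uid] <- resname
  ins <- data.frame(serial = max(a$serial) + seq_along(stub$names),
                    name = stub$names, element = stub$elements,
                    chain = a$chain[a$uid == uid][1],
                    resno = a$resno[a$uid == uid][1],
                    icode = a$icode[a$uid == uid][1],
                    resname = resname,
                    x = stub$xyz[, 1], y = stub$xyz[, 2], z = stub$xyz[, 3],
                    bfactor = 0, hetero = FALSE, stringsAsFactors = FALSE)
  a$uid <- NULL
  out <- new_structure(rbind(a, ins))
  out$numbering <- s$numbering
  attr(out, "ligand_chem") <- attr(s, "ligand_chem")
  out
}

#' Plant a ligand with prescribed interactions into a receptor
#'
#' For each planted interaction the target residue is (if necessary)
#' mutated to a type carrying the required chemical group, an idealised
#' side-chain stub is built pointing away from the bundle, and a matching
#' ligand group is placed so the planted geometry holds by construction:
#' salt bridges by charged-group centroid distance, hydrogen bonds by
#' donor-acceptor distance, pi stacks by parallel ring geometry at the
#' given centroid distance, hydrophobic contacts by apolar carbon pairs.
#'
#' @param receptor a `mol_structure` (e.g. [build_bundle()])
#' @param plan list of plants, each
#'   `list(kind =, residue = uid, distance =)`; supported kinds are
#'   salt_bridge, hbond, pi_stack, hydrophobic
#' @param ligand_template ligand chemistry (default
#'   [synthetic_ligand_template()])
#' @param clash minimum tolerated distance between ligand atoms and
#'   anything else
#' @return a `mol_structure` with the ligand as chain "L" residue LIG 1
#'   and the template attached as `attr(, "ligand_chem")`
#' @export
plant_complex <- function(receptor, plan,
                          ligand_template = synthetic_ligand_template(),
                          clash = 2.0) {
  s <- receptor
  tpl <- read_ligand_template(ligand_template)
  lig <- list(); lig_serial <- 0L; lig_grp <- integer(0); cur_grp <- 0L
  cas_all <- coords(s, select_atoms(s, "calpha"))
  bundle_c <- colMeans(cas_all)
  add_lig <- function(nm, el, xyz) {
    lig_serial <<- lig_serial + 1L
    lig_grp <<- c(lig_grp, cur_grp)
    lig[[length(lig) + 1L]] <<- data.frame(
      serial = 90000L + lig_serial, name = nm, element = el, chain = "L",
      resno = 1L, icode = "", resname = "LIG",
      x = xyz[1], y = xyz[2], z = xyz[3], bfactor = 0, hetero = TRUE,
      stringsAsFactors = FALSE)
  }
  used <- character(0)
  copy_n <- 0L
  uniq <- function(base) {
    if (!base %in% used) { used <<- c(used, base); return(base) }
    copy_n <<- copy_n + 1L
    nm <- paste0(base, ".", copy_n); used <<- c(used, nm); nm
  }
  for (p in plan) {
    cur_grp <- cur_grp + 1L
    uid <- p$residue
    d <- p$distance %||% switch(p$kind, salt_bridge = 3.0, hbond = 3.0,
                                pi_stack = 3.8, hydrophobic = 3.8)
    dirs <- .candidate_dirs(s, uid, bundle_c)
    if (p$kind %in% c("salt_bridge", "pi_stack")) {
      resname <- if (p$kind == "salt_bridge") "ARG" else "PHE"
      placed <- FALSE
      for (u in dirs) {
        s_try <- mutate_residue(s, uid, resname, direction = u)
        at <- s_try$atoms
        stub_idx <- which(at$uid == uid &
                          !at$name %in% c("N", "H", "CA", "C", "O"))
        other <- which(at$uid != uid)
        if (min(cross_dist(coords(s_try, stub_idx),
                           coords(s_try, other))) < 1.8) next
        fr <- .frame_of(u)
        if (p$kind == "salt_bridge") {
          gi <- which(at$uid == uid & at$name %in% .CHARGED[[resname]]$atoms)
          cen <- centroid(coords(s_try, gi))
          # carboxylate C beyond the O centroid, O-O axis out of the
          # guanidinium plane: bidentate-like geometry without C..N contact
          cc <- cen + (d + 0.625) * fr$u
          lig_xyz <- rbind(cc,
                           cc - 1.25 * (0.5 * fr$u - 0.81 * fr$w),
                           cc - 1.25 * (0.5 * fr$u + 0.81 * fr$w))
          lig_nm <- c("C1", "O1", "O2"); lig_el <- c("C", "O", "O")
        } else {
          gi <- which(at$uid == uid & at$name %in% .AROMATIC[[resname]])
          m <- coords(s_try, gi)
          cen <- centroid(m)
          nrm <- plane_normal(m)
          if (sum(nrm * fr$u) < 0) nrm <- -nrm
          cen2 <- cen + d * nrm
          fr2 <- .frame_of(nrm)
          lig_xyz <- t(vapply(0:5, function(i) {
            a <- i * pi / 3
            cen2 + 1.39 * (cos(a) * fr2$v + sin(a) * fr2$w)
          }, numeric(3)))
          lig_nm <- paste0("C", 2:7); lig_el <- rep("C", 6)
        }
        if (min(cross_dist(lig_xyz, coords(s_try))) < min(clash, d - 0.8))
          next
        s <- s_try
        for (i in seq_along(lig_nm))
          add_lig(uniq(lig_nm[i]), lig_el[i], lig_xyz[i, ])
        placed <- TRUE
        break
      }
      if (!placed)
        stop("unsatisfiable plan: no clash-free ", p$kind, " placement at ", uid)
    } else if (p$kind == "hbond") {
      oi <- which(s$atoms$uid == uid & s$atoms$name == "O")
      o_xyz <- as.numeric(coords(s, oi))
      add_lig(uniq("N1"), "N", .place_single(s, o_xyz, d, dirs[[1]], clash))
    } else if (p$kind == "hydrophobic") {
      cbi <- which(s$atoms$uid == uid & s$atoms$name == "CB")
      if (!length(cbi)) stop("residue has no CB for hydrophobic plant: ", uid)
      cb <- as.numeric(coords(s, cbi))
      add_lig(uniq("C8"), "C", .place_single(s, cb, d, dirs[[1]], clash))
    } else stop("unknown plant kind: ", p$kind)
  }
  if (!length(lig)) {
    attr(s, "ligand_chem") <- tpl
    attr(s, "plan") <- plan
    return(s)
  }
  lig_df <- do.call(rbind, lig)
  a <- s$atoms; a$uid <- NULL
  out <- new_structure(rbind(a, lig_df))
  out$numbering <- s$numbering
  # clash checks: ligand vs receptor, and ligand groups against each other
  li <- which(out$atoms$chain == "L")
  dm <- cross_dist(coords(out, li), coords(out, setdiff(seq_len(nrow(out$atoms)), li)))
  if (min(dm) < clash)
    stop(sprintf("unsatisfiable plan: ligand-receptor clash at %.2f A", min(dm)))
  if (max(lig_grp) > 1L) {
    lxyz <- coords(out, li)
    dmx <- cross_dist(lxyz, lxyz)
    same <- outer(lig_grp, lig_grp, "==")
    if (min(dmx[!same]) < clash)
      stop(sprintf("unsatisfiable plan: planted ligand groups clash at %.2f A",
                   min(dmx[!same])))
  }
  attr(out, "ligand_chem") <- tpl
  attr(out, "plan") <- plan
  out
}

#' Harmonically jittered trajectory around a structure
#'
#' Frames are the input coordinates plus i.i.d. Gaussian noise with the
#' given per-coordinate standard deviation -- a minimal model of
#' equilibrium fluctuation about a mean structure. Deterministic given
#' the seed.
#'
#' @param s0 a `mol_structure`
#' @param sigma per-coordinate standard deviation, Angstrom (scalar or
#'   per-atom vector)
#' @param n_frames number of frames
#' @param seed RNG seed
#' @return a `mol_trajectory`
#' @export
jitter_trajectory <- function(s0, sigma, n_frames, seed = 1L) {
  if (any(sigma < 0)) stop("sigma must be non-negative")
  nat <- nrow(s0$atoms)
  sigma <- rep(sigma, length.out = nat)
  set.seed(seed)
  base <- coords(s0)
  arr <- array(rnorm(nat * 3 * n_frames, sd = sigma), dim = c(nat, 3, n_frames))
  arr <- arr + array(base, dim = c(nat, 3, n_frames))
  new_trajectory(s0, arr)
}

#' Multi-state Gaussian ensemble with analytic free energies
#'
#' One-dimensional harmonic states u_k(x) = kappa_k (x - mu_k)^2 / 2 in
#' reduced units. Samples are drawn from each state's Boltzmann density
#' (a Gaussian with sd 1/sqrt(kappa_k)); the reduced-potential matrix is
#' evaluated analytically and the exact reduced free energies
#' f_k = -ln sqrt(2 pi / kappa_k) are returned (anchored at state 1), so
#' estimator output can be checked against closed form.
#'
#' @param kappa per-state force constants (> 0)
#' @param mu per-state means (recycled, default 0)
#' @param n per-state sample counts (recycled)
#' @param temperature Kelvin (metadata only; u is already reduced)
#' @param seed RNG seed
#' @return list(ensemble = [new_ensemble()], f_true = analytic f_k - f_1)
#' @export
gen_ensemble <- function(kappa, mu = 0, n = 1000, temperature = 300,
                         seed = 1L) {
  if (any(kappa <= 0)) stop("kappa must be positive")
  k <- length(kappa)
  mu <- rep(mu, length.out = k)
  n <- rep(n, length.out = k)
  set.seed(seed)
  x <- unlist(lapply(seq_len(k), function(i)
    rnorm(n[i], mean = mu[i], sd = 1 / sqrt(kappa[i]))))
  u <- vapply(x, function(xi) kappa * (xi - mu)^2 / 2, numeric(k))
  u <- matrix(u, nrow = k)
  f_true <- -log(sqrt(2 * pi / kappa))
  list(ensemble = new_ensemble(u, n, temperature),
       f_true = f_true - f_true[1])
}
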
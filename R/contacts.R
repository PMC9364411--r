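# Geometric detection of noncovalent interactions.
#
# Criteria follow the PLIP-style geometric rules commonly used for
# protein-ligand interaction profiling; every cutoff is a config value
# (see contact_params).

#' Geometric cutoffs for interaction detection
#'
#' @param salt_bridge max distance between centroids of oppositely charged
#'   groups, Angstrom
#' @param hbond_da max donor-acceptor heavy-atom distance when an explicit
#'   hydrogen is present, Angstrom
#' @param hbond_angle min D-H...A angle, degrees
#' @param hbond_heavy heavy-atom-only fallback donor-acceptor cutoff used
#'   when the donor carries no explicit hydrogen, Angstrom
#' @param pi_dist max ring-centroid distance, Angstrom
#' @param pi_parallel max inter-plane angle for parallel stacking, degrees
#' @param pi_tshape inter-plane angle window for T-shaped stacking, degrees
#' @param pi_offset max in-plane centroid offset, Angstrom
#' @param hydrophobic max apolar-carbon pair distance, Angstrom
#' @export
contact_params <- function(salt_bridge = 5.5,
                           hbond_da = 3.6, hbond_angle = 120, hbond_heavy = 3.5,
                           pi_dist = 5.5, pi_parallel = 30,
                           pi_tshape = c(60, 90), pi_offset = 2.0,
                           hydrophobic = 4.0) {
  as.list(environment())
}

# hydrogens covalently attached to a donor heavy atom (same residue, < 1.3 A)
.attached_h <- function(s, donor_idx) {
  a <- s$atoms
  h <- which(a$element == "H" & a$uid == a$uid[donor_idx])
  if (!length(h)) return(integer(0))
  d <- cross_dist(coords(s, donor_idx), coords(s, h))[1, ]
  h[d < 1.3]
}

.protein_groups <- function(s, idx, his_protonated = character()) {
  a <- s$atoms
  sub <- a[idx, , drop = FALSE]
  uids <- unique(sub$uid)
  charged <- list(); rings <- list()
  donors <- integer(0); acceptors <- integer(0); apolar <- integer(0)
  for (u in uids) {
    ri <- idx[sub$uid == u]
    rn <- a$resname[ri[1]]
    nm <- a$name[ri]
    tpl <- .CHARGED[[rn]]
    if (!is.null(tpl) && (!tpl$protonation || u %in% his_protonated)) {
      g <- ri[nm %in% tpl$atoms]
      if (length(g)) charged[[u]] <- list(uid = u, sign = tpl$sign, idx = g)
    }
    arom <- .AROMATIC[[rn]]
    if (!is.null(arom)) {
      g <- ri[nm %in% arom]
      if (length(g) >= 3) rings[[u]] <- list(uid = u, idx = g)
    }
    donors <- c(donors, ri[nm == "N"], ri[nm %in% .SC_DONORS[[rn]]])
    acceptors <- c(acceptors, ri[nm == "O"], ri[nm %in% .SC_ACCEPTORS[[rn]]])
    apolar <- c(apolar, ri[nm %in% .APOLAR[[rn]]])
  }
  list(charged = charged, rings = rings, donors = donors,
       acceptors = acceptors, apolar = apolar)
}

.ligand_groups <- function(s, idx, chem) {
  a <- s$atoms
  nm <- a$name[idx]
  role_of <- setNames(chem$role, chem$atom)
  ring_of <- setNames(chem$ring, chem$atom)
  role <- role_of[sub("\\.\\d+$", "", nm)]       # planted copies keep base name + suffix
  role[is.na(role)] <- role_of[nm][is.na(role)]
  role[is.na(role)] <- "none"
  ring <- ring_of[sub("\\.\\d+$", "", nm)]
  ring[is.na(ring) | role != "ring"] <- ""
  charged <- list()
  acid <- idx[role == "acid_O"]
  if (length(acid)) charged[["LIG-"]] <- list(uid = "LIG", sign = -1L, idx = acid)
  base <- idx[role == "base_N"]
  if (length(base)) charged[["LIG+"]] <- list(uid = "LIG", sign = +1L, idx = base)
  rings <- list()
  for (rid in setdiff(unique(ring), "")) {
    g <- idx[ring == rid]
    if (length(g) >= 3) rings[[rid]] <- list(uid = "LIG", idx = g)
  }
  list(charged = charged, rings = rings,
       donors = idx[role %in% c("donor", "base_N")],
       acceptors = idx[role %in% c("acceptor", "acid_O")],
       apolar = idx[role == "apolar"])
}

.hbond_pairs <- function(s, don, acc, p) {
  if (!length(don) || !length(acc)) return(NULL)
  out <- list()
  dm <- cross_dist(coords(s, don), coords(s, acc))
  for (i in seq_along(don)) {
    hs <- .attached_h(s, don[i])
    for (j in seq_along(acc)) {
      if (s$atoms$uid[don[i]] == s$atoms$uid[acc[j]]) next
      d <- dm[i, j]
      if (length(hs)) {
        if (d > p$hbond_da) next
        ang <- max(vapply(hs, function(h)
          angle_deg(coords(s, don[i])[1, ], coords(s, h)[1, ],
                    coords(s, acc[j])[1, ]), 0))
        if (ang >= p$hbond_angle)
          out[[length(out) + 1L]] <- c(i = don[i], j = acc[j], d = d, ang = ang)
      } else if (d <= p$hbond_heavy) {
        out[[length(out) + 1L]] <- c(i = don[i], j = acc[j], d = d, ang = NA)
      }
    }
  }
  if (!length(out)) NULL else do.call(rbind, out)
}

#' Detect noncovalent protein-ligand interactions in one structure
#'
#' Applies geometric rules per interaction kind: salt bridges as
#' centroid distance between opposite formal-charge groups; hydrogen bonds
#' by donor-acceptor distance and D-H...A angle (heavy-atom fallback when
#' the donor carries no hydrogen); pi stacking by ring-centroid distance,
#' inter-plane angle (parallel or T-shaped window) and in-plane offset;
#' hydrophobic contacts as apolar carbon pairs. Protein chemistry comes
#' from built-in residue templates; ligand chemistry from a template
#' (see [read_ligand_template()]).
#'
#' @param s a `mol_structure`
#' @param ligand selection expression (or atom indices) for the ligand
#' @param kinds subset of `c("salt_bridge","hbond","pi_stack","hydrophobic")`
#' @param ligand_chem ligand template data.frame; defaults to
#'   `attr(s, "ligand_chem")`
#' @param params [contact_params()]
#' @param his_protonated residue uids of His residues to treat as charged
#' @param frame_index frame index stored in the records
#' @return data.frame with columns kind, residue, partner, dist, angle,
#'   offset, frame
#' @export
detect_interactions <- function(s, ligand,
                                kinds = c("salt_bridge", "hbond", "pi_stack",
                                          "hydrophobic"),
                                ligand_chem = attr(s, "ligand_chem"),
                                params = contact_params(),
                                his_protonated = character(),
                                frame_index = 0L) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  lig_idx <- if (is.numeric(ligand)) as.integer(ligand) else select_atoms(s, ligand)
  if (!length(lig_idx)) stop("ligand selection is empty")
  if (is.null(ligand_chem))
    stop("no ligand chemistry template (ligand_chem) available")
  ligand_chem <- read_ligand_template(ligand_chem)
  prot_idx <- setdiff(seq_len(nrow(s$atoms)), lig_idx)
  pg <- .protein_groups(s, prot_idx, his_protonated)
  lg <- .ligand_groups(s, lig_idx, ligand_chem)
  rec <- list()
  add <- function(kind, residue, dist, angle = NA, offset = NA)
    rec[[length(rec) + 1L]] <<- data.frame(kind = kind, residue = residue,
      partner = "LIG", dist = dist, angle = angle, offset = offset,
      frame = frame_index, stringsAsFactors = FALSE)

  if ("salt_bridge" %in% kinds && length(lg$charged) && length(pg$charged)) {
    for (gl in lg$charged) for (gp in pg$charged) {
      if (gl$sign * gp$sign >= 0) next
      d <- vnorm(centroid(coords(s, gl$idx)) - centroid(coords(s, gp$idx)))
      if (d <= params$salt_bridge) add("salt_bridge", gp$uid, d)
    }
  }
  if ("hbond" %in% kinds) {
    hb1 <- .hbond_pairs(s, lg$donors, pg$acceptors, params)
    hb2 <- .hbond_pairs(s, pg$donors, lg$acceptors, params)
    for (hb in list(hb1, hb2)) if (!is.null(hb))
      for (r in seq_len(nrow(hb))) {
        uid_i <- s$atoms$uid[hb[r, "i"]]; uid_j <- s$atoms$uid[hb[r, "j"]]
        resu <- if (uid_i %in% s$atoms$uid[prot_idx]) uid_i else uid_j
        add("hbond", resu, hb[r, "d"], hb[r, "ang"])
      }
  }
  if ("pi_stack" %in% kinds && length(lg$rings) && length(pg$rings)) {
    for (rl in lg$rings) for (rp in pg$rings) {
      ml <- coords(s, rl$idx); mp <- coords(s, rp$idx)
      cl <- centroid(ml); cp <- centroid(mp)
      d <- vnorm(cl - cp)
      if (d > params$pi_dist) next
      ang <- plane_angle(plane_normal(ml), plane_normal(mp))
      par_ok <- ang <= params$pi_parallel
      t_ok <- ang >= params$pi_tshape[1] && ang <= params$pi_tshape[2]
      if (!par_ok && !t_ok) next
      off <- min(ring_offset(cl, plane_normal(ml), cp),
                 ring_offset(cp, plane_normal(mp), cl))
      if (off <= params$pi_offset) add("pi_stack", rp$uid, d, ang, off)
    }
  }
  if ("hydrophobic" %in% kinds && length(lg$apolar) && length(pg$apolar)) {
    dm <- cross_dist(coords(s, lg$apolar), coords(s, pg$apolar))
    hit <- which(dm <= params$hydrophobic, arr.ind = TRUE)
    if (nrow(hit)) {
      uids <- s$atoms$uid[pg$apolar[hit[, 2]]]
      for (u in unique(uids)) {
        sel <- uids == u
        add("hydrophobic", u, min(dm[hit[sel, , drop = FALSE]]))
      }
    }
  }
  if (!length(rec))
    return(data.frame(kind = character(), residue = character(),
                      partner = character(), dist = numeric(),
                      angle = numeric(), offset = numeric(),
                      frame = integer(), stringsAsFactors = FALSE))
  out <- do.call(rbind, rec)
  out <- out[!duplicated(out[, c("kind", "residue")]), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Interaction fingerprint over a trajectory window
#'
#' For every (residue, interaction kind) pair observed in the window,
#' reports the occupancy: the fraction of window frames in which the
#' interaction is detected. Rows are limited to residues that actually
#' contact the ligand (every detected interaction lies within its kind's
#' geometric cutoff).
#'
#' @param t a `mol_trajectory`
#' @param ligand ligand selection expression
#' @param window integer vector of frame indices (default: all frames)
#' @param ... passed to [detect_interactions()]
#' @return data.frame residue, kind, occupancy (class `fingerprint`), with
#'   a residue x kind occupancy matrix in `attr(, "matrix")`
#' @export
fingerprint <- function(t, ligand, window = NULL, ...) {
  if (is.null(window)) window <- seq_len(n_frames(t))
  if (!length(window)) stop("empty frame window")
  if (any(window < 1 | window > n_frames(t))) stop("window outside trajectory")
  counts <- list()
  chem <- attr(t$topology, "ligand_chem")
  for (f in window) {
    s <- frame_structure(t, f)
    attr(s, "ligand_chem") <- chem
    det <- detect_interactions(s, ligand, frame_index = f, ...)
    if (nrow(det)) {
      key <- paste(det$residue, det$kind, sep = "\r")
      for (k in key) counts[[k]] <- (counts[[k]] %||% 0L) + 1L
    }
  }
  if (!length(counts)) {
    fp <- data.frame(residue = character(), kind = character(),
                     occupancy = numeric(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(names(counts), "\r", fixed = TRUE)
    fp <- data.frame(residue = vapply(parts, `[`, "", 1),
                     kind = vapply(parts, `[`, "", 2),
                     occupancy = unlist(counts) / length(window),
                     stringsAsFactors = FALSE)
    fp <- fp[order(fp$residue, fp$kind), ]
    rownames(fp) <- NULL
  }
  m <- if (nrow(fp)) {
    tab <- tapply(fp$occupancy, list(fp$residue, fp$kind), sum)
    tab[is.na(tab)] <- 0
    tab
  } else matrix(numeric(0), 0, 0)
  structure(fp, matrix = m, class = c("fingerprint", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Salt-bridge distance series
#'
#' Per frame, the minimum distance over all (acidic oxygen, basic nitrogen)
#' atom pairs between the two selections, as used for carboxylate-arginine
#' salt bridges. Ties at the minimum resolve to the first pair in atom
#' order.
#'
#' @param t a `mol_trajectory`
#' @param acid_group selection for the acidic partner (its O atoms are used)
#' @param base_group selection for the basic partner (its N atoms are used)
#' @return object of class `distance_series`: list(values, mean, sd, pairs)
#' @export
saltbridge_series <- function(t, acid_group, base_group) {
  s <- t$topology
  ai <- select_atoms(s, acid_group); bi <- select_atoms(s, base_group)
  ai <- ai[s$atoms$element[ai] == "O"]
  bi <- bi[s$atoms$element[bi] == "N"]
  if (!length(ai)) stop("acid selection contains no oxygen atoms")
  if (!length(bi)) stop("base selection contains no nitrogen atoms")
  nf <- n_frames(t)
  v <- numeric(nf)
  for (f in seq_len(nf)) {
    m <- t$coords[, , f]
    v[f] <- min(cross_dist(m[ai, , drop = FALSE], m[bi, , drop = FALSE]))
  }
  structure(list(values = v, mean = mean(v), sd = stats::sd(v),
                 acid_atoms = ai, base_atoms = bi),
            class = "distance_series")
}

#' @export
print.distance_series <- function(x, ...) {
  cat(sprintf("<distance_series> %d frames: mean %.3f A, sd %.3f A\n",
              length(x$values), x$mean, x$sd))
  invisible(x)
}

#' @export
plot.distance_series <- function(x, ...) {
  graphics::plot(seq_along(x$values), x$values, type = "l",
                 xlab = "frame", ylab = "distance (A)", ...)
  graphics::abline(h = x$mean, lty = 2)
  invisible(x)
}

#' Write a fingerprint as a TSV matrix
#' @param fp a [fingerprint()] result
#' @param file output path
#' @export
write_fingerprint <- function(fp, file) {
  m <- attr(fp, "matrix")
  df <- data.frame(residue = rownames(m), as.data.frame(m), check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
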
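# Chemistry templates for the geometric detectors.
#
# Charged-group templates follow standard protonation at pH 7: Asp/Glu
# carboxylates, Lys epsilon-amine, Arg guanidinium; His counts as positive
# only when explicitly flagged protonated.

.CHARGED <- list(
  ARG = list(atoms = c("NE", "NH1", "NH2"), sign = +1L, protonation = FALSE),
  LYS = list(atoms = "NZ",                  sign = +1L, protonation = FALSE),
  HIS = list(atoms = c("ND1", "NE2"),       sign = +1L, protonation = TRUE),
  ASP = list(atoms = c("OD1", "OD2"),       sign = -1L, protonation = FALSE),
  GLU = list(atoms = c("OE1", "OE2"),       sign = -1L, protonation = FALSE)
)

.AROMATIC <- list(
  PHE = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TYR = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  HIS = c("CG", "ND1", "CD2", "CE1", "NE2"),
  TRP = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

.SC_DONORS <- list(
  SER = "OG", THR = "OG1", TYR = "OH", ASN = "ND2", GLN = "NE2",
  TRP = "NE1", LYS = "NZ", ARG = c("NE", "NH1", "NH2"), HIS = c("ND1", "NE2")
)

.SC_ACCEPTORS <- list(
  ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"), SER = "OG", THR = "OG1",
  TYR = "OH", ASN = "OD1", GLN = "OE1", HIS = c("ND1", "NE2"), MET = "SD"
)

.APOLAR <- list(
  ALA = "CB", VAL = c("CB", "CG1", "CG2"), LEU = c("CB", "CG", "CD1", "CD2"),
  ILE = c("CB", "CG1", "CG2", "CD1"), MET = c("CB", "CG", "CE"),
  PRO = c("CB", "CG", "CD"),
  PHE = c("CB", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  TRP = c("CB", "CG", "CD2", "CE3", "CZ2", "CZ3", "CH2"),
  TYR = c("CB", "CG", "CD1", "CD2", "CE1", "CE2")
)

# Bondi van der Waals radii, Angstrom
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
            F = 1.47, CL = 1.75, BR = 1.85, I = 1.98)

#' Van der Waals radii for a vector of element symbols
#'
#' Bondi radii by default; a custom table (named vector or a two-column TSV
#' `element<TAB>radius`) may override or extend.
#'
#' @param elements character vector of element symbols
#' @param table optional named numeric vector or TSV path
#' @export
vdw_radii <- function(elements, table = NULL) {
  tab <- .BONDI
  if (!is.null(table)) {
    if (is.character(table)) {
      df <- read.delim(table, sep = "\t", header = TRUE)
      table <- setNames(df[[2]], toupper(df[[1]]))
    }
    tab[names(table)] <- table
  }
  r <- tab[toupper(elements)]
  if (any(is.na(r)))
    stop("no van der Waals radius for element(s): ",
         paste(unique(elements[is.na(r)]), collapse = ", "))
  unname(r)
}

#' Read a ligand chemistry template
#'
#' The detectors know protein chemistry from residue templates; ligand
#' chemistry is supplied as a TSV with columns `atom`, `element`, `role`
#' and optional `ring` (ring id grouping aromatic members). Recognised
#' roles: `acid_O`, `acid_C`, `base_N`, `ring`, `donor`, `acceptor`,
#' `apolar`, `none`.
#'
#' @param path TSV path or an equivalent data.frame
#' @export
read_ligand_template <- function(path) {
  df <- if (is.data.frame(path)) path
        else read.delim(path, sep = "\t", header = TRUE,
                        colClasses = "character")
  if (!all(c("atom", "element", "role") %in% names(df)))
    stop("ligand template needs columns atom, element, role")
  if (is.null(df$ring)) df$ring <- ""
  df$ring[is.na(df$ring)] <- ""
  df
}

# ---- geometry helpers ---------------------------------------------------

vnorm <- function(v) sqrt(sum(v^2))
unitv <- function(v) v / vnorm(v)

# distance matrix between two coordinate sets (rows)
cross_dist <- function(a, b) {
  a2 <- rowSums(a^2); b2 <- rowSums(b^2)
  d2 <- outer(a2, b2, "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0
  sqrt(d2)
}

centroid <- function(m) colMeans(m)

# least-squares plane normal of >= 3 points
plane_normal <- function(m) {
  c0 <- sweep(m, 2, colMeans(m))
  sv <- svd(c0)
  unitv(sv$v[, 3])
}

# acute angle between two planes, degrees
plane_angle <- function(n1, n2) {
  ca <- abs(sum(n1 * n2))
  acos(min(1, ca)) * 180 / pi
}

# in-plane offset of centroid c2 relative to ring (c1, n1)
ring_offset <- function(c1, n1, c2) {
  d <- c2 - c1
  vnorm(d - sum(d * n1) * n1)
}

angle_deg <- function(a, b, c) {
  v1 <- unitv(a - b); v2 <- unitv(c - b)
  acos(max(-1, min(1, sum(v1 * v2)))) * 180 / pi
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2); n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  x <- sum(n1 * n2); y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

pracma_cross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}
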
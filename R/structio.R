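#' @importFrom stats rnorm sd quantile setNames uniroot integrate optim runif
#' @importFrom utils read.delim write.table head
NULL

res_uid <- function(chain, resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == "", "", icode)
  paste0(chain, ":", resno, icode)
}

#' Construct a molecular structure
#'
#' The central container of the package: an ordered atom table plus an
#' optional generic residue-numbering map (e.g. Ballesteros-Weinstein labels
#' such as "5.39", or loop labels such as "ICL2").
#'
#' @param atoms data.frame with columns `serial`, `name`, `element`, `chain`,
#'   `resno`, `icode`, `resname`, `x`, `y`, `z`, `bfactor`, `hetero`.
#'   Coordinates are in Angstrom.
#' @param numbering optional data.frame with columns `chain`, `resno`,
#'   `icode`, `label` mapping residues to generic labels.
#' @return object of class `mol_structure`
#' @export
new_structure <- function(atoms, numbering = NULL) {
  need <- c("serial", "name", "element", "chain", "resno", "icode",
            "resname", "x", "y", "z", "bfactor", "hetero")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0L) stop("empty structure: no atoms")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite coordinates")
  if (anyDuplicated(atoms$serial)) stop("duplicate atom serial numbers")
  atoms$icode[is.na(atoms$icode)] <- ""
  atoms$uid <- res_uid(atoms$chain, atoms$resno, atoms$icode)
  rownames(atoms) <- NULL
  s <- list(atoms = atoms, numbering = NULL)
  class(s) <- "mol_structure"
  if (!is.null(numbering)) s <- apply_numbering(s, numbering)
  s
}

#' @export
print.mol_structure <- function(x, ...) {
  rs <- residues(x)
  cat(sprintf("<mol_structure> %d atoms, %d residues, %d chain(s)%s\n",
              nrow(x$atoms), nrow(rs), length(unique(x$atoms$chain)),
              if (is.null(x$numbering)) "" else
                sprintf(", %d labelled residues", nrow(x$numbering))))
  invisible(x)
}

#' Atom coordinates as an n x 3 matrix
#' @param s a `mol_structure`
#' @param idx optional atom indices
#' @export
coords <- function(s, idx = NULL) {
  m <- as.matrix(s$atoms[, c("x", "y", "z")])
  rownames(m) <- NULL
  if (is.null(idx)) m else m[idx, , drop = FALSE]
}

set_coords <- function(s, m) {
  stopifnot(nrow(m) == nrow(s$atoms))
  s$atoms$x <- m[, 1]; s$atoms$y <- m[, 2]; s$atoms$z <- m[, 3]
  s
}

#' Residue table of a structure
#'
#' One row per residue in atom order: chain, resno, icode, resname, uid and
#' (when a numbering map is attached) the generic label.
#' @param s a `mol_structure`
#' @export
residues <- function(s) {
  a <- s$atoms
  keep <- !duplicated(a$uid)
  r <- data.frame(chain = a$chain[keep], resno = a$resno[keep],
                  icode = a$icode[keep], resname = a$resname[keep],
                  uid = a$uid[keep], stringsAsFactors = FALSE)
  if (!is.null(s$numbering)) {
    r$label <- s$numbering$label[match(r$uid, s$numbering$uid)]
  } else r$label <- NA_character_
  rownames(r) <- NULL
  r
}

#' Attach a generic residue numbering map
#'
#' Maps residues (chain, resno, icode) to generic labels, e.g. the
#' Ballesteros-Weinstein positions "5.39" used across class A GPCRs, or
#' region labels such as "ICL2" shared by several residues. Selections can
#' then address residues by label.
#'
#' @param s a `mol_structure`
#' @param map data.frame with columns `chain`, `resno`, `icode`, `label`, or
#'   the path of a 4-column TSV file with those headers.
#' @param on_unmapped what to do when a map row names a residue absent from
#'   the structure: "error" (default) or "warn" (row dropped).
#' @export
apply_numbering <- function(s, map, on_unmapped = c("error", "warn")) {
  on_unmapped <- match.arg(on_unmapped)
  if (is.character(map) && length(map) == 1L) {
    map <- read.delim(map, sep = "\t", header = TRUE,
                      colClasses = c(chain = "character", icode = "character",
                                     label = "character"))
  }
  map <- as.data.frame(map)
  if (nrow(map) == 0L) return(s)
  need <- c("chain", "resno", "icode", "label")
  if (!all(need %in% names(map)))
    stop("numbering map needs columns: ", paste(need, collapse = ", "))
  map$icode[is.na(map$icode)] <- ""
  map$uid <- res_uid(map$chain, map$resno, map$icode)
  known <- unique(s$atoms$uid)
  bad <- setdiff(map$uid, known)
  if (length(bad)) {
    msg <- paste("numbering map names residues absent from structure:",
                 paste(bad, collapse = ", "))
    if (on_unmapped == "error") stop(msg)
    warning(msg)
    map <- map[map$uid %in% known, , drop = FALSE]
  }
  s$numbering <- map[, c("chain", "resno", "icode", "label", "uid")]
  s
}

# ---- PDB io (wrapping bio3d) -------------------------------------------

.pdb_text_to_file <- function(text) {
  if (length(text) == 1L && !grepl("\n", text) && file.exists(text)) return(text)
  f <- tempfile(fileext = ".pdb")
  writeLines(unlist(strsplit(paste(text, collapse = "\n"), "\n")), f)
  f
}

.validate_pdb_lines <- function(lines) {
  rec <- substr(lines, 1, 6)
  is_at <- rec %in% c("ATOM  ", "HETATM")
  if (!any(is_at)) stop("empty input: no ATOM/HETATM records")
  for (i in which(is_at)) {
    ln <- lines[i]
    if (nchar(ln) < 54)
      stop(sprintf("malformed PDB record at line %d: fewer than 54 columns", i))
    xyz <- suppressWarnings(as.numeric(c(substr(ln, 31, 38), substr(ln, 39, 46),
                                         substr(ln, 47, 54))))
    if (any(is.na(xyz)))
      stop(sprintf("malformed PDB record at line %d: non-numeric coordinate field", i))
  }
  invisible(TRUE)
}

.bio3d_to_atoms <- function(pdb) {
  a <- pdb$atom
  alt <- a$alt; alt[is.na(alt)] <- ""
  keep <- alt %in% c("", "A")          # deterministic geometry: first altloc only
  a <- a[keep, , drop = FALSE]
  elem <- a$elesy
  elem[is.na(elem) | elem == ""] <- toupper(substr(trimws(a$elety[is.na(elem) | elem == ""]), 1, 1))
  icode <- a$insert; icode[is.na(icode)] <- ""
  chain <- a$chain; chain[is.na(chain)] <- ""
  data.frame(serial = a$eleno, name = trimws(a$elety), element = toupper(trimws(elem)),
             chain = chain, resno = a$resno, icode = icode,
             resname = trimws(a$resid), x = a$x, y = a$y, z = a$z,
             bfactor = ifelse(is.na(a$b), 0, a$b), hetero = a$type == "HETATM",
             stringsAsFactors = FALSE)
}

#' Parse a PDB structure
#'
#' Reads fixed-column PDB (v3.3 ATOM/HETATM/MODEL/ENDMDL/TER records) from a
#' file or from a character string. Only the first MODEL is kept; alternate
#' locations other than '' / 'A' are dropped. Parsing is delegated to
#' \pkg{bio3d} after a light fixed-column validation that reports the first
#' offending line.
#'
#' @param text PDB file path or PDB-format text
#' @return a [new_structure()] object
#' @export
parse_pdb <- function(text) {
  f <- .pdb_text_to_file(text)
  lines <- readLines(f, warn = FALSE)
  .validate_pdb_lines(lines)
  pdb <- bio3d::read.pdb(f, multi = FALSE, verbose = FALSE, ATOM.only = TRUE)
  atoms <- .bio3d_to_atoms(pdb)
  keep <- !duplicated(atoms$serial)    # multi-model file read flat: keep model 1
  if (!all(keep)) atoms <- atoms[keep, , drop = FALSE]
  new_structure(atoms)
}

#' Parse a multi-model PDB as a trajectory
#'
#' Each MODEL becomes one frame; the topology (atom identities) is taken
#' from MODEL 1. All models must contain the same number of atoms.
#'
#' @param text PDB file path or PDB-format text
#' @param frame_times optional numeric vector of frame times, ns
#' @return a `mol_trajectory`
#' @export
parse_multimodel <- function(text, frame_times = NULL) {
  f <- .pdb_text_to_file(text)
  lines <- readLines(f, warn = FALSE)
  .validate_pdb_lines(lines)
  rec <- substr(lines, 1, 6)
  model_starts <- which(rec == "MODEL ")
  if (length(model_starts) > 1L) {
    ends <- which(rec == "ENDMDL")
    if (length(ends) != length(model_starts))
      stop("unbalanced MODEL/ENDMDL records")
    counts <- mapply(function(a, b) sum(rec[a:b] %in% c("ATOM  ", "HETATM")),
                     model_starts, ends)
    if (length(unique(counts)) != 1L)
      stop("topology mismatch: models contain different atom counts (",
           paste(counts, collapse = ", "), ")")
  }
  pdb <- bio3d::read.pdb(f, multi = TRUE, verbose = FALSE, ATOM.only = TRUE)
  atoms <- .bio3d_to_atoms(pdb)
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  nf <- nrow(xyz)
  keep <- !duplicated(atoms$serial)
  atoms <- atoms[keep, , drop = FALSE]
  nat <- nrow(atoms)
  arr <- array(NA_real_, dim = c(nat, 3, nf))
  for (i in seq_len(nf)) {
    m <- matrix(xyz[i, ], ncol = 3, byrow = TRUE)
    arr[, , i] <- m[which(keep), , drop = FALSE]
  }
  topo <- set_coords(new_structure(atoms), arr[, , 1])
  new_trajectory(topo, arr, frame_times)
}

#' Write a structure as PDB text
#'
#' @param s a `mol_structure`
#' @param file optional path; when NULL the PDB text is returned invisibly
#'   as a character vector of lines.
#' @export
write_pdb <- function(s, file = NULL) {
  stopifnot(inherits(s, "mol_structure"))
  xyz <- coords(s)
  if (any(abs(xyz) >= 10000))
    stop("coordinate magnitude >= 10000 A cannot be represented in fixed-column PDB")
  a <- s$atoms
  tmp <- tempfile(fileext = ".pdb")
  bio3d::write.pdb(file = tmp,
                   xyz = as.vector(t(xyz)),
                   type = ifelse(a$hetero, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name,
                   resid = a$resname, chain = a$chain, resno = a$resno,
                   insert = ifelse(a$icode == "", NA, a$icode),
                   b = a$bfactor, elesy = a$element)
  lines <- readLines(tmp, warn = FALSE)
  unlink(tmp)
  if (is.null(file)) return(invisible(lines))
  writeLines(lines, file)
  invisible(lines)
}

#' Write a trajectory as a multi-model PDB
#' @param t a `mol_trajectory`
#' @param file output path
#' @export
write_multimodel <- function(t, file) {
  stopifnot(inherits(t, "mol_trajectory"))
  con <- file(file, "w")
  on.exit(close(con))
  for (i in seq_len(n_frames(t))) {
    writeLines(sprintf("MODEL     %4d", i), con)
    body <- write_pdb(set_coords(t$topology, t$coords[, , i]))
    writeLines(body[!body %in% "END"], con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(file)
}

# ---- Trajectory ---------------------------------------------------------

#' Construct a trajectory
#'
#' @param topology a `mol_structure` giving atom identities (its coordinates
#'   are frame 1 unless `coords` disagrees, in which case `coords` wins)
#' @param coords array of dim (n_atoms, 3, n_frames), Angstrom
#' @param frame_times optional numeric, ns
#' @export
new_trajectory <- function(topology, coords, frame_times = NULL) {
  stopifnot(inherits(topology, "mol_structure"))
  if (length(dim(coords)) != 3 || dim(coords)[2] != 3)
    stop("coords must be an (n_atoms, 3, n_frames) array")
  if (dim(coords)[1] != nrow(topology$atoms))
    stop("topology mismatch: coords rows != topology atoms")
  if (!is.null(frame_times) && length(frame_times) != dim(coords)[3])
    stop("frame_times length != number of frames")
  t <- list(topology = set_coords(topology, coords[, , 1]),
            coords = coords, frame_times = frame_times)
  class(t) <- "mol_trajectory"
  t
}

#' @export
print.mol_trajectory <- function(x, ...) {
  cat(sprintf("<mol_trajectory> %d frames x %d atoms\n",
              n_frames(x), dim(x$coords)[1]))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param t a `mol_trajectory`
#' @export
n_frames <- function(t) dim(t$coords)[3]

#' Extract one frame as a structure
#' @param t a `mol_trajectory`
#' @param i frame index (1-based)
#' @export
frame_structure <- function(t, i) {
  stopifnot(i >= 1, i <= n_frames(t))
  set_coords(t$topology, t$coords[, , i])
}

# ---- Selections ---------------------------------------------------------

.BACKBONE <- c("N", "CA", "C", "O")

.match_clause <- function(s, clause) {
  a <- s$atoms
  clause <- trimws(clause)
  neg <- FALSE
  if (startsWith(clause, "not ")) { neg <- TRUE; clause <- trimws(sub("^not ", "", clause)) }
  hit <- if (clause == "all") rep(TRUE, nrow(a))
  else if (clause == "protein") !a$hetero
  else if (clause == "hetero") a$hetero
  else if (clause == "backbone") a$name %in% .BACKBONE & !a$hetero
  else if (clause == "calpha") a$name == "CA" & !a$hetero
  else {
    parts <- strsplit(clause, "\\s+")[[1]]
    if (length(parts) < 2) stop("cannot parse selection clause: '", clause, "'")
    key <- parts[1]
    vals <- strsplit(paste(parts[-1], collapse = ""), ",")[[1]]
    switch(key,
      chain = a$chain %in% vals,
      resname = a$resname %in% toupper(vals),
      name = a$name %in% toupper(vals),
      elem = a$element %in% toupper(vals),
      resid = {
        nums <- unlist(lapply(vals, function(v) {
          if (grepl("-", v) && !startsWith(v, "-")) {
            ab <- as.integer(strsplit(v, "-")[[1]]); seq(ab[1], ab[2])
          } else as.integer(v)
        }))
        a$resno %in% nums
      },
      label = {
        if (is.null(s$numbering)) rep(FALSE, nrow(a))
        else a$uid %in% s$numbering$uid[s$numbering$label %in% vals]
      },
      stop("unknown selection keyword: '", key, "'"))
  }
  if (neg) !hit else hit
}

#' Resolve a selection expression to atom indices
#'
#' A small deterministic selection language: clauses joined by `and`, each
#' one of `all`, `protein`, `hetero`, `backbone`, `calpha`,
#' `chain A[,B]`, `resid 5-10[,12]`, `resname ALA[,LIG]`, `name CA[,CB]`,
#' `elem C`, `label 5.39` (generic numbering labels), optionally negated
#' with a leading `not`. The result is an ordered, duplicate-free integer
#' vector of atom indices.
#'
#' @param s a `mol_structure`
#' @param expr selection string
#' @export
select_atoms <- function(s, expr) {
  stopifnot(is.character(expr), length(expr) == 1L)
  clauses <- strsplit(expr, "\\s+and\\s+")[[1]]
  hit <- rep(TRUE, nrow(s$atoms))
  for (cl in clauses) hit <- hit & .match_clause(s, cl)
  which(hit)
}

#' Residue uids matched by a selection
#' @inheritParams select_atoms
#' @export
select_residues <- function(s, expr) {
  unique(s$atoms$uid[select_atoms(s, expr)])
}
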
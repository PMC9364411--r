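# Residue interaction networks and allosteric path analysis.
#
# Network construction follows the closest-atom / multiple-interaction-type
# convention of structure-based contact-map tools: an edge exists when the
# minimum inter-residue atom distance qualifies under at least one kind,
# and each edge is labelled with every qualifying kind. Graphs are
# unweighted for path analysis (paths count nodes, not energies).

#' Cutoffs for residue interaction network construction
#'
#' @param hbond donor-acceptor heavy-atom cutoff, Angstrom
#' @param ionic charged-group centroid cutoff, Angstrom
#' @param pi_stack ring-centroid cutoff, Angstrom
#' @param vdw_slack added to the sum of van der Waals radii, Angstrom
#' @param seq_exclusion minimum |i - j| in residue number for same-chain
#'   pairs (sequence neighbours are not edges)
#' @export
rin_params <- function(hbond = 3.5, ionic = 4.0, pi_stack = 6.5,
                       vdw_slack = 0.5, seq_exclusion = 2L) {
  as.list(environment())
}

#' Build a residue interaction network
#'
#' Nodes are residues; an undirected edge connects two residues when at
#' least one interaction kind qualifies geometrically: hydrogen bond
#' (donor/acceptor roles within `hbond`), ionic (opposite-charge group
#' centroids within `ionic`), pi stacking (ring centroids within
#' `pi_stack`) or van der Waals (closest atoms within radii sum +
#' `vdw_slack`). Same-chain pairs closer than `seq_exclusion` in sequence
#' are excluded.
#'
#' @param s a `mol_structure` with >= 3 residues
#' @param params [rin_params()]
#' @param his_protonated His residue uids carrying a positive charge
#' @return object of class `contact_network`: list(nodes, edges, graph)
#' @export
build_rin <- function(s, params = rin_params(), his_protonated = character()) {
  rs <- residues(s)
  if (nrow(rs) < 3) stop("need >= 3 residues to build a network")
  a <- s$atoms
  idx_all <- seq_len(nrow(a))
  pg <- .protein_groups(s, idx_all, his_protonated)
  res_idx <- split(idx_all, a$uid)[rs$uid]
  radii <- vdw_radii(a$element)
  don_set <- pg$donors; acc_set <- pg$acceptors
  chg <- pg$charged; rng <- pg$rings
  xyz <- coords(s)

  edges <- list()
  n <- nrow(rs)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ui <- rs$uid[i]; uj <- rs$uid[j]
    if (rs$chain[i] == rs$chain[j] &&
        abs(rs$resno[i] - rs$resno[j]) < params$seq_exclusion) next
    ii <- res_idx[[ui]]; jj <- res_idx[[uj]]
    dm <- cross_dist(xyz[ii, , drop = FALSE], xyz[jj, , drop = FALSE])
    mind <- min(dm)
    maxcut <- max(params$pi_stack, params$ionic,
                  max(radii[ii]) + max(radii[jj]) + params$vdw_slack)
    if (mind > maxcut) next
    kinds <- character(0)
    # van der Waals: closest atoms within radii sum + slack
    rsum <- outer(radii[ii], radii[jj], "+") + params$vdw_slack
    if (any(dm <= rsum)) kinds <- c(kinds, "vdw")
    # hydrogen bond: donor in one residue, acceptor in the other
    di <- intersect(ii, don_set); aj <- intersect(jj, acc_set)
    dj <- intersect(jj, don_set); ai <- intersect(ii, acc_set)
    hb <- FALSE
    if (length(di) && length(aj))
      hb <- min(cross_dist(xyz[di, , drop = FALSE], xyz[aj, , drop = FALSE])) <= params$hbond
    if (!hb && length(dj) && length(ai))
      hb <- min(cross_dist(xyz[dj, , drop = FALSE], xyz[ai, , drop = FALSE])) <= params$hbond
    if (hb) kinds <- c(kinds, "hbond")
    # ionic: opposite charge group centroids
    gi <- chg[[ui]]; gj <- chg[[uj]]
    if (!is.null(gi) && !is.null(gj) && gi$sign * gj$sign < 0 &&
        vnorm(centroid(xyz[gi$idx, , drop = FALSE]) -
              centroid(xyz[gj$idx, , drop = FALSE])) <= params$ionic)
      kinds <- c(kinds, "ionic")
    # pi stacking: ring centroids
    ri <- rng[[ui]]; rj <- rng[[uj]]
    if (!is.null(ri) && !is.null(rj) &&
        vnorm(centroid(xyz[ri$idx, , drop = FALSE]) -
              centroid(xyz[rj$idx, , drop = FALSE])) <= params$pi_stack)
      kinds <- c(kinds, "pi_stack")
    if (length(kinds))
      edges[[length(edges) + 1L]] <-
        data.frame(a = ui, b = uj, kinds = paste(sort(kinds), collapse = ","),
                   min_dist = mind, stringsAsFactors = FALSE)
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(a = character(), b = character(), kinds = character(),
               min_dist = numeric(), stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(
    edges[, c("a", "b")], directed = FALSE,
    vertices = data.frame(name = rs$uid))
  net <- list(nodes = rs, edges = edges, graph = g)
  class(net) <- "contact_network"
  net
}

#' @export
print.contact_network <- function(x, ...) {
  cat(sprintf("<contact_network> %d residues, %d interactions\n",
              nrow(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Betweenness centrality of every residue
#'
#' Pair-count betweenness over unweighted shortest paths with fractional
#' credit when multiple shortest paths exist; computed per connected
#' component. Optionally normalised by (n-1)(n-2)/2.
#'
#' @param net a [build_rin()] network
#' @param normalized logical
#' @return data.frame node, betweenness (class `centrality_profile`)
#' @export
rin_betweenness <- function(net, normalized = FALSE) {
  g <- net$graph
  b <- if (igraph::vcount(g) < 3) setNames(rep(0, igraph::vcount(g)),
                                           igraph::V(g)$name)
       else igraph::betweenness(g, directed = FALSE, normalized = normalized)
  out <- data.frame(node = names(b), betweenness = unname(b),
                    stringsAsFactors = FALSE)
  attr(out, "normalized") <- normalized
  class(out) <- c("centrality_profile", "data.frame")
  out
}

#' All shortest paths between two residues
#'
#' Enumerates every path of minimal hop count between `src` and `dst`,
#' ordered lexicographically by node sequence. Path length is reported as
#' the number of traversed edges; a disconnected pair yields an empty set
#' with infinite length.
#'
#' @param net a [build_rin()] network
#' @param src,dst node names (residue uids)
#' @return object of class `path_set`: list(paths, length, src, dst)
#' @export
rin_shortest_paths <- function(net, src, dst) {
  g <- net$graph
  vn <- igraph::V(g)$name
  if (!src %in% vn || !dst %in% vn) stop("src/dst not in network")
  if (src == dst)
    return(structure(list(paths = list(src), length = 0, src = src, dst = dst,
                          mean_betweenness = NA_real_), class = "path_set"))
  res <- suppressWarnings(
    igraph::all_shortest_paths(g, from = src, to = dst, mode = "all"))
  paths <- lapply(res$vpaths, function(p) igraph::V(g)$name[as.integer(p)])
  if (!length(paths))
    return(structure(list(paths = list(), length = Inf, src = src, dst = dst,
                          mean_betweenness = numeric(0)), class = "path_set"))
  key <- vapply(paths, paste, "", collapse = "\r")
  paths <- paths[order(key)]
  structure(list(paths = paths, length = length(paths[[1]]) - 1L,
                 src = src, dst = dst, mean_betweenness = NULL),
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> %s -> %s: %d path(s), length %s\n",
              x$src, x$dst, length(x$paths), format(x$length)))
  for (p in head(x$paths, 10)) cat("  ", paste(p, collapse = " - "), "\n")
  invisible(x)
}

#' Filter shortest paths by intermediate-node betweenness
#'
#' Retains paths whose intermediate nodes all have betweenness at or above
#' the given percentile of the profile, the usual device for focusing on
#' allosterically relevant routes; each surviving path is annotated with
#' the mean betweenness of its intermediate nodes.
#'
#' @param paths a [rin_shortest_paths()] result
#' @param prof a [rin_betweenness()] profile
#' @param percentile threshold percentile in (0, 100)
#' @return filtered `path_set` with `mean_betweenness` per path
#' @export
filter_paths <- function(paths, prof, percentile = 75) {
  stopifnot(percentile > 0, percentile < 100)
  if (!length(paths$paths)) return(paths)
  thr <- as.numeric(quantile(prof$betweenness, percentile / 100))
  bmap <- setNames(prof$betweenness, prof$node)
  keep <- logical(length(paths$paths)); mb <- numeric(length(paths$paths))
  for (i in seq_along(paths$paths)) {
    p <- paths$paths[[i]]
    mid <- p[-c(1, length(p))]
    keep[i] <- !length(mid) || all(bmap[mid] >= thr)
    mb[i] <- if (length(mid)) mean(bmap[mid]) else NA_real_
  }
  structure(list(paths = paths$paths[keep], length = paths$length,
                 src = paths$src, dst = paths$dst,
                 mean_betweenness = mb[keep], threshold = thr),
            class = "path_set")
}

#' Representative (medoid) structure of a trajectory window
#'
#' Returns the frame minimising the summed pairwise superposed RMSD over
#' the selection -- a physically valid stand-in for the "average structure"
#' used as network input (plain coordinate averaging deforms geometry).
#'
#' @param t a `mol_trajectory`
#' @param window frame indices (default all)
#' @param selection atoms used for superposition/RMSD (default C-alpha)
#' @return a `mol_structure` with attribute `frame` (the medoid index)
#' @export
medoid_structure <- function(t, window = NULL, selection = "calpha") {
  if (is.null(window)) window <- seq_len(n_frames(t))
  stopifnot(all(window >= 1 & window <= n_frames(t)))
  if (length(window) == 1L) {
    s <- frame_structure(t, window)
    attr(s, "frame") <- window
    return(s)
  }
  idx <- if (is.numeric(selection)) as.integer(selection)
         else select_atoms(t$topology, selection)
  if (!length(idx)) stop("empty selection")
  k <- length(window)
  rmsdm <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- kabsch(t$coords[idx, , window[i]], t$coords[idx, , window[j]])$rmsd
    rmsdm[i, j] <- rmsdm[j, i] <- r
  }
  best <- window[which.min(rowSums(rmsdm))]
  s <- frame_structure(t, best)
  attr(s, "frame") <- best
  s
}

#' Representative structure via single-linkage RMSD clustering
#'
#' Clusters window frames by single linkage on pairwise superposed RMSD
#' with the given cutoff and returns the medoid of the largest cluster --
#' the classic "largest cluster representative" of MD cluster analysis.
#' [medoid_structure()] over the whole window is the simpler default; this
#' variant is useful when a window mixes distinct conformational states.
#'
#' @inheritParams medoid_structure
#' @param cutoff single-linkage RMSD cutoff, Angstrom
#' @return a `mol_structure` with attributes `frame` and `cluster_size`
#' @export
cluster_representative <- function(t, window = NULL, selection = "calpha",
                                   cutoff = 2.0) {
  if (is.null(window)) window <- seq_len(n_frames(t))
  if (length(window) == 1L) return(medoid_structure(t, window, selection))
  idx <- if (is.numeric(selection)) as.integer(selection)
         else select_atoms(t$topology, selection)
  k <- length(window)
  rmsdm <- matrix(0, k, k)
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    r <- kabsch(t$coords[idx, , window[i]], t$coords[idx, , window[j]])$rmsd
    rmsdm[i, j] <- rmsdm[j, i] <- r
  }
  cl <- stats::cutree(stats::hclust(stats::as.dist(rmsdm), method = "single"),
                      h = cutoff)
  big <- as.integer(names(which.max(table(cl))))
  members <- which(cl == big)
  sub <- rmsdm[members, members, drop = FALSE]
  best <- members[which.min(rowSums(sub))]
  s <- frame_structure(t, window[best])
  attr(s, "frame") <- window[best]
  attr(s, "cluster_size") <- length(members)
  s
}

#' Export a network as an edge-list TSV or GraphML
#' @param net a [build_rin()] network
#' @param file output path
#' @param format "tsv" (node_a, node_b, kinds, min_dist) or "graphml"
#' @export
write_rin <- function(net, file, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$edges, file, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    g <- net$graph
    if (nrow(net$edges)) {
      igraph::E(g)$kinds <- net$edges$kinds
      igraph::E(g)$min_dist <- net$edges$min_dist
    }
    igraph::write_graph(g, file, format = "graphml")
  }
  invisible(file)
}
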
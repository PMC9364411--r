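# Fixtures and independent oracles used across the suite.

# bare structure from coordinates (single-element atoms)
mk_atoms <- function(xyz, element = "C", name = element, chain = "A",
                     resno = seq_len(nrow(xyz)), resname = "UNK",
                     hetero = FALSE) {
  new_structure(data.frame(
    serial = seq_len(nrow(xyz)), name = rep(name, length.out = nrow(xyz)),
    element = rep(element, length.out = nrow(xyz)),
    chain = rep(chain, length.out = nrow(xyz)),
    resno = rep(resno, length.out = nrow(xyz)), icode = "",
    resname = rep(resname, length.out = nrow(xyz)),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], bfactor = 0,
    hetero = rep(hetero, length.out = nrow(xyz)), stringsAsFactors = FALSE))
}

random_rotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2+b^2-c^2-d^2, 2*(b*c-a*d),     2*(b*d+a*c),
           2*(b*c+a*d),     a^2-b^2+c^2-d^2, 2*(c*d-a*b),
           2*(b*d-a*c),     2*(c*d+a*b),     a^2-b^2-c^2+d^2),
         3, 3, byrow = TRUE)
}

rigid_transform <- function(s, rot = random_rotation(), shift = rnorm(3, sd = 5)) {
  m <- coords(s) %*% t(rot)
  set_coords(s, sweep(m, 2, shift, "+"))
}

# ---- graph oracles (independent of igraph) -----------------------------

# adjacency list from an edge matrix (2 columns of 1-based node ids)
adj_list <- function(n, edges) {
  adj <- vector("list", n)
  if (nrow(edges)) for (r in seq_len(nrow(edges))) {
    i <- edges[r, 1]; j <- edges[r, 2]
    adj[[i]] <- c(adj[[i]], j); adj[[j]] <- c(adj[[j]], i)
  }
  lapply(adj, function(x) sort(unique(x)))
}

bfs_dist <- function(adj, src) {
  n <- length(adj)
  d <- rep(Inf, n); d[src] <- 0
  q <- src
  while (length(q)) {
    v <- q[1]; q <- q[-1]
    for (u in adj[[v]]) if (d[u] == Inf) { d[u] <- d[v] + 1; q <- c(q, u) }
  }
  d
}

# all shortest paths src -> dst by backward enumeration over the BFS DAG
enumerate_shortest <- function(adj, src, dst) {
  d <- bfs_dist(adj, src)
  if (!is.finite(d[dst])) return(list())
  walk <- function(v) {
    if (v == src) return(list(src))
    preds <- adj[[v]][d[adj[[v]]] == d[v] - 1]
    out <- list()
    for (p in preds) for (tail in walk(p))
      out[[length(out) + 1L]] <- c(tail, v)
    out
  }
  walk(dst)
}

# pair-count betweenness with fractional credit, by explicit enumeration
brute_betweenness <- function(adj) {
  n <- length(adj)
  b <- numeric(n)
  if (n < 3) return(b)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    paths <- enumerate_shortest(adj, s, t)
    np <- length(paths)
    if (np == 0) next
    for (p in paths) {
      mid <- p[-c(1, length(p))]
      if (length(mid)) b[mid] <- b[mid] + 1 / np
    }
  }
  b
}

# contact_network wrapper around a bare graph, for the path/centrality API
toy_net <- function(n, edges, labels = as.character(seq_len(n))) {
  g <- igraph::graph_from_data_frame(
    data.frame(a = labels[edges[, 1]], b = labels[edges[, 2]]),
    directed = FALSE, vertices = data.frame(name = labels))
  structure(list(nodes = data.frame(uid = labels),
                 edges = data.frame(a = labels[edges[, 1]],
                                    b = labels[edges[, 2]]),
                 graph = g), class = "contact_network")
}

random_graph <- function(n, p) {
  pairs <- t(combn(n, 2))
  keep <- runif(nrow(pairs)) < p
  pairs[keep, , drop = FALSE]
}

# ---- thermodynamics oracles --------------------------------------------

# two-state BAR as a scalar root problem (independent of the MBAR solver)
bar_oracle <- function(u, counts) {
  stopifnot(nrow(u) == 2)
  h <- function(d) {
    logd <- apply(rbind(log(counts[1]) - u[1, ],
                        log(counts[2]) + d - u[2, ]), 2, function(col) {
      mx <- max(col); mx + log(sum(exp(col - mx)))
    })
    v <- -u[2, ] - logd
    mx <- max(v)
    -(mx + log(sum(exp(v - mx)))) - d
  }
  uniroot(h, c(-100, 100), tol = 1e-12)$root
}

# factorised 6-D quadrature of the Boresch restrained configurational
# integral (exact sin-theta and r^2 Jacobians, peak +/- 12 sigma limits)
boresch_quadrature <- function(r, temperature = 300, v0 = 1660) {
  kB <- 0.0019872041
  kT <- kB * temperature
  k <- c(r$K_d, r$K_theta, r$K_phi)
  if (r$convention == "full") k <- 2 * k
  sg <- sqrt(kT / k)
  tA <- r$theta_A * pi / 180; tB <- r$theta_B * pi / 180
  ph <- c(r$phi_A, r$phi_B, r$phi_C) * pi / 180
  Ir <- integrate(function(x) x^2 * exp(-k[1] * (x - r$d)^2 / (2 * kT)),
                  max(0, r$d - 12 * sg[1]), r$d + 12 * sg[1],
                  rel.tol = 1e-12)$value
  It <- function(t0, kk, s) integrate(function(x)
    sin(x) * exp(-kk * (x - t0)^2 / (2 * kT)),
    max(0, t0 - 12 * s), min(pi, t0 + 12 * s), rel.tol = 1e-12)$value
  Ip <- function(p0, kk, s) integrate(function(x)
    exp(-kk * (x - p0)^2 / (2 * kT)),
    p0 - min(pi, 12 * s), p0 + min(pi, 12 * s), rel.tol = 1e-12)$value
  z <- Ir * It(tA, k[2], sg[2]) * It(tB, k[3], sg[3]) *
    Ip(ph[1], k[4], sg[4]) * Ip(ph[2], k[5], sg[5]) * Ip(ph[3], k[6], sg[6])
  kT * log(8 * pi^2 * v0 / z)
}

# spherical-cap closed form for the SASA of two intersecting equal spheres
two_sphere_sasa <- function(r1, r2, d) {
  if (d >= r1 + r2) return(4 * pi * (r1^2 + r2^2))
  x1 <- (d^2 + r1^2 - r2^2) / (2 * d)
  h1 <- r1 - x1; h2 <- r2 - (d - x1)
  (4 * pi * r1^2 - 2 * pi * r1 * h1) + (4 * pi * r2^2 - 2 * pi * r2 * h2)
}
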
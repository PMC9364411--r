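test_that("edges require geometric proximity and exclude sequence neighbours", {
  # two residues 10 A apart: no edge
  far <- mk_atoms(rbind(c(0, 0, 0), c(10, 0, 0), c(0, 30, 0)),
                  element = "C", name = "CA", resno = c(1, 5, 9),
                  resname = "ALA")
  expect_equal(nrow(build_rin(far)$edges), 0L)
  # planted Asp-Arg pair at 3.2 A carries an ionic label
  b <- build_bundle(2, 10, ring_radius = 8)
  b <- mdlens:::mutate_residue(b, "A:5", "ARG")
  arg_n <- which(b$atoms$uid == "A:5" & b$atoms$name %in% c("NE", "NH1", "NH2"))
  cen <- colMeans(coords(b, arg_n))
  b <- mdlens:::mutate_residue(b, "A:105", "ASP")
  asp_o <- which(b$atoms$uid == "A:105" & b$atoms$name %in% c("OD1", "OD2"))
  shift <- cen + c(3.2, 0, 0) - colMeans(coords(b, asp_o))
  m <- coords(b); m[asp_o, ] <- sweep(m[asp_o, ], 2, shift, "+")
  b <- mdlens:::set_coords(b, m)
  e <- build_rin(b)$edges
  row <- e[e$a == "A:105" & e$b == "A:5" | e$a == "A:5" & e$b == "A:105", ]
  expect_equal(nrow(row), 1L)
  expect_true(grepl("ionic", row$kinds))
})

test_that("an ideal helix is hydrogen-bond linked at i, i+4", {
  h <- build_helix(20)
  e <- build_rin(h)$edges
  resno <- function(u) as.integer(sub("A:", "", u))
  i4 <- e[abs(resno(e$a) - resno(e$b)) == 4, ]
  expect_equal(nrow(i4), 16L)
  expect_true(all(grepl("hbond", i4$kinds)))
})

test_that("network edges are invariant under rigid-body transforms", {
  set.seed(5)
  b <- build_bundle(3, 10, ring_radius = 8)
  e0 <- build_rin(b)$edges
  b2 <- rigid_transform(b)
  e1 <- build_rin(b2)$edges
  expect_identical(e0[, c("a", "b", "kinds")], e1[, c("a", "b", "kinds")])
  expect_equal(e0$min_dist, e1$min_dist, tolerance = 1e-8)
})

test_that("interaction count grows monotonically with every cutoff", {
  b <- build_bundle(3, 12, ring_radius = 8)
  n_tight <- nrow(build_rin(b, rin_params(hbond = 3.0, vdw_slack = 0.2))$edges)
  n_mid <- nrow(build_rin(b)$edges)
  n_loose <- nrow(build_rin(b, rin_params(hbond = 4.5, vdw_slack = 1.5,
                                          ionic = 6, pi_stack = 8))$edges)
  expect_lte(n_tight, n_mid)
  expect_lte(n_mid, n_loose)
})

test_that("betweenness matches hand results on canonical graphs", {
  path3 <- toy_net(3, rbind(c(1, 2), c(2, 3)), labels = c("A", "B", "C"))
  b <- rin_betweenness(path3)
  expect_equal(b$betweenness[b$node == "B"], 1)
  expect_equal(b$betweenness[b$node != "B"], c(0, 0))
  k4 <- toy_net(4, t(combn(4, 2)))
  expect_equal(rin_betweenness(k4)$betweenness, rep(0, 4))
})

test_that("betweenness and path enumeration equal brute-force oracles", {
  set.seed(42)
  for (trial in 1:20) {
    n <- sample(5:30, 1)
    edges <- random_graph(n, runif(1, 0.1, 0.35))
    if (!nrow(edges)) next
    net <- toy_net(n, edges)
    adj <- adj_list(n, edges)
    expect_equal(rin_betweenness(net)$betweenness, brute_betweenness(adj),
                 tolerance = 1e-9)
    src <- sample(n, 1); dst <- sample(n, 1)
    got <- rin_shortest_paths(net, as.character(src), as.character(dst))
    want <- enumerate_shortest(adj, src, dst)
    if (src == dst) {
      expect_equal(got$length, 0)
    } else if (!length(want)) {
      expect_equal(got$length, Inf)
      expect_equal(length(got$paths), 0L)
    } else {
      want_chr <- sort(vapply(want, function(p)
        paste(as.character(p), collapse = "\r"), ""))
      got_chr <- sort(vapply(got$paths, paste, "", collapse = "\r"))
      expect_identical(got_chr, want_chr)
      expect_equal(got$length, length(want[[1]]) - 1L)
    }
  }
})

test_that("square-cycle paths, self paths and disconnected pairs behave", {
  sq <- toy_net(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(4, 1)),
                labels = c("A", "B", "C", "D"))
  ps <- rin_shortest_paths(sq, "A", "C")
  expect_equal(length(ps$paths), 2L)
  expect_identical(ps$paths[[1]], c("A", "B", "C"))
  expect_identical(ps$paths[[2]], c("A", "D", "C"))
  expect_equal(rin_shortest_paths(sq, "A", "A")$length, 0)
  disc <- toy_net(4, rbind(c(1, 2), c(3, 4)))
  expect_equal(rin_shortest_paths(disc, "1", "4")$length, Inf)
})

test_that("a lone bridge node carries maximal betweenness", {
  # two K4 communities joined through node 9
  e <- rbind(t(combn(1:4, 2)), t(combn(5:8, 2)), c(4, 9), c(9, 5))
  net <- toy_net(9, e)
  b <- rin_betweenness(net)
  expect_equal(b$node[which.max(b$betweenness)], "9")
})

test_that("path filtering drops low-centrality intermediates", {
  net <- toy_net(4, rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
  prof <- rin_betweenness(net)
  ps <- rin_shortest_paths(net, "1", "3")
  keep_all <- filter_paths(ps, prof, percentile = 10)
  expect_equal(length(keep_all$paths), 2L)
  # raise one path's intermediate above, push the other below
  prof$betweenness <- c(0, 5, 0, 0.1)
  filt <- filter_paths(ps, prof, percentile = 75)
  expect_equal(length(filt$paths), 1L)
  expect_identical(filt$paths[[1]], c("1", "2", "3"))
  expect_equal(filt$mean_betweenness, 5)
  # threshold above the maximum leaves only direct paths
  direct <- rin_shortest_paths(net, "1", "2")
  expect_equal(length(filter_paths(direct, prof, 99)$paths), 1L)
})

test_that("the medoid minimises the pairwise RMSD sum", {
  set.seed(9)
  h <- build_helix(8)
  tr <- jitter_trajectory(h, 0.3, 12, seed = 4)
  med <- medoid_structure(tr)
  idx <- select_atoms(h, "calpha")
  k <- n_frames(tr)
  sums <- vapply(seq_len(k), function(i) {
    sum(vapply(seq_len(k), function(j)
      if (i == j) 0 else kabsch(tr$coords[idx, , i], tr$coords[idx, , j])$rmsd,
      0))
  }, 0)
  expect_equal(attr(med, "frame"), which.min(sums))
  # identical frames: first frame wins; one displaced frame never wins
  tr0 <- jitter_trajectory(h, 0, 5, seed = 1)
  expect_equal(attr(medoid_structure(tr0), "frame"), 1L)
  trd <- tr0
  trd$coords[, , 3] <- trd$coords[, , 3] * 1.5   # deformed outlier frame
  expect_false(attr(medoid_structure(trd), "frame") == 3L)
})

test_that("cluster representatives come from the dominant conformation", {
  h <- build_helix(8)
  ext <- build_helix(8, phi = 180, psi = 180)
  arr <- array(0, dim = c(nrow(h$atoms), 3, 9))
  set.seed(14)
  for (i in 1:9) {
    base <- if (i <= 6) coords(h) else coords(ext)   # 6 helix, 3 extended
    arr[, , i] <- base + rnorm(length(base), sd = 0.1)
  }
  tr <- new_trajectory(h, arr)
  rep <- cluster_representative(tr, cutoff = 2.0)
  expect_lte(attr(rep, "frame"), 6L)
  expect_equal(attr(rep, "cluster_size"), 6L)
  # network export round-trips through both formats
  net <- build_rin(build_bundle(3, 10))
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".graphml")
  write_rin(net, f1)
  expect_equal(nrow(read.delim(f1)), nrow(net$edges))
  write_rin(net, f2, format = "graphml")
  g2 <- igraph::read_graph(f2, format = "graphml")
  expect_equal(igraph::ecount(g2), nrow(net$edges))
})
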
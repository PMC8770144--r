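test_that("assignment hypotheses contain the truth and nest with d_tol", {
  cell <- mithrene_cell(); sym <- mC()
  fr <- mith_frames_clean()
  checked <- 0
  for (f in fr$frames) {
    if (is.null(f$truth) || nrow(f$spots) < 3) next
    nodes <- candidate_assignments(f, cell, sym, d_tol = 0.005)
    for (i in seq_len(nrow(f$truth$hkl))) {
      th <- f$truth$hkl[i, ]
      hit <- nodes$spot == i &
        ((nodes$h == th[1] & nodes$k == th[2] & nodes$l == th[3]) |
           (nodes$h == -th[1] & nodes$k == -th[2] & nodes$l == -th[3]))
      expect_true(any(hit))
    }
    # hypothesis count grows monotonically with d_tol
    n1 <- nrow(candidate_assignments(f, cell, sym, d_tol = 0.001))
    n2 <- nrow(candidate_assignments(f, cell, sym, d_tol = 0.004))
    n3 <- nrow(candidate_assignments(f, cell, sym, d_tol = 0.01))
    expect_true(n1 <= n2 && n2 <= n3)
    checked <- checked + 1
    if (checked >= 12) break
  }
  expect_gte(checked, 5)
})

test_that("the consistency graph connects exactly the geometrically compatible pairs", {
  cell <- mithrene_cell(); sym <- mC()
  hkl <- rbind(c(2, 0, 2), c(1, 1, 5), c(-1, 1, 8), c(0, 2, 4), c(3, 1, -2))
  f <- exact_frame(cell, hkl, rotation_about(c(1, 2, 3), 25))
  nodes <- candidate_assignments(f, cell, sym, d_tol = 0.002)
  g <- consistency_graph(f, nodes, cell, pair_tol = 0.0015)
  # the truth assignment nodes form a complete subgraph
  ti <- vapply(seq_len(nrow(hkl)), function(i)
    which(nodes$spot == i & nodes$h == hkl[i, 1] & nodes$k == hkl[i, 2] &
            nodes$l == hkl[i, 3])[1], integer(1))
  expect_false(any(is.na(ti)))
  expect_true(all(g$adjacency[t(utils::combn(ti, 2))]))
  # hypotheses of the same spot are never adjacent
  for (s in unique(nodes$spot)) {
    same <- which(nodes$spot == s)
    if (length(same) > 1)
      expect_false(any(g$adjacency[same, same]))
  }
  # zero tolerance on noisy data: an edgeless graph
  fn <- f
  set.seed(1)
  fn$spots$sx <- fn$spots$sx + rnorm(5, 0, 1e-4)
  gn <- consistency_graph(fn, nodes, cell, pair_tol = 0)
  expect_equal(sum(gn$adjacency), 0)
})

test_that("max_clique is exact against subset enumeration and deterministic", {
  # single triangle
  adj <- matrix(FALSE, 3, 3); adj[1, 2] <- adj[2, 1] <- adj[2, 3] <- adj[3, 2] <- adj[1, 3] <- adj[3, 1] <- TRUE
  expect_equal(max_clique(adj), 1:3)
  expect_length(max_clique(matrix(FALSE, 0, 0)), 0)
  set.seed(77)
  for (i in 1:30) {
    n <- 12
    adj <- matrix(runif(n * n) < 0.45, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    got <- max_clique(adj)
    oracle <- brute_force_max_clique(adj)
    expect_equal(length(got), length(oracle))
    # verify the returned set is a clique
    if (length(got) > 1) expect_true(all(adj[t(utils::combn(got, 2))]))
    expect_identical(got, max_clique(adj))   # deterministic
  }
})

test_that("equal-size cliques break ties toward the smaller summed mismatch", {
  # two disjoint triangles; the second has smaller edge weights
  adj <- matrix(FALSE, 6, 6)
  for (p in list(c(1, 2), c(1, 3), c(2, 3), c(4, 5), c(4, 6), c(5, 6))) {
    adj[p[1], p[2]] <- TRUE; adj[p[2], p[1]] <- TRUE
  }
  w <- matrix(1, 6, 6); w[4:6, 4:6] <- 0.01
  g <- structure(list(adjacency = adj, mismatch = w,
                      nodes = data.frame(spot = 1:6)),
                 class = "consistency_graph")
  expect_equal(max_clique(g), 4:6)
})

test_that("exact frames index to the exact orientation; tiny frames do not", {
  cell <- mithrene_cell(); sym <- mC()
  hkl <- rbind(c(2, 0, 2), c(1, 1, 5), c(-1, 1, 8), c(0, 2, 4), c(3, 1, -2), c(1, -1, 11))
  R <- rotation_about(c(-1, 1, 2), 55)
  f <- exact_frame(cell, hkl, R)
  sol <- index_frame(f, cell, sym)
  expect_false(is.null(sol))
  expect_equal(nrow(sol$assignments), 6)
  ops <- ambiguity_ops(sym, find_pseudosymmetry_ops(cell, sym, tol = 0.01))
  expect_lt(misorientation_angle(f$truth$A, sol$A, ops, cell = cell), 1e-4)
  # solutions never refine the cell: A'A reproduces the reciprocal metric
  expect_lt(norm(t(sol$A) %*% sol$A - reciprocal_metric(cell), "F") /
              norm(reciprocal_metric(cell), "F"), 1e-9)
  # two spots are below the minimum clique
  f2 <- exact_frame(cell, hkl[1:2, ])
  expect_null(index_frame(f2, cell, sym))
  # collinear reciprocal vectors cannot fix an orientation
  f3 <- exact_frame(cell, rbind(c(0, 0, 2), c(0, 0, 4), c(0, 0, 6), c(0, 0, 8)))
  expect_null(index_frame(f3, cell, sym))
})

test_that("indexing handles the enantiomorph blindness of pair distances", {
  # pair distances cannot distinguish an assignment from its global Friedel
  # flip; the fit must pick the proper rotation. Exercised across many
  # random orientations.
  cell <- mithrene_cell(); sym <- mC()
  hkl <- rbind(c(2, 0, 2), c(1, 1, 5), c(-1, 1, 8), c(0, 2, 4), c(3, 1, -2))
  ops <- ambiguity_ops(sym, find_pseudosymmetry_ops(cell, sym, tol = 0.01))
  set.seed(9)
  for (i in 1:15) {
    ax <- rnorm(3); ang <- runif(1, 0, 180)
    f <- exact_frame(cell, hkl, rotation_about(ax, ang))
    sol <- index_frame(f, cell, sym)
    expect_false(is.null(sol))
    expect_lt(misorientation_angle(f$truth$A, sol$A, ops, cell = cell), 1e-4)
  }
})

test_that("batch indexing prefers the true cell over a stretched distractor", {
  fr <- mith_frames_default()
  sub <- fr; sub$frames <- fr$frames[1:150]
  mith <- mithrene_cell()
  stretch <- unit_cell(mith$a * 1.03, mith$b, mith$c, 90, mith$beta, 90)
  r_true <- index_dataset(sub, mith, mC())
  r_str <- index_dataset(sub, stretch, mC())
  expect_gt(r_true$rate, r_str$rate)
  expect_gt(r_true$rate, 0.5)
})

test_that("accepted solutions carry few misassigned spots at default noise", {
  fr <- mith_frames_default()
  sub <- fr; sub$frames <- fr$frames[1:200]
  cell <- mithrene_cell(); sym <- mC()
  res <- index_dataset(sub, cell, sym)
  ops <- ambiguity_ops(sym, find_pseudosymmetry_ops(cell, sym, tol = 0.01))
  mis <- 0; tot <- 0
  for (sol in res$solutions) {
    th <- sub$frames[[sol$frame_id]]$truth$hkl[sol$assignments$spot, , drop = FALSE]
    for (i in seq_len(nrow(sol$assignments))) {
      tot <- tot + 1
      got <- as.integer(sol$assignments[i, c("h", "k", "l")])
      ok <- any(vapply(ops, function(M) all(as.integer(M %*% th[i, ]) == got),
                       logical(1)))
      if (!ok) mis <- mis + 1
    }
  }
  expect_gt(tot, 300)
  expect_lt(mis / tot, 0.02)
})
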
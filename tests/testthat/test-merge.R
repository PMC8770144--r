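make_obs <- function(df, symmetry = mC()) {
  df$sigma <- if (is.null(df$sigma)) 0.05 * abs(df$intensity) else df$sigma
  smsfx:::finalize_obs(df[, c("frame_id", "rh", "rk", "rl", "intensity", "sigma")],
                       symmetry)
}

test_that("simple merging reproduces hand arithmetic and flags singletons", {
  obs <- make_obs(data.frame(frame_id = 1:4,
                             rh = c(2, 2, 2, 1), rk = c(0, 0, 0, 1),
                             rl = c(2, 2, 2, 4),
                             intensity = c(10, 12, 14, 7)))
  m <- merge_simple(obs)
  r <- m[m$h == 2 & m$k == 0 & m$l == 2, ]
  expect_equal(r$I, 12)
  expect_equal(r$sigma, 2 / sqrt(3), tolerance = 1e-12)   # SEM of {10,12,14}
  expect_equal(r$n, 3L)
  s <- m[m$n == 1, ]
  expect_true(s$single)
  expect_equal(s$sigma, 0.5 * abs(s$I))                   # sentinel policy
})

test_that("merging is invariant to frame order and to pre-reduction representatives", {
  sym <- mC()
  set.seed(6)
  n <- 60
  H <- cbind(sample(c(-2, 0, 2, 4), n, TRUE), sample(-3:3, n, TRUE),
             sample(-8:8, n, TRUE))
  H <- H[rowSums(H != 0) > 0 & centring_allowed(H, "C"), , drop = FALSE]
  df <- data.frame(frame_id = sample(1:10, nrow(H), TRUE),
                   rh = H[, 1], rk = H[, 2], rl = H[, 3],
                   intensity = runif(nrow(H), 1, 100))
  m1 <- merge_simple(make_obs(df))
  m2 <- merge_simple(make_obs(df[sample(nrow(df)), ]))
  expect_equal(m1, m2)
  # replace raw indices by random Laue images: the merge must not change
  df3 <- df
  for (i in seq_len(nrow(df3))) {
    S <- sym$ops[[sample(length(sym$ops), 1)]]
    df3[i, c("rh", "rk", "rl")] <- as.integer(S %*% as.numeric(df[i, c("rh", "rk", "rl")]))
  }
  m3 <- merge_simple(make_obs(df3))
  expect_equal(m1, m3)
})

test_that("scaling recovers a known frame scale exactly and keeps unit scale at 1", {
  base <- data.frame(frame_id = 1L, rh = c(2, 1, 3, 0), rk = c(0, 1, 1, 2),
                     rl = c(2, 4, -2, 6), intensity = c(10, 40, 25, 5))
  copy <- base; copy$frame_id <- 2L; copy$intensity <- 5 * base$intensity
  obs <- make_obs(rbind(base, copy))
  ref <- merge_simple(make_obs(base))
  out <- scale_and_remerge(obs, ref)
  sc <- out$frame_scales
  expect_equal(sc$scale[sc$frame_id == 1], 1.0, tolerance = 1e-12)
  expect_equal(sc$scale[sc$frame_id == 2], 5.0, tolerance = 1e-12)
  expect_equal(out$merged$I, ref$I, tolerance = 1e-12)
  # frames with too little reference overlap are dropped and reported
  lone <- data.frame(frame_id = 3L, rh = 4, rk = 2, rl = 10, intensity = 3)
  out2 <- scale_and_remerge(make_obs(rbind(base, copy, lone)), ref, min_common = 3)
  expect_true(out2$frame_scales$dropped[out2$frame_scales$frame_id == 3])
})

test_that("two-step scaling does not degrade correlation with truth on dispersed frames", {
  cell <- mithrene_cell(); sym <- mC()
  cfg <- sim_config(cell, sym, frame_scale_dispersion = 0.6, seed = 55)
  fr <- simulate_dataset(cfg, 900)
  obs <- observations_from_truth(fr, sym)
  m1 <- merge_simple(obs)
  m2 <- scale_and_remerge(obs, m1)$merged
  c1 <- cor_vs_truth(m1, cell)
  c2 <- cor_vs_truth(m2, cell)
  expect_gte(c2, c1 - 1e-6)
})

test_that("resolution cutoff honours the outer-shell multiplicity target", {
  cell <- mithrene_cell(); sym <- mC()
  refl <- reflection_list(cell, sym, d_min = 1.2)
  asu <- unique(reduce_to_asu(as.matrix(refl[, c("h", "k", "l")]), sym))
  d <- d_spacing(cell, asu)
  # uniform multiplicity 12 everywhere: the full range is returned
  m_uniform <- structure(data.frame(h = asu[, 1], k = asu[, 2], l = asu[, 3],
                                    I = 1, sigma = 0.1, n = 12L, single = FALSE),
                         class = c("merged_set", "data.frame"))
  rc <- resolution_cutoff(m_uniform, cell)
  expect_true(rc$in_target)
  expect_equal(rc$d_min, min(d), tolerance = 1e-6)
  # multiplicity decaying with resolution shell: 24, 22, ..., 6; the band
  # [10, 15] is met deepest at the shell with mean 10
  q3 <- 1 / d^3
  edges <- seq(min(q3), max(q3), length.out = 11)
  edges[11] <- edges[11] * (1 + 1e-12)
  shell_of <- findInterval(q3, edges, rightmost.closed = TRUE, all.inside = TRUE)
  m_dec <- m_uniform; m_dec$n <- as.integer(26 - 2 * shell_of)
  rc2 <- resolution_cutoff(m_dec, cell)
  expect_true(rc2$in_target)
  # direct recount of the outer shell actually selected by the cutoff
  tab <- rc2$table
  row <- which(abs(tab$d_lo - rc2$d_min) < 1e-9)
  in_shell <- d <= tab$d_hi[row] + 1e-9 & d >= tab$d_lo[row] - 1e-9
  recount <- mean(m_dec$n[in_shell])
  expect_gte(recount, 10); expect_lte(recount, 15)
  expect_equal(recount, rc2$achieved)
  # unreachable target: warning and best effort
  m_low <- m_uniform; m_low$n <- 4L
  expect_warning(rc3 <- resolution_cutoff(m_low, cell), "no shell")
  expect_false(rc3$in_target)
})

test_that("a deliberate 50/50 reindexing scramble is detected and reversed", {
  cell <- mithrene_cell(); sym <- mC()
  ops <- find_pseudosymmetry_ops(cell, sym, tol = 0.01)
  twin <- unclass(ops[[1]])
  # noise-off limit: constructed frames whose intensities are exactly
  # frame scale x |F|^2 of a random draw of lattice reflections
  refl <- reflection_list(cell, sym, d_min = 1.3)
  H <- as.matrix(refl[, c("h", "k", "l")])
  ts <- default_toy_structure()
  set.seed(1)
  rows <- lapply(1:300, function(f) {
    k <- sample(2:8, 1)
    pick <- H[sample(nrow(H), k), , drop = FALSE]
    data.frame(frame_id = f, rh = pick[, 1], rk = pick[, 2], rl = pick[, 3],
               intensity = stats::rlnorm(1, 0, 0.4) *
                 toy_structure_factor(ts, pick, cell))
  })
  obs <- make_obs(do.call(rbind, rows))
  fids <- unique(obs$frame_id)
  flipped <- sample(fids, length(fids) %/% 2)
  raw <- as.matrix(obs[, c("rh", "rk", "rl")])
  sel <- obs$frame_id %in% flipped
  raw[sel, ] <- raw[sel, , drop = FALSE] %*% t(twin)
  scr <- make_obs(data.frame(frame_id = obs$frame_id, rh = raw[, 1],
                             rk = raw[, 2], rl = raw[, 3],
                             intensity = obs$intensity, sigma = obs$sigma))
  ref <- truth_f2_table(reduce_to_asu(rbind(H, H %*% t(twin)), sym), cell)
  fixed <- resolve_indexing_ambiguity(scr, ops, ref)
  # exact reference, no noise: every frame's labels return to the truth
  # convention (frames made only of operator-invariant reflections match
  # under either setting)
  truth_lab <- paste(obs$h, obs$k, obs$l)
  fin_lab <- paste(fixed$obs$h, fixed$obs$k, fixed$obs$l)
  per_frame <- tapply(fin_lab == truth_lab, obs$frame_id, all)
  expect_equal(mean(per_frame), 1.0)
  # the scramble hurts the merged correlation; resolution (plus reference
  # scaling, which removes the per-frame scales exactly here) restores it
  c_scr <- cor_vs_truth(merge_simple(scr), cell)
  c_fix <- cor_vs_truth(scale_and_remerge(fixed$obs, ref)$merged, cell)
  expect_gt(c_fix, c_scr)
  expect_gt(c_fix, 0.999)
  # identity-only operator set is a no-op
  noop <- resolve_indexing_ambiguity(scr, list(), ref)
  expect_equal(as.data.frame(noop$obs), as.data.frame(scr))
})

test_that("absence statistics separate allowed and centring-forbidden classes", {
  cell <- mithrene_cell(); sym <- mC()
  fr <- mith_frames_default()
  obs <- observations_from_truth(fr, sym)
  tab <- absence_statistics(obs, centring_classifier("C"))
  expect_equal(tab$count[tab$class == "forbidden"], 0L)   # simulator emits none
  expect_true(tab$absent[tab$class == "forbidden"])
  expect_false(tab$absent[tab$class == "allowed"])
  # inject weak forbidden-class observations: detected well below the allowed class
  n_inj <- max(10, round(0.01 * nrow(obs)))
  inj <- data.frame(frame_id = rep(1L, n_inj),
                    rh = rep(1, n_inj), rk = rep(0, n_inj),
                    rl = seq_len(n_inj),
                    intensity = stats::rnorm(n_inj, 0, 0.5),
                    sigma = rep(1, n_inj))
  obs2 <- make_obs(rbind(as.data.frame(obs)[, names(inj)], inj))
  tab2 <- absence_statistics(obs2, centring_classifier("C"))
  f <- tab2[tab2$class == "forbidden", ]
  a <- tab2[tab2$class == "allowed", ]
  expect_equal(f$count, n_inj)
  expect_lt(f$mean_i_over_sigma, 2)
  expect_gt(a$mean_i_over_sigma, f$mean_i_over_sigma)
  expect_true(f$absent); expect_false(a$absent)
  # a tautological class covers everything
  tab3 <- absence_statistics(obs, function(h) rep("all", nrow(h)))
  expect_equal(tab3$count, nrow(obs))
})

test_that("SEM errors are consistent with half-dataset spread", {
  cell <- mithrene_cell(); sym <- mC()
  fr <- mith_frames_default()
  obs <- observations_from_truth(fr, sym)
  m <- merge_simple(obs)
  keep <- m$n >= 6
  key_m <- paste(m$h, m$k, m$l)[keep]
  # half-dataset split by frame parity
  even <- merge_simple(obs[obs$frame_id %% 2 == 0, ])
  odd <- merge_simple(obs[obs$frame_id %% 2 == 1, ])
  ke <- paste(even$h, even$k, even$l); ko <- paste(odd$h, odd$k, odd$l)
  common <- intersect(intersect(ke, ko), key_m)
  ie <- even$I[match(common, ke)]; io <- odd$I[match(common, ko)]
  spread <- abs(ie - io) / 2
  sems <- m$sigma[keep][match(common, key_m)]
  ratio <- median(spread / sems)
  expect_gt(ratio, 1 / 1.5)
  expect_lt(ratio, 1.5)
})
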
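# independent M20 oracle: direct enumeration with d_spacing, no shared code
# with compute_m20 beyond the cell metric itself
m20_oracle <- function(peaks, cell, symmetry, cap = 1e4) {
  d_obs <- sort(peaks, decreasing = TRUE)[seq_len(min(20, length(peaks)))]
  Qobs <- 1 / d_obs^2
  Q20 <- max(Qobs)
  rng <- -15:15
  H <- as.matrix(expand.grid(rng, rng, rng))
  H <- H[rowSums(H != 0) > 0, ]
  H <- H[centring_allowed(H, symmetry), ]
  q <- 1 / d_spacing(cell, H)^2
  H <- H[q <= Q20 * (1 + 1e-9), , drop = FALSE]
  q <- q[q <= Q20 * (1 + 1e-9)]
  asu <- reduce_to_asu(H, symmetry)
  keep <- !duplicated(asu)
  qu <- sort(q[keep])
  qu <- qu[c(TRUE, diff(qu) / qu[-length(qu)] > 1e-5)]
  mean_dq <- mean(vapply(Qobs, function(x) min(abs(x - qu)), numeric(1)))
  n20 <- length(qu)
  if (mean_dq < Q20 / (2 * n20 * cap)) return(cap)
  min(cap, Q20 / (2 * mean_dq * n20))
}

test_that("M20 agrees with a direct enumeration oracle and behaves as de Wolff's merit", {
  cell <- unit_cell(6, 8, 10); sym <- lattice_symmetry("oP")
  lines <- predict_lines(cell, sym, d_min = 1.8)
  peaks <- lines[seq_len(20)]
  # exact peaks: capped perfect fit
  expect_equal(compute_m20(peaks, cell, sym), 1e4)
  # noisy peaks: matches the oracle
  set.seed(2)
  noisy <- peaks * (1 + rnorm(20, 0, 0.002))
  expect_equal(compute_m20(noisy, cell, sym), m20_oracle(noisy, cell, sym),
               tolerance = 1e-6)
  # a perturbed cell scores strictly lower
  worse <- unit_cell(6 * 1.02, 8, 10)
  expect_lt(compute_m20(noisy, worse, sym), compute_m20(noisy, cell, sym))
  # halving the volume densifies predicted lines and lowers M20
  half <- unit_cell(6, 8, 5)
  expect_lt(compute_m20(noisy, half, sym), compute_m20(noisy, cell, sym))
  expect_warning(compute_m20(noisy[1:10], cell, sym), "10 peaks")
})

test_that("M* is zero for on-line mass, linear in intensity, and ranks the true cell", {
  cell <- unit_cell(6, 8, 10); sym <- lattice_symmetry("oP")
  # pattern whose whole mass sits (to bin-centre precision) on a predicted
  # line of a cubic candidate: numerator ~ 0 so M* ~ 0
  pat1 <- synthesize_powder(rep(2.5, 100), n_bins = 1, d_range = c(2.49999, 2.50001))
  ms0 <- compute_mstar(pat1, unit_cell(2.5, 2.5, 2.5), lattice_symmetry("cP"),
                       m20 = 100)
  expect_lt(ms0, 1e-6)
  # linearity in I
  lines <- predict_lines(cell, sym, d_min = 2.2)
  pat <- synthesize_powder(rep(lines, each = 20) * (1 + 2e-4), n_bins = 300)
  pat_k <- pat; pat_k$counts <- 3 * pat$counts
  expect_equal(compute_mstar(pat_k, cell, sym, m20 = 100),
               3 * compute_mstar(pat, cell, sym, m20 = 100), tolerance = 1e-12)
  # true cell vs 3%-stretched distractor on simulated data
  fr <- mith_frames_default()
  mith <- mithrene_cell()
  patm <- pick_peaks(synthesize_powder(harvest_d_spacings(fr)))
  stretch <- unit_cell(mith$a * 1.03, mith$b, mith$c, 90, mith$beta, 90)
  expect_lt(compute_mstar(patm, mith, mC()), compute_mstar(patm, stretch, mC()))
  expect_error(compute_mstar(synthesize_powder(2.5), unit_cell(40, 40, 40),
                             lattice_symmetry("cP"), m20 = 1),
               NA)  # dense cell still defined
})

test_that("the naive grid recovers a synthetic orthorhombic cell within 0.5%", {
  cellT <- unit_cell(6, 8, 10); sym <- lattice_symmetry("oP")
  cfg <- sim_config(cellT, sym, d_min = 1.5, seed = 3)
  fr <- simulate_dataset(cfg, 600)
  pat <- pick_peaks(synthesize_powder(harvest_d_spacings(fr)))
  cands <- naive_candidate_grid(pat, bravais = "oP", volume_range = c(200, 1200))
  hit <- vapply(cands, function(cl)
    all(abs(sort(c(cl$a, cl$b, cl$c)) - c(6, 8, 10)) / c(6, 8, 10) < 0.005),
    logical(1))
  expect_true(any(hit))

  # user-supplied candidates pass through verbatim
  user <- unit_cell(11.3, 12.4, 13.5)
  cands2 <- naive_candidate_grid(pat, bravais = "oP", volume_range = c(200, 1200),
                                 user_cells = list(user))
  expect_true(any(vapply(cands2, function(cl) identical(as.numeric(cl),
                                                        as.numeric(user)), logical(1))))
  # a volume window excluding the true volume excludes the true cell
  cands3 <- naive_candidate_grid(pat, bravais = "oP", volume_range = c(1500, 2000))
  hit3 <- vapply(cands3, function(cl)
    all(abs(sort(c(cl$a, cl$b, cl$c)) - c(6, 8, 10)) / c(6, 8, 10) < 0.005),
    logical(1))
  expect_false(any(hit3))
})

test_that("candidate evaluation ranks by indexing rate with M* tie-break", {
  fr <- mith_frames_default()
  mith <- mithrene_cell()
  pat <- pick_peaks(synthesize_powder(harvest_d_spacings(fr)))
  # restrict to a subset of frames to keep the scan fast
  sub <- fr; sub$frames <- fr$frames[1:120]
  cands <- list(
    list(cell = mith, symmetry = mC()),
    list(cell = unit_cell(mith$b, mith$a, mith$c, 90, mith$beta, 90), symmetry = mC()),
    list(cell = unit_cell(mith$a * 1.03, mith$b, mith$c, 90, mith$beta, 90), symmetry = mC()))
  sc <- evaluate_candidates(sub, cands, pattern = pat)
  expect_s3_class(sc, "candidate_scores")
  expect_equal(sc$candidate[1], 1)               # truth wins the rate ranking
  expect_true(all(diff(sc$indexing_rate) <= 0))  # sorted descending
  expect_true(all(sc$indexing_rate >= 0 & sc$indexing_rate <= 1))
  # frames below the minimum clique size index nothing
  tiny <- fr
  tiny$frames <- lapply(fr$frames[1:20], function(f) {
    f$spots <- f$spots[seq_len(min(2, nrow(f$spots))), , drop = FALSE]; f })
  sc0 <- evaluate_candidates(tiny, cands[1])
  expect_equal(sc0$indexing_rate, 0)
})

test_that("candidate ranking is invariant to frame order", {
  fr <- mith_frames_default()
  sub <- fr; sub$frames <- fr$frames[1:80]
  perm <- sub; perm$frames <- sub$frames[sample(80)]
  p <- indexer_params()
  r1 <- index_dataset(sub, mithrene_cell(), mC(), p)
  r2 <- index_dataset(perm, mithrene_cell(), mC(), p)
  expect_equal(r1$rate, r2$rate)
  expect_equal(r1$n_indexed, r2$n_indexed)
})
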
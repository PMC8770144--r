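# Shared fixtures. Table-derived reference cells, and lazily built (cached)
# simulated datasets reused across test files.

mithrene_cell <- function() unit_cell(5.938, 7.325, 29.202, 90, 95.44, 90)
thiorene_cell <- function() unit_cell(7.290, 5.879, 28.072, 90, 93.80, 90)
tethrene_cell <- function() unit_cell(5.900, 7.424, 30.258, 90, 97.686, 90)
mC <- function() lattice_symmetry("mC")

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, build) {
  if (!exists(key, .fixture_cache)) assign(key, build(), .fixture_cache)
  get(key, .fixture_cache)
}

# 500 default-noise frames of the monoclinic C test lattice
mith_frames_default <- function() cached("mith_default", function() {
  simulate_dataset(sim_config(mithrene_cell(), mC(), seed = 101), 500)
})

# noise-free (exact centroids, no intensity noise) frames, default optics
mith_frames_clean <- function() cached("mith_clean", function() {
  simulate_dataset(sim_config(mithrene_cell(), mC(), centroid_noise = 0,
                              intensity_noise = 0, seed = 102), 300)
})

# a frame built directly in reciprocal space: exact spots from a chosen
# orientation, no detector involved — for indexing unit tests
exact_frame <- function(cell, hkl, R = diag(3), frame_id = 1L) {
  B <- b_matrix(cell)
  X <- hkl %*% t(B) %*% t(R)
  d <- 1 / sqrt(rowSums(X^2))
  list(frame_id = frame_id, wavelength = 1.0,
       spots = data.frame(fast = 0, slow = 0, sx = X[, 1], sy = X[, 2],
                          sz = X[, 3], d = d,
                          intensity = rep(1, nrow(X)), sigma = rep(0.05, nrow(X))),
       truth = list(A = R %*% B, hkl = hkl, scale = 1))
}

rotation_about <- function(axis, angle_deg) {
  u <- axis / sqrt(sum(axis^2))
  th <- angle_deg * pi / 180
  K <- rbind(c(0, -u[3], u[2]), c(u[3], 0, -u[1]), c(-u[2], u[1], 0))
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# independent exhaustive maximum-clique oracle (all vertex subsets)
brute_force_max_clique <- function(adj) {
  n <- nrow(adj)
  best <- integer(0)
  for (mask in seq_len(2^n) - 1L) {
    v <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(v) <= length(best)) next
    ok <- TRUE
    if (length(v) > 1) {
      pairs <- utils::combn(v, 2)
      ok <- all(adj[t(pairs)])
    }
    if (ok) best <- v
  }
  best
}

# ground-truth |F|^2 table for a merged/observation set
truth_f2_table <- function(hkl_matrix, cell) {
  H <- unique(hkl_matrix)
  data.frame(h = H[, 1], k = H[, 2], l = H[, 3],
             I = toy_structure_factor(default_toy_structure(), H, cell))
}

cor_vs_truth <- function(merged, cell, min_n = 2) {
  tf <- truth_f2_table(as.matrix(merged[, c("h", "k", "l")]), cell)
  key <- paste(merged$h, merged$k, merged$l)
  tk <- paste(tf$h, tf$k, tf$l)
  idx <- match(key, tk)
  ok <- !is.na(idx) & merged$n >= min_n
  stats::cor(merged$I[ok], tf$I[idx[ok]])
}
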
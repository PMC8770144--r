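#' Lattice symmetry: Bravais type, Laue group and centring
#'
#' Bundles the pieces of symmetry the processing pipeline needs: the Bravais
#' letter (which fixes the centring condition on allowed hkl) and the Laue
#' group (the point group including inversion, under which intensities are
#' merged). Only Laue groups and centring predicates are carried; full
#' space-group machinery is out of scope.
#'
#' @param bravais One of `"aP","mP","mC","oP","oC","oF","oI","tP","tI",
#'   "hP","hR","cP","cF","cI"`.
#' @param laue_group Laue group label; default inferred from the Bravais
#'   class (e.g. `"2/m"` for monoclinic, `"mmm"` for orthorhombic).
#' @return An object of class `lattice_symmetry` with fields `bravais`,
#'   `laue_group`, `centring` (single letter) and `ops` (list of 3x3 integer
#'   matrices forming the Laue group, inversion included).
#' @export
lattice_symmetry <- function(bravais, laue_group = NULL) {
  valid <- c("aP", "mP", "mC", "oP", "oC", "oF", "oI", "tP", "tI",
             "hP", "hR", "cP", "cF", "cI")
  if (!bravais %in% valid) stop("unknown Bravais type: ", bravais)
  if (is.null(laue_group)) {
    laue_group <- switch(substr(bravais, 1, 1),
                         a = "-1", m = "2/m", o = "mmm", t = "4/mmm",
                         h = if (bravais == "hR") "-3m" else "6/mmm",
                         c = "m-3m")
  }
  structure(list(bravais = bravais,
                 laue_group = laue_group,
                 centring = substr(bravais, 2, 2),
                 ops = laue_ops(laue_group)),
            class = "lattice_symmetry")
}

#' @export
print.lattice_symmetry <- function(x, ...) {
  cat(sprintf("lattice symmetry: %s, Laue group %s (%d ops), centring %s\n",
              x$bravais, x$laue_group, length(x$ops), x$centring))
  invisible(x)
}

# Group closure from generator matrices (acting on hkl column vectors).
group_closure <- function(gens) {
  key <- function(m) paste(as.integer(m), collapse = ",")
  ops <- list(diag(3))
  seen <- key(diag(3))
  queue <- gens
  while (length(queue)) {
    g <- queue[[1]]; queue <- queue[-1]
    k <- key(g)
    if (k %in% seen) next
    seen <- c(seen, k); ops <- c(ops, list(g))
    for (h in ops) {
      queue <- c(queue, list(g %*% h), list(h %*% g))
    }
    if (length(ops) > 96) stop("group closure did not terminate")
  }
  ops
}

#' Laue group operators
#'
#' Returns the full set of integer 3x3 matrices of the Laue group acting on
#' Miller indices (inversion always included). Hexagonal/trigonal groups use
#' hexagonal axes; `"-3m"` uses the rhombohedral-obverse hexagonal setting.
#'
#' @param label One of `"-1","2/m","mmm","4/m","4/mmm","-3","-3m","6/m",
#'   "6/mmm","m-3","m-3m"`.
#' @return List of 3x3 integer matrices.
#' @export
laue_ops <- function(label) {
  inv <- -diag(3)
  two_b <- diag(c(-1, 1, -1))          # 2-fold along b
  two_c <- diag(c(-1, -1, 1))          # 2-fold along c
  two_a <- diag(c(1, -1, -1))
  four_c <- rbind(c(0, -1, 0), c(1, 0, 0), c(0, 0, 1))   # 4+ along c
  three_hex <- rbind(c(0, 1, 0), c(-1, -1, 0), c(0, 0, 1)) # 3+ along c, hex axes
  two_110 <- rbind(c(0, 1, 0), c(1, 0, 0), c(0, 0, -1))  # 2-fold along [110]
  three_111 <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0)) # cyclic xyz
  gens <- switch(label,
    "-1"    = list(),
    "2/m"   = list(two_b),
    "mmm"   = list(two_a, two_b),
    "4/m"   = list(four_c),
    "4/mmm" = list(four_c, two_a),
    "-3"    = list(three_hex),
    "-3m"   = list(three_hex, two_110),
    "6/m"   = list(three_hex, two_c),
    "6/mmm" = list(three_hex, two_c, two_110),
    "m-3"   = list(three_111, two_c, two_a),
    "m-3m"  = list(three_111, four_c),
    stop("unknown Laue group: ", label))
  group_closure(c(gens, list(inv)))
}

#' Centring condition on Miller indices
#'
#' @param hkl Length-3 integer vector or n x 3 matrix.
#' @param centring Single letter `"P","A","B","C","F","I","R"`, or a
#'   [lattice_symmetry()] object.
#' @return Logical vector: TRUE where the reflection is allowed by the
#'   lattice centring.
#' @export
centring_allowed <- function(hkl, centring) {
  if (inherits(centring, "lattice_symmetry")) centring <- centring$centring
  H <- as_hkl_matrix(hkl)
  h <- H[, 1]; k <- H[, 2]; l <- H[, 3]
  switch(centring,
         P = rep(TRUE, nrow(H)),
         A = (k + l) %% 2 == 0,
         B = (h + l) %% 2 == 0,
         C = (h + k) %% 2 == 0,
         I = (h + k + l) %% 2 == 0,
         F = (h %% 2 == k %% 2) & (k %% 2 == l %% 2),
         R = (-h + k + l) %% 3 == 0,
         stop("unknown centring: ", centring))
}

#' Reduce Miller indices to a canonical asymmetric-unit representative
#'
#' Canonical representative of the orbit of `hkl` under the Laue group
#' (inversion/Friedel included): the lexicographic maximum over the orbit,
#' comparing h, then k, then l. Deterministic and idempotent.
#'
#' @param hkl Length-3 integer vector or n x 3 matrix (no (0,0,0) rows).
#' @param symmetry A [lattice_symmetry()].
#' @return Canonical indices, same shape as the input.
#' @export
reduce_to_asu <- function(hkl, symmetry) {
  H <- as_hkl_matrix(hkl)
  if (any(rowSums(H != 0) == 0)) stop("cannot reduce hkl = (0,0,0)")
  ops <- symmetry$ops
  # stack orbit images: for each op, H %*% t(op)  (h' = M h, rows are h')
  best <- H %*% t(ops[[1]])
  if (length(ops) > 1) {
    for (i in 2:length(ops)) {
      cand <- H %*% t(ops[[i]])
      repl <- (cand[, 1] > best[, 1]) |
        (cand[, 1] == best[, 1] & cand[, 2] > best[, 2]) |
        (cand[, 1] == best[, 1] & cand[, 2] == best[, 2] & cand[, 3] > best[, 3])
      best[repl, ] <- cand[repl, , drop = FALSE]
    }
  }
  storage.mode(best) <- "integer"
  if (is.matrix(hkl)) best else as.integer(best[1, ])
}

#' Orbit of a reflection under the Laue group
#'
#' @param hkl Length-3 integer vector.
#' @param symmetry A [lattice_symmetry()].
#' @return Matrix of distinct symmetry-equivalent indices (Friedel included).
#' @export
hkl_orbit <- function(hkl, symmetry) {
  stopifnot(length(hkl) == 3)
  imgs <- t(vapply(symmetry$ops, function(M) as.integer(M %*% hkl), integer(3)))
  unique(imgs)
}

#' Reindexing operator
#'
#' An integer 3x3 matrix with determinant +-1 acting on Miller indices,
#' h' = M h; its inverse-transpose acts on the basis. Used both for
#' pseudosymmetry (indexing-ambiguity) operators and for settings changes.
#'
#' @param M 3x3 integer matrix, det +-1.
#' @return Object of class `reindex_op` (the matrix itself, classed).
#' @export
reindex_op <- function(M) {
  M <- as.matrix(M)
  if (!all(dim(M) == c(3, 3))) stop("reindex operator must be 3x3")
  if (any(abs(M - round(M)) > 1e-9)) stop("reindex operator entries must be integers")
  M <- round(M)
  if (abs(abs(det(M)) - 1) > 1e-9) stop("reindex operator must have det +-1")
  storage.mode(M) <- "integer"
  structure(M, class = c("reindex_op", "matrix"))
}

#' @export
print.reindex_op <- function(x, ...) {
  cat(sprintf("reindex operator (%s)\n",
              paste(apply(unclass(x), 1, function(r) paste(r, collapse = " ")),
                    collapse = " / ")))
  invisible(x)
}

#' Apply a reindexing operator to Miller indices
#' @param op A [reindex_op()] (or plain integer 3x3 matrix).
#' @param hkl Length-3 vector or n x 3 matrix.
#' @return Remapped indices, same shape.
#' @export
apply_reindex <- function(op, hkl) {
  H <- as_hkl_matrix(hkl)
  out <- H %*% t(unclass(op))
  storage.mode(out) <- "integer"
  if (is.matrix(hkl)) out else as.integer(out[1, ])
}

op_key <- function(M) paste(as.integer(M), collapse = ",")

#' Discover metric-pseudosymmetry (indexing-ambiguity) operators
#'
#' Scans integer matrices M with entries bounded by `bound` and det +-1 for
#' operators that leave the cell metric approximately invariant,
#' ||M G M' - G||_F / ||G||_F <= tol, but are not members of the Laue group.
#' Such operators map the lattice almost onto itself in inequivalent
#' settings: each indexed frame may adopt any of them, which merges as
#' pseudo-merohedral twinning unless resolved against a reference.
#'
#' One representative per left coset of the Laue group is returned (if M
#' qualifies, every S M with S in the Laue group describes the same
#' ambiguity). An empty list means no ambiguity at this tolerance.
#'
#' @param cell A [unit_cell()].
#' @param symmetry A [lattice_symmetry()].
#' @param tol Relative Frobenius tolerance on the metric deviation.
#'   Default 0.005: larger than cell-parameter noise, smaller than the real
#'   symmetry breaks relevant here (e.g. beta - 90 of a few degrees).
#' @param bound Entry bound of the integer search (default 2).
#' @return List of [reindex_op()] coset representatives.
#' @export
find_pseudosymmetry_ops <- function(cell, symmetry, tol = 0.005, bound = 2L) {
  if (tol <= 0) stop("tol must be positive")
  G <- metric_tensor(cell)
  nG <- norm(G, "F")
  rng <- seq.int(-bound, bound)
  rows <- as.matrix(expand.grid(h = rng, k = rng, l = rng))
  qf <- rowSums((rows %*% G) * rows)  # r G r' for every candidate row
  # prefilter: row i of M must have quadratic form close to G[i,i]
  cand <- lapply(1:3, function(i) which(abs(qf - G[i, i]) <= tol * nG))
  found <- list()
  for (i1 in cand[[1]]) {
    r1 <- rows[i1, ]
    for (i2 in cand[[2]]) {
      r2 <- rows[i2, ]
      g12 <- sum(r1 * (G %*% r2))
      if (abs(g12 - G[1, 2]) > tol * nG) next
      for (i3 in cand[[3]]) {
        r3 <- rows[i3, ]
        M <- rbind(r1, r2, r3, deparse.level = 0)
        dM <- r1[1] * (r2[2] * r3[3] - r2[3] * r3[2]) -
              r1[2] * (r2[1] * r3[3] - r2[3] * r3[1]) +
              r1[3] * (r2[1] * r3[2] - r2[2] * r3[1])
        if (abs(dM) != 1) next
        if (norm(M %*% G %*% t(M) - G, "F") / nG > tol) next
        found <- c(found, list(M))
      }
    }
  }
  if (!length(found)) return(list())
  # coset reduction modulo the Laue group: M ~ S M
  laue_keys <- vapply(symmetry$ops, op_key, character(1))
  reps <- list(); seen <- character(0)
  for (M in found) {
    imgs <- lapply(symmetry$ops, function(S) S %*% M)
    keys <- vapply(imgs, op_key, character(1))
    if (any(keys %in% laue_keys)) next      # identity coset: not an ambiguity
    ck <- min(keys)
    if (ck %in% seen) next
    seen <- c(seen, ck)
    # deterministic representative: lexicographically smallest key
    reps <- c(reps, list(reindex_op(imgs[[order(keys)[1]]])))
  }
  reps[order(vapply(reps, function(m) sum(abs(m)), numeric(1)),
             vapply(reps, op_key, character(1)))]
}

#' Full indexing-equivalence operator set
#'
#' Group closure of the Laue operators together with any metric
#' pseudosymmetry operators: the complete set of hkl remappings under which
#' an indexing solution of a single still is indistinguishable. Two
#' orientation matrices related through any of these describe the same
#' physical indexing.
#'
#' @param symmetry A [lattice_symmetry()].
#' @param extra_ops List of [reindex_op()] (e.g. from
#'   [find_pseudosymmetry_ops()]).
#' @return List of 3x3 integer matrices (a finite group).
#' @export
ambiguity_ops <- function(symmetry, extra_ops = list()) {
  group_closure(c(symmetry$ops, lapply(extra_ops, unclass)))
}

#' Misorientation angle between two orientation matrices
#'
#' Smallest rotation angle relating two settings `A1`, `A2` (each mapping
#' hkl to lab reciprocal vectors), minimised over a set of reindexing
#' operators (typically the Laue group plus any pseudosymmetry operators):
#' the indexing solution is only defined up to those.
#'
#' When `cell` is supplied the comparison is strain-aware: for each operator
#' the equivalent target orientation is the nearest pure rotation
#' representing the reindexed setting (`A1 M^-1 B^-1` polar-decomposed), so
#' a metric-pseudosymmetry operator's intrinsic lattice strain does not
#' count as misorientation. Without `cell`, the nearest rotation to
#' `A1 (A2 M)^-1` is used directly.
#'
#' @param A1,A2 3x3 orientation matrices (A = R B).
#' @param ops List of 3x3 integer matrices to minimise over (identity is
#'   always included).
#' @param cell Optional [unit_cell()] both settings refer to.
#' @return Angle in degrees.
#' @export
misorientation_angle <- function(A1, A2, ops = list(), cell = NULL) {
  ops <- c(list(diag(3)), lapply(ops, unclass))
  nearest_rotation <- function(Q) {
    sv <- svd(Q)
    sv$u %*% diag(c(1, 1, det(sv$u %*% t(sv$v)))) %*% t(sv$v)
  }
  angle_of <- function(R) {
    rad2deg(acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))))
  }
  best <- Inf
  if (is.null(cell)) {
    for (M in ops) {
      # if frame 2 indexed with h' = M h, its equivalent matrix is A2 M
      R <- nearest_rotation(A1 %*% solve(A2 %*% M))
      best <- min(best, angle_of(R))
    }
  } else {
    B <- b_matrix(cell)
    Binv <- solve(B)
    R2 <- nearest_rotation(A2 %*% Binv)
    for (M in ops) {
      Req <- nearest_rotation(A1 %*% solve(M) %*% Binv)
      best <- min(best, angle_of(Req %*% t(R2)))
    }
  }
  best
}
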
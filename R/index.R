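#' Indexer parameters
#'
#' Tolerances of the sparse-frame maximum-clique indexer.
#'
#' @param d_tol Relative d-spacing tolerance for spot-to-hkl hypothesis
#'   assignment (default 0.005, bracketing the ~0.3% beam bandwidth plus
#'   centroid noise).
#' @param pair_tol Absolute tolerance (1/Angstrom) on the difference between
#'   the measured inter-spot reciprocal distance and the one computed from
#'   the candidate cell (default 0.0015).
#' @param min_clique Minimum clique size (spots) to accept a solution;
#'   3 non-collinear reciprocal vectors are the minimum that fix a rotation.
#' @param frac_cut Fractional Miller-index cutoff for accepting additional
#'   spots after the clique orientation fit: a spot joins the solution when
#'   its back-computed indices deviate from integers by less than this on
#'   every axis (default 0.1, the tight small-molecule setting; 0.3 is the
#'   macromolecular default).
#' @param rms_tol Acceptance threshold on the rms reciprocal-space residual
#'   of the final solution (1/Angstrom).
#' @param max_nodes Cap on assignment nodes per frame (hypotheses beyond the
#'   cap are dropped, worst relative d mismatch first).
#' @return Named list of class `indexer_params`.
#' @export
indexer_params <- function(d_tol = 0.005, pair_tol = 0.0015, min_clique = 3,
                           frac_cut = 0.1, rms_tol = 0.003, max_nodes = 350) {
  if (d_tol < 0 || pair_tol < 0 || rms_tol <= 0) stop("tolerances must be non-negative")
  if (min_clique < 3) stop("min_clique must be at least 3")
  structure(list(d_tol = d_tol, pair_tol = pair_tol, min_clique = min_clique,
                 frac_cut = frac_cut, rms_tol = rms_tol, max_nodes = max_nodes),
            class = "indexer_params")
}

#' Spot-to-hkl assignment hypotheses for one frame
#'
#' For every spot, all lattice reflections (centring-allowed, full sphere —
#' both Friedel mates and all symmetry images are separate hypotheses) whose
#' d spacing matches the observed one within `d_tol` relative.
#'
#' @param frame A single frame (element of `sfx_frames$frames`).
#' @param cell Candidate [unit_cell()].
#' @param symmetry A [lattice_symmetry()].
#' @param d_tol Relative d tolerance.
#' @param lattice Optional precomputed [reflection_list()] (for batch reuse).
#' @return Data frame of assignment nodes: `spot`, `h`, `k`, `l`, `reld`.
#' @export
candidate_assignments <- function(frame, cell, symmetry, d_tol = 0.005,
                                  lattice = NULL) {
  sp <- frame$spots
  if (!nrow(sp)) return(data.frame(spot = integer(0), h = integer(0),
                                   k = integer(0), l = integer(0),
                                   reld = numeric(0)))
  if (is.null(lattice))
    lattice <- reflection_list(cell, symmetry, d_min = min(sp$d) * (1 - 3 * d_tol))
  out <- vector("list", nrow(sp))
  for (i in seq_len(nrow(sp))) {
    rel <- abs(sp$d[i] - lattice$d) / lattice$d
    m <- which(rel <= d_tol)
    if (length(m))
      out[[i]] <- data.frame(spot = i, h = lattice$h[m], k = lattice$k[m],
                             l = lattice$l[m], reld = rel[m])
  }
  res <- do.call(rbind, out)
  if (is.null(res)) res <- data.frame(spot = integer(0), h = integer(0),
                                      k = integer(0), l = integer(0),
                                      reld = numeric(0))
  rownames(res) <- NULL
  res
}

#' Pairwise reciprocal-space consistency graph
#'
#' Nodes are (spot, hkl-hypothesis) pairs. Two nodes are connected when they
#' belong to distinct spots and the measured inter-spot reciprocal distance
#' ||s_i - s_j|| agrees with the cell-computed |x(hkl_i) - x(hkl_j)| within
#' `pair_tol`; two hypotheses of one spot are never adjacent. Measured s
#' vectors are taken on the per-shot nominal-wavelength Ewald sphere.
#'
#' @param frame A single frame.
#' @param nodes Assignment nodes from [candidate_assignments()].
#' @param cell Candidate [unit_cell()].
#' @param pair_tol Absolute tolerance in 1/Angstrom.
#' @return List of class `consistency_graph`: `adjacency` (logical matrix),
#'   `mismatch` (numeric matrix of |measured - computed| distances),
#'   `nodes`.
#' @export
consistency_graph <- function(frame, nodes, cell, pair_tol = 0.0015) {
  n <- nrow(nodes)
  S <- as.matrix(frame$spots[nodes$spot, c("sx", "sy", "sz"), drop = FALSE])
  Gs <- reciprocal_metric(cell)
  H <- as.matrix(nodes[, c("h", "k", "l"), drop = FALSE])
  if (n) {
    # measured pair distances
    d2 <- as.matrix(stats::dist(S))
    # computed pair distances from the metric: |B (h_i - h_j)|
    QH <- H %*% Gs
    g <- rowSums(QH * H)
    cross <- QH %*% t(H)
    calc2 <- outer(g, g, "+") - 2 * cross
    calc <- sqrt(pmax(calc2, 0))
    mism <- abs(d2 - calc)
    adj <- mism <= pair_tol
    same_spot <- outer(nodes$spot, nodes$spot, "==")
    adj[same_spot] <- FALSE
    diag(adj) <- FALSE
  } else {
    adj <- matrix(logical(0), 0, 0)
    mism <- matrix(numeric(0), 0, 0)
  }
  structure(list(adjacency = adj, mismatch = mism, nodes = nodes),
            class = "consistency_graph")
}

#' Exact maximum clique
#'
#' Branch-and-bound search (greedy-colouring bound) for the maximum clique
#' of a consistency graph; among cliques of equal size the one with the
#' smallest summed pairwise mismatch is returned. Deterministic for a given
#' input.
#'
#' @param graph A [consistency_graph()], or a bare logical adjacency matrix.
#' @return Integer vector of node indices (empty when the graph is empty or
#'   edgeless with fewer than one node).
#' @export
max_clique <- function(graph) {
  if (inherits(graph, "consistency_graph")) {
    adj <- graph$adjacency; w <- graph$mismatch
  } else {
    adj <- graph
    w <- matrix(0, nrow(adj), ncol(adj))
  }
  if (!nrow(adj)) return(integer(0))
  .max_clique_bb(adj, w)
}

fit_orientation <- function(S, BH) {
  # orthogonal Procrustes: rotation R minimising sum |s_i - R (B h)_i|^2
  M <- t(S) %*% BH
  sv <- svd(M)
  d <- det(sv$u %*% t(sv$v))
  sv$u %*% diag(c(1, 1, d)) %*% t(sv$v)
}

#' Index one sparse still frame
#'
#' Pipeline: d-spacing assignment hypotheses, pairwise consistency graph,
#' exact maximum clique, orthogonal-Procrustes orientation fit against the
#' cell's B matrix, extension to further spots whose back-computed
#' fractional Miller indices are within `frac_cut` of integers on every
#' axis, and a final orientation-only re-refinement (the cell is never
#' refined). Degenerate cliques (collinear reciprocal vectors) and
#' solutions above the rms residual threshold are rejected.
#'
#' @param frame A single frame.
#' @param cell Candidate [unit_cell()].
#' @param symmetry A [lattice_symmetry()].
#' @param params An [indexer_params()].
#' @param lattice Optional precomputed [reflection_list()].
#' @return An `indexing_solution` (list with `frame_id`, `A`, `assignments`,
#'   `clique_size`, `rms`) or NULL when the frame does not index.
#' @export
index_frame <- function(frame, cell, symmetry, params = indexer_params(),
                        lattice = NULL) {
  sp <- frame$spots
  if (nrow(sp) < params$min_clique) return(NULL)
  nodes <- candidate_assignments(frame, cell, symmetry, params$d_tol, lattice)
  if (nrow(nodes) > params$max_nodes) {
    nodes <- nodes[order(nodes$reld)[seq_len(params$max_nodes)], , drop = FALSE]
    rownames(nodes) <- NULL
  }
  if (length(unique(nodes$spot)) < params$min_clique) return(NULL)
  g <- consistency_graph(frame, nodes, cell, params$pair_tol)
  cl <- max_clique(g)
  if (length(cl) < params$min_clique) return(NULL)
  picked <- nodes[cl, , drop = FALSE]
  B <- b_matrix(cell)
  S <- as.matrix(sp[picked$spot, c("sx", "sy", "sz"), drop = FALSE])
  BH <- as.matrix(picked[, c("h", "k", "l")]) %*% t(B)
  # reject degenerate (collinear) clique geometry
  sv <- svd(BH)
  if (sv$d[2] < 1e-4 * sv$d[1]) return(NULL)
  # pairwise distances are blind to a global Friedel flip: the clique may be
  # the enantiomorph image of the real assignment, which no proper rotation
  # fits. Fit both hypotheses and keep the better one.
  R_pos <- fit_orientation(S, BH)
  R_neg <- fit_orientation(S, -BH)
  rms_pos <- sqrt(mean(rowSums((S - BH %*% t(R_pos))^2)))
  rms_neg <- sqrt(mean(rowSums((S + BH %*% t(R_neg))^2)))
  if (rms_neg < rms_pos) {
    picked[, c("h", "k", "l")] <- -picked[, c("h", "k", "l")]
    BH <- -BH
    R <- R_neg
  } else {
    R <- R_pos
  }
  A <- R %*% B
  # extension: unassigned spots whose fractional indices are near-integral
  assigned <- picked[, c("spot", "h", "k", "l")]
  free <- setdiff(seq_len(nrow(sp)), assigned$spot)
  if (length(free)) {
    Sfree <- as.matrix(sp[free, c("sx", "sy", "sz"), drop = FALSE])
    hfrac <- Sfree %*% t(solve(A))
    hint <- round(hfrac)
    dev <- abs(hfrac - hint)
    ok <- apply(dev, 1, max) < params$frac_cut &
      rowSums(hint != 0) > 0 &
      centring_allowed(hint, symmetry)
    if (any(ok)) {
      add <- data.frame(spot = free[ok], h = hint[ok, 1],
                        k = hint[ok, 2], l = hint[ok, 3])
      # one spot per hkl: keep the smallest deviation
      add <- add[order(apply(dev[ok, , drop = FALSE], 1, max)), , drop = FALSE]
      key <- paste(add$h, add$k, add$l)
      add <- add[!duplicated(key), , drop = FALSE]
      key0 <- paste(assigned$h, assigned$k, assigned$l)
      add <- add[!paste(add$h, add$k, add$l) %in% key0, , drop = FALSE]
      assigned <- rbind(assigned, add)
    }
  }
  # orientation-only re-refinement on all assigned spots (cell fixed);
  # extension spots that degrade the fit are shed, worst first — the clique
  # itself is never pruned
  n_clique <- length(cl)
  repeat {
    S2 <- as.matrix(sp[assigned$spot, c("sx", "sy", "sz"), drop = FALSE])
    BH2 <- as.matrix(assigned[, c("h", "k", "l")]) %*% t(B)
    R <- fit_orientation(S2, BH2)
    rms <- sqrt(mean(rowSums((S2 - BH2 %*% t(R))^2)))
    if (rms <= params$rms_tol || nrow(assigned) <= n_clique) break
    per_spot <- sqrt(rowSums((S2 - BH2 %*% t(R))^2))
    ext <- seq_len(nrow(assigned)) > n_clique
    worst <- which(ext)[which.max(per_spot[ext])]
    assigned <- assigned[-worst, , drop = FALSE]
  }
  A <- R %*% B
  if (rms > params$rms_tol) return(NULL)
  assigned <- assigned[order(assigned$spot), , drop = FALSE]
  rownames(assigned) <- NULL
  structure(list(frame_id = frame$frame_id, A = A, assignments = assigned,
                 clique_size = length(cl), rms = rms),
            class = "indexing_solution")
}

#' @export
print.indexing_solution <- function(x, ...) {
  cat(sprintf("indexing solution: frame %s, %d spots assigned (clique %d), rms %.2e 1/A\n",
              format(x$frame_id), nrow(x$assignments), x$clique_size, x$rms))
  invisible(x)
}

#' Index a batch of frames
#'
#' Runs [index_frame()] over all frames; per-frame failures (including
#' errors) count as non-indexed. A "hit" is a frame with at least one spot.
#'
#' @param frames An `sfx_frames` object.
#' @param cell Candidate [unit_cell()].
#' @param symmetry A [lattice_symmetry()].
#' @param params An [indexer_params()].
#' @return Object of class `indexing_results`: list with `solutions` (one
#'   per indexed frame), `n_hits`, `n_indexed`, `rate`.
#' @export
index_dataset <- function(frames, cell, symmetry, params = indexer_params()) {
  sp_counts <- vapply(frames$frames, function(f) nrow(f$spots), integer(1))
  n_hits <- sum(sp_counts > 0)
  dmin_obs <- suppressWarnings(
    min(vapply(frames$frames,
               function(f) if (nrow(f$spots)) min(f$spots$d) else Inf, numeric(1))))
  lattice <- if (is.finite(dmin_obs))
    reflection_list(cell, symmetry, d_min = dmin_obs * (1 - 3 * params$d_tol))
  else NULL
  sols <- list()
  for (fr in frames$frames) {
    if (!nrow(fr$spots)) next
    sol <- tryCatch(index_frame(fr, cell, symmetry, params, lattice),
                    error = function(e) NULL)
    if (!is.null(sol)) sols[[length(sols) + 1L]] <- sol
  }
  structure(list(solutions = sols, n_hits = n_hits, n_indexed = length(sols),
                 rate = if (n_hits) length(sols) / n_hits else 0),
            class = "indexing_results")
}

#' @export
print.indexing_results <- function(x, ...) {
  cat(sprintf("indexing results: %d / %d hit frames indexed (rate %.3f)\n",
              x$n_indexed, x$n_hits, x$rate))
  invisible(x)
}
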
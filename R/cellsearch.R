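#' Predicted powder lines of a candidate cell
#'
#' Distinct calculated d values (centring-allowed, symmetry-unique, merged
#' within a relative epsilon) in a resolution window.
#'
#' @param cell A [unit_cell()].
#' @param symmetry A [lattice_symmetry()].
#' @param d_min,d_max Resolution window in Angstrom.
#' @param eps Relative spacing below which two calculated lines merge.
#' @return Sorted (descending d) numeric vector of line positions.
#' @export
predict_lines <- function(cell, symmetry, d_min, d_max = Inf, eps = 1e-5) {
  refl <- reflection_list(cell, symmetry, d_min)
  refl <- refl[refl$d <= d_max, , drop = FALSE]
  if (!nrow(refl)) return(numeric(0))
  asu <- reduce_to_asu(as.matrix(refl[, c("h", "k", "l")]), symmetry)
  keep <- !duplicated(asu)
  d <- sort(refl$d[keep], decreasing = TRUE)
  # merge metrically coincident lines from distinct orbits
  out <- d[c(TRUE, abs(diff(d)) / d[-1] > eps)]
  out
}

M20_CEILING <- 1e4

#' de Wolff M20 figure of merit
#'
#' With Q = 1/d^2: M20 = Q20 / (2 <|dQ|> N20), where Q20 is the 20th
#' observed line's Q, <|dQ|> the mean absolute difference between each
#' observed Q and the nearest calculated line, and N20 the number of
#' distinct calculated lines (centring-allowed, symmetry-unique) with
#' Q <= Q20. Larger is better. A perfect fit is capped at 1e4 to keep
#' rankings finite.
#'
#' @param peaks Observed peak d values (Angstrom); at least 20, or fewer
#'   with a warning (all are then used).
#' @param cell Candidate [unit_cell()].
#' @param symmetry A [lattice_symmetry()].
#' @return M20 (dimensionless, positive).
#' @export
compute_m20 <- function(peaks, cell, symmetry) {
  d_obs <- sort(peaks, decreasing = TRUE)
  if (length(d_obs) < 20)
    warning(sprintf("only %d peaks supplied; M20 computed over all of them", length(d_obs)))
  n_use <- min(20L, length(d_obs))
  d_obs <- d_obs[seq_len(n_use)]
  Qobs <- 1 / d_obs^2
  Q20 <- max(Qobs)
  d_lines <- predict_lines(cell, symmetry, d_min = 1 / sqrt(Q20) * 0.999)
  Qcalc <- 1 / d_lines^2
  Qcalc <- Qcalc[Qcalc <= Q20 * (1 + 1e-9)]
  if (!length(Qcalc)) stop("candidate cell predicts no lines in the observed range")
  dq <- vapply(Qobs, function(q) min(abs(q - Qcalc)), numeric(1))
  mean_dq <- mean(dq)
  n20 <- length(Qcalc)
  if (mean_dq <= Q20 / (2 * n20 * M20_CEILING)) return(M20_CEILING)
  min(M20_CEILING, Q20 / (2 * mean_dq * n20))
}

#' M* candidate-cell figure of merit
#'
#' M* = (sum over pattern points of I * delta-d) / M20, where delta-d is the
#' unsigned distance (Angstrom) from each pattern point's d to the nearest
#' line predicted by the candidate, and I the point's counts. Lower is
#' better: a cell whose predicted lines sit under all the pattern mass gets
#' a numerator near zero, and the M20 denominator rewards line-efficient
#' cells.
#'
#' @param pattern A [synthesize_powder()] pattern with picked peaks (peaks are used for
#'   the M20 denominator; the sum runs over all pattern bins).
#' @param cell Candidate [unit_cell()].
#' @param symmetry A [lattice_symmetry()].
#' @param d_range Optional length-2 d window for the sum (default: pattern range).
#' @param m20 Optional precomputed M20 (otherwise computed from the
#'   pattern's picked peaks).
#' @return M* (dimensionless, >= 0).
#' @export
compute_mstar <- function(pattern, cell, symmetry, d_range = NULL, m20 = NULL) {
  stopifnot(inherits(pattern, "powder_pattern"))
  if (isTRUE(pattern$empty) || !length(pattern$counts)) stop("empty powder pattern")
  if (is.null(m20)) {
    if (is.null(pattern$peaks) || !nrow(pattern$peaks))
      stop("pattern has no picked peaks; run pick_peaks() or supply m20")
    m20 <- compute_m20(pattern$peaks$d, cell, symmetry)
  }
  mid <- bin_midpoints(pattern)
  d <- 1 / mid
  keep <- pattern$counts > 0
  if (!is.null(d_range)) keep <- keep & d >= min(d_range) & d <= max(d_range)
  d <- d[keep]; I <- pattern$counts[keep]
  if (!length(d)) stop("no pattern mass in the requested d range")
  lines <- predict_lines(cell, symmetry,
                         d_min = min(d) * 0.98, d_max = max(d) * 1.02)
  if (!length(lines)) stop("candidate cell predicts no lines in range")
  dd <- vapply(d, function(x) min(abs(x - lines)), numeric(1))
  sum(I * dd) / m20
}

# Mean |Q_obs - nearest Q_calc| of the observed peaks against a candidate
# (a, b, c, beta), plus a count of unexplained peaks. Fast enough to score
# thousands of grid points: the reflection box is enumerated directly from
# the reciprocal parameters, without symmetry reduction (duplicate lines do
# not change nearest-line distances).
peak_q_mismatch <- function(a, b, c, beta, qobs, centring = "P") {
  sb <- sin(deg2rad(beta)); cb <- cos(deg2rad(beta))
  as2 <- 1 / (a * sb)^2; bs2 <- 1 / b^2; cs2 <- 1 / (c * sb)^2
  ac <- -2 * cb / (a * c * sb^2)             # 2 a* c* cos(beta*)
  qmax <- max(qobs) * 1.05
  hmax <- ceiling(a * sqrt(qmax)) + 1L
  kmax <- ceiling(b * sqrt(qmax)) + 1L
  lmax <- ceiling(c * sqrt(qmax)) + 1L
  h <- seq.int(-hmax, hmax); k <- seq.int(0L, kmax); l <- seq.int(0L, lmax)
  # signed h with k, l >= 0 covers all distinct Q values of a monoclinic
  # (or higher) lattice
  hl_q <- outer(h^2 * as2, l^2 * cs2, "+") + outer(h, l) * ac
  if (centring == "C") {
    qc <- numeric(0)
    for (ki in k) {
      hs <- h[(abs(h) + ki) %% 2 == 0]
      if (!length(hs)) next
      block <- hl_q[match(hs, h), , drop = FALSE] + ki^2 * bs2
      qc <- c(qc, block[block > 1e-9 & block <= qmax])
    }
  } else {
    qc <- as.vector(outer(as.vector(hl_q), k^2 * bs2, "+"))
    qc <- qc[qc > 1e-9 & qc <= qmax]
  }
  if (!length(qc)) return(Inf)
  qc <- sort(qc)
  idx <- findInterval(qobs, qc)
  lo <- pmax(idx, 1L); hi <- pmin(idx + 1L, length(qc))
  mism <- mean(pmin(abs(qobs - qc[lo]), abs(qobs - qc[hi])))
  # de Wolff-style density penalty: a cell that explains the peaks only by
  # predicting lines everywhere scores no better than a sparse exact fit
  mism * length(qc)
}

# Nearest predicted (h,k,l) for each observed Q under a candidate cell.
nearest_hkl_for_peaks <- function(a, b, c, beta, qobs, centring = "P") {
  sb <- sin(deg2rad(beta)); cb <- cos(deg2rad(beta))
  as2 <- 1 / (a * sb)^2; bs2 <- 1 / b^2; cs2 <- 1 / (c * sb)^2
  ac <- -2 * cb / (a * c * sb^2)
  qmax <- max(qobs) * 1.05
  hmax <- ceiling(a * sqrt(qmax)) + 1L
  kmax <- ceiling(b * sqrt(qmax)) + 1L
  lmax <- ceiling(c * sqrt(qmax)) + 1L
  H <- as.matrix(expand.grid(h = -hmax:hmax, k = 0:kmax, l = 0:lmax))
  H <- H[rowSums(H != 0) > 0, , drop = FALSE]
  if (centring != "P") H <- H[centring_allowed(H, centring), , drop = FALSE]
  qc <- H[, 1]^2 * as2 + H[, 2]^2 * bs2 + H[, 3]^2 * cs2 + H[, 1] * H[, 3] * ac
  keep <- qc > 1e-9 & qc <= qmax
  H <- H[keep, , drop = FALSE]; qc <- qc[keep]
  idx <- vapply(qobs, function(q) which.min(abs(q - qc)), integer(1))
  list(hkl = H[idx, , drop = FALSE], dq = abs(qobs - qc[idx]))
}

# Assignment / least-squares refinement: Q(hkl) is linear in the reciprocal
# metric coefficients (a*^2, b*^2, c*^2 and the monoclinic cross term), so
# alternating nearest-line assignment with an analytic fit converges over a
# far wider basin than direct minimisation of the line mismatch.
assign_ls_refine <- function(p0, qobs, centring, monoclinic, iters = 5) {
  p <- p0
  for (it in seq_len(iters)) {
    asg <- nearest_hkl_for_peaks(p[1], p[2], p[3], p[4], qobs, centring)
    H <- asg$hkl
    X <- cbind(H[, 1]^2, H[, 2]^2, H[, 3]^2)
    if (monoclinic) X <- cbind(X, H[, 1] * H[, 3])
    # robust trim of badly assigned peaks
    w <- as.numeric(asg$dq <= 4 * stats::median(asg$dq) + 1e-12)
    if (sum(w) < ncol(X) + 2) return(NULL)
    fit <- tryCatch(stats::lsfit(X, qobs, wt = w, intercept = FALSE),
                    error = function(e) NULL)
    if (is.null(fit)) return(NULL)
    cf <- fit$coefficients
    if (any(!is.finite(cf)) || any(cf[1:3] <= 0)) return(NULL)
    as_ <- sqrt(cf[1]); bs <- sqrt(cf[2]); cs <- sqrt(cf[3])
    if (monoclinic) {
      cbs <- cf[4] / (2 * as_ * cs)
      if (abs(cbs) >= 0.8) return(NULL)
      sbs <- sqrt(1 - cbs^2)
      p <- c(1 / (as_ * sbs), 1 / bs, 1 / (cs * sbs), rad2deg(acos(-cbs)))
    } else {
      p <- c(1 / as_, 1 / bs, 1 / cs, 90)
    }
    if (any(p[1:3] <= 1.5) || any(p[1:3] > 200)) return(NULL)
  }
  p
}

#' Naive candidate-cell grid search
#'
#' A deliberately simple built-in candidate generator standing in for a full
#' powder-indexing engine (which is external prior art): axis-length
#' hypotheses are taken as small integer multiples of the picked peak d
#' values (sparse still statistics rarely sample the axis fundamentals
#' directly), combined per Bravais class inside a volume window, scored by
#' the mean 1/d^2 mismatch of the observed peaks, locally refined, and the
#' survivors ranked by M*. Hand-supplied candidate cells are first-class:
#' they pass through verbatim and are ranked alongside.
#'
#' @param pattern A [synthesize_powder()] pattern with picked peaks.
#' @param bravais Bravais letter pair searched (`"oP"`, `"mP"`, `"mC"`
#'   supported by the built-in grid).
#' @param volume_range Length-2 admissible volume window (Angstrom^3).
#' @param user_cells Optional list of [unit_cell()] to include verbatim.
#' @param n_keep Number of candidates returned.
#' @param max_axis_multiple Axis hypotheses use d, 2d, ... up to this
#'   multiple of each peak d (default 5).
#' @return List of [unit_cell()] sorted by M* (user cells always included).
#' @export
naive_candidate_grid <- function(pattern, bravais = "oP",
                                 volume_range = c(100, 3000),
                                 user_cells = list(), n_keep = 10,
                                 max_axis_multiple = 5) {
  stopifnot(inherits(pattern, "powder_pattern"))
  sym <- lattice_symmetry(bravais)
  centring <- sym$centring
  monoclinic <- substr(bravais, 1, 1) == "m"
  refined <- list()
  if (!is.null(pattern$peaks) && nrow(pattern$peaks) >= 3) {
    dpk <- sort(unique(pattern$peaks$d), decreasing = TRUE)
    qobs <- 1 / dpk^2
    pool <- sort(as.vector(outer(dpk, seq_len(max_axis_multiple))))
    pool <- pool[pool >= 2.5 & pool <= 3 * max(volume_range)^(1 / 3)]
    # dedupe at 1%: well inside the assignment-LS refinement basin, so no
    # axis hypothesis is lost by thinning
    pool <- pool[c(TRUE, diff(pool) / pool[-length(pool)] > 0.01)]
    cap <- if (monoclinic) 22L else 64L  # monoclinic grid also spans beta
    if (length(pool) > cap) pool <- pool[round(seq(1, length(pool), length.out = cap))]
    betas <- if (monoclinic) seq(90, 115, by = 5) else 90
    grid <- list(); gscore <- numeric(0)
    for (a in pool) for (b in pool) for (cc in pool) {
      if (!monoclinic && (a > b || b > cc)) next   # canonical a <= b <= c
      if (monoclinic && a > cc) next               # beta pairs a with c
      for (be in betas) {
        v <- a * b * cc * sin(deg2rad(be))
        if (v < volume_range[1] || v > volume_range[2]) next
        grid[[length(grid) + 1L]] <- c(a, b, cc, be)
        gscore[length(grid)] <- peak_q_mismatch(a, b, cc, be, qobs, centring)
      }
    }
    if (length(grid)) {
      # the raw grid merit has a basin narrower than the grid spacing, so a
      # generous shortlist is refined by assignment least squares before the
      # expensive ranking
      short <- grid[order(gscore)[seq_len(min(400, length(grid)))]]
      refined <- list()
      for (p0 in short) {
        p <- assign_ls_refine(p0, qobs, centring, monoclinic)
        if (is.null(p)) next
        v <- p[1] * p[2] * p[3] * sin(deg2rad(p[4]))
        if (v < volume_range[1] * 0.8 || v > volume_range[2] * 1.2) next
        if (!monoclinic) p[1:3] <- sort(p[1:3])
        refined[[length(refined) + 1L]] <- unit_cell(p[1], p[2], p[3], 90, p[4], 90)
      }
      # dedupe refined cells (0.5% on every parameter)
      if (length(refined)) {
        keys <- vapply(refined, function(cl)
          paste(round(as.numeric.unit_cell(cl) / 0.005), collapse = ","), character(1))
        refined <- refined[!duplicated(keys)]
        sc <- vapply(refined, function(cl)
          peak_q_mismatch(cl$a, cl$b, cl$c, cl$beta, qobs, centring), numeric(1))
        refined <- refined[order(sc)[seq_len(min(25, length(refined)))]]
      }
    }
  }
  all_cells <- c(user_cells, refined)
  if (!length(all_cells)) return(list())
  sc <- vapply(all_cells, function(cl) tryCatch(
    compute_mstar(pattern, cl, sym), error = function(e) Inf), numeric(1))
  keep <- order(sc)[seq_len(min(n_keep, length(all_cells)))]
  keep <- sort(unique(c(seq_along(user_cells), keep)))  # user cells always pass
  all_cells[keep][order(sc[keep])]
}

#' Score candidate cells by indexing rate (and M20 / M*)
#'
#' Runs the sparse-frame indexer over all hit frames for each candidate and
#' tabulates the fraction indexed, together with the powder figures of merit
#' when a pattern is supplied. Candidates are ranked by indexing rate,
#' descending, ties broken by lower M*. The correct cell is expected to
#' combine the highest indexing rate with a low M*. Indexer failures on
#' individual frames count as non-indexed and are never fatal.
#'
#' @param frames An `sfx_frames` object.
#' @param candidates List of [unit_cell()], or list of lists with fields
#'   `cell` and `symmetry`.
#' @param symmetry Default [lattice_symmetry()] for bare cells.
#' @param pattern Optional [synthesize_powder()] pattern with picked peaks for
#'   M20 / M*.
#' @param params Indexer parameters, see [indexer_params()].
#' @return Data frame of class `candidate_scores` with one row per
#'   candidate: cell parameters, `m20`, `m_star`, `indexing_rate`,
#'   `n_indexed`, `n_hits`, sorted by rate.
#' @export
evaluate_candidates <- function(frames, candidates, symmetry = NULL,
                                pattern = NULL, params = indexer_params()) {
  rows <- lapply(seq_along(candidates), function(i) {
    cand <- candidates[[i]]
    if (is_unit_cell(cand)) cand <- list(cell = cand, symmetry = symmetry)
    if (is.null(cand$symmetry)) stop("no symmetry given for candidate ", i)
    res <- index_dataset(frames, cand$cell, cand$symmetry, params = params)
    m20 <- m_star <- NA_real_
    if (!is.null(pattern)) {
      m20 <- tryCatch(suppressWarnings(compute_m20(pattern$peaks$d, cand$cell, cand$symmetry)),
                      error = function(e) NA_real_)
      m_star <- tryCatch(compute_mstar(pattern, cand$cell, cand$symmetry, m20 = m20),
                         error = function(e) NA_real_)
    }
    data.frame(candidate = i,
               a = cand$cell$a, b = cand$cell$b, c = cand$cell$c,
               alpha = cand$cell$alpha, beta = cand$cell$beta, gamma = cand$cell$gamma,
               bravais = cand$symmetry$bravais,
               m20 = m20, m_star = m_star,
               indexing_rate = res$rate, n_indexed = res$n_indexed,
               n_hits = res$n_hits)
  })
  out <- do.call(rbind, rows)
  ord <- order(-out$indexing_rate, ifelse(is.na(out$m_star), Inf, out$m_star))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_scores", "data.frame")
  out
}

#' @export
plot.candidate_scores <- function(x, ...) {
  graphics::plot(x$m_star, x$indexing_rate, xlab = "M*",
                 ylab = "indexing rate", pch = 19, ...)
  graphics::text(x$m_star, x$indexing_rate, labels = x$candidate, pos = 3, cex = 0.8)
  invisible(x)
}
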
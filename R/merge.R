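#' Build an observation table from indexing results
#'
#' One row per assigned spot: frame id, the raw (as-indexed) Miller indices,
#' their canonical asymmetric-unit representative, and the spot intensity
#' with its estimated sigma.
#'
#' @param results An `indexing_results` object (from [index_dataset()]).
#' @param frames The `sfx_frames` object that was indexed.
#' @param symmetry A [lattice_symmetry()] used for the reduction.
#' @return Data frame of class `observation_table` with columns `frame_id`,
#'   `h`, `k`, `l` (asymmetric unit), `rh`, `rk`, `rl` (raw), `intensity`,
#'   `sigma`. The symmetry is attached as an attribute.
#' @export
observations <- function(results, frames, symmetry) {
  rows <- lapply(results$solutions, function(sol) {
    sp <- frames$frames[[sol$frame_id]]$spots
    a <- sol$assignments
    data.frame(frame_id = sol$frame_id, rh = a$h, rk = a$k, rl = a$l,
               intensity = sp$intensity[a$spot], sigma = sp$sigma[a$spot])
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(frame_id = integer(0), rh = integer(0), rk = integer(0),
                      rl = integer(0), intensity = numeric(0), sigma = numeric(0))
  finalize_obs(out, symmetry)
}

#' Build an observation table from simulator ground truth
#'
#' Same layout as [observations()] but using the simulator's truth hkl
#' labels instead of an indexing run; the clean input for merging tests.
#'
#' @param frames A simulated `sfx_frames` object (truth blocks present).
#' @param symmetry A [lattice_symmetry()].
#' @return An `observation_table`.
#' @export
observations_from_truth <- function(frames, symmetry) {
  rows <- lapply(frames$frames, function(fr) {
    if (is.null(fr$truth) || !nrow(fr$spots)) return(NULL)
    data.frame(frame_id = fr$frame_id,
               rh = fr$truth$hkl[, 1], rk = fr$truth$hkl[, 2],
               rl = fr$truth$hkl[, 3],
               intensity = fr$spots$intensity, sigma = fr$spots$sigma)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no truth-labelled spots in these frames")
  finalize_obs(out, symmetry)
}

finalize_obs <- function(df, symmetry) {
  if (nrow(df)) {
    asu <- reduce_to_asu(as.matrix(df[, c("rh", "rk", "rl")]), symmetry)
    df$h <- asu[, 1]; df$k <- asu[, 2]; df$l <- asu[, 3]
  } else {
    df$h <- integer(0); df$k <- integer(0); df$l <- integer(0)
  }
  df <- df[, c("frame_id", "h", "k", "l", "rh", "rk", "rl", "intensity", "sigma")]
  rownames(df) <- NULL
  attr(df, "symmetry") <- symmetry
  class(df) <- c("observation_table", "data.frame")
  df
}

hkl_key <- function(h, k, l) paste(h, k, l, sep = ",")

#' Merge symmetry-equivalent observations by simple averaging
#'
#' Unweighted mean intensity per unique (asymmetric-unit) hkl; the
#' uncertainty is the standard error of the mean of the contributing
#' observations. Reflections measured only once have no defined SEM and get
#' a sentinel sigma of `single_sigma_fraction * |I|`, flagged in the
#' `single` column.
#'
#' @param obs An `observation_table`.
#' @param single_sigma_fraction Sentinel sigma fraction for n = 1 (default 0.5).
#' @return Data frame of class `merged_set`: `h`, `k`, `l`, `I`, `sigma`,
#'   `n` (multiplicity), `single`; symmetry attached as attribute.
#' @export
merge_simple <- function(obs, single_sigma_fraction = 0.5) {
  if (!nrow(obs)) stop("empty observation table")
  key <- hkl_key(obs$h, obs$k, obs$l)
  grp <- split(obs$intensity, key)
  keys <- names(grp)
  n <- lengths(grp)
  I <- vapply(grp, mean, numeric(1))
  sds <- vapply(grp, function(x) if (length(x) >= 2) stats::sd(x) else NA_real_, numeric(1))
  sigma <- ifelse(n >= 2, sds / sqrt(n), single_sigma_fraction * abs(I))
  hkl <- do.call(rbind, strsplit(keys, ","))
  out <- data.frame(h = as.integer(hkl[, 1]), k = as.integer(hkl[, 2]),
                    l = as.integer(hkl[, 3]), I = unname(I),
                    sigma = unname(sigma), n = unname(as.integer(n)),
                    single = unname(n == 1))
  out <- out[order(out$h, out$k, out$l), ]
  rownames(out) <- NULL
  attr(out, "symmetry") <- attr(obs, "symmetry")
  class(out) <- c("merged_set", "data.frame")
  out
}

#' @export
print.merged_set <- function(x, ...) {
  cat(sprintf("merged set: %d unique reflections, mean multiplicity %.1f, %d singletons\n",
              nrow(x), mean(x$n), sum(x$single)))
  invisible(x)
}

#' Two-step merging: scale each frame to a reference, then re-merge
#'
#' For each frame a single multiplicative scale
#' k = sum(I_obs * I_ref) / sum(I_ref^2) is fit over the reflections the
#' frame shares with the reference set (least-squares through the origin);
#' observations are divided by k and re-merged by [merge_simple()]. Frames
#' sharing fewer than `min_common` reflections with the reference, or with a
#' non-positive fitted scale, are dropped and reported.
#'
#' @param obs An `observation_table`.
#' @param reference A `merged_set` (typically the first-pass simple merge, a
#'   later iteration, or model-derived intensities).
#' @param min_common Minimum common reflections per frame (default 3).
#' @param single_sigma_fraction Passed to [merge_simple()].
#' @return List with `merged` (the re-merged `merged_set`), `frame_scales`
#'   (data frame `frame_id`, `scale`, `n_common`, `dropped`).
#' @export
scale_and_remerge <- function(obs, reference, min_common = 3,
                              single_sigma_fraction = 0.5) {
  if (!nrow(obs)) stop("empty observation table")
  refkey <- hkl_key(reference$h, reference$k, reference$l)
  obskey <- hkl_key(obs$h, obs$k, obs$l)
  iref <- reference$I[match(obskey, refkey)]
  fids <- unique(obs$frame_id)
  scales <- data.frame(frame_id = fids, scale = NA_real_,
                       n_common = 0L, dropped = FALSE)
  keep_rows <- rep(FALSE, nrow(obs))
  scaled <- obs$intensity
  for (i in seq_along(fids)) {
    rows <- which(obs$frame_id == fids[i])
    common <- rows[!is.na(iref[rows])]
    denom <- sum(iref[common]^2)
    scales$n_common[i] <- length(common)
    if (length(common) < min_common || denom <= 0) {
      scales$dropped[i] <- TRUE
      next
    }
    k <- sum(obs$intensity[common] * iref[common]) / denom
    if (!is.finite(k) || k <= 0) { scales$dropped[i] <- TRUE; next }
    scales$scale[i] <- k
    scaled[rows] <- obs$intensity[rows] / k
    keep_rows[rows] <- TRUE
  }
  if (!any(keep_rows)) stop("all frames dropped: reference overlap too small")
  obs2 <- obs[keep_rows, , drop = FALSE]
  obs2$intensity <- scaled[keep_rows]
  obs2 <- finalize_obs(as.data.frame(obs2)[, c("frame_id", "rh", "rk", "rl",
                                               "intensity", "sigma")],
                       attr(obs, "symmetry"))
  list(merged = merge_simple(obs2, single_sigma_fraction),
       frame_scales = scales)
}

#' Resolution cutoff targeting outer-shell multiplicity
#'
#' Splits the merged set into equal-volume resolution shells (uniform in
#' 1/d^3) and returns the most generous (smallest) d_min whose outer shell
#' has mean multiplicity inside `target` (default 10-15). If no shell
#' qualifies, the nearest achievable cutoff is returned with a warning.
#'
#' @param merged A `merged_set`.
#' @param cell The [unit_cell()] (needed to compute d per reflection).
#' @param shells Number of shells (default 10).
#' @param target Length-2 admissible band of outer-shell mean multiplicity.
#' @return List with `d_min`, `achieved` (outer-shell mean multiplicity at
#'   the cutoff), `in_target`, and the per-shell `table` (`d_lo`, `d_hi`,
#'   `n_refl`, `mean_multiplicity`).
#' @export
resolution_cutoff <- function(merged, cell, shells = 10, target = c(10, 15)) {
  if (!nrow(merged)) stop("empty merged set")
  d <- d_spacing(cell, as.matrix(merged[, c("h", "k", "l")]))
  q3 <- 1 / d^3
  edges <- seq(min(q3), max(q3), length.out = shells + 1)
  edges[shells + 1] <- edges[shells + 1] * (1 + 1e-12)
  shell_of <- findInterval(q3, edges, rightmost.closed = TRUE, all.inside = TRUE)
  tab <- data.frame(shell = seq_len(shells),
                    d_hi = 1 / edges[-(shells + 1)]^(1 / 3),
                    d_lo = 1 / edges[-1]^(1 / 3),
                    n_refl = as.integer(tabulate(shell_of, shells)),
                    mean_multiplicity = vapply(seq_len(shells), function(s) {
                      m <- merged$n[shell_of == s]
                      if (length(m)) mean(m) else NA_real_
                    }, numeric(1)))
  ok <- which(!is.na(tab$mean_multiplicity) &
                tab$mean_multiplicity >= target[1] &
                tab$mean_multiplicity <= target[2])
  if (length(ok)) {
    pick <- max(ok)  # deepest shell inside the band: most generous cutoff
    in_target <- TRUE
  } else {
    dev <- pmin(abs(tab$mean_multiplicity - target[1]),
                abs(tab$mean_multiplicity - target[2]))
    pick <- which.min(dev)
    in_target <- FALSE
    warning(sprintf("no shell reaches %g-%g multiplicity; nearest is shell %d (%.1f)",
                    target[1], target[2], pick, tab$mean_multiplicity[pick]))
  }
  list(d_min = tab$d_lo[pick], achieved = tab$mean_multiplicity[pick],
       in_target = in_target, table = tab)
}

#' Resolve a pseudo-merohedral indexing ambiguity against a reference
#'
#' When the lattice metric is nearly compatible with a higher symmetry,
#' frames index in inequivalent but metrically similar settings related by
#' reindexing operators; merged naively this simulates twinning. For each
#' frame, the agreement between its intensities and the reference is scored
#' under every operator's hkl remapping — the (negative) dispersion of log
#' intensity ratios, a scale-invariant measure that stays informative for
#' the two-or-three-reflection frames sparse stills produce — and the best
#' operator is applied (ties resolve to the identity, which is always
#' evaluated first). Frames with fewer than 2 reference-common reflections
#' under every operator are left unchanged and flagged.
#'
#' @param obs An `observation_table`.
#' @param ops List of [reindex_op()] (the identity is prepended if absent).
#' @param reference A `merged_set` or any data frame with `h`, `k`, `l`, `I`.
#' @return List with `obs` (corrected table), `frame_ops` (data frame
#'   `frame_id`, `op`, `score`; op 1 is the identity), `flagged` (frame ids
#'   left unresolved).
#' @export
resolve_indexing_ambiguity <- function(obs, ops, reference) {
  if (!nrow(reference)) stop("empty reference")
  symmetry <- attr(obs, "symmetry")
  idkey <- op_key(diag(3))
  ops <- lapply(ops, unclass)
  if (!any(vapply(ops, function(m) op_key(m) == idkey, logical(1))))
    ops <- c(list(diag(3)), ops)
  else
    ops <- c(ops[vapply(ops, function(m) op_key(m) == idkey, logical(1))],
             ops[!vapply(ops, function(m) op_key(m) == idkey, logical(1))])
  refkey <- hkl_key(reference$h, reference$k, reference$l)
  fids <- unique(obs$frame_id)
  raw <- as.matrix(obs[, c("rh", "rk", "rl")])
  # precompute remapped asu keys per operator
  keymaps <- lapply(ops, function(M) {
    rem <- raw %*% t(M)
    asu <- reduce_to_asu(rem, symmetry)
    hkl_key(asu[, 1], asu[, 2], asu[, 3])
  })
  choice <- integer(length(fids)); corr <- rep(NA_real_, length(fids))
  flagged <- integer(0)
  for (i in seq_along(fids)) {
    rows <- which(obs$frame_id == fids[i])
    best_op <- 1L; best_cor <- -Inf; any_eval <- FALSE
    for (j in seq_along(ops)) {
      iref <- reference$I[match(keymaps[[j]][rows], refkey)]
      com <- !is.na(iref)
      if (sum(com) < 2) next
      # agreement score: negative dispersion of log(I / I_ref). Under the
      # correct setting the ratio is the frame scale times a bounded
      # partiality; under a wrong setting it inherits the full dynamic range
      # of the intensities. Unlike Pearson correlation this stays
      # informative for the 2-3 reflection frames sparse stills produce.
      flo <- 1e-6 * max(reference$I, na.rm = TRUE)
      lr <- log(pmax(obs$intensity[rows][com], flo)) - log(pmax(iref[com], flo))
      cc <- -stats::sd(lr)
      if (!is.finite(cc)) next
      any_eval <- TRUE
      if (cc > best_cor + 1e-12) { best_cor <- cc; best_op <- j }
    }
    if (!any_eval) {
      flagged <- c(flagged, fids[i])
      choice[i] <- 1L
    } else {
      choice[i] <- best_op; corr[i] <- best_cor
    }
  }
  # apply chosen operators
  newraw <- raw
  for (j in seq_along(ops)) {
    if (j == 1 && op_key(ops[[1]]) == idkey) next
    rows <- which(obs$frame_id %in% fids[choice == j])
    if (length(rows)) newraw[rows, ] <- raw[rows, , drop = FALSE] %*% t(ops[[j]])
  }
  df <- data.frame(frame_id = obs$frame_id, rh = newraw[, 1], rk = newraw[, 2],
                   rl = newraw[, 3], intensity = obs$intensity, sigma = obs$sigma)
  list(obs = finalize_obs(df, symmetry),
       frame_ops = data.frame(frame_id = fids, op = choice, score = corr),
       flagged = flagged)
}

#' Centring-violation classifier
#'
#' Builds a classifier for [absence_statistics()] labelling each reflection
#' `"allowed"` or `"forbidden"` under a lattice-centring rule.
#'
#' @param centring Centring letter (`"A","B","C","F","I","R"`).
#' @return Function mapping an n x 3 hkl matrix to labels.
#' @export
centring_classifier <- function(centring) {
  force(centring)
  function(hkl) factor(ifelse(centring_allowed(hkl, centring),
                              "allowed", "forbidden"),
                       levels = c("allowed", "forbidden"))
}

#' c-glide classifier (h0l: l odd forbidden)
#'
#' Labels h0l reflections `"h0l_even"` / `"h0l_odd"` (the class a c glide
#' perpendicular to b extinguishes) and everything else `"other"`.
#'
#' @return Classifier function for [absence_statistics()].
#' @export
c_glide_classifier <- function() {
  function(hkl) {
    H <- as_hkl_matrix(hkl)
    out <- rep("other", nrow(H))
    h0l <- H[, 2] == 0
    out[h0l & H[, 3] %% 2 == 0] <- "h0l_even"
    out[h0l & H[, 3] %% 2 != 0] <- "h0l_odd"
    factor(out, levels = c("h0l_even", "h0l_odd", "other"))
  }
}

#' Systematic-absence statistics
#'
#' Splits reflections into classes by a predicate on hkl (e.g. centring
#' allowed vs forbidden, or glide-extinguished classes) and reports count
#' and mean I/sigma per class. A class is judged absent when it has no
#' observations or its mean I/sigma falls below `threshold`.
#'
#' @param x An `observation_table` (raw hkl are used) or a `merged_set`.
#' @param classifier Function mapping an n x 3 hkl matrix to class labels,
#'   e.g. [centring_classifier()].
#' @param threshold Mean-I/sigma level below which a class is called absent.
#' @return Data frame with `class`, `count`, `mean_i_over_sigma`, `absent`.
#' @export
absence_statistics <- function(x, classifier, threshold = 2) {
  if (inherits(x, "observation_table")) {
    H <- as.matrix(x[, c("rh", "rk", "rl")])
    I <- x$intensity; s <- x$sigma
  } else {
    H <- as.matrix(x[, c("h", "k", "l")])
    I <- x$I; s <- x$sigma
  }
  labels <- classifier(H)
  # factor classifiers declare their full class set, so empty classes are
  # reported with count 0
  all_classes <- if (is.factor(labels)) levels(labels) else sort(unique(labels))
  labels <- as.character(labels)
  isig <- I / s
  out <- data.frame(class = all_classes,
                    count = as.integer(table(factor(labels, all_classes))),
                    mean_i_over_sigma = vapply(all_classes, function(cl) {
                      v <- isig[labels == cl]
                      if (length(v)) mean(v) else NA_real_
                    }, numeric(1)))
  out$absent <- out$count == 0 |
    (!is.na(out$mean_i_over_sigma) & out$mean_i_over_sigma < threshold)
  rownames(out) <- NULL
  out
}
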
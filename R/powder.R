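#' Harvest d spacings from spot observations
#'
#' Converts every spot centroid to a d spacing using its own shot's measured
#' wavelength — the step that removes shot-to-shot energy jitter and makes
#' the aggregated histogram sharp. Spots at (or numerically at) the beam
#' centre have undefined scattering angle and are skipped.
#'
#' @param frames An `sfx_frames` object (simulated or read from disk).
#' @param weight `"count"` (default) for unit weights or `"intensity"`.
#' @return Data frame with columns `d` (Angstrom) and `weight`; skipped
#'   spots are counted in `attr(, "n_skipped")`.
#' @export
harvest_d_spacings <- function(frames, weight = c("count", "intensity")) {
  weight <- match.arg(weight)
  det_ <- frames$detector
  ds <- list(); ws <- list(); skipped <- 0L
  for (fr in frames$frames) {
    sp <- fr$spots
    if (!nrow(sp)) next
    s <- centroid_to_s(det_, fr$wavelength, sp$fast, sp$slow)
    q <- sqrt(rowSums(s^2))
    ok <- q > 1e-9
    skipped <- skipped + sum(!ok)
    if (!any(ok)) next
    ds[[length(ds) + 1L]] <- 1 / q[ok]
    ws[[length(ws) + 1L]] <- if (weight == "count") rep(1, sum(ok)) else sp$intensity[ok]
  }
  out <- data.frame(d = unlist(ds), weight = unlist(ws))
  if (!nrow(out)) out <- data.frame(d = numeric(0), weight = numeric(0))
  attr(out, "n_skipped") <- skipped
  out
}

#' Synthesize a sharpened virtual powder pattern
#'
#' Bins harvested d spacings into a histogram over q = 1/d. Because each
#' spot was measured at sub-pixel precision and converted with its own shot
#' wavelength, the histogram is much sharper than a conventional radial
#' average: it amounts to a high-resolution powder diffractogram built from
#' thousands of still shots.
#'
#' @param d_list Data frame from [harvest_d_spacings()] (columns `d`,
#'   `weight`), or a bare numeric vector of d values.
#' @param n_bins Number of uniform q bins (default 2000).
#' @param d_range Optional length-2 d range (Angstrom) to histogram.
#' @return Object of class `powder_pattern`: list with `edges` (q bin
#'   edges), `counts`, `d_min`, `d_max` and (after [pick_peaks()]) `peaks`.
#' @export
synthesize_powder <- function(d_list, n_bins = 2000, d_range = NULL) {
  if (is.numeric(d_list)) d_list <- data.frame(d = d_list, weight = rep(1, length(d_list)))
  empty <- nrow(d_list) == 0
  if (empty) {
    pat <- structure(list(edges = numeric(0), counts = numeric(0),
                          d_min = NA_real_, d_max = NA_real_,
                          peaks = data.frame(d = numeric(0), height = numeric(0)),
                          empty = TRUE),
                     class = "powder_pattern")
    warning("empty d list: returning an empty powder pattern")
    return(pat)
  }
  q <- 1 / d_list$d
  if (is.null(d_range)) {
    qlim <- range(q)
    if (qlim[1] == qlim[2]) qlim <- qlim + c(-0.5, 0.5) / stats::median(d_list$d) * 0.01
  } else {
    qlim <- sort(1 / d_range)
    inside <- q >= qlim[1] & q <= qlim[2]
    q <- q[inside]; d_list <- d_list[inside, , drop = FALSE]
  }
  edges <- seq(qlim[1], qlim[2], length.out = n_bins + 1)
  idx <- findInterval(q, edges, rightmost.closed = TRUE, all.inside = TRUE)
  counts <- vapply(seq_len(n_bins), function(i) sum(d_list$weight[idx == i]), numeric(1))
  structure(list(edges = edges, counts = counts,
                 d_min = 1 / qlim[2], d_max = 1 / qlim[1],
                 peaks = NULL, empty = FALSE),
            class = "powder_pattern")
}

#' @export
print.powder_pattern <- function(x, ...) {
  if (isTRUE(x$empty)) { cat("powder pattern: empty\n"); return(invisible(x)) }
  cat(sprintf("powder pattern: %d bins over d = %.3f..%.3f A, total mass %g\n",
              length(x$counts), x$d_min, x$d_max, sum(x$counts)))
  if (!is.null(x$peaks) && nrow(x$peaks))
    cat(sprintf("  %d picked peaks, strongest at d = %.4f A\n",
                nrow(x$peaks), x$peaks$d[which.max(x$peaks$height)]))
  invisible(x)
}

#' @export
plot.powder_pattern <- function(x, ...) {
  if (isTRUE(x$empty)) stop("cannot plot an empty pattern")
  mid <- (x$edges[-1] + x$edges[-length(x$edges)]) / 2
  graphics::plot(mid, x$counts, type = "h", xlab = "q = 1/d (1/A)",
                 ylab = "counts", ...)
  if (!is.null(x$peaks) && nrow(x$peaks))
    graphics::points(1 / x$peaks$d, x$peaks$height, pch = 4, col = 2)
  invisible(x)
}

bin_midpoints <- function(pattern) {
  (pattern$edges[-1] + pattern$edges[-length(pattern$edges)]) / 2
}

#' Pick peaks from a powder pattern
#'
#' Local maxima above a noise floor (default 5x the median non-zero bin
#' count), refined to sub-bin precision by a parabolic fit through the
#' maximum and its neighbours, ranked by height; the top `n_peaks` are
#' returned sorted by d descending. Automates the hand-selection of strong
#' peaks used for powder indexing.
#'
#' @param pattern A [synthesize_powder()] pattern.
#' @param n_peaks Number of peaks wanted (default 20).
#' @param floor_factor Noise-floor multiplier on the median bin count.
#' @return The pattern with a `peaks` data frame (`d`, `height`) attached.
#' @export
pick_peaks <- function(pattern, n_peaks = 20, floor_factor = 5) {
  stopifnot(inherits(pattern, "powder_pattern"))
  if (isTRUE(pattern$empty)) stop("cannot pick peaks from an empty pattern")
  y <- pattern$counts
  mid <- bin_midpoints(pattern)
  floor_ <- floor_factor * stats::median(y)
  n <- length(y)
  is_max <- y > pmax(c(-Inf, y[-n]), c(y[-1], -Inf)) & y > floor_
  # strict on one side, allow plateau ties on the other
  idx <- which(is_max)
  if (!length(idx)) {
    pattern$peaks <- data.frame(d = numeric(0), height = numeric(0))
    return(pattern)
  }
  qpk <- numeric(length(idx)); hpk <- numeric(length(idx))
  dq <- mid[2] - mid[1]
  for (j in seq_along(idx)) {
    i <- idx[j]
    if (i > 1 && i < n) {
      y0 <- y[i - 1]; y1 <- y[i]; y2 <- y[i + 1]
      den <- (y0 - 2 * y1 + y2)
      delta <- if (den != 0) 0.5 * (y0 - y2) / den else 0
      delta <- max(-0.5, min(0.5, delta))
      qpk[j] <- mid[i] + delta * dq
      hpk[j] <- y1 - 0.25 * (y0 - y2) * delta
    } else {
      qpk[j] <- mid[i]; hpk[j] <- y[i]
    }
  }
  ord <- order(hpk, decreasing = TRUE)
  if (length(ord) < n_peaks)
    warning(sprintf("only %d peaks above the noise floor (asked for %d)",
                    length(ord), n_peaks))
  take <- ord[seq_len(min(n_peaks, length(ord)))]
  pk <- data.frame(d = 1 / qpk[take], height = hpk[take])
  pk <- pk[order(pk$d, decreasing = TRUE), ]
  rownames(pk) <- NULL
  pattern$peaks <- pk
  pattern
}

#' Rescale a powder pattern to the Cu K-alpha 2-theta axis
#'
#' Transforms the q axis to the diffraction angle a laboratory Cu K-alpha
#' source (lambda = 1.5406 A) would measure, via Bragg's law, for direct
#' overlay with laboratory PXRD. Bins beyond the Cu K-alpha Ewald sphere
#' (d < lambda/2) are dropped with a warning.
#'
#' @param pattern A [synthesize_powder()] pattern.
#' @return Data frame with columns `two_theta` (degrees, ascending) and
#'   `counts`.
#' @export
export_cuka_scale <- function(pattern) {
  stopifnot(inherits(pattern, "powder_pattern"))
  if (isTRUE(pattern$empty)) stop("empty pattern")
  lam <- 1.5406
  mid <- bin_midpoints(pattern)
  d <- 1 / mid
  ok <- d >= lam / 2
  if (any(!ok)) warning(sprintf("%d bins beyond the Cu K-alpha sphere dropped", sum(!ok)))
  tth <- d_to_two_theta(d[ok], lam)
  out <- data.frame(two_theta = tth, counts = pattern$counts[ok])
  out[order(out$two_theta), , drop = FALSE]
}
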
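#' Beam model
#'
#' @param nominal_energy Nominal photon energy in keV.
#' @param bandwidth Fractional within-shot bandwidth Delta-E/E (top-hat),
#'   default 0.003 (the ~0.3% natural XFEL SASE bandwidth).
#' @param shot_jitter Fractional sigma of the shot-to-shot central energy
#'   (Gaussian); the per-shot central energy is recorded as "measured".
#' @return Object of class `beam_model`.
#' @export
beam_model <- function(nominal_energy = 12.012, bandwidth = 0.003, shot_jitter = 0.001) {
  if (nominal_energy <= 0) stop("nominal_energy must be positive")
  if (bandwidth < 0 || shot_jitter < 0) stop("bandwidth and shot_jitter must be >= 0")
  structure(list(nominal_energy = nominal_energy, bandwidth = bandwidth,
                 shot_jitter = shot_jitter), class = "beam_model")
}

#' Detector model
#'
#' A single flat panel normal to the beam. The lab frame is right-handed
#' with the beam along +z; pixel coordinates are 0-based (fast, slow) with
#' fast along lab +x and slow along lab +y.
#'
#' @param distance Sample-to-detector distance in mm.
#' @param beam_centre Numeric length 2, (fast, slow) beam centre in pixels.
#' @param pixel_size Pixel edge in mm.
#' @param n_fast,n_slow Panel dimensions in pixels.
#' @return Object of class `detector_model`.
#' @export
detector_model <- function(distance = 60, beam_centre = c(1500, 1500),
                           pixel_size = 0.075, n_fast = 3000, n_slow = 3000) {
  if (distance <= 0) stop("distance must be positive")
  if (pixel_size <= 0) stop("pixel_size must be positive")
  if (beam_centre[1] < 0 || beam_centre[1] >= n_fast ||
      beam_centre[2] < 0 || beam_centre[2] >= n_slow)
    stop("beam centre must lie on the panel")
  structure(list(distance = distance, beam_centre = beam_centre,
                 pixel_size = pixel_size, n_fast = n_fast, n_slow = n_slow),
            class = "detector_model")
}

#' Simulation configuration
#'
#' Conditions of the serial still-shot experiment the simulator emulates:
#' one randomly oriented microcrystal per hit frame, a narrow-band beam with
#' per-shot energy jitter, sparse patterns (a handful of reflections per
#' hit), per-frame scale variation, and blank (non-hit) frames.
#'
#' @param cell Generating [unit_cell()].
#' @param symmetry [lattice_symmetry()] (centring restricts emitted hkl).
#' @param beam A [beam_model()].
#' @param detector A [detector_model()].
#' @param mosaicity Mosaic half-width in degrees (default 0.3).
#' @param d_min Resolution limit in Angstrom for emitted reflections.
#' @param hit_fraction Fraction of frames containing a crystal.
#' @param frame_scale_dispersion Lognormal sigma of the per-frame scale.
#' @param centroid_noise Gaussian sigma of centroid error, pixels.
#' @param intensity_noise Lognormal sigma of multiplicative intensity noise.
#' @param structure A [toy_structure()] supplying ground-truth |F|^2.
#' @param seed Integer seed; fixes the entire simulated stream.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(cell,
                       symmetry,
                       beam = beam_model(),
                       detector = detector_model(),
                       mosaicity = 0.3,
                       d_min = 1.2,
                       hit_fraction = 0.9,
                       frame_scale_dispersion = 0.3,
                       centroid_noise = 0.1,
                       intensity_noise = 0.1,
                       structure = default_toy_structure(),
                       seed = 1L) {
  stopifnot(is_unit_cell(cell), inherits(symmetry, "lattice_symmetry"),
            inherits(beam, "beam_model"), inherits(detector, "detector_model"))
  if (d_min <= 0) stop("d_min must be positive")
  if (hit_fraction < 0 || hit_fraction > 1) stop("hit_fraction must be in [0,1]")
  if (mosaicity < 0 || centroid_noise < 0 || intensity_noise < 0 ||
      frame_scale_dispersion < 0) stop("noise parameters must be >= 0")
  structure(list(cell = cell, symmetry = symmetry, beam = beam,
                 detector = detector, mosaicity = mosaicity, d_min = d_min,
                 hit_fraction = hit_fraction,
                 frame_scale_dispersion = frame_scale_dispersion,
                 centroid_noise = centroid_noise,
                 intensity_noise = intensity_noise,
                 structure = structure, seed = as.integer(seed)),
            class = "sim_config")
}

#' Enumerate centring-allowed reflections to a resolution limit
#'
#' All integer hkl (excluding (0,0,0), full sphere, not reduced to the
#' asymmetric unit) allowed by the lattice centring with d >= d_min.
#'
#' @param cell A [unit_cell()].
#' @param symmetry A [lattice_symmetry()] (or centring letter).
#' @param d_min Resolution limit in Angstrom.
#' @return Data frame with columns h, k, l, d.
#' @export
reflection_list <- function(cell, symmetry, d_min) {
  if (d_min <= 0) stop("d_min must be positive")
  # safe index bounds from the direct axis lengths
  hmax <- ceiling(cell$a / d_min) + 1L
  kmax <- ceiling(cell$b / d_min) + 1L
  lmax <- ceiling(cell$c / d_min) + 1L
  H <- as.matrix(expand.grid(h = -hmax:hmax, k = -kmax:kmax, l = -lmax:lmax))
  H <- H[rowSums(H != 0) > 0, , drop = FALSE]
  H <- H[centring_allowed(H, symmetry), , drop = FALSE]
  d <- d_spacing(cell, H)
  keep <- d >= d_min
  data.frame(h = H[keep, 1], k = H[keep, 2], l = H[keep, 3], d = d[keep])
}

# Uniform random rotation matrices via normalized quaternions.
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# Lab-frame scattering vectors from pixel centroids at a given wavelength.
# Beam along +z; s = w*(u - z_hat) with u the unit diffracted-ray direction
# and w = 1/lambda. Returns an n x 3 matrix (Angstrom^-1).
centroid_to_s <- function(detector, wavelength, fast, slow) {
  X <- (fast - detector$beam_centre[1]) * detector$pixel_size
  Y <- (slow - detector$beam_centre[2]) * detector$pixel_size
  D <- detector$distance
  nrm <- sqrt(X^2 + Y^2 + D^2)
  w <- 1 / wavelength
  cbind(w * X / nrm, w * Y / nrm, w * (D / nrm - 1))
}

#' Simulate a serial still-diffraction dataset
#'
#' For each hit frame a random orientation is drawn; a reflection is emitted
#' when its Ewald-offset (the fractional difference between the wavenumber
#' that would satisfy Bragg's condition exactly and the shot's central
#' wavenumber) is within the half-width set by the bandwidth plus a
#' mosaicity term, when d >= d_min, and when the diffracted ray lands on the
#' panel. The reciprocal point is projected onto the Ewald sphere of the
#' nearest in-band wavelength before the detector projection, so stills are
#' geometrically exact. Recorded intensity is frame scale x partiality x
#' |F|^2 x multiplicative noise; partiality is Gaussian in the Ewald offset
#' and equals 1 exactly on the sphere. A fraction (1 - hit_fraction) of
#' frames is blank. The same seed reproduces the stream bit for bit.
#'
#' @param config A [sim_config()].
#' @param n_frames Number of frames to simulate.
#' @return Object of class `sfx_frames`: list with `frames` (each a list
#'   with `frame_id`, `wavelength`, `spots` data frame and a `truth` block
#'   carrying the orientation matrix A, per-spot hkl and the frame scale),
#'   plus the `detector`, `beam` and `config` used.
#' @export
simulate_dataset <- function(config, n_frames) {
  stopifnot(inherits(config, "sim_config"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  det_ <- config$detector; beam <- config$beam
  B <- b_matrix(config$cell)
  refl <- reflection_list(config$cell, config$symmetry, config$d_min)
  Hall <- as.matrix(refl[, c("h", "k", "l")])
  F2 <- toy_structure_factor(config$structure, Hall, config$cell)
  Xcrys <- Hall %*% t(B)                      # crystal-frame reciprocal vectors
  lambda0 <- energy_to_wavelength(beam$nominal_energy)
  mos_rad <- deg2rad(config$mosaicity)

  # warn (once, in metadata) if d_min is beyond the detector edge
  edge_mm <- min(det_$beam_centre[1], det_$n_fast - 1 - det_$beam_centre[1],
                 det_$beam_centre[2], det_$n_slow - 1 - det_$beam_centre[2]) *
    det_$pixel_size
  tth_edge <- atan2(edge_mm, det_$distance)
  d_edge <- lambda0 / (2 * sin(tth_edge / 2))
  edge_warning <- config$d_min < d_edge

  frames <- vector("list", n_frames)
  for (i in seq_len(n_frames)) {
    hit <- stats::runif(1) < config$hit_fraction
    wl_shot <- lambda0 * (1 + stats::rnorm(1) * beam$shot_jitter)
    fr <- list(frame_id = i, wavelength = wl_shot,
               spots = empty_spot_table(),
               truth = NULL)
    if (edge_warning) fr$warning <- "d_min is beyond the detector edge resolution"
    if (hit) {
      R <- random_rotation()
      scale <- stats::rlnorm(1, 0, config$frame_scale_dispersion)
      A <- R %*% B
      X <- Xcrys %*% t(R)                      # lab reciprocal vectors
      q2 <- rowSums(X^2)
      qn <- sqrt(q2)
      wc <- 1 / wl_shot
      sin_th <- pmin(qn / (2 * wc), 1)
      ok <- X[, 3] < 0 & qn < 2 * wc
      wB <- rep(NA_real_, nrow(X))
      wB[ok] <- q2[ok] / (-2 * X[ok, 3])       # Bragg-satisfying wavenumber
      # nearest in-band wavenumber, and the excitation distance there:
      # how far the point sits from that Ewald sphere (mosaic rotation
      # must bridge it, so the gate is q * mosaic half-angle)
      wlo <- wc * (1 - beam$bandwidth / 2)
      whi <- wc * (1 + beam$bandwidth / 2)
      wd_all <- pmin(pmax(wB, wlo), whi)
      e_wd <- abs(sqrt(pmax(0, q2 + 2 * wd_all * X[, 3] + wd_all^2)) - wd_all)
      sel <- which(ok & e_wd <= qn * mos_rad / 2 + 1e-12)
      if (length(sel) && beam$bandwidth > 0 && mos_rad > 0) {
        # effective recorded wavenumber: the spot integrates photons over
        # the whole band, weighted by the mosaic rocking curve centred on
        # the Bragg-satisfying wavenumber (truncated-Gaussian mean), rather
        # than only the in-band wavelength nearest to it
        sig_w <- (qn[sel] * mos_rad / 2) / (4 * sin_th[sel]^2)
        al <- (wlo - wB[sel]) / sig_w
        be <- (whi - wB[sel]) / sig_w
        zmass <- pmax(stats::pnorm(be) - stats::pnorm(al), 1e-300)
        wd_all[sel] <- wB[sel] +
          sig_w * (stats::dnorm(al) - stats::dnorm(be)) / zmass
        wd_all[sel] <- pmin(pmax(wd_all[sel], wlo), whi)
      }
      if (length(sel)) {
        wd <- wd_all[sel]
        q <- qn[sel]
        z <- -q^2 / (2 * wd)                   # on-sphere z component
        rt <- sqrt(pmax(0, q^2 - z^2))
        txy <- sqrt(X[sel, 1]^2 + X[sel, 2]^2)
        keep <- txy > 1e-12 & rt > 1e-12
        sel <- sel[keep]
        if (length(sel)) {
          wd <- wd[keep]; z <- z[keep]; rt <- rt[keep]; txy <- txy[keep]
          xs <- X[sel, 1] / txy * rt
          ys <- X[sel, 2] / txy * rt
          uz <- (z + wd) / wd                  # cos(2 theta)
          onward <- uz > 0
          sel <- sel[onward]
          if (length(sel)) {
            wd <- wd[onward]; xs <- xs[onward]; ys <- ys[onward]
            z <- z[onward]; uz <- uz[onward]
            ux <- xs / wd; uy <- ys / wd
            pxmm <- det_$distance * ux / uz
            pymm <- det_$distance * uy / uz
            fast <- det_$beam_centre[1] + pxmm / det_$pixel_size +
              stats::rnorm(length(sel)) * config$centroid_noise
            slow <- det_$beam_centre[2] + pymm / det_$pixel_size +
              stats::rnorm(length(sel)) * config$centroid_noise
            onpanel <- fast >= 0 & fast <= det_$n_fast - 1 &
              slow >= 0 & slow <= det_$n_slow - 1
            sel <- sel[onpanel]
            if (length(sel)) {
              fast <- fast[onpanel]; slow <- slow[onpanel]
              # partiality: Gaussian in the angular offset from the exact
              # Bragg condition at the central wavelength, with width the
              # mosaic half-angle plus the bandwidth-equivalent angle
              e_wc <- abs(sqrt(pmax(0, q2[sel] + 2 * wc * X[sel, 3] + wc^2)) - wc)
              ang <- e_wc / qn[sel]
              sig_ang <- (mos_rad / 2 + sin_th[sel] * beam$bandwidth / 2) / 2
              part <- ifelse(sig_ang > 0, exp(-ang^2 / (2 * sig_ang^2)), 1)
              inten <- scale * part * F2[sel] *
                exp(stats::rnorm(length(sel)) * config$intensity_noise)
              sig <- pmax(0.05 * inten, 1e-9)
              smeas <- centroid_to_s(det_, wl_shot, fast, slow)
              dobs <- 1 / sqrt(rowSums(smeas^2))
              fr$spots <- data.frame(fast = fast, slow = slow,
                                     sx = smeas[, 1], sy = smeas[, 2],
                                     sz = smeas[, 3], d = dobs,
                                     intensity = inten, sigma = sig)
              fr$truth <- list(A = A, hkl = unname(Hall[sel, , drop = FALSE]),
                               scale = scale)
            }
          }
        }
      }
      if (is.null(fr$truth))
        fr$truth <- list(A = A, hkl = matrix(integer(0), 0, 3), scale = scale)
    }
    frames[[i]] <- fr
  }
  structure(list(frames = frames, detector = det_, beam = beam, config = config),
            class = "sfx_frames")
}

empty_spot_table <- function() {
  data.frame(fast = numeric(0), slow = numeric(0), sx = numeric(0),
             sy = numeric(0), sz = numeric(0), d = numeric(0),
             intensity = numeric(0), sigma = numeric(0))
}

#' @export
print.sfx_frames <- function(x, ...) {
  ns <- vapply(x$frames, function(f) nrow(f$spots), integer(1))
  cat(sprintf("sfx_frames: %d frames, %d hits, median %g spots/hit\n",
              length(x$frames), sum(ns > 0),
              if (any(ns > 0)) stats::median(ns[ns > 0]) else 0))
  invisible(x)
}

#' Spots-per-hit summary
#' @param frames An `sfx_frames` object.
#' @return Integer vector of spot counts over hit frames (>= 1 spot).
#' @export
spots_per_hit <- function(frames) {
  ns <- vapply(frames$frames, function(f) nrow(f$spots), integer(1))
  ns[ns > 0]
}
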
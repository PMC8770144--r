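# Text formats: versioned spot-list files, SHELX HKLF4 reflection files,
# two-column powder exports, candidate-cell lists and a minimal CIF cell
# block. All formats are line-oriented and diffable; doubles are written
# with 17 significant digits so that parse(write(x)) round-trips exactly.

SPOTLIST_VERSION <- 1L

num <- function(x) sprintf("%.17g", x)

fnv1a <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  mulmod <- function(a) {
    lo <- a %% 65536; hi <- a %/% 65536
    (((hi * 16777619) %% 65536) * 65536 + lo * 16777619) %% 4294967296
  }
  for (b in bytes) h <- mulmod(bitwXor(as.integer(h %% 2147483648), b) + (h %/% 2147483648) * 2147483648)
  sprintf("%08x", as.integer(h %% 2147483648))
}

config_hash <- function(config) {
  fnv1a(paste(utils::capture.output(utils::str(config, digits.d = 15)), collapse = "\n"))
}

#' Write a spot-list file
#'
#' Versioned line-oriented text format carrying the detector geometry and
#' beam header, one `F` record per frame (id, shot wavelength), one `S`
#' record per spot (frame id, fast, slow, intensity, sigma) and, for
#' simulated data, a truth sidecar (`T`: per-frame orientation matrix and
#' scale; `H`: per-spot Miller indices). Scattering vectors and d spacings
#' are derived quantities and are recomputed on read.
#'
#' @param frames An `sfx_frames` object.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_spot_list <- function(frames, path) {
  det_ <- frames$detector; beam <- frames$beam
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(
    sprintf("#smsfx-spotlist v%d", SPOTLIST_VERSION),
    sprintf("#hash %s", config_hash(frames$config)),
    sprintf("#geometry distance=%s pixel_size=%s n_fast=%d n_slow=%d centre_fast=%s centre_slow=%s",
            num(det_$distance), num(det_$pixel_size), det_$n_fast, det_$n_slow,
            num(det_$beam_centre[1]), num(det_$beam_centre[2])),
    sprintf("#beam nominal_energy=%s bandwidth=%s shot_jitter=%s",
            num(beam$nominal_energy), num(beam$bandwidth), num(beam$shot_jitter))
  ), con)
  truth_lines <- character(0)
  for (fr in frames$frames) {
    writeLines(sprintf("F %d %s", fr$frame_id, num(fr$wavelength)), con)
    sp <- fr$spots
    if (nrow(sp))
      writeLines(sprintf("S %d %s %s %s %s", fr$frame_id, num(sp$fast),
                         num(sp$slow), num(sp$intensity), num(sp$sigma)), con)
    if (!is.null(fr$truth)) {
      truth_lines <- c(truth_lines,
        sprintf("T %d %s %s", fr$frame_id,
                paste(num(as.vector(t(fr$truth$A))), collapse = " "),
                num(fr$truth$scale)))
      if (nrow(fr$truth$hkl))
        truth_lines <- c(truth_lines,
          sprintf("H %d %d %d %d %d", fr$frame_id, seq_len(nrow(fr$truth$hkl)),
                  fr$truth$hkl[, 1], fr$truth$hkl[, 2], fr$truth$hkl[, 3]))
    }
  }
  if (length(truth_lines)) {
    writeLines("#truth", con)
    writeLines(truth_lines, con)
  }
  invisible(path)
}

parse_kv <- function(line, lineno) {
  parts <- strsplit(sub("^#\\S+ ", "", line), " ")[[1]]
  kv <- strsplit(parts, "=")
  bad <- vapply(kv, length, integer(1)) != 2
  if (any(bad)) stop(sprintf("malformed header at line %d: %s", lineno, line))
  stats::setNames(vapply(kv, `[`, character(1), 2), vapply(kv, `[`, character(1), 1))
}

#' Read a spot-list file
#'
#' Inverse of [write_spot_list()]. Strictly versioned; malformed records,
#' version mismatches and spots referencing unknown frames are reported with
#' their line number. Scattering vectors and d spacings are recomputed from
#' the stored centroids, geometry and per-shot wavelengths.
#'
#' @param path Input file.
#' @return An `sfx_frames` object (truth blocks restored when present).
#' @export
read_spot_list <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#smsfx-spotlist v", lines[1]))
    stop("not a spot-list file (missing signature line)")
  ver <- as.integer(sub("^#smsfx-spotlist v", "", lines[1]))
  if (is.na(ver) || ver != SPOTLIST_VERSION)
    stop(sprintf("unsupported spot-list version at line 1: %s", lines[1]))
  geom <- beam_kv <- NULL
  frames <- list(); order_ids <- integer(0)
  spot_rows <- list()
  truth_A <- list(); truth_hkl <- list()
  for (i in seq_along(lines)) {
    ln <- lines[i]
    if (ln == "" || ln == "#truth") next
    if (startsWith(ln, "#geometry")) { geom <- parse_kv(ln, i); next }
    if (startsWith(ln, "#beam")) { beam_kv <- parse_kv(ln, i); next }
    if (startsWith(ln, "#")) next
    tok <- strsplit(ln, " ", fixed = TRUE)[[1]]
    tag <- tok[1]
    if (tag == "F") {
      if (length(tok) != 3) stop(sprintf("malformed frame record at line %d", i))
      id <- as.integer(tok[2])
      frames[[as.character(id)]] <- list(frame_id = id,
                                         wavelength = as.numeric(tok[3]))
      order_ids <- c(order_ids, id)
    } else if (tag == "S") {
      if (length(tok) != 6) stop(sprintf("malformed spot record at line %d", i))
      id <- tok[2]
      if (is.null(frames[[id]]))
        stop(sprintf("spot at line %d references unknown frame %s", i, id))
      spot_rows[[id]] <- c(spot_rows[[id]], list(as.numeric(tok[3:6])))
    } else if (tag == "T") {
      if (length(tok) != 12) stop(sprintf("malformed truth record at line %d", i))
      id <- tok[2]
      if (is.null(frames[[id]]))
        stop(sprintf("truth record at line %d references unknown frame %s", i, id))
      truth_A[[id]] <- list(A = matrix(as.numeric(tok[3:11]), 3, 3, byrow = TRUE),
                            scale = as.numeric(tok[12]))
    } else if (tag == "H") {
      if (length(tok) != 6) stop(sprintf("malformed truth-hkl record at line %d", i))
      id <- tok[2]
      if (is.null(frames[[id]]))
        stop(sprintf("truth-hkl record at line %d references unknown frame %s", i, id))
      truth_hkl[[id]] <- rbind(truth_hkl[[id]], as.integer(tok[3:6]))
    } else stop(sprintf("unknown record type '%s' at line %d", tag, i))
  }
  if (is.null(geom)) stop("missing #geometry header")
  if (is.null(beam_kv)) stop("missing #beam header")
  det_ <- detector_model(distance = as.numeric(geom["distance"]),
                         beam_centre = as.numeric(c(geom["centre_fast"], geom["centre_slow"])),
                         pixel_size = as.numeric(geom["pixel_size"]),
                         n_fast = as.integer(geom["n_fast"]),
                         n_slow = as.integer(geom["n_slow"]))
  beam <- beam_model(nominal_energy = as.numeric(beam_kv["nominal_energy"]),
                     bandwidth = as.numeric(beam_kv["bandwidth"]),
                     shot_jitter = as.numeric(beam_kv["shot_jitter"]))
  out <- lapply(as.character(order_ids), function(id) {
    fr <- frames[[id]]
    rows <- spot_rows[[id]]
    if (length(rows)) {
      m <- do.call(rbind, rows)
      s <- centroid_to_s(det_, fr$wavelength, m[, 1], m[, 2])
      fr$spots <- data.frame(fast = m[, 1], slow = m[, 2],
                             sx = s[, 1], sy = s[, 2], sz = s[, 3],
                             d = 1 / sqrt(rowSums(s^2)),
                             intensity = m[, 3], sigma = m[, 4])
    } else fr$spots <- empty_spot_table()
    if (!is.null(truth_A[[id]])) {
      hk <- truth_hkl[[id]]
      hkl <- if (is.null(hk)) matrix(integer(0), 0, 3) else {
        hk <- hk[order(hk[, 1]), , drop = FALSE]
        hk[, 2:4, drop = FALSE]
      }
      fr$truth <- list(A = truth_A[[id]]$A, hkl = hkl, scale = truth_A[[id]]$scale)
    }
    fr
  })
  structure(list(frames = out, detector = det_, beam = beam, config = NULL),
            class = "sfx_frames")
}

#' Write a SHELX HKLF4 reflection file
#'
#' Fixed-format records: h, k, l in three 4-character integer fields, I and
#' sigma(I) in two 8-character fixed-point fields (two decimals), terminated
#' by an all-zero record. Values that do not fit their field are an error.
#'
#' @param merged A `merged_set` (or data frame with `h`,`k`,`l`,`I`,`sigma`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_hklf4 <- function(merged, path) {
  if (!nrow(merged)) stop("refusing to write an empty reflection file")
  if (any(abs(merged[, c("h", "k", "l")]) >= 10000))
    stop("Miller index magnitude >= 10000 does not fit the HKLF4 field")
  fi <- sprintf("%8.2f", merged$I)
  fs <- sprintf("%8.2f", merged$sigma)
  if (any(nchar(fi) > 8) || any(nchar(fs) > 8))
    stop("intensity or sigma overflows the 8-character HKLF4 field")
  lines <- sprintf("%4d%4d%4d%s%s", merged$h, merged$k, merged$l, fi, fs)
  writeLines(c(lines, sprintf("%4d%4d%4d%8.2f%8.2f", 0L, 0L, 0L, 0, 0)), path)
  invisible(path)
}

#' Read a SHELX HKLF4 reflection file
#' @param path Input file.
#' @return Data frame with `h`, `k`, `l`, `I`, `sigma`.
#' @export
read_hklf4 <- function(path) {
  lines <- readLines(path)
  h <- as.integer(substr(lines, 1, 4))
  k <- as.integer(substr(lines, 5, 8))
  l <- as.integer(substr(lines, 9, 12))
  I <- as.numeric(substr(lines, 13, 20))
  s <- as.numeric(substr(lines, 21, 28))
  stop_at <- which(h == 0 & k == 0 & l == 0)[1]
  if (!is.na(stop_at)) {
    keep <- seq_len(stop_at - 1)
    h <- h[keep]; k <- k[keep]; l <- l[keep]; I <- I[keep]; s <- s[keep]
  }
  data.frame(h = h, k = k, l = l, I = I, sigma = s)
}

#' Write a two-column powder pattern export
#'
#' @param pattern A `powder_pattern`.
#' @param path Output file.
#' @param axis `"q"` (1/d) or `"twotheta"` (Cu K-alpha scale).
#' @return `path`, invisibly.
#' @export
write_powder_table <- function(pattern, path, axis = c("q", "twotheta")) {
  axis <- match.arg(axis)
  if (axis == "q") {
    df <- data.frame(q = bin_midpoints(pattern), counts = pattern$counts)
  } else {
    cuka <- export_cuka_scale(pattern)
    df <- data.frame(two_theta = cuka$two_theta, counts = cuka$counts)
  }
  utils::write.table(df, path, row.names = FALSE, quote = FALSE, sep = "\t")
  invisible(path)
}

#' Write / read candidate-cell lists
#'
#' One candidate per line: six cell parameters followed by the Bravais
#' letter pair, whitespace-separated.
#'
#' @param cells List of [unit_cell()].
#' @param bravais Character vector of Bravais types (recycled).
#' @param path File path.
#' @return `path` invisibly (write); list of `list(cell, symmetry)` (read).
#' @export
write_candidate_list <- function(cells, bravais, path) {
  bravais <- rep_len(bravais, length(cells))
  lines <- vapply(seq_along(cells), function(i) {
    p <- as.numeric.unit_cell(cells[[i]])
    paste(c(num(p), bravais[i]), collapse = " ")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_candidate_list
#' @export
read_candidate_list <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  lapply(seq_along(lines), function(i) {
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(tok) != 7) stop(sprintf("malformed candidate at line %d", i))
    p <- as.numeric(tok[1:6])
    list(cell = unit_cell(p[1], p[2], p[3], p[4], p[5], p[6]),
         symmetry = lattice_symmetry(tok[7]))
  })
}

#' Minimal CIF-style cell block I/O
#'
#' Writes / reads the six cell parameters and the Bravais letter as a
#' minimal CIF-like block (`_cell_length_a` ... `_cell_angle_gamma`,
#' `_smsfx_bravais`).
#'
#' @param cell A [unit_cell()].
#' @param bravais Bravais letter pair.
#' @param path File path.
#' @return `path` invisibly (write); `list(cell, symmetry)` (read).
#' @export
write_cell_cif <- function(cell, bravais, path) {
  writeLines(c("data_smsfx_cell",
               sprintf("_cell_length_a %s", num(cell$a)),
               sprintf("_cell_length_b %s", num(cell$b)),
               sprintf("_cell_length_c %s", num(cell$c)),
               sprintf("_cell_angle_alpha %s", num(cell$alpha)),
               sprintf("_cell_angle_beta %s", num(cell$beta)),
               sprintf("_cell_angle_gamma %s", num(cell$gamma)),
               sprintf("_smsfx_bravais %s", bravais)), path)
  invisible(path)
}

#' @rdname write_cell_cif
#' @export
read_cell_cif <- function(path) {
  lines <- readLines(path)
  get <- function(key) {
    ln <- grep(paste0("^", key, " "), lines, value = TRUE)
    if (!length(ln)) stop("missing CIF item: ", key)
    strsplit(trimws(ln[1]), "\\s+")[[1]][2]
  }
  cell <- unit_cell(as.numeric(get("_cell_length_a")),
                    as.numeric(get("_cell_length_b")),
                    as.numeric(get("_cell_length_c")),
                    as.numeric(get("_cell_angle_alpha")),
                    as.numeric(get("_cell_angle_beta")),
                    as.numeric(get("_cell_angle_gamma")))
  list(cell = cell, symmetry = lattice_symmetry(get("_smsfx_bravais")))
}
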
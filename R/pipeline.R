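#' Run configuration
#'
#' Builds the structured configuration driving [run_pipeline()] and the
#' command-line interface, from a named list or a JSON file. Unknown keys
#' (at the top level and inside every block) are rejected; every output
#' artifact echoes a hash of the effective configuration in its header or
#' log so runs are attributable. All randomness flows from the single
#' `seed`.
#'
#' @param x Named list of settings, or the path to a JSON file of them.
#'   Recognised top-level keys: `seed`, `cell` (six numbers), `bravais`,
#'   `n_frames`, and blocks `beam`, `detector`, `simulate`, `powder`,
#'   `index`, `merge`.
#' @return Object of class `smsfx_config`: the fully defaulted configuration.
#' @export
smsfx_config <- function(x = list()) {
  if (is.character(x)) x <- jsonlite::read_json(x, simplifyVector = TRUE)
  defaults <- list(
    seed = 1L,
    cell = c(5.938, 7.325, 29.202, 90, 95.44, 90),
    bravais = "mC",
    n_frames = 200L,
    beam = list(nominal_energy = 12.012, bandwidth = 0.003, shot_jitter = 0.001),
    detector = list(distance = 60, beam_centre = c(1500, 1500),
                    pixel_size = 0.075, n_fast = 3000L, n_slow = 3000L),
    simulate = list(mosaicity = 0.3, d_min = 1.2, hit_fraction = 0.9,
                    frame_scale_dispersion = 0.3, centroid_noise = 0.1,
                    intensity_noise = 0.1),
    powder = list(n_bins = 2000L, n_peaks = 20L, floor_factor = 5),
    index = list(d_tol = 0.005, pair_tol = 0.0015, min_clique = 3L,
                 frac_cut = 0.1, rms_tol = 0.003, max_nodes = 350L),
    merge = list(min_common = 3L, single_sigma_fraction = 0.5,
                 shells = 10L, target_multiplicity = c(10, 15))
  )
  merge_block <- function(def, got, where) {
    if (is.null(got)) return(def)
    unknown <- setdiff(names(got), names(def))
    if (length(unknown))
      stop(sprintf("unknown configuration key%s in %s: %s",
                   if (length(unknown) > 1) "s" else "", where,
                   paste(unknown, collapse = ", ")))
    def[names(got)] <- got
    def
  }
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "))
  cfg <- defaults
  for (key in intersect(names(x), c("seed", "cell", "bravais", "n_frames")))
    cfg[[key]] <- x[[key]]
  for (key in c("beam", "detector", "simulate", "powder", "index", "merge"))
    cfg[[key]] <- merge_block(defaults[[key]], x[[key]], key)
  if (length(cfg$cell) != 6) stop("cell must be six numbers")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "smsfx_config")
}

#' @export
print.smsfx_config <- function(x, ...) {
  cat(sprintf("smsfx config: cell (%s) %s, %d frames, seed %d, hash %s\n",
              paste(format(x$cell, digits = 6), collapse = ", "),
              x$bravais, x$n_frames, x$seed, config_hash(unclass(x))))
  invisible(x)
}

config_sim <- function(cfg) {
  sim_config(cell = do.call(unit_cell, as.list(cfg$cell)),
             symmetry = lattice_symmetry(cfg$bravais),
             beam = do.call(beam_model, cfg$beam),
             detector = do.call(detector_model, cfg$detector),
             mosaicity = cfg$simulate$mosaicity,
             d_min = cfg$simulate$d_min,
             hit_fraction = cfg$simulate$hit_fraction,
             frame_scale_dispersion = cfg$simulate$frame_scale_dispersion,
             centroid_noise = cfg$simulate$centroid_noise,
             intensity_noise = cfg$simulate$intensity_noise,
             seed = cfg$seed)
}

config_indexer <- function(cfg) do.call(indexer_params, cfg$index)

pipeline_log <- function(out_dir, stage, lines, cfg) {
  path <- file.path(out_dir, "pipeline.log")
  con <- file(path, "a"); on.exit(close(con))
  writeLines(sprintf("[%s] config=%s %s", stage, config_hash(unclass(cfg)), lines), con)
}

#' Run the processing pipeline
#'
#' Orchestrates the stages `simulate` (write a spot list), `powder`
#' (pattern + peak list), `search-cell` (candidate scoring table), `index`
#' (per-frame solutions and the indexing rate), `merge` (two-step merged
#' intensities) and `export` (HKLF4 reflection file). Each stage writes its
#' artifact into `out_dir` together with a log line carrying the effective
#' configuration hash and the stage counts; stages re-run independently from
#' the artifacts already present, and a missing upstream artifact is an
#' error naming the stage that produces it.
#'
#' @param config An [smsfx_config()] (or anything it accepts).
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run, in pipeline order.
#' @param candidates Optional list of `list(cell, symmetry)` for
#'   `search-cell` (defaults to the configured cell plus grid candidates).
#' @param reference Optional reference set (data frame `h`,`k`,`l`,`I`) for
#'   merge-stage scaling; default is the first-pass simple merge.
#' @return Named list of artifact paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "powder", "index", "merge", "export"),
                         candidates = NULL, reference = NULL) {
  cfg <- if (inherits(config, "smsfx_config")) config else smsfx_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(spots = file.path(out_dir, "spots.txt"),
                powder = file.path(out_dir, "powder.tsv"),
                peaks = file.path(out_dir, "peaks.txt"),
                candidates = file.path(out_dir, "candidates.csv"),
                solutions = file.path(out_dir, "solutions.txt"),
                scales = file.path(out_dir, "frame_scales.csv"),
                merged = file.path(out_dir, "merged.csv"),
                hklf4 = file.path(out_dir, "merged.hkl"))
  known <- c("simulate", "powder", "search-cell", "index", "merge", "export")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))

  need_frames <- function() {
    if (!file.exists(paths$spots))
      stop("missing spot list ", paths$spots, "; run the 'simulate' stage first")
    read_spot_list(paths$spots)
  }
  cell <- do.call(unit_cell, as.list(cfg$cell))
  sym <- lattice_symmetry(cfg$bravais)

  if ("simulate" %in% stages) {
    frames <- simulate_dataset(config_sim(cfg), cfg$n_frames)
    write_spot_list(frames, paths$spots)
    ns <- vapply(frames$frames, function(f) nrow(f$spots), integer(1))
    pipeline_log(out_dir, "simulate",
                 sprintf("frames=%d hits=%d spots=%d seed=%d",
                         length(ns), sum(ns > 0), sum(ns), cfg$seed), cfg)
  }
  if ("powder" %in% stages) {
    frames <- need_frames()
    pat <- synthesize_powder(harvest_d_spacings(frames), n_bins = cfg$powder$n_bins)
    pat <- pick_peaks(pat, n_peaks = cfg$powder$n_peaks,
                      floor_factor = cfg$powder$floor_factor)
    write_powder_table(pat, paths$powder)
    utils::write.table(pat$peaks, paths$peaks, row.names = FALSE, quote = FALSE, sep = "\t")
    pipeline_log(out_dir, "powder",
                 sprintf("spots=%d peaks=%d", sum(pat$counts), nrow(pat$peaks)), cfg)
  }
  if ("search-cell" %in% stages) {
    frames <- need_frames()
    if (!file.exists(paths$powder))
      stop("missing powder pattern ", paths$powder, "; run the 'powder' stage first")
    pat <- synthesize_powder(harvest_d_spacings(frames), n_bins = cfg$powder$n_bins)
    pat <- pick_peaks(pat, n_peaks = cfg$powder$n_peaks,
                      floor_factor = cfg$powder$floor_factor)
    if (is.null(candidates))
      candidates <- c(list(list(cell = cell, symmetry = sym)),
                      lapply(naive_candidate_grid(pat, bravais = cfg$bravais,
                                                  volume_range = cell_volume(cell) * c(0.4, 2.5)),
                             function(cl) list(cell = cl, symmetry = sym)))
    scores <- evaluate_candidates(frames, candidates, pattern = pat,
                                  params = config_indexer(cfg))
    utils::write.csv(scores, paths$candidates, row.names = FALSE)
    pipeline_log(out_dir, "search-cell",
                 sprintf("candidates=%d best_rate=%.3f", nrow(scores),
                         scores$indexing_rate[1]), cfg)
  }
  if ("index" %in% stages) {
    frames <- need_frames()
    res <- index_dataset(frames, cell, sym, params = config_indexer(cfg))
    con <- file(paths$solutions, "w")
    writeLines(sprintf("#smsfx-solutions version=1 hash=%s rate=%s n_indexed=%d n_hits=%d",
                       config_hash(unclass(cfg)), num(res$rate),
                       res$n_indexed, res$n_hits), con)
    for (sol in res$solutions) {
      writeLines(sprintf("A %d %s", sol$frame_id,
                         paste(num(as.vector(t(sol$A))), collapse = " ")), con)
      writeLines(sprintf("X %d %d %d %d %d", sol$frame_id, sol$assignments$spot,
                         sol$assignments$h, sol$assignments$k, sol$assignments$l), con)
    }
    close(con)
    pipeline_log(out_dir, "index",
                 sprintf("indexed=%d hits=%d rate=%.3f", res$n_indexed,
                         res$n_hits, res$rate), cfg)
  }
  if ("merge" %in% stages) {
    frames <- need_frames()
    if (!file.exists(paths$solutions))
      stop("missing solutions ", paths$solutions, "; run the 'index' stage first")
    res <- read_solutions(paths$solutions)
    obs <- observations(res, frames, sym)
    first <- merge_simple(obs, cfg$merge$single_sigma_fraction)
    ref <- if (is.null(reference)) first else reference
    second <- scale_and_remerge(obs, ref, min_common = cfg$merge$min_common,
                                single_sigma_fraction = cfg$merge$single_sigma_fraction)
    utils::write.csv(second$merged, paths$merged, row.names = FALSE)
    utils::write.csv(second$frame_scales, paths$scales, row.names = FALSE)
    pipeline_log(out_dir, "merge",
                 sprintf("obs=%d uniques=%d dropped_frames=%d", nrow(obs),
                         nrow(second$merged), sum(second$frame_scales$dropped)), cfg)
  }
  if ("export" %in% stages) {
    if (!file.exists(paths$merged))
      stop("missing merged intensities ", paths$merged, "; run the 'merge' stage first")
    merged <- utils::read.csv(paths$merged)
    # HKLF4 fields are fixed-width: rescale into range when necessary
    mx <- max(abs(merged$I), merged$sigma)
    if (mx > 99999.99) {
      sc <- 99999.99 / mx
      merged$I <- merged$I * sc
      merged$sigma <- merged$sigma * sc
    }
    write_hklf4(merged, paths$hklf4)
    pipeline_log(out_dir, "export", sprintf("reflections=%d", nrow(merged)), cfg)
  }
  invisible(paths)
}

#' Read a pipeline solutions file
#'
#' @param path Solutions file written by the `index` stage.
#' @return An `indexing_results` object.
#' @export
read_solutions <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#smsfx-solutions version=1", lines[1]))
    stop("not a solutions file")
  hdr <- parse_kv(lines[1], 1)
  sols <- list(); cur <- NULL
  for (i in seq_along(lines)[-1]) {
    tok <- strsplit(lines[i], " ", fixed = TRUE)[[1]]
    if (tok[1] == "A") {
      if (!is.null(cur)) sols[[length(sols) + 1L]] <- cur
      cur <- structure(list(frame_id = as.integer(tok[2]),
                            A = matrix(as.numeric(tok[3:11]), 3, 3, byrow = TRUE),
                            assignments = data.frame(spot = integer(0), h = integer(0),
                                                     k = integer(0), l = integer(0)),
                            clique_size = NA_integer_, rms = NA_real_),
                       class = "indexing_solution")
    } else if (tok[1] == "X") {
      if (is.null(cur)) stop(sprintf("assignment before any solution at line %d", i))
      cur$assignments <- rbind(cur$assignments,
                               data.frame(spot = as.integer(tok[3]), h = as.integer(tok[4]),
                                          k = as.integer(tok[5]), l = as.integer(tok[6])))
    } else stop(sprintf("unknown record '%s' at line %d", tok[1], i))
  }
  if (!is.null(cur)) sols[[length(sols) + 1L]] <- cur
  structure(list(solutions = sols,
                 n_hits = as.integer(hdr["n_hits"]),
                 n_indexed = as.integer(hdr["n_indexed"]),
                 rate = as.numeric(hdr["rate"])),
            class = "indexing_results")
}
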
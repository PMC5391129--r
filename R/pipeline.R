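#' Simulate, render and analyse a population founder-by-founder
#'
#' End-to-end driver: renders each founder's lane as its own small movie,
#' runs the measurement pipeline ([analyze_movie()]), matches tracks back
#' to ground-truth cells, and pools per-cell results. Processing one
#' founder at a time keeps images small and memory flat, so populations of
#' hundreds of complete cell cycles are practical.
#'
#' @param population A `cell_population`.
#' @param noise Render with the configured noise (`TRUE`) or noise-free.
#' @param n_bins Profile bins.
#' @param grid Kymograph grid.
#' @param keep_kymographs Collect per-cell fluorescence and shape
#'   kymographs for complete cells (default `TRUE`).
#' @return An object of class `population_analysis`: list with `cells`
#'   (tracked cells + matched truth `cell_id`), `obs`, `foci`, `sept`
#'   (as in [analyze_movie()], with a `cell_id` column added and track ids
#'   made unique across founders), `kymo_fluor`, `kymo_shape` (named lists
#'   keyed by truth cell id when matched), `match` diagnostics,
#'   `frame_interval`.
#' @export
process_population <- function(population, noise = TRUE, n_bins = 51,
                               grid = c(101, 101),
                               keep_kymographs = TRUE) {
  founders <- unique(population$frames$founder)
  acc <- list(cells = list(), obs = list(), foci = list(), sept = list(),
              match = list())
  kf <- list(); ks <- list()
  for (fd in founders) {
    movie <- render_movie(population, founders = fd, noise = noise)
    an <- analyze_movie(movie, n_bins = n_bins)
    mt <- match_tracks_to_truth(an, movie)
    relabel <- setNames(paste0(fd, ".", mt$track_id), mt$track_id)
    id_of <- setNames(mt$cell_id, mt$track_id)

    cells <- an$tracks$cells |>
      dplyr::mutate(
        cell_id = unname(id_of[.data$track_id]),
        track_id = unname(relabel[.data$track_id]),
        mother_id = ifelse(is.na(.data$mother_id), NA_character_,
                           unname(relabel[.data$mother_id])),
        founder = fd)
    retag <- function(tb) dplyr::mutate(
      tb, cell_id = unname(id_of[.data$track_id]),
      track_id = unname(relabel[.data$track_id]))
    acc$cells[[fd]] <- cells
    acc$obs[[fd]] <- retag(an$obs)
    acc$foci[[fd]] <- retag(an$foci)
    acc$sept[[fd]] <- retag(an$sept)
    acc$match[[fd]] <- dplyr::mutate(mt, founder = fd)

    if (keep_kymographs) {
      for (ch in c("fluor", "shape")) {
        kl <- analysis_kymographs(an, channel = ch, grid = grid)
        for (tid in names(kl)) {
          key <- id_of[[tid]] %||% paste0(fd, ".", tid)
          if (is.na(key)) key <- paste0(fd, ".", tid)
          if (ch == "fluor") kf[[key]] <- kl[[tid]] else
            ks[[key]] <- kl[[tid]]
        }
      }
    }
  }
  structure(list(
    cells = dplyr::bind_rows(acc$cells),
    obs = dplyr::bind_rows(acc$obs),
    foci = dplyr::bind_rows(acc$foci),
    sept = dplyr::bind_rows(acc$sept),
    match = dplyr::bind_rows(acc$match),
    kymo_fluor = kf, kymo_shape = ks,
    frame_interval = population$config$frame_interval),
    class = "population_analysis")
}

#' @export
print.population_analysis <- function(x, ...) {
  cat("<population_analysis>", nrow(x$cells), "tracks,",
      sum(x$cells$complete), "complete cycles,",
      length(x$kymo_fluor), "kymographs\n")
  invisible(x)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' Rebuilds a `sim_movie`-shaped object from the fluorescence and
#' bright-field multi-page TIFFs. Page intensities are the writer's
#' per-page min-max rescaling; all downstream analysis uses relative
#' thresholds, so absolute scale is irrelevant.
#'
#' @param fluor_path,bf_path TIFF paths.
#' @param pixel_size um per pixel.
#' @param frame_interval Minutes between frames.
#' @param n_stack_planes Bright-field planes per frame.
#' @param psf_sigma Point-spread sd (um), for focus detection defaults.
#' @return A list of class `sim_movie` (without ground truth).
#' @export
read_movie_tiff <- function(fluor_path, bf_path, pixel_size,
                            frame_interval, n_stack_planes = 32,
                            psf_sigma = 0.08) {
  fl <- tiff::readTIFF(fluor_path, all = TRUE)
  bf <- tiff::readTIFF(bf_path, all = TRUE)
  n_frames <- length(fl)
  if (length(bf) != n_frames * n_stack_planes) {
    stop("bright-field page count is not frames x planes.", call. = FALSE)
  }
  frames <- lapply(seq_len(n_frames), function(i) {
    planes <- bf[seq((i - 1) * n_stack_planes + 1, i * n_stack_planes)]
    list(fluor = fl[[i]],
         bf_stack = array(unlist(planes),
                          dim = c(dim(fl[[i]]), n_stack_planes)))
  })
  structure(list(frames = frames, frame_index = seq_len(n_frames) - 1L,
                 times = (seq_len(n_frames) - 1L) * frame_interval,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 geometry = NULL, truth = NULL,
                 config = list(psf_sigma = psf_sigma),
                 overcrowded = FALSE), class = "sim_movie")
}

#' Run a configured pipeline step and write its artifacts
#'
#' Configuration-driven front end used by the command-line script. Each
#' run writes its artifacts, a fully resolved `config.yaml`, and a
#' `manifest.csv` with MD5 checksums, so identical configs and seeds
#' reproduce identical files.
#'
#' @param config A named list (or path to a YAML file) with at least
#'   `subcommand` (`"simulate"`, `"assay"`, `"analyze"` or `"endtoend"`)
#'   and `out_dir`; other fields by subcommand:
#'   \describe{
#'     \item{simulate/endtoend}{`preset` (or any [sim_config()] fields
#'       under `sim`), `duration` (default 2.4 generations), `n_founders`,
#'       `seed`.}
#'     \item{assay}{`counts` (CSV path), optional `n_boot`, `seed`.}
#'     \item{analyze}{`fluor`, `bf` (TIFF paths), `pixel_size`,
#'       `frame_interval`, `n_stack_planes`.}
#'   }
#' @return Invisibly, the manifest tibble (`path`, `md5`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  sub <- config$subcommand %||% stop("`subcommand` missing.", call. = FALSE)
  out_dir <- config$out_dir %||% stop("`out_dir` missing.", call. = FALSE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  written <- character()

  build_cfg <- function() {
    do.call(sim_config, c(list(preset = config$preset %||% "Ec-slow"),
                          config$sim %||% list()))
  }

  if (sub == "simulate") {
    cfg <- build_cfg()
    duration <- config$duration %||% (2.4 * cfg$generation_time)
    pop <- simulate_population(cfg, duration = duration, seed = seed,
                               n_founders = config$n_founders %||% 1)
    movie <- render_movie(pop)
    written <- c(written, write_movie_tiff(movie, out_dir,
                                           config$name %||% "movie"))
  } else if (sub == "assay") {
    counts <- read.csv(config$counts)
    grp <- if ("condition" %in% names(counts))
      split(counts, counts$condition) else list(all = counts)
    res <- purrr::imap_dfr(grp, function(tb, cond) {
      fit <- if ((config$n_boot %||% 0) > 0)
        bootstrap_ci(tb, n_boot = config$n_boot, seed = seed) else
          estimate_excision(tb)
      dplyr::mutate(glance(fit), condition = cond,
                    warnings = length(fit$warnings))
    })
    p <- file.path(out_dir, "excision_estimates.csv")
    write.csv(res, p, row.names = FALSE)
    written <- c(written, p)
  } else if (sub == "analyze") {
    movie <- read_movie_tiff(config$fluor, config$bf,
                             pixel_size = config$pixel_size,
                             frame_interval = config$frame_interval,
                             n_stack_planes = config$n_stack_planes %||% 32)
    an <- analyze_movie(movie)
    written <- c(written, write_analysis_csvs(an, out_dir))
  } else if (sub == "endtoend") {
    cfg <- build_cfg()
    duration <- config$duration %||% (2.4 * cfg$generation_time)
    pop <- simulate_population(cfg, duration = duration, seed = seed,
                               n_founders = config$n_founders %||% 20)
    pa <- process_population(pop)
    written <- c(written, write_population_outputs(pa, out_dir))
  } else {
    stop("unknown subcommand '", sub, "'.", call. = FALSE)
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(c(config, list(seed = seed)), cfg_path)
  written <- c(written, cfg_path)
  manifest <- tibble::tibble(path = written,
                             md5 = unname(tools::md5sum(written)))
  mpath <- file.path(out_dir, "manifest.csv")
  write.csv(manifest, mpath, row.names = FALSE)
  invisible(manifest)
}

#' Write per-frame tracked label masks as a multi-page TIFF
#'
#' Rasterises each analysed frame's tracked regions into an integer label
#' image (labels follow the order of first appearance of each track) and
#' writes one page per frame.
#'
#' @param analysis A `cell_analysis`.
#' @param path Output TIFF path.
#' @return Invisibly, `path`.
#' @export
write_label_masks <- function(analysis, path) {
  tr <- analysis$tracks
  ids <- unique(tr$observations$track_id)
  pages <- lapply(tr$frame_index, function(k) {
    lab <- matrix(0L, tr$dim_img[1], tr$dim_img[2])
    ob <- tr$observations[tr$observations$frame == k, ]
    for (r in seq_len(nrow(ob))) {
      lab[ob$region[[r]]$pixels[[1]]] <- match(ob$track_id[r], ids)
    }
    lab / max(length(ids), 1)
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  invisible(path)
}

write_analysis_csvs <- function(an, out_dir) {
  obs_path <- file.path(out_dir, "observations.csv")
  write.csv(dplyr::select(an$obs, -"shape_profile", -"fluor_profile"),
            obs_path, row.names = FALSE)
  masks_path <- file.path(out_dir, "label_masks.tif")
  write_label_masks(an, masks_path)
  foci_path <- file.path(out_dir, "foci.csv")
  write.csv(an$foci, foci_path, row.names = FALSE)
  sept_path <- file.path(out_dir, "septation.csv")
  write.csv(an$sept, sept_path, row.names = FALSE)
  cells_path <- file.path(out_dir, "cells.csv")
  write.csv(an$tracks$cells, cells_path, row.names = FALSE)
  c(obs_path, masks_path, foci_path, sept_path, cells_path)
}

write_population_outputs <- function(pa, out_dir) {
  written <- character()
  for (ch in c("fluor", "shape")) {
    kl <- if (ch == "fluor") pa$kymo_fluor else pa$kymo_shape
    if (!length(kl)) next
    cons <- consensus_image(kl)
    p <- file.path(out_dir, paste0("consensus_", ch, ".tif"))
    tiff::writeTIFF(clamp(unclass(cons), 0, 1), p, bits.per.sample = 16)
    written <- c(written, p)
  }
  ok <- dplyr::filter(pa$sept, !is.na(.data$sept_frame),
                      .data$track_id %in%
                        pa$cells$track_id[pa$cells$complete]) |>
    dplyr::select("track_id", "sept_frame")
  if (nrow(ok)) {
    aligned <- align_to_septation(
      dplyr::select(pa$obs, "track_id", "frame", "n_foci") |>
        dplyr::rename(cell_id = "track_id"),
      dplyr::rename(ok, cell_id = "track_id"),
      pa$frame_interval,
      foci = dplyr::select(pa$foci, "track_id", "frame", "x") |>
        dplyr::rename(cell_id = "track_id"))
    p <- file.path(out_dir, "aligned_series.csv")
    write.csv(tibble::as_tibble(aligned), p, row.names = FALSE)
    written <- c(written, p)
  }
  summ <- list(
    n_tracks = nrow(pa$cells),
    n_complete = sum(pa$cells$complete),
    n_septation_calls = sum(!is.na(pa$sept$sept_frame)),
    split_time = if (length(pa$kymo_fluor) > 0)
      estimate_split_time(consensus_image(pa$kymo_fluor)) else NA)
  p <- file.path(out_dir, "summary.json")
  jsonlite::write_json(summ, p, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  c(written, p)
}
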
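#' Run the full image-analysis pipeline on a movie
#'
#' Reconstructs a shape image from every bright-field stack, segments it,
#' tracks cells and genealogy across frames, measures per-frame long-axis
#' shape and fluorescence profiles, detects fluorescent foci, and calls
#' septation onset per cell. This is the measurement path; it never touches
#' the simulator's ground truth.
#'
#' @param movie A `sim_movie` (from [render_movie()] or
#'   [read_movie_tiff()]).
#' @param n_bins Profile bin count (default 51).
#' @param psf_sigma_px Point-spread sd in pixels for focus detection;
#'   defaults to the movie config when present, else 1.5.
#' @param shape_stat Projection statistic for
#'   [reconstruct_shape_image()].
#' @return An object of class `cell_analysis`: list with
#'   \describe{
#'     \item{tracks}{the [track_and_genealogy()] `lineage_set`.}
#'     \item{obs}{tibble per track per frame: `track_id`, `frame`, `time`,
#'       `length_um`, `n_foci`, `merged`, plus list-columns
#'       `shape_profile` and `fluor_profile`.}
#'     \item{foci}{tibble per focus: `track_id`, `frame`, `x` (old pole =
#'       0 when polarity is known, low axis end otherwise), `d`,
#'       `intensity`.}
#'     \item{sept}{tibble of septation calls: `track_id`, `sept_frame`,
#'       `position`, `depth` (`NA` frame when never detected).}
#'   }
#'   plus `frame_interval` and `pixel_size`.
#' @export
analyze_movie <- function(movie, n_bins = 51, psf_sigma_px = NULL,
                          shape_stat = "sd") {
  px <- movie$pixel_size
  psf_sigma_px <- psf_sigma_px %||%
    (movie$config$psf_sigma / px) %||% 1.5

  segs <- vector("list", length(movie$frames))
  shapes <- vector("list", length(movie$frames))
  for (i in seq_along(movie$frames)) {
    shapes[[i]] <- reconstruct_shape_image(movie$frames[[i]]$bf_stack,
                                           stat = shape_stat,
                                           pixel_size = px)
    segs[[i]] <- segment_cells(shapes[[i]], pixel_size = px)
  }
  tracks <- track_and_genealogy(segs, frame_index = movie$frame_index,
                                frame_interval = movie$frame_interval)

  pol <- setNames(tracks$cells$old_pole_low, tracks$cells$track_id)
  resp_cache <- vector("list", length(movie$frames))
  obs_rows <- vector("list", nrow(tracks$observations))
  foci_rows <- vector("list", nrow(tracks$observations))
  for (r in seq_len(nrow(tracks$observations))) {
    ob <- tracks$observations[r, ]
    fi <- match(ob$frame, movie$frame_index)
    region <- ob$region[[1]]
    nb <- adaptive_bins(region, n_bins)
    sp <- long_axis_profile(unclass(shapes[[fi]]), region, nb)
    fp <- long_axis_profile(movie$frames[[fi]]$fluor, region, nb)
    if (is.null(resp_cache[[fi]])) {
      resp_cache[[fi]] <- log_response(movie$frames[[fi]]$fluor,
                                       psf_sigma_px)
    }
    fc <- detect_foci(movie$frames[[fi]]$fluor, region, psf_sigma_px,
                      extent = refine_axial_extent(unclass(shapes[[fi]]),
                                                   region),
                      response = resp_cache[[fi]])
    old_low <- pol[[ob$track_id]]
    x <- if (!is.na(old_low) && !old_low) 1 - fc$x_rel else fc$x_rel
    obs_rows[[r]] <- tibble::tibble(
      track_id = ob$track_id, frame = ob$frame, time = ob$time,
      length_um = region$length_um, cx_px = region$cx,
      cy_px = region$cy, angle = region$angle, n_foci = nrow(fc),
      merged = ob$merged,
      shape_profile = list(as.numeric(sp)),
      fluor_profile = list(as.numeric(fp)))
    foci_rows[[r]] <- if (nrow(fc)) tibble::tibble(
      track_id = ob$track_id, frame = ob$frame, x = x, d = fc$d,
      intensity = fc$intensity) else NULL
  }
  obs <- dplyr::bind_rows(obs_rows)
  foci <- dplyr::bind_rows(foci_rows)
  if (!nrow(foci)) {
    foci <- tibble::tibble(track_id = character(), frame = integer(),
                           x = numeric(), d = numeric(),
                           intensity = numeric())
  }

  sept <- obs |>
    dplyr::group_by(.data$track_id) |>
    dplyr::arrange(.data$frame, .by_group = TRUE) |>
    dplyr::summarise(call = list(
      if (dplyr::n() >= 3)
        detect_septation(.data$shape_profile,
                         frame_index = .data$frame) else NULL),
      .groups = "drop")
  sept <- dplyr::bind_rows(purrr::map2(sept$track_id, sept$call,
    function(tid, cl) {
      if (is.null(cl)) tibble::tibble(track_id = tid,
                                      sept_frame = NA_integer_,
                                      position = NA_real_,
                                      depth = NA_real_)
      else tibble::tibble(track_id = tid,
                          sept_frame = as.integer(cl$sept_frame),
                          position = cl$position, depth = cl$depth)
    }))

  structure(list(tracks = tracks, obs = obs, foci = foci, sept = sept,
                 frame_interval = movie$frame_interval,
                 pixel_size = px),
            class = "cell_analysis")
}

# cap the profile bin count so every slice spans >= ~1.5 px of the long
# axis; sub-pixel bins sample single edge pixels and produce spike noise
adaptive_bins <- function(region, n_bins) {
  span <- region$proj_max - region$proj_min + 1
  max(15L, min(n_bins, as.integer(floor(span / 1.5))))
}

#' @export
print.cell_analysis <- function(x, ...) {
  cat("<cell_analysis>", nrow(x$tracks$cells), "tracks,",
      sum(x$tracks$cells$complete), "complete;",
      sum(!is.na(x$sept$sept_frame)), "septation call(s)\n")
  invisible(x)
}

#' Match tracked cells to simulator ground-truth cells
#'
#' Assigns each track the ground-truth cell whose true footprint contains
#' the track's centroid in the most shared frames. Used only by recovery
#' and equivalence tests — the measurement path itself never sees truth.
#'
#' @param analysis A `cell_analysis`.
#' @param movie The `sim_movie` the analysis was run on.
#' @return A tibble `track_id`, `cell_id` (truth), `n_matched`,
#'   `n_frames`, plus `mother_ok`: whether the tracked mother link agrees
#'   with the truth genealogy.
#' @export
match_tracks_to_truth <- function(analysis, movie) {
  px <- movie$pixel_size
  g <- movie$geometry
  ob <- analysis$tracks$observations
  votes <- tibble::tibble(
    track_id = ob$track_id, frame = ob$frame,
    cx_um = vapply(ob$region, function(r) (r$cx + 0.5) * px, numeric(1)),
    cy_um = vapply(ob$region, function(r) (r$cy + 0.5) * px, numeric(1)))
  hit <- votes |>
    dplyr::inner_join(
      dplyr::select(g, "cell_id", "frame", "x_left_um", "x_right_um",
                    "y_um"),
      by = "frame", relationship = "many-to-many") |>
    dplyr::filter(.data$cx_um >= .data$x_left_um,
                  .data$cx_um <= .data$x_right_um,
                  abs(.data$cy_um - .data$y_um) < 1) |>
    dplyr::count(.data$track_id, .data$cell_id, name = "n_matched")
  best <- hit |>
    dplyr::group_by(.data$track_id) |>
    dplyr::slice_max(.data$n_matched, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  out <- analysis$tracks$cells |>
    dplyr::select("track_id", "mother_id") |>
    dplyr::left_join(best, by = "track_id") |>
    dplyr::left_join(dplyr::count(analysis$obs, .data$track_id,
                                  name = "n_frames"),
                     by = "track_id")
  truth_mother <- setNames(movie$truth$cells$mother_id,
                           movie$truth$cells$cell_id)
  track_cell <- setNames(out$cell_id, out$track_id)
  out$mother_ok <- purrr::map2_lgl(out$mother_id, out$cell_id,
    function(mid, cid) {
      if (is.na(cid)) return(NA)
      tm <- truth_mother[[cid]] %||% NA_character_
      if (is.na(mid)) is.na(tm)
      else !is.na(tm) && identical(track_cell[[mid]], tm)
    })
  dplyr::select(out, "track_id", "cell_id", "n_matched", "n_frames",
                "mother_ok")
}

#' Per-cell cycle kymographs for all complete cells of an analysis
#'
#' @param analysis A `cell_analysis`.
#' @param channel `"fluor"` or `"shape"`.
#' @param grid Kymograph grid (default 101 x 101).
#' @return Named list of `kymograph` objects, one per complete cell with
#'   known polarity and >= 2 frames.
#' @export
analysis_kymographs <- function(analysis, channel = c("fluor", "shape"),
                                grid = c(101, 101)) {
  channel <- match.arg(channel)
  col <- if (channel == "fluor") "fluor_profile" else "shape_profile"
  cells <- dplyr::filter(analysis$tracks$cells, .data$complete,
                         .data$polarity_known)
  out <- list()
  for (i in seq_len(nrow(cells))) {
    ob <- analysis$obs |>
      dplyr::filter(.data$track_id == cells$track_id[i]) |>
      dplyr::arrange(.data$frame)
    if (nrow(ob) < 2) next
    fr <- (ob$time - ob$time[1]) / (ob$time[nrow(ob)] - ob$time[1])
    out[[cells$track_id[i]]] <- cycle_kymograph(
      ob[[col]], old_pole_low = cells$old_pole_low[i],
      cycle_fractions = fr, grid = grid, channel = channel)
  }
  out
}

#' Snapshot analysis of a single rendered frame
#'
#' Measurement-path analogue of [snapshot_sample()]: segments one frame's
#' shape image, detects foci per cell, and classifies constriction from the
#' shape profile dip (no temporal information). Orientation is arbitrary:
#' each cell is reported in its low-to-high axis orientation, mirrored with
#' probability 1/2 under the given seed.
#'
#' @param movie A `sim_movie`.
#' @param frame Frame index to analyse.
#' @param seed Seed for the orientation coin flips.
#' @param n_bins Profile bins.
#' @param psf_sigma_px Point-spread sd in pixels (default from config).
#' @return A tibble like [snapshot_sample()]'s: `cell_id` (region id as
#'   character), `length_um`, `constricting`, `n_foci`, `flipped`,
#'   `foci_x` list-column.
#' @export
snapshot_analyze <- function(movie, frame, seed = 1,
                             n_bins = 51, psf_sigma_px = NULL) {
  px <- movie$pixel_size
  psf_sigma_px <- psf_sigma_px %||% (movie$config$psf_sigma / px)
  fi <- match(frame, movie$frame_index)
  if (is.na(fi)) stop("frame not rendered.", call. = FALSE)
  shape <- reconstruct_shape_image(movie$frames[[fi]]$bf_stack,
                                   pixel_size = px)
  seg <- segment_cells(shape, pixel_size = px)
  resp <- log_response(movie$frames[[fi]]$fluor, psf_sigma_px)
  purrr::map_dfr(seq_len(nrow(seg)), function(r) {
    region <- seg[r, , drop = FALSE]
    fc <- detect_foci(movie$frames[[fi]]$fluor, region, psf_sigma_px,
                      extent = refine_axial_extent(unclass(shape), region),
                      response = resp)
    sp <- long_axis_profile(unclass(shape), region,
                            adaptive_bins(region, n_bins))
    fl <- local_seed(stable_hash(paste0(seed, "/snapflip/", r)),
                     runif(1) < 0.5)
    x <- if (fl) 1 - fc$x_rel else fc$x_rel
    tibble::tibble(cell_id = as.character(region$region_id),
                   length_um = region$length_um,
                   constricting = has_constriction(sp),
                   n_foci = nrow(fc), flipped = fl,
                   foci_x = list(sort(x)))
  })
}
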
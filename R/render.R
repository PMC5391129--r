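#' Render a simulated population into fluorescence and bright-field movies
#'
#' Produces, for every frame, a fluorescence image (sum of isotropic
#' Gaussian spots at the true focus positions, plus background and additive
#' Gaussian noise) and a bright-field defocus stack (`n_stack_planes` planes
#' spanning +/- `stack_range_um`). The bright-field optics model is
#' deliberately simple and fully analytic: each cell body contributes a
#' defocus-signed, defocus-blurred rectangle (contrast proportional to the
#' defocus height, blur growing with it), and from septation onset onward a
#' transverse Gaussian "dark line" of growing depth erodes the contrast at
#' the constriction site. Because every term is separable in x and y, a
#' plane is a single outer product per lane, which is what makes rendering
#' hundreds of cell cycles cheap.
#'
#' Cells of each founder occupy one horizontal lane; lanes are stacked
#' vertically. Coordinates are pixel-centred and 0-based: pixel `(0, 0)` is
#' the top-left, a point at `x` um falls in column `floor(x / pixel_size)`.
#'
#' @param population A `cell_population` from [simulate_population()].
#' @param founders Optional character vector of founder ids to render
#'   (default: all). Rendering founders separately keeps images small.
#' @param frames Optional integer vector of frame indices to render.
#' @param noise If `FALSE`, suppress all additive noise regardless of the
#'   config (used for oracle-equivalence checks); defaults to `TRUE`.
#' @param seed Seed for the rendering noise; defaults to the population
#'   seed. Noise streams are derived per frame so subsetting frames does not
#'   reshuffle other frames.
#' @return An object of class `sim_movie`: a list with `frames` (a list,
#'   one element per rendered frame, each holding `fluor` (matrix) and
#'   `bf_stack` (ny x nx x nplanes array)), `frame_index`, `times`,
#'   `pixel_size`, `frame_interval`, `geometry` (per-frame cell placement in
#'   pixels), `truth` (cell/foci tables restricted to the rendered scene,
#'   with pixel coordinates), `config`, and `overcrowded` flag.
#' @export
render_movie <- function(population, founders = NULL, frames = NULL,
                         noise = TRUE, seed = population$seed) {
  stopifnot(inherits(population, "cell_population"))
  cfg <- population$config
  px <- cfg$pixel_size

  fr <- population$frames
  fo <- population$foci
  if (!is.null(founders)) {
    fr <- dplyr::filter(fr, .data$founder %in% founders)
    fo <- dplyr::filter(fo, .data$founder %in% founders)
  }
  if (!is.null(frames)) {
    fr <- dplyr::filter(fr, .data$frame %in% frames)
    fo <- dplyr::filter(fo, .data$frame %in% frames)
  }
  if (!nrow(fr)) {
    # empty scene: one background-only frame
    fr <- fr[0, ]
  }

  lanes <- sort(unique(fr$founder))
  lane_pitch <- cfg$width_um + 1.2   # um between lane centres
  margin_x <- 0.8                    # um of padding left/right
  lane_y <- setNames(0.8 + cfg$width_um / 2 +
                       (seq_along(lanes) - 1) * lane_pitch, lanes)
  x_max <- if (nrow(fr)) max(fr$x0_um + fr$length_um) else 3
  nx <- ceiling((x_max + 2 * margin_x) / px)
  ny <- ceiling((max(lane_y, 0.8 + cfg$width_um / 2) +
                   cfg$width_um / 2 + 0.8) / px)

  frame_ids <- if (nrow(fr)) sort(unique(fr$frame)) else
    (frames %||% 0L)[1]

  geom <- fr |>
    dplyr::mutate(
      y_um = lane_y[.data$founder],
      x_left_um = .data$x0_um + margin_x,
      x_right_um = .data$x0_um + margin_x + .data$length_um,
      sep_x_um = (.data$x_left_um + .data$x_right_um) / 2)
  truth_foci <- fo |>
    dplyr::mutate(x_img_um = .data$x_um + margin_x,
                  y_img_um = lane_y[.data$founder])

  yy <- (seq_len(ny) - 0.5) * px
  xx <- (seq_len(nx) - 0.5) * px
  zz <- seq(-cfg$stack_range_um, cfg$stack_range_um,
            length.out = cfg$n_stack_planes)
  half_w <- cfg$width_um / 2
  sigma0 <- 0.06       # in-focus edge blur (um)
  blur_slope <- 0.3    # blur growth per um of defocus
  z0 <- 0.5            # defocus (um) of peak bright-field contrast;
                       # contrast decays at large defocus
  sep_sigma <- 0.15    # septum dark-line width (um)

  out_frames <- vector("list", length(frame_ids))
  for (fi in seq_along(frame_ids)) {
    k <- frame_ids[fi]
    g <- geom[geom$frame == k, , drop = FALSE]
    f <- truth_foci[truth_foci$frame == k, , drop = FALSE]

    fluor <- matrix(cfg$background, ny, nx)
    s <- cfg$psf_sigma
    for (ln in lanes) {
      fl <- f[f$founder == ln, , drop = FALSE]
      if (!nrow(fl)) next
      gy <- exp(-(yy - lane_y[[ln]])^2 / (2 * s^2))
      gx <- rep(0, nx)
      for (j in seq_len(nrow(fl))) {
        gx <- gx + cfg$spot_amplitude *
          exp(-(xx - fl$x_img_um[j])^2 / (2 * s^2))
      }
      fluor <- fluor + outer(gy, gx)
    }

    bf <- array(0, dim = c(ny, nx, cfg$n_stack_planes))
    for (p in seq_along(zz)) {
      z <- zz[p]
      amp <- cfg$bf_contrast * (z / z0) * exp(0.5 - z^2 / (2 * z0^2))
      sz <- sqrt(sigma0^2 + (blur_slope * z)^2)
      plane <- matrix(0, ny, nx)
      for (ln in lanes) {
        gl <- g[g$founder == ln, , drop = FALSE]
        if (!nrow(gl)) next
        by <- pnorm((yy - (lane_y[[ln]] - half_w)) / sz) -
          pnorm((yy - (lane_y[[ln]] + half_w)) / sz)
        bx <- rep(0, nx)
        for (j in seq_len(nrow(gl))) {
          body <- pnorm((xx - gl$x_left_um[j]) / sz) -
            pnorm((xx - gl$x_right_um[j]) / sz)
          if (gl$septum_depth[j] > 0) {
            se <- sqrt(sep_sigma^2 + sz^2)
            body <- body - gl$septum_depth[j] * (sep_sigma / se) *
              exp(-(xx - gl$sep_x_um[j])^2 / (2 * se^2))
          }
          bx <- bx + body
        }
        plane <- plane + outer(by, bx)
      }
      bf[, , p] <- amp * plane
    }

    if (noise && (cfg$noise_sd > 0 || cfg$bf_noise_sd > 0)) {
      local_seed(stable_hash(paste0(seed, "/render/", k)), {
        if (cfg$noise_sd > 0) {
          fluor <- fluor + matrix(rnorm(ny * nx, 0, cfg$noise_sd), ny, nx)
        }
        if (cfg$bf_noise_sd > 0) {
          bf <- bf + array(rnorm(length(bf), 0, cfg$bf_noise_sd), dim(bf))
        }
      })
    }
    out_frames[[fi]] <- list(fluor = fluor, bf_stack = bf)
  }

  structure(list(
    frames = out_frames,
    frame_index = frame_ids,
    times = frame_ids * cfg$frame_interval,
    pixel_size = px,
    frame_interval = cfg$frame_interval,
    geometry = geom,
    truth = list(cells = population$cells, frames = geom,
                 foci = truth_foci),
    config = cfg,
    overcrowded = FALSE), class = "sim_movie")
}

#' @export
print.sim_movie <- function(x, ...) {
  d <- if (length(x$frames)) dim(x$frames[[1]]$bf_stack) else c(0, 0, 0)
  cat("<sim_movie>", length(x$frames), "frames,",
      d[1], "x", d[2], "px,", d[3], "BF planes,",
      sprintf("pixel %g um\n", x$pixel_size))
  invisible(x)
}

#' Ground-truth label mask for a rendered frame
#'
#' Rasterises the true cell rectangles of one rendered frame into an
#' integer label matrix (0 = background), for segmentation-recovery tests.
#'
#' @param movie A `sim_movie`.
#' @param frame Frame index (as in `movie$frame_index`).
#' @return Integer matrix of the same size as the rendered images; the
#'   attribute `"cell_ids"` maps label values to cell ids.
#' @export
true_label_mask <- function(movie, frame) {
  g <- movie$geometry
  g <- g[g$frame == frame, , drop = FALSE]
  d <- dim(movie$frames[[match(frame, movie$frame_index)]]$fluor)
  lab <- matrix(0L, d[1], d[2])
  px <- movie$pixel_size
  half_w <- movie$config$width_um / 2
  yy <- (seq_len(d[1]) - 0.5) * px
  xx <- (seq_len(d[2]) - 0.5) * px
  for (j in seq_len(nrow(g))) {
    rows <- which(yy > g$y_um[j] - half_w & yy < g$y_um[j] + half_w)
    cols <- which(xx > g$x_left_um[j] & xx < g$x_right_um[j])
    lab[rows, cols] <- j
  }
  attr(lab, "cell_ids") <- g$cell_id
  lab
}

#' Write a rendered movie to disk
#'
#' Writes one multi-page TIFF per channel (fluorescence: one page per
#' frame; bright-field: one page per plane per frame, plane-major within
#' frame), a sidecar CSV ground-truth table (cell id, frame, length, lane
#' position, septation flag and focus positions) and a YAML echo of the
#' fully resolved configuration.
#'
#' @param movie A `sim_movie`.
#' @param dir Output directory (created if needed).
#' @param name Base name for the files.
#' @return Invisibly, a character vector of the files written.
#' @export
write_movie_tiff <- function(movie, dir, name = "movie") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- function(m) {
    hi <- max(m); lo <- min(m)
    if (hi <= lo) matrix(0, nrow(m), ncol(m)) else (m - lo) / (hi - lo)
  }
  fl_path <- file.path(dir, paste0(name, "_fluor.tif"))
  bf_path <- file.path(dir, paste0(name, "_bf.tif"))
  tiff::writeTIFF(lapply(movie$frames, function(fr) scale(fr$fluor)),
                  fl_path, bits.per.sample = 16)
  bf_pages <- unlist(lapply(movie$frames, function(fr) {
    lapply(seq_len(dim(fr$bf_stack)[3]),
           function(p) scale(fr$bf_stack[, , p]))
  }), recursive = FALSE)
  tiff::writeTIFF(bf_pages, bf_path, bits.per.sample = 16)

  truth <- movie$geometry |>
    dplyr::left_join(
      movie$truth$foci |>
        dplyr::group_by(.data$cell_id, .data$frame) |>
        dplyr::summarise(
          foci_x_rel = paste(signif(.data$x_rel, 6), collapse = ";"),
          .groups = "drop"),
      by = c("cell_id", "frame")) |>
    dplyr::select("cell_id", "frame", "time", "length_um", "x0_um",
                  "constricting", "septum_depth", "n_foci", "foci_x_rel")
  truth_path <- file.path(dir, paste0(name, "_truth.csv"))
  write.csv(truth, truth_path, row.names = FALSE)

  cfg_path <- file.path(dir, paste0(name, "_config.yaml"))
  cfg <- movie$config
  class(cfg) <- NULL
  yaml::write_yaml(cfg, cfg_path)
  invisible(c(fl_path, bf_path, truth_path, cfg_path))
}
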
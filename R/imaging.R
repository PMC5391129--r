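#' Reconstruct a cell-shape image from a bright-field defocus stack
#'
#' Collapses a through-focus bright-field stack into a single
#' high-contrast shape image by a per-pixel projection statistic. Because
#' the bright-field contrast of a cell body reverses sign through focus,
#' the per-pixel standard deviation (default) across planes is near zero in
#' the background and large inside cells, while a constriction (septum)
#' locally reduces it, appearing as a transverse dark line.
#'
#' @param stack A `ny x nx x nplanes` array, or a list of equally sized
#'   matrices (>= 2 planes).
#' @param stat Projection statistic: `"sd"` (default), `"range"`
#'   (max - min), or `"gradient"` (max - min of the plane-to-plane
#'   differences).
#' @param pixel_size Optional pixel size (um) carried as an attribute.
#' @return A matrix of class `shape_image` with attributes `pixel_size`,
#'   `stat` and `n_planes`.
#' @export
reconstruct_shape_image <- function(stack, stat = c("sd", "range",
                                                    "gradient"),
                                    pixel_size = NULL) {
  stat <- match.arg(stat)
  if (is.list(stack)) {
    dims <- unique(lapply(stack, dim))
    if (length(dims) != 1) {
      stop("all planes must have identical dimensions.", call. = FALSE)
    }
    stack <- array(unlist(stack), dim = c(dims[[1]], length(stack)))
  }
  if (length(dim(stack)) != 3 || dim(stack)[3] < 2) {
    stop("`stack` must hold at least 2 planes.", call. = FALSE)
  }
  d <- dim(stack)
  m <- matrix(stack, d[1] * d[2], d[3])
  img <- switch(stat,
    sd = {
      mu <- rowMeans(m)
      sqrt(pmax(rowSums((m - mu)^2) / (d[3] - 1), 0))
    },
    range = {
      apply(m, 1, max) - apply(m, 1, min)
    },
    gradient = {
      dm <- m[, -1, drop = FALSE] - m[, -d[3], drop = FALSE]
      if (ncol(dm) == 1) abs(dm[, 1]) else
        apply(dm, 1, max) - apply(dm, 1, min)
    })
  structure(matrix(img, d[1], d[2]), class = "shape_image",
            pixel_size = pixel_size, stat = stat, n_planes = d[3])
}

#' Segment cells in a shape image
#'
#' Global threshold (Otsu by default on the rescaled image), light
#' morphological cleanup (closing with a 3-pixel brush to bridge
#' constriction dips, opening to drop specks), connected components, and a
#' minimum-area filter. Region geometry follows the second-moment principal
#' axis; length is the maximal extent of the region along it.
#'
#' @param shape A `shape_image` (or plain matrix).
#' @param pixel_size um per pixel; taken from the `shape_image` attribute
#'   when present.
#' @param threshold Optional absolute threshold on the image values;
#'   default is Otsu's threshold.
#' @param min_area_px Minimum region area in pixels (default 40).
#' @return A tibble of regions, one row per cell: `region_id`, `area_px`,
#'   centroid (`cx`, `cy`, 0-based pixel coordinates), principal-axis
#'   `angle` (radians, oriented with non-negative cosine), `length_um`,
#'   `width_um`, bounding extent along the axis (`proj_min`, `proj_max`,
#'   pixels), and a list-column `pixels` of linear pixel indices. The
#'   attribute `"dim"` holds the image size, `"pixel_size"` the
#'   calibration. Empty segmentation gives a zero-row tibble.
#' @export
segment_cells <- function(shape, pixel_size = attr(shape, "pixel_size"),
                          threshold = NULL, min_area_px = 40) {
  if (is.null(pixel_size)) {
    stop("`pixel_size` must be provided (um per pixel).", call. = FALSE)
  }
  img <- unclass(shape)
  rng <- range(img)
  empty <- tibble::tibble(
    region_id = integer(), area_px = integer(), cx = numeric(),
    cy = numeric(), angle = numeric(), length_um = numeric(),
    width_um = numeric(), proj_min = numeric(), proj_max = numeric(),
    pixels = list())
  attr(empty, "dim_img") <- dim(img)
  attr(empty, "pixel_size") <- pixel_size
  if (rng[2] <= rng[1]) return(empty)

  norm <- (img - rng[1]) / (rng[2] - rng[1])
  thr <- if (is.null(threshold)) EBImage::otsu(norm, range = c(0, 1)) else
    (threshold - rng[1]) / (rng[2] - rng[1])
  mask <- norm > thr
  kern <- EBImage::makeBrush(3, shape = "box")
  mask <- EBImage::closing(mask, kern)
  mask <- EBImage::opening(mask, kern)
  lab <- EBImage::bwlabel(mask)
  n <- max(lab)
  if (n == 0) return(empty)

  rows <- lapply(seq_len(n), function(id) {
    idx <- which(lab == id)
    if (length(idx) < min_area_px) return(NULL)
    region_props(idx, dim(img), pixel_size, id)
  })
  out <- dplyr::bind_rows(rows[!vapply(rows, is.null, logical(1))])
  if (!nrow(out)) return(empty)
  out$region_id <- seq_len(nrow(out))
  attr(out, "dim_img") <- dim(img)
  attr(out, "pixel_size") <- pixel_size
  out
}

# Geometry of one connected region from its linear pixel indices.
region_props <- function(idx, dim_img, pixel_size, id) {
  ny <- dim_img[1]
  y <- (idx - 1) %% ny          # 0-based row
  x <- (idx - 1) %/% ny         # 0-based col
  cx <- mean(x); cy <- mean(y)
  cxx <- mean((x - cx)^2) + 1 / 12
  cyy <- mean((y - cy)^2) + 1 / 12
  cxy <- mean((x - cx) * (y - cy))
  theta <- 0.5 * atan2(2 * cxy, cxx - cyy)
  if (cos(theta) < 0) theta <- theta + pi
  if (abs(cos(theta)) < 1e-12 && sin(theta) < 0) theta <- theta + pi
  ux <- cos(theta); uy <- sin(theta)
  proj <- (x - cx) * ux + (y - cy) * uy
  perp <- -(x - cx) * uy + (y - cy) * ux
  tibble::tibble(
    region_id = id, area_px = length(idx),
    cx = cx, cy = cy, angle = theta,
    length_um = (max(proj) - min(proj) + 1) * pixel_size,
    width_um = (max(perp) - min(perp) + 1) * pixel_size,
    proj_min = min(proj), proj_max = max(proj),
    pixels = list(idx))
}

#' Sub-pixel axial extent of a cell from its shape-image profile
#'
#' The binary mask's axial extent is quantised to whole pixels and biased
#' by bleed-over from close neighbours. This helper locates each cell pole
#' at sub-pixel precision as the point where the 1-px-binned long-axis
#' shape profile crosses half its interior level (the mid-level of a
#' blurred edge marks the true boundary), extrapolating along the edge
#' slope when the mask was cut above that level. Used to map focus
#' positions to relative long-axis coordinates.
#'
#' @param image The shape-image matrix.
#' @param region One-row region table.
#' @param rel_level Crossing level relative to the interior intensity
#'   (default 0.5).
#' @return `c(lo, hi)`: pole positions in the region's principal-axis
#'   projection coordinate (pixels, relative to the centroid).
#' @export
refine_axial_extent <- function(image, region, rel_level = 0.5) {
  idx <- region$pixels[[1]]
  ny <- nrow(image); nx <- ncol(image)
  ym <- (idx - 1) %% ny
  xm <- (idx - 1) %/% ny
  ux <- cos(region$angle); uy <- sin(region$angle)
  fallback <- c(region$proj_min - 0.5, region$proj_max + 0.5)
  # sample the full oriented band through the cell body (not just mask
  # pixels), padded axially so the profile drops toward background
  pad <- 4L
  xs <- max(min(xm) - pad, 0):min(max(xm) + pad, nx - 1)
  ys <- max(min(ym) - pad, 0):min(max(ym) + pad, ny - 1)
  gx <- rep(xs, each = length(ys))
  gy <- rep(ys, times = length(xs))
  q <- (gx - region$cx) * ux + (gy - region$cy) * uy
  perp <- -(gx - region$cx) * uy + (gy - region$cy) * ux
  perp_m <- -(xm - region$cx) * uy + (ym - region$cy) * ux
  wlim <- max(max(perp_m) - 1, 1)
  sel <- abs(perp) <= wlim
  if (!any(sel)) return(fallback)
  v <- image[gy[sel] + 1 + gx[sel] * ny]
  b <- round(q[sel])
  prof <- tapply(v, b, mean)
  pos <- as.numeric(names(prof))
  o <- order(pos)
  pos <- pos[o]; prof <- as.numeric(prof)[o]
  qr <- quantile(pos, c(0.3, 0.7))
  interior <- median(prof[pos >= qr[1] & pos <= qr[2]])
  bg <- min(prof)
  lev <- bg + rel_level * (interior - bg)
  centre_i <- which.min(abs(pos))
  one_side <- function(dir) {
    # walk outward from the centre; first crossing below `lev`
    ii <- if (dir < 0) rev(seq_len(centre_i)) else
      centre_i:length(pos)
    below <- which(prof[ii] < lev)
    if (!length(below)) return(NA_real_)
    k <- below[1]
    if (k == 1) return(NA_real_)
    i2 <- ii[k]; i1 <- ii[k - 1]
    pos[i1] + (lev - prof[i1]) / (prof[i2] - prof[i1]) *
      (pos[i2] - pos[i1])
  }
  lo <- one_side(-1)
  hi <- one_side(1)
  if (!is.finite(lo) || !is.finite(hi) || hi - lo < 2) return(fallback)
  c(lo, hi)
}

#' Rebuild an integer label matrix from a segmentation table
#'
#' @param regions A tibble from [segment_cells()].
#' @return Integer matrix with `region_id` labels.
#' @export
region_label_matrix <- function(regions) {
  d <- attr(regions, "dim_img")
  lab <- matrix(0L, d[1], d[2])
  for (i in seq_len(nrow(regions))) {
    lab[regions$pixels[[i]]] <- regions$region_id[i]
  }
  lab
}
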
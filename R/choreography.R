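#' Mean-intensity profile along a cell's long axis
#'
#' Partitions the region's pixels into `n_bins` equal-length slices
#' perpendicular to the principal axis and averages the image intensity in
#' each slice. Empty bins (possible for ragged masks) are filled by linear
#' interpolation from their neighbours. The profile runs from the low end
#' of the principal axis to the high end; orient it by pole polarity before
#' stacking into a kymograph.
#'
#' @param image Intensity matrix (same geometry as the segmentation).
#' @param region One-row region table (from [segment_cells()]).
#' @param n_bins Number of slices (default 51).
#' @return Numeric vector of length `n_bins` with class
#'   `long_axis_profile`.
#' @export
long_axis_profile <- function(image, region, n_bins = 51) {
  idx <- region$pixels[[1]]
  if (!length(idx)) stop("region has zero area.", call. = FALSE)
  ny <- nrow(image)
  y <- (idx - 1) %% ny
  x <- (idx - 1) %/% ny
  ux <- cos(region$angle); uy <- sin(region$angle)
  q <- (x - region$cx) * ux + (y - region$cy) * uy
  lo <- region$proj_min; hi <- region$proj_max
  bin <- pmin(pmax(floor((q - lo) / (hi - lo + 1e-9) * n_bins) + 1, 1),
              n_bins)
  v <- image[idx]
  p <- vapply(seq_len(n_bins), function(b) {
    sel <- bin == b
    if (any(sel)) mean(v[sel]) else NA_real_
  }, numeric(1))
  if (anyNA(p)) {
    ok <- which(!is.na(p))
    p <- approx(ok, p[ok], xout = seq_len(n_bins), rule = 2)$y
  }
  structure(p, class = "long_axis_profile", n_bins = n_bins)
}

#' Rescale a profile to the unit interval
#'
#' Maps the minimum to 0 and the maximum to 1, as done per time point when
#' stacking projections into a kymograph, so that every frame (and hence
#' every cell) contributes equally to consensus images. A constant profile
#' maps to all zeros and is flagged via the `"constant"` attribute.
#'
#' @param p A numeric profile.
#' @return The rescaled profile (attributes preserved).
#' @export
normalize_profile <- function(p) {
  rng <- range(p)
  out <- if (rng[2] > rng[1]) (p - rng[1]) / (rng[2] - rng[1]) else
    rep(0, length(p))
  attributes(out) <- attributes(p)
  attr(out, "constant") <- rng[2] <= rng[1]
  out
}

#' Cell-cycle kymograph from per-frame profiles
#'
#' Stacks a cell's per-frame long-axis profiles into a matrix over
#' normalised cycle time (rows; 0 = first observed frame after birth,
#' 1 = last frame before division) by normalised cell length (columns;
#' 0 = old pole, 1 = new pole). Each profile is min-max rescaled, oriented
#' old pole first, resampled linearly to the column grid; rows are then
#' placed at their cycle fractions and resampled linearly to the row grid.
#'
#' @param profiles List of numeric profiles, one per frame of a complete
#'   cell cycle, each running low-end to high-end of the cell axis.
#' @param old_pole_low `TRUE` when the old pole is at the low end (profiles
#'   are then used as-is, otherwise reversed). Must be known.
#' @param cycle_fractions Optional numeric vector of cycle fractions for
#'   the frames; defaults to equally spaced over \[0, 1\].
#' @param grid `c(T, X)` output grid (default 101 x 101).
#' @param channel Label stored on the result (`"fluor"` or `"shape"`).
#' @return A `T x X` matrix of class `kymograph` with attributes `channel`
#'   and `cycle_fractions`.
#' @export
cycle_kymograph <- function(profiles, old_pole_low,
                            cycle_fractions = NULL, grid = c(101, 101),
                            channel = "fluor") {
  if (is.na(old_pole_low)) {
    stop("pole polarity is unknown; a cycle kymograph needs an oriented ",
         "cell (observed birth).", call. = FALSE)
  }
  nf <- length(profiles)
  if (nf < 2) stop("need at least 2 frames.", call. = FALSE)
  cycle_fractions <- cycle_fractions %||% seq(0, 1, length.out = nf)
  if (length(cycle_fractions) != nf) {
    stop("`cycle_fractions` must match the number of profiles.",
         call. = FALSE)
  }
  Tn <- grid[1]; Xn <- grid[2]
  rows <- matrix(NA_real_, nf, Xn)
  xout <- seq(0, 1, length.out = Xn)
  for (i in seq_len(nf)) {
    p <- as.numeric(normalize_profile(profiles[[i]]))
    if (!old_pole_low) p <- rev(p)
    xin <- if (length(p) == Xn) xout else
      seq(0, 1, length.out = length(p))
    rows[i, ] <- approx(xin, p, xout = xout, rule = 2)$y
  }
  out <- matrix(NA_real_, Tn, Xn)
  tout <- seq(0, 1, length.out = Tn)
  for (j in seq_len(Xn)) {
    out[, j] <- approx(cycle_fractions, rows[, j], xout = tout,
                       rule = 2)$y
  }
  structure(out, class = "kymograph", channel = channel,
            cycle_fractions = cycle_fractions)
}

#' Population consensus image from kymographs
#'
#' Element-wise mean of per-cell kymographs on a common grid; each cell
#' contributes equally because every constituent row was min-max rescaled.
#'
#' @param kymographs Non-empty list of `kymograph` matrices with identical
#'   dimensions.
#' @return Matrix of class `consensus_image` with attributes `n_cells` and
#'   `channel`.
#' @export
consensus_image <- function(kymographs) {
  if (!length(kymographs)) {
    stop("`kymographs` must be a non-empty list.", call. = FALSE)
  }
  dims <- unique(lapply(kymographs, dim))
  if (length(dims) != 1) {
    stop("all kymographs must share one grid.", call. = FALSE)
  }
  acc <- Reduce(`+`, lapply(kymographs, unclass))
  structure(acc / length(kymographs), class = "consensus_image",
            n_cells = length(kymographs),
            channel = attr(kymographs[[1]], "channel"))
}

#' Detect septation onset from a cell's shape profiles
#'
#' Scans a cell's life for the first persistent mid-cell constriction. For
#' each frame the (lightly smoothed) long-axis shape profile is compared
#' against a quadratic baseline fitted to the flanks of its central 60%
#' (the detection window itself is excluded from the fit, so a genuine
#' constriction neither bends the baseline nor inflates the noise
#' estimate). A constriction is called at the first frame whose profile
#' shows a minimum within the central `window` dipping below the baseline
#' by at least `k` times a robust noise scale — the median absolute
#' deviation of the flank residuals, floored at 4% of the profile range so
#' that only an appreciable fraction of the cell's own contrast counts as
#' a visible indentation — provided the dip persists at a stable position
#' (within 8% of the cell length) in the following frame.
#'
#' @param profiles List of raw (unnormalised) shape profiles, one per
#'   frame, in temporal order (>= 3 frames).
#' @param frame_index Optional frame indices (default `0:(n-1)`).
#' @param k Dip threshold in noise-scale units (default 3).
#' @param window Central detection window in relative length units
#'   (default `c(0.35, 0.65)`; septa form at mid-cell).
#' @param baseline_window Region used for the baseline fit (default the
#'   central 60%, `c(0.2, 0.8)`).
#' @return A one-row tibble (`sept_frame`, `position`, `depth`) or `NULL`
#'   when no constriction is ever detected (a valid outcome).
#' @export
detect_septation <- function(profiles, frame_index = NULL, k = 3,
                             window = c(0.35, 0.65),
                             baseline_window = c(0.2, 0.8)) {
  nf <- length(profiles)
  if (nf < 3) stop("need at least 3 frames.", call. = FALSE)
  frame_index <- frame_index %||% (seq_len(nf) - 1L)
  dip <- lapply(profiles, profile_dip, k = k, window = window,
                baseline_window = baseline_window)
  for (i in seq_len(nf - 1)) {
    a <- dip[[i]]; b <- dip[[i + 1]]
    if (!is.null(a) && !is.null(b) && a$hit && b$hit &&
        abs(a$position - b$position) <= 0.08) {
      return(tibble::tibble(sept_frame = frame_index[i],
                            position = a$position, depth = a$depth))
    }
  }
  NULL
}

# one-frame dip statistics behind detect_septation / has_constriction
profile_dip <- function(p, k = 3, window = c(0.35, 0.65),
                        baseline_window = c(0.2, 0.8)) {
  n <- length(p)
  if (n >= 7) {
    # light 1-2-1 smoothing: single-bin noise shrinks, the multi-bin
    # septum dip survives
    ps <- p
    ps[2:(n - 1)] <- (p[1:(n - 2)] + 2 * p[2:(n - 1)] + p[3:n]) / 4
    p <- ps
  }
  rel <- (seq_len(n) - 0.5) / n
  base_sel <- rel >= baseline_window[1] & rel <= baseline_window[2]
  win_sel <- which(rel >= window[1] & rel <= window[2])
  # the baseline is fitted on the flanks of the central region only, so a
  # genuine constriction neither bends the fit nor inflates the noise
  # scale; quadratic terms absorb the broad intensity dome of short cells
  flank_sel <- which(base_sel)[!(which(base_sel) %in% win_sel)]
  if (length(flank_sel) < 6 || length(win_sel) < 3) return(NULL)
  fit <- lm(y ~ x + I(x^2),
            data = list(y = p[flank_sel], x = rel[flank_sel]))
  res <- p[flank_sel] - fitted(fit)
  # noise floor at 4% of the profile range: a constriction must be an
  # appreciable fraction of the cell's own contrast to count as visible
  scale <- max(mad(res), 0.04 * diff(range(p)), 1e-12)
  cf <- coef(fit)
  rwin <- p[win_sel] -
    (cf[1] + cf[2] * rel[win_sel] + cf[3] * rel[win_sel]^2)
  i_min <- which.min(rwin)
  list(hit = rwin[i_min] <= -k * scale,
       position = rel[win_sel[i_min]],
       depth = -rwin[i_min])
}

#' Classify a single shape profile as constricting or not
#'
#' Applies the same mid-cell dip criterion as [detect_septation()] to one
#' profile, without the temporal persistence requirement — the snapshot
#' analogue of manually scoring a "visible indentation".
#'
#' @inheritParams detect_septation
#' @param profile A raw long-axis shape profile.
#' @return Logical: does the profile show a mid-cell constriction dip?
#' @export
has_constriction <- function(profile, k = 3, window = c(0.35, 0.65),
                             baseline_window = c(0.2, 0.8)) {
  d <- profile_dip(as.numeric(profile), k = k, window = window,
                   baseline_window = baseline_window)
  !is.null(d) && d$hit
}

#' Estimate the sister-separation time from a fluorescence consensus image
#'
#' In a fluorescence consensus image the unseparated focus forms a single
#' mid-cell ridge; once sisters separate, intensity leaves the cell centre.
#' Because each cell's rows are individually 0-1 rescaled, the consensus
#' value at mid-cell approximates the fraction of cells not yet separated
#' at that cycle fraction. The separation time is estimated as the first
#' row (persisting one further row) where the mean intensity within a
#' narrow central window falls below `level`; with `level = 0.5` this
#' estimates the median separation fraction.
#'
#' @param consensus A fluorescence `consensus_image` (or kymograph).
#' @param center_window Half-width of the mid-cell window in relative
#'   length units (default 0.03).
#' @param level Crossing level (default 0.5).
#' @return Estimated separation cycle fraction, or `NA` if the central
#'   intensity never falls below `level`.
#' @export
estimate_split_time <- function(consensus, center_window = 0.03,
                                level = 0.5) {
  m <- unclass(consensus)
  Xn <- ncol(m); Tn <- nrow(m)
  xpos <- seq(0, 1, length.out = Xn)
  sel <- abs(xpos - 0.5) <= center_window
  central <- rowMeans(m[, sel, drop = FALSE])
  below <- central < level
  hits <- which(below[-Tn] & below[-1])
  if (!length(hits)) return(NA_real_)
  (hits[1] - 1) / (Tn - 1)
}
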
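#' Simulate a population of growing, dividing cells with a tracked locus
#'
#' Generates rod-shaped cells elongating exponentially and dividing at
#' mid-cell, each carrying fluorescent foci marking a chromosomal terminus
#' locus. Per-cell cycle timings (`t_sep`, `t_con`) are drawn from truncated
#' normals on cycle fractions; focus positions follow a birth-position ->
#' mid-cell -> quarter-position relaxation trajectory with per-frame jitter.
#' All latent quantities (true lengths, focus positions, separation and
#' septation-onset times, genealogy, pole polarity) are returned as ground
#' truth.
#'
#' Randomness is reproducible and *stable*: every cell consumes a private
#' RNG stream derived by hashing its lineage identifier together with the
#' master seed, so adding founders or lengthening the run never reshuffles
#' the randomness of existing cells.
#'
#' Cells of one founder are laid out end-to-end along the x axis of a lane
#' (one lane per founder), daughters replacing their mother in place with a
#' small gap opened at scission; this keeps mask overlap between consecutive
#' frames high for tracking while avoiding cell collisions.
#'
#' @param config A [sim_config()].
#' @param duration Simulated time (min); must cover at least one generation.
#' @param seed Master integer seed.
#' @param n_founders Number of independent founder cells (lanes).
#' @param founder_phase Cycle phase of each founder at time 0: `NULL`
#'   (default) draws a uniform random phase per founder, desynchronising
#'   the lanes as in an exponentially growing culture; a numeric scalar or
#'   vector (in \[0, 1)) fixes it, e.g. `0` starts every founder at birth.
#' @return An object of class `cell_population`: a list with tibbles
#'   `cells` (one row per cell: identifiers, genealogy, birth/division
#'   times, cycle timings, polarity), `frames` (one row per cell per frame:
#'   length, lane position, constriction state), `foci` (one row per focus
#'   per frame: positions in pole-oriented `u`, lane-oriented `x_rel`, and
#'   absolute `x_um` coordinates), and the `config`, `duration`, `seed`.
#' @examples
#' pop <- simulate_population(sim_config("Ec-slow"), duration = 200, seed = 1)
#' dplyr::count(pop$foci, frame)
#' @export
simulate_population <- function(config, duration, seed, n_founders = 1,
                                founder_phase = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.finite(duration) || duration <= 0) {
    stop("`duration` must be positive.", call. = FALSE)
  }
  if (duration < config$generation_time) {
    stop("`duration` must cover at least one generation time.",
         call. = FALSE)
  }
  validate_sim_config(config)

  if (!is.null(founder_phase)) {
    founder_phase <- rep_len(founder_phase, n_founders)
    if (any(founder_phase < 0 | founder_phase >= 1)) {
      stop("`founder_phase` must lie in [0, 1).", call. = FALSE)
    }
  }
  cells <- list(); frames <- list(); foci <- list()
  for (i in seq_len(n_founders)) {
    fid <- paste0("F", i)
    phase <- if (is.null(founder_phase)) {
      local_seed(stable_hash(paste0(seed, "/phase/", fid)), runif(1))
    } else founder_phase[i]
    queue <- list(list(id = fid, founder = fid, mother = NA_character_,
                       birth = -phase * config$generation_time,
                       birth_length = NA_real_,
                       old_pole_left = TRUE, polarity_known = FALSE,
                       birth_observed = FALSE, born_u = NULL))
    while (length(queue)) {
      spec <- queue[[1]]; queue <- queue[-1]
      res <- simulate_cell(spec, config, duration, seed)
      cells[[length(cells) + 1]] <- res$cell
      frames[[length(frames) + 1]] <- res$frames
      foci[[length(foci) + 1]] <- res$foci
      queue <- c(queue, res$daughters)
    }
  }
  cells <- dplyr::bind_rows(cells)
  frames <- dplyr::bind_rows(frames)
  foci <- if (length(foci)) dplyr::bind_rows(foci) else
    tibble::tibble(cell_id = character(), frame = integer(),
                   time = numeric(), focus_id = integer(),
                   u = numeric(), x_rel = numeric())

  # lane layout: live cells of a founder stacked left-to-right in lineage
  # order (path key), gap opened between cells
  frames <- frames |>
    dplyr::group_by(.data$founder, .data$frame) |>
    dplyr::arrange(.data$path_key, .by_group = TRUE) |>
    dplyr::mutate(
      x0_um = cumsum(dplyr::lag(.data$length_um + config$gap_um,
                                default = 0))) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$frame, .data$founder, .data$path_key)

  foci <- foci |>
    dplyr::left_join(
      dplyr::select(frames, "cell_id", "frame", "x0_um", "length_um",
                    "founder"),
      by = c("cell_id", "frame")) |>
    dplyr::mutate(x_um = .data$x0_um + .data$x_rel * .data$length_um)

  structure(list(cells = cells, frames = frames, foci = foci,
                 config = config, duration = duration, seed = seed,
                 n_founders = n_founders),
            class = "cell_population")
}

#' @export
print.cell_population <- function(x, ...) {
  cat("<cell_population>", nrow(x$cells), "cells,",
      length(unique(x$frames$frame)), "frames,",
      x$n_founders, "founder(s)\n")
  cat("  complete cycles:", sum(x$cells$complete), "\n")
  invisible(x)
}

relax_to <- function(t, t0, u0, target, tau) {
  target + (u0 - target) * exp(-pmax(t - t0, 0) / tau)
}

# Simulate one cell: draw its private randomness, lay out focus-trajectory
# stages, emit per-frame truth, and return daughter specs.
simulate_cell <- function(spec, cfg, duration, seed) {
  drawn <- local_seed(stable_hash(paste0(seed, "/", spec$id)), {
    gen_time <- max(rtruncnorm1(cfg$generation_time, cfg$gen_time_sd,
                                0.5 * cfg$generation_time,
                                1.5 * cfg$generation_time),
                    2 * cfg$frame_interval)
    birth_length <- if (is.na(spec$birth_length)) {
      rlnorm(1, log(cfg$birth_length_mean) -
               0.5 * log(1 + cfg$birth_length_cv^2),
             sqrt(log(1 + cfg$birth_length_cv^2)))
    } else spec$birth_length
    if (is.finite(cfg$sep_hazard)) {
      # truncated-exponential separation age (constant hazard within cycle)
      pmax_q <- 1 - exp(-cfg$sep_hazard * gen_time)
      sep_age <- -log(1 - runif(1) * pmax_q) / cfg$sep_hazard
      t_sep_frac <- sep_age / gen_time
    } else {
      t_sep_frac <- rtruncnorm1(cfg$t_sep_mean, cfg$t_sep_sd, 0, 1)
    }
    t_con_frac <- rtruncnorm1(cfg$t_con_mean, cfg$t_con_sd, 0, 1)
    split_flags <- if (cfg$overlap_rounds) runif(2) < cfg$p_late else
      c(FALSE, FALSE)
    # jitter draws are taken lazily below but inside this same stream:
    # pre-draw a generous block so the count is independent of analysis
    life_span <- if (cfg$scission_enabled) gen_time else
      max(gen_time, duration - spec$birth)
    jitter_block <- rnorm(4 * (ceiling(life_span / cfg$frame_interval) + 2),
                          0, cfg$focus_jitter_sd)
    list(gen_time = gen_time, birth_length = birth_length,
         t_sep_frac = t_sep_frac, t_con_frac = t_con_frac,
         split_flags = split_flags, jitter = jitter_block)
  })

  birth <- spec$birth
  division <- birth + drawn$gen_time
  born_u <- spec$born_u %||% cfg$birth_focus_position
  born1 <- length(born_u) == 1
  tau <- cfg$relocation_time
  targets <- sort(cfg$post_sep_targets)

  # trajectory stages (all in pole coordinates u: old pole = 0)
  sep_time <- if (born1) birth + drawn$t_sep_frac * drawn$gen_time else NA
  con_time <- birth + drawn$t_con_frac * drawn$gen_time

  if (born1) {
    stage1 <- list(t0 = birth, u0 = born_u, target = 0.5)
    u_at_sep <- relax_to(sep_time, stage1$t0, stage1$u0, stage1$target, tau)
    stage2 <- list(
      t0 = sep_time,
      u0 = clamp(c(u_at_sep - cfg$sep_jump, u_at_sep + cfg$sep_jump),
                 0.02, 0.98),
      target = targets)
  } else {
    stage1 <- NULL
    ord <- order(born_u)
    stage2 <- list(t0 = birth, u0 = born_u[ord], target = targets)
  }
  two_foci_from <- stage2$t0

  late_time <- birth + cfg$late_split_frac * drawn$gen_time
  stage3 <- NULL
  if (cfg$overlap_rounds && any(drawn$split_flags) &&
      late_time > two_foci_from && late_time < division) {
    p2 <- relax_to(late_time, stage2$t0, stage2$u0, stage2$target, tau)
    u0 <- c(); tg <- c()
    for (k in 1:2) {
      if (drawn$split_flags[k]) {
        u0 <- c(u0, clamp(c(p2[k] - 0.04, p2[k] + 0.04), 0.02, 0.98))
        tg <- c(tg, stage2$target[k] - 0.05, stage2$target[k] + 0.05)
      } else {
        u0 <- c(u0, p2[k]); tg <- c(tg, stage2$target[k])
      }
    }
    stage3 <- list(t0 = late_time, u0 = u0, target = tg)
  }

  positions_at <- function(t) {
    if (!is.null(stage3) && t >= stage3$t0) {
      relax_to(t, stage3$t0, stage3$u0, stage3$target, tau)
    } else if (t >= two_foci_from) {
      relax_to(t, stage2$t0, stage2$u0, stage2$target, tau)
    } else {
      relax_to(t, stage1$t0, stage1$u0, stage1$target, tau)
    }
  }

  # frames this cell is alive and imaged
  divides <- cfg$scission_enabled && division <= duration
  t_end <- if (cfg$scission_enabled) min(division, duration + 1e-9) else
    duration + 1e-9
  k0 <- max(ceiling(birth / cfg$frame_interval - 1e-9), 0L)
  k1 <- floor(t_end / cfg$frame_interval + 1e-9)
  kk <- if (k1 >= k0) seq.int(k0, k1) else integer(0)
  tt <- kk * cfg$frame_interval
  keep <- tt >= birth - 1e-9 & (tt < division - 1e-9 | !cfg$scission_enabled)
  kk <- kk[keep]; tt <- tt[keep]

  lengths <- drawn$birth_length * exp(cfg$growth_rate * (tt - birth))
  septum_depth <- ifelse(
    !cfg$scission_enabled | tt < con_time, 0,
    pmin(0.9, 0.3 + 0.6 * (tt - con_time) /
           max(division - con_time, cfg$frame_interval)))

  path_key <- gsub("[^LR]", "", spec$id)
  foci_rows <- vector("list", length(tt))
  nf <- integer(length(tt))
  ji <- 0L
  for (i in seq_along(tt)) {
    u <- positions_at(tt[i])
    jit <- drawn$jitter[ji + seq_along(u)]
    jit[is.na(jit)] <- 0
    ji <- ji + length(u)
    u <- clamp(u + jit, 0.01, 0.99)
    nf[i] <- length(u)
    foci_rows[[i]] <- tibble::tibble(
      cell_id = spec$id, frame = kk[i], time = tt[i],
      focus_id = seq_along(u), u = u,
      x_rel = if (spec$old_pole_left) u else 1 - u)
  }

  frames <- tibble::tibble(
    cell_id = spec$id, founder = spec$founder, path_key = path_key,
    frame = kk, time = tt, length_um = lengths,
    constricting = cfg$scission_enabled & tt >= con_time - 1e-9,
    septum_depth = septum_depth, n_foci = nf,
    old_pole_left = spec$old_pole_left)

  daughters <- list()
  if (divides) {
    u_div <- clamp(positions_at(division), 0.01, 0.99)
    old_half <- u_div < 0.5
    u_old <- 2 * u_div[old_half]             # daughter with mother's old pole
    u_new <- 2 * (1 - u_div[!old_half])      # daughter with mother's new pole
    L_d <- drawn$birth_length * exp(cfg$growth_rate * drawn$gen_time) / 2
    # lane sides: mother's old pole sits lane-left iff old_pole_left
    left_u <- if (spec$old_pole_left) u_old else u_new
    right_u <- if (spec$old_pole_left) u_new else u_old
    witnessed <- division > 1e-9   # divisions before time 0 are unobserved
    mk <- function(side, uu) {
      list(id = paste0(spec$id, ":", side), founder = spec$founder,
           mother = spec$id, birth = division, birth_length = L_d,
           old_pole_left = (side == "L"), polarity_known = witnessed,
           birth_observed = witnessed, born_u = sort(uu))
    }
    if (length(left_u)) daughters <- c(daughters, list(mk("L", left_u)))
    if (length(right_u)) daughters <- c(daughters, list(mk("R", right_u)))
  }

  cell <- tibble::tibble(
    cell_id = spec$id, founder = spec$founder,
    mother_id = spec$mother, birth_time = birth,
    division_time = if (cfg$scission_enabled) division else NA_real_,
    divided = divides,
    birth_length = drawn$birth_length, gen_time = drawn$gen_time,
    t_sep_frac = if (born1) drawn$t_sep_frac else NA_real_,
    t_con_frac = drawn$t_con_frac,
    sep_time = if (born1) sep_time else NA_real_,
    con_time = con_time,
    born_foci = length(born_u),
    old_pole_left = spec$old_pole_left,
    polarity_known = spec$polarity_known,
    birth_observed = spec$birth_observed,
    complete = spec$birth_observed && divides)

  list(cell = cell, frames = frames,
       foci = dplyr::bind_rows(foci_rows), daughters = daughters)
}

#' Snapshot a simulated population with arbitrary cell orientation
#'
#' Emulates a snapshot experiment on agar pads: one observation per cell
#' alive at `time`, with each cell's orientation mirrored with probability
#' 1/2 (seeded, stable per cell) so that pole identity is discarded, as in
#' snapshot image analysis where genealogy is unknown.
#'
#' @param population A `cell_population` from [simulate_population()].
#' @param time Time (min) at which to sample; snapped to the nearest frame.
#' @param seed Integer seed for the orientation coin flips.
#' @return A tibble with one row per cell: `cell_id`, `time`, `length_um`,
#'   `constricting`, `n_foci`, `flipped`, and a list-column `foci_x` of
#'   relative long-axis focus positions in the reported (possibly mirrored)
#'   orientation.
#' @export
snapshot_sample <- function(population, time, seed) {
  stopifnot(inherits(population, "cell_population"))
  dt <- population$config$frame_interval
  k <- round(time / dt)
  fr <- dplyr::filter(population$frames, .data$frame == k)
  if (!nrow(fr)) {
    stop("no cells alive at the requested time.", call. = FALSE)
  }
  fo <- dplyr::filter(population$foci, .data$frame == k)
  fr |>
    dplyr::mutate(
      flipped = vapply(.data$cell_id, function(id) {
        local_seed(stable_hash(paste0(seed, "/flip/", id)),
                   runif(1) < 0.5)
      }, logical(1)),
      foci_x = purrr::map2(.data$cell_id, .data$flipped, function(id, fl) {
        x <- fo$x_rel[fo$cell_id == id]
        if (fl) 1 - x else x
      }),
      time = .data$time) |>
    dplyr::select("cell_id", "time", "length_um", "constricting",
                  "n_foci", "flipped", "foci_x")
}
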
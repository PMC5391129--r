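#' Simulation configuration for synthetic cell lineages and movies
#'
#' Builds the parameter set that drives [simulate_population()] and
#' [render_movie()]. Every parameter has a documented default; named presets
#' bundle the growth conditions used throughout the package. Cell-cycle
#' timings are expressed as fractions of the cell cycle (0 = birth,
#' 1 = division): `t_sep` is when sister foci of the tracked terminus locus
#' visibly separate, `t_con` when the division-septum constriction first
#' becomes optically detectable.
#'
#' Presets (all fields fully populated, only highlights listed):
#' \describe{
#'   \item{`"Ec-slow"`}{Slow-growing *E. coli* (92 min generation time,
#'     4 min frames): sister termini separate at ~80% of the cycle,
#'     coincident with constriction onset; the single focus is born
#'     new-pole-proximal.}
#'   \item{`"Ec-fast"`}{Fast-growing *E. coli* (40 min, 2 min frames):
#'     separation at ~40% of the cycle, well before constriction (~60%);
#'     overlapping replication rounds enabled, so late 3--4 foci splitting
#'     occurs and some cells are born with two foci.}
#'   \item{`"Vc-slow"`, `"Vc-fast"`}{*V. cholerae*-like choreography: the
#'     focus is polar at birth, reaches mid-cell, and sister separation
#'     trails constriction onset.}
#'   \item{`"dMatP"`}{Slow growth with premature terminus release
#'     (separation at ~55% of the cycle), emulating loss of the
#'     MatP/matS tether.}
#'   \item{`"ftsK-ATP-"`}{Slow growth with separation deferred to the very
#'     end of the cycle, emulating a translocation-dead FtsK motor.}
#' }
#'
#' @param preset Optional preset name (see Details); `...` overrides
#'   individual fields.
#' @param ... Named fields overriding the preset/defaults:
#' \describe{
#'   \item{generation_time}{Mean cell-cycle duration (min).}
#'   \item{growth_rate}{Exponential elongation rate (1/min); defaults to
#'     `log(2)/generation_time` so cells double in length per cycle.}
#'   \item{gen_time_sd}{Between-cell sd of the cycle duration (min).}
#'   \item{birth_length_mean, birth_length_cv}{Founder birth length (um)
#'     and coefficient of variation.}
#'   \item{width_um}{Cell width (um), fixed.}
#'   \item{t_sep_mean, t_sep_sd}{Cycle fraction of sister-focus separation
#'     (truncated normal).}
#'   \item{t_con_mean, t_con_sd}{Cycle fraction of first optically visible
#'     constriction.}
#'   \item{sep_hazard}{Optional constant separation hazard (1/min). When
#'     finite, the separation *time after birth* is exponential with this
#'     rate (truncated to the cycle) instead of a truncated-normal cycle
#'     fraction; used for duplication-rate calibration.}
#'   \item{birth_focus_position}{Relative long-axis position of the focus
#'     at birth, old pole = 0, new pole = 1.}
#'   \item{post_sep_targets}{Pair of relative positions sister foci relocate
#'     to after separation (default 0.25, 0.75).}
#'   \item{relocation_time}{Relaxation time constant of focus movement
#'     toward its target (min).}
#'   \item{sep_jump}{Half-separation (cell-length fraction) imposed the
#'     moment sisters split, so two resolvable foci appear at once.}
#'   \item{focus_jitter_sd}{Per-frame positional jitter sd (cell-length
#'     fraction).}
#'   \item{overlap_rounds}{Enable overlapping replication rounds: cells with
#'     two foci may split them late in the cycle (3--4 foci) and their
#'     daughters are then born with two foci.}
#'   \item{late_split_frac, p_late}{Cycle fraction at which late splitting
#'     happens and its per-focus probability.}
#'   \item{scission_enabled}{If `FALSE`, cells elongate without dividing
#'     (filament / cephalexin mode).}
#'   \item{frame_interval}{Imaging interval (min).}
#'   \item{pixel_size}{um per pixel.}
#'   \item{psf_sigma}{Gaussian point-spread sd of the fluorescence channel
#'     (um).}
#'   \item{background, spot_amplitude, noise_sd}{Fluorescence intensity
#'     offset, per-spot peak amplitude, additive Gaussian noise sd.}
#'   \item{n_stack_planes, stack_range_um}{Bright-field defocus stack: plane
#'     count (default 32) spanning +/- `stack_range_um` (default 1.6 um).}
#'   \item{bf_contrast, bf_noise_sd}{Bright-field cell-body contrast
#'     amplitude and per-plane noise sd.}
#'   \item{gap_um}{Gap opened between sibling cells at scission (um).}
#'   \item{seed}{Default master seed recorded in the config.}
#' }
#' @return A list with class `sim_config`.
#' @examples
#' cfg <- sim_config("Ec-slow")
#' cfg$t_sep_mean
#' @export
sim_config <- function(preset = NULL, ...) {
  base <- list(
    generation_time = 60,
    growth_rate = NA_real_,
    gen_time_sd = 2,
    birth_length_mean = 2.0,
    birth_length_cv = 0.07,
    width_um = 1.0,
    t_sep_mean = 0.8, t_sep_sd = 0.05,
    t_con_mean = 0.8, t_con_sd = 0.05,
    sep_hazard = NA_real_,
    birth_focus_position = 0.8,
    post_sep_targets = c(0.25, 0.75),
    relocation_time = 6,
    sep_jump = 0.06,
    focus_jitter_sd = 0.01,
    overlap_rounds = FALSE,
    late_split_frac = 0.9,
    p_late = 0.4,
    scission_enabled = TRUE,
    frame_interval = 4,
    pixel_size = 0.064,
    psf_sigma = 0.08,
    background = 100,
    spot_amplitude = 500,
    noise_sd = 5,
    n_stack_planes = 32,
    stack_range_um = 1.6,
    bf_contrast = 60,
    bf_noise_sd = 3,
    gap_um = 0.45,
    seed = 1L)

  presets <- list(
    "Ec-slow" = list(generation_time = 92, gen_time_sd = 3,
                     birth_length_mean = 2.0,
                     t_sep_mean = 0.80, t_con_mean = 0.80,
                     birth_focus_position = 0.8, frame_interval = 4),
    "Ec-fast" = list(generation_time = 40, gen_time_sd = 1.5,
                     birth_length_mean = 2.5,
                     t_sep_mean = 0.40, t_con_mean = 0.60,
                     birth_focus_position = 0.55, overlap_rounds = TRUE,
                     frame_interval = 2),
    "Vc-slow" = list(generation_time = 80, gen_time_sd = 2.5,
                     birth_length_mean = 1.6,
                     t_sep_mean = 0.90, t_con_mean = 0.80,
                     birth_focus_position = 0.95, frame_interval = 4),
    "Vc-fast" = list(generation_time = 23, gen_time_sd = 1,
                     birth_length_mean = 1.8,
                     t_sep_mean = 0.85, t_con_mean = 0.70,
                     birth_focus_position = 0.9, frame_interval = 2),
    "dMatP"   = list(generation_time = 92, gen_time_sd = 3,
                     birth_length_mean = 2.0,
                     t_sep_mean = 0.55, t_con_mean = 0.80,
                     birth_focus_position = 0.8, frame_interval = 4),
    "ftsK-ATP-" = list(generation_time = 92, gen_time_sd = 3,
                       birth_length_mean = 2.0,
                       t_sep_mean = 0.97, t_sep_sd = 0.02,
                       t_con_mean = 0.85,
                       birth_focus_position = 0.8, frame_interval = 4))

  cfg <- base
  if (!is.null(preset)) {
    if (!preset %in% names(presets)) {
      stop("unknown preset '", preset, "'; available: ",
           paste(names(presets), collapse = ", "), call. = FALSE)
    }
    cfg <- modifyList(cfg, presets[[preset]])
    cfg$preset <- preset
  }
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), c(names(base), "preset"))
    if (length(bad)) {
      stop("unknown sim_config field(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    cfg <- modifyList(cfg, dots)
  }
  if (is.na(cfg$growth_rate)) {
    cfg$growth_rate <- log(2) / cfg$generation_time
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot_msg <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  stopifnot_msg(cfg$generation_time > 0, "generation_time must be > 0")
  stopifnot_msg(cfg$frame_interval > 0, "frame_interval must be > 0")
  for (fld in c("t_sep_mean", "t_con_mean", "birth_focus_position",
                "late_split_frac")) {
    stopifnot_msg(cfg[[fld]] >= 0 && cfg[[fld]] <= 1,
                  paste(fld, "must lie in [0, 1]"))
  }
  for (fld in c("t_sep_sd", "t_con_sd", "gen_time_sd", "focus_jitter_sd",
                "birth_length_cv", "noise_sd", "bf_noise_sd")) {
    stopifnot_msg(cfg[[fld]] >= 0, paste(fld, "must be >= 0"))
  }
  stopifnot_msg(length(cfg$post_sep_targets) == 2 &&
                  all(cfg$post_sep_targets >= 0 & cfg$post_sep_targets <= 1),
                "post_sep_targets must be two fractions in [0, 1]")
  stopifnot_msg(cfg$pixel_size > 0 && cfg$psf_sigma > 0,
                "pixel_size and psf_sigma must be > 0")
  stopifnot_msg(cfg$n_stack_planes >= 2, "n_stack_planes must be >= 2")
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>", if (!is.null(x$preset)) paste0("preset: ", x$preset),
      "\n")
  cat(sprintf("  generation time %g min (frames every %g min)\n",
              x$generation_time, x$frame_interval))
  cat(sprintf("  t_sep %.2f +/- %.2f, t_con %.2f +/- %.2f (cycle fractions)\n",
              x$t_sep_mean, x$t_sep_sd, x$t_con_mean, x$t_con_sd))
  cat(sprintf("  overlap_rounds: %s, scission: %s\n",
              x$overlap_rounds, x$scission_enabled))
  invisible(x)
}

#' Configuration of a simulated cassette-excision plating experiment
#'
#' Parameters of the stochastic plating simulator [simulate_plating()].
#' Each founder lineage carries an intact (non-recombined) cassette; at each
#' exponential-phase division the cassette excises with probability
#' `f_indep` plus, in a recA+ strain, `f_dep` (the homologous-recombination
#' -linked component). Lag and stationary phases contribute no divisions and
#' hence no recombination.
#'
#' @param f_indep recA-independent per-division excision probability.
#' @param f_dep recA-dependent per-division excision probability (applies
#'   only when `recA_plus` is `TRUE`).
#' @param recA_plus Is the strain recA+?
#' @param n_generations_exp Number of exponential-phase divisions.
#' @param lag_divisions,stationary_divisions Divisions nominally assigned to
#'   lag/stationary phases; modeled as zero actual divisions (default 0).
#' @param initial_cells Number of founder lineages followed.
#' @param colonies_sampled Colonies scored per plating.
#' @param seed Default seed recorded in the config.
#' @return A list with class `plating_sim_config`.
#' @export
plating_sim_config <- function(f_indep = 0.01, f_dep = 0.04,
                               recA_plus = TRUE,
                               n_generations_exp = 20,
                               lag_divisions = 0, stationary_divisions = 0,
                               initial_cells = 1e4,
                               colonies_sampled = 200,
                               seed = 1L) {
  if (f_indep < 0 || f_dep < 0 || f_indep + f_dep > 1) {
    stop("need 0 <= f_indep + f_dep <= 1.", call. = FALSE)
  }
  if (n_generations_exp < 0 || lag_divisions < 0 || stationary_divisions < 0) {
    stop("division counts must be >= 0.", call. = FALSE)
  }
  if (initial_cells < 1) stop("initial_cells must be >= 1.", call. = FALSE)
  if (colonies_sampled < 1) {
    stop("colonies_sampled must be >= 1 (a plating with no colonies ",
         "scores nothing).", call. = FALSE)
  }
  structure(list(
    f_indep = f_indep, f_dep = f_dep, recA_plus = recA_plus,
    n_generations_exp = n_generations_exp,
    lag_divisions = lag_divisions,
    stationary_divisions = stationary_divisions,
    initial_cells = initial_cells, colonies_sampled = colonies_sampled,
    seed = seed), class = "plating_sim_config")
}
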
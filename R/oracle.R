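#' Ground-truth observation tables under the movie observation protocol
#'
#' These helpers compute, directly from simulator ground truth, exactly
#' what an ideal measurement of a rendered movie would see, under the same
#' observation protocol as the tracker: frames lie on the imaging lattice;
#' a division only counts once two post-scission frames confirm it; a
#' septation onset is only called when the constriction is visible in two
#' consecutive frames of the mother's life. They are the independent
#' reference against which the imaging pipeline is validated — the pipeline
#' itself never reads these tables.
#'
#' @param population A `cell_population`.
#' @return `truth_cells_observed()`: the population's `cells` tibble with
#'   `div_frame`, `obs_complete` (complete cycle under the protocol) and
#'   `sept_frame` columns added.
#' @name truth-oracle
NULL

#' @rdname truth-oracle
#' @export
truth_cells_observed <- function(population) {
  dt <- population$config$frame_interval
  max_frame <- max(population$frames$frame)
  population$cells |>
    dplyr::mutate(
      div_frame = ifelse(.data$divided,
                         ceiling(.data$division_time / dt - 1e-9), NA),
      obs_complete = .data$birth_observed & .data$divided &
        !is.na(.data$div_frame) & (.data$div_frame + 1) <= max_frame,
      sept_frame = purrr::pmap_dbl(
        list(.data$con_time, .data$division_time, .data$birth_time),
        function(con, div, birth) {
          if (is.na(div)) return(NA_real_)
          f <- ceiling((con - 1e-9) / dt)
          first <- ceiling((birth - 1e-9) / dt)
          # call needs the dip visible in this frame and the next, both
          # within the mother's life, and >= 3 observed frames in total
          last <- ceiling(div / dt - 1e-9) - 1
          if (last - first + 1 < 3) return(NA_real_)
          if (f < first) f <- first
          if (f + 1 > last) return(NA_real_)
          f
        }))
}

#' @rdname truth-oracle
#' @param complete_only Restrict to protocol-complete cells (default).
#' @return `truth_observations()`: tibble `cell_id`, `frame`, `time`,
#'   `length_um`, `n_foci`.
#' @export
truth_observations <- function(population, complete_only = TRUE) {
  keep <- truth_cells_observed(population)
  if (complete_only) keep <- dplyr::filter(keep, .data$obs_complete)
  population$frames |>
    dplyr::semi_join(keep, by = "cell_id") |>
    dplyr::select("cell_id", "frame", "time", "length_um", "n_foci")
}

#' @rdname truth-oracle
#' @return `truth_septation()`: tibble `cell_id`, `sept_frame` for
#'   protocol-complete cells.
#' @export
truth_septation <- function(population) {
  truth_cells_observed(population) |>
    dplyr::filter(.data$obs_complete) |>
    dplyr::transmute(.data$cell_id,
                     sept_frame = as.integer(.data$sept_frame))
}

#' @rdname truth-oracle
#' @return `truth_foci_table()`: tibble `cell_id`, `frame`, `x` (old pole
#'   = 0), `d` for protocol-complete cells.
#' @export
truth_foci_table <- function(population, complete_only = TRUE) {
  keep <- truth_cells_observed(population)
  if (complete_only) keep <- dplyr::filter(keep, .data$obs_complete)
  population$foci |>
    dplyr::semi_join(keep, by = "cell_id") |>
    dplyr::transmute(.data$cell_id, .data$frame, x = .data$u,
                     d = abs(.data$u - 0.5))
}
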
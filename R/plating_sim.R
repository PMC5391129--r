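#' Simulate a cassette-excision plating experiment
#'
#' Follows `initial_cells` founder lineages through a lag phase (no
#' divisions), `n_generations_exp` exponential-phase divisions, and a
#' stationary phase (no divisions). At each exponential division a lineage
#' still carrying the intact cassette excises it with probability
#' `f_indep` (+ `f_dep` when the strain is recA+); excision is irreversible.
#' The initial and final platings then score `colonies_sampled` colonies by
#' binomial sampling of the lineage non-recombined fraction. Culture cell
#' counts follow deterministic doubling, `Nf = Ni * 2^n`.
#'
#' @param pcfg A [plating_sim_config()].
#' @param seed Integer seed; defaults to the seed recorded in `pcfg`.
#' @param replicate Replicate identifier stored in the output row.
#' @return A one-row tibble with columns `replicate`, `Ni`, `Nf`,
#'   `colonies_total_i`, `colonies_white_i`, `colonies_total_f`,
#'   `colonies_white_f`, plus the latent truth `true_f` (per-division
#'   excision probability in effect) and `true_nonrec_fraction` (lineage
#'   fraction still non-recombined at plating). White colonies are the
#'   recombined ones (excision abolishes beta-galactosidase).
#' @examples
#' simulate_plating(plating_sim_config(f_indep = 0.01, f_dep = 0.04))
#' @export
simulate_plating <- function(pcfg, seed = pcfg$seed, replicate = 1L) {
  stopifnot(inherits(pcfg, "plating_sim_config"))
  f <- pcfg$f_indep + if (pcfg$recA_plus) pcfg$f_dep else 0
  local_seed(seed, {
    # lag: no divisions, no recombination
    nonrec <- pcfg$initial_cells
    # initial plating happens before induction of exponential growth
    white_i <- rbinom(1, pcfg$colonies_sampled,
                      1 - nonrec / pcfg$initial_cells)
    for (g in seq_len(pcfg$n_generations_exp)) {
      nonrec <- rbinom(1, nonrec, 1 - f)
    }
    # stationary: no divisions, no recombination
    frac <- nonrec / pcfg$initial_cells
    white_f <- rbinom(1, pcfg$colonies_sampled, 1 - frac)
    tibble::tibble(
      replicate = replicate,
      Ni = pcfg$initial_cells,
      Nf = pcfg$initial_cells * 2^pcfg$n_generations_exp,
      colonies_total_i = pcfg$colonies_sampled,
      colonies_white_i = white_i,
      colonies_total_f = pcfg$colonies_sampled,
      colonies_white_f = white_f,
      true_f = f,
      true_nonrec_fraction = frac)
  })
}

#' Simulate a table of replicate plating experiments
#'
#' @inheritParams simulate_plating
#' @param n_replicates Number of independent replicate platings.
#' @return A tibble with one row per replicate (see [simulate_plating()]).
#' @export
simulate_plating_replicates <- function(pcfg, n_replicates, seed = pcfg$seed) {
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    simulate_plating(pcfg, seed = stable_hash(paste0(seed, "/rep/", r)),
                     replicate = r)
  })
}
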
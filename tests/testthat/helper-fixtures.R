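# Shared fixtures, built once per test run and memoised.
#
# The small end-to-end populations used across test files are expensive to
# render, so they are cached in this environment.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# a small slow-growth population with full ground truth
small_slow_pop <- function() {
  fixture("small_slow_pop", function() {
    cfg <- sim_config("Ec-slow")
    simulate_population(cfg, duration = 2.3 * cfg$generation_time,
                        seed = 5, n_founders = 4)
  })
}

# zero-noise rendered movie + analysis of one founder of the above
small_zero_noise <- function() {
  fixture("small_zero_noise", function() {
    pop <- small_slow_pop()
    movie <- render_movie(pop, founders = "F1", noise = FALSE)
    list(pop = pop, movie = movie, analysis = analyze_movie(movie))
  })
}

# a tiny deterministic single-cell config: no jitter, no timing noise;
# caller overrides take precedence
rigid_config <- function(...) {
  args <- list(generation_time = 40, gen_time_sd = 0, birth_length_cv = 0,
               t_sep_sd = 0, t_con_sd = 0, focus_jitter_sd = 0,
               t_sep_mean = 0.8, t_con_mean = 0.8,
               birth_focus_position = 0.8, frame_interval = 2,
               noise_sd = 0, bf_noise_sd = 0)
  dots <- list(...)
  args[names(dots)] <- dots
  do.call(sim_config, args)
}

expect_tibble <- function(x, nrow = NULL) {
  expect_s3_class(x, "tbl_df")
  if (!is.null(nrow)) expect_identical(nrow(x), as.integer(nrow))
}
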
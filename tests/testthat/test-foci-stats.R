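test_that("mid-cell fraction uses a strict 5% threshold", {
  expect_equal(midcell_fraction(c(0.01, 0.04, 0.20)), 2 / 3)
  expect_equal(midcell_fraction(rep(0.5, 4)), 0)
  expect_equal(midcell_fraction(c(0.05)), 0)          # exactly at: excluded
  expect_equal(midcell_fraction(c(0.049999)), 1)
  expect_equal(midcell_fraction(tibble::tibble(d = c(0.01, 0.2))), 0.5)
  expect_error(midcell_fraction(numeric(0)), "no foci")
})

test_that("snapshot summaries classify cells as in the figure panels", {
  cells <- tibble::tibble(
    cell_id = as.character(1:10), length_um = seq(2, 4, length.out = 10),
    constricting = FALSE, n_foci = 1L,
    foci_x = lapply(1:10, function(i) 0.5))
  ss <- snapshot_stats(cells)
  expect_identical(ss$n_cells, 10L)
  expect_identical(nrow(ss$classes), 1L)
  expect_identical(ss$classes$n_cells, 10L)
  expect_identical(ss$classes$focus_class, "1")
  expect_false(ss$classes$constricting)
  expect_equal(ss$classes$midcell_fraction, 1)
  expect_tibble(ss$positions, 10)
  empty <- snapshot_stats(cells[0, ])
  expect_identical(empty$n_cells, 0L)
  expect_identical(nrow(empty$classes), 0L)
  # class counts always partition the population
  cells$n_foci <- c(1L, 1L, 2L, 2L, 3L, 4L, 0L, 1L, 2L, 3L)
  cells$constricting <- rep(c(FALSE, TRUE), 5)
  ss2 <- snapshot_stats(cells)
  expect_identical(sum(ss2$classes$n_cells), 10L)
})

test_that("septation alignment re-indexes time and tallies focus classes", {
  obs <- tibble::tibble(
    cell_id = rep(c("a", "b"), each = 5),
    frame = rep(3:7, 2),
    n_foci = c(1L, 1L, 1L, 2L, 2L,   2L, 2L, 2L, 2L, 3L))
  sept <- tibble::tibble(cell_id = c("a", "b"), sept_frame = c(7L, 5L))
  al <- align_to_septation(obs, sept, frame_interval = 2)
  tb <- tibble::as_tibble(al)
  # cell a's frame 7 maps to offset 0; cell b's frame 5 likewise
  expect_true(0 %in% tb$offset)
  at0 <- tb[tb$offset == 0, ]
  expect_identical(at0$n_cells, 2L)
  expect_identical(at0$n1, 0L)       # both cells already >= 2 foci at 0
  expect_equal(at0$freq2, 1)
  # frequencies sum to one wherever no zero-focus cells contribute
  expect_true(all(abs(tb$freq1 + tb$freq2 + tb$freq3p - 1) < 1e-12))
  expect_true(all(diff(tb$offset) == 2))
  expect_error(align_to_septation(obs, sept[0, ], 2), "no cell")
})

test_that("duplication rate counts persistent 1-to-2 transitions per minute", {
  # 50 at-risk cells at offset 0, 10 duplicate over one 2-min frame
  obs <- tibble::tibble(
    cell_id = rep(sprintf("c%02d", 1:50), each = 3),
    frame = rep(0:2, 50),
    n_foci = 1L)
  obs$n_foci[obs$frame >= 1 & obs$cell_id %in% sprintf("c%02d", 1:10)] <- 2L
  sept <- tibble::tibble(cell_id = unique(obs$cell_id), sept_frame = 0L)
  al <- align_to_septation(obs, sept, frame_interval = 2)
  expect_equal(duplication_rate(al, 0), (10 / 50) / 2 * 100)
  # a blink (2 then back to 1) does not count
  obs2 <- obs
  obs2$n_foci[obs2$frame == 2 & obs2$cell_id == "c01"] <- 1L
  al2 <- align_to_septation(obs2, sept, frame_interval = 2)
  expect_equal(duplication_rate(al2, 0), (9 / 50) / 2 * 100)
  # zero transitions give a zero rate; no at-risk cells give an error
  obs3 <- dplyr::mutate(obs, n_foci = 2L)
  al3 <- align_to_septation(obs3, sept, 2)
  expect_error(duplication_rate(al3, 0), "at-risk")
  obs4 <- dplyr::mutate(obs, n_foci = 1L)
  al4 <- align_to_septation(obs4, sept, 2)
  expect_equal(duplication_rate(al4, 0), 0)
})

test_that("hazard-mode separation is recovered by the duplication rate", {
  h <- 0.02  # per minute
  cfg <- sim_config("Ec-slow", sep_hazard = h, t_con_mean = 0.5,
                    focus_jitter_sd = 0)
  pop <- simulate_population(cfg, duration = 2.2 * cfg$generation_time,
                             seed = 21, n_founders = 120)
  al <- align_to_septation(truth_observations(pop), truth_septation(pop),
                           cfg$frame_interval)
  dt <- cfg$frame_interval
  expected <- 100 * (1 - exp(-h * dt)) / dt
  percell <- attr(al, "percell")
  for (off in c(-8, 0)) {
    n_risk <- sum(percell$offset == off & percell$n_foci == 1)
    rate <- duplication_rate(al, off)
    p_hat <- rate * dt / 100
    se <- 100 * sqrt(p_hat * (1 - p_hat) / n_risk) / dt
    expect_lt(abs(rate - expected), 3 * max(se, 1e-6))
  }
})

test_that("random snapshot orientation symmetrises the position distribution", {
  cfg <- sim_config("Ec-slow", birth_focus_position = 0.85)
  pop <- simulate_population(cfg, duration = 2.3 * cfg$generation_time,
                             seed = 17, n_founders = 60)
  xs <- unlist(snapshot_sample(pop, time = 150, seed = 2)$foci_x)
  off <- xs[abs(xs - 0.5) > 1e-6]
  n_left <- sum(off < 0.5)
  p <- stats::binom.test(n_left, length(off), 0.5)$p.value
  expect_gt(p, 0.01)
})
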
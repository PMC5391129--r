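test_that("presets fully populate valid configurations", {
  for (p in c("Ec-slow", "Ec-fast", "Vc-slow", "Vc-fast", "dMatP",
              "ftsK-ATP-")) {
    cfg <- sim_config(p)
    expect_true(all(c(cfg$t_sep_mean, cfg$t_con_mean) >= 0))
    expect_true(all(c(cfg$t_sep_mean, cfg$t_con_mean) <= 1))
    expect_gt(cfg$frame_interval, 0)
    expect_gte(cfg$t_sep_sd, 0)
    expect_length(cfg$post_sep_targets, 2)
    # every numeric field populated (sep_hazard is deliberately NA-able)
    num <- cfg[setdiff(names(cfg), c("preset", "sep_hazard"))]
    expect_false(any(vapply(num, function(x) anyNA(x), logical(1))))
  }
  # fast growth separates before constriction; slow growth coincides
  expect_lt(sim_config("Ec-fast")$t_sep_mean,
            sim_config("Ec-fast")$t_con_mean)
  expect_equal(sim_config("Ec-slow")$t_sep_mean,
               sim_config("Ec-slow")$t_con_mean)
  expect_error(sim_config("nope"), "unknown preset")
  expect_error(sim_config(t_sep_mean = 1.5), "\\[0, 1\\]")
  expect_error(sim_config(bogus_field = 1), "unknown sim_config")
})

test_that("a rigid cell shows 1 focus at mid-cell before separation, 2 after", {
  cfg <- rigid_config()
  pop <- simulate_population(cfg, duration = 40, seed = 1,
                             founder_phase = 0)
  fr <- pop$foci
  # cycle fraction 0.5 (t = 20): single focus, relaxed to mid-cell
  at_half <- fr[fr$time == 20, ]
  expect_identical(nrow(at_half), 1L)
  expect_lt(abs(at_half$u - 0.5), 0.02)
  # cycle fraction 0.9 (t = 36 > t_sep = 32): two foci
  at_late <- fr[fr$time == 36, ]
  expect_identical(nrow(at_late), 2L)
  expect_true(all(abs(at_late$u - 0.5) > 0.02))
})

test_that("deterministic growth doubles the population every generation", {
  cfg <- rigid_config()
  pop <- simulate_population(cfg, duration = 120, seed = 1,
                             founder_phase = 0)
  final <- pop$frames[pop$frames$frame == max(pop$frames$frame), ]
  expect_identical(nrow(final), 8L)     # 2^3 after 3 generations
  expect_error(simulate_population(cfg, duration = 10, seed = 1),
               "one generation")
})

test_that("identical seeds reproduce the population bit for bit", {
  cfg <- sim_config("Ec-fast")
  a <- simulate_population(cfg, duration = 60, seed = 9, n_founders = 2)
  b <- simulate_population(cfg, duration = 60, seed = 9, n_founders = 2)
  expect_identical(a$cells, b$cells)
  expect_identical(a$frames, b$frames)
  expect_identical(a$foci, b$foci)
  c3 <- simulate_population(cfg, duration = 60, seed = 10, n_founders = 2)
  expect_false(identical(a$foci, c3$foci))
})

test_that("per-cell streams are stable under population growth", {
  cfg <- sim_config("Ec-fast")
  a <- simulate_population(cfg, duration = 60, seed = 9, n_founders = 1)
  b <- simulate_population(cfg, duration = 60, seed = 9, n_founders = 3)
  shared <- intersect(a$cells$cell_id, b$cells$cell_id)
  expect_identical(
    a$cells[a$cells$cell_id %in% shared, ],
    b$cells[b$cells$cell_id %in% shared & b$cells$founder == "F1", ])
})

test_that("scission conserves foci between mother and daughters", {
  pop <- small_slow_pop()
  div <- pop$cells[pop$cells$divided & pop$cells$birth_time >= 0, ]
  checked <- 0L
  for (i in seq_len(nrow(div))) {
    kids <- pop$cells[!is.na(pop$cells$mother_id) &
                        pop$cells$mother_id == div$cell_id[i], ]
    if (nrow(kids) == 0) next
    expect_identical(nrow(kids), 2L)
    expect_identical(sum(kids$born_foci), 2L)  # slow preset: 2 at division
    checked <- checked + 1L
  }
  expect_gte(checked, 3L)
})

test_that("overlapping rounds produce 3-4 focus cells and 2-focus births", {
  cfg <- sim_config("Ec-fast")
  pop <- simulate_population(cfg, duration = 3 * cfg$generation_time,
                             seed = 4, n_founders = 6)
  expect_true(any(pop$frames$n_foci >= 3))
  expect_true(all(pop$frames$n_foci <= 4))
  expect_true(any(pop$cells$born_foci == 2))
  # conservation at each division: daughters inherit all mother foci
  div <- pop$cells[pop$cells$divided, ]
  for (i in seq_len(nrow(div))) {
    kids <- pop$cells[!is.na(pop$cells$mother_id) &
                        pop$cells$mother_id == div$cell_id[i], ]
    if (nrow(kids) < 2) next
    mother_last <- pop$frames[pop$frames$cell_id == div$cell_id[i], ]
    if (!nrow(mother_last)) next
    n_last <- mother_last$n_foci[which.max(mother_last$frame)]
    # foci can still split between the last imaged frame and scission
    expect_gte(sum(kids$born_foci), n_last)
    expect_lte(sum(kids$born_foci), 4L)
  }
})

test_that("snapshot sampling mirrors cells and discards pole identity", {
  cfg <- rigid_config(birth_focus_position = 0.2, relocation_time = 1e6)
  pop <- simulate_population(cfg, duration = 40, seed = 2,
                             founder_phase = 0)
  snap <- snapshot_sample(pop, time = 10, seed = 3)
  expect_tibble(snap, 1)
  x <- snap$foci_x[[1]]
  u <- pop$foci$u[pop$foci$time == 10]
  expect_equal(x, if (snap$flipped) 1 - u else u, tolerance = 1e-9)

  # population snapshot: lengths span birth to division (factor >= 2)
  cfg2 <- sim_config("Ec-slow")
  pop2 <- simulate_population(cfg2, duration = 2.3 * cfg2$generation_time,
                              seed = 8, n_founders = 12)
  snap2 <- snapshot_sample(pop2, time = 180, seed = 1)
  expect_gte(max(snap2$length_um) / min(snap2$length_um), 1.8)
  # mid-cycle slow growth: every cell shows a single focus at zero noise
  cfg3 <- rigid_config()
  pop3 <- simulate_population(cfg3, duration = 40, seed = 1,
                              founder_phase = 0)
  snap3 <- snapshot_sample(pop3, time = 20, seed = 1)
  expect_true(all(snap3$n_foci == 1))
})

test_that("plating config enforces probability and count bounds", {
  expect_error(plating_sim_config(f_indep = 0.6, f_dep = 0.6), "<= 1")
  expect_error(plating_sim_config(colonies_sampled = 0), ">= 1")
  expect_error(plating_sim_config(initial_cells = 0), ">= 1")
})
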
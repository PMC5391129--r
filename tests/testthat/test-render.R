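test_that("an empty scene renders pure background with the configured noise", {
  cfg <- sim_config("Ec-slow", noise_sd = 4)
  pop <- simulate_population(cfg, duration = 100, seed = 1)
  # restrict to a founder id that does not exist -> empty scene
  mv <- render_movie(pop, founders = "nope", frames = 0L)
  img <- mv$frames[[1]]$fluor
  expect_equal(mean(img), cfg$background, tolerance = 0.5)
  expect_equal(sd(as.vector(img)), 4, tolerance = 0.5)
})

test_that("zero-noise fluorescence peaks at the true focus pixels", {
  cfg <- rigid_config()
  pop <- simulate_population(cfg, duration = 40, seed = 1,
                             founder_phase = 0)
  mv <- render_movie(pop, frames = 10L, noise = FALSE)
  img <- mv$frames[[1]]$fluor
  tf <- mv$truth$foci[mv$truth$foci$frame == 10, ]
  expect_identical(nrow(tf), 1L)
  peak <- which(img == max(img), arr.ind = TRUE)[1, ]
  expect_equal(unname(peak["col"] - 1),
               unname(floor(tf$x_img_um / mv$pixel_size)), tolerance = 1)
  expect_equal(unname(peak["row"] - 1),
               unname(floor(tf$y_img_um / mv$pixel_size)), tolerance = 1)
})

test_that("rendering fidelity: all local fluorescence maxima sit within 1 px of truth", {
  cfg <- sim_config("Ec-fast", noise_sd = 0, bf_noise_sd = 0,
                    focus_jitter_sd = 0)
  pop <- simulate_population(cfg, duration = 2.2 * cfg$generation_time,
                             seed = 6, n_founders = 2)
  k <- 30L
  mv <- render_movie(pop, frames = k, noise = FALSE)
  img <- mv$frames[[1]]$fluor
  tf <- mv$truth$foci[mv$truth$foci$frame == k, ]
  for (i in seq_len(nrow(tf))) {
    cx <- floor(tf$x_img_um[i] / mv$pixel_size) + 1
    cy <- floor(tf$y_img_um[i] / mv$pixel_size) + 1
    patch <- img[(cy - 2):(cy + 2), (cx - 2):(cx + 2)]
    peak <- which(patch == max(patch), arr.ind = TRUE)[1, ]
    expect_lte(max(abs(peak - 3)), 1)
  }
})

test_that("a constricting cell's shape profile dips in the central 30%", {
  cfg <- rigid_config(t_con_mean = 0.6)
  pop <- simulate_population(cfg, duration = 40, seed = 1,
                             founder_phase = 0)
  k <- 17L   # t = 34 min = 85% of the cycle, past constriction onset
  mv <- render_movie(pop, frames = k, noise = FALSE)
  sh <- reconstruct_shape_image(mv$frames[[1]]$bf_stack,
                                pixel_size = mv$pixel_size)
  seg <- segment_cells(sh, pixel_size = mv$pixel_size)
  expect_identical(nrow(seg), 1L)
  p <- as.numeric(long_axis_profile(unclass(sh), seg[1, ], 41))
  rel <- (which.min(p[6:36]) + 5 - 0.5) / 41   # search away from poles
  expect_gt(rel, 0.35)
  expect_lt(rel, 0.65)
})

test_that("thresholded shape masks recover the true cell footprint (IoU >= 0.8)", {
  sz <- small_zero_noise()
  mv <- sz$movie
  k <- mv$frame_index[20]
  sh <- reconstruct_shape_image(mv$frames[[20]]$bf_stack,
                                pixel_size = mv$pixel_size)
  seg <- segment_cells(sh, pixel_size = mv$pixel_size)
  lab_true <- true_label_mask(mv, k)
  lab_seg <- region_label_matrix(seg)
  for (id in unique(lab_true[lab_true > 0])) {
    truth <- lab_true == id
    best <- 0
    for (sid in unique(lab_seg[lab_seg > 0])) {
      got <- lab_seg == sid
      iou <- sum(truth & got) / sum(truth | got)
      best <- max(best, iou)
    }
    expect_gte(best, 0.8)
  }
})

test_that("movies round-trip through TIFF with sidecar truth and config", {
  cfg <- sim_config("Ec-fast")
  pop <- simulate_population(cfg, duration = 1.3 * cfg$generation_time,
                             seed = 2, n_founders = 1)
  mv <- render_movie(pop)
  td <- withr::local_tempdir()
  files <- write_movie_tiff(mv, td, "roundtrip")
  expect_true(all(file.exists(files)))
  truth <- read.csv(file.path(td, "roundtrip_truth.csv"))
  expect_true(all(c("cell_id", "frame", "length_um", "n_foci") %in%
                    names(truth)))
  cfg_back <- yaml::read_yaml(file.path(td, "roundtrip_config.yaml"))
  expect_equal(cfg_back$generation_time, cfg$generation_time)
  mv2 <- read_movie_tiff(file.path(td, "roundtrip_fluor.tif"),
                         file.path(td, "roundtrip_bf.tif"),
                         pixel_size = cfg$pixel_size,
                         frame_interval = cfg$frame_interval,
                         n_stack_planes = cfg$n_stack_planes)
  expect_identical(length(mv2$frames), length(mv$frames))
  expect_identical(dim(mv2$frames[[1]]$bf_stack),
                   dim(mv$frames[[1]]$bf_stack))
})
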
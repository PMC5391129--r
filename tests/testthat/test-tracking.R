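# build a synthetic segmentation table from rectangles (no rendering)
fake_frame <- function(rects, dim_img = c(24, 120), pixel_size = 0.064) {
  rows <- lapply(seq_along(rects), function(i) {
    r <- rects[[i]]  # c(x0, x1, y0, y1), 0-based inclusive
    px <- as.vector(outer((r[3]:r[4]) + 1, (r[1]:r[2]) * dim_img[1], "+"))
    difcycle:::region_props(px, dim_img, pixel_size, i)
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "dim_img") <- dim_img
  attr(out, "pixel_size") <- pixel_size
  out
}

test_that("a lone cell yields one lineage with undefined polarity", {
  frames <- lapply(1:10, function(i) fake_frame(list(c(10, 40 + i, 8, 16))))
  tr <- track_and_genealogy(frames)
  expect_identical(nrow(tr$cells), 1L)
  expect_identical(tr$cells$n_frames, 10L)
  expect_false(tr$cells$divided)
  expect_true(is.na(tr$cells$old_pole_low))
  expect_false(tr$cells$polarity_known)
  expect_error(track_and_genealogy(frames[1]), "at least 2")
})

test_that("a clean one-to-two split becomes a division with facing new poles", {
  before <- list(c(10, 69, 8, 16))
  after <- list(c(10, 36, 8, 16), c(43, 69, 8, 16))
  frames <- c(lapply(1:3, function(i) fake_frame(before)),
              lapply(1:3, function(i) fake_frame(after)))
  tr <- track_and_genealogy(frames)
  cells <- tr$cells
  expect_identical(nrow(cells), 3L)
  mother <- cells[is.na(cells$mother_id), ]
  kids <- cells[!is.na(cells$mother_id), ]
  expect_true(mother$divided)
  expect_identical(mother$division_frame, 3L)
  expect_identical(nrow(kids), 2L)
  expect_true(all(kids$complete == FALSE))  # daughters have not divided
  expect_true(all(kids$birth_observed))
  expect_true(all(kids$polarity_known))
  # left daughter's new pole faces right (old pole low), and vice versa
  left <- kids[which.min(vapply(kids$track_id, function(id) {
    ob <- tr$observations[tr$observations$track_id == id, ]
    ob$region[[1]]$cx
  }, numeric(1))), ]
  right <- kids[kids$track_id != left$track_id, ]
  expect_true(left$old_pole_low)     # new pole at the high (facing) end
  expect_false(right$old_pole_low)
})

test_that("a transient split that re-merges is analysed as one cell", {
  whole <- list(c(10, 69, 8, 16))
  split <- list(c(10, 38, 8, 16), c(41, 69, 8, 16))  # 2 px gap, no move
  frames <- c(lapply(1:2, function(i) fake_frame(whole)),
              list(fake_frame(split)),
              lapply(1:2, function(i) fake_frame(whole)))
  tr <- track_and_genealogy(frames)
  expect_identical(nrow(tr$cells), 1L)
  expect_false(tr$cells$divided)
  merged <- tr$observations[tr$observations$frame == 2, ]
  expect_true(merged$merged)
  # the merged observation spans the whole pair
  expect_equal(merged$region[[1]]$length_um,
               fake_frame(whole)$length_um[1], tolerance = 0.01)
})

test_that("lineages form a forest and polarity never flips", {
  sz <- small_zero_noise()
  an <- sz$analysis
  cells <- an$tracks$cells
  # every non-root has exactly one mother, which exists
  kids <- cells[!is.na(cells$mother_id), ]
  expect_true(all(kids$mother_id %in% cells$track_id))
  expect_identical(anyDuplicated(cells$track_id), 0L)
  # mothers have at most two daughters
  expect_true(all(table(kids$mother_id) <= 2))
  # polarity is a per-cell constant by construction: recorded once
  expect_true(all(!cells$polarity_known | !is.na(cells$old_pole_low)))
})

test_that("tracking recovers the true genealogy on rendered movies", {
  cfg <- sim_config("Ec-slow")
  pop <- simulate_population(cfg, duration = 2.3 * cfg$generation_time,
                             seed = 31, n_founders = 4)
  pa <- process_population(pop, noise = TRUE, keep_kymographs = FALSE)
  checkable <- pa$match[!is.na(pa$match$mother_ok), ]
  expect_gte(nrow(checkable), 20)
  expect_gte(mean(checkable$mother_ok), 0.95)
  # complete cycles agree with the observation-protocol truth
  tco <- truth_cells_observed(pop)
  expect_setequal(na.omit(pa$cells$cell_id[pa$cells$complete]),
                  tco$cell_id[tco$obs_complete])
})
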
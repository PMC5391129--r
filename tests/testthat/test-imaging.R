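test_that("shape reconstruction projects stacks as documented", {
  const <- array(3, dim = c(8, 10, 5))
  img <- reconstruct_shape_image(const)
  expect_true(all(img == 0))
  two <- list(matrix(1:20, 4, 5), matrix(1:20, 4, 5))
  expect_true(all(reconstruct_shape_image(two, "sd") == 0))
  expect_true(all(reconstruct_shape_image(two, "range") == 0))
  expect_error(reconstruct_shape_image(list(matrix(0, 2, 2),
                                            matrix(0, 3, 3))),
               "identical dimensions")
  expect_error(reconstruct_shape_image(array(0, dim = c(4, 4, 1))),
               "at least 2")
  # sign-reversing contrast: sd picks up the cell, mean would not
  a <- matrix(0, 6, 6); a[3:4, 2:5] <- 1
  stack <- array(c(a, -a), dim = c(6, 6, 2))
  img2 <- reconstruct_shape_image(stack)
  expect_true(all(img2[a == 1] > 0))
  expect_true(all(img2[a == 0] == 0))
})

test_that("segmentation finds isolated cells and nothing in blank images", {
  sz <- small_zero_noise()
  mv <- sz$movie
  for (i in c(5, 20)) {
    sh <- reconstruct_shape_image(mv$frames[[i]]$bf_stack,
                                  pixel_size = mv$pixel_size)
    seg <- segment_cells(sh, pixel_size = mv$pixel_size)
    truth_n <- sum(mv$geometry$frame == mv$frame_index[i])
    expect_identical(nrow(seg), as.integer(truth_n))
    # masks disjoint within the frame
    all_px <- unlist(seg$pixels)
    expect_identical(anyDuplicated(all_px), 0L)
    # idempotence of the geometry summaries under re-labelling
    lab <- region_label_matrix(seg)
    expect_identical(sort(unique(as.vector(lab[lab > 0]))),
                     seg$region_id)
  }
  blank <- structure(matrix(0, 30, 30), class = "shape_image",
                     pixel_size = 0.064)
  expect_identical(nrow(segment_cells(blank, pixel_size = 0.064)), 0L)
})

test_that("region geometry reports axis-aligned lengths in microns", {
  sz <- small_zero_noise()
  mv <- sz$movie
  i <- 15
  sh <- reconstruct_shape_image(mv$frames[[i]]$bf_stack,
                                pixel_size = mv$pixel_size)
  seg <- segment_cells(sh, pixel_size = mv$pixel_size)
  g <- mv$geometry[mv$geometry$frame == mv$frame_index[i], ]
  for (r in seq_len(nrow(seg))) {
    cx_um <- (seg$cx[r] + 0.5) * mv$pixel_size
    hit <- g[g$x_left_um <= cx_um & g$x_right_um >= cx_um, ]
    expect_identical(nrow(hit), 1L)
    expect_equal(seg$length_um[r], hit$length_um, tolerance = 0.08)
    expect_gte(seg$length_um[r], seg$width_um[r])
    expect_lt(abs(sin(seg$angle[r])), 0.1)  # lanes are horizontal
  }
})

test_that("sub-pixel extent refinement stays within a pixel of the mask edges", {
  sz <- small_zero_noise()
  mv <- sz$movie
  sh <- reconstruct_shape_image(mv$frames[[15]]$bf_stack,
                                pixel_size = mv$pixel_size)
  seg <- segment_cells(sh, pixel_size = mv$pixel_size)
  for (r in seq_len(nrow(seg))) {
    ext <- refine_axial_extent(unclass(sh), seg[r, ])
    expect_lt(abs(ext[1] - (seg$proj_min[r] - 0.5)), 1.5)
    expect_lt(abs(ext[2] - (seg$proj_max[r] + 0.5)), 1.5)
    expect_gt(ext[2] - ext[1], 2)
  }
})
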
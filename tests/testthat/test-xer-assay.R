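test_that("division counts follow log2 of the fold expansion", {
  expect_equal(count_divisions(1e6, 1.024e9), 10)
  expect_equal(count_divisions(1000, 8000), 3)
  expect_equal(count_divisions(5e5, 5e5), 0)
  expect_error(count_divisions(0, 10), "positive")
  expect_error(count_divisions(1000, 500), "shrinking")
  expect_equal(count_divisions(1000, 500, allow_shrinking = TRUE), -1)
})

test_that("excision frequency reproduces the published plating estimates", {
  # E. coli LB: ~5% per generation
  expect_equal(as.numeric(excision_frequency(0.364, 19.3)), 0.05102,
               tolerance = 1e-3)
  # E. coli recA-: little more than 1% per generation
  expect_equal(as.numeric(excision_frequency(0.798, 19.9)), 0.01127,
               tolerance = 1e-3)
  # V. cholerae recA-: ~26% per generation
  expect_equal(as.numeric(excision_frequency(0.137, 6.5)), 0.26347,
               tolerance = 1e-3)
  # trivial anchors
  expect_equal(as.numeric(excision_frequency(1.0, 10)), 0)
  expect_equal(as.numeric(excision_frequency(0.25, 2)), 0.5)
})

test_that("frequencies outside the 10-90% window are flagged, invalid input errors", {
  f <- excision_frequency(0.95, 10)
  expect_match(attr(f, "warnings"), "monitoring window")
  expect_null(attr(excision_frequency(0.5, 10), "warnings"))
  expect_error(excision_frequency(0.5, 10, Ri = 0.4), "exceeds")
  expect_error(excision_frequency(0.5, 0), "positive")
  expect_error(excision_frequency(0, 10), "\\(0, 1\\]")
})

test_that("predict/estimate round-trip is exact to 1e-12 and monotone", {
  f <- seq(0, 0.9, by = 0.05)
  for (n in c(1, 7, 19.3, 30)) {
    rf <- predict_final_ratio(f, n)
    back <- as.numeric(excision_frequency(rf, n))
    expect_equal(back, f, tolerance = 1e-12)
  }
  # f strictly decreasing in Rf at fixed n, and in n at fixed Rf < 1
  rf <- seq(0.05, 0.95, by = 0.05)
  fr <- as.numeric(excision_frequency(rf, 10))
  expect_true(all(diff(fr) < 0))
  nn <- seq(2, 30, by = 2)
  fn <- as.numeric(excision_frequency(0.5, nn))
  expect_true(all(diff(fn) < 0))
})

test_that("recA-dependency matches its definition and flags negatives", {
  expect_equal(reca_dependency(0.05, 0.05), 0)
  expect_equal(reca_dependency(0.05, 0), 1)
  f_plus <- as.numeric(excision_frequency(0.364, 19.3))
  f_minus <- as.numeric(excision_frequency(0.798, 19.9))
  expect_equal(reca_dependency(f_plus, f_minus), 0.779, tolerance = 1e-2)
  expect_warning(d <- reca_dependency(0.01, 0.02), "unclamped")
  expect_equal(d, -1)
  expect_error(reca_dependency(0, 0.01), "> 0")
})

test_that("estimate_excision derives ratios from colony counts and aggregates", {
  tab <- tibble::tibble(
    replicate = 1:3,
    Ni = 1e6, Nf = 1e6 * 2^10,
    colonies_total_f = 200, colonies_white_f = c(120, 130, 110))
  fit <- estimate_excision(tab)
  expect_s3_class(fit, "excision_fit")
  td <- tidy(fit)
  expect_tibble(td, 3)
  expect_equal(td$Rf, 1 - c(120, 130, 110) / 200)
  expect_equal(td$n, rep(10, 3))
  expect_equal(glance(fit)$f, mean(td$f))
  # pooled mode applies the formula once to the pooled ratio
  pooled <- estimate_excision(tab, aggregate = "pooled")
  expect_equal(glance(pooled)$f,
               as.numeric(excision_frequency(mean(td$Rf), 10)))
})

test_that("bootstrap interval collapses for identical replicates and spans spread ones", {
  same <- tibble::tibble(replicate = 1:4, Ni = 1e6, Nf = 1e6 * 2^10,
                         Rf = 0.4)
  fit <- bootstrap_ci(same, n_boot = 200, seed = 1)
  expect_equal(fit$estimate$ci_low, fit$estimate$ci_high)
  expect_equal(fit$estimate$ci_low, fit$estimate$f)

  two <- tibble::tibble(replicate = 1:2, Ni = 1e6, Nf = 1e6 * 2^10,
                        Rf = c(0.3, 0.5))
  fit2 <- bootstrap_ci(two, n_boot = 500, seed = 2)
  fs <- as.numeric(excision_frequency(c(0.3, 0.5), 10))
  expect_lte(fit2$estimate$ci_low, max(fs))
  expect_gte(fit2$estimate$ci_high, min(fs))
  expect_error(bootstrap_ci(two[1, ], n_boot = 10, seed = 1),
               ">= 2 replicates")
  # deterministic given the seed
  fit3 <- bootstrap_ci(two, n_boot = 500, seed = 2)
  expect_identical(fit2$estimate, fit3$estimate)
})
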
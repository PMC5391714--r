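test_that("frequency is bounded by the outcrossing rate and tends to it near the source", {
  models <- random_models(30)
  for (m in models) {
    xs <- c(0.05, 0.5, 2, 10, 50, 200)
    fr <- frequency_at(m, xs)
    expect_true(all(fr >= 0 & fr <= m$t_B + 1e-15))
    # b infinite, R = 0: donor pollen saturates as x -> 0+
    expect_equal(frequency_at(m, 1e-9), m$t_B, tolerance = 1e-6)
  }
})

test_that("frequency declines monotonically with distance for the default geometry", {
  for (m in random_models(20, seed = 7)) {
    xs <- exp(seq(log(0.01), log(500), length.out = 250))
    fr <- frequency_at(m, xs)
    expect_true(all(diff(fr) <= 1e-14))
  }
})

test_that("frequency increases with outcrossing rate and crossability at fixed distance", {
  base <- list(pollen_diameter = 60, release_height = 1, wind_speed = 3)
  x <- 12
  fr_t <- vapply(c(1, 5, 20, 60), function(tb)
    frequency_at(do.call(pmgf, c(base, outcrossing_rate = tb,
                                 crossability = 90)), x), numeric(1))
  expect_true(all(diff(fr_t) > 0))
  fr_d <- vapply(c(10, 40, 70, 100), function(dl)
    frequency_at(do.call(pmgf, c(base, outcrossing_rate = 10,
                                 crossability = dl)), x), numeric(1))
  expect_true(all(diff(fr_d) > 0))
})

test_that("finite donor depth never exceeds the infinite-depth worst case", {
  for (m in random_models(15, seed = 99)) {
    for (b in c(5, 50)) {
      mb <- pmgf(pollen_diameter = m$params["pollen_diameter"],
                 release_height = m$params["release_height"],
                 outcrossing_rate = m$params["outcrossing_rate"],
                 crossability = m$params["crossability"],
                 wind_speed = m$params["wind_speed"],
                 donor_depth = b)
      xs <- c(0.5, 5, 40)
      expect_true(all(frequency_at(mb, xs) <= frequency_at(m, xs) + 1e-15))
    }
  }
})

test_that("kernel CDF is recoverable from computed frequencies by algebraic inversion", {
  # Phi(x) = delta (t_B - F) / (delta t_B + (1 - delta) F)
  for (m in random_models(25, seed = 31)) {
    xs <- c(0.2, 1, 7, 30, 120)
    F <- frequency_at(m, xs)
    phi_implied <- m$delta * (m$t_B - F) / (m$delta * m$t_B + (1 - m$delta) * F)
    expect_equal(phi_implied, kernel_cdf(m$kernel, xs), tolerance = 1e-12)
  }
})

test_that("x at or below the recipient offset yields F = t_B exactly", {
  m <- pmgf(pollen_diameter = 40, release_height = 0.5, outcrossing_rate = 1,
            crossability = 90, wind_speed = 1, recipient_offset = 2)
  expect_equal(frequency_at(m, 1.5), m$t_B)
  expect_equal(frequency_at(m, 2), m$t_B)
  expect_lt(frequency_at(m, 2.5), m$t_B)
})

test_that("frequency curves agree point-wise with scalar evaluation", {
  m <- pmgf(preset = "rice")
  cv <- frequency_curve(m, 0.3, 12, step = 0.7)
  expect_equal(cv$frequency, frequency_at(m, cv$distance))
  expect_true(all(diff(cv$distance) > 0))
  # single-point range collapses to the scalar value
  one <- frequency_curve(m, 5, 5, step = 1)
  expect_equal(nrow(one), 1L)
  expect_equal(one$frequency, frequency_at(m, 5))
  expect_error(frequency_curve(m, 10, 2), "PROPER")
  expect_error(frequency_curve(m, -1, 2), "PROPER")
})

test_that("isolation distance equals an exhaustive grid scan and brackets the threshold", {
  models <- random_models(100, seed = 404)
  for (m in models) {
    thr <- m$t_B * stats::runif(1, 0.005, 0.8)
    res <- try(isolation_distance(m, thr, x_min = 0.5, x_max = 400,
                                  resolution = 0.5), silent = TRUE)
    grid <- seq(0.5, 400, by = 0.5)
    fr <- frequency_at(m, grid)
    idx <- which(fr <= thr)
    if (!length(idx)) {
      expect_s3_class(res, "try-error")
      expect_match(attr(res, "condition")$message, "not reached")
    } else {
      expect_false(inherits(res, "try-error"))
      expect_equal(res$distance, grid[idx[1]])
      expect_lte(res$achieved_frequency, thr)
      if (res$distance > 0.5)
        expect_gt(frequency_at(m, res$distance - 0.5), thr)
    }
  }
})

test_that("thresholds at or above the outcrossing rate are met at the search start", {
  m <- pmgf(preset = "wheat")
  res <- isolation_distance(m, m$t_B, x_min = 0.1, x_max = 50)
  expect_equal(res$distance, 0.1)
})

test_that("model construction validates all five parameters and rejects x <= 0", {
  expect_error(pmgf(pollen_diameter = 1000, release_height = 0.5,
                    outcrossing_rate = 1, crossability = 90, wind_speed = 1),
               "PROPER.*pollen_diameter")
  expect_error(pmgf(preset = "rice", wind_speed = -2), "PROPER.*wind_speed")
  expect_error(pmgf(pollen_diameter = 40), "missing parameter")
  m <- pmgf(preset = "rice")
  expect_error(frequency_at(m, -5), "PROPER.*distance")
  expect_error(frequency_at(m, 0), "PROPER.*distance")
})

test_that("model methods print, summarise and predict consistently", {
  m <- pmgf(preset = "maize")
  expect_output(print(m), "maize|pollen diameter")
  expect_output(summary(m), "Gene-flow frequency")
  expect_named(coef(m), c("pollen_diameter", "release_height",
                          "outcrossing_rate", "crossability", "wind_speed"))
  expect_equal(predict(m, 10), frequency_at(m, 10) * 100)
  expect_equal(predict(m, 10, units = "fraction"), frequency_at(m, 10))
})
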
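test_that("shipped presets carry the published parameter sets", {
  expect_setequal(pmgf_presets(), c("rice", "wheat", "maize"))
  rice <- pmgf_preset("rice")
  expect_equal(unlist(rice[c("pollen_diameter", "release_height",
                             "outcrossing_rate", "crossability",
                             "wind_speed")]),
               c(pollen_diameter = 40, release_height = 0.5,
                 outcrossing_rate = 1, crossability = 90, wind_speed = 1))
  wheat <- pmgf_preset("wheat")
  expect_equal(wheat$pollen_diameter, 50)
  expect_equal(wheat$outcrossing_rate, 0.5)
  expect_equal(wheat$wind_speed, 4.5)
  maize <- pmgf_preset("maize")
  expect_equal(maize$pollen_diameter, 100)
  expect_equal(maize$release_height, 1.5)
  expect_equal(maize$outcrossing_rate, 50)
  expect_equal(maize$wind_speed, 5)
})

test_that("unknown presets raise a lookup error listing the alternatives", {
  expect_error(pmgf_preset("barley"), "rice.*wheat.*maize")
})

test_that("preset modification is validated, non-destructive and idempotent", {
  maize <- pmgf_preset("maize")
  m3 <- preset_modify(maize, "wind_speed", 3)
  expect_equal(m3$wind_speed, 3)
  expect_equal(maize$wind_speed, 5)              # original untouched
  same <- preset_modify(maize, "wind_speed", 5)  # identity override
  expect_equal(same, maize)
  expect_error(preset_modify(maize, "pollen_diameter", 1000), "PROPER")
})

test_that("presets round-trip through the YAML file unchanged", {
  tmp <- tempfile(fileext = ".yaml")
  src <- preset_file()
  writeLines(readLines(src), tmp)
  for (nm in pmgf_presets()) {
    expect_equal(pmgf_preset(nm, file = tmp), pmgf_preset(nm))
  }
})

test_that("a model built from a preset matches the explicit parameterization", {
  a <- pmgf(preset = "wheat")
  b <- pmgf(pollen_diameter = 50, release_height = 0.5,
            outcrossing_rate = 0.5, crossability = 90, wind_speed = 4.5)
  expect_equal(predict(a, c(1, 10, 40)), predict(b, c(1, 10, 40)))
  # explicit argument overrides the preset value
  c3 <- pmgf(preset = "maize", wind_speed = 3)
  expect_equal(unname(coef(c3)["wind_speed"]), 3)
})
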
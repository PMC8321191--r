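test_that("parametric attenuation has a single upward K-edge jump", {
  g <- make_band_grid(100, 13, 70, "keV")
  s <- parametric_attenuation(g, edge_energy = 25.5, amp_pre = 10,
                              amp_post = 50)
  below <- g$centers < 25.5
  # discontinuous upward crossing at the edge
  expect_gt(s$values[which(!below)[1]], s$values[rev(which(below))[1]])
  # monotone decreasing on each side
  expect_true(all(diff(s$values[below]) < 0))
  expect_true(all(diff(s$values[!below]) < 0))
  # exactly one outlier jump in the diff sequence
  d <- diff(s$values)
  expect_equal(sum(d > 0), 1L)

  # equal amplitudes: continuous everywhere
  s2 <- parametric_attenuation(g, 25.5, 10, 10)
  expect_true(all(diff(s2$values) < 0))
  expect_lt(max(abs(diff(s2$values))) / max(s2$values), 0.3)

  # closed-form power-law ratio: value at 2*edge is 2^-3 of value just
  # above the edge for decay 3 and zero background
  g3 <- make_band_grid(1000, 10, 90, "keV")
  s3 <- parametric_attenuation(g3, 20, 1, 1, decay_exponent = 3,
                               background_amp = 0)
  v_at <- function(e) s3$values[band_index(g3, e)]
  expect_equal(v_at(40.01) / v_at(20.01), 2^-3, tolerance = 0.02)
})

test_that("mass-fraction mixing is linear and preserves edge jumps", {
  g <- make_band_grid(60, 13, 70, "keV")
  base <- parametric_attenuation(g, 40, 2, 2, 1.2, 0.5)
  dop <- parametric_attenuation(g, 26, 10, 60)
  m1 <- mix_attenuation(base, dop, 1, 0)
  expect_equal(m1$values, base$values)

  # constant spectra 1 and 101 mix to 0.99 + 1.01 = 2
  c1 <- hyperdr:::new_material_spectrum("a", rep(1, 60), "attenuation", g)
  c2 <- hyperdr:::new_material_spectrum("b", rep(101, 60), "attenuation", g)
  expect_equal(mix_attenuation(c1, c2, 0.99, 0.01)$values, rep(2, 60))

  # edge jump scales by the dopant fraction
  jump_of <- function(s) {
    i <- band_index(g, 26)
    s$values[i + 1] - s$values[i]
  }
  mix <- mix_attenuation(base, dop, 0.99, 0.01)
  expect_equal(jump_of(mix) - 0.99 * jump_of(base), 0.01 * jump_of(dop),
               tolerance = 1e-12)

  g2 <- make_band_grid(61, 13, 70, "keV")
  dop2 <- parametric_attenuation(g2, 26, 10, 60)
  expect_error(mix_attenuation(base, dop2), "different grids")
  expect_error(mix_attenuation(base, dop, 0.5, 0.4), "sum to 1")
})

test_that("X-ray source is smooth, unimodal, weak at the range edges", {
  for (n in c(100, 300)) {
    g <- make_band_grid(n, 13, 70, "keV")
    src <- make_xray_source(g)
    v <- src$values
    i <- which.max(v)
    expect_gt(i, 1)
    expect_lt(i, n)
    # unimodal: increases to the peak, decreases after
    expect_true(all(diff(v[1:i]) > 0))
    expect_true(all(diff(v[i:n]) < 0))
    expect_lt(v[1] / max(v), 0.05)
    expect_lt(v[n] / max(v), 0.05)
    expect_equal(max(v), 1)
    expect_true(all(v[2:(n - 1)] > 0))
  }
})

test_that("solar irradiance suppresses the water-vapor bands", {
  g <- tiny_nm_grid(200)
  irr <- make_solar_irradiance(g)
  inband <- g$centers >= 1350 & g$centers <= 1400
  expect_true(all(irr$values[inband] < 0.01 * max(irr$values)))
  inband2 <- g$centers >= 1800 & g$centers <= 1950
  expect_true(all(irr$values[inband2] < 0.01 * max(irr$values)))

  clean <- make_solar_irradiance(g, absorption_bands = list())
  expect_true(all(clean$values > 0))
  # in-band values scale by exactly the configured factor
  half <- make_solar_irradiance(g, absorption_bands = list(c(1350, 1400, 0.5)))
  expect_equal(half$values[inband], 0.5 * clean$values[inband])
  expect_equal(half$values[!inband], clean$values[!inband])

  expect_warning(make_solar_irradiance(g, list(c(5000, 6000, 0.001))),
                 "outside")
})

test_that("water-band bin indices follow the centers formula", {
  # 200 bins over 450-2400 nm; centers at 450 + (i + 0.5) * 9.75 (0-based)
  g <- make_band_grid(200, 450, 2400, "nm")
  suppressed0 <- which(g$centers >= 1350 & g$centers <= 1400) - 1L
  # oracle: smallest i with center >= 1350 is ceil((1350-450)/9.75 - 0.5),
  # largest with center <= 1400 is floor((1400-450)/9.75 - 0.5)
  expect_equal(suppressed0,
               seq(ceiling((1350 - 450) / 9.75 - 0.5),
                   floor((1400 - 450) / 9.75 - 0.5)))
  expect_equal(suppressed0, 92:96)
  irr <- make_solar_irradiance(g)
  expect_equal(which(irr$values < 0.01 * max(irr$values) &
                       g$centers < 1600) - 1L, 92:96)
})

test_that("reflectance libraries are reproducible, distinct and bounded", {
  g <- tiny_nm_grid()
  lib1 <- make_reflectance_library(g, 60, seed = 5)
  lib2 <- make_reflectance_library(g, 60, seed = 5)
  expect_identical(lib1, lib2)
  expect_length(lib1$spectra, 60)
  vals <- sapply(lib1$spectra, function(s) s$values)
  expect_true(all(vals >= 0 & vals <= 1))
  d2 <- as.matrix(stats::dist(t(vals)))
  expect_true(all(d2[upper.tri(d2)] > 0))
  lib3 <- make_reflectance_library(g, 60, seed = 6)
  expect_false(identical(lib1, lib3))
})

test_that("two-column tables resample onto the grid", {
  g <- make_band_grid(10, 0, 10, "nm")
  # table exactly at the grid centers: returned unchanged
  tf <- withr::local_tempfile(fileext = ".txt")
  vals <- runif(10, 0.2, 0.8)
  writeLines(c("# comment", sprintf("%.12g %.12g", g$centers, vals)), tf)
  s <- load_two_column_spectrum(tf, g, "linear", kind = "reflectance")
  expect_equal(s$values, vals)

  # two rows (0,0)-(10,10): linear midpoint at 5 is 5
  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 0", "10 10"), tf2)
  s2 <- load_two_column_spectrum(tf2, make_band_grid(2, 0, 10, "nm"),
                                 "linear")
  expect_equal(s2$values[1], 2.5)
  expect_equal(s2$values[2], 7.5)

  # loglog recovers a pure power law from 3 samples
  g3 <- make_band_grid(8, 1, 9, "keV")
  tf3 <- withr::local_tempfile(fileext = ".txt")
  ax <- c(0.5, 3, 12)
  writeLines(sprintf("%.10g %.10g", ax, 7 * ax^-2.5), tf3)
  s3 <- load_two_column_spectrum(tf3, g3, "loglog")
  expect_equal(s3$values, 7 * g3$centers^-2.5, tolerance = 1e-9)

  # nearest-neighbour extrapolation outside the table
  g4 <- make_band_grid(4, 0, 40, "nm")
  tf4 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("10 1", "20 2"), tf4)
  s4 <- load_two_column_spectrum(tf4, g4, "linear")
  expect_equal(s4$values, c(1, 1.5, 2, 2))
})

test_that("the packaged synthetic attenuation table loads onto any grid", {
  tbl <- system.file("extdata", "silver_attenuation_synthetic.txt",
                     package = "hyperdr")
  expect_true(nzchar(tbl))
  g <- make_band_grid(100, 13, 70, "keV")
  ag <- load_two_column_spectrum(tbl, g, "loglog")
  expect_length(ag$values, 100)
  expect_true(all(ag$values > 0))
  # the table carries the silver K-edge: a single upward jump near 25.5 keV
  jumps <- which(diff(ag$values) > 0)
  expect_true(all(abs(g$centers[jumps] - 25.514) < 1.5))
})

test_that("malformed tables report the offending line", {
  g <- make_band_grid(4, 0, 10, "nm")
  tf <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 1", "0.5 2"), tf)
  expect_error(load_two_column_spectrum(tf, g), "line 2")
  tf2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# only comments"), tf2)
  expect_error(load_two_column_spectrum(tf2, g), "at least 2")
  tf3 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 1", "2 oops"), tf3)
  expect_error(load_two_column_spectrum(tf3, g), "line 2")
})

test_that("write-out and reload round-trips grid-aligned spectra", {
  g <- make_band_grid(30, 13, 70, "keV")
  s <- parametric_attenuation(g, 26, 5, 25)
  tf <- withr::local_tempfile(fileext = ".txt")
  write_two_column_spectrum(s, tf)
  s2 <- load_two_column_spectrum(tf, g, "loglog")
  expect_equal(s2$values, s$values, tolerance = 1e-9)
})

test_that("generated spectra are finite, nonnegative and length-matched", {
  g <- make_band_grid(50, 13, 70, "keV")
  lib <- make_attenuation_library(g, c(35, 47, 60))
  for (s in lib$spectra) {
    expect_length(s$values, 50)
    expect_true(all(is.finite(s$values)))
    expect_true(all(s$values >= 0))
  }
  gn <- tiny_nm_grid()
  rl <- make_reflectance_library(gn, 5, seed = 1)
  for (s in rl$spectra) expect_length(s$values, gn$n_bins)
  expect_error(hyperdr:::new_material_spectrum("x", rep(1.5, 10),
                                               "reflectance",
                                               make_band_grid(10, 0, 1, "nm")),
               "\\[0, 1\\]")
})
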
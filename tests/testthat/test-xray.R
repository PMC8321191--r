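test_that("phantom sampling is sized, seeded and range-respecting", {
  ph <- sample_phantom(120, seed = 3)
  expect_equal(nrow(ph$cylinders), 120)
  expect_identical(ph, sample_phantom(120, seed = 3))
  expect_false(identical(ph, sample_phantom(120, seed = 4)))
  # axes are unit vectors
  a <- ph$cylinders[, c("ax", "ay", "az")]
  expect_equal(sqrt(rowSums(a^2)), rep(1, 120), tolerance = 1e-9)
  # degenerate range: all radii equal
  ph2 <- sample_phantom(10, radius_range = c(0.03, 0.03), seed = 1)
  expect_equal(ph2$cylinders$radius, rep(0.03, 10))
  expect_error(sample_phantom(0), ">= 1")
  expect_error(sample_phantom(5, radius_range = c(-0.1, 0.2)), "positive")
})

test_that("material assignment matches the few- and many-material setups", {
  ph <- sample_phantom(120, seed = 9)
  few <- assign_materials(ph, "few", seed = 2)
  tab <- table(few$cylinders$material_id)
  expect_equal(as.integer(tab[["Z47"]]), 2L)
  expect_equal(as.integer(tab[["Z48"]]), 118L)

  many <- assign_materials(ph, "many", seed = 2)
  tab2 <- table(many$cylinders$material_id)
  expect_length(tab2, 60)
  expect_true(all(tab2 == 2))
  expect_setequal(names(tab2), sprintf("Z%d", 30:89))

  expect_identical(assign_materials(ph, "few", seed = 5),
                   assign_materials(ph, "few", seed = 5))
  expect_error(assign_materials(sample_phantom(2, seed = 1), "few"),
               "at least 3")
  expect_error(assign_materials(sample_phantom(100, seed = 1), "many"),
               "exactly 120")
})

test_that("analytic ray-cylinder path lengths match closed-form cases", {
  cyl <- list(cx = 0, cy = 0, cz = 0, ax = 0, ay = 0, az = 1,
              radius = 0.25, half_length = 0.4)
  # perpendicular chord through the center: 2 * radius
  expect_equal(ray_cylinder_pathlength(c(-2, 0, 0), c(1, 0, 0), cyl), 0.5)
  # ray along the axis inside the tube: 2 * half_length
  expect_equal(ray_cylinder_pathlength(c(0.1, 0, -3), c(0, 0, 1), cyl), 0.8)
  # miss
  expect_equal(ray_cylinder_pathlength(c(-2, 0.3, 0), c(1, 0, 0), cyl), 0)
  # tangent returns 0
  expect_equal(ray_cylinder_pathlength(c(-2, 0.25, 0), c(1, 0, 0), cyl), 0)
  expect_error(ray_cylinder_pathlength(c(0, 0, 0), c(1, 1, 0), cyl), "unit")
})

test_that("analytic projector agrees with the voxel-summation oracle", {
  withr::with_seed(31, {
    errs <- replicate(120, {
      cyl <- list(cx = runif(1, -0.3, 0.3), cy = runif(1, -0.3, 0.3),
                  cz = runif(1, -0.3, 0.3), ax = 0, ay = 0, az = 0,
                  radius = runif(1, 0.05, 0.2),
                  half_length = runif(1, 0.1, 0.4))
      a <- random_unit()
      cyl$ax <- a[1]; cyl$ay <- a[2]; cyl$az <- a[3]
      o <- c(runif(1, -1, 1), -3, runif(1, -1, 1))
      d <- c(cyl$cx, cyl$cy, cyl$cz) + rnorm(3, sd = 0.05) - o
      d <- d / sqrt(sum(d^2))
      ana <- ray_cylinder_pathlength(o, d, cyl)
      vox <- voxel_pathlength(o, d, cyl, cyl$radius / 200)
      if (ana < 1e-9 && vox <= cyl$radius / 50) 0
      else abs(ana - vox) / max(ana, vox)
    })
    expect_lt(max(errs), 0.01)
  })
})

test_that("projection maps are additive over materials and silhouettes connect", {
  geom <- cone_beam_geometry(64, 32)
  ph <- sample_phantom(6, seed = 12)
  ph_all <- ph
  ph_all$cylinders$material_id <- rep("all", 6)
  total <- project_pathlengths(ph_all, geom)
  ph_split <- ph
  ph_split$cylinders$material_id <- rep(c("a", "b", "c"), 2)
  parts <- project_pathlengths(ph_split, geom)
  expect_equal(parts[, , "a"] + parts[, , "b"] + parts[, , "c"],
               total[, , "all"], tolerance = 1e-12)

  # empty phantom projects to zero
  ph0 <- ph
  ph0$cylinders <- ph$cylinders[0, ]
  expect_true(all(project_pathlengths(ph0, geom) == 0))

  # single cylinder silhouette: nonzero support present and contiguous rows
  ph1 <- ph
  ph1$cylinders <- ph$cylinders[1, ]
  ph1$cylinders$material_id <- "m"
  p1 <- project_pathlengths(ph1, geom)
  expect_gt(sum(p1 > 0), 0)
  rows <- which(rowSums(p1[, , 1]) > 0)
  expect_equal(rows, seq(min(rows), max(rows)))
})

test_that("Beer-Lambert rendering: zero paths give unit transmittance and
           transmittance decreases with path length", {
  g <- tiny_kev_grid()
  lib <- make_attenuation_library(g, c(47, 48))
  src <- make_xray_source(g)
  paths <- array(0, c(8, 8, 2))
  dimnames(paths) <- list(NULL, NULL, c("Z47", "Z48"))
  class(paths) <- c("pathlength_maps", "array")
  r <- render_xray_cube(paths, lib, src, noise = FALSE)
  expect_equal(r$cube, array(1, c(8, 8, g$n_bins)))
  expect_identical(r$cube, r$clean)

  # monotonicity: increasing any material's path length cannot raise
  # transmittance at any bin
  paths2 <- paths
  paths2[5, 5, "Z47"] <- 0.1
  r2 <- render_xray_cube(paths2, lib, src, noise = FALSE)
  expect_true(all(r2$clean[5, 5, ] < 1))
  paths3 <- paths2
  paths3[5, 5, "Z47"] <- 0.2
  r3 <- render_xray_cube(paths3, lib, src, noise = FALSE)
  expect_true(all(r3$clean[5, 5, ] <= r2$clean[5, 5, ]))
})

test_that("flatfield-corrected noisy cube converges to the clean cube at
           high flux", {
  # law-of-large-numbers check: the Poisson deviation of the corrected
  # transmittance scales as sqrt(T / (flux * i0)); at flux 1e7 even the
  # weakest edge bin of this 10-bin source (i0 ~ 0.013) is below 0.01
  g <- tiny_kev_grid(10)
  lib <- make_attenuation_library(g, c(47, 48))
  src <- make_xray_source(g)
  paths <- array(withr::with_seed(99, runif(64 * 2, 0, 0.1)), c(8, 8, 2))
  dimnames(paths) <- list(NULL, NULL, c("Z47", "Z48"))
  class(paths) <- c("pathlength_maps", "array")
  r <- render_xray_cube(paths, lib, src, noise = TRUE, flux_scale = 1e7,
                        seed = 5)
  clean <- render_xray_cube(paths, lib, src, noise = FALSE)$clean
  expect_lt(max(abs(r$cube - clean)), 0.01)
  # and the noise does shrink with flux (one decade gives ~sqrt(10))
  r2 <- render_xray_cube(paths, lib, src, noise = TRUE, flux_scale = 1e5,
                         seed = 5)
  expect_gt(max(abs(r2$cube - clean)), max(abs(r$cube - clean)))
})

test_that("flatfield correction is unbiased over many noisy pixels", {
  g <- make_band_grid(4, 13, 70, "keV")
  lib <- make_attenuation_library(g, c(47))
  src <- make_xray_source(g)
  paths <- array(0.05, c(60, 60, 1))
  dimnames(paths) <- list(NULL, NULL, "Z47")
  class(paths) <- c("pathlength_maps", "array")
  clean <- render_xray_cube(paths, lib, src, noise = FALSE)$clean
  r <- render_xray_cube(paths, lib, src, noise = TRUE, flux_scale = 2000,
                        n_flatfields = 50, seed = 77)
  # mean of (corrected - clean) over >= 10^4 pixels should be within a few
  # standard errors of zero at every bin
  for (b in 1:4) {
    resid <- r$cube[, , b] - clean[, , b]
    se <- stats::sd(resid) / sqrt(length(resid))
    expect_lt(abs(mean(resid)), 6 * se + 1e-4)
  }
})

test_that("ground-truth labels mark the target silhouette", {
  ds <- tiny_xray_dataset()
  geom <- ds$extras$geometry
  ph <- assign_materials(sample_phantom(10, seed = 21), "few", seed = 21)
  paths <- project_pathlengths(ph, geom)
  gt <- xray_ground_truth(paths, "Z47")
  expect_setequal(unique(as.vector(gt)), c(0L, 1L))
  expect_equal(gt == 1, paths[, , "Z47"] > 0)
  # no target cylinders: all-zero map
  gt0 <- xray_ground_truth(paths, "Z99")
  expect_true(all(gt0 == 0))
  # relabeling non-targets leaves the label map unchanged
  ph2 <- ph
  ph2$cylinders$material_id[ph2$cylinders$material_id == "Z48"] <- "Z50"
  paths2 <- project_pathlengths(ph2, geom)
  expect_equal(xray_ground_truth(paths2, "Z47"), gt)
})

test_that("the silver K-edge signature is visible inside its silhouette", {
  cfg <- xray_config(n_images = 1, size = 64, n_bins = 100, noise = FALSE,
                     raw_factor = 2L)
  ds <- build_xray_dataset(cfg, seed = 11)
  lab <- ds$labels[[1]]
  expect_gt(sum(lab), 0)
  m <- apply(ds$cubes[[1]], 3, function(b) mean(b[lab == 1]))
  eb <- band_index(ds$grid, kedge_energy(47))
  drop <- m[eb] - m[eb + 1]
  expect_gt(drop, 0)
  # the edge drop dominates the typical inter-bin difference elsewhere
  expect_gt(drop, 5 * stats::median(abs(diff(m))[-eb]))
})

test_that("X-ray dataset containers share geometry across variants", {
  cfg_clean <- xray_config(n_images = 2, size = 32, n_bins = 40,
                           noise = FALSE, raw_factor = 2L)
  cfg_noisy <- xray_config(n_images = 2, size = 32, n_bins = 40,
                           noise = TRUE, raw_factor = 2L)
  a <- build_xray_dataset(cfg_clean, seed = 5)
  b <- build_xray_dataset(cfg_noisy, seed = 5)
  # same master seed: identical phantom geometry, hence identical labels
  expect_identical(a$labels, b$labels)
  expect_false(identical(a$cubes, b$cubes))
  # determinism: regeneration gives an identical container
  a2 <- build_xray_dataset(cfg_clean, seed = 5)
  expect_identical(a, a2)
  expect_equal(length(a$cubes), 2)
  expect_equal(dim(a$cubes[[1]]), c(32, 32, 40))
  expect_equal(a$provenance$image_seeds, b$provenance$image_seeds)
})
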
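#' Random cylinder phantom
#'
#' Samples a 3D phantom of capped cylinders with uniformly random centers,
#' orientations, radii and half-lengths inside a cube-shaped volume of edge
#' length 1 centered at the origin (world units).
#'
#' @param n_cylinders Number of cylinders (>= 1).
#' @param radius_range,half_length_range Uniform sampling ranges, as
#'   fractions of the volume edge.
#' @param center_margin Centers are drawn uniformly from the box shrunk by
#'   this margin, keeping cylinders inside the volume.
#' @param seed Integer seed; the phantom is reproducible given the seed.
#' @return A `phantom`: data frame of cylinders (`cx, cy, cz, ax, ay, az,
#'   radius, half_length, material_id`) plus the bounding half-edge.
#' @export
sample_phantom <- function(n_cylinders = 120,
                           radius_range = c(0.02, 0.06),
                           half_length_range = c(0.10, 0.40),
                           center_margin = 0.08, seed = 1L) {
  if (n_cylinders < 1) stop("n_cylinders must be >= 1")
  if (diff(range(radius_range)) < 0 || any(radius_range <= 0) ||
      any(half_length_range <= 0))
    stop("radius and half-length ranges must be positive")
  cyl <- withr::with_seed(seed, {
    n <- n_cylinders
    # isotropic random axes
    u <- stats::rnorm(n); v <- stats::rnorm(n); w <- stats::rnorm(n)
    nrm <- sqrt(u^2 + v^2 + w^2)
    nrm[nrm < 1e-12] <- 1
    half <- 0.5 - center_margin
    data.frame(
      cx = stats::runif(n, -half, half),
      cy = stats::runif(n, -half, half),
      cz = stats::runif(n, -half, half),
      ax = u / nrm, ay = v / nrm, az = w / nrm,
      radius = stats::runif(n, radius_range[1], radius_range[2]),
      half_length = stats::runif(n, half_length_range[1],
                                 half_length_range[2]),
      material_id = NA_character_,
      stringsAsFactors = FALSE)
  })
  structure(list(cylinders = cyl, half_edge = 0.5,
                 n_cylinders = n_cylinders),
            class = "phantom")
}

#' Assign materials to phantom cylinders
#'
#' In `"few"` mode two randomly chosen cylinders get silver (`Z47`) and the
#' remainder cadmium (`Z48`), the designed confounder with an adjacent
#' K-edge. In `"many"` mode the 60 elements Z = 30 (zinc) .. 89 (actinium)
#' are each uniquely assigned to two randomly chosen cylinders; silver is
#' the target in both modes.
#'
#' @param phantom A `phantom`.
#' @param mode `"few"` or `"many"`.
#' @param seed Integer seed.
#' @return The phantom with `material_id` filled in.
#' @export
assign_materials <- function(phantom, mode = c("few", "many"), seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(phantom, "phantom"))
  n <- phantom$n_cylinders
  ids <- withr::with_seed(seed, {
    if (mode == "few") {
      if (n < 3) stop("few-material mode needs at least 3 cylinders")
      ids <- rep("Z48", n)
      ids[sample.int(n, 2)] <- "Z47"
      ids
    } else {
      zs <- 30:89
      if (n != 2L * length(zs))
        stop(sprintf("many-material mode needs exactly %d cylinders",
                     2L * length(zs)))
      sample(rep(sprintf("Z%d", zs), each = 2))
    }
  })
  phantom$cylinders$material_id <- ids
  phantom$mode <- mode
  phantom
}

#' Cone-beam acquisition geometry
#'
#' Point source on the -y axis, square detector plane on the +y axis,
#' volume of edge 1 centered at the origin. Raw detector pixels are traced
#' with central rays and box-averaged down to the output resolution.
#'
#' @param raw_res Raw detector resolution (default 1536).
#' @param out_res Output projection resolution (default 512); must divide
#'   `raw_res`.
#' @param sod,odd Source-object and object-detector distances (equal by
#'   default).
#' @param det_size Physical detector edge length; the default makes the
#'   volume silhouette fill roughly 90% of the detector.
#' @return A `cone_beam_geometry`.
#' @export
cone_beam_geometry <- function(raw_res = 1536L, out_res = 512L,
                               sod = 1.5, odd = 1.5, det_size = 2.2) {
  if (raw_res %% out_res != 0)
    stop("raw_res must be an integer multiple of out_res")
  if (sod <= 0 || odd < 0) stop("invalid source/detector distances")
  structure(list(raw_res = as.integer(raw_res),
                 out_res = as.integer(out_res),
                 sod = sod, odd = odd, det_size = det_size),
            class = "cone_beam_geometry")
}

#' Exact ray path length through a finite capped cylinder
#'
#' Closed-form Euclidean length of the intersection of a ray with a capped
#' cylinder (quadratic for the infinite tube clipped by the two cap planes);
#' 0 when disjoint or tangent.
#'
#' @param origin,direction Ray origin and unit direction (3-vectors).
#' @param cylinder One-row data frame or list with `cx, cy, cz, ax, ay, az,
#'   radius, half_length`.
#' @return Nonnegative path length.
#' @export
ray_cylinder_pathlength <- function(origin, direction, cylinder) {
  d <- as.numeric(direction)
  if (abs(sqrt(sum(d^2)) - 1) > 1e-6) stop("direction must be a unit vector")
  ray_cyl_pathlength_cpp(as.numeric(origin), d,
                         c(cylinder$cx, cylinder$cy, cylinder$cz),
                         c(cylinder$ax, cylinder$ay, cylinder$az),
                         cylinder$radius, cylinder$half_length)
}

#' Per-material accumulated path-length maps
#'
#' Projects every cylinder onto the detector with the analytic ray-cylinder
#' intersection, accumulating path length per material, and box-averages the
#' raw detector down to the output resolution.
#'
#' @param phantom A `phantom` with materials assigned (or not: a single
#'   pseudo-material `"all"` is used).
#' @param geom A `cone_beam_geometry`.
#' @return A `pathlength_maps` object: array `(out_res, out_res, n_mat)`
#'   with material ids as the third dimnames.
#' @export
project_pathlengths <- function(phantom, geom) {
  stopifnot(inherits(phantom, "phantom"), inherits(geom, "cone_beam_geometry"))
  cyl <- phantom$cylinders
  ids <- cyl$material_id
  if (all(is.na(ids))) ids <- rep("all", nrow(cyl))
  mats <- unique(ids)
  midx <- match(ids, mats)
  cm <- as.matrix(cyl[, c("cx", "cy", "cz", "ax", "ay", "az",
                          "radius", "half_length")])
  paths <- if (nrow(cm) == 0) {
    array(0, dim = c(geom$out_res, geom$out_res, length(mats)))
  } else {
    project_cylinders_cpp(cm, midx, length(mats), geom$raw_res, geom$out_res,
                          geom$sod, geom$odd, geom$det_size)
  }
  dimnames(paths) <- list(NULL, NULL, mats)
  structure(paths, class = c("pathlength_maps", "array"))
}

#' Flux calibration for the Poisson noise model
#'
#' Picks the photon flux scale so that the unattenuated expected count in
#' the lowest-flux edge bin of the source spectrum is `target_snr^2`, i.e.
#' the first and last bins have pixel SNR around `target_snr` (< 2): the
#' edge bins of the corrected cubes are dominated by noise, while mid-range
#' bins stay usable.
#'
#' @param source A `source_spectrum`.
#' @param target_snr Target SNR at the weakest edge bin (default 1.5).
#' @return Scalar flux scale (photons per unit source value).
#' @export
calibrate_flux <- function(source, target_snr = 1.5) {
  v <- source$values / max(source$values)
  edge <- min(v[1], v[length(v)])
  target_snr^2 / max(edge, 1e-12)
}

#' Render a hyperspectral X-ray transmittance cube
#'
#' Beer-Lambert transmission through the per-material path-length maps:
#' `I(p,b) = I0(b) * exp(-sum_m mu_m(b) * l_m(p))`. With noise on, photon
#' counts are Poisson draws of `flux_scale * I`, the flatfield is the
#' average of `n_flatfields` Poisson draws of the object-free intensity,
#' and the returned cube is the flatfield-corrected transmittance
#' counts/flatfield. The clean transmittance cube `exp(-sum mu*l)` is always
#' returned alongside.
#'
#' @param paths A `pathlength_maps`.
#' @param library A `spectral_library` containing every material in `paths`.
#' @param source A `source_spectrum` on the same grid.
#' @param noise Apply Poisson noise (default TRUE).
#' @param flux_scale Photon flux scale; default `calibrate_flux(source)`.
#' @param n_flatfields Number of flatfield images averaged (default 50).
#' @param seed Integer seed for the noise draws.
#' @return List with `cube` (corrected transmittance, `(H, W, n_bins)`) and
#'   `clean` (noise-free transmittance).
#' @export
render_xray_cube <- function(paths, library, source, noise = TRUE,
                             flux_scale = NULL, n_flatfields = 50L,
                             seed = 1L) {
  stopifnot(inherits(paths, "pathlength_maps"),
            inherits(library, "spectral_library"),
            inherits(source, "source_spectrum"))
  mats <- dimnames(paths)[[3]]
  missing_mat <- setdiff(mats, names(library$spectra))
  if (length(missing_mat))
    stop("materials missing from library: ",
         paste(missing_mat, collapse = ", "))
  grid <- library$grid
  if (!grids_equal(grid, source$grid))
    stop("library and source are on different grids")
  H <- dim(paths)[1]; W <- dim(paths)[2]; B <- grid$n_bins
  mu <- vapply(mats, function(m) library$spectra[[m]]$values, numeric(B))
  mu <- matrix(mu, nrow = B)
  tr <- beer_lambert_cpp(unclass(paths), mu)        # (H*W) x B
  clean <- array(tr, dim = c(H, W, B))
  if (!noise)
    return(list(cube = clean, clean = clean))
  if (is.null(flux_scale)) flux_scale <- calibrate_flux(source)
  if (flux_scale <= 0) stop("flux_scale must be positive")
  i0 <- source$values / max(source$values)
  withr::with_seed(seed, {
    lam <- flux_scale * tr * rep(i0, each = H * W)
    counts <- matrix(stats::rpois(length(lam), lam), nrow = H * W)
    # sum of n iid Poisson(mu) draws is Poisson(n*mu): draw the flatfield
    # average in one pass
    flat_lam <- n_flatfields * flux_scale * i0
    flat <- matrix(stats::rpois(H * W * B, rep(flat_lam, each = H * W)),
                   nrow = H * W) / n_flatfields
    corrected <- counts / flat
    bad <- !is.finite(corrected)
    if (any(bad)) {
      warning(sprintf("%d zero-flatfield pixels replaced by clean values",
                      sum(bad)))
      corrected[bad] <- tr[bad]
    }
    list(cube = array(corrected, dim = c(H, W, B)), clean = clean)
  })
}

#' Ground-truth label map for a target material
#'
#' Class 1 where the target material's accumulated path length exceeds the
#' threshold, class 0 elsewhere.
#'
#' @param paths A `pathlength_maps`.
#' @param target_material Material id (default `"Z47"`, silver).
#' @param threshold Path-length threshold (default 0).
#' @return Integer label matrix.
#' @export
xray_ground_truth <- function(paths, target_material = "Z47",
                              threshold = 0) {
  stopifnot(inherits(paths, "pathlength_maps"))
  mats <- dimnames(paths)[[3]]
  if (!target_material %in% mats)
    return(matrix(0L, dim(paths)[1], dim(paths)[2]))
  m <- paths[, , target_material]
  matrix(as.integer(m > threshold), dim(paths)[1], dim(paths)[2])
}

#' Configuration for the simulated X-ray dataset
#'
#' Defaults follow the full-scale study configuration (100 images of
#' 512 x 512 pixels, 300 bins over 13-70 keV, 120 cylinders, raw detector
#' 1536 x 1536); `desk_scale = TRUE` switches to a configuration that
#' completes in minutes on one CPU (25 images, 128 x 128, 100 bins).
#'
#' @param n_images,size,n_bins Dataset dimensions.
#' @param mode `"few"` (2 silver / 118 cadmium) or `"many"` (60 elements x 2).
#' @param noise Poisson noise on or off.
#' @param n_cylinders Cylinders per phantom.
#' @param e_min,e_max Energy range in keV.
#' @param raw_factor Detector supersampling factor (raw = factor * size).
#' @param flux_scale Photon flux; `NULL` = calibrated via [calibrate_flux()].
#' @param n_flatfields Flatfield images averaged.
#' @param desk_scale Use the desk-scale defaults.
#' @return An `xray_config` list.
#' @export
xray_config <- function(n_images = 100L, size = 512L, n_bins = 300L,
                        mode = "few", noise = TRUE, n_cylinders = 120L,
                        e_min = 13, e_max = 70, raw_factor = 3L,
                        flux_scale = NULL, n_flatfields = 50L,
                        desk_scale = FALSE) {
  if (desk_scale) {
    if (missing(n_images)) n_images <- 25L
    if (missing(size)) size <- 128L
    if (missing(n_bins)) n_bins <- 100L
  }
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 n_bins = as.integer(n_bins), mode = mode, noise = noise,
                 n_cylinders = as.integer(n_cylinders),
                 e_min = e_min, e_max = e_max,
                 raw_factor = as.integer(raw_factor),
                 flux_scale = flux_scale,
                 n_flatfields = as.integer(n_flatfields)),
            class = "xray_config")
}

#' Build a simulated hyperspectral X-ray dataset
#'
#' Renders `n_images` independent cylinder phantoms under a shared band
#' grid, source spectrum and attenuation library. Per-image seeds are
#' derived from the master seed, so any variant (clean/noisy, few/many)
#' built from the same master seed shares phantom geometry per image index
#' and any single image can be regenerated in isolation.
#'
#' @param config An `xray_config`.
#' @param seed Master integer seed.
#' @param max_bytes Preflight limit: generation aborts before any work if
#'   the cubes would exceed this many bytes in memory (default 8e9).
#' @return A `dataset_container` with binary labels (1 = silver target).
#' @export
build_xray_dataset <- function(config = xray_config(), seed = 1L,
                               max_bytes = 8e9) {
  stopifnot(inherits(config, "xray_config"))
  est <- dataset_storage(config$n_images, config$n_bins, config$size,
                         config$size, bytes_per_value = 8)$bytes
  if (est > max_bytes)
    stop(sprintf(
      "dataset would occupy %.1f GB in memory (limit %.1f GB); use a %s",
      est / 1e9, max_bytes / 1e9,
      "smaller configuration or raise max_bytes"))
  grid <- make_band_grid(config$n_bins, config$e_min, config$e_max, "keV")
  source <- make_xray_source(grid)
  zs <- if (config$mode == "few") c(47L, 48L) else 30:89
  library <- make_attenuation_library(grid, zs)
  geom <- cone_beam_geometry(raw_res = config$raw_factor * config$size,
                             out_res = config$size)
  image_seeds <- withr::with_seed(seed,
    sample.int(.Machine$integer.max - 1L, config$n_images))
  flux <- if (is.null(config$flux_scale)) calibrate_flux(source)
          else config$flux_scale
  cubes <- vector("list", config$n_images)
  labels <- vector("list", config$n_images)
  for (i in seq_len(config$n_images)) {
    s <- image_seeds[i]
    ph <- sample_phantom(config$n_cylinders, seed = s)
    ph <- assign_materials(ph, config$mode, seed = s)
    paths <- project_pathlengths(ph, geom)
    rend <- render_xray_cube(paths, library, source, noise = config$noise,
                             flux_scale = flux,
                             n_flatfields = config$n_flatfields, seed = s)
    cubes[[i]] <- rend$cube
    labels[[i]] <- xray_ground_truth(paths, "Z47")
  }
  new_dataset_container(
    cubes = cubes, labels = labels, grid = grid,
    class_names = c("background", "silver"),
    provenance = list(module = "xray_simulator", config = unclass(config),
                      master_seed = seed, image_seeds = image_seeds,
                      flux_scale = flux,
                      version = as.character(utils::packageVersion("hyperdr"))),
    extras = list(source = source, library = library, geometry = geom))
}
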
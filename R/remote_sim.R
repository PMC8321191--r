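#' Place non-overlapping disks by rejection sampling
#'
#' Samples disk radii and centers uniformly and rejects candidates that
#' overlap an already-accepted disk of the same group or extend outside the
#' image. With `group_sizes` given, the non-overlap constraint applies only
#' within each group (used for the overlap variant where target disks may
#' cover background disks).
#'
#' @param n_disks Number of disks (>= 1).
#' @param m,n Image height and width in pixels.
#' @param radius_range Radius range in pixels.
#' @param max_attempts Total rejection-sampling budget.
#' @param seed Integer seed.
#' @param group_sizes Optional integer vector partitioning the disks into
#'   groups (sums to `n_disks`); `NULL` = one group.
#' @return A `disk_layout`: data frame (`x, y, r, group, material_id,
#'   is_target`) plus the image size.
#' @export
place_disks <- function(n_disks, m, n, radius_range = c(4, 12),
                        max_attempts = 1000L * n_disks, seed = 1L,
                        group_sizes = NULL) {
  if (n_disks < 1) stop("n_disks must be >= 1")
  if (any(radius_range <= 0)) stop("radius_range must be positive")
  if (is.null(group_sizes)) group_sizes <- n_disks
  if (sum(group_sizes) != n_disks) stop("group_sizes must sum to n_disks")
  group_of <- rep(seq_along(group_sizes), group_sizes)
  disks <- withr::with_seed(seed, {
    xs <- ys <- rs <- numeric(n_disks)
    placed <- 0L
    attempts <- 0L
    while (placed < n_disks) {
      if (attempts >= max_attempts)
        stop("disk placement failed after max_attempts; ",
             "use smaller radii or fewer disks")
      attempts <- attempts + 1L
      r <- stats::runif(1, radius_range[1], radius_range[2])
      if (2 * r + 2 >= min(m, n)) next
      x <- stats::runif(1, r + 1, n - r)
      y <- stats::runif(1, r + 1, m - r)
      g <- group_of[placed + 1L]
      ok <- TRUE
      if (placed > 0L) {
        same <- which(group_of[seq_len(placed)] == g)
        if (length(same))
          ok <- all((xs[same] - x)^2 + (ys[same] - y)^2 >
                      (rs[same] + r)^2)
      }
      if (ok) {
        placed <- placed + 1L
        xs[placed] <- x; ys[placed] <- y; rs[placed] <- r
      }
    }
    data.frame(x = xs, y = ys, r = rs, group = group_of,
               material_id = NA_character_, is_target = FALSE,
               stringsAsFactors = FALSE)
  })
  structure(list(disks = disks, m = m, n = n,
                 n_groups = length(group_sizes)),
            class = "disk_layout")
}

#' Brute-force pairwise overlap audit
#'
#' Exhaustive O(n^2) check that no two disks of the same group overlap
#' (center distance > sum of radii for every pair).
#'
#' @param layout A `disk_layout`.
#' @return TRUE if no same-group pair overlaps.
#' @export
audit_overlap <- function(layout) {
  d <- layout$disks
  nd <- nrow(d)
  if (nd < 2) return(TRUE)
  for (i in seq_len(nd - 1)) {
    for (j in seq(i + 1, nd)) {
      if (d$group[i] != d$group[j]) next
      dist <- sqrt((d$x[i] - d$x[j])^2 + (d$y[i] - d$y[j])^2)
      if (dist <= d$r[i] + d$r[j]) return(FALSE)
    }
  }
  TRUE
}

#' Assign materials and target flags to a disk layout
#'
#' Each of `n_materials` materials is placed on exactly `per_material`
#' disks; the first `n_targets` material ids are flagged as targets. In a
#' two-group layout (overlap variant) targets are assigned within the
#' second group and background materials within the first.
#'
#' @param layout A `disk_layout` with `n_materials * per_material` disks.
#' @param n_materials,per_material Material grid.
#' @param n_targets Number of target materials (classes 1..n_targets).
#' @param seed Integer seed.
#' @return The layout with `material_id` and `is_target` filled in.
#' @export
assign_remote_materials <- function(layout, n_materials, per_material,
                                    n_targets, seed = 1L) {
  stopifnot(inherits(layout, "disk_layout"))
  d <- layout$disks
  if (nrow(d) != n_materials * per_material)
    stop("n_disks must equal n_materials * per_material")
  if (n_targets > n_materials) stop("n_targets exceeds n_materials")
  ids <- sprintf("mat_%02d", seq_len(n_materials))
  target_ids <- ids[seq_len(n_targets)]
  assignment <- withr::with_seed(seed, {
    if (layout$n_groups == 2) {
      tgt_rows <- which(d$group == 2)
      bg_rows <- which(d$group == 1)
      if (length(tgt_rows) != n_targets * per_material)
        stop("target group size must be n_targets * per_material")
      a <- character(nrow(d))
      a[tgt_rows] <- sample(rep(target_ids, each = per_material))
      a[bg_rows] <- sample(rep(setdiff(ids, target_ids),
                               each = per_material))
      a
    } else {
      sample(rep(ids, each = per_material))
    }
  })
  d$material_id <- assignment
  d$is_target <- assignment %in% target_ids
  layout$disks <- d
  layout$n_targets <- n_targets
  layout
}

rasterize_layout <- function(layout) {
  # per-pixel material index (0 = background); target disks are drawn
  # last so they sit on top of background-material disks in the overlap
  # variant. `under_idx` holds the covered (non-target) layer for
  # compositing.
  d <- layout$disks
  ord <- order(d$is_target)      # backgrounds first, targets on top
  m <- layout$m; n <- layout$n
  mat_idx <- matrix(0L, m, n)
  xs <- col(mat_idx); ys <- row(mat_idx)
  mat_levels <- sort(unique(d$material_id))
  under_idx <- matrix(0L, m, n)
  for (k in ord) {
    inside <- (xs - d$x[k])^2 + (ys - d$y[k])^2 <= d$r[k]^2
    if (!isTRUE(d$is_target[k]))
      under_idx[inside] <- match(d$material_id[k], mat_levels)
    mat_idx[inside] <- match(d$material_id[k], mat_levels)
  }
  list(mat_idx = mat_idx, under_idx = under_idx, mat_levels = mat_levels)
}

#' Render a hyperspectral remote-sensing scene
#'
#' Radiance is the per-pixel material reflectance multiplied by the solar
#' irradiance spectrum, with a constant soil-like background reflectance
#' outside the disks. Gaussian noise with standard deviation
#' `noise_sd_fraction` times the maximum radiance is added, then a
#' flatfield correction divides by the irradiance, floored at 1e-3 of its
#' maximum so that water-absorption bins come out noise-dominated rather
#' than infinite. Labels are 0 for background and non-target materials and
#' 1..n_targets for the target materials.
#'
#' @param layout A `disk_layout` with materials assigned.
#' @param library A `spectral_library` covering all assigned materials.
#' @param irradiance A `source_spectrum` on the same grid.
#' @param noise_sd_fraction Gaussian noise level (default 0.001 = 1/1000 of
#'   the maximum signal); 0 disables noise.
#' @param background_reflectance Reflectance outside disks (default 0.2).
#' @param blend_alpha Compositing weight where a target disk covers a
#'   background-material disk: 1 (default) replaces the underlying
#'   reflectance outright; values in (0, 1) mix
#'   `alpha * target + (1 - alpha) * underlying` for sensitivity tests.
#' @param seed Integer seed for the noise.
#' @return List with `cube` (corrected, `(m, n, n_bins)`), `clean`
#'   (noise-free corrected cube) and `labels`.
#' @export
render_remote_scene <- function(layout, library, irradiance,
                                noise_sd_fraction = 0.001,
                                background_reflectance = 0.2,
                                blend_alpha = 1, seed = 1L) {
  if (blend_alpha < 0 || blend_alpha > 1)
    stop("blend_alpha must be in [0, 1]")
  stopifnot(inherits(layout, "disk_layout"),
            inherits(library, "spectral_library"),
            inherits(irradiance, "source_spectrum"))
  if (noise_sd_fraction < 0) stop("noise_sd_fraction must be >= 0")
  grid <- library$grid
  if (!grids_equal(grid, irradiance$grid))
    stop("library and irradiance are on different grids")
  d <- layout$disks
  missing_mat <- setdiff(unique(d$material_id), names(library$spectra))
  if (length(missing_mat))
    stop("materials missing from library: ",
         paste(missing_mat, collapse = ", "))
  ras <- rasterize_layout(layout)
  B <- grid$n_bins
  # reflectance rows: row 1 = background, then materials in level order
  refl <- rbind(background_reflectance,
                t(vapply(ras$mat_levels,
                         function(id) library$spectra[[id]]$values,
                         numeric(B))))
  irr <- irradiance$values
  refl_pix <- refl[ras$mat_idx + 1L, , drop = FALSE]
  if (blend_alpha < 1) {
    covered <- ras$mat_idx != ras$under_idx & ras$mat_idx > 0
    if (any(covered))
      refl_pix[covered, ] <- blend_alpha * refl_pix[covered, , drop = FALSE] +
        (1 - blend_alpha) *
          refl[ras$under_idx + 1L, , drop = FALSE][covered, , drop = FALSE]
  }
  radiance <- refl_pix * rep(irr, each = layout$m * layout$n)   # (m*n) x B
  denom <- pmax(irr, 1e-3 * max(irr))
  clean <- radiance / rep(denom, each = layout$m * layout$n)
  cube <- if (noise_sd_fraction > 0) {
    sd <- noise_sd_fraction * max(radiance)
    noisy <- withr::with_seed(seed,
      radiance + stats::rnorm(length(radiance), sd = sd))
    noisy / rep(denom, each = layout$m * layout$n)
  } else clean
  # labels: target materials map to 1..n_targets by material order
  tgt_ids <- sort(unique(d$material_id[d$is_target]))
  lab_of_level <- ifelse(ras$mat_levels %in% tgt_ids,
                         match(ras$mat_levels, tgt_ids), 0L)
  labels <- matrix(c(0L, lab_of_level)[ras$mat_idx + 1L],
                   layout$m, layout$n)
  dims <- c(layout$m, layout$n, B)
  list(cube = array(cube, dims), clean = array(clean, dims),
       labels = labels)
}

#' Configuration for the simulated remote-sensing dataset
#'
#' Defaults follow the full-scale study configuration (100 images of
#' 512 x 512 pixels, 200 bins over 450-2400 nm, 360 disks = 60 materials
#' x 6, 10 target classes); `desk_scale = TRUE` switches to 25 images,
#' 128 x 128, 64 bins, 90 disks (15 materials x 6) with 5 targets. Disk
#' radii default to 4-12 px at 512 x 512, scaled proportionally with image
#' size.
#'
#' @param n_images,size,n_bins Dataset dimensions.
#' @param n_materials,per_material,n_targets Material layout.
#' @param noise Gaussian noise on or off.
#' @param overlap Overlap variant (targets drawn over background disks).
#' @param noise_sd_fraction Noise level as a fraction of max radiance.
#' @param background_reflectance Constant background reflectance.
#' @param lambda_min,lambda_max Wavelength range in nm.
#' @param radius_range Disk radii in px; `NULL` = `c(4, 12) * size / 512`.
#' @param desk_scale Use the desk-scale defaults.
#' @return A `remote_config` list.
#' @export
remote_config <- function(n_images = 100L, size = 512L, n_bins = 200L,
                          n_materials = 60L, per_material = 6L,
                          n_targets = 10L, noise = TRUE, overlap = FALSE,
                          noise_sd_fraction = 0.001,
                          background_reflectance = 0.2,
                          lambda_min = 450, lambda_max = 2400,
                          radius_range = NULL, desk_scale = FALSE) {
  if (desk_scale) {
    if (missing(n_images)) n_images <- 25L
    if (missing(size)) size <- 128L
    if (missing(n_bins)) n_bins <- 64L
    if (missing(n_materials)) n_materials <- 15L
    if (missing(n_targets)) n_targets <- 5L
  }
  if (is.null(radius_range)) radius_range <- c(4, 12) * size / 512
  structure(list(n_images = as.integer(n_images), size = as.integer(size),
                 n_bins = as.integer(n_bins),
                 n_materials = as.integer(n_materials),
                 per_material = as.integer(per_material),
                 n_targets = as.integer(n_targets),
                 noise = noise, overlap = overlap,
                 noise_sd_fraction = noise_sd_fraction,
                 background_reflectance = background_reflectance,
                 lambda_min = lambda_min, lambda_max = lambda_max,
                 radius_range = radius_range),
            class = "remote_config")
}

#' Build a simulated hyperspectral remote-sensing dataset
#'
#' Renders `n_images` independent disk scenes under one shared reflectance
#' library and solar irradiance spectrum. Per-image seeds derive from the
#' master seed, so the clean/noisy and overlap/no-overlap variants built
#' from the same master seed share disk layouts per image index.
#'
#' @param config A `remote_config`.
#' @param seed Master integer seed.
#' @param max_bytes Preflight limit: generation aborts before any work if
#'   the cubes would exceed this many bytes in memory (default 8e9).
#' @return A `dataset_container` with labels 0..n_targets.
#' @export
build_remote_dataset <- function(config = remote_config(), seed = 1L,
                                 max_bytes = 8e9) {
  stopifnot(inherits(config, "remote_config"))
  est <- dataset_storage(config$n_images, config$n_bins, config$size,
                         config$size, bytes_per_value = 8)$bytes
  if (est > max_bytes)
    stop(sprintf(
      "dataset would occupy %.1f GB in memory (limit %.1f GB); use a %s",
      est / 1e9, max_bytes / 1e9,
      "smaller configuration or raise max_bytes"))
  grid <- make_band_grid(config$n_bins, config$lambda_min,
                         config$lambda_max, "nm")
  irr <- make_solar_irradiance(grid)
  lib_seed <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, 1))
  library <- make_reflectance_library(grid, config$n_materials,
                                      seed = lib_seed)
  image_seeds <- withr::with_seed(seed + 1L,
    sample.int(.Machine$integer.max - 1L, config$n_images))
  n_disks <- config$n_materials * config$per_material
  group_sizes <- if (config$overlap)
    c((config$n_materials - config$n_targets) * config$per_material,
      config$n_targets * config$per_material) else NULL
  nsf <- if (config$noise) config$noise_sd_fraction else 0
  cubes <- vector("list", config$n_images)
  labels <- vector("list", config$n_images)
  for (i in seq_len(config$n_images)) {
    s <- image_seeds[i]
    layout <- place_disks(n_disks, config$size, config$size,
                          radius_range = config$radius_range, seed = s,
                          group_sizes = group_sizes)
    layout <- assign_remote_materials(layout, config$n_materials,
                                      config$per_material,
                                      config$n_targets, seed = s)
    sc <- render_remote_scene(layout, library, irr,
                              noise_sd_fraction = nsf,
                              background_reflectance =
                                config$background_reflectance,
                              seed = s)
    cubes[[i]] <- sc$cube
    labels[[i]] <- sc$labels
  }
  new_dataset_container(
    cubes = cubes, labels = labels, grid = grid,
    class_names = c("background",
                    sprintf("target_%02d", seq_len(config$n_targets))),
    provenance = list(module = "remote_simulator",
                      config = unclass(config), master_seed = seed,
                      image_seeds = image_seeds, library_seed = lib_seed,
                      version = as.character(utils::packageVersion("hyperdr"))),
    extras = list(irradiance = irr, library = library))
}
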
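CONTAINER_FORMAT_VERSION <- 1L

#' Dataset container
#'
#' In-memory container for a generated hyperspectral dataset: per-image
#' cubes `(H, W, n_bins)`, integer label maps, the band grid, class names
#' and full generator provenance (module, config, master seed, per-image
#' seeds, package version) - enough to regenerate the dataset
#' byte-identically.
#'
#' @param cubes List of `(H, W, n_bins)` arrays.
#' @param labels List of `(H, W)` integer matrices.
#' @param grid The `band_grid` of the spectral axis.
#' @param class_names Character vector, index c+1 names class c.
#' @param provenance Named list of generator metadata.
#' @param extras Optional named list (source spectra, libraries, geometry).
#' @return A `dataset_container`.
#' @export
new_dataset_container <- function(cubes, labels, grid, class_names,
                                  provenance = list(), extras = list()) {
  stopifnot(is.list(cubes), is.list(labels),
            length(cubes) == length(labels),
            inherits(grid, "band_grid"))
  for (i in seq_along(cubes)) {
    dc <- dim(cubes[[i]])
    if (length(dc) != 3 || dc[3] != grid$n_bins)
      stop(sprintf("cube %d is not (H, W, %d)", i, grid$n_bins))
    if (!all(dim(labels[[i]]) == dc[1:2]))
      stop(sprintf("label map %d does not match cube %d", i, i))
  }
  need <- c("module", "config", "master_seed", "image_seeds", "version")
  if (length(setdiff(need, names(provenance))))
    warning("incomplete provenance: missing ",
            paste(setdiff(need, names(provenance)), collapse = ", "))
  structure(list(cubes = cubes, labels = labels, grid = grid,
                 class_names = class_names, provenance = provenance,
                 extras = extras,
                 format_version = CONTAINER_FORMAT_VERSION),
            class = "dataset_container")
}

#' @export
print.dataset_container <- function(x, ...) {
  d <- dim(x$cubes[[1]])
  cat(sprintf(
    "dataset_container: %d images of %d x %d, %d %s bins, %d classes (%s)\n",
    length(x$cubes), d[1], d[2], x$grid$n_bins, x$grid$unit,
    length(x$class_names),
    if (length(x$provenance)) x$provenance$module else "unknown origin"))
  invisible(x)
}

#' Number of images in a container
#' @param container A `dataset_container`.
#' @export
n_images <- function(container) length(container$cubes)

#' Write / read a dataset container
#'
#' Serializes the container losslessly to a single versioned file
#' (R serialization, xz-free gzip). Arrays round-trip bit-identically.
#'
#' @param container A `dataset_container`.
#' @param path File path.
#' @return `read_container` returns the `dataset_container`.
#' @export
write_container <- function(container, path) {
  stopifnot(inherits(container, "dataset_container"))
  saveRDS(container, path)
  invisible(path)
}

#' @rdname write_container
#' @export
read_container <- function(path) {
  if (!file.exists(path)) stop("no such container file: ", path)
  x <- tryCatch(readRDS(path),
                error = function(e) stop("corrupt or truncated container: ",
                                         conditionMessage(e)))
  if (!inherits(x, "dataset_container"))
    stop("file is not a dataset container")
  if (!identical(x$format_version, CONTAINER_FORMAT_VERSION))
    stop(sprintf(
      "container format version %s needs migration (current %d)",
      x$format_version, CONTAINER_FORMAT_VERSION))
  x
}

#' Declared storage size of a dataset shape
#'
#' Size of the raw cube payload implied by a dataset shape at a given
#' element width, computed from the declared dimensions only (no data are
#' generated). The full-scale X-ray configuration (100 images, 300 bins,
#' 512 x 512) at float32 gives 31.5 GB.
#'
#' @param n_images,n_bins,height,width Declared dimensions.
#' @param bytes_per_value Element width in bytes (default 4, float32).
#' @return List with `bytes` and `gb` (decimal GB).
#' @export
dataset_storage <- function(n_images, n_bins, height, width,
                            bytes_per_value = 4) {
  b <- unname(as.numeric(n_images) * n_bins * height * width *
                bytes_per_value)
  list(bytes = b, gb = b / 1e9)
}

#' Declared shape of a dataset configuration
#' @param config An `xray_config` or `remote_config`.
#' @return Named vector (n_images, n_bins, height, width).
#' @export
dataset_shape <- function(config) {
  stopifnot(inherits(config, "xray_config") ||
              inherits(config, "remote_config"))
  c(n_images = config$n_images, n_bins = config$n_bins,
    height = config$size, width = config$size)
}

#' Convert transmittance cubes to absorbance
#'
#' Applies `-log(max(x, eps))` to every cube: under Beer-Lambert physics
#' absorbance is linear in material path lengths, which can ease training
#' relative to the multiplicative transmittance representation. Labels and
#' provenance are preserved (with an `absorbance` marker).
#'
#' @param container A `dataset_container` of transmittance cubes.
#' @param eps Floor applied before the logarithm (default 1e-6).
#' @return The transformed `dataset_container`.
#' @export
to_absorbance <- function(container, eps = 1e-6) {
  stopifnot(inherits(container, "dataset_container"))
  container$cubes <- lapply(container$cubes,
                            function(cb) -log(pmax(cb, eps)))
  container$provenance$absorbance <- TRUE
  container
}

#' Export one spectral band as a grayscale image
#'
#' Min-max scaled 8-bit grayscale PNG of a single band of a single image,
#' for visual inspection of the simulated data.
#'
#' @param container A `dataset_container`.
#' @param image_idx,bin_idx 1-based indices.
#' @param path Output `.png` path.
#' @return The path, invisibly.
#' @export
export_band_image <- function(container, image_idx, bin_idx, path) {
  stopifnot(inherits(container, "dataset_container"))
  if (image_idx < 1 || image_idx > n_images(container))
    stop("image_idx out of range")
  if (bin_idx < 1 || bin_idx > container$grid$n_bins)
    stop("bin_idx out of range")
  band <- container$cubes[[image_idx]][, , bin_idx]
  rng <- range(band)
  scaled <- if (diff(rng) < 1e-300) band * 0
            else (band - rng[1]) / diff(rng)
  png::writePNG(scaled, path)
  invisible(path)
}
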
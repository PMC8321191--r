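# Small fixtures built in code, shared across test files.

tiny_kev_grid <- function(n = 40) make_band_grid(n, 13, 70, "keV")
tiny_nm_grid <- function(n = 64) make_band_grid(n, 450, 2400, "nm")

# brute-force voxel-stepping path length oracle for the analytic projector
voxel_pathlength <- function(origin, dir, cyl, step) {
  ts <- seq(0, 8, by = step)
  pts <- cbind(origin[1] + ts * dir[1], origin[2] + ts * dir[2],
               origin[3] + ts * dir[3])
  rel <- sweep(pts, 2, c(cyl$cx, cyl$cy, cyl$cz))
  a <- c(cyl$ax, cyl$ay, cyl$az)
  ax <- as.vector(rel %*% a)
  perp2 <- rowSums(rel^2) - ax^2
  sum(perp2 <= cyl$radius^2 & abs(ax) <= cyl$half_length) * step
}

random_unit <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

# a tiny clean X-ray dataset reused by several tests (built once per run)
tiny_xray_dataset <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- build_xray_dataset(
        xray_config(n_images = 4, size = 32, n_bins = 40, noise = FALSE,
                    raw_factor = 2L),
        seed = 7)
    cache
  }
})
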
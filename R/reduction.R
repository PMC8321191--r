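#' Spectral reduction scheme
#'
#' The reduction subnetwork is described by the list of layer widths
#' `D = [r0, r1, ..., r_dD]`: `r0` equals the number of spectral bins of
#' the attached data and the final entry is the number of reduced channels
#' `Nr`. Depth 1 (a single linear combination layer) gives the best
#' segmentation results in practice; deeper schemes are supported.
#'
#' @param D Integer vector of layer widths, length >= 2, all >= 1.
#' @return A `reduction_scheme`.
#' @export
reduction_scheme <- function(D) {
  D <- as.integer(D)
  if (length(D) < 2) stop("a reduction scheme needs at least [r0, Nr]")
  if (any(D < 1)) stop("all layer widths must be >= 1")
  if (any(diff(D) > 0))
    warning("reduction scheme is not non-increasing; this expands channels")
  structure(list(D = D, depth = length(D) - 1L, n_in = D[1],
                 n_out = D[length(D)]),
            class = "reduction_scheme")
}

#' Number of trainable parameters in a reduction scheme
#'
#' Sum over consecutive layer pairs of `r_{i-1} * r_i` weights plus `r_i`
#' biases.
#'
#' @param scheme A `reduction_scheme` (or plain integer vector).
#' @return Integer parameter count.
#' @export
reduction_param_count <- function(scheme) {
  D <- if (inherits(scheme, "reduction_scheme")) scheme$D else as.integer(scheme)
  sum(D[-length(D)] * D[-1] + D[-1])
}

#' Initialize reduction parameters
#'
#' Default initialization sets every weight and bias to zero (the
#' initialization under which the end-to-end training results were
#' obtained); `"xavier"` draws Glorot-normal weights for ablations.
#'
#' @param scheme A `reduction_scheme`.
#' @param mode `"zeros"` (default) or `"xavier"`.
#' @param seed Integer seed (xavier mode).
#' @param leak Leaky ReLU slope for negative inputs, in (0, 1]; default
#'   0.01, guarding against dying-ReLU collapse in the narrow final layers
#'   (1 makes the subnetwork purely linear).
#' @param final_activation Apply the Leaky ReLU after the last layer too
#'   (default TRUE).
#' @return `reduction_params`: per-layer weight matrices `W` (`r_i` x
#'   `r_{i-1}`) and bias vectors `b`, plus `leak` and the scheme.
#' @export
init_reduction <- function(scheme, mode = c("zeros", "xavier"), seed = 1L,
                           leak = 0.01, final_activation = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(scheme, "reduction_scheme"))
  if (leak <= 0 || leak > 1) stop("leak must be in (0, 1]")
  D <- scheme$D
  make_layer <- function(i) {
    w <- if (mode == "zeros") matrix(0, D[i + 1], D[i])
         else matrix(stats::rnorm(D[i + 1] * D[i],
                                  sd = sqrt(2 / (D[i] + D[i + 1]))),
                     D[i + 1], D[i])
    list(W = w, b = numeric(D[i + 1]))
  }
  layers <- if (mode == "xavier") {
    withr::with_seed(seed, lapply(seq_len(scheme$depth), make_layer))
  } else {
    lapply(seq_len(scheme$depth), make_layer)
  }
  structure(list(layers = layers, leak = leak, scheme = scheme,
                 final_activation = final_activation),
            class = "reduction_params")
}

leaky_relu <- function(x, a) pmax(x, 0) + a * pmin(x, 0)
leaky_relu_grad <- function(x, a) (x >= 0) + a * (x < 0)

#' Apply the spectral reduction subnetwork
#'
#' Per pixel, iteratively computes `z_i = LeakyReLU(W_i z_{i-1} + b_i)`:
#' purely spectral 1x1 combinations, so the output at a pixel depends only
#' on the input spectrum at that pixel.
#'
#' @param cube `(H, W, r0)` hyperspectral array.
#' @param params `reduction_params` whose `r0` matches the cube.
#' @return `(H, W, Nr)` reduced array.
#' @export
reduction_forward <- function(cube, params) {
  stopifnot(inherits(params, "reduction_params"))
  d <- dim(cube)
  if (length(d) != 3 || d[3] != params$scheme$n_in)
    stop(sprintf("cube has %s channels; scheme expects %d",
                 if (length(d) == 3) d[3] else "?", params$scheme$n_in))
  x <- matrix(cube, d[1] * d[2], d[3])
  out <- reduction_fw_cache(x, params)$z
  array(out, c(d[1], d[2], params$scheme$n_out))
}

# forward keeping pre-activations for backprop; x is (npix x r0)
reduction_fw_cache <- function(x, params) {
  nl <- length(params$layers)
  pres <- vector("list", nl)
  ins <- vector("list", nl)
  z <- x
  for (i in seq_len(nl)) {
    ins[[i]] <- z
    pre <- z %*% t(params$layers[[i]]$W)
    pre <- sweep(pre, 2, params$layers[[i]]$b, "+")
    pres[[i]] <- pre
    z <- if (i < nl || params$final_activation)
      leaky_relu(pre, params$leak) else pre
  }
  list(z = z, pres = pres, ins = ins)
}

# backprop: dz is (npix x Nr); returns grads per layer (and input grad)
reduction_bw <- function(cache, params, dz) {
  nl <- length(params$layers)
  grads <- vector("list", nl)
  g <- dz
  for (i in rev(seq_len(nl))) {
    if (i < nl || params$final_activation)
      g <- g * leaky_relu_grad(cache$pres[[i]], params$leak)
    grads[[i]] <- list(W = t(g) %*% cache$ins[[i]], b = colSums(g))
    g <- g %*% params$layers[[i]]$W
  }
  list(layers = grads, dinput = g)
}

#' First-layer weight curves over the spectral axis
#'
#' Returns the rows of the first reduction layer's weight matrix as curves
#' over the input bins - the quantity inspected to see which spectral
#' features (K-edge straddles, suppressed noisy bands) the network learned.
#'
#' @param params `reduction_params` (trained or raw).
#' @param grid Optional `band_grid` to attach axis values.
#' @return List with `curves` (`r1` x `r0` matrix, one row per first-layer
#'   output channel) and `bands` (axis values or bin indices).
#' @export
extract_weight_curves <- function(params, grid = NULL) {
  stopifnot(inherits(params, "reduction_params"))
  w <- params$layers[[1]]$W
  bands <- if (is.null(grid)) seq_len(ncol(w)) else grid$centers
  list(curves = w, bands = bands)
}

#' Locate a K-edge signature in a weight curve
#'
#' A reduction layer that has learned to straddle a K-edge weights the
#' bins just below and just above the edge with opposite signs, so the
#' curve's extremes bracket the edge bin. Reports the argmax/argmin bins,
#' a contrast score (peak minus valley over the robust spread of the
#' curve away from the edge) and whether the global extremes straddle the
#' bin containing `edge_energy`: one extreme within 5 bins below-or-at,
#' the other within 5 bins at-or-above. The check is sign-invariant -
#' with a one-channel reduction the sign of the compressed image is
#' arbitrary, so peak-below/valley-above and its mirror both count.
#'
#' @param curve Numeric weight curve of length `n_bins`.
#' @param grid The keV `band_grid`.
#' @param edge_energy K-edge energy in keV.
#' @return List `peak_bin`, `valley_bin`, `contrast`, `localized`.
#' @export
kedge_localization <- function(curve, grid, edge_energy) {
  stopifnot(inherits(grid, "band_grid"), length(curve) == grid$n_bins)
  if (grid$unit != "keV") stop("K-edge localization needs a keV grid")
  peak <- which.max(curve)
  valley <- which.min(curve)
  eb <- band_index(grid, edge_energy)
  away <- abs(seq_along(curve) - eb) > 5
  spread <- stats::mad(curve[away])
  if (!is.finite(spread) || spread < 1e-12)
    spread <- stats::sd(curve[away])
  contrast <- if (!is.finite(spread) || spread < 1e-12) {
    if (curve[peak] - curve[valley] < 1e-12) 0 else Inf
  } else {
    (curve[peak] - curve[valley]) / spread
  }
  straddle <- function(lo, hi) {
    lo >= eb - 5 && lo <= eb && hi >= eb && hi <= eb + 5
  }
  localized <- straddle(peak, valley) || straddle(valley, peak)
  list(peak_bin = peak, valley_bin = valley, contrast = contrast,
       localized = localized)
}
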
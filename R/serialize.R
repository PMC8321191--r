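#' Save / load a trained model
#'
#' @param model A `trained_model`.
#' @param path File path.
#' @return `load_model` returns the `trained_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "trained_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  x <- readRDS(path)
  if (!inherits(x, "trained_model")) stop("file is not a trained model")
  x
}

#' Export a spectral reduction as a portable JSON compressor
#'
#' The trained reduction subnetwork (or a fitted baseline reducer) is a
#' small standalone spectral compressor; this writes it as plain JSON so
#' compression can be applied independently of the segmentation CNN.
#'
#' @param reduction A `reduction_params` or `linear_reducer` (or a
#'   `trained_model`, whose reduction component is taken).
#' @param path Output `.json` path.
#' @export
export_reduction <- function(reduction, path) {
  if (inherits(reduction, "trained_model")) reduction <- reduction$reduction
  obj <- if (inherits(reduction, "reduction_params")) {
    list(type = "reduction_network", D = reduction$scheme$D,
         leak = reduction$leak,
         final_activation = reduction$final_activation,
         layers = lapply(reduction$layers, function(l)
           list(W = l$W, b = l$b)))
  } else if (inherits(reduction, "linear_reducer")) {
    list(type = "linear_reducer", kind = reduction$kind,
         transform = reduction$transform, offset = reduction$offset)
  } else stop("not a reduction object")
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a portable reduction compressor
#' @param path A `.json` file written by [export_reduction()].
#' @return A `reduction_params` or `linear_reducer`.
#' @export
import_reduction <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE,
                             simplifyDataFrame = FALSE,
                             simplifyMatrix = TRUE)
  as_mat <- function(w, nrow, ncol) {
    if (is.matrix(w)) w else matrix(unlist(w), nrow, ncol, byrow = TRUE)
  }
  if (identical(obj$type, "reduction_network")) {
    scheme <- suppressWarnings(reduction_scheme(obj$D))
    params <- init_reduction(scheme, leak = obj$leak,
                             final_activation = obj$final_activation)
    for (i in seq_along(params$layers)) {
      params$layers[[i]]$W <- as_mat(obj$layers[[i]]$W,
                                     scheme$D[i + 1], scheme$D[i])
      params$layers[[i]]$b <- as.numeric(obj$layers[[i]]$b)
    }
    params
  } else if (identical(obj$type, "linear_reducer")) {
    tr <- obj$transform
    if (!is.matrix(tr)) tr <- matrix(unlist(tr), ncol = length(obj$offset),
                                     byrow = TRUE)
    structure(list(kind = obj$kind, transform = tr,
                   offset = as.numeric(obj$offset), nr = nrow(tr),
                   n_bins = ncol(tr), n_pixels = NA_integer_,
                   extras = list()),
              class = "linear_reducer")
  } else stop("unknown reduction file type")
}

#' Apply a reduction to every cube of a dataset container
#'
#' @param container A `dataset_container`.
#' @param reduction A `reduction_params` or `linear_reducer`.
#' @return A new `dataset_container` whose cubes hold the reduced
#'   channels (band grid replaced by channel indices over a unit axis).
#' @export
reduce_container <- function(container, reduction) {
  stopifnot(inherits(container, "dataset_container"))
  cubes <- lapply(container$cubes,
                  function(cb) apply_reduction_any(cb, reduction))
  nr <- dim(cubes[[1]])[3]
  prov <- container$provenance
  prov$reduced <- TRUE
  out <- container
  out$cubes <- cubes
  # reduced channels live on a unitless index axis
  out$grid <- structure(list(n_bins = nr, axis_min = 0, axis_max = nr,
                             unit = container$grid$unit,
                             centers = seq_len(nr) - 0.5, width = 1),
                        class = "band_grid")
  out$provenance <- prov
  out
}
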
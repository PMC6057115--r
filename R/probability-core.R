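#' @useDynLib synscreen, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pnorm rnorm sd
NULL

PROB_STAGES <- c("foreground", "blob2d", "punctum3d", "synapse")

# internal constructor: carries voxel geometry forward so densities can be
# computed from any downstream object without re-threading the source volume
new_probability_map <- function(values, stage, geom) {
  stopifnot(stage %in% PROB_STAGES)
  structure(
    list(values = values, stage = stage,
         pixel_size_xy = geom$pixel_size_xy,
         slice_thickness = geom$slice_thickness,
         channel_name = geom$channel_name),
    class = "probability_map")
}

#' @export
print.probability_map <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("probability_map [%s] '%s': %d x %d x %d, range [%.4g, %.4g]\n",
              x$stage, x$channel_name, d[1], d[2], d[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Gaussian background model of a channel
#'
#' Models the whole channel as background noise and signal as outliers: the
#' background is a normal distribution whose parameters are the arithmetic
#' mean and the population (divide-by-n) standard deviation of all voxel
#' intensities.
#'
#' @param volume An [image_volume()].
#' @return A list of class `background_model` with fields `mean` and `sd`.
#' @details A constant channel has zero variance and cannot score outliers;
#'   it is rejected with error `"degenerate background"` rather than mapped
#'   to an uninformative all-0.5 probability map.
#' @export
estimate_background <- function(volume) {
  stopifnot(inherits(volume, "image_volume"))
  x <- volume$intensities
  if (length(x) == 0L) stop("empty input")
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))  # population convention
  if (s == 0) stop("degenerate background")
  structure(list(mean = m, sd = s), class = "background_model")
}

#' Per-voxel foreground probability
#'
#' The probability that a voxel is signal rather than background is one minus
#' its lower-tail background probability under the Gaussian background model,
#' i.e. the standard normal CDF of its z-score:
#' `p = pnorm((I - mean) / sd)`.  A voxel at the background mean scores 0.5;
#' the map is monotone non-decreasing in intensity and invariant to adding a
#' constant to the whole channel (when the model is re-estimated).
#'
#' @param volume An [image_volume()].
#' @param model A `background_model`; defaults to [estimate_background()] of
#'   `volume`.
#' @return A `probability_map` with stage `"foreground"`.
#' @export
foreground_probability <- function(volume, model = estimate_background(volume)) {
  stopifnot(inherits(volume, "image_volume"))
  if (!is.finite(model$sd) || model$sd <= 0) stop("background sd must be > 0")
  p <- pnorm((volume$intensities - model$mean) / model$sd)
  new_probability_map(p, "foreground", volume)
}

#' In-plane blob probability by window products
#'
#' Enforces the minimum expected 2D blob size: for every voxel, on its slice,
#' the probabilities in each `window_xy` region are multiplied, and the voxel
#' receives the maximum product over all windows that lie fully inside the
#' slice and contain it.  A qualifying blob thus stamps its probability onto
#' every voxel it covers; voxels whose every covering window is clipped by the
#' slice border receive 0 (a blob must have full minimum support).
#'
#' Products are accumulated in log space and exponentiated once, so large
#' windows do not underflow; the result equals the direct product to within
#' 1e-12.
#'
#' @param fg A `probability_map` with stage `"foreground"`.
#' @param window_xy Integer pair `(rows, cols)` of the minimum in-plane blob
#'   size in pixels; default 2 x 2 (0.2 x 0.2 um at 100 nm pixels).
#' @return A `probability_map` with stage `"blob2d"`.
#' @export
blob2d_probability <- function(fg, window_xy = c(2L, 2L)) {
  stopifnot(inherits(fg, "probability_map"))
  if (fg$stage != "foreground")
    stop("'fg' must be a foreground-stage probability map")
  w <- as.integer(round(window_xy))
  if (length(w) == 1L) w <- c(w, w)
  d <- dim(fg$values)
  if (any(w < 1L)) stop("window must be at least 1 x 1")
  if (w[1] > d[2] || w[2] > d[3]) stop("window larger than the slice")
  out <- array(0, d)
  for (z in seq_len(d[1]))
    out[z, , ] <- window_product_max(fg$values[z, , ], w[1], w[2])
  new_probability_map(out, "blob2d", fg)
}

# product over every fully-interior wy x wx window, then max over the windows
# containing each pixel; log-space for numerical robustness
window_product_max <- function(m, wy, wx) {
  ny <- nrow(m); nx <- ncol(m)
  L <- log(m)                               # 0 -> -Inf annihilates a window
  ay <- ny - wy + 1L; ax <- nx - wx + 1L    # anchor grid (top-left corners)
  S <- matrix(0, ay, ax)
  for (dy in 0:(wy - 1L)) for (dx in 0:(wx - 1L))
    S <- S + L[(1L + dy):(ay + dy), (1L + dx):(ax + dx), drop = FALSE]
  R <- matrix(-Inf, ny, nx)
  for (dy in 0:(wy - 1L)) for (dx in 0:(wx - 1L)) {
    ry <- (1L + dy):(ay + dy); rx <- (1L + dx):(ax + dx)
    R[ry, rx] <- pmax(R[ry, rx], S)
  }
  exp(R)
}

#' Consecutive-slice span probability
#'
#' Enforces the minimum section span of a 3D punctum: at each `(y, x)`
#' position the blob probabilities of every run of `span_slices` consecutive
#' slices are multiplied, and each voxel receives the maximum product over the
#' runs containing its slice.  Both slices of a 2-slice punctum therefore
#' carry the punctum's probability.  `span_slices = 1` is the identity.
#'
#' @param blob A `probability_map` with stage `"blob2d"`.
#' @param span_slices Minimum number of consecutive slices (>= 1).
#' @return A `probability_map` with stage `"punctum3d"`.
#' @export
span_probability <- function(blob, span_slices = 2L) {
  stopifnot(inherits(blob, "probability_map"))
  if (blob$stage != "blob2d")
    stop("'blob' must be a blob2d-stage probability map")
  s <- as.integer(round(span_slices))
  if (s < 1L) stop("span must be at least 1 slice")
  d <- dim(blob$values)
  if (s > d[1]) stop("span exceeds stack depth")
  if (s == 1L)  # identity, bit-for-bit
    return(new_probability_map(blob$values, "punctum3d", blob))
  L <- log(blob$values)
  na <- d[1] - s + 1L                       # number of runs
  S <- array(0, c(na, d[2], d[3]))
  for (dz in 0:(s - 1L))
    S <- S + L[(1L + dz):(na + dz), , , drop = FALSE]
  R <- array(-Inf, d)
  for (dz in 0:(s - 1L)) {
    rz <- (1L + dz):(na + dz)
    R[rz, , ] <- pmax(R[rz, , , drop = FALSE], S)
  }
  new_probability_map(exp(R), "punctum3d", blob)
}
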
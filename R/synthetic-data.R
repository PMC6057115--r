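#' Specification of a synthetic two-channel array-tomography volume
#'
#' Describes a ground-truthed synthetic dataset with the statistical
#' structure the detector assumes: Gaussian background noise, compact
#' multi-slice candidate and reference puncta with planted colocalized /
#' adjacent / isolated relationships, single-slice contaminant specks, and
#' occasional giant clusters emulating erratic labeling.
#'
#' Puncta are separable blobs: an isotropic in-plane Gaussian intensity
#' profile (truncated to a square footprint) repeated identically over the
#' punctum's slice extent, added onto the background.  Amplitudes are in
#' background-SD units, so detectability is stated as a signal-to-noise
#' ratio.
#'
#' @param shape Volume dimensions `(nz, ny, nx)`; default `c(8, 256, 256)`.
#' @param pixel_size_xy,slice_thickness Voxel geometry in nm (default
#'   100 / 70, so micrometer queries convert to the usual 2 px / 2 slices).
#' @param background_mean,background_sd Gaussian background parameters in
#'   intensity units (default 1000 / 100); values are clamped at 0.
#' @param amplitude Punctum peak amplitude in background-SD units (default
#'   10, a high-SNR regime).
#' @param sigma_xy In-plane Gaussian sigma in pixels (default 1).
#' @param footprint_radius Truncation radius of the in-plane profile in
#'   pixels (default 1, a 3 x 3 footprint).
#' @param z_extent Punctum slice span (default 3).
#' @param n_candidate Number of candidate-channel puncta.
#' @param adjacency_fraction,colocalization_fraction Fractions of candidate
#'   puncta given an adjacent / perfectly colocalized reference partner; the
#'   remainder are isolated (no reference punctum nearby).
#' @param n_reference_only Reference puncta with no candidate partner.
#' @param n_specks Single-slice contaminants in the candidate channel
#'   (bright, but spanning exactly 1 slice).
#' @param n_giant_clusters Large clusters in the candidate channel emulating
#'   erratic labeling (in-plane sigma `cluster_sigma_xy`, footprint 4x wider,
#'   full-depth span capped at 4 slices).
#' @param cluster_sigma_xy In-plane sigma of giant clusters, pixels.
#' @param adjacency_offset_xy In-plane offset range (pixels, Chebyshev) of an
#'   adjacent partner; default `c(2, 3)`, inside the 6 x 6 search window.
#' @param adjacency_offset_z Slice offset range of an adjacent partner;
#'   default `c(0, 1)`.
#' @param min_separation Minimum in-plane Chebyshev distance between planted
#'   object centers (partners excepted), pixels; default 12 keeps isolated
#'   objects outside any default search window.
#' @param seed RNG seed recorded in the ground truth; the generator is
#'   deterministic given the spec.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(shape = c(8L, 256L, 256L),
                           pixel_size_xy = 100, slice_thickness = 70,
                           background_mean = 1000, background_sd = 100,
                           amplitude = 10, sigma_xy = 1,
                           footprint_radius = 1L, z_extent = 3L,
                           n_candidate = 50L,
                           adjacency_fraction = 0,
                           colocalization_fraction = 0,
                           n_reference_only = 0L,
                           n_specks = 0L,
                           n_giant_clusters = 0L,
                           cluster_sigma_xy = 6,
                           adjacency_offset_xy = c(2L, 3L),
                           adjacency_offset_z = c(0L, 1L),
                           min_separation = 12L,
                           seed = 1L) {
  spec <- list(shape = as.integer(shape),
               pixel_size_xy = pixel_size_xy, slice_thickness = slice_thickness,
               background_mean = background_mean, background_sd = background_sd,
               amplitude = amplitude, sigma_xy = sigma_xy,
               footprint_radius = as.integer(footprint_radius),
               z_extent = as.integer(z_extent),
               n_candidate = as.integer(n_candidate),
               adjacency_fraction = adjacency_fraction,
               colocalization_fraction = colocalization_fraction,
               n_reference_only = as.integer(n_reference_only),
               n_specks = as.integer(n_specks),
               n_giant_clusters = as.integer(n_giant_clusters),
               cluster_sigma_xy = cluster_sigma_xy,
               adjacency_offset_xy = as.integer(adjacency_offset_xy),
               adjacency_offset_z = as.integer(adjacency_offset_z),
               min_separation = as.integer(min_separation),
               seed = as.integer(seed))
  stopifnot(length(spec$shape) == 3L, all(spec$shape >= 1L),
            spec$background_sd > 0, spec$amplitude >= 0,
            spec$adjacency_fraction >= 0, spec$colocalization_fraction >= 0,
            spec$adjacency_fraction + spec$colocalization_fraction <= 1,
            spec$n_candidate >= 0L, spec$n_reference_only >= 0L,
            spec$n_specks >= 0L, spec$n_giant_clusters >= 0L,
            spec$z_extent >= 1L, spec$z_extent <= spec$shape[1],
            spec$min_separation >= 1L)
  class(spec) <- "synthetic_spec"
  spec
}

#' Generate a ground-truthed synthetic dataset
#'
#' Draws the background of each channel from the spec's Gaussian noise model
#' (clamped at 0), plants candidate and reference puncta with the requested
#' adjacency / colocalization structure plus specks and giant clusters, and
#' rounds intensities to integers (camera counts).  Deterministic given the
#' spec (the spec's `seed` seeds the session RNG via `set.seed()`).
#'
#' @param spec A [synthetic_spec()].
#' @return List with `channels` (named list of [image_volume()]s,
#'   `"candidate"` and `"reference"`) and `truth`, a data frame of class
#'   `ground_truth` with one row per planted object: `channel`, `type` (one
#'   of `"synaptic-pair"`, `"isolated"`, `"speck"`, `"cluster"`), center
#'   `z, y, x` (1-based voxel coordinates) and `pair_id` linking candidate
#'   and reference partners (`NA` for unpaired objects).  The spec's seed is
#'   attached as attribute `seed`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  d <- spec$shape
  n_adj <- round(spec$n_candidate * spec$adjacency_fraction)
  n_col <- min(round(spec$n_candidate * spec$colocalization_fraction),
               spec$n_candidate - n_adj)
  n_iso <- spec$n_candidate - n_adj - n_col

  margin_xy <- max(spec$footprint_radius,
                   if (spec$n_giant_clusters > 0L) 4 * ceiling(spec$cluster_sigma_xy) else 0L,
                   max(spec$adjacency_offset_xy)) + 1L
  zr <- (spec$z_extent - 1L) %/% 2L
  z_lo <- 1L + zr + max(spec$adjacency_offset_z)
  z_hi <- d[1] - (spec$z_extent - 1L - zr) - max(spec$adjacency_offset_z)
  n_total <- spec$n_candidate + spec$n_specks + spec$n_giant_clusters
  if (n_total > 0L) {
    if (z_lo > z_hi) stop("volume too shallow for the punctum z extent")
    if (2L * margin_xy + 4L >= min(d[2], d[3])) stop("volume too small in plane")
  }
  centers <- place_centers(n_total, d, margin_xy, z_lo, z_hi,
                           spec$min_separation)
  i_cand <- seq_len(spec$n_candidate)
  i_speck <- spec$n_candidate + seq_len(spec$n_specks)
  i_clus <- spec$n_candidate + spec$n_specks + seq_len(spec$n_giant_clusters)

  truth <- list()
  cand <- array(0, d); ref <- array(0, d)
  amp <- spec$amplitude * spec$background_sd
  types <- rep(c("synaptic-pair", "synaptic-pair", "isolated"),
               c(n_adj, n_col, n_iso))
  pair_id <- 0L
  for (i in i_cand) {
    ctr <- centers[i, ]
    cand <- add_punctum(cand, ctr, amp, spec$sigma_xy,
                        spec$footprint_radius, spec$z_extent)
    rec <- data.frame(channel = "candidate", type = types[i],
                      z = ctr[1], y = ctr[2], x = ctr[3], pair_id = NA_integer_)
    if (i <= n_adj) {                      # adjacent reference partner
      pair_id <- pair_id + 1L
      off <- adjacency_offset(spec)
      pctr <- ctr + off
      ref <- add_punctum(ref, pctr, amp, spec$sigma_xy,
                         spec$footprint_radius, spec$z_extent)
      rec$pair_id <- pair_id
      truth[[length(truth) + 1L]] <-
        data.frame(channel = "reference", type = "synaptic-pair",
                   z = pctr[1], y = pctr[2], x = pctr[3], pair_id = pair_id)
    } else if (i <= n_adj + n_col) {       # perfectly colocalized partner
      pair_id <- pair_id + 1L
      ref <- add_punctum(ref, ctr, amp, spec$sigma_xy,
                         spec$footprint_radius, spec$z_extent)
      rec$pair_id <- pair_id
      truth[[length(truth) + 1L]] <-
        data.frame(channel = "reference", type = "synaptic-pair",
                   z = ctr[1], y = ctr[2], x = ctr[3], pair_id = pair_id)
    }
    truth[[length(truth) + 1L]] <- rec
  }
  for (i in i_speck) {                     # single-slice contaminants
    ctr <- centers[i, ]
    cand <- add_punctum(cand, ctr, amp, spec$sigma_xy,
                        spec$footprint_radius, 1L)
    truth[[length(truth) + 1L]] <-
      data.frame(channel = "candidate", type = "speck",
                 z = ctr[1], y = ctr[2], x = ctr[3], pair_id = NA_integer_)
  }
  for (i in i_clus) {                      # erratic-labeling clusters
    ctr <- centers[i, ]
    cand <- add_punctum(cand, ctr, amp, spec$cluster_sigma_xy,
                        4L * ceiling(spec$cluster_sigma_xy),
                        min(4L, d[1]))
    truth[[length(truth) + 1L]] <-
      data.frame(channel = "candidate", type = "cluster",
                 z = ctr[1], y = ctr[2], x = ctr[3], pair_id = NA_integer_)
  }

  noise <- function() pmax(array(rnorm(prod(d), spec$background_mean,
                                       spec$background_sd), d), 0)
  mk <- function(signal, name)
    image_volume(round(pmax(noise() + signal, 0)),
                 spec$pixel_size_xy, spec$slice_thickness, name)
  channels <- list(candidate = mk(cand, "candidate"),
                   reference = mk(ref, "reference"))
  truth <- if (length(truth)) do.call(rbind, truth)
           else data.frame(channel = character(), type = character(),
                           z = integer(), y = integer(), x = integer(),
                           pair_id = integer())
  attr(truth, "seed") <- spec$seed
  class(truth) <- c("ground_truth", "data.frame")
  list(channels = channels, truth = truth)
}

# rejection-sample object centers with a minimum in-plane Chebyshev
# separation; fully-interior margins are enforced by the sampling ranges
place_centers <- function(n, d, margin_xy, z_lo, z_hi, min_sep) {
  if (n == 0L) return(matrix(integer(), 0L, 3L))
  ys <- xs <- zs <- integer(n)
  tries <- 0L
  for (i in seq_len(n)) {
    repeat {
      tries <- tries + 1L
      if (tries > 200L * n + 10000L) stop("infeasible packing")
      y <- sample((1L + margin_xy):(d[2] - margin_xy), 1L)
      x <- sample((1L + margin_xy):(d[3] - margin_xy), 1L)
      if (i == 1L) break
      prev <- seq_len(i - 1L)
      if (min(pmax(abs(ys[prev] - y), abs(xs[prev] - x))) >= min_sep) break
    }
    zs[i] <- sample(z_lo:z_hi, 1L)
    ys[i] <- y; xs[i] <- x
  }
  cbind(z = zs, y = ys, x = xs)
}

adjacency_offset <- function(spec) {
  r_xy <- spec$adjacency_offset_xy
  r_z <- spec$adjacency_offset_z
  mag <- if (r_xy[1] == r_xy[2]) r_xy[1] else sample(r_xy[1]:r_xy[2], 1L)
  ang <- sample(0:3, 1L)                  # axis-aligned; keeps Chebyshev = mag
  dyx <- switch(ang + 1L, c(mag, 0L), c(-mag, 0L), c(0L, mag), c(0L, -mag))
  dz <- if (r_z[1] == r_z[2]) r_z[1] else sample(r_z[1]:r_z[2], 1L)
  c(dz * sample(c(-1L, 1L), 1L), dyx)
}

# add a separable blob: truncated in-plane Gaussian, flat z profile
add_punctum <- function(vol, center, amp, sigma, radius, z_extent) {
  d <- dim(vol)
  zr <- (z_extent - 1L) %/% 2L
  zz <- (center[1] - zr):(center[1] - zr + z_extent - 1L)
  zz <- zz[zz >= 1L & zz <= d[1]]
  yy <- (center[2] - radius):(center[2] + radius)
  xx <- (center[3] - radius):(center[3] + radius)
  keep_y <- yy >= 1L & yy <= d[2]; keep_x <- xx >= 1L & xx <= d[3]
  prof <- outer(exp(-(yy - center[2])^2 / (2 * sigma^2)),
                exp(-(xx - center[3])^2 / (2 * sigma^2)))[keep_y, keep_x,
                                                          drop = FALSE]
  for (z in zz)
    vol[z, yy[keep_y], xx[keep_x]] <- vol[z, yy[keep_y], xx[keep_x]] + amp * prof
  vol
}

#' Score detections against planted ground truth
#'
#' Greedy one-to-one matching (closest pairs first) of detected centroids to
#' planted object centers within a radius, in voxel units.
#'
#' @param detected A `punctum_set` or `synapse_set`.
#' @param truth A `ground_truth` data frame from [generate_dataset()].
#' @param match_radius Maximum centroid-to-center Euclidean distance in
#'   voxels (>= 1).
#' @param channel Which truth channel to score against (default
#'   `"candidate"`).
#' @param types Which truth object types count as ground truth; defaults to
#'   real puncta (`"synaptic-pair"`, `"isolated"`), excluding specks and
#'   clusters.
#' @return List with `precision` (`NA` when nothing was detected), `recall`,
#'   and `n_matched`, `n_detected`, `n_planted`.
#' @export
score_against_truth <- function(detected, truth, match_radius = 2,
                                channel = "candidate",
                                types = c("synaptic-pair", "isolated")) {
  stopifnot(inherits(detected, "punctum_set"), match_radius >= 1)
  tt <- truth[truth$channel == channel & truth$type %in% types, , drop = FALSE]
  det <- detected$puncta
  n_det <- nrow(det); n_pl <- nrow(tt)
  if (n_det == 0L || n_pl == 0L)
    return(list(precision = if (n_det == 0L) NA_real_ else 0,
                recall = if (n_pl == 0L) NA_real_ else 0,
                n_matched = 0L, n_detected = n_det, n_planted = n_pl))
  dist2 <- outer(det$z, tt$z, "-")^2 + outer(det$y, tt$y, "-")^2 +
    outer(det$x, tt$x, "-")^2
  ok <- which(dist2 <= match_radius^2, arr.ind = TRUE)
  ok <- ok[order(dist2[ok]), , drop = FALSE]
  used_d <- logical(n_det); used_t <- logical(n_pl); m <- 0L
  for (k in seq_len(nrow(ok))) {
    i <- ok[k, 1]; j <- ok[k, 2]
    if (!used_d[i] && !used_t[j]) { used_d[i] <- used_t[j] <- TRUE; m <- m + 1L }
  }
  list(precision = m / n_det, recall = m / n_pl,
       n_matched = m, n_detected = n_det, n_planted = n_pl)
}
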
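#' Spatial relationship between candidate and reference puncta
#'
#' A target synapse is declared where a candidate punctum is colocalized with
#' or adjacent to reference puncta.  Colocalization searches a 2 x 2 pixel
#' in-plane window on the same slice (both markers on the same synaptic
#' side); adjacency searches a 6 x 6 pixel window and one slice up or down
#' (e.g. presynaptic vs postsynaptic partners, which may sit on neighboring
#' sections).
#'
#' Even-sized windows have no central pixel; the search neighborhood is taken
#' symmetric with reach `floor(window / 2)` pixels per in-plane axis (1 px for
#' the 2 x 2 colocalization window, 3 px for the 6 x 6 adjacency window).
#'
#' @param kind `"colocalized"` or `"adjacent"`.
#' @param window_xy In-plane search window in pixels; defaults 2 (colocalized)
#'   or 6 (adjacent).  A single value is used for both axes.
#' @param z_reach Slices the reference may be offset in z; defaults 0
#'   (colocalized) or 1 (adjacent).
#' @return An object of class `relationship`.
#' @export
relationship <- function(kind = c("colocalized", "adjacent"),
                         window_xy = NULL, z_reach = NULL) {
  kind <- match.arg(kind)
  if (is.null(window_xy)) window_xy <- if (kind == "colocalized") 2L else 6L
  if (is.null(z_reach)) z_reach <- if (kind == "colocalized") 0L else 1L
  if (length(window_xy) == 1L) window_xy <- rep(window_xy, 2L)
  window_xy <- as.integer(round(window_xy))
  z_reach <- as.integer(round(z_reach))
  stopifnot(length(window_xy) == 2L, all(window_xy >= 1L),
            length(z_reach) == 1L, z_reach >= 0L)
  if (kind == "adjacent" && any(window_xy < 2L))
    stop("adjacency window must be at least the colocalization window")
  structure(list(kind = kind, window_xy = window_xy, z_reach = z_reach),
            class = "relationship")
}

#' Synapse query: candidate channel plus reference relationships
#'
#' Bundles the candidate antibody's minimum punctum size with one or more
#' reference antibodies, each carrying its own minimum punctum size and its
#' relationship (colocalized or adjacent) to the candidate.  All channel
#' names must be distinct and at least one reference is required: a synapse
#' is only declared where the candidate punctum and every reference punctum
#' coincide under the stated relationships.
#'
#' @param candidate A [punctum_query()] for the candidate channel.
#' @param references A list of references, each a list with elements `query`
#'   (a [punctum_query()]) and `rel` (a [relationship()]); a single reference
#'   may be passed unwrapped.
#' @param threshold Probability threshold used when segmenting the synapse
#'   map (default 0.9).
#' @return An object of class `synapse_query`.
#' @export
synapse_query <- function(candidate, references, threshold = 0.9) {
  stopifnot(inherits(candidate, "punctum_query"))
  if (!is.null(references$query)) references <- list(references)
  if (length(references) == 0L) stop("query requires at least one reference")
  for (r in references)
    stopifnot(inherits(r$query, "punctum_query"), inherits(r$rel, "relationship"))
  chans <- c(candidate$channel_name,
             vapply(references, function(r) r$query$channel_name, ""))
  if (anyDuplicated(chans))
    stop("candidate and reference channel names must be distinct")
  stopifnot(is.numeric(threshold), length(threshold) == 1L,
            threshold > 0, threshold < 1)
  structure(list(candidate = candidate, references = references,
                 threshold = threshold),
            class = "synapse_query")
}

#' Association factor of a reference channel
#'
#' For every voxel, the maximum reference punctum probability found within
#' the relationship's search neighborhood: in-plane reach
#' `floor(window / 2)` pixels per axis and z offsets within `z_reach` slices.
#' Neighborhoods are clipped at the volume border (a maximum over a partial
#' neighborhood is well-defined).  Multiplying the candidate's punctum map by
#' this factor keeps candidate probability only where a reference punctum is
#' close enough.
#'
#' @param reference_prob A `probability_map` with stage `"punctum3d"` for the
#'   reference channel.
#' @param rel A [relationship()].
#' @return A `probability_map` (stage `"punctum3d"`) of the same shape.
#' @export
association_factor <- function(reference_prob, rel) {
  stopifnot(inherits(reference_prob, "probability_map"),
            inherits(rel, "relationship"))
  if (reference_prob$stage != "punctum3d")
    stop("'reference_prob' must be a punctum3d-stage probability map")
  d <- dim(reference_prob$values)
  reach <- rel$window_xy %/% 2L
  if (2L * reach[1] + 1L > d[2] || 2L * reach[2] + 1L > d[3])
    stop("search window exceeds image extent")
  v <- dilate_axis(reference_prob$values, 3L, reach[2])
  v <- dilate_axis(v, 2L, reach[1])
  v <- dilate_axis(v, 1L, rel$z_reach)
  new_probability_map(v, "punctum3d", reference_prob)
}

# max over offsets in [-reach, reach] along one axis of a (z,y,x) array,
# clipped at the borders; box max filters are separable across axes
dilate_axis <- function(a, axis, reach) {
  n <- dim(a)[axis]
  if (reach == 0L || n == 1L) return(a)
  out <- a
  lo <- function(k) 1L:(n - k)
  hi <- function(k) (1L + k):n
  for (k in seq_len(min(reach, n - 1L))) {
    if (axis == 1L) {
      out[lo(k), , ] <- pmax(out[lo(k), , , drop = FALSE], a[hi(k), , , drop = FALSE])
      out[hi(k), , ] <- pmax(out[hi(k), , , drop = FALSE], a[lo(k), , , drop = FALSE])
    } else if (axis == 2L) {
      out[, lo(k), ] <- pmax(out[, lo(k), , drop = FALSE], a[, hi(k), , drop = FALSE])
      out[, hi(k), ] <- pmax(out[, hi(k), , drop = FALSE], a[, lo(k), , drop = FALSE])
    } else {
      out[, , lo(k)] <- pmax(out[, , lo(k), drop = FALSE], a[, , hi(k), drop = FALSE])
      out[, , hi(k)] <- pmax(out[, , hi(k), drop = FALSE], a[, , lo(k), drop = FALSE])
    }
  }
  out
}

#' Synapse probability map for a query
#'
#' Computes the candidate channel's punctum probability map and multiplies
#' it, voxel by voxel, by the association factor of every reference channel
#' (a probabilistic AND over the query's relationships).  No thresholding
#' happens here: the map is thresholded only after the cross-channel
#' association, by [detect_synapses()] or [segment_puncta()].
#'
#' @param channels Named list of [image_volume()]s covering every channel the
#'   query mentions; all must share the same shape.
#' @param query A [synapse_query()].
#' @return A `probability_map` with stage `"synapse"`, named after the
#'   candidate channel.
#' @export
synapse_probability <- function(channels, query) {
  stopifnot(inherits(query, "synapse_query"))
  chans <- c(query$candidate$channel_name,
             vapply(query$references, function(r) r$query$channel_name, ""))
  missing <- setdiff(chans, names(channels))
  if (length(missing))
    stop("missing channels: ", paste(missing, collapse = ", "))
  shapes <- vapply(channels[chans], function(v) paste(dim(v$intensities),
                                                      collapse = "x"), "")
  if (length(unique(shapes)) != 1L) stop("channels not aligned")
  cand <- compute_punctum_probability(channels[[query$candidate$channel_name]],
                                      query$candidate)
  p <- cand$values
  for (r in query$references) {
    ref <- compute_punctum_probability(channels[[r$query$channel_name]], r$query)
    p <- p * association_factor(ref, r$rel)$values
  }
  new_probability_map(p, "synapse", cand)
}

#' Detect target synapses
#'
#' Thresholds the synapse probability map of [synapse_probability()] at the
#' query's threshold and labels connected components; each component is one
#' detected target synapse containing the candidate antibody.
#'
#' @inheritParams synapse_probability
#' @param remediate Apply the split-artifact closing (see [segment_puncta()]).
#' @return A `synapse_set` (a `punctum_set` over the synapse map) carrying
#'   the query as provenance in its `query` field.
#' @export
detect_synapses <- function(channels, query, remediate = TRUE) {
  s <- segment_puncta(synapse_probability(channels, query),
                      threshold = query$threshold, remediate = remediate)
  s$query <- query
  s
}
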
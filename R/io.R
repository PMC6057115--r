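#' Read a channel from a multi-page grayscale TIFF
#'
#' Pages become slices in order, giving an array indexed `(z, y, x)`.  Voxel
#' geometry always comes from the caller (or the run configuration), never
#' from TIFF tags, which are unreliable in array-tomography exports.
#'
#' @param path TIFF file, one grayscale page per section.
#' @param channel_name Channel name to attach; defaults to the file stem.
#' @param pixel_size_xy,slice_thickness Voxel geometry in nm.
#' @param scale Multiplier applied to the values `tiff::readTIFF()` returns
#'   (which are normalized to `[0, 1]`); 65535 restores 16-bit integer
#'   counts, the convention [write_channel_stack()] writes.
#' @param round_to_int Round restored values to integers (exact round-trip
#'   for integer-valued data written at 16 bits).
#' @return An [image_volume()].
#' @export
read_channel_stack <- function(path, channel_name = NULL,
                               pixel_size_xy = 100, slice_thickness = 70,
                               scale = 65535, round_to_int = TRUE) {
  if (!file.exists(path)) stop("cannot read file: ", path)
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE),
                    error = function(e) stop("unreadable TIFF: ", path,
                                             " (", conditionMessage(e), ")"))
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("TIFF has zero pages: ", path)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1]   # tolerate single-band planar pages
    p
  })
  dims <- vapply(pages, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("TIFF pages have differing dimensions: ", path)
  a <- array(0, c(length(pages), dims[1, 1], dims[2, 1]))
  for (z in seq_along(pages)) a[z, , ] <- pages[[z]]
  a <- a * scale
  if (isTRUE(round_to_int)) a <- round(a)
  if (is.null(channel_name))
    channel_name <- sub("\\.[^.]*$", "", basename(path))
  image_volume(a, pixel_size_xy, slice_thickness, channel_name)
}

#' Write a channel, probability map or label volume as multi-page TIFF
#'
#' `write_channel_stack()` stores intensities as 16-bit integers (values are
#' divided by `scale`, by default 65535, and must land in `[0, 1]`).
#' `write_probability_map()` stores probabilities as 32-bit float pages.
#' `write_label_stack()` stores a segmentation's labels as 16-bit integers.
#'
#' @param volume An [image_volume()].
#' @param path Output file.
#' @param scale Full-scale intensity for 16-bit storage.
#' @return The path, invisibly.
#' @export
write_channel_stack <- function(volume, path, scale = 65535) {
  stopifnot(inherits(volume, "image_volume"))
  x <- volume$intensities / scale
  if (min(x) < 0 || max(x) > 1)
    stop("intensities outside [0, ", scale, "]; adjust 'scale'")
  write_pages(x, path, bits = 16L)
}

#' @rdname write_channel_stack
#' @param map A `probability_map`.
#' @export
write_probability_map <- function(map, path) {
  stopifnot(inherits(map, "probability_map"))
  write_pages(map$values, path, bits = 32L)
}

#' @rdname write_channel_stack
#' @param puncta A `punctum_set` or `synapse_set`.
#' @export
write_label_stack <- function(puncta, path) {
  stopifnot(inherits(puncta, "punctum_set"))
  if (nrow(puncta$puncta) > 65535L) stop("more than 65535 labels")
  write_pages(puncta$label_volume / 65535, path, bits = 16L)
}

write_pages <- function(a, path, bits) {
  pages <- lapply(seq_len(dim(a)[1]), function(z) a[z, , ])
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  invisible(path)
}

#' Write a punctum or synapse table as CSV
#'
#' One row per object: `id`, centroid `z, y, x`, `voxel_count`.  Plain UTF-8
#' CSV with a header row, `.` decimal mark and comma separator.
#'
#' @param puncta A `punctum_set` or `synapse_set`.
#' @param path Output file.
#' @return The path, invisibly.
#' @export
write_puncta_csv <- function(puncta, path) {
  stopifnot(inherits(puncta, "punctum_set"))
  utils::write.csv(puncta$puncta[c("id", "z", "y", "x", "voxel_count")],
                   path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Write measurement reports
#'
#' `write_report_csv()` writes one row per candidate per query;
#' `write_report_json()` writes the same measures nested under provenance
#' (query parameters, threshold, seed, package version).
#'
#' @param reports A `measurement_report` or list of them.
#' @param path Output file.
#' @param seed Seed recorded in the provenance block (JSON only).
#' @return The path, invisibly.
#' @export
write_report_csv <- function(reports, path) {
  utils::write.csv(report_table(reports), path, row.names = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_report_csv
#' @export
write_report_json <- function(reports, path, seed = NULL) {
  if (inherits(reports, "measurement_report")) reports <- list(reports)
  payload <- list(
    provenance = list(
      package = "synscreen",
      version = as.character(utils::packageVersion("synscreen")),
      seed = seed),
    reports = lapply(reports, function(r) {
      q <- r$query
      list(channel_name = r$channel_name,
           query_label = if (is.null(r$query_label)) "" else r$query_label,
           measures = r[c("punctum_density", "mean_punctum_volume",
                          "sd_punctum_volume", "target_synapse_density",
                          "tsr", "tsr_raw", "split_artifact",
                          "n_puncta", "n_synapses", "total_volume")],
           query = list(
             threshold = q$threshold,
             candidate = unclass(q$candidate),
             references = lapply(q$references, function(rr)
               list(query = unclass(rr$query), rel = unclass(rr$rel)))))
    }))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read and validate a run configuration
#'
#' Configurations are YAML or JSON (decided by file extension) and describe a
#' run: `channels` (name to TIFF path map), `pixel_size_xy` /
#' `slice_thickness` (nm), `candidate` (channel name), `references` (list of
#' `channel` / `kind`, with optional `window_xy`, `z_reach`,
#' `min_span_z_um`), `min_blob_xy_um`, `min_span_z_um`, `threshold`,
#' `remediate`, `expected_max_density`, `seed`.  Validation collects every
#' problem before failing, so a bad config is reported in full.
#'
#' @param path Config file (`.yaml`, `.yml` or `.json`).
#' @return A validated list of class `run_config` (with defaults filled in).
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("cannot read config: ", path)
  cfg <- switch(tolower(tools::file_ext(path)),
                "yaml" = , "yml" = yaml::read_yaml(path),
                "json" = jsonlite::read_json(path, simplifyVector = TRUE),
                stop("config must be .yaml, .yml or .json: ", path))
  validate_run_config(cfg)
}

validate_run_config <- function(cfg) {
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)
  # normalize shapes a JSON/YAML round-trip may produce
  if (!is.null(cfg$channels) && is.atomic(cfg$channels))
    cfg$channels <- as.list(cfg$channels)
  if (is.data.frame(cfg$references))
    cfg$references <- lapply(seq_len(nrow(cfg$references)), function(i)
      as.list(cfg$references[i, , drop = FALSE]))
  defaults <- list(pixel_size_xy = 100, slice_thickness = 70,
                   min_blob_xy_um = c(0.2, 0.2), min_span_z_um = 0.14,
                   threshold = 0.9, remediate = TRUE, seed = 1L)
  for (nm in names(defaults)) if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
  if (is.null(cfg$channels) || length(cfg$channels) == 0L)
    note("'channels' must map at least one channel name to a file path")
  else {
    if (is.null(names(cfg$channels)) || any(!nzchar(names(cfg$channels))))
      note("'channels' entries must be named")
    for (p in unlist(cfg$channels))
      if (!file.exists(p)) note(paste0("channel file does not exist: ", p))
  }
  if (is.null(cfg$candidate)) note("'candidate' channel name is required")
  else if (!is.null(names(cfg$channels)) && !cfg$candidate %in% names(cfg$channels))
    note(paste0("candidate channel '", cfg$candidate, "' not among channels"))
  if (is.null(cfg$references) || length(cfg$references) == 0L)
    note("query requires at least one reference")
  else for (r in cfg$references) {
    if (is.null(r$channel)) note("every reference needs a 'channel'")
    else if (!is.null(names(cfg$channels)) && !r$channel %in% names(cfg$channels))
      note(paste0("reference channel '", r$channel, "' not among channels"))
    if (!is.null(r$kind) && !r$kind %in% c("colocalized", "adjacent"))
      note(paste0("reference kind must be 'colocalized' or 'adjacent', got '",
                  r$kind, "'"))
  }
  if (!is.numeric(cfg$threshold) || cfg$threshold <= 0 || cfg$threshold >= 1)
    note("'threshold' must lie strictly between 0 and 1")
  if (!is.numeric(cfg$pixel_size_xy) || cfg$pixel_size_xy <= 0)
    note("'pixel_size_xy' must be a positive number of nanometers")
  if (!is.numeric(cfg$slice_thickness) || cfg$slice_thickness <= 0)
    note("'slice_thickness' must be a positive number of nanometers")
  if (length(problems))
    stop("invalid run configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  class(cfg) <- "run_config"
  cfg
}

# build package objects from a validated config
config_to_query <- function(cfg) {
  cand <- punctum_query(cfg$candidate, cfg$min_blob_xy_um, cfg$min_span_z_um)
  refs <- lapply(cfg$references, function(r) {
    kind <- if (is.null(r$kind)) "adjacent" else r$kind
    span <- if (is.null(r$min_span_z_um)) cfg$min_span_z_um else r$min_span_z_um
    blob <- if (is.null(r$min_blob_xy_um)) cfg$min_blob_xy_um else r$min_blob_xy_um
    list(query = punctum_query(r$channel, blob, span),
         rel = relationship(kind,
                            window_xy = r$window_xy,
                            z_reach = r$z_reach))
  })
  synapse_query(cand, refs, threshold = cfg$threshold)
}

config_load_channels <- function(cfg) {
  out <- lapply(names(cfg$channels), function(nm)
    read_channel_stack(cfg$channels[[nm]], nm,
                       cfg$pixel_size_xy, cfg$slice_thickness))
  names(out) <- names(cfg$channels)
  out
}
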
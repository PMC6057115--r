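#' Target synapse density per cubic micrometer
#'
#' Number of detected target synapses divided by the total imaged volume.
#' When the expected density of the target synapse population is known (on
#' the order of 1 per um^3 for excitatory and 0.15 per um^3 for inhibitory
#' synapses in rodent neocortex), a much lower value suggests low antibody
#' sensitivity or concentration, and a much higher value non-specific
#' binding.
#'
#' @param synapses A `synapse_set` from [detect_synapses()].
#' @return Density in synapses per um^3.
#' @export
target_synapse_density <- function(synapses) {
  stopifnot(inherits(synapses, "punctum_set"))
  punctum_density(synapses)
}

#' Target specificity ratio
#'
#' The fraction of candidate-antibody puncta associated with a detected
#' target synapse: detected synapse count divided by detected punctum count.
#' Values run from 1 (every punctum sits at a target synapse) down to 0 (none
#' does).  A ratio above 1 is an artifact of thresholding splitting a single
#' punctum in two; segmenting with remediation on (the default closing in
#' [segment_puncta()]) repairs it.
#'
#' @param synapses A `synapse_set`.
#' @param puncta The candidate channel's `punctum_set` over the same volume.
#' @return The ratio, or `NA` (with a warning) when no puncta were detected,
#'   so that "no signal" is distinguishable from "no specificity".
#' @export
target_specificity_ratio <- function(synapses, puncta) {
  stopifnot(inherits(synapses, "punctum_set"), inherits(puncta, "punctum_set"))
  np <- nrow(puncta$puncta)
  if (np == 0L) {
    warning("no detected puncta: target specificity ratio is undefined")
    return(NA_real_)
  }
  nrow(synapses$puncta) / np
}

#' Evaluate one candidate antibody under one query
#'
#' Runs punctum detection on the candidate channel and synapse detection for
#' the query, and assembles the four antibody-performance measures: punctum
#' density, punctum volume mean and SD, target synapse density, and target
#' specificity ratio (TSR).  Both the remediated TSR (split-artifact closing
#' on, the headline value) and the raw TSR (closing off) are reported; a raw
#' value above 1 flags a split artifact.  The identity
#' `tsr * punctum_density == target_synapse_density` holds by construction
#' over a common volume.
#'
#' @param channels Named list of [image_volume()]s.
#' @param query A [synapse_query()].
#' @return A list of class `measurement_report`; see
#'   [report_table()] for the tabular form.
#' @export
evaluate_antibody <- function(channels, query) {
  stopifnot(inherits(query, "synapse_query"))
  cand_name <- query$candidate$channel_name
  cand_prob <- compute_punctum_probability(channels[[cand_name]], query$candidate)
  puncta <- segment_puncta(cand_prob, query$threshold, remediate = TRUE)
  puncta_raw <- segment_puncta(cand_prob, query$threshold, remediate = FALSE)
  syn_prob <- synapse_probability(channels, query)
  synapses <- segment_puncta(syn_prob, query$threshold, remediate = TRUE)
  synapses$query <- query
  synapses_raw <- segment_puncta(syn_prob, query$threshold, remediate = FALSE)
  vs <- punctum_volume_stats(puncta)
  tsr <- if (nrow(puncta$puncta) > 0L)
    target_specificity_ratio(synapses, puncta) else NA_real_
  tsr_raw <- if (nrow(puncta_raw$puncta) > 0L)
    nrow(synapses_raw$puncta) / nrow(puncta_raw$puncta) else NA_real_
  structure(
    list(channel_name = cand_name,
         punctum_density = punctum_density(puncta),
         mean_punctum_volume = vs$mean_volume,
         sd_punctum_volume = vs$sd_volume,
         target_synapse_density = target_synapse_density(synapses),
         tsr = tsr,
         tsr_raw = tsr_raw,
         split_artifact = is.finite(tsr_raw) && tsr_raw > 1,
         n_puncta = nrow(puncta$puncta),
         n_synapses = nrow(synapses$puncta),
         total_volume = total_volume_um3(puncta),
         empty = vs$empty,
         query = query,
         puncta = puncta, synapses = synapses),
    class = "measurement_report")
}

#' @export
print.measurement_report <- function(x, ...) {
  cat(sprintf("measurement_report '%s'\n", x$channel_name))
  cat(sprintf("  puncta: %d (density %.4g per um^3, volume %.3g +/- %.3g px)\n",
              x$n_puncta, x$punctum_density,
              x$mean_punctum_volume, x$sd_punctum_volume))
  cat(sprintf("  target synapses: %d (density %.4g per um^3)\n",
              x$n_synapses, x$target_synapse_density))
  cat(sprintf("  target specificity ratio: %s (raw %s%s)\n",
              format(round(x$tsr, 4)), format(round(x$tsr_raw, 4)),
              if (isTRUE(x$split_artifact)) ", split artifact" else ""))
  invisible(x)
}

#' Tabulate measurement reports
#'
#' @param reports A `measurement_report` or list of them.
#' @return One data-frame row per report with the scalar measures.
#' @export
report_table <- function(reports) {
  if (inherits(reports, "measurement_report")) reports <- list(reports)
  cols <- c("channel_name", "punctum_density", "mean_punctum_volume",
            "sd_punctum_volume", "target_synapse_density", "tsr", "tsr_raw",
            "split_artifact", "n_puncta", "n_synapses", "total_volume")
  do.call(rbind, lapply(reports, function(r) {
    df <- as.data.frame(r[cols])
    df$query_label <- if (!is.null(r$query_label)) r$query_label else ""
    df
  }))
}

#' Query presets of increasing stringency
#'
#' Four named minimum-size presets for comparing antibody measurements under
#' varying stringency, given as candidate / reference minimum spans (all
#' presets keep the 0.2 x 0.2 um in-plane minimum):
#' Q1 0.07 / 0.07 um (1 slice / 1 slice), Q2 0.14 / 0.07 um (2 / 1),
#' Q3 0.14 / 0.14 um (2 / 2), Q4 0.21 / 0.07 um (3 / 1).
#' The single-slice Q1 is the most permissive and the least reliable for
#' ranking; Q2, the medium-stringency two-slice query, is the recommended
#' starting point.
#'
#' @return Named list of variants, each a list with `candidate_span_um` and
#'   `reference_span_um`.
#' @export
query_presets <- function() {
  list(Q1 = list(candidate_span_um = 0.07, reference_span_um = 0.07),
       Q2 = list(candidate_span_um = 0.14, reference_span_um = 0.07),
       Q3 = list(candidate_span_um = 0.14, reference_span_um = 0.14),
       Q4 = list(candidate_span_um = 0.21, reference_span_um = 0.07))
}

#' Evaluate an antibody under a sweep of query stringencies
#'
#' Re-runs [evaluate_antibody()] with the base query's minimum span
#' requirements replaced by each variant (candidate and reference spans in
#' micrometers); in-plane minima, relationships and threshold are unchanged.
#'
#' @param channels Named list of [image_volume()]s.
#' @param base_query A [synapse_query()].
#' @param variants Named list of variants as in [query_presets()] (the
#'   default).
#' @return A list of `measurement_report`s, one per variant, each tagged with
#'   its `query_label`.
#' @export
run_query_sweep <- function(channels, base_query, variants = query_presets()) {
  stopifnot(inherits(base_query, "synapse_query"))
  out <- vector("list", length(variants))
  names(out) <- names(variants)
  for (i in seq_along(variants)) {
    v <- variants[[i]]
    q <- base_query
    q$candidate$min_span_z_um <- v$candidate_span_um
    for (j in seq_along(q$references))
      q$references[[j]]$query$min_span_z_um <- v$reference_span_um
    rep <- evaluate_antibody(channels, q)
    rep$query_label <- names(variants)[i]
    out[[i]] <- rep
  }
  out
}

#' Rank candidate antibodies and exclude implausible ones
#'
#' Screening verdicts for a set of candidate-antibody reports obtained under
#' the same query family.  Candidates whose target synapse density exceeds
#' the user-supplied biological prior (`expected_max_density`, e.g. about
#' 1 per um^3 for excitatory and 0.15 per um^3 for inhibitory synapses in
#' rodent neocortex) are excluded with reason `"implausible density"`: a
#' density far above what the tissue can contain reflects non-specific
#' binding, not sensitivity.  The remaining candidates are ranked by target
#' specificity ratio, descending, with ties broken by target synapse density
#' descending (then by channel name, so the order is total and independent
#' of input order).  Candidates with an undefined TSR (no detected puncta)
#' rank last among the non-excluded.
#'
#' @param reports List of `measurement_report`s, one per candidate.
#' @param expected_max_density Maximum biologically plausible target synapse
#'   density, per um^3.
#' @return A data frame of class `screening_verdict` with one row per
#'   candidate: `channel_name`, `tsr`, `target_synapse_density`, `excluded`,
#'   `reason`, `rank` (`NA` for excluded candidates), ordered best first with
#'   excluded candidates at the bottom.
#' @export
rank_candidates <- function(reports, expected_max_density) {
  if (inherits(reports, "measurement_report")) reports <- list(reports)
  stopifnot(length(reports) > 0L, is.numeric(expected_max_density),
            expected_max_density > 0)
  tab <- data.frame(
    channel_name = vapply(reports, function(r) r$channel_name, ""),
    tsr = vapply(reports, function(r) as.numeric(r$tsr), 0),
    target_synapse_density =
      vapply(reports, function(r) r$target_synapse_density, 0))
  tab$excluded <- tab$target_synapse_density > expected_max_density
  tab$reason <- ifelse(tab$excluded, "implausible density", "")
  kept <- which(!tab$excluded)
  ord <- kept[order(-ifelse(is.na(tab$tsr[kept]), -Inf, tab$tsr[kept]),
                    -tab$target_synapse_density[kept],
                    tab$channel_name[kept])]
  tab$rank <- NA_integer_
  tab$rank[ord] <- seq_along(ord)
  out <- tab[c(ord, which(tab$excluded)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("screening_verdict", "data.frame")
  out
}
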
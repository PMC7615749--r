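#' Correlate Ca2+ response metrics with vascular response metrics
#'
#' Pearson and Spearman coefficients with two-sided p-values on paired
#' per-structure Ca2+ and per-vessel dilation metrics.
#'
#' @param ca_metric numeric vector (one value per structure).
#' @param dilation_metric numeric vector, same length and pairing.
#' @return list `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`, `n`.
#' @export
correlate_responses <- function(ca_metric, dilation_metric) {
  ok <- is.finite(ca_metric) & is.finite(dilation_metric)
  x <- ca_metric[ok]; y <- dilation_metric[ok]
  if (length(x) < 3) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(x) == 0 || sd(y) == 0)
    stop("zero-variance input; correlation undefined", call. = FALSE)
  pe <- cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value,
       n = length(x))
}

#' Summarize one recording into analysis-ready tables
#'
#' Aggregates the stage outputs of a single recording into the standard
#' summary quantities (vessel peak percent change and AUC, soma and endfoot
#' responder fractions, per-ROI response metrics) and tidy one-row-per-unit
#' tables with recording identifiers, suitable for nested mixed-model fitting
#' elsewhere. Metrics are taken from the stage outputs verbatim, never
#' recomputed. Missing stages leave explicit NA gaps.
#'
#' @param recording_id identifier carried into every table row.
#' @param vessel_metrics output of [response_metrics()] (or NULL).
#' @param diameter_trace output of [diameter_timeseries()] (or NULL).
#' @param soma list with `events`, `roi_ids`, `dff` from
#'   [detect_all_transients()] (or NULL).
#' @param endfoot_events event table from [detect_kymo_events()] (or NULL).
#' @param stimulus_window 0-based inclusive frame range of the stimulus.
#' @param n_frames recording length in frames.
#' @return list of class `recording_summary`: scalar `summary` list plus tidy
#'   data frames `vessel`, `rois`, `soma_events`, `endfoot_events`.
#' @export
summarize_recording <- function(recording_id, vessel_metrics = NULL,
                                diameter_trace = NULL, soma = NULL,
                                endfoot_events = NULL,
                                stimulus_window = NULL, n_frames = NULL) {
  sw <- stimulus_window %||% attr(diameter_trace, "stimulus_window")
  peak <- vessel_metrics$peak_percent %||% NA_real_
  auc <- vessel_metrics$auc %||% NA_real_

  rois <- data.frame()
  soma_responders <- NA_real_
  if (!is.null(soma)) {
    ids <- soma$roi_ids
    ev <- soma$events
    in_win <- function(id) {
      e <- ev[ev$roi_id == id, , drop = FALSE]
      if (is.null(sw)) nrow(e) > 0 else
        any(e$onset_frame <= sw[2] & e$offset_frame >= sw[1])
    }
    rois <- data.frame(
      recording = recording_id, roi_id = ids,
      n_events = vapply(ids, function(i) sum(ev$roi_id == i), numeric(1)),
      peak_dff = vapply(ids, function(i) {
        e <- ev$peak_dff[ev$roi_id == i]
        if (length(e)) max(e) else NA_real_
      }, numeric(1)),
      dff_area = vapply(seq_along(ids), function(j) {
        d <- soma$dff[, j]
        sum(pmax(d, 0))
      }, numeric(1)),
      responder = vapply(ids, in_win, logical(1)))
    soma_responders <- mean(rois$responder)
  }

  ef_ev <- endfoot_events
  endfoot_responder <- if (is.null(ef_ev)) NA_real_ else as.numeric(nrow(ef_ev) > 0)

  vessel <- if (!is.null(diameter_trace)) {
    cbind(recording = recording_id, as.data.frame(diameter_trace))
  } else data.frame()

  soma_ev_tab <- if (!is.null(soma) && nrow(soma$events) > 0) {
    cbind(recording = recording_id, soma$events)
  } else data.frame()
  ef_ev_tab <- if (!is.null(ef_ev) && nrow(ef_ev) > 0) {
    cbind(recording = recording_id, as.data.frame(ef_ev))
  } else data.frame()

  structure(list(
    summary = list(recording = recording_id,
                   vessel_peak_percent = peak, vessel_auc = auc,
                   soma_responder_fraction = soma_responders,
                   endfoot_responder = endfoot_responder,
                   n_rois = if (is.null(soma)) NA_integer_ else length(soma$roi_ids),
                   n_soma_events = if (is.null(soma)) NA_integer_ else nrow(soma$events),
                   n_endfoot_events = if (is.null(ef_ev)) NA_integer_ else nrow(ef_ev)),
    vessel = vessel, rois = rois, soma_events = soma_ev_tab,
    endfoot_events = ef_ev_tab), class = "recording_summary")
}

#' @export
print.recording_summary <- function(x, ...) {
  s <- x$summary
  cat(sprintf("<recording_summary> %s\n", s$recording))
  cat(sprintf("  vessel: peak %+.1f%%, AUC %.4f\n",
              s$vessel_peak_percent, s$vessel_auc))
  cat(sprintf("  somata: %s ROIs, %s events, responder fraction %s\n",
              s$n_rois, s$n_soma_events,
              format(s$soma_responder_fraction, digits = 3)))
  cat(sprintf("  endfoot events: %s\n", s$n_endfoot_events))
  invisible(x)
}
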
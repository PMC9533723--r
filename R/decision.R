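# Recording-level decisions: per-cycle probabilities are thresholded
# (default 0.5) into SM/PPM cycle votes and combined by majority; a
# segmentation failure short-circuits to PPM with recording score 0.
# Ties and boundary probabilities go to PPM, the clinically conservative
# choice (an uncertain murmur remains a referral).

#' Classify a single cardiac cycle from its probability
#'
#' `"SM"` iff `p > threshold` (strict: the boundary goes to the safe PPM
#' class).
#'
#' @param p probability (vectorized) in \[0, 1\].
#' @param threshold decision threshold in (0, 1), default 0.5.
#' @return Character vector of `"SM"` / `"PPM"`.
#' @export
classify_cycle <- function(p, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1) stopf("threshold must be in (0, 1)")
  if (any(p < 0 | p > 1)) stopf("probabilities must lie in [0, 1]")
  ifelse(p > threshold, "SM", "PPM")
}

#' Recording-level SM/PPM decision
#'
#' On segmentation failure the recording is directly classified PPM with
#' recording score 0. Otherwise each cycle votes via
#' [classify_cycle()] and the majority decides; a tie goes to PPM. The
#' recording score (used for ROC sweeps) is the mean cycle probability.
#'
#' @param seg_result a [segment_recording()] result, or a logical scalar
#'   interpreted as `segmentation_failed`.
#' @param cycle_probs per-cycle probabilities (one per segmented cycle);
#'   ignored on failure.
#' @param threshold per-cycle decision threshold (default 0.5).
#' @param id recording identifier carried into the decision.
#' @return An object of class `recording_decision`: `label` (`"SM"` or
#'   `"PPM"`), `cycle_probs`, `recording_score`, `threshold`,
#'   `segmentation_failed`, `votes_sm`, `votes_total`, `id`.
#' @export
classify_recording <- function(seg_result, cycle_probs = numeric(),
                               threshold = 0.5, id = NULL) {
  failed <- if (is.logical(seg_result)) seg_result
            else if (inherits(seg_result, "pcg_segmentation")) !seg_result$success
            else stopf("seg_result must be a pcg_segmentation or a logical")
  if (failed) {
    out <- list(id = id, label = "PPM", cycle_probs = numeric(),
                recording_score = 0, threshold = threshold,
                segmentation_failed = TRUE, votes_sm = 0L, votes_total = 0L)
    return(structure(out, class = "recording_decision"))
  }
  if (!length(cycle_probs))
    stopf("successful segmentation requires at least one cycle probability")
  if (inherits(seg_result, "pcg_segmentation") &&
      length(cycle_probs) != length(seg_result$cycles))
    stopf("expected %d cycle probabilities, got %d",
          length(seg_result$cycles), length(cycle_probs))
  votes <- classify_cycle(cycle_probs, threshold)
  votes_sm <- sum(votes == "SM")
  n <- length(votes)
  structure(list(id = id,
                 label = if (votes_sm > n / 2) "SM" else "PPM",
                 cycle_probs = cycle_probs,
                 recording_score = mean(cycle_probs),
                 threshold = threshold, segmentation_failed = FALSE,
                 votes_sm = votes_sm, votes_total = n),
            class = "recording_decision")
}

#' @export
print.recording_decision <- function(x, ...) {
  if (x$segmentation_failed)
    cat(sprintf("<recording_decision%s> PPM (segmentation failed, score 0)\n",
                if (is.null(x$id)) "" else paste0(" ", x$id)))
  else
    cat(sprintf(
      "<recording_decision%s> %s (votes %d/%d at threshold %.2f, score %.3f)\n",
      if (is.null(x$id)) "" else paste0(" ", x$id),
      x$label, x$votes_sm, x$votes_total, x$threshold, x$recording_score))
  invisible(x)
}

#' Export a recording decision as JSON
#'
#' @param decision a [classify_recording()] result.
#' @param path output path, or `NULL` to return the JSON string.
#' @return The JSON string, invisibly when written to a file.
#' @export
decision_json <- function(decision, path = NULL) {
  stopifnot(inherits(decision, "recording_decision"))
  obj <- list(id = decision$id, label = decision$label,
              recording_score = decision$recording_score,
              cycle_probs = decision$cycle_probs,
              segmentation_failed = decision$segmentation_failed,
              threshold = decision$threshold)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
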
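# Evaluation harness: confusion-matrix metrics with SM (Still's murmur) as
# the positive class, empirical ROC/AUC, stratified five-fold
# cross-validation, and held-out testing with the "excluding failed
# segmentation" variant.

#' Confusion counts with SM as the positive class
#'
#' A true positive is a known Still's murmur classified SM; a true negative
#' is a known not-Still's recording classified PPM. `no_murmur` and `other`
#' both count as not-Still's.
#'
#' @param decisions predicted labels: a named character vector of
#'   `"SM"`/`"PPM"`, or a list of [classify_recording()] decisions (ids
#'   taken from the objects).
#' @param truths named character vector of true diagnostic labels
#'   (`"stills"`, `"other"`, `"no_murmur"`) or logical (TRUE = Still's);
#'   names must match the decision ids.
#' @return A list of class `confusion_counts` with `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(decisions, truths) {
  if (is.list(decisions) && !is.character(decisions)) {
    ids <- vapply(decisions, function(d) d$id %||% NA_character_, "")
    decisions <- stats::setNames(vapply(decisions, `[[`, "", "label"), ids)
  }
  if (is.null(names(decisions)) || is.null(names(truths)))
    stopf("decisions and truths must be named by recording id")
  if (!setequal(names(decisions), names(truths)))
    stopf("decision and truth id sets differ")
  truths <- truths[names(decisions)]
  pos <- if (is.logical(truths)) truths else truths == "stills"
  pred_sm <- decisions == "SM"
  structure(list(tp = sum(pos & pred_sm), fp = sum(!pos & pred_sm),
                 tn = sum(!pos & !pred_sm), fn = sum(pos & !pred_sm)),
            class = "confusion_counts")
}

#' Sensitivity, specificity and accuracy from confusion counts
#'
#' `sensitivity = 100 tp / (tp + fn)`, `specificity = 100 tn / (tn + fp)`,
#' `accuracy = 100 (tp + tn) / n`, all as percentages with SM as the
#' positive class (note this is reversed relative to pathology-detection
#' conventions: here sensitivity measures correct identification of the
#' innocent murmur).
#'
#' @param counts a [confusion()] result, or a list/vector with elements
#'   `tp`, `fp`, `tn`, `fn`.
#' @return Named numeric vector `c(sensitivity, specificity, accuracy)` in
#'   percent (unrounded; print to 0.1%).
#' @export
pcg_metrics <- function(counts) {
  tp <- counts[["tp"]]; fp <- counts[["fp"]]
  tn <- counts[["tn"]]; fn <- counts[["fn"]]
  if (tp + fn == 0) stopf("no positive (Still's) recordings evaluated")
  if (tn + fp == 0) stopf("no negative (not-Still's) recordings evaluated")
  c(sensitivity = 100 * tp / (tp + fn),
    specificity = 100 * tn / (tn + fp),
    accuracy = 100 * (tp + tn) / (tp + fp + tn + fn))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("tp %d  fp %d  tn %d  fn %d\n", x$tp, x$fp, x$tn, x$fn))
  m <- try(pcg_metrics(x), silent = TRUE)
  if (!inherits(m, "try-error"))
    cat(sprintf("sensitivity %.1f%%  specificity %.1f%%  accuracy %.1f%%\n",
                m[1], m[2], m[3]))
  invisible(x)
}

#' Empirical ROC curve and trapezoidal AUC
#'
#' Sweeps the recording-score threshold over every distinct score (predicted
#' SM iff score >= threshold), yielding one (FPR, TPR) point per distinct
#' score plus the endpoints (0,0) and (1,1); tied scores are grouped. The
#' AUC is the trapezoidal area, equal to the pairwise concordance
#' probability with ties counted 1/2. Recordings that failed segmentation
#' enter with score 0.
#'
#' @param scores named numeric recording scores in \[0, 1\].
#' @param truths named truth labels as in [confusion()].
#' @return A list of class `pcg_roc` with `points` (data.frame `threshold`,
#'   `fpr`, `tpr`) and `auc`.
#' @export
roc_and_auc <- function(scores, truths) {
  if (!is.null(names(scores)) && !is.null(names(truths))) {
    if (!setequal(names(scores), names(truths)))
      stopf("score and truth id sets differ")
    truths <- truths[names(scores)]
  } else if (length(scores) != length(truths))
    stopf("scores and truths must have equal length")
  pos <- if (is.logical(truths)) truths else truths == "stills"
  if (!any(pos) || all(pos)) stopf("both classes must be present for a ROC")
  np <- sum(pos); nn <- sum(!pos)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(thr, function(t) sum(scores[pos] >= t) / np, 1)
  fpr <- vapply(thr, function(t) sum(scores[!pos] >= t) / nn, 1)
  pts <- data.frame(threshold = c(Inf, thr, -Inf),
                    fpr = c(0, fpr, 1), tpr = c(0, tpr, 1))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "pcg_roc")
}

#' @export
print.pcg_roc <- function(x, ...) {
  cat(sprintf("<pcg_roc> %d points, AUC = %.3f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Plot a ROC curve
#' @param x a [roc_and_auc()] result.
#' @param ... passed to [graphics::plot()].
#' @export
plot.pcg_roc <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$tpr, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity", ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' Stratified k-fold assignment of recordings
#'
#' Partitions recording ids into `k` folds, stratified by diagnostic label
#' so that each fold holds (as nearly as possible) the same 1/k share of
#' every class -- with k = 5, each validation fold contains 20% of the
#' Still's and 20% of the other recordings. Deterministic given `seed`.
#'
#' @param manifest a manifest data.frame (`id`, `label` columns used).
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return An object of class `fold_plan`: `k`, `assignments` (named
#'   integer vector id -> fold), `strata`, `seed`.
#' @export
make_folds <- function(manifest, k = 5, seed = 1L) {
  tab <- table(manifest$label)
  if (any(tab < k))
    stopf("stratum '%s' has fewer than k = %d recordings",
          names(tab)[which.min(tab)], k)
  assignments <- with_seed(seed, {
    a <- integer(nrow(manifest))
    names(a) <- manifest$id
    for (lab in names(tab)) {
      ii <- which(manifest$label == lab)
      a[ii[sample.int(length(ii))]] <- rep_len(seq_len(k), length(ii))
    }
    a
  })
  structure(list(k = as.integer(k), assignments = assignments,
                 strata = stats::setNames(manifest$label, manifest$id),
                 seed = as.integer(seed)),
            class = "fold_plan")
}

## ---- pipeline plumbing -----------------------------------------------------

#' Run preprocessing, segmentation and featurization on one recording
#'
#' @param recording a [pcg_recording()].
#' @param config a [pipeline_config()].
#' @return A list: `id`, `label`, `location`, `failed` (segmentation
#'   failure flag), `failure_reason`, `specs` (55 x 129 x n array or `NULL`),
#'   `seg` (the segmentation result).
#' @export
process_recording <- function(recording, config = pipeline_config()) {
  f <- config$filter
  spec <- bandpass_spec(f$order, f$low_hz, f$high_hz, recording$fs_hz)
  filtered <- apply_bandpass(recording, spec)
  s <- config$segmentation
  seg <- segment_recording(filtered, threshold_sd = s$threshold_sd,
                           merge_gap_s = s$merge_gap_s,
                           min_len_s = s$min_len_s,
                           saturation_frac = s$saturation_frac,
                           min_cycles = s$min_cycles, cv_max = s$cv_max)
  specs <- NULL
  if (seg$success) {
    ft <- config$features
    specs <- featurize_segmentation(seg, nfft = ft$nfft, win = ft$window,
                                    overlap = ft$overlap,
                                    target_frames = ft$target_frames)
  }
  list(id = recording$id, label = recording$label,
       location = recording$location, failed = !seg$success,
       failure_reason = seg$failure_reason, specs = specs, seg = seg)
}

#' Prepare a dataset for training/evaluation
#'
#' Reads (or takes in-memory) recordings, bandpass filters, segments and
#' featurizes each one once; the result is reused across folds.
#'
#' @param recordings either a manifest data.frame (recordings read from
#'   `path` at `config$working_fs_hz`) or a list of [pcg_recording()]s.
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return A named list (by id) of [process_recording()] results.
#' @export
prepare_dataset <- function(recordings, config = pipeline_config(),
                            verbose = FALSE) {
  if (is.data.frame(recordings)) {
    manifest <- validate_manifest(recordings)
    recordings <- lapply(seq_len(nrow(manifest)), function(i)
      read_wav(manifest$path[i], target_fs = config$working_fs_hz,
               id = manifest$id[i], label = manifest$label[i],
               location = manifest$location[i]))
  }
  out <- lapply(recordings, function(r) {
    if (verbose) message("processing ", r$id)
    process_recording(r, config)
  })
  stats::setNames(out, vapply(out, `[[`, "", "id"))
}

# Gather labeled cycle spectrograms from prepared recordings.
gather_cycles <- function(prepared, ids) {
  specs <- list(); labels <- numeric(0)
  for (id in ids) {
    p <- prepared[[id]]
    if (p$failed) next
    n <- dim(p$specs)[3]
    for (j in seq_len(n)) specs[[length(specs) + 1L]] <- p$specs[, , j]
    labels <- c(labels, rep(as.numeric(p$label == "stills"), n))
  }
  list(specs = specs, labels = labels)
}

# Classify prepared recordings with a fitted model.
decide_prepared <- function(model, prepared, ids, threshold = 0.5) {
  lapply(ids, function(id) {
    p <- prepared[[id]]
    if (p$failed)
      classify_recording(TRUE, threshold = threshold, id = id)
    else
      classify_recording(p$seg, predict(model, p$specs),
                         threshold = threshold, id = id)
  })
}

eval_decisions <- function(decisions, truths, variant = "all") {
  ids <- vapply(decisions, `[[`, "", "id")
  names(decisions) <- ids
  failed <- vapply(decisions, `[[`, TRUE, "segmentation_failed")
  if (variant == "excluding_failed") {
    decisions <- decisions[!failed]
    truths <- truths[names(decisions)]
  }
  counts <- confusion(decisions, truths)
  scores <- stats::setNames(
    vapply(decisions, `[[`, 1, "recording_score"),
    names(decisions))
  roc <- try(roc_and_auc(scores, truths), silent = TRUE)
  if (inherits(roc, "try-error")) roc <- NULL
  # Excluding failed-segmentation recordings can legitimately empty a class
  # (e.g. every pathological recording failed); report NA metrics then.
  m <- tryCatch(pcg_metrics(counts),
                error = function(e) c(sensitivity = NA_real_,
                                      specificity = NA_real_,
                                      accuracy = NA_real_))
  structure(list(counts = counts, sensitivity = m[["sensitivity"]],
                 specificity = m[["specificity"]],
                 accuracy = m[["accuracy"]],
                 roc = roc, auc = if (is.null(roc)) NA_real_ else roc$auc,
                 scores = scores,
                 n_failed_segmentation = sum(failed), variant = variant,
                 per_fold = NULL),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> variant = %s\n", x$variant))
  print(x$counts)
  if (!is.na(x$auc)) cat(sprintf("AUC = %.3f\n", x$auc))
  if (x$n_failed_segmentation > 0)
    cat(sprintf("failed segmentation: %d recording(s), classified PPM\n",
                x$n_failed_segmentation))
  invisible(x)
}

#' Subset a manifest according to a training strategy
#'
#' The four location/class strategies: `all_locations_all` (every
#' recording), `all_locations_murmurs` (murmur recordings only),
#' `llsb_all` (LLSB recordings), `llsb_murmurs` (LLSB murmur recordings --
#' the best-performing strategy).
#'
#' @param manifest a manifest data.frame.
#' @param strategy one of the four strategy names.
#' @return The filtered manifest.
#' @export
apply_strategy <- function(manifest, strategy = c("all_locations_all",
                                                  "all_locations_murmurs",
                                                  "llsb_all",
                                                  "llsb_murmurs")) {
  strategy <- match.arg(strategy)
  m <- manifest
  if (strategy %in% c("llsb_all", "llsb_murmurs"))
    m <- filter_manifest(m, location = "LLSB")
  if (strategy %in% c("all_locations_murmurs", "llsb_murmurs"))
    m <- filter_manifest(m, labels = c("stills", "other"))
  m
}

#' Five-fold cross-validated evaluation
#'
#' Applies the strategy filter, prepares every recording once, then for each
#' fold trains the CNN on the other folds' cycles and classifies the held
#' fold's recordings. Fold-level confusion counts are summed (pooled) into
#' the aggregate report; every recording is classified exactly once.
#'
#' @param recordings manifest data.frame or list of [pcg_recording()]s.
#' @param strategy see [apply_strategy()].
#' @param config a [pipeline_config()].
#' @param k number of folds (default 5).
#' @param seed fold-assignment seed.
#' @param verbose print per-fold progress.
#' @return An `eval_report` with `per_fold` reports attached.
#' @export
crossval <- function(recordings, strategy = "llsb_murmurs",
                     config = pipeline_config(), k = 5, seed = 1L,
                     verbose = FALSE) {
  if (is.data.frame(recordings)) {
    manifest <- apply_strategy(validate_manifest(recordings), strategy)
  } else {
    manifest <- data.frame(
      id = vapply(recordings, `[[`, "", "id"),
      path = NA_character_,
      label = vapply(recordings, `[[`, "", "label"),
      location = vapply(recordings, `[[`, "", "location"),
      stringsAsFactors = FALSE)
    keep <- apply_strategy(manifest, strategy)$id
    recordings <- recordings[manifest$id %in% keep]
    manifest <- manifest[manifest$id %in% keep, ]
  }
  truths <- stats::setNames(manifest$label, manifest$id)
  if (sum(truths == "stills") == 0 || all(truths == "stills"))
    stopf("strategy '%s' leaves a single-class dataset", strategy)
  prepared <- prepare_dataset(if (is.data.frame(recordings)) manifest
                              else recordings, config, verbose = verbose)
  plan <- make_folds(manifest, k = k, seed = seed)

  all_decisions <- list()
  per_fold <- vector("list", k)
  for (fold in seq_len(k)) {
    val_ids <- names(plan$assignments)[plan$assignments == fold]
    train_ids <- setdiff(manifest$id, val_ids)
    if (verbose) message(sprintf("fold %d: %d train / %d validation",
                                 fold, length(train_ids), length(val_ids)))
    tr <- gather_cycles(prepared, train_ids)
    cnn_cfg <- do.call(murmur_cnn_config, config$cnn)
    train_cfg <- do.call(murmur_train_config, config$train)
    model <- fit_murmur_cnn(tr$specs, tr$labels, cnn_cfg, train_cfg)
    dec <- decide_prepared(model, prepared, val_ids,
                           threshold = config$decision$threshold)
    per_fold[[fold]] <- eval_decisions(dec, truths[val_ids])
    all_decisions <- c(all_decisions, dec)
  }
  report <- eval_decisions(all_decisions, truths)
  report$per_fold <- per_fold
  report$fold_plan <- plan
  report
}

#' Held-out test evaluation
#'
#' Trains on every training recording and evaluates the disjoint test set,
#' reporting both the all-recordings variant and the variant excluding
#' recordings that failed segmentation. Per-recording scores by true class
#' (scatter data) are included in each report.
#'
#' @param train_recordings,test_recordings manifests or lists of
#'   [pcg_recording()]s with disjoint ids.
#' @param config a [pipeline_config()].
#' @param verbose print progress.
#' @return A list with `all` and `excluding_failed` `eval_report`s and the
#'   fitted `model`.
#' @export
heldout_test <- function(train_recordings, test_recordings,
                         config = pipeline_config(), verbose = FALSE) {
  get_ids <- function(x) if (is.data.frame(x)) x$id
                         else vapply(x, `[[`, "", "id")
  get_truth <- function(x) if (is.data.frame(x))
    stats::setNames(x$label, x$id)
  else stats::setNames(vapply(x, `[[`, "", "label"), get_ids(x))
  if (length(intersect(get_ids(train_recordings), get_ids(test_recordings))))
    stopf("train and test sets share recording ids")
  prep_tr <- prepare_dataset(train_recordings, config, verbose = verbose)
  prep_te <- prepare_dataset(test_recordings, config, verbose = verbose)
  tr <- gather_cycles(prep_tr, names(prep_tr))
  model <- fit_murmur_cnn(tr$specs, tr$labels,
                          do.call(murmur_cnn_config, config$cnn),
                          do.call(murmur_train_config, config$train))
  dec <- decide_prepared(model, prep_te, names(prep_te),
                         threshold = config$decision$threshold)
  truths <- get_truth(test_recordings)
  list(all = eval_decisions(dec, truths),
       excluding_failed = eval_decisions(dec, truths,
                                         variant = "excluding_failed"),
       decisions = dec, model = model)
}
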
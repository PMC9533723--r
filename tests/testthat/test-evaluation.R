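test_that("confusion counts with SM positive", {
  ids <- sprintf("r%02d", 1:20)
  truths <- stats::setNames(rep(c("stills", "other"), each = 10), ids)
  perfect <- stats::setNames(rep(c("SM", "PPM"), each = 10), ids)
  c1 <- confusion(perfect, truths)
  expect_equal(unclass(c1)[c("tp", "fp", "tn", "fn")],
               list(tp = 10L, fp = 0L, tn = 10L, fn = 0L))
  all_ppm <- stats::setNames(rep("PPM", 20), ids)
  c2 <- confusion(all_ppm, truths)
  expect_equal(c2$fn, 10L)
  expect_equal(c2$tn, 10L)
  # permutation invariance
  sh <- sample(ids)
  c3 <- confusion(perfect[sh], truths)
  expect_equal(unclass(c3), unclass(c1))
  # no_murmur counts as not-Still's
  t2 <- truths; t2[11:15] <- "no_murmur"
  expect_equal(confusion(perfect, t2)$tn, 10L)
  expect_error(confusion(perfect[-1], truths), "differ")
})

test_that("metrics reproduce the printed worked examples", {
  m <- pcg_metrics(list(tp = 54, fp = 1, tn = 59, fn = 6))
  expect_equal(round(m[["sensitivity"]], 1), 90.0)
  expect_equal(round(m[["specificity"]], 1), 98.3)
  expect_equal(round(m[["accuracy"]], 1), 94.2)
  m2 <- pcg_metrics(list(tp = 54, fp = 1, tn = 46, fn = 5))
  expect_equal(round(m2[["sensitivity"]], 1), 91.5)
  expect_equal(round(m2[["specificity"]], 1), 97.9)
  expect_equal(round(m2[["accuracy"]], 1), 94.3)
  expect_equal(pcg_metrics(list(tp = 10, fp = 0, tn = 10, fn = 0)),
               c(sensitivity = 100, specificity = 100, accuracy = 100))
  expect_error(pcg_metrics(list(tp = 0, fp = 0, tn = 5, fn = 0)),
               "positive")
})

test_that("ROC endpoints, degenerate cases, and a hand-computed AUC", {
  pos <- c(TRUE, TRUE, FALSE, FALSE)
  # perfectly separated
  r <- roc_and_auc(c(0.9, 0.8, 0.3, 0.1), pos)
  expect_equal(r$auc, 1.0)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)
  # identical scores: chance
  expect_equal(roc_and_auc(rep(0.4, 4), pos)$auc, 0.5)
  # stills 0.9, 0.8 vs other 0.85, 0.1: 3 of 4 concordant pairs
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.85, 0.1), pos)$auc, 0.75)
  expect_equal(concordance_auc(c(0.9, 0.8, 0.85, 0.1), pos), 0.75)
  expect_error(roc_and_auc(c(0.1, 0.2), c(TRUE, TRUE)), "both classes")
})

test_that("trapezoidal AUC equals pairwise concordance on random sets", {
  withr::with_seed(33, {
    for (rep in 1:25) {
      n <- sample(10:60, 1)
      pos <- c(TRUE, TRUE, FALSE, sample(c(TRUE, FALSE), n - 3, TRUE))
      scores <- round(stats::runif(n), sample(c(1, 2, 3), 1))  # force ties
      got <- roc_and_auc(scores, pos)$auc
      expect_equal(got, concordance_auc(scores, pos), tolerance = 1e-12)
    }
  })
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(44, {
    scores <- stats::runif(80)
    pos <- stats::runif(80) < 0.4
    scores[pos] <- scores[pos] + 0.3
    got <- roc_and_auc(scores, pos)$auc
    want <- as.numeric(pROC::auc(pROC::roc(response = pos,
                                           predictor = scores,
                                           quiet = TRUE, direction = "<")))
    expect_equal(got, want, tolerance = 1e-12)
  })
})

test_that("stratified folds partition each class evenly", {
  manifest <- data.frame(id = sprintf("r%03d", 1:150),
                         path = "x", label = rep(c("stills", "other"),
                                                 c(50, 100)),
                         location = "LLSB", stringsAsFactors = FALSE)
  plan <- make_folds(manifest, k = 5, seed = 3)
  expect_setequal(names(plan$assignments), manifest$id)
  for (f in 1:5) {
    ids <- names(plan$assignments)[plan$assignments == f]
    expect_equal(sum(manifest$label[match(ids, manifest$id)] == "stills"), 10)
    expect_equal(sum(manifest$label[match(ids, manifest$id)] == "other"), 20)
  }
  # determinism and seed sensitivity
  expect_identical(plan$assignments, make_folds(manifest, 5, 3)$assignments)
  expect_false(identical(plan$assignments,
                         make_folds(manifest, 5, 4)$assignments))
  small <- manifest[c(1:3, 51:60), ]
  expect_error(make_folds(small, k = 5), "fewer than")
})

test_that("strategy filters select the right manifest subsets", {
  m <- data.frame(id = sprintf("r%02d", 1:12), path = "x",
                  label = rep(c("stills", "other", "no_murmur"), 4),
                  location = rep(c("LLSB", "apex"), each = 6),
                  stringsAsFactors = FALSE)
  expect_equal(nrow(apply_strategy(m, "all_locations_all")), 12)
  expect_equal(nrow(apply_strategy(m, "all_locations_murmurs")), 8)
  expect_equal(nrow(apply_strategy(m, "llsb_all")), 6)
  a <- apply_strategy(m, "llsb_murmurs")
  expect_equal(nrow(a), 4)
  expect_true(all(a$location == "LLSB" & a$label != "no_murmur"))
})

test_that("cross-validation pools fold counts without leakage", {
  # small in-memory cohort; tiny CNN so the test stays fast
  recs <- lapply(1:20, function(i) {
    cls <- if (i <= 10) "stills" else "holosystolic"
    synthesize_recording(synth_params(murmur_class = cls, duration_s = 8,
                                      seed = 600 + i),
                         id = sprintf("cv%02d_%s", i, cls))$recording
  })
  cfg <- pipeline_config(overrides = list(
    cnn = list(conv_filters = c(4L, 4L, 8L), dense_units = c(8L, 8L)),
    train = list(epochs = 2L, batch_size = 16L)))
  rep5 <- crossval(recs, strategy = "llsb_murmurs", config = cfg, k = 5,
                   seed = 11)
  expect_length(rep5$per_fold, 5)
  # every recording classified exactly once across validation folds
  all_ids <- names(rep5$scores)
  expect_setequal(all_ids, vapply(recs, `[[`, "", "id"))
  expect_equal(anyDuplicated(all_ids), 0)
  # aggregate counts are the sums of the fold counts
  for (fld in c("tp", "fp", "tn", "fn")) {
    expect_equal(rep5$counts[[fld]],
                 sum(vapply(rep5$per_fold, function(r) r$counts[[fld]], 1L)))
  }
  # fold plan: no id in both train and validation of the same fold (by
  # construction of the partition, train = complement of validation)
  plan <- rep5$fold_plan
  expect_equal(anyDuplicated(names(plan$assignments)), 0)
})

test_that("held-out testing reports both variants consistently", {
  mk <- function(cls, n, tag, base) lapply(seq_len(n), function(i)
    synthesize_recording(synth_params(murmur_class = cls, duration_s = 8,
                                      seed = base + i),
                         id = sprintf("%s%02d", tag, i))$recording)
  train <- c(mk("stills", 6, "tr_s", 700), mk("holosystolic", 6, "tr_h", 720))
  test <- c(mk("stills", 4, "te_s", 740),
            mk("holosystolic", 4, "te_h", 760))
  cfg <- pipeline_config(overrides = list(
    cnn = list(conv_filters = c(4L, 4L, 8L), dense_units = c(8L, 8L)),
    train = list(epochs = 3L, batch_size = 16L)))
  res <- heldout_test(train, test, cfg)
  expect_equal(res$all$variant, "all")
  expect_equal(res$excluding_failed$variant, "excluding_failed")
  expect_gte(res$all$n_failed_segmentation, 0)
  # excluding-failed metrics recomputed independently from the decisions
  dec <- res$decisions
  keep <- !vapply(dec, `[[`, TRUE, "segmentation_failed")
  labels <- stats::setNames(vapply(dec, `[[`, "", "label"),
                            vapply(dec, `[[`, "", "id"))[keep]
  truths <- stats::setNames(
    ifelse(grepl("te_s", names(labels)), "stills", "other"), names(labels))
  expect_equal(unclass(res$excluding_failed$counts),
               unclass(confusion(labels, truths)))
  # the all-recordings variant counts every test recording
  cts <- res$all$counts
  expect_equal(cts$tp + cts$fp + cts$tn + cts$fn, 8L)
  # overlapping ids are rejected
  expect_error(heldout_test(train, train, cfg), "share")
})
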
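# Leave-one-subject-out orchestration of the three pipelines and the
# ensemble.

#' Run configuration for the LOSO workflow
#'
#' Collects every tunable hyperparameter of the three pipelines and the
#' segmentation stage. Defaults follow the package's reference setup:
#' 1-s windows with 50% overlap, RBF SVM with gamma 0.001 and C 1000,
#' ReliefF with 10 neighbours over 256 sampled instances (ranking only —
#' all 55 features are kept unless `n_keep_features` is set), per-channel
#' LDA at the maximum 9 components with automatic shrinkage, KNN with
#' k = 5, and the convolutional configuration of [cnn_config()].
#'
#' @param window_seconds window length in seconds.
#' @param overlap window overlap fraction.
#' @param svm_gamma,svm_cost RBF SVM hyperparameters.
#' @param relieff_k ReliefF neighbours per class.
#' @param relieff_n_samples sampled instances for ReliefF (`"all"` or a
#'   count; clamped to the training size).
#' @param n_keep_features top-ranked features kept for the SVM (`NULL` =
#'   keep all 55, rank only).
#' @param lda_components discriminant directions per channel (`NULL` =
#'   number of classes - 1).
#' @param lda_shrinkage within-class scatter shrinkage (`"auto"` or a
#'   number in `[0, 1]`).
#' @param knn_k KNN neighbour count.
#' @param cnn a [cnn_config()].
#' @param macro_f1 macro-F1 convention for reports ("mean" or "harmonic").
#' @return object of class `loso_config`.
#' @export
loso_config <- function(window_seconds = 1, overlap = 0.5,
                        svm_gamma = 0.001, svm_cost = 1000,
                        relieff_k = 10, relieff_n_samples = 256,
                        n_keep_features = NULL, lda_components = NULL,
                        lda_shrinkage = "auto", knn_k = 5,
                        cnn = cnn_config(), macro_f1 = "mean") {
  structure(list(window_seconds = window_seconds, overlap = overlap,
                 svm_gamma = svm_gamma, svm_cost = svm_cost,
                 relieff_k = relieff_k,
                 relieff_n_samples = relieff_n_samples,
                 n_keep_features = n_keep_features,
                 lda_components = lda_components,
                 lda_shrinkage = lda_shrinkage, knn_k = knn_k, cnn = cnn,
                 macro_f1 = macro_f1),
            class = "loso_config")
}

segment_subject_set <- function(recordings, subjects, config) {
  keep <- Filter(function(r) r$subject_id %in% subjects, recordings)
  # canonical (subject, trial) order: fold results do not depend on the
  # order recordings were supplied in
  ord <- order(vapply(keep, `[[`, integer(1), "subject_id"),
               vapply(keep, `[[`, integer(1), "trial_no"))
  segs <- lapply(keep[ord], segment_recording,
                 window_seconds = config$window_seconds,
                 overlap = config$overlap)
  bind_segments(segs)
}

run_fold <- function(fold, recordings, config, seed) {
  train_seg <- segment_subject_set(recordings, fold$train, config)
  test_seg <- segment_subject_set(recordings, fold$test, config)
  if (length(unique(train_seg$labels)) < 2) {
    warning(sprintf("fold with test subject %d skipped: training set has < 2 classes",
                    fold$test))
    return(NULL)
  }
  if (dim(test_seg$values)[1] == 0) {
    warning(sprintf("fold with test subject %d skipped: no test segments",
                    fold$test))
    return(NULL)
  }
  fold_seed <- derive_seed(seed, 3L, fold$test)
  cw <- class_weights(train_seg$labels)

  # pipeline 1: handcrafted features -> z-score -> ReliefF -> OvA RBF SVM
  fm_train <- extract_features(train_seg)
  fm_test <- extract_features(test_seg)
  zp <- zscore_fit(fm_train)
  ztr <- zscore_apply(zp, fm_train)
  zte <- zscore_apply(zp, fm_test)
  n_samp <- config$relieff_n_samples
  if (!identical(n_samp, "all")) {
    n_samp <- min(n_samp, nrow(ztr$values))
  }
  fw <- relieff_rank(ztr, k_neighbors = config$relieff_k,
                     n_samples = n_samp, seed = fold_seed)
  n_keep <- config$n_keep_features %||% ncol(ztr$values)
  str_sel <- select_features(ztr, fw, n_keep)
  ste_sel <- select_features(zte, fw, n_keep)
  svm_model <- train_svm(str_sel, class_weights = cw,
                         gamma = config$svm_gamma, cost = config$svm_cost)
  pred_fe <- predict_svm(svm_model, ste_sel)

  # pipeline 2: per-channel LDA -> concatenation -> KNN
  proj <- lda_fit(train_seg, n_components = config$lda_components,
                  shrinkage = config$lda_shrinkage)
  knn_model <- knn_train(lda_transform(proj, train_seg), k = config$knn_k)
  pred_lda <- knn_predict(knn_model, lda_transform(proj, test_seg))

  # pipeline 3: per-channel 1D CNN
  cnn_cfg <- config$cnn
  cnn_cfg$seed <- derive_seed(seed, 4L, fold$test)
  model <- build_cnn(cnn_cfg, dim(train_seg$values)[2],
                     dim(train_seg$values)[3],
                     classes = unique(train_seg$labels))
  model <- train_cnn(model, train_seg, class_weights = cw)
  pred_cnn <- predict_cnn(model, test_seg)

  data.frame(subject = test_seg$subject_ids, trial = test_seg$trial_ids,
             true = test_seg$labels, fe = pred_fe, lda = pred_lda,
             cnn = pred_cnn,
             ensemble = majority_vote(pred_fe, pred_lda, pred_cnn),
             stringsAsFactors = FALSE)
}

#' Leave-one-subject-out evaluation of the ensemble
#'
#' For each fold of the leave-one-subject-out plan: segments the training
#' and held-out recordings separately (the split precedes segmentation, so
#' no window mixes subjects), fits the three pipelines on the training
#' subjects only, predicts the held-out subject, and fuses the decisions
#' by majority vote. Out-of-fold predictions are pooled over all folds and
#' a single classification report is computed per pipeline and for the
#' ensemble.
#'
#' Folds are independent tasks and may run in parallel (`n_workers > 1`,
#' forked processes); per-fold seeds derive deterministically from `seed`
#' and the test subject id, so results are identical for any worker count.
#' A fold whose training set covers fewer than two classes is skipped with
#' a warning.
#'
#' @param recordings list of `har_recording` objects (>= 2 subjects).
#' @param config a [loso_config()].
#' @param n_workers number of parallel fold workers.
#' @param seed integer root seed for all per-fold randomness.
#' @param class_order fixed class ordering for reports; defaults to the
#'   canonical activity order restricted to observed labels.
#' @return object of class `har_loso`: list with `predictions` (pooled
#'   data frame with columns subject, trial, true, fe, lda, cnn,
#'   ensemble), `reports` (one `classification_report` per pipeline plus
#'   `ensemble`), `fold_plan` and `skipped` (test subjects of skipped
#'   folds).
#' @export
run_loso <- function(recordings, config = loso_config(), n_workers = 1,
                     seed = 1, class_order = NULL) {
  stopifnot(all(vapply(recordings, inherits, logical(1), "har_recording")))
  plan <- make_fold_plan(vapply(recordings, `[[`, integer(1), "subject_id"))
  worker <- function(fold) {
    msgs <- character(0)
    res <- withCallingHandlers(
      run_fold(fold, recordings, config, seed),
      warning = function(w) {
        msgs <<- c(msgs, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    list(result = res, warnings = msgs)
  }
  results <- if (n_workers > 1) {
    parallel::mclapply(plan, worker, mc.cores = n_workers,
                       mc.preschedule = FALSE)
  } else {
    lapply(plan, worker)
  }
  for (r in results) {
    for (msg in r$warnings) warning(msg, call. = FALSE)
  }
  preds <- lapply(results, `[[`, "result")
  skipped <- vapply(plan[vapply(preds, is.null, logical(1))], `[[`,
                    integer(1), "test")
  pooled <- do.call(rbind, preds)
  if (is.null(pooled) || nrow(pooled) == 0) {
    stop("all folds were skipped; no predictions to report")
  }
  observed <- unique(c(pooled$true, pooled$fe, pooled$lda, pooled$cnn))
  if (is.null(class_order)) {
    canonical <- unname(activity_classes())
    class_order <- if (all(observed %in% canonical)) {
      intersect(canonical, observed)
    } else {
      sort(observed)
    }
  }
  reports <- lapply(c(fe = "fe", lda = "lda", cnn = "cnn",
                      ensemble = "ensemble"), function(col) {
    classification_report(pooled$true, pooled[[col]], class_order,
                          macro_f1 = config$macro_f1)
  })
  structure(list(predictions = pooled, reports = reports,
                 fold_plan = plan, skipped = skipped),
            class = "har_loso")
}

#' @export
print.har_loso <- function(x, ...) {
  cat(sprintf("<har_loso> %d folds (%d skipped), %d pooled test segments\n",
              length(x$fold_plan), length(x$skipped),
              nrow(x$predictions)))
  acc <- vapply(x$reports, `[[`, numeric(1), "accuracy")
  f1 <- vapply(x$reports, function(r) unname(r$macro["f1"]), numeric(1))
  for (nm in names(x$reports)) {
    cat(sprintf("  %-8s accuracy %.3f  macro F1 %.3f\n", nm, acc[nm],
                f1[nm]))
  }
  invisible(x)
}
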
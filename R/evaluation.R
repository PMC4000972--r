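#' Per-patient random half-split
#'
#' Independently for each patient, a seeded random permutation of that
#' patient's clips assigns the first half to training and the rest to
#' testing. Odd clip counts send the extra clip to training (ceil rule).
#' Identical seeds give identical splits. Patients are processed in sorted
#' id order so the plan does not depend on input ordering.
#'
#' @param clip_ids character vector of clip identifiers.
#' @param patient_ids character vector, same length, patient of each clip.
#' @param seed integer seed.
#' @param group_ids optional grouping vector (e.g. source recording ids):
#'   when supplied, whole groups are assigned to one side, so sibling clips
#'   segmented from the same recording never straddle the split.
#' @return a list of class `split_plan` with `train` and `test` clip-id
#'   vectors and the `seed`.
#' @export
half_split_per_patient <- function(clip_ids, patient_ids, seed,
                                   group_ids = NULL) {
  stopifnot(length(clip_ids) == length(patient_ids))
  if (anyDuplicated(clip_ids))
    stop("clip ids must be unique", call. = FALSE)
  units <- if (is.null(group_ids)) clip_ids else as.character(group_ids)
  stopifnot(length(units) == length(clip_ids))
  train <- character(0); test <- character(0)
  with_seed(seed, {
    for (p in sort(unique(patient_ids))) {
      sel <- patient_ids == p
      uu <- unique(units[sel])
      if (length(uu) < 2L)
        stop(sprintf("patient '%s' has fewer than 2 clips (or clip groups); cannot half-split", p),
             call. = FALSE)
      perm <- uu[sample.int(length(uu))]
      n_train <- ceiling(length(uu) / 2)
      tr_units <- perm[seq_len(n_train)]
      train <- c(train, clip_ids[sel & units %in% tr_units])
      test <- c(test, clip_ids[sel & !(units %in% tr_units)])
    }
  })
  structure(list(train = train, test = test, seed = as.integer(seed)),
            class = "split_plan")
}

#' Classification accuracy
#'
#' @param predictions,labels equal-length vectors of class labels.
#' @return the fraction of positions where they agree.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) != length(labels))
    stop("`predictions` and `labels` must have equal length", call. = FALSE)
  if (length(labels) == 0L)
    stop("accuracy of an empty prediction set is undefined", call. = FALSE)
  mean(predictions == labels)
}

#' Run the repeated per-patient half-split experiment
#'
#' The full evaluation protocol: for each of `n_repeats` repeats, clips are
#' split per patient into random halves ([half_split_per_patient()] with
#' seed `base_seed + repeat`), the box constraint C is chosen by
#' cross-validation on the training half only ([select_C()]), an SVM is
#' fitted on the training half (feature scaling statistics also come from
#' the training half only), the test half is predicted, and clip-level
#' accuracy is recorded. The report carries every per-repeat accuracy and
#' their arithmetic mean.
#'
#' @param features either a [compute_features()] data.frame (columns
#'   `clip_id`, `patient_id`, `label`, `fNNN...`) or a bare feature matrix,
#'   in which case `labels`, `patient_ids` and optionally `clip_ids` must be
#'   given.
#' @param labels,patient_ids,clip_ids used only when `features` is a matrix.
#' @param n_repeats number of repeated splits (default 5).
#' @param base_seed integer; repeat `r` splits with seed `base_seed + r`.
#' @param C_grid candidate box constraints for [select_C()].
#' @param kernel an [svm_kernel()]; default linear.
#' @param k cross-validation folds inside each training half.
#' @param group_ids optional recording-level grouping passed to the splitter.
#' @return an object of class `evaluation_report`: per-repeat data.frame
#'   (`repeat_`, `seed`, `C`, `accuracy`), `mean_accuracy`, `n_repeats`,
#'   `base_seed`, `config` and `config_hash`.
#' @export
run_experiment <- function(features, labels = NULL, patient_ids = NULL,
                           clip_ids = NULL, n_repeats = 5L, base_seed = 1L,
                           C_grid = c(0.01, 0.1, 1, 10, 100),
                           kernel = svm_kernel("linear"), k = 5L,
                           group_ids = NULL) {
  if (is.data.frame(features)) {
    x <- feature_matrix(features)
    labels <- features$label
    patient_ids <- features$patient_id
    clip_ids <- features$clip_id
  } else {
    x <- as.matrix(features)
    if (is.null(labels) || is.null(patient_ids))
      stop("matrix input requires `labels` and `patient_ids`", call. = FALSE)
    if (is.null(clip_ids)) clip_ids <- sprintf("clip%04d", seq_len(nrow(x)))
  }
  if (is.character(labels) || is.factor(labels))
    labels <- label_to_class(as.character(labels))
  labels <- as.numeric(labels)
  stopifnot(nrow(x) == length(labels), nrow(x) == length(patient_ids),
            nrow(x) == length(clip_ids))
  if (length(unique(labels)) < 2L)
    stop("both classes must be present in the dataset", call. = FALSE)
  rownames(x) <- clip_ids

  rows <- vector("list", n_repeats)
  for (r in seq_len(n_repeats)) {
    seed_r <- as.integer(base_seed) + r
    plan <- half_split_per_patient(clip_ids, patient_ids, seed = seed_r,
                                   group_ids = group_ids)
    tr <- clip_ids %in% plan$train
    if (length(unique(labels[tr])) < 2L)
      stop("training half contains a single class; enlarge or rebalance the dataset",
           call. = FALSE)
    C <- select_C(x[tr, , drop = FALSE], labels[tr], grid = C_grid, k = k,
                  kernel = kernel, seed = seed_r + 100000L)
    fit <- svm_fit(x[tr, , drop = FALSE], labels[tr], C = C, kernel = kernel)
    pred <- predict(fit, x[!tr, , drop = FALSE])
    rows[[r]] <- data.frame(repeat_ = r, seed = seed_r, C = as.numeric(C),
                            accuracy = accuracy(pred, labels[!tr]))
  }
  repeats <- do.call(rbind, rows)
  config <- list(n_repeats = as.integer(n_repeats),
                 base_seed = as.integer(base_seed),
                 C_grid = C_grid, kernel = unclass(kernel), k = as.integer(k),
                 grouped = !is.null(group_ids))
  structure(
    list(repeats = repeats, mean_accuracy = mean(repeats$accuracy),
         n_repeats = as.integer(n_repeats), base_seed = as.integer(base_seed),
         config = config,
         config_hash = config_hash(deparse(config))),
    class = "evaluation_report"
  )
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %d repeated per-patient half-splits (base seed %d)\n",
              x$n_repeats, x$base_seed))
  for (i in seq_len(nrow(x$repeats)))
    cat(sprintf("  repeat %d (seed %d): C = %g, accuracy = %.4f\n",
                x$repeats$repeat_[i], x$repeats$seed[i], x$repeats$C[i],
                x$repeats$accuracy[i]))
  cat(sprintf("  mean accuracy: %.4f\n", x$mean_accuracy))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' Writes per-repeat accuracies, their mean, the seeds and a configuration
#' fingerprint. Identical inputs and seeds produce byte-identical files.
#'
#' @param report an [run_experiment()] report.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "evaluation_report"))
  obj <- list(
    n_repeats = report$n_repeats,
    base_seed = report$base_seed,
    config_hash = report$config_hash,
    repeats = lapply(seq_len(nrow(report$repeats)), function(i) {
      as.list(report$repeats[i, c("repeat_", "seed", "C", "accuracy")])
    }),
    mean_accuracy = report$mean_accuracy
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
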
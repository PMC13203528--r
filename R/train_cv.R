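#' Subject-grouped k-fold assignment
#'
#' Assigns every subject to exactly one test fold, so no subject appears
#' on both sides of any split. Folds are balanced by subject count.
#'
#' @param trials List of [imu_trial()] objects, or a character vector of
#'   subject identifiers (one per trial).
#' @param k Number of folds.
#' @param seed Shuffling seed.
#' @return Integer vector of fold assignments (one per trial), with
#'   `attr(, "subject_folds")` naming each subject's fold.
#' @export
group_kfold_split <- function(trials, k = 5, seed = 42) {
  subjects <- if (is.character(trials)) trials
              else vapply(trials, function(t) t$subject_id, character(1))
  uniq <- unique(subjects)
  if (length(uniq) < k)
    stop("need at least ", k, " distinct subjects for ", k, " folds")
  set.seed(seed)
  ord <- sample(uniq)
  sf <- stats::setNames(rep(seq_len(k), length.out = length(ord)), ord)
  folds <- unname(sf[subjects])
  attr(folds, "subject_folds") <- sf
  folds
}

# guard: error if any subject sits in both train and test of a fold
check_no_leakage <- function(train_subj, test_subj) {
  both <- intersect(unique(train_subj), unique(test_subj))
  if (length(both))
    stop("subject leakage across the split: ", paste(both, collapse = ", "))
  invisible(TRUE)
}

#' Subject-grouped cross-validation of the full pipeline
#'
#' For each fold: split trials by subject, window the data, augment the
#' fall windows of the training side only, train with the fixed recipe
#' and run one inference pass on the sealed test side. Reports
#' window-level and trial-level metrics per fold and their means.
#'
#' @param trials List of annotated [imu_trial()] objects.
#' @param k Folds (default 5).
#' @param win_cfg A [windowing_config()].
#' @param madgwick_cfg A [madgwick_config()].
#' @param aug_cfg An [augment_config()].
#' @param spec A [fallnet_spec()].
#' @param control A [train_config()].
#' @param split_seed Seed of the subject shuffle.
#' @param verbose Progress messages.
#' @return A list of class `cv_report`: `folds` (per-fold lists with
#'   window/trial metrics and predictions) and `mean` (averaged trial and
#'   window F1, recall, precision, specificity, accuracy).
#' @export
run_cross_validation <- function(trials, k = 5, win_cfg = windowing_config(),
                                 madgwick_cfg = madgwick_config(),
                                 aug_cfg = augment_config(),
                                 spec = fallnet_spec(),
                                 control = train_config(), split_seed = 42,
                                 verbose = FALSE) {
  ws <- build_dataset(trials, win_cfg, madgwick_cfg)
  folds <- group_kfold_split(trials, k = k, seed = split_seed)
  sf <- attr(folds, "subject_folds")
  trial_fall <- stats::setNames(
    vapply(trials, function(t) as.integer(t$is_fall), integer(1)),
    vapply(trials, function(t) t$trial_id, character(1)))
  fold_out <- vector("list", k)
  for (f in seq_len(k)) {
    test_subj <- names(sf)[sf == f]
    is_test <- ws$subject %in% test_subj
    tr <- ws[which(!is_test)]
    te <- ws[which(is_test)]
    attr(tr, "role") <- "train"
    attr(te, "role") <- "test"
    check_no_leakage(tr$subject, te$subject)
    aug <- aug_cfg
    aug$seed <- aug_cfg$seed + f  # independent augmentation stream per fold
    tr <- augment_falls(tr, aug)
    if (verbose)
      message(sprintf("fold %d: %d train / %d test windows", f,
                      n_windows(tr), n_windows(te)))
    fit <- fallnet_fit(tr, spec = spec, control = control)
    probs <- predict(fit, te, type = "prob")
    wm <- window_metrics(probs, te$label)
    tm <- trial_max_voting(probs, te$trial_id,
                           trial_fall[te$trial_id])
    fold_out[[f]] <- list(fold = f, test_subjects = test_subj,
                          window = wm, trial = tm, probs = probs,
                          labels = te$label, trial_id = te$trial_id,
                          activity = te$activity, model = fit)
  }
  metric_names <- c("f1", "recall", "precision", "specificity", "accuracy")
  mean_of <- function(level) {
    vals <- sapply(fold_out, function(fo)
      unlist(fo[[level]][metric_names]))
    rowMeans(vals, na.rm = TRUE)
  }
  structure(list(folds = fold_out,
                 mean = list(trial = mean_of("trial"),
                             window = mean_of("window"))),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat("Subject-grouped cross-validation (", length(x$folds), " folds)\n", sep = "")
  cat("trial-level means: ",
      paste(sprintf("%s %.4f", names(x$mean$trial), x$mean$trial),
            collapse = ", "), "\n")
  cat("window-level means:",
      paste(sprintf("%s %.4f", names(x$mean$window), x$mean$window),
            collapse = ", "), "\n")
  invisible(x)
}
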
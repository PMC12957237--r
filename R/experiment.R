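#' Write or read a whole session as a fixture directory
#'
#' One sub-directory per run (`run-01`, `run-02`, ...), each a
#' [write_fixture()] directory.
#'
#' @param session List of per-run lists (`recording`, `events`).
#' @param path Parent directory.
#' @return `write_session_fixture()`: `path`, invisibly.
#' @export
write_session_fixture <- function(session, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (s in session)
    write_fixture(s$recording, s$events,
                  file.path(path, sprintf("run-%02d", s$recording$run_id)))
  invisible(path)
}

#' @rdname write_session_fixture
#' @export
read_session_fixture <- function(path) {
  dirs <- sort(list.dirs(path, recursive = FALSE))
  dirs <- dirs[grepl("run-[0-9]+$", dirs)]
  if (!length(dirs)) stop_format("no run-* directories under '%s'", path, field = "path")
  lapply(dirs, read_fixture)
}

#' Default end-to-end experiment configuration
#'
#' @param plan A [fold_plan()].
#' @param model A binary [scbam_config()].
#' @param train A [train_config()].
#' @param n_components CSP components per pair.
#' @param bands A [band_spec()].
#' @param window_len,step Window geometry in samples.
#' @param n_perm Permutation-test shuffles.
#' @param seed Master seed; fans out to the validation split, per-pair weight
#'   init/shuffling, and the permutation draws.
#' @return List of class `scbam_experiment_config`.
#' @export
experiment_config <- function(plan = fold_plan(), model = scbam_config(),
                              train = train_config(), n_components = 12,
                              bands = band_spec(), window_len = 600,
                              step = 300, n_perm = 5000, seed = 1L) {
  train$seed <- as.integer(seed)
  structure(list(plan = plan, model = model, train = train,
                 n_components = n_components, bands = bands,
                 window_len = window_len, step = step, n_perm = n_perm,
                 seed = as.integer(seed)),
            class = "scbam_experiment_config")
}

trial_votes <- function(window_labels, trial_ids) {
  ids <- unique(trial_ids)
  data.frame(trial_id = ids,
             pred = vapply(ids, function(id)
               vote_trial(window_labels[trial_ids == id]), integer(1)))
}

#' Run the full decoding experiment on a session
#'
#' Executes the complete offline workflow: preprocessing (train-run-fitted
#' z-score, CAR, notch cascade, artifact-based run rejection, overlapped
#' windowing), run-wise splitting with a trial-level validation hold-out,
#' pair-specific FBCSP fitting, training of the `choose(K, 2)` binary
#' attention classifiers, window-level prediction, trial-level majority
#' voting, one-vs-one multiclass voting with two-stage tie-breaking, and the
#' statistical evaluation (accuracy, kappa, permutation p, bootstrap CI over
#' pair accuracies, ROC points, learning curves). Fully reproducible from the
#' fixture hash, configuration and seed recorded in the report.
#'
#' @param session A session list (from [simulate_session()] or
#'   [read_session_fixture()]) or a path to a session fixture directory.
#' @param config An [experiment_config()].
#' @return An object of class `scbam_eval_report`.
#' @export
run_experiment <- function(session, config = experiment_config()) {
  if (is.character(session)) session <- read_session_fixture(session)
  fixture_hash <- rlang::hash(lapply(session, function(s)
    list(s$recording$signal, s$events)))
  fs <- session[[1]]$recording$fs

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      rlang::abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   class = "scbam_stage_error", parent = e))
  }

  prep <- stage("preprocess", preprocess_session(
    session, train_runs = config$plan$train_runs,
    window_len = config$window_len, step = config$step))
  splits <- stage("split", split_by_runs(
    prep$windows, config$plan,
    val_fraction = config$train$val_fraction, seed = config$seed))
  ensemble <- stage("train", train_ovo(
    splits, fs, model_cfg = config$model, train_cfg = config$train,
    n_components = config$n_components, bands = config$bands))

  classes <- ensemble$class_set
  test_truth <- trial_votes(splits$test$labels, splits$test$trial_ids)
  names(test_truth)[2] <- "truth"

  binary <- list()
  for (nm in names(ensemble$classifiers)) {
    cl <- ensemble$classifiers[[nm]]
    pair <- cl$class_pair
    keep <- splits$test$labels %in% pair
    wtest <- subset_windows(splits$test, keep)
    probs <- predict(cl$net, featurize(wtest, cl$fbcsp))
    wlab <- pair[max.col(probs, ties.method = "first")]
    tv <- trial_votes(wlab, wtest$trial_ids)
    truth <- test_truth$truth[match(tv$trial_id, test_truth$trial_id)]
    cm <- confusion_matrix(truth, tv$pred, classes = pair)
    perm <- permutation_test(truth, tv$pred, n_perm = config$n_perm,
                             seed = config$seed + 101L)
    roc <- roc_points(probs[, 2], wtest$labels, positive = pair[2])
    binary[[nm]] <- list(
      class_pair = pair, confusion = cm, accuracy = accuracy(cm),
      kappa = cohens_kappa(cm), window_accuracy = mean(wlab == wtest$labels),
      permutation_p = perm$p, permutation_p_raw = perm$p_raw,
      roc = roc, history = cl$history)
  }

  ovo <- stage("ovo_predict", ovo_predict(ensemble, splits$test))
  tv5 <- trial_votes(ovo$labels, splits$test$trial_ids)
  truth5 <- test_truth$truth[match(tv5$trial_id, test_truth$trial_id)]
  cm5 <- confusion_matrix(truth5, tv5$pred, classes = classes)
  perm5 <- permutation_test(truth5, tv5$pred, n_perm = config$n_perm,
                            seed = config$seed + 202L)
  pair_acc <- vapply(binary, `[[`, numeric(1), "accuracy")
  ci <- bootstrap_ci(pair_acc, seed = config$seed + 303L)

  structure(list(
    binary = binary,
    pair_accuracies = pair_acc,
    pair_kappas = vapply(binary, `[[`, numeric(1), "kappa"),
    pair_accuracy_ci = ci,
    multiclass = list(
      confusion = cm5, accuracy = accuracy(cm5), kappa = cohens_kappa(cm5),
      window_accuracy = mean(ovo$labels == splits$test$labels),
      permutation_p = perm5$p, permutation_p_raw = perm5$p_raw,
      null_accuracies = perm5$null_accuracies),
    n_trials = list(train = length(unique(splits$train$trial_ids)),
                    val = length(unique(splits$val$trial_ids)),
                    test = nrow(test_truth)),
    provenance = list(seed = config$seed, fixture_hash = fixture_hash,
                      config_hash = rlang::hash(config),
                      rejected_runs = prep$rejected_runs)),
    class = "scbam_eval_report")
}

#' @export
print.scbam_eval_report <- function(x, ...) {
  cat("<scbam_eval_report>\n")
  cat(sprintf("  binary pairs: %d, mean accuracy %.4f (kappa %.4f)\n",
              length(x$binary), mean(x$pair_accuracies), mean(x$pair_kappas)))
  cat(sprintf("  multiclass accuracy %.4f (kappa %.4f), permutation p = %.4g\n",
              x$multiclass$accuracy, x$multiclass$kappa, x$multiclass$permutation_p))
  cat(sprintf("  trials train/val/test: %d/%d/%d\n",
              x$n_trials$train, x$n_trials$val, x$n_trials$test))
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report A `scbam_eval_report`.
#' @param path Output file.
#' @export
report_to_json <- function(report, path) {
  stripped <- report
  stripped$multiclass$null_accuracies <- NULL
  for (nm in names(stripped$binary)) {
    stripped$binary[[nm]]$confusion <- unclass(stripped$binary[[nm]]$confusion)
    stripped$binary[[nm]]$roc$points <- as.list(stripped$binary[[nm]]$roc$points)
    stripped$binary[[nm]]$history <- as.list(stripped$binary[[nm]]$history)
  }
  stripped$multiclass$confusion <- unclass(stripped$multiclass$confusion)
  jsonlite::write_json(unclass(stripped), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
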
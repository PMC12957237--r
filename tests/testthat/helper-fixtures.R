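# Shared fixtures, all generated in code. The "tiny" profile keeps the full
# protocol shape (30 s baseline, 3-4 s rests, 5 s tasks, balanced cues, fs 600)
# on a small grid with few trials so end-to-end properties stay affordable.

tiny_montage <- function(n = 4) make_grid_montage(n, n, 8.6)

tiny_spec <- function(effect_size = 1, seed = 1, n_runs = 5, trials_per_run = 10) {
  sim_spec(n_runs = n_runs, trials_per_run = trials_per_run,
           effect_size = effect_size, seed = seed)
}

tiny_model_cfg <- function(...) {
  scbam_config(conv1_filters = 16, reduction_ratio = 4, conv2_filters = 8,
               dense_hidden = 16, ...)
}

# A feature map with controllable metadata, for split/vote arithmetic tests.
fake_features <- function(n_runs = 10, trials_per_run = 25, windows_per_trial = 9,
                          n_classes = 5, C = 12, R = 6, seed = 1) {
  n_trials <- n_runs * trials_per_run
  n <- n_trials * windows_per_trial
  withr::with_seed(seed, {
    labels_tr <- rep(rep(seq_len(n_classes), trials_per_run / n_classes), n_runs)
    structure(list(
      values = array(stats::rnorm(n * C * R), c(n, C, R)),
      labels = rep(labels_tr, each = windows_per_trial),
      trial_ids = rep(seq_len(n_trials), each = windows_per_trial),
      run_ids = rep(rep(seq_len(n_runs), each = trials_per_run), each = windows_per_trial)),
      class = "scbam_feature_map")
  })
}

# Linearly separable synthetic feature maps for classifier sanity checks.
separable_features <- function(n_trials_per_class = 20, windows_per_trial = 9,
                               gap = 3, seed = 1, C = 12, R = 6) {
  n <- 2 * n_trials_per_class * windows_per_trial
  withr::with_seed(seed, {
    lab_tr <- rep(c(1, 2), each = n_trials_per_class)
    labels <- rep(lab_tr, each = windows_per_trial)
    x <- array(stats::rnorm(n * C * R), c(n, C, R))
    x[labels == 2, 2, 3] <- x[labels == 2, 2, 3] + gap
    structure(list(values = x, labels = labels,
                   trial_ids = rep(seq_len(2 * n_trials_per_class), each = windows_per_trial),
                   run_ids = rep(1L, n)),
              class = "scbam_feature_map")
  })
}

# Binary pipeline on a simulated session: preprocess, split, FBCSP, train one
# pairwise classifier, return trial-level test accuracy and predictions.
binary_pipeline <- function(session, pair = c(1, 5), plan = fold_plan(1:3, 4:5),
                            n_components = 8, epochs = 5, seed = 1,
                            model_cfg = tiny_model_cfg(), val_fraction = 0.2) {
  model_cfg$input_shape <- c(n_components, 6)
  prep <- preprocess_session(session, train_runs = plan$train_runs)
  splits <- split_by_runs(prep$windows, plan, val_fraction = val_fraction, seed = seed)
  fb <- fit_fbcsp(splits$train, pair, fs = session[[1]]$recording$fs, n_components)
  f_tr <- featurize(subset_windows(splits$train, splits$train$labels %in% pair), fb)
  f_va <- featurize(subset_windows(splits$val, splits$val$labels %in% pair), fb)
  f_te <- featurize(subset_windows(splits$test, splits$test$labels %in% pair), fb)
  fit <- train_binary(list(train = f_tr, val = f_va), pair, model_cfg,
                      train_config(epochs = epochs, seed = seed,
                                   val_fraction = val_fraction))
  probs <- predict(fit$net, f_te)
  wlab <- pair[max.col(probs, ties.method = "first")]
  ids <- unique(f_te$trial_ids)
  pred <- vapply(ids, function(id) vote_trial(wlab[f_te$trial_ids == id]), integer(1))
  truth <- vapply(ids, function(id) f_te$labels[match(id, f_te$trial_ids)], numeric(1))
  list(accuracy = mean(pred == truth), pred = pred, truth = truth,
       window_probs = probs, fit = fit)
}
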
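#' Run-wise train/test fold plan
#'
#' Training and test sets are separated by whole runs (default: runs 1-8 train,
#' runs 9-10 test) so that no trial — and no fitted statistic — crosses the
#' boundary.
#'
#' @param train_runs,test_runs Disjoint integer vectors of run ids.
#' @return An object of class `scbam_fold_plan`.
#' @export
fold_plan <- function(train_runs = 1:8, test_runs = 9:10) {
  if (length(intersect(train_runs, test_runs)))
    stop_invalid("train and test run sets overlap: %s",
                 paste(intersect(train_runs, test_runs), collapse = ", "))
  structure(list(train_runs = train_runs, test_runs = test_runs),
            class = "scbam_fold_plan")
}

subset_features <- function(fm, idx) {
  structure(list(values = fm$values[idx, , , drop = FALSE],
                 labels = fm$labels[idx], trial_ids = fm$trial_ids[idx],
                 run_ids = fm$run_ids[idx], class_pair = fm$class_pair),
            class = "scbam_feature_map")
}

#' Split windows or features by runs, with a trial-level validation hold-out
#'
#' Partitions by run membership, then carves a validation set out of the
#' training partition by sampling whole trials (stratified by class) until
#' `val_fraction` of the training trials is reached. No trial id ever appears
#' in more than one partition.
#'
#' @param x A `scbam_window_set` or `scbam_feature_map` carrying `run_ids`,
#'   `trial_ids` and `labels`.
#' @param plan A [fold_plan()].
#' @param val_fraction Fraction of training trials moved to validation.
#' @param seed Seed for the validation draw.
#' @return List with `train`, `val`, `test` partitions of the same class as `x`.
#' @export
split_by_runs <- function(x, plan, val_fraction = 0.10, seed = 1L) {
  stopifnot(inherits(plan, "scbam_fold_plan"))
  if (is.null(x$run_ids)) stop_invalid("input carries no run ids")
  take <- if (inherits(x, "scbam_feature_map")) subset_features else subset_windows
  tr_idx <- which(x$run_ids %in% plan$train_runs)
  te_idx <- which(x$run_ids %in% plan$test_runs)
  trials <- unique(data.frame(trial_id = x$trial_ids[tr_idx],
                              label = x$labels[tr_idx]))
  val_trials <- with_seed(seed, {
    unlist(lapply(split(trials$trial_id, trials$label), function(ids) {
      k <- round(val_fraction * length(ids))
      if (k > 0) sample(ids, k) else integer(0)
    }))
  })
  va_idx <- tr_idx[x$trial_ids[tr_idx] %in% val_trials]
  tr_idx <- setdiff(tr_idx, va_idx)
  list(train = take(x, tr_idx), val = take(x, va_idx), test = take(x, te_idx))
}

#' Trial-level majority vote
#'
#' Assigns a trial the modal label of its constituent window predictions;
#' exact ties (impossible for the binary 9-window case) fall back to the
#' smallest label. The one-vs-one ensemble applies its own tie rules before
#' this function is reached.
#'
#' @param window_predictions Nonempty vector of class labels.
#' @return The modal label.
#' @export
vote_trial <- function(window_predictions) {
  if (!length(window_predictions)) stop_invalid("empty prediction list")
  tab <- table(window_predictions)
  as.integer(names(tab)[which.max(tab)])   # which.max takes the first (smallest label) on ties
}

#' Train the one-vs-one classifier ensemble
#'
#' Fits, for every unordered class pair, a pair-specific FBCSP extractor on
#' the training windows of those two classes and a binary sandwich-attention
#' classifier on the resulting feature maps — `choose(K, 2)` classifiers in
#' total (10 for five fingers). Per-pair seeds derive from the master training
#' seed so the whole ensemble is reproducible.
#'
#' @param splits Output of [split_by_runs()] on a `scbam_window_set`.
#' @param fs Sampling rate in Hz.
#' @param model_cfg A binary [scbam_config()].
#' @param train_cfg A [train_config()].
#' @param n_components CSP components per pair.
#' @param bands A [band_spec()].
#' @param band_first Per-band CSP fitting (see [fit_fbcsp()]).
#' @return An object of class `scbam_ovo`: `classifiers` (named list
#'   `"a_b"` of `fbcsp`, `net`, `history`, `class_pair`), `class_set`.
#' @export
train_ovo <- function(splits, fs, model_cfg = scbam_config(),
                      train_cfg = train_config(), n_components = 12,
                      bands = band_spec(), band_first = FALSE) {
  classes <- sort(unique(splits$train$labels))
  model_cfg$input_shape <- c(n_components, length(bands$bands))
  pairs <- utils::combn(classes, 2, simplify = FALSE)
  classifiers <- list()
  for (pi in seq_along(pairs)) {
    pair <- pairs[[pi]]
    fb <- fit_fbcsp(splits$train, pair, fs, n_components, bands, band_first)
    f_tr <- featurize(subset_windows(splits$train, splits$train$labels %in% pair), fb)
    f_va <- featurize(subset_windows(splits$val, splits$val$labels %in% pair), fb)
    cfg <- train_cfg
    cfg$seed <- train_cfg$seed + pi
    fit <- train_binary(list(train = f_tr, val = f_va), pair, model_cfg, cfg)
    classifiers[[paste(pair, collapse = "_")]] <-
      list(fbcsp = fb, net = fit$net, history = fit$history, class_pair = pair)
  }
  structure(list(classifiers = classifiers, class_set = classes),
            class = "scbam_ovo")
}

#' Resolve one-vs-one votes for a single window
#'
#' Stage 1: each pairwise classifier casts one vote; a unique tally maximum
#' wins. Stage 2 (tie): votes are recounted using only classifiers whose pair
#' is a subset of the tied candidate set. Stage 3 (still tied): each remaining
#' candidate's softmax probabilities are summed over all classifiers involving
#' it and the maximum wins; any residual exact tie goes to the smallest label.
#'
#' @param pairs List of length-2 class vectors, one per classifier.
#' @param votes Vector of voted labels, one per classifier.
#' @param probs Matrix (classifiers x 2) of softmax probabilities aligned with
#'   `pairs` columns.
#' @return List with `label`, `tally`, `stage` (1, 2 or 3).
#' @export
ovo_vote <- function(pairs, votes, probs) {
  classes <- sort(unique(unlist(pairs)))
  tally <- vapply(classes, function(k) sum(votes == k), numeric(1))
  names(tally) <- classes
  tied <- classes[tally == max(tally)]
  if (length(tied) == 1L)
    return(list(label = tied, tally = tally, stage = 1L))
  sub <- vapply(pairs, function(p) all(p %in% tied), logical(1))
  if (any(sub)) {
    sub_tally <- vapply(tied, function(k) sum(votes[sub] == k), numeric(1))
    tied2 <- tied[sub_tally == max(sub_tally)]
    if (length(tied2) == 1L)
      return(list(label = tied2, tally = tally, stage = 2L))
  } else tied2 <- tied
  cum <- vapply(tied2, function(k) {
    s <- 0
    for (i in seq_along(pairs)) {
      j <- match(k, pairs[[i]])
      if (!is.na(j)) s <- s + probs[i, j]
    }
    s
  }, numeric(1))
  winners <- tied2[cum == max(cum)]
  list(label = min(winners), tally = tally, stage = 3L)
}

#' Multiclass prediction of windows through the one-vs-one ensemble
#'
#' Every window is featurized once per pair-specific FBCSP and evaluated by
#' all `choose(K, 2)` classifiers; votes are resolved by [ovo_vote()].
#'
#' @param ensemble A [train_ovo()] ensemble.
#' @param windows A `scbam_window_set`.
#' @return List with `labels` (per-window prediction), `tallies`
#'   (windows x classes vote counts) and `prob_tables` (per-pair probability
#'   matrices).
#' @export
ovo_predict <- function(ensemble, windows) {
  stopifnot(inherits(ensemble, "scbam_ovo"))
  expected <- vapply(utils::combn(ensemble$class_set, 2, simplify = FALSE),
                     paste, character(1), collapse = "_")
  missing <- setdiff(expected, names(ensemble$classifiers))
  if (length(missing))
    stop_invalid("ensemble is missing pairwise classifier(s): %s",
                 paste(missing, collapse = ", "))
  clfs <- ensemble$classifiers
  n_w <- dim(windows$data)[1]
  pair_list <- lapply(clfs, `[[`, "class_pair")
  probs <- lapply(clfs, function(cl)
    predict(cl$net, featurize(windows, cl$fbcsp)))
  labels <- integer(n_w)
  tallies <- matrix(0, n_w, length(ensemble$class_set),
                    dimnames = list(NULL, ensemble$class_set))
  for (w in seq_len(n_w)) {
    pv <- vapply(seq_along(clfs), function(i) {
      pair_list[[i]][max.col(probs[[i]][w, , drop = FALSE], ties.method = "first")]
    }, numeric(1))
    pm <- t(vapply(probs, function(p) p[w, ], numeric(2)))
    r <- ovo_vote(pair_list, pv, pm)
    labels[w] <- r$label
    tallies[w, ] <- r$tally
  }
  list(labels = labels, tallies = tallies, prob_tables = probs)
}
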
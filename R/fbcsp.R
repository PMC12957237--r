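#' Canonical EEG rhythm bands
#'
#' The default filter bank: delta (1-4 Hz), alpha (8-12), beta (12-30), gamma
#' (30-50), high gamma (75-115) and super high gamma (125-150), each realized
#' as a zero-phase 4th-order Butterworth band-pass.
#'
#' @param filter_order Transfer-function order of each band-pass.
#' @return An object of class `scbam_band_spec`.
#' @export
band_spec <- function(filter_order = 4) {
  bands <- list(delta = c(1, 4), alpha = c(8, 12), beta = c(12, 30),
                gamma = c(30, 50), high_gamma = c(75, 115),
                super_high_gamma = c(125, 150))
  structure(list(bands = bands, filter_order = filter_order),
            class = "scbam_band_spec")
}

#' Average trace-normalized class covariance
#'
#' Per-window channel covariances (rows centered) are trace-normalized, then
#' averaged over all windows of the class, and a small ridge
#' (`1e-6 x mean diagonal`) is added for conditioning.
#'
#' @param windows A `scbam_window_set`.
#' @param label Class whose windows enter the average.
#' @return A symmetric positive-definite channels x channels matrix.
#' @export
class_covariance <- function(windows, label) {
  idx <- which(windows$labels == label)
  if (!length(idx)) stop_invalid("no windows with label %s", label)
  n_chan <- dim(windows$data)[2]
  acc <- matrix(0, n_chan, n_chan)
  for (w in idx) {
    X <- windows$data[w, , , drop = TRUE]
    if (n_chan == 1L) X <- matrix(X, nrow = 1L)
    X <- X - rowMeans(X)
    C <- tcrossprod(X) / ncol(X)
    tr <- sum(diag(C))
    if (tr > 0) acc <- acc + C / tr
  }
  C <- acc / length(idx)
  C + diag(1e-6 * mean(diag(C)), n_chan)
}

#' Common spatial pattern filters for a class pair
#'
#' Solves the two-class variance-ratio criterion by whitening the composite
#' covariance `C1 + C2` and eigendecomposing the whitened `C1`. Filters satisfy
#' `w' (C1 + C2) w = 1`; the returned set holds the `n_components / 2` filters
#' with the largest eigenvalues (maximal class-1 variance ratio) followed by
#' the `n_components / 2` with the smallest. Spatial patterns (for topography
#' export) are the pseudo-inverse of the selected filter matrix.
#'
#' @param C1,C2 Class covariance matrices (see [class_covariance()]).
#' @param n_components Even number of retained components (default 12, 6 per
#'   class).
#' @param class_pair Optional length-2 vector recording which labels the
#'   filters discriminate.
#' @return An object of class `scbam_csp`: `W` (channels x n_components filter
#'   matrix), `patterns` (n_components x channels), `eigenvalues`,
#'   `class_pair`, `n_components`.
#' @export
fit_csp <- function(C1, C2, n_components = 12, class_pair = NULL) {
  if (!all(dim(C1) == dim(C2))) stop_invalid("C1 and C2 must have identical shape")
  if (n_components %% 2 != 0) stop_invalid("n_components must be even")
  n_chan <- nrow(C1)
  if (n_components > n_chan)
    stop_invalid("n_components (%d) exceeds channel count (%d)", n_components, n_chan)
  Cc <- (C1 + C2 + t(C1 + C2)) / 2
  ec <- eigen(Cc, symmetric = TRUE)
  if (max(ec$values) <= 0)
    stop_numerical("composite covariance C1 + C2 is not positive definite")
  # rank-aware whitening: directions carried only by the ridge (e.g. the
  # common-average-reference null space) are excluded so no filter can land
  # in a zero-variance subspace
  keep <- ec$values > 1e-6 * max(ec$values)
  rank <- sum(keep)
  if (rank < n_components)
    stop_numerical("composite covariance C1 + C2 has rank %d < %d requested components",
                   rank, n_components)
  P <- diag(1 / sqrt(ec$values[keep]), nrow = rank) %*%
    t(ec$vectors[, keep, drop = FALSE])              # whitening: P Cc P' = I
  S <- P %*% C1 %*% t(P)
  S <- (S + t(S)) / 2
  es <- eigen(S, symmetric = TRUE)                   # values descending in (0, 1)
  W_full <- t(P) %*% es$vectors
  half <- n_components / 2L
  sel <- c(seq_len(half), seq(rank - half + 1L, rank))
  W <- W_full[, sel, drop = FALSE]
  for (j in seq_len(ncol(W))) {                       # sign: dominant coefficient positive
    k <- which.max(abs(W[, j]))
    if (W[k, j] < 0) W[, j] <- -W[, j]
  }
  structure(list(W = W, patterns = MASS::ginv(W), eigenvalues = es$values[sel],
                 class_pair = class_pair, n_components = as.integer(n_components)),
            class = "scbam_csp")
}

#' Band-pass a set of component traces through the filter bank
#'
#' @param component_signals Array windows x components x samples.
#' @param bands A [band_spec()].
#' @param fs Sampling rate in Hz.
#' @return Array windows x components x bands x samples of zero-phase filtered
#'   traces.
#' @export
apply_filter_bank <- function(component_signals, bands, fs) {
  stopifnot(inherits(bands, "scbam_band_spec"))
  d <- dim(component_signals)
  R <- length(bands$bands)
  out <- array(0, dim = c(d[1], d[2], R, d[3]))
  X <- matrix(aperm(component_signals, c(3, 2, 1)), nrow = d[3])  # time x (comp, window)
  for (r in seq_len(R)) {
    filt <- butter_bandpass(bands$bands[[r]][1], bands$bands[[r]][2], fs,
                            bands$filter_order)
    Y <- zero_phase_filter_mat(filt, X, pad = 300L)
    out[, , r, ] <- aperm(array(Y, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
  }
  out
}

#' Log centered mean power of a trace
#'
#' `log(mean((x - mean(x))^2) + 1e-12)`; the epsilon floors constant traces.
#'
#' @param x Numeric vector.
#' @return Scalar log power.
#' @export
log_power <- function(x) log(mean((x - mean(x))^2) + 1e-12)

#' Fit a filter-bank CSP feature extractor
#'
#' Default pipeline order fits one broadband CSP on the preprocessed windows
#' and band-passes the resulting component traces (one topography per
#' component). `band_first = TRUE` instead fits a separate CSP per band
#' (classic filter-bank CSP) for comparison.
#'
#' @param windows_train Training `scbam_window_set` (two classes).
#' @param class_pair Length-2 vector of the labels to discriminate.
#' @param fs Sampling rate in Hz.
#' @param n_components Retained CSP components.
#' @param bands A [band_spec()].
#' @param band_first Fit per-band CSPs instead of one broadband CSP.
#' @return An object of class `scbam_fbcsp` holding the fitted CSP(s), bands
#'   and geometry; pass to [featurize()].
#' @export
fit_fbcsp <- function(windows_train, class_pair, fs, n_components = 12,
                      bands = band_spec(), band_first = FALSE) {
  stopifnot(length(class_pair) == 2)
  keep <- windows_train$labels %in% class_pair
  ws <- subset_windows(windows_train, keep)
  if (band_first) {
    csps <- lapply(seq_along(bands$bands), function(r) {
      filt <- butter_bandpass(bands$bands[[r]][1], bands$bands[[r]][2], fs,
                              bands$filter_order)
      wsb <- ws
      d <- dim(ws$data)
      X <- matrix(aperm(ws$data, c(3, 2, 1)), nrow = d[3])
      Y <- zero_phase_filter_mat(filt, X, pad = 300L)
      wsb$data <- aperm(array(Y, dim = c(d[3], d[2], d[1])), c(3, 2, 1))
      fit_csp(class_covariance(wsb, class_pair[1]),
              class_covariance(wsb, class_pair[2]),
              n_components, class_pair)
    })
    csp <- csps[[1]]
  } else {
    csp <- fit_csp(class_covariance(ws, class_pair[1]),
                   class_covariance(ws, class_pair[2]),
                   n_components, class_pair)
    csps <- NULL
  }
  structure(list(csp = csp, per_band_csp = csps, bands = bands, fs = fs,
                 n_components = as.integer(n_components),
                 class_pair = class_pair, band_first = band_first),
            class = "scbam_fbcsp")
}

#' Transform windows into log-power feature maps
#'
#' Projects each window through the fitted spatial filters, band-passes the
#' component traces through the filter bank and reduces every
#' (component, band) trace to its log centered mean power, yielding a
#' windows x components x bands array (12 x 6 per window under the defaults).
#'
#' @param windows A `scbam_window_set`.
#' @param model A fitted [fit_fbcsp()] extractor.
#' @return An object of class `scbam_feature_map`: `values` (windows x C x R),
#'   `labels`, `trial_ids`, `run_ids`, `class_pair`.
#' @export
featurize <- function(windows, model) {
  stopifnot(inherits(model, "scbam_fbcsp"))
  d <- dim(windows$data)
  n_w <- d[1]; n_chan <- d[2]; n_t <- d[3]
  C <- model$n_components
  R <- length(model$bands$bands)
  vals <- array(0, dim = c(n_w, C, R))
  if (n_w == 0L)
    return(structure(list(values = vals, labels = windows$labels,
                          trial_ids = windows$trial_ids, run_ids = windows$run_ids,
                          class_pair = model$class_pair),
                     class = "scbam_feature_map"))
  Xm <- matrix(aperm(windows$data, c(3, 1, 2)), nrow = n_t * n_w)  # (time, window) x chan
  for (r in seq_len(R)) {
    W <- if (model$band_first) model$per_band_csp[[r]]$W else model$csp$W
    filt <- butter_bandpass(model$bands$bands[[r]][1], model$bands$bands[[r]][2],
                            model$fs, model$bands$filter_order)
    Y <- Xm %*% W                                   # (time, window) x C
    Ym <- matrix(Y, nrow = n_t)                     # time x (window, comp)
    Fm <- zero_phase_filter_mat(filt, Ym, pad = 300L)
    p <- colMeans(Fm^2) - colMeans(Fm)^2
    vals[, , r] <- matrix(log(pmax(p, 0) + 1e-12), nrow = n_w)
  }
  structure(list(values = vals, labels = windows$labels,
                 trial_ids = windows$trial_ids, run_ids = windows$run_ids,
                 class_pair = model$class_pair),
            class = "scbam_feature_map")
}

#' Export CSP spatial patterns for topographic plotting
#'
#' Writes one row per (component, electrode) with the electrode's grid
#' coordinates and the pattern weight, ready for scalp-map plotting.
#'
#' @param model A `scbam_fbcsp` or `scbam_csp`.
#' @param montage The recording montage.
#' @param file Output CSV path.
#' @export
export_csp_patterns <- function(model, montage, file) {
  csp <- if (inherits(model, "scbam_fbcsp")) model$csp else model
  A <- csp$patterns                     # components x channels
  df <- do.call(rbind, lapply(seq_len(nrow(A)), function(k) {
    data.frame(component = k, electrode = montage$coords$electrode,
               x = montage$coords$x, y = montage$coords$y, weight = A[k, ])
  }))
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
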
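make_ws <- function(data, labels) {
  structure(list(data = data, labels = labels,
                 trial_ids = seq_along(labels), run_ids = rep(1L, length(labels)),
                 window_len = dim(data)[3], step = dim(data)[3]),
            class = "scbam_window_set")
}

# Brute-force Rayleigh-quotient search: the independent oracle for CSP.
rayleigh_argmax <- function(C1, C2, n_draws = 1e5, seed = 1) {
  withr::with_seed(seed, {
    d <- nrow(C1)
    W <- matrix(rnorm(n_draws * d), d)
    W <- sweep(W, 2, sqrt(colSums(W^2)), `/`)
    J <- colSums(W * (C1 %*% W)) / colSums(W * (C2 %*% W))
    list(best = W[, which.max(J)], worst = W[, which.min(J)],
         Jmax = max(J), Jmin = min(J))
  })
}

angle_deg <- function(u, v) {
  c <- abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, c)) * 180 / pi
}

test_that("class covariances are normalized, averaged and ridge-conditioned", {
  set.seed(1)
  ws <- make_ws(array(rnorm(10 * 4 * 10000), c(10, 4, 10000)), rep(1L, 10))
  C <- class_covariance(ws, 1)
  expect_true(isSymmetric(C))
  expect_equal(diag(C), rep(0.25, 4), tolerance = 0.02)  # I / channels after trace norm
  expect_lt(max(abs(C[upper.tri(C)])), 0.02)
  expect_true(all(eigen(C, symmetric = TRUE, only.values = TRUE)$values > 0))

  one <- make_ws(array(rnorm(100), c(1, 1, 100)), 1L)
  expect_equal(class_covariance(one, 1)[1, 1], 1, tolerance = 1e-5)

  dup <- make_ws(ws$data[c(1:10, 1:10), , ], rep(1L, 20))
  expect_equal(class_covariance(dup, 1), C)

  expect_error(class_covariance(ws, 99), class = "scbam_invalid_argument")
})

test_that("identical class covariances give no discrimination", {
  set.seed(2)
  A <- crossprod(matrix(rnorm(36), 6))
  m <- fit_csp(A, A, n_components = 4)
  expect_equal(m$eigenvalues, rep(0.5, 4), tolerance = 1e-9)
  J <- diag(t(m$W) %*% A %*% m$W) / diag(t(m$W) %*% A %*% m$W)
  expect_equal(J, rep(1, 4))
})

test_that("CSP filters match the brute-force variance-ratio oracle", {
  C1 <- diag(c(4, 1, 1)); C2 <- diag(c(1, 1, 4))
  m <- fit_csp(C1, C2, n_components = 2)
  oracle <- rayleigh_argmax(C1, C2)
  expect_lt(angle_deg(m$W[, 1], c(1, 0, 0)), 1)
  expect_lt(angle_deg(m$W[, 2], c(0, 0, 1)), 1)
  expect_lt(angle_deg(m$W[, 1], oracle$best), 1)
  expect_lt(angle_deg(m$W[, 2], oracle$worst), 1)
  J1 <- drop(t(m$W[, 1]) %*% C1 %*% m$W[, 1] / (t(m$W[, 1]) %*% C2 %*% m$W[, 1]))
  J2 <- drop(t(m$W[, 2]) %*% C1 %*% m$W[, 2] / (t(m$W[, 2]) %*% C2 %*% m$W[, 2]))
  expect_equal(J1, 4, tolerance = 1e-9)
  expect_equal(J2, 1 / 4, tolerance = 1e-9)

  # random 3-channel SPD problems: extreme filters still match the oracle
  for (seed in 1:3) {
    withr::with_seed(seed, {
      A1 <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.1
      A2 <- crossprod(matrix(rnorm(9), 3)) + diag(3) * 0.1
    })
    mm <- fit_csp(A1, A2, n_components = 2)
    oo <- rayleigh_argmax(A1, A2, seed = seed)
    expect_lt(angle_deg(mm$W[, 1], oo$best), 1)
    expect_lt(angle_deg(mm$W[, 2], oo$worst), 1)
  }
})

test_that("CSP returns the requested components with the whitening convention", {
  set.seed(3)
  C1 <- crossprod(matrix(rnorm(256), 16)) + diag(16)
  C2 <- crossprod(matrix(rnorm(256), 16)) + diag(16)
  m <- fit_csp(C1, C2, n_components = 12)
  expect_equal(ncol(m$W), 12)
  expect_equal(dim(m$patterns), c(12, 16))
  # w' (C1 + C2) w = 1 for every filter
  expect_equal(diag(t(m$W) %*% (C1 + C2) %*% m$W), rep(1, 12), tolerance = 1e-9)
  # eigenvalues ordered [6 largest, 6 smallest]
  expect_true(all(m$eigenvalues[1:6] > m$eigenvalues[7:12]))
  expect_equal(m$patterns, MASS::ginv(m$W), tolerance = 1e-9)

  # class-role symmetry: lambda <-> 1 - lambda
  ms <- fit_csp(C2, C1, n_components = 12)
  expect_equal(sort(ms$eigenvalues), sort(1 - m$eigenvalues), tolerance = 1e-9)

  expect_error(fit_csp(C1, C2, n_components = 18), class = "scbam_invalid_argument")
  expect_error(fit_csp(-C1, -C2, 2), class = "scbam_numerical_error")
})

test_that("CSP is invariant to a global amplitude scale", {
  set.seed(4)
  ws <- make_ws(array(rnorm(20 * 5 * 300), c(20, 5, 300)), rep(c(1L, 2L), 10))
  ws$data[ws$labels == 2, 2, ] <- ws$data[ws$labels == 2, 2, ] * 3
  m1 <- fit_csp(class_covariance(ws, 1), class_covariance(ws, 2), 4)
  ws2 <- ws; ws2$data <- ws$data * 7.3
  m2 <- fit_csp(class_covariance(ws2, 1), class_covariance(ws2, 2), 4)
  expect_equal(m1$W, m2$W, tolerance = 1e-6)
})

test_that("the filter bank isolates rhythms", {
  fs <- 600
  t <- seq(0, 5, by = 1 / fs)
  x <- array(0, c(1, 1, length(t)))
  x[1, 1, ] <- sin(2 * pi * 10 * t)
  out <- apply_filter_bank(x, band_spec(), fs)
  expect_equal(dim(out)[3], 6)
  rms_in <- sqrt(mean(x^2))
  rms_alpha <- sqrt(mean(out[1, 1, 2, ]^2))        # alpha band: 8-12 Hz
  rms_delta <- sqrt(mean(out[1, 1, 1, ]^2))
  expect_gt(rms_alpha / rms_in, 10^(-1 / 20))      # < 1 dB loss
  expect_lt(rms_delta / rms_in, 0.05)

  zero <- apply_filter_bank(array(0, c(2, 3, 600)), band_spec(), fs)
  expect_equal(zero, array(0, c(2, 3, 6, 600)))

  bad <- band_spec(); bad$bands$super_high_gamma <- c(125, 350)
  expect_error(apply_filter_bank(x, bad, fs), class = "scbam_invalid_argument")
})

test_that("log centered mean power has its closed forms", {
  t <- seq(0, 100, by = 1 / 600)
  expect_equal(log_power(sin(2 * pi * 10 * t)), log(0.5), tolerance = 1e-3)
  expect_equal(log_power(rep(4.2, 1000)), log(1e-12))
})

test_that("featurize produces finite 12 x 6 feature planes from fitted filters", {
  set.seed(5)
  ws <- make_ws(array(rnorm(40 * 16 * 600), c(40, 16, 600)), rep(c(1L, 2L), 20))
  fb <- fit_fbcsp(ws, c(1, 2), fs = 600, n_components = 12)
  fm <- featurize(ws, fb)
  expect_equal(dim(fm$values), c(40, 12, 6))
  expect_true(all(is.finite(fm$values)))
  expect_identical(fm$labels, ws$labels)

  # band-first variant keeps the same output geometry
  fb2 <- fit_fbcsp(ws, c(1, 2), fs = 600, n_components = 4, band_first = TRUE)
  fm2 <- featurize(ws, fb2)
  expect_equal(dim(fm2$values), c(40, 4, 6))
  expect_true(all(is.finite(fm2$values)))
})

test_that("CSP patterns export with electrode coordinates", {
  set.seed(6)
  ws <- make_ws(array(rnorm(20 * 9 * 300), c(20, 9, 300)), rep(c(1L, 2L), 10))
  fb <- fit_fbcsp(ws, c(1, 2), fs = 600, n_components = 4)
  f <- withr::local_tempfile(fileext = ".csv")
  export_csp_patterns(fb, tiny_montage(3), f)
  df <- read.csv(f)
  expect_equal(names(df), c("component", "electrode", "x", "y", "weight"))
  expect_equal(nrow(df), 4 * 9)
})
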
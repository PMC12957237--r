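test_that("configs validate their invariants", {
  expect_error(scbam_config(reduction_ratio = 7), class = "scbam_invalid_argument")
  expect_error(scbam_config(conv1_kernel = c(0, 5)), class = "scbam_invalid_argument")
  expect_error(build_model(scbam_config(variant = "nonsense")),
               class = "scbam_invalid_argument")
  expect_error(build_model(scbam_config(variant = "CTF")),
               class = "scbam_invalid_argument")
  expect_error(build_model(scbam_config(variant = "CSA")),
               class = "scbam_invalid_argument")
})

test_that("the full-size architecture reproduces the printed intermediate shapes", {
  net <- build_model(scbam_config(), seed = 1)
  s <- summary(net)
  expect_equal(s$output_shape[s$layer == "conv1"], "(128, 12, 6)")
  att <- s[s$layer == "filter_attention", ]
  expect_match(att$detail, "hidden_width=8")       # 128 / 16
  expect_equal(s$output_shape[s$layer == "maxpool"], "(32, 6, 3)")
  expect_equal(s$output_shape[nrow(s)], "(2)")
})

test_that("forward passes give normalized, deterministic probabilities", {
  net <- build_model(tiny_model_cfg(), seed = 2)
  x <- array(rnorm(7 * 12 * 6), c(7, 12, 6))
  p1 <- predict(net, x)
  expect_equal(rowSums(p1), rep(1, 7), tolerance = 1e-6)
  expect_true(all(p1 > 0 & p1 < 1))
  expect_identical(p1, predict(net, x))            # eval mode has no RNG
})

test_that("untrained attention blocks gate at one half", {
  M <- array(rnorm(32 * 12 * 6), c(32, 12, 6))
  fa <- filter_attention(M, r = 16)                # zero weights by default
  expect_equal(fa$M_f, rep(0.5, 32))
  expect_equal(fa$M_prime, M / 2)
  expect_error(filter_attention(M, r = 5), class = "scbam_invalid_argument")

  sa <- spatial_rhythm_attention(fa$M_prime)
  expect_equal(dim(sa$M_cr), c(12, 6))
  expect_equal(sa$M_cr, matrix(0.5, 12, 6))
  expect_equal(sa$M_dprime, fa$M_prime / 2)

  # any finite weights keep the gates strictly inside (0, 1)
  w <- list(W0 = matrix(rnorm(32 * 2), 32, 2), b0 = rnorm(2),
            W1 = matrix(rnorm(2 * 32), 2, 32), b1 = rnorm(32))
  fa2 <- filter_attention(M, r = 16, weights = w)
  expect_true(all(fa2$M_f > 0 & fa2$M_f < 1))
})

test_that("ablation variants change the parameter inventory as designed", {
  cfg <- tiny_model_cfg()
  inv <- function(variant) {
    c2 <- cfg; c2$variant <- variant
    param_inventory(build_model(c2, seed = 1))
  }
  scbam <- inv("SCBAM"); twoc <- inv("two_convs")
  expect_equal(sum(twoc$n_params[twoc$attention]), 0)
  expect_equal(sum(scbam$attention), 2)
  expect_true(all(scbam$n_params[scbam$attention] > 0))
  expect_lt(sum(twoc$n_params), sum(scbam$n_params))

  expect_false("conv2" %in% inv("fCBAM")$layer)
  expect_false("conv1" %in% inv("CBAMs")$layer)
  expect_equal(sum(inv("SA1")$attention), 1)
  expect_equal(sum(inv("SA2")$attention), 1)
  expect_true(all(c("conv0", "conv1") %in% inv("C-SCBAM")$layer))
  expect_true(all(c("conv2", "conv3") %in% inv("SCBAM-C")$layer))
})

test_that("attention order is structurally meaningful", {
  cfg <- tiny_model_cfg()
  cfg2 <- cfg; cfg2$variant <- "SA2A1"
  a <- build_model(cfg, seed = 7)
  b <- build_model(cfg2, seed = 7)
  x <- array(rnorm(4 * 12 * 6), c(4, 12, 6))
  expect_false(isTRUE(all.equal(predict(a, x), predict(b, x))))
})

test_that("analytic gradients match finite differences", {
  cfg <- scbam_config(conv1_filters = 8, reduction_ratio = 4, conv2_filters = 4,
                      dense_hidden = 8)
  net <- build_model(cfg, seed = 3)
  x <- array(rnorm(3 * 12 * 6), c(3, 12, 6))
  y <- scbam:::one_hot(c(1, 2, 1), c(1, 2))
  loss_fn <- function(nn) {
    fw <- scbam:::net_forward(nn, x)
    -mean(log(rowSums(fw$probs * y) + 1e-12))
  }
  fwd <- scbam:::net_forward(net, x)
  grads <- scbam:::net_backward(net, fwd, y)
  set.seed(11)
  for (li in seq_along(net$layers)) {
    for (nm in names(net$layers[[li]]$params)) {
      p <- net$layers[[li]]$params[[nm]]
      k <- sample(length(p), 1)
      eps <- 1e-6
      np <- net
      np$layers[[li]]$params[[nm]][k] <- p[k] + eps
      lp <- loss_fn(np)
      np$layers[[li]]$params[[nm]][k] <- p[k] - eps
      lm <- loss_fn(np)
      gnum <- (lp - lm) / (2 * eps)
      gan <- grads[[li]][[nm]][k]
      expect_lt(abs(gnum - gan) / max(1e-6, abs(gnum) + abs(gan)), 1e-3)
    }
  }
})

test_that("dropout only acts during training", {
  net <- build_model(tiny_model_cfg(dropout = 0.5), seed = 4)
  x <- array(rnorm(6 * 12 * 6), c(6, 12, 6))
  e1 <- scbam:::net_forward(net, x, training = FALSE)$probs
  e2 <- scbam:::net_forward(net, x, training = FALSE)$probs
  expect_identical(e1, e2)
  set.seed(1)
  t1 <- scbam:::net_forward(net, x, training = TRUE)$probs
  t2 <- scbam:::net_forward(net, x, training = TRUE)$probs
  expect_false(identical(t1, t2))
})
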
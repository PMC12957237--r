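# Minimal CNN engine used by the attention classifier.
#
# Batches are 4D arrays (N, C, H, W) in R's column-major order (batch index
# fastest). Convolutions are realized as im2col gathers plus BLAS matmuls;
# gather index matrices are memoized per geometry. Everything here is plain
# deterministic numerics: the only RNG use is weight init and dropout masks,
# both driven by explicitly passed seeds.

.geom_cache <- new.env(parent = emptyenv())

memo_get <- function(key, maker) {
  if (is.null(.geom_cache[[key]])) .geom_cache[[key]] <- maker()
  .geom_cache[[key]]
}

# Geometry for shift-and-add same-padding convolution. The padded activation
# lives as a matrix with rows indexed (n, hp, wp) and channels as columns; for
# every kernel offset (ki, kj) `rows[[k]]` selects the padded rows aligned with
# the output positions, and `interior` are the rows holding the unpadded input.
conv_geom <- function(N, H, W, kh, kw) {
  if (kh %% 2 == 0 || kw %% 2 == 0)
    stop_invalid("same-padding convolution requires odd kernel sizes")
  key <- paste("conv", N, H, W, kh, kw, sep = "_")
  memo_get(key, function() {
    ph <- (kh - 1L) / 2L; pw <- (kw - 1L) / 2L
    Hp <- H + 2L * ph; Wp <- W + 2L * pw
    n_v <- rep(seq_len(N), times = H * W)
    oh_v <- rep(rep(seq_len(H), each = N), times = W)
    ow_v <- rep(seq_len(W), each = N * H)
    rows <- vector("list", kh * kw)
    k <- 0L
    for (kj in seq_len(kw)) for (ki in seq_len(kh)) {
      k <- k + 1L
      rows[[k]] <- n_v + N * ((oh_v + ki - 2L) + Hp * (ow_v + kj - 2L))
    }
    interior <- n_v + N * ((oh_v + ph - 1L) + Hp * (ow_v + pw - 1L))
    list(rows = rows, interior = interior, ph = ph, pw = pw, Hp = Hp, Wp = Wp)
  })
}

broadcast_map <- function(N, F, HW) {
  # x position (n, f, b) -> spatial-map position (n, b)
  key <- paste("bmap", N, F, HW, sep = "_")
  memo_get(key, function() {
    rep(seq_len(N), times = F * HW) + N * rep(seq.int(0L, HW - 1L), each = N * F)
  })
}

glorot_uniform <- function(fan_in, fan_out, dims) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dim = dims)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- convolution ------------------------------------------------------------

conv_fwd <- function(params, x, relu) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  F_out <- ncol(params$W)
  kh <- params$kh; kw <- params$kw
  g <- conv_geom(N, H, W, kh, kw)
  xp2 <- matrix(0, N * g$Hp * g$Wp, C)             # rows (n, hp, wp), cols c
  xp2[g$interior, ] <- matrix(aperm(x, c(1, 3, 4, 2)), N * H * W, C)
  out_mat <- matrix(rep(params$b, each = N * H * W), N * H * W, F_out)
  for (k in seq_len(kh * kw)) {
    blk <- seq.int((k - 1L) * C + 1L, k * C)
    out_mat <- out_mat + xp2[g$rows[[k]], , drop = FALSE] %*%
      params$W[blk, , drop = FALSE]
  }
  out <- aperm(array(out_mat, c(N, H, W, F_out)), c(1, 4, 2, 3))
  mask <- NULL
  if (relu) { mask <- out > 0; out <- out * mask }
  list(out = out, cache = list(xp2 = xp2, g = g, dims = d, mask = mask,
                               F_out = F_out))
}

conv_bwd <- function(params, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  d <- cache$dims; N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  g <- cache$g; kh <- params$kh; kw <- params$kw
  dmat <- matrix(aperm(dout, c(1, 3, 4, 2)), ncol = cache$F_out)
  dW <- matrix(0, nrow(params$W), cache$F_out)
  dxp2 <- matrix(0, nrow(cache$xp2), C)
  for (k in seq_len(kh * kw)) {
    blk <- seq.int((k - 1L) * C + 1L, k * C)
    rk <- g$rows[[k]]
    dW[blk, ] <- crossprod(cache$xp2[rk, , drop = FALSE], dmat)
    dxp2[rk, ] <- dxp2[rk, , drop = FALSE] +
      tcrossprod(dmat, params$W[blk, , drop = FALSE])
  }
  dx <- aperm(array(dxp2[g$interior, , drop = FALSE], c(N, H, W, C)), c(1, 4, 2, 3))
  list(dx = dx, grads = list(W = dW, b = colSums(dmat)))
}

# ---- filter (channel) attention --------------------------------------------

chatt_fwd <- function(params, x) {
  d <- dim(x); N <- d[1]; F <- d[2]; HW <- d[3] * d[4]
  xm <- matrix(x, nrow = N * F)                    # (n, f) x (h, w)
  gap <- matrix(rowMeans(xm), N, F)
  amax <- max.col(xm, ties.method = "first")
  mx <- matrix(xm[cbind(seq_len(N * F), amax)], N, F)
  pre_g <- gap %*% params$W0 + rep(params$b0, each = N)
  pre_m <- mx %*% params$W0 + rep(params$b0, each = N)
  hg <- pre_g * (pre_g > 0); hm <- pre_m * (pre_m > 0)
  logit <- (hg + hm) %*% params$W1 + rep(2 * params$b1, each = N)
  s <- sigmoid(logit)                              # N x F
  out <- x * as.vector(s)                          # recycled over (h, w) blocks
  list(out = out,
       cache = list(x = x, s = s, gap = gap, mx = mx, amax = amax,
                    pre_g = pre_g, pre_m = pre_m, hg = hg, hm = hm,
                    N = N, F = F, HW = HW))
}

chatt_bwd <- function(params, cache, dout) {
  N <- cache$N; F <- cache$F; HW <- cache$HW
  s <- cache$s
  dx <- dout * as.vector(s)
  ds <- matrix(rowSums(matrix(dout * cache$x, nrow = N * F)), N, F)
  dlogit <- ds * s * (1 - s)
  dW1 <- crossprod(cache$hg + cache$hm, dlogit)
  db1 <- 2 * colSums(dlogit)
  dh <- tcrossprod(dlogit, params$W1)
  dpre_g <- dh * (cache$pre_g > 0)
  dpre_m <- dh * (cache$pre_m > 0)
  dW0 <- crossprod(cache$gap, dpre_g) + crossprod(cache$mx, dpre_m)
  db0 <- colSums(dpre_g) + colSums(dpre_m)
  dgap <- tcrossprod(dpre_g, params$W0)
  dmx <- tcrossprod(dpre_m, params$W0)
  dx <- dx + as.vector(dgap) / HW                  # GAP spreads evenly
  pos <- seq_len(N * F) + N * F * (cache$amax - 1L)
  dx[pos] <- dx[pos] + as.vector(dmx)              # MP routes to the argmax
  list(dx = dx, grads = list(W0 = dW0, b0 = db0, W1 = dW1, b1 = db1))
}

# ---- spatial/rhythm attention ----------------------------------------------

spatt_fwd <- function(params, x) {
  d <- dim(x); N <- d[1]; F <- d[2]; H <- d[3]; W <- d[4]; HW <- H * W
  m2 <- matrix(aperm(x, c(2, 1, 3, 4)), nrow = F)  # F x (n, h, w)
  avg <- colMeans(m2)
  t2 <- t(m2)
  amax <- max.col(t2, ties.method = "first")
  mxv <- t2[cbind(seq_len(N * HW), amax)]
  z <- array(0, c(N, 2, H, W))
  z[, 1, , ] <- array(avg, c(N, H, W))
  z[, 2, , ] <- array(mxv, c(N, H, W))
  cf <- conv_fwd(params, z, relu = FALSE)          # single-output 3x3 conv
  mv <- sigmoid(as.vector(cf$out))                 # (n, h, w) order
  midx <- broadcast_map(N, F, HW)
  mrep <- mv[midx]
  out <- x * mrep
  list(out = out,
       cache = list(x = x, mv = mv, midx = midx, amax = amax,
                    conv_cache = cf$cache, N = N, F = F, H = H, W = W))
}

spatt_bwd <- function(params, cache, dout) {
  N <- cache$N; F <- cache$F; H <- cache$H; W <- cache$W; HW <- H * W
  mrep <- cache$mv[cache$midx]
  dx <- dout * mrep
  dprod <- dout * cache$x
  dm_v <- colSums(matrix(aperm(dprod, c(2, 1, 3, 4)), nrow = F))   # (n, h, w)
  dlog <- dm_v * cache$mv * (1 - cache$mv)
  cb <- conv_bwd(params, cache$conv_cache, array(dlog, c(N, 1, H, W)))
  dz <- cb$dx
  davg_v <- as.vector(dz[, 1, , ])
  dmax_v <- as.vector(dz[, 2, , ])
  dx <- dx + (davg_v / F)[cache$midx]
  i <- seq_len(N * HW)
  n <- (i - 1L) %% N + 1L
  b <- (i - 1L) %/% N
  pos <- n + N * ((cache$amax - 1L) + F * b)
  dx[pos] <- dx[pos] + dmax_v
  list(dx = dx, grads = cb$grads)
}

# ---- max pooling (2x2, stride 2) -------------------------------------------

pool_fwd <- function(x) {
  d <- dim(x); N <- d[1]; C <- d[2]; H <- d[3]; W <- d[4]
  Ho <- H %/% 2L; Wo <- W %/% 2L
  ri <- seq(1L, 2L * Ho, by = 2L); ci <- seq(1L, 2L * Wo, by = 2L)
  best <- x[, , ri, ci, drop = FALSE]
  src <- array(1L, dim(best))
  k <- 1L
  for (di in 0:1) for (dj in 0:1) {
    if (di == 0 && dj == 0) next
    k <- k + 1L
    sl <- x[, , ri + di, ci + dj, drop = FALSE]
    upd <- sl > best
    best[upd] <- sl[upd]
    src[upd] <- k
  }
  list(out = best, cache = list(src = src, dims = d, Ho = Ho, Wo = Wo))
}

pool_bwd <- function(cache, dout) {
  d <- cache$dims
  dx <- array(0, d)
  ri <- seq(1L, 2L * cache$Ho, by = 2L); ci <- seq(1L, 2L * cache$Wo, by = 2L)
  k <- 0L
  for (di in 0:1) for (dj in 0:1) {
    k <- k + 1L
    mask <- cache$src == k
    tmp <- dx[, , ri + di, ci + dj, drop = FALSE]
    tmp[mask] <- tmp[mask] + dout[mask]
    dx[, , ri + di, ci + dj] <- tmp
  }
  list(dx = dx)
}

# ---- dense / dropout --------------------------------------------------------

dense_fwd <- function(params, x, relu) {
  out <- x %*% params$W + rep(params$b, each = nrow(x))
  mask <- NULL
  if (relu) { mask <- out > 0; out <- out * mask }
  list(out = out, cache = list(x = x, mask = mask))
}

dense_bwd <- function(params, cache, dout) {
  if (!is.null(cache$mask)) dout <- dout * cache$mask
  list(dx = tcrossprod(dout, params$W),
       grads = list(W = crossprod(cache$x, dout), b = colSums(dout)))
}

dropout_fwd <- function(x, p, training) {
  if (!training || p <= 0) return(list(out = x, cache = list(mask = NULL)))
  mask <- (stats::runif(length(x)) >= p) / (1 - p)
  dim(mask) <- dim(x)
  list(out = x * mask, cache = list(mask = mask))
}
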
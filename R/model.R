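#' Configuration of the sandwich attention classifier
#'
#' Describes the SCBAM architecture: a convolution (128 filters, 5x5, stride 1,
#' same padding, ReLU) ahead of two sequential attention blocks — filter
#' attention (shared two-layer MLP with reduction ratio `r` on global average-
#' and max-pooled descriptors, summed under a sigmoid gate) then a spatial/rhythm
#' attention (3x3 single-map convolution over stacked cross-filter average and
#' max planes) — followed by a second convolution (32 filters, 3x3, ReLU), 2x2
#' max pooling, a ReLU dense layer, dropout and a softmax head. `variant`
#' selects the ablation/ordering variants studied alongside the full model.
#'
#' @param variant One of `"SCBAM"`, `"SA2A1"` (attention order swapped),
#'   `"C-SCBAM"` / `"SCBAM-C"` (extra convolution before/after),
#'   `"fCBAM"` (no second conv), `"CBAMs"` (no first conv), `"SA1"` / `"SA2"`
#'   (single attention block in the sandwich), `"CBAM"` (attention only),
#'   `"two_convs"` (no attention). `"CTF"` and `"CSA"` are recognised design
#'   identifiers without an implementation.
#' @param conv1_filters,conv1_kernel First convolution size.
#' @param reduction_ratio MLP bottleneck ratio `r` of the filter attention.
#' @param spatial_kernel Kernel of the spatial-attention convolution.
#' @param conv2_filters,conv2_kernel Second convolution size.
#' @param pool Max-pool size (stride equal to size).
#' @param dropout Dropout rate before the softmax head.
#' @param dense_hidden Width of the ReLU dense layer.
#' @param n_classes Output classes (2 for the pairwise classifiers).
#' @param input_shape `(components, rhythms)` plane fed per window.
#' @return An object of class `scbam_config`.
#' @export
scbam_config <- function(variant = "SCBAM", conv1_filters = 128,
                         conv1_kernel = c(5, 5), reduction_ratio = 16,
                         spatial_kernel = c(3, 3), conv2_filters = 32,
                         conv2_kernel = c(3, 3), pool = c(2, 2),
                         dropout = 0.3, dense_hidden = 64, n_classes = 2,
                         input_shape = c(12, 6)) {
  if (any(c(conv1_kernel, conv2_kernel, spatial_kernel) < 1))
    stop_invalid("kernel dimensions must be >= 1")
  if (conv1_filters %% reduction_ratio != 0)
    stop_invalid("reduction_ratio (%d) must divide conv1_filters (%d)",
                 reduction_ratio, conv1_filters)
  structure(list(variant = variant, conv1_filters = conv1_filters,
                 conv1_kernel = conv1_kernel, reduction_ratio = reduction_ratio,
                 spatial_kernel = spatial_kernel, conv2_filters = conv2_filters,
                 conv2_kernel = conv2_kernel, pool = pool, dropout = dropout,
                 dense_hidden = dense_hidden, n_classes = n_classes,
                 input_shape = input_shape),
            class = "scbam_config")
}

variant_sequence <- function(variant) {
  switch(variant,
    "SCBAM"   = c("conv1", "chatt", "spatt", "conv2"),
    "SA2A1"   = c("conv1", "spatt", "chatt", "conv2"),
    "C-SCBAM" = c("conv0", "conv1", "chatt", "spatt", "conv2"),
    "SCBAM-C" = c("conv1", "chatt", "spatt", "conv2", "conv3"),
    "fCBAM"   = c("conv1", "chatt", "spatt"),
    "CBAMs"   = c("chatt", "spatt", "conv2"),
    "SA1"     = c("conv1", "chatt", "conv2"),
    "SA2"     = c("conv1", "spatt", "conv2"),
    "CBAM"    = c("chatt", "spatt"),
    "two_convs" = c("conv1", "conv2"),
    "CTF"     = stop_invalid("variant 'CTF' (conv + multi-head transformer) is a design identifier without an implementation"),
    "CSA"     = stop_invalid("variant 'CSA' (conv + self-attention) is a design identifier without an implementation"),
    stop_invalid("unknown model variant '%s'", variant)
  )
}

#' Build a sandwich attention network
#'
#' Instantiates the architecture described by a [scbam_config()] with
#' fan-based uniform (Glorot) weight initialization under the given seed. The
#' returned network is a pure function of its weights: forward passes in
#' evaluation mode are deterministic.
#'
#' @param config A [scbam_config()].
#' @param seed Integer seed for weight initialization.
#' @return An object of class `scbam_net`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "scbam_config"))
  tokens <- variant_sequence(config$variant)
  H <- config$input_shape[1]; W <- config$input_shape[2]
  layers <- list()
  shape <- c(1L, H, W)                              # (filters, comps, rhythms)
  with_seed(seed, {
    add <- function(l) layers[[length(layers) + 1L]] <<- l
    conv_layer <- function(name, filters, kernel) {
      kh <- kernel[1]; kw <- kernel[2]
      fan_in <- shape[1] * kh * kw; fan_out <- filters * kh * kw
      l <- list(type = "conv2d", name = name, kh = kh, kw = kw,
                params = list(W = glorot_uniform(fan_in, fan_out,
                                                 c(shape[1] * kh * kw, filters)),
                              b = numeric(filters)))
      shape <<- c(filters, shape[2], shape[3])
      l
    }
    for (tok in tokens) {
      if (tok %in% c("conv0", "conv1")) {
        add(conv_layer(tok, config$conv1_filters, config$conv1_kernel))
      } else if (tok %in% c("conv2", "conv3")) {
        add(conv_layer(tok, config$conv2_filters, config$conv2_kernel))
      } else if (tok == "chatt") {
        nf <- shape[1]
        hidden <- if (nf %% config$reduction_ratio == 0) nf %/% config$reduction_ratio
                  else max(1L, nf %/% config$reduction_ratio)
        add(list(type = "channel_attention", name = "filter_attention",
                 hidden = as.integer(hidden), r = config$reduction_ratio,
                 params = list(W0 = glorot_uniform(nf, hidden, c(nf, hidden)),
                               b0 = numeric(hidden),
                               W1 = glorot_uniform(hidden, nf, c(hidden, nf)),
                               b1 = numeric(nf))))
      } else if (tok == "spatt") {
        kh <- config$spatial_kernel[1]; kw <- config$spatial_kernel[2]
        add(list(type = "spatial_attention", name = "spatial_rhythm_attention",
                 kh = kh, kw = kw,
                 params = list(W = glorot_uniform(2 * kh * kw, kh * kw,
                                                  c(2 * kh * kw, 1L)),
                               b = numeric(1))))
      }
    }
    add(list(type = "maxpool", name = "maxpool", params = list()))
    shape <- c(shape[1], shape[2] %/% 2L, shape[3] %/% 2L)
    add(list(type = "flatten", name = "flatten", params = list()))
    flat <- prod(shape)
    add(list(type = "dense", name = "dense_hidden", relu = TRUE,
             params = list(W = glorot_uniform(flat, config$dense_hidden,
                                              c(flat, config$dense_hidden)),
                           b = numeric(config$dense_hidden))))
    add(list(type = "dropout", name = "dropout", p = config$dropout,
             params = list()))
    add(list(type = "dense", name = "dense_out", relu = FALSE,
             params = list(W = glorot_uniform(config$dense_hidden, config$n_classes,
                                              c(config$dense_hidden, config$n_classes)),
                           b = numeric(config$n_classes))))
  })
  structure(list(config = config, layers = layers, init_seed = as.integer(seed)),
            class = "scbam_net")
}

# Forward pass; x is (N, H, W) or (N, 1, H, W). Returns logits, probs, caches.
net_forward <- function(net, x, training = FALSE) {
  if (length(dim(x)) == 3L)
    x <- array(x, c(dim(x)[1], 1L, dim(x)[2], dim(x)[3]))
  caches <- vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    l <- net$layers[[i]]
    r <- switch(l$type,
      conv2d = { rr <- conv_fwd(c(l$params, kh = l$kh, kw = l$kw), x, relu = TRUE)
                 list(out = rr$out, cache = rr$cache) },
      channel_attention = chatt_fwd(l$params, x),
      spatial_attention = { pp <- l$params; pp$kh <- l$kh; pp$kw <- l$kw
                            spatt_fwd(pp, x) },
      maxpool = pool_fwd(x),
      flatten = list(out = matrix(x, nrow = dim(x)[1]),
                     cache = list(dims = dim(x))),
      dense = dense_fwd(l$params, x, relu = l$relu),
      dropout = dropout_fwd(x, l$p, training),
      stop_numerical("unknown layer type %s", l$type))
    caches[[i]] <- r$cache
    x <- r$out
  }
  logits <- x
  p <- exp(logits - apply(logits, 1, max))
  probs <- p / rowSums(p)
  list(logits = logits, probs = probs, caches = caches)
}

# Backward pass from softmax cross-entropy; y is an N x K one-hot matrix.
net_backward <- function(net, fwd, y) {
  n <- nrow(y)
  dout <- (fwd$probs - y) / n
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    l <- net$layers[[i]]
    cache <- fwd$caches[[i]]
    r <- switch(l$type,
      conv2d = { pp <- l$params; pp$kh <- l$kh; pp$kw <- l$kw
                 conv_bwd(pp, cache, dout) },
      channel_attention = chatt_bwd(l$params, cache, dout),
      spatial_attention = { pp <- l$params; pp$kh <- l$kh; pp$kw <- l$kw
                            spatt_bwd(pp, cache, dout) },
      maxpool = pool_bwd(cache, dout),
      flatten = list(dx = array(dout, cache$dims)),
      dense = dense_bwd(l$params, cache, dout),
      dropout = list(dx = if (is.null(cache$mask)) dout else dout * cache$mask))
    grads[i] <- list(r$grads)      # keep NULL placeholders for param-free layers
    dout <- r$dx
  }
  grads
}

#' Class probabilities for feature windows
#'
#' @param object A trained or freshly built `scbam_net`.
#' @param newdata A `scbam_feature_map` or an array (windows x comps x rhythms).
#' @param ... Unused.
#' @return Matrix windows x classes of softmax probabilities (rows sum to 1).
#' @export
predict.scbam_net <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "scbam_feature_map")) newdata$values else newdata
  net_forward(object, x, training = FALSE)$probs
}

#' Architecture summary table
#'
#' One row per layer with its output shape, parameter count and salient
#' details (the filter-attention row records its MLP hidden width).
#'
#' @param object A `scbam_net`.
#' @param ... Unused.
#' @return data.frame with columns `layer`, `type`, `output_shape`,
#'   `n_params`, `detail`.
#' @export
summary.scbam_net <- function(object, ...) {
  probe <- array(0, c(1, 1, object$config$input_shape[1], object$config$input_shape[2]))
  rows <- list()
  x <- probe
  for (l in object$layers) {
    r <- switch(l$type,
      conv2d = { pp <- l$params; pp$kh <- l$kh; pp$kw <- l$kw
                 conv_fwd(pp, x, relu = TRUE) },
      channel_attention = chatt_fwd(l$params, x),
      spatial_attention = { pp <- l$params; pp$kh <- l$kh; pp$kw <- l$kw
                            spatt_fwd(pp, x) },
      maxpool = pool_fwd(x),
      flatten = list(out = matrix(x, nrow = dim(x)[1])),
      dense = dense_fwd(l$params, x, relu = l$relu),
      dropout = list(out = x))
    x <- r$out
    shp <- if (is.matrix(x)) paste0("(", ncol(x), ")")
           else paste0("(", paste(dim(x)[-1], collapse = ", "), ")")
    detail <- switch(l$type,
      channel_attention = sprintf("hidden_width=%d, r=%d", l$hidden, l$r),
      conv2d = sprintf("%dx%d same", l$kh, l$kw),
      dropout = sprintf("p=%g", l$p),
      "")
    rows[[length(rows) + 1L]] <- data.frame(
      layer = l$name, type = l$type, output_shape = shp,
      n_params = sum(lengths(lapply(l$params, function(p) p))),
      detail = detail, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Parameter inventory by module group
#'
#' @param net A `scbam_net`.
#' @return data.frame with per-layer parameter counts and whether the layer is
#'   an attention block.
#' @export
param_inventory <- function(net) {
  do.call(rbind, lapply(net$layers, function(l) data.frame(
    layer = l$name, type = l$type,
    n_params = sum(vapply(l$params, length, numeric(1))),
    attention = l$type %in% c("channel_attention", "spatial_attention"),
    stringsAsFactors = FALSE)))
}

count_params <- function(net) sum(param_inventory(net)$n_params)

# ---- functional attention operations ---------------------------------------

#' Filter-domain attention on a single feature map
#'
#' Computes the 1D filter attention gate `sigmoid(MLP(GAP(M)) + MLP(MP(M)))`
#' with a shared bottleneck MLP (width `F / r`) and returns both the gate and
#' the refined map. With all-zero weights (the default untrained module) the
#' gate is 0.5 everywhere.
#'
#' @param M Array filters x comps x rhythms.
#' @param r Reduction ratio; must divide the filter count.
#' @param weights Optional list `W0` (F x F/r), `b0`, `W1` (F/r x F), `b1`;
#'   zeros when omitted.
#' @return List with `M_f` (per-filter gate in (0,1)) and `M_prime`.
#' @export
filter_attention <- function(M, r = 16, weights = NULL) {
  nf <- dim(M)[1]
  if (nf %% r != 0) stop_invalid("reduction ratio %d does not divide filter count %d", r, nf)
  hidden <- nf %/% r
  w <- weights %||% list(W0 = matrix(0, nf, hidden), b0 = numeric(hidden),
                         W1 = matrix(0, hidden, nf), b1 = numeric(nf))
  x <- array(M, c(1, dim(M)))
  x <- aperm(x, c(1, 2, 3, 4))
  r_ <- chatt_fwd(w, x)
  list(M_f = as.vector(r_$cache$s), M_prime = array(r_$out, dim(M)))
}

#' Spatial/rhythm attention on a single feature map
#'
#' Pools the map across the filter axis (average and max), stacks the two
#' descriptor planes, applies one zero-padded 3x3 convolution producing a
#' single map, and gates the input with its sigmoid.
#'
#' @param M_prime Array filters x comps x rhythms.
#' @param weights Optional list `W` (18 x 1) and `b`; zeros when omitted.
#' @return List with `M_cr` (comps x rhythms gate in (0,1)) and `M_dprime`.
#' @export
spatial_rhythm_attention <- function(M_prime, weights = NULL) {
  d <- dim(M_prime)
  w <- weights %||% list(W = matrix(0, 18, 1), b = numeric(1))
  w$kh <- 3L; w$kw <- 3L
  r_ <- spatt_fwd(w, array(M_prime, c(1, d)))
  list(M_cr = matrix(r_$cache$mv, d[2], d[3]),
       M_dprime = array(r_$out, d))
}
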
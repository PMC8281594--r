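# Declarative 1D-CNN construction with exact shape and parameter
# accounting, plus the forward/backward passes used by the trainer.
#
# All convolutions are kernel 3, stride 1, no padding ("valid", so each
# conv shortens the signal by 2); all poolings are max, size 2, stride 2.
# Hidden activations are ReLU; the head is a logistic sigmoid (binary,
# one unit, AF the positive class) or softmax (three classes). The
# canonical architecture is 13 convolutions in 5 blocks
# (64-64 | 128-128 | 256x3 | 512x3 | 512x3), each block closed by a max
# pool, then dense 1000 - dense 1000 - output, on a 2700-sample input.
# Biases are carried by every trainable layer.

conv_spec <- function(filters) list(kind = "conv", filters = as.integer(filters),
                                    kernel = 3L, stride = 1L,
                                    activation = "relu")
pool_spec <- function() list(kind = "maxpool", size = 2L, stride = 2L)
dense_spec <- function(units) list(kind = "dense", units = as.integer(units),
                                   activation = "relu")

.canonical_filters <- c(64L, 64L, NA, 128L, 128L, NA, 256L, 256L, 256L, NA,
                        512L, 512L, 512L, NA, 512L, 512L, 512L, NA)

build_feature_layers <- function(filters) {
  lapply(filters, function(f) if (is.na(f)) pool_spec() else conv_spec(f))
}

#' Canonical 13-convolution model configuration
#'
#' The fixed architecture: five convolution blocks
#' (64-64, 128-128, 256-256-256, 512-512-512, 512-512-512), each followed
#' by a max pool, then two dense-1000 layers and the class head. Input is
#' one channel of 2700 samples.
#'
#' @param n_classes 2 (N vs AF, sigmoid head with one unit) or 3
#'   (N/AF/NON_AF, softmax head).
#' @return an object of class `rhythm_cnn_config`.
#' @seealso [small_model_config()] for a scaled-down variant,
#'   [rhythm_cnn()] to build the network.
#' @export
model_config <- function(n_classes = 2L) {
  if (!n_classes %in% c(2L, 3L)) abort("n_classes must be 2 or 3")
  structure(list(layers = c(build_feature_layers(.canonical_filters),
                            list(list(kind = "flatten"),
                                 dense_spec(1000L), dense_spec(1000L),
                                 list(kind = "output",
                                      units = if (n_classes == 2L) 1L else 3L,
                                      activation = if (n_classes == 2L)
                                        "sigmoid" else "softmax"))),
                 n_classes = as.integer(n_classes), input_length = 2700L,
                 input_channels = 1L, canonical = TRUE),
            class = "rhythm_cnn_config")
}

#' Scaled-down model configuration
#'
#' Same layer conventions as [model_config()] (conv kernel 3 stride 1,
#' pool 2/2, ReLU, sigmoid/softmax head) with a reduced stack for fast
#' experiments: by default two convolution blocks (8-8, 16-16), three
#' additional pooling stages that coarsen the feature map before the
#' head (limiting how much sample-position detail the dense layer can
#' memorize on small training sets), and a dense-2000 layer.
#'
#' @param n_classes 2 or 3.
#' @param input_length episode length in samples; default 2700.
#' @param filters integer vector of conv filter counts with `NA` marking
#'   a max pool.
#' @param dense integer vector of dense layer widths.
#' @return an object of class `rhythm_cnn_config`.
#' @export
small_model_config <- function(n_classes = 2L, input_length = 2700L,
                               filters = c(8L, 8L, NA, 16L, 16L, NA,
                                           NA, NA, NA),
                               dense = 2000L) {
  if (!n_classes %in% c(2L, 3L)) abort("n_classes must be 2 or 3")
  stopifnot(is_count(input_length, min = 4L))
  structure(list(layers = c(build_feature_layers(as.integer(filters)),
                            list(list(kind = "flatten")),
                            lapply(dense, dense_spec),
                            list(list(kind = "output",
                                      units = if (n_classes == 2L) 1L else 3L,
                                      activation = if (n_classes == 2L)
                                        "sigmoid" else "softmax"))),
                 n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 input_channels = 1L, canonical = FALSE),
            class = "rhythm_cnn_config")
}

validate_config <- function(config) {
  stopifnot(inherits(config, "rhythm_cnn_config"))
  n_conv <- 0L
  n_pool <- 0L
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    if (ly$kind == "conv") {
      n_conv <- n_conv + 1L
      if (ly$kernel != 3L || ly$stride != 1L)
        abort("layer %d: conv layers must use kernel 3, stride 1", i)
      if (!identical(ly$activation, "relu"))
        abort("layer %d: hidden activation must be relu", i)
    } else if (ly$kind == "maxpool") {
      n_pool <- n_pool + 1L
      if (ly$size != 2L || ly$stride != 2L)
        abort("layer %d: pool layers must use size 2, stride 2", i)
    }
  }
  if (isTRUE(config$canonical)) {
    if (n_conv != 13L || n_pool != 5L)
      abort("canonical architecture requires 13 conv and 5 pool layers, got %d/%d",
            n_conv, n_pool)
    if (config$input_length != 2700L)
      abort("canonical architecture requires input_length 2700")
  }
  out <- config$layers[[length(config$layers)]]
  ok_head <- (config$n_classes == 2L && out$units == 1L &&
                out$activation == "sigmoid") ||
             (config$n_classes == 3L && out$units == 3L &&
                out$activation == "softmax")
  if (!ok_head)
    abort("output head must be sigmoid/1 unit (2-class) or softmax/3 units (3-class)")
  invisible(config)
}

#' Per-layer shape and parameter trace
#'
#' Walks the configuration and reports, for every layer, the output
#' length, output channels (dense widths count as channels of length 1),
#' and trainable parameter count (biases included everywhere).
#'
#' @param config a `rhythm_cnn_config` (or a built [rhythm_cnn()]).
#' @return data.frame with columns `name`, `output_length`,
#'   `output_channels`, `parameters`.
#' @export
shape_trace <- function(config) {
  if (inherits(config, "rhythm_cnn")) config <- config$config
  validate_config(config)
  len <- config$input_length
  ch <- config$input_channels
  rows <- list()
  counts <- c(conv = 0L, maxpool = 0L, dense = 0L)
  for (ly in config$layers) {
    if (ly$kind == "conv") {
      counts["conv"] <- counts["conv"] + 1L
      params <- (ly$kernel * ch + 1L) * ly$filters
      len <- len - (ly$kernel - 1L)
      ch <- ly$filters
      name <- sprintf("conv%d", counts["conv"])
    } else if (ly$kind == "maxpool") {
      counts["maxpool"] <- counts["maxpool"] + 1L
      len <- len %/% ly$stride
      params <- 0L
      name <- sprintf("maxpool%d", counts["maxpool"])
    } else if (ly$kind == "flatten") {
      len <- len * ch
      ch <- 1L
      params <- 0L
      name <- "flatten"
    } else if (ly$kind == "dense") {
      counts["dense"] <- counts["dense"] + 1L
      params <- (len + 1L) * ly$units
      len <- ly$units
      name <- sprintf("dense%d", counts["dense"])
    } else if (ly$kind == "output") {
      params <- (len + 1L) * ly$units
      len <- ly$units
      name <- "output"
    } else abort("unknown layer kind '%s'", ly$kind)
    rows[[length(rows) + 1L]] <- data.frame(
      name = name, output_length = len, output_channels = ch,
      parameters = params, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Total trainable parameter count
#'
#' @param x a `rhythm_cnn_config` or built [rhythm_cnn()].
#' @return integer-valued numeric: sum of the [shape_trace()] parameter
#'   column (biases included in every layer).
#' @export
count_parameters <- function(x) sum(shape_trace(x)$parameters)

# fan-in-scaled (He-style) uniform initial weights, U(-sqrt(6/fan_in), +);
# conv kernels stored as (kernel*in_ch) x out
init_weights <- function(config, seed) {
  trace <- shape_trace(config)
  len <- config$input_length
  ch <- config$input_channels
  weights <- list()
  with_seed(seed, {
    i <- 0L
    for (ly in config$layers) {
      i <- i + 1L
      if (ly$kind == "conv") {
        fan_in <- ly$kernel * ch
        lim <- sqrt(6 / fan_in)
        weights[[i]] <- list(W = matrix(stats::runif(fan_in * ly$filters,
                                                     -lim, lim),
                                        fan_in, ly$filters),
                             b = numeric(ly$filters))
        len <- len - 2L
        ch <- ly$filters
      } else if (ly$kind == "maxpool") {
        len <- len %/% 2L
        weights[[i]] <- list()
      } else if (ly$kind == "flatten") {
        len <- len * ch
        ch <- 1L
        weights[[i]] <- list()
      } else {
        units <- ly$units
        lim <- sqrt(6 / len)
        weights[[i]] <- list(W = matrix(stats::runif(len * units, -lim, lim),
                                        len, units),
                             b = numeric(units))
        len <- units
      }
    }
  })
  weights
}

#' Build the network
#'
#' Constructs a weight-initialized network handle from a declarative
#' configuration. The handle can emit its [shape_trace()] without running
#' any data; initialization is fan-in-scaled uniform (He-style, suited to
#' ReLU stacks), fully determined by `seed`.
#'
#' @param config a `rhythm_cnn_config` from [model_config()] or
#'   [small_model_config()].
#' @param seed integer seed for weight initialization.
#' @param init initialize weights now? `FALSE` gives a shape-only handle
#'   (weights created lazily by the trainer).
#' @return an object of class `rhythm_cnn`.
#' @export
rhythm_cnn <- function(config = model_config(), seed = 1L, init = TRUE) {
  validate_config(config)
  structure(list(config = config, seed = as.integer(seed),
                 weights = if (init) init_weights(config, seed) else NULL,
                 trace = shape_trace(config)),
            class = "rhythm_cnn")
}

#' @export
print.rhythm_cnn <- function(x, ...) {
  cat(sprintf("<rhythm_cnn> %d-class, input %d x %d, %s parameters\n",
              x$config$n_classes, x$config$input_length,
              x$config$input_channels,
              format(count_parameters(x), big.mark = ",")))
  cat(sprintf("  %d conv / %d pool / %d dense layers%s\n",
              sum(x$trace$parameters > 0 & grepl("^conv", x$trace$name)),
              sum(grepl("^maxpool", x$trace$name)),
              sum(grepl("^dense", x$trace$name)),
              if (is.null(x$weights)) " (weights not initialized)" else ""))
  invisible(x)
}

#' @export
summary.rhythm_cnn <- function(object, ...) {
  tr <- object$trace
  cat(sprintf("%-10s %14s %9s %12s\n", "layer", "output_length",
              "channels", "parameters"))
  for (i in seq_len(nrow(tr)))
    cat(sprintf("%-10s %14d %9d %12s\n", tr$name[i], tr$output_length[i],
                tr$output_channels[i],
                format(tr$parameters[i], big.mark = ",")))
  cat(sprintf("Total parameters: %s\n",
              format(sum(tr$parameters), big.mark = ",")))
  invisible(tr)
}

# ---- forward / backward ----------------------------------------------------

# Batches are arrays of dim (length, channels, batch); the flattened
# feature vector for one sample is column-major over (length, channels).

im2col <- function(A, kernel) {
  d <- dim(A)
  L_out <- d[1L] - kernel + 1L
  M <- matrix(0, L_out * d[3L], kernel * d[2L])
  for (t in seq_len(kernel)) {
    blk <- A[t:(t + L_out - 1L), , , drop = FALSE]
    M[, ((t - 1L) * d[2L] + 1L):(t * d[2L])] <-
      matrix(aperm(blk, c(1L, 3L, 2L)), L_out * d[3L], d[2L])
  }
  M
}

conv_forward <- function(A, W, b, kernel = 3L) {
  d <- dim(A)
  L_out <- d[1L] - kernel + 1L
  M <- im2col(A, kernel)
  Y <- sweep(M %*% W, 2L, b, `+`)
  out <- aperm(array(Y, c(L_out, d[3L], ncol(W))), c(1L, 3L, 2L))
  list(out = out, M = M)
}

conv_backward <- function(dOut, cache_M, W, in_dim, kernel = 3L) {
  d_out <- dim(dOut)                 # (L_out, C_out, B)
  L_out <- d_out[1L]
  dY <- matrix(aperm(dOut, c(1L, 3L, 2L)), L_out * d_out[3L], d_out[2L])
  dW <- crossprod(cache_M, dY)
  db <- colSums(dY)
  dM <- tcrossprod(dY, W)
  dA <- array(0, in_dim)
  C_in <- in_dim[2L]
  for (t in seq_len(kernel)) {
    blk <- array(dM[, ((t - 1L) * C_in + 1L):(t * C_in)],
                 c(L_out, d_out[3L], C_in))
    dA[t:(t + L_out - 1L), , ] <- dA[t:(t + L_out - 1L), , , drop = FALSE] +
      aperm(blk, c(1L, 3L, 2L))
  }
  list(dA = dA, dW = dW, db = db)
}

pool_forward <- function(A) {
  d <- dim(A)
  Lp <- d[1L] %/% 2L
  a1 <- A[seq.int(1L, 2L * Lp, 2L), , , drop = FALSE]
  a2 <- A[seq.int(2L, 2L * Lp, 2L), , , drop = FALSE]
  mask <- a1 >= a2
  list(out = pmax(a1, a2), mask = mask, in_dim = d)
}

pool_backward <- function(dOut, cache) {
  dA <- array(0, cache$in_dim)
  Lp <- dim(dOut)[1L]
  dA[seq.int(1L, 2L * Lp, 2L), , ] <- dOut * cache$mask
  dA[seq.int(2L, 2L * Lp, 2L), , ] <- dOut * !cache$mask
  dA
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1L, max)
  E <- exp(Z)
  E / rowSums(E)
}

# forward through all layers; X is a (batch x input_length) matrix.
# Returns the head output (batch x units) and, if keep_cache, per-layer
# caches for backprop.
cnn_forward <- function(net, X, keep_cache = FALSE) {
  config <- net$config
  B <- nrow(X)
  A <- array(t(X), c(config$input_length, config$input_channels, B))
  caches <- vector("list", length(config$layers))
  cur <- A
  flat <- NULL
  for (i in seq_along(config$layers)) {
    ly <- config$layers[[i]]
    if (ly$kind == "conv") {
      cf <- conv_forward(cur, net$weights[[i]]$W, net$weights[[i]]$b)
      pre <- cf$out
      mask <- pre > 0
      cur <- pre * mask
      if (keep_cache) caches[[i]] <- list(M = cf$M, mask = mask,
                                          in_dim = c(dim(cf$out)[1L] + 2L,
                                                     dim(cf$M)[2L] %/% 3L, B))
    } else if (ly$kind == "maxpool") {
      pf <- pool_forward(cur)
      cur <- pf$out
      if (keep_cache) caches[[i]] <- pf
    } else if (ly$kind == "flatten") {
      d <- dim(cur)
      flat <- t(matrix(cur, d[1L] * d[2L], d[3L]))   # B x features
      if (keep_cache) caches[[i]] <- list(in_dim = d)
      cur <- NULL
    } else if (ly$kind == "dense") {
      pre <- sweep(flat %*% net$weights[[i]]$W, 2L, net$weights[[i]]$b, `+`)
      mask <- pre > 0
      if (keep_cache) caches[[i]] <- list(X = flat, mask = mask)
      flat <- pre * mask
    } else {                                          # output
      Z <- sweep(flat %*% net$weights[[i]]$W, 2L, net$weights[[i]]$b, `+`)
      if (keep_cache) caches[[i]] <- list(X = flat)
      flat <- if (ly$activation == "sigmoid") 1 / (1 + exp(-Z))
              else softmax_rows(Z)
    }
  }
  list(probs = flat, caches = caches)
}

# backward pass; dZ is the gradient at the head pre-activation
# (batch x units). Returns gradients in the same nested layout as weights.
cnn_backward <- function(net, caches, dZ) {
  config <- net$config
  grads <- vector("list", length(config$layers))
  dflat <- NULL
  dcur <- NULL
  for (i in rev(seq_along(config$layers))) {
    ly <- config$layers[[i]]
    if (ly$kind %in% c("dense", "output")) {
      cache <- caches[[i]]
      if (ly$kind == "dense") dZ_i <- dflat * cache$mask else dZ_i <- dZ
      grads[[i]] <- list(dW = crossprod(cache$X, dZ_i), db = colSums(dZ_i))
      dflat <- tcrossprod(dZ_i, net$weights[[i]]$W)
    } else if (ly$kind == "flatten") {
      d <- caches[[i]]$in_dim
      dcur <- array(t(dflat), d)
    } else if (ly$kind == "maxpool") {
      dcur <- pool_backward(dcur, caches[[i]])
    } else {                                          # conv
      cache <- caches[[i]]
      dPre <- dcur * cache$mask
      cb <- conv_backward(dPre, cache$M, net$weights[[i]]$W, cache$in_dim)
      grads[[i]] <- list(dW = cb$dW, db = cb$db)
      dcur <- cb$dA
    }
  }
  grads
}

#' Predict class probabilities and labels for episodes
#'
#' @param object a built [rhythm_cnn()].
#' @param episodes a numeric matrix (episodes x input_length), a list of
#'   [ecg_episode()]s, or an episode store data.frame.
#' @param batch_size forward-pass batch size.
#' @param ... unused.
#' @return data.frame, one row per episode in input order: one
#'   probability column per class (summing to 1) and a `label` column.
#'   Binary classification thresholds P(AF) at 0.5, with a tie broken
#'   toward AF; three-class takes the arg-max.
#' @export
predict.rhythm_cnn <- function(object, episodes, batch_size = 64L, ...) {
  if (is.null(object$weights))
    object$weights <- init_weights(object$config, object$seed)
  L <- object$config$input_length
  if (is.list(episodes) && !is.data.frame(episodes)) {
    lens <- vapply(episodes, function(e) length(e$values), integer(1L))
    bad <- which(lens != L)
    if (length(bad))
      abort("episode %d has length %d; the model expects %d",
            bad[1L], lens[bad[1L]], L)
    X <- do.call(rbind, lapply(episodes, function(e) e$values))
  } else {
    X <- if (is.data.frame(episodes)) episode_matrix(episodes) else episodes
    if (!is.numeric(X)) abort("episodes must be numeric")
    if (ncol(X) != L)
      abort("episode length %d does not match model input length %d",
            ncol(X), L)
  }
  n <- nrow(X)
  probs <- NULL
  for (s in seq.int(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    p <- cnn_forward(object, X[idx, , drop = FALSE])$probs
    probs <- rbind(probs, p)
  }
  if (object$config$n_classes == 2L) {
    p_af <- as.numeric(probs[, 1L])
    out <- data.frame(p_N = 1 - p_af, p_AF = p_af,
                      label = ifelse(p_af >= 0.5, "AF", "N"),
                      stringsAsFactors = FALSE)
  } else {
    colnames(probs) <- rhythm_classes()
    out <- data.frame(p_N = probs[, "N"], p_AF = probs[, "AF"],
                      p_NON_AF = probs[, "NON_AF"],
                      label = rhythm_classes()[max.col(probs,
                                                       ties.method = "first")],
                      stringsAsFactors = FALSE)
  }
  out
}
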
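#' Configuration of the dual-stream network
#'
#' Two parallel convolutional streams process the same input: stream 1 with
#' 3x3 kernels throughout, stream 2 with 5x5. Each stream has three blocks of
#' two convolutions, batch normalization, dropout, and a 2x2 max-pool, so the
#' spatial size shrinks by 2^3 = 8. The flattened stream features
#' \eqn{F_{S1}} and \eqn{F_{S2}} are concatenated into \eqn{F_{total}}, and a
#' single dense layer maps \eqn{F_{total}} to one embedding vector
#' \eqn{\nu_\kappa} per class; the prediction score of class \eqn{\kappa} is
#' the norm of the squashed \eqn{\nu_\kappa} (bounded in `[0, 1)` so a 0.5
#' threshold is meaningful for multi-label tasks).
#'
#' @param input_size Input side in pixels; must be divisible by 8.
#' @param filters Conv filter counts per block (length 3), same in both streams.
#' @param kernel_s1,kernel_s2 Kernel sides of streams 1 and 2 (odd, distinct).
#' @param dropout_rate Dropout fraction per block.
#' @param embedding_len Length of each per-class embedding vector.
#' @param n_classes Number of classes of the current task head.
#' @param task `"single"` (one label per image; prediction = argmax score) or
#'   `"multi"` (prediction = score > 0.5 per class).
#' @return A `model_config` list (blocks_per_stream = 3, convs_per_block = 2
#'   are fixed).
#' @export
model_config <- function(input_size = 128, filters = c(16, 32, 64),
                         kernel_s1 = 3, kernel_s2 = 5,
                         dropout_rate = 0.25, embedding_len = 8,
                         n_classes = 2, task = c("single", "multi")) {
  task <- match.arg(task)
  if (input_size %% 8 != 0) {
    abort("model_config: input_size must be divisible by 2^3 = 8 (three max-pools)")
  }
  if (length(filters) != 3 || any(filters < 1)) {
    abort("model_config: filters must give 3 positive widths (one per block)")
  }
  if (kernel_s1 == kernel_s2) abort("model_config: the two streams must use different kernel sizes")
  if (kernel_s1 %% 2 == 0 || kernel_s2 %% 2 == 0) abort("model_config: kernels must be odd")
  structure(
    list(
      input_size = input_size, filters = as.integer(filters),
      blocks_per_stream = 3L, convs_per_block = 2L,
      kernel_s1 = kernel_s1, kernel_s2 = kernel_s2, pool = 2L,
      dropout_rate = dropout_rate, embedding_len = as.integer(embedding_len),
      n_classes = as.integer(n_classes), task = task
    ),
    class = "model_config"
  )
}

stream_feature_len <- function(cfg) {
  (cfg$input_size / 8)^2 * cfg$filters[3]
}

init_stream <- function(cfg, kernel) {
  cin <- 1L
  blocks <- list()
  for (b in 1:3) {
    cout <- cfg$filters[b]
    blocks[[paste0("b", b)]] <- list(
      conv1 = list(w = he_init(kernel, kernel, cin, cout), b = numeric(cout)),
      conv2 = list(w = he_init(kernel, kernel, cout, cout), b = numeric(cout)),
      bn = list(gamma = rep(1, cout), beta = numeric(cout))
    )
    cin <- cout
  }
  blocks
}

init_head <- function(cfg) {
  fan_in <- 2 * stream_feature_len(cfg)
  n_out <- cfg$n_classes * cfg$embedding_len
  # the 0.25 factor keeps initial raw embedding norms well below 1, in the
  # sensitive region of the squash map, so score gradients do not vanish at
  # the start of training
  list(
    w = matrix(rnorm(fan_in * n_out) * 0.25 / sqrt(fan_in), fan_in, n_out),
    b = numeric(n_out)
  )
}

init_bn_state <- function(cfg) {
  lapply(setNames(1:3, paste0("b", 1:3)), function(b) {
    list(mean = numeric(cfg$filters[b]), var = rep(1, cfg$filters[b]))
  })
}

#' Build a dual-stream model
#'
#' Initializes all weights (He initialization for convolutions) from the
#' current RNG stream, or from `seed` if given.
#'
#' @param cfg A [model_config()].
#' @param seed Optional seed for weight initialization.
#' @return A `dual_stream_model`.
#' @export
build_model <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  make <- function() {
    list(
      s1 = init_stream(cfg, cfg$kernel_s1),
      s2 = init_stream(cfg, cfg$kernel_s2),
      head = init_head(cfg)
    )
  }
  params <- if (is.null(seed)) make() else with_local_seed(seed, make())
  model <- structure(
    list(
      cfg = cfg,
      params = params,
      bn_state = list(s1 = init_bn_state(cfg), s2 = init_bn_state(cfg))
    ),
    class = "dual_stream_model"
  )
  model
}

#' Number of trainable parameters of a model
#' @param model A `dual_stream_model`.
#' @return Integer count.
#' @export
n_params <- function(model) {
  total <- 0
  walk_tree <- function(x) {
    if (is.list(x)) {
      lapply(x, walk_tree)
    } else {
      total <<- total + length(x)
    }
    invisible(NULL)
  }
  walk_tree(model$params)
  total
}

#' Structural descriptor of a built network
#'
#' One row per layer, reporting kind, kernel size, output channels, and output
#' spatial size, for both streams and the head.
#'
#' @param model A `dual_stream_model`.
#' @return Tibble with columns `stream`, `block`, `layer`, `kind`, `kernel`,
#'   `channels_out`, `spatial_out`.
#' @export
model_descriptor <- function(model) {
  cfg <- model$cfg
  rows <- list()
  for (sname in c("s1", "s2")) {
    kernel <- if (sname == "s1") cfg$kernel_s1 else cfg$kernel_s2
    size <- cfg$input_size
    for (b in 1:3) {
      cout <- cfg$filters[b]
      rows[[length(rows) + 1]] <- tibble(
        stream = sname, block = b,
        layer = c("conv1", "conv2", "batch_norm", "dropout", "max_pool"),
        kind = c("conv", "conv", "batch_norm", "dropout", "max_pool"),
        kernel = c(kernel, kernel, NA, NA, cfg$pool),
        channels_out = cout,
        spatial_out = c(size, size, size, size, size / 2)
      )
      size <- size / 2
    }
  }
  rows[[length(rows) + 1]] <- tibble(
    stream = "head", block = NA_integer_, layer = "dense", kind = "dense",
    kernel = NA_real_, channels_out = cfg$n_classes * cfg$embedding_len,
    spatial_out = NA_real_
  )
  dplyr::bind_rows(rows)
}

stream_forward <- function(blocks, bn_states, x, dropout_rate, training) {
  caches <- list()
  for (b in 1:3) {
    bl <- blocks[[b]]
    z1 <- conv_fwd(x, bl$conv1$w, bl$conv1$b)
    r1 <- relu_fwd(z1)
    z2 <- conv_fwd(r1$y, bl$conv2$w, bl$conv2$b)
    bn <- bn_fwd(z2, bl$bn$gamma, bl$bn$beta, bn_states[[b]], training)
    bn_states[[b]] <- bn$state
    r2 <- relu_fwd(bn$y)
    dr <- dropout_fwd(r2$y, dropout_rate, training)
    pl <- pool_fwd(dr$y)
    caches[[b]] <- list(
      x_in = x, m1 = r1$mask, a1 = r1$y,
      bn = list(xhat = bn$xhat, invstd = bn$invstd),
      m2 = r2$mask, act = r2$y, drop_mask = dr$mask, pool = pl
    )
    x <- pl$y
  }
  list(out = x, caches = caches, bn_states = bn_states)
}

stream_backward <- function(blocks, caches, dy) {
  grads <- list()
  for (b in 3:1) {
    cc <- caches[[b]]
    bl <- blocks[[b]]
    d <- pool_bwd(dy, cc$pool)
    d <- dropout_bwd(d, cc$drop_mask)
    d_act <- d # gradient at the post-ReLU activation of the block's last conv
    d <- relu_bwd(d, cc$m2)
    bnb <- bn_bwd(d, cc$bn, bl$bn$gamma)
    cb2 <- conv_bwd(cc$a1, bl$conv2$w, bnb$dx)
    d <- relu_bwd(cb2$dx, cc$m1)
    cb1 <- conv_bwd(cc$x_in, bl$conv1$w, d)
    grads[[paste0("b", b)]] <- list(
      conv1 = list(w = cb1$dw, b = cb1$db),
      conv2 = list(w = cb2$dw, b = cb2$db),
      bn = list(gamma = bnb$dgamma, beta = bnb$dbeta)
    )
    if (b == 3) grads$d_last_act <- d_act
    dy <- cb1$dx
  }
  grads[paste0("b", 1:3)] <- grads[paste0("b", 1:3)]
  grads
}

#' Forward pass of the dual-stream model
#'
#' @param model A `dual_stream_model`.
#' @param x Input array `[H, W, 1, N]` (or a single `H x W` matrix), gray
#'   levels normalized to `[0, 1]`.
#' @param training Logical; enables dropout and batch statistics. Inference
#'   (`FALSE`, the default) is deterministic.
#' @param keep_cache Keep intermediate activations for a backward pass.
#' @return List with `scores` (N x n_classes matrix of per-class embedding
#'   norms, all in `[0, 1)`), `vectors` (embedding_len x n_classes x N array
#'   of squashed class vectors), `f_s1`, `f_s2`, `f_total` (N x feature
#'   matrices), and `cache` when requested.
#' @export
model_forward <- function(model, x, training = FALSE, keep_cache = FALSE) {
  cfg <- model$cfg
  if (is.matrix(x)) x <- array(x, c(dim(x), 1, 1))
  d <- dim(x)
  if (length(d) != 4 || d[1] != cfg$input_size || d[2] != cfg$input_size || d[3] != 1) {
    abort(sprintf(
      "input shape mismatch: expected [%d, %d, 1, N], got [%s]",
      cfg$input_size, cfg$input_size, paste(d, collapse = ", ")
    ))
  }
  N <- d[4]
  s1 <- stream_forward(model$params$s1, model$bn_state$s1, x, cfg$dropout_rate, training)
  s2 <- stream_forward(model$params$s2, model$bn_state$s2, x, cfg$dropout_rate, training)
  flen <- stream_feature_len(cfg)
  f_s1 <- t(matrix(s1$out, flen, N))
  f_s2 <- t(matrix(s2$out, flen, N))
  f_total <- cbind(f_s1, f_s2)
  z <- f_total %*% model$params$head$w +
    matrix(model$params$head$b, N, length(model$params$head$b), byrow = TRUE)
  v_raw <- array(t(z), c(cfg$embedding_len, cfg$n_classes, N))
  u <- sqrt(apply(v_raw^2, c(2, 3), sum)) # n_classes x N raw norms
  s <- squash_norm(u)
  scale <- array(rep(squash_norm(u) / pmax(u, 1e-12), each = cfg$embedding_len),
    dim = dim(v_raw)
  )
  vectors <- v_raw * scale
  res <- list(
    scores = t(s), vectors = vectors,
    f_s1 = f_s1, f_s2 = f_s2, f_total = f_total
  )
  if (keep_cache) {
    res$cache <- list(
      x = x, s1 = s1, s2 = s2, f_total = f_total,
      v_raw = v_raw, u = u, N = N
    )
  }
  if (training) {
    res$bn_state <- list(s1 = s1$bn_states, s2 = s2$bn_states)
  }
  res
}

#' Backward pass from score gradients to parameter gradients
#'
#' @param model A `dual_stream_model`.
#' @param cache Cache from [model_forward()] with `keep_cache = TRUE`.
#' @param dscores N x n_classes matrix of loss gradients with respect to the
#'   class scores.
#' @return List with `grads` (same shape as `model$params`) and
#'   `d_last_act` (per-stream gradients at the final conv activations, used by
#'   Grad-CAM).
#' @export
model_backward <- function(model, cache, dscores) {
  cfg <- model$cfg
  N <- cache$N
  u <- cache$u # n_classes x N
  ds <- t(dscores) # n_classes x N
  # chain through the squash norm: dL/dv_raw = dL/ds * s'(u) * v_raw / u
  coef <- ds * squash_norm_grad(u) / pmax(u, 1e-12)
  dv <- cache$v_raw * array(rep(coef, each = cfg$embedding_len), dim = dim(cache$v_raw))
  dz <- t(matrix(dv, cfg$embedding_len * cfg$n_classes, N))
  dW <- crossprod(cache$f_total, dz)
  db <- colSums(dz)
  dF <- dz %*% t(model$params$head$w)
  flen <- stream_feature_len(cfg)
  side <- cfg$input_size / 8
  df1 <- array(t(dF[, seq_len(flen), drop = FALSE]), c(side, side, cfg$filters[3], N))
  df2 <- array(t(dF[, flen + seq_len(flen), drop = FALSE]), c(side, side, cfg$filters[3], N))
  g1 <- stream_backward(model$params$s1, cache$s1$caches, df1)
  g2 <- stream_backward(model$params$s2, cache$s2$caches, df2)
  list(
    grads = list(
      s1 = g1[paste0("b", 1:3)],
      s2 = g2[paste0("b", 1:3)],
      head = list(w = dW, b = db)
    ),
    d_last_act = list(s1 = g1$d_last_act, s2 = g2$d_last_act),
    last_act = list(s1 = cache$s1$caches[[3]]$act, s2 = cache$s2$caches[[3]]$act)
  )
}

#' Replace the classification head for a new task
#'
#' Both stream backbones are preserved bit-exactly (including batch-norm
#' statistics); the dense head is reinitialized from the current RNG stream
#' (or `seed`) for the new class count and task kind.
#'
#' @param model A trained `dual_stream_model`.
#' @param n_classes Class count of the new task.
#' @param task `"single"` or `"multi"`.
#' @param seed Optional seed for head initialization.
#' @return The model with a fresh head.
#' @export
swap_head <- function(model, n_classes, task = c("single", "multi"), seed = NULL) {
  task <- match.arg(task)
  cfg <- model$cfg
  cfg$n_classes <- as.integer(n_classes)
  cfg$task <- task
  model$cfg <- cfg
  model$params$head <- if (is.null(seed)) {
    init_head(cfg)
  } else {
    with_local_seed(seed, init_head(cfg))
  }
  model
}

#' Predict class scores and labels for image records
#'
#' @param object A `dual_stream_model`.
#' @param records Record tibble with a `pixels` column, or a 4-D input array.
#' @param class_names Optional class names for the score columns.
#' @param batch_size Images per forward batch.
#' @param ... Unused.
#' @return Tibble with one row per image: `image_id`, score columns (one per
#'   class) and `predicted` (character label for single-label tasks, list of
#'   labels for multi-label).
#' @export
predict.dual_stream_model <- function(object, records, class_names = NULL,
                                      batch_size = 64, ...) {
  x <- records_to_input(records, object$cfg$input_size)
  ids <- if (is.data.frame(records)) records$image_id else sprintf("input_%d", seq_len(dim(x)[4]))
  N <- dim(x)[4]
  scores <- matrix(NA_real_, N, object$cfg$n_classes)
  for (start in seq(1, N, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, N)
    scores[sel, ] <- model_forward(object, x[, , , sel, drop = FALSE])$scores
  }
  if (is.null(class_names)) class_names <- paste0("class_", seq_len(ncol(scores)))
  colnames(scores) <- class_names
  pred <- if (object$cfg$task == "single") {
    class_names[max.col(scores, ties.method = "first")]
  } else {
    apply(scores, 1, function(r) list(class_names[r > 0.5]))
  }
  out <- tibble(image_id = ids)
  out <- dplyr::bind_cols(out, as_tibble(scores))
  out$predicted <- if (object$cfg$task == "single") pred else map(pred, 1)
  out
}

# stack record pixels into a normalized [H, W, 1, N] input array
records_to_input <- function(records, input_size) {
  if (is.array(records) && length(dim(records)) == 4) {
    return(records)
  }
  px <- records$pixels
  if (length(px) == 0) abort("no images to stack")
  if (any(map_int(px, nrow) != input_size)) {
    abort(sprintf(
      "image size mismatch: model expects %d x %d inputs",
      input_size, input_size
    ))
  }
  x <- array(0, c(input_size, input_size, 1, length(px)))
  for (i in seq_along(px)) x[, , 1, i] <- px[[i]] / 255
  x
}

#' Backbone / head parameter checksums
#'
#' @param model A `dual_stream_model`.
#' @param part `"backbone"` (both streams) or `"head"`.
#' @return Character hash.
#' @export
model_checksum <- function(model, part = c("backbone", "head")) {
  part <- match.arg(part)
  if (part == "backbone") {
    param_hash(list(model$params$s1, model$params$s2, model$bn_state))
  } else {
    param_hash(model$params$head)
  }
}

#' Save / load a model checkpoint
#'
#' The checkpoint embeds the full `model_config`, all parameters, and batch
#' normalization statistics.
#'
#' @param model A `dual_stream_model`.
#' @param path File path.
#' @return `path` (save) or the model (load).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "dual_stream_model"))
  model
}

#' @export
print.dual_stream_model <- function(x, ...) {
  cfg <- x$cfg
  cat(sprintf(
    "<dual_stream_model> input %dx%d, filters [%s], kernels %dx%d | %dx%d, %d classes (%s), %d parameters\n",
    cfg$input_size, cfg$input_size, paste(cfg$filters, collapse = ", "),
    cfg$kernel_s1, cfg$kernel_s1, cfg$kernel_s2, cfg$kernel_s2,
    cfg$n_classes, cfg$task, n_params(x)
  ))
  invisible(x)
}
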
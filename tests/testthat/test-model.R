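test_that("the descriptor reports the mandated architecture", {
  cfg <- model_config(
    input_size = 128, filters = c(16, 32, 64),
    embedding_len = 8, n_classes = 2
  )
  m <- build_model(cfg, seed = 1)
  d <- model_descriptor(m)
  convs <- d[d$kind == "conv", ]
  pools <- d[d$kind == "max_pool", ]
  expect_equal(sum(convs$stream == "s1"), 6) # 3 blocks x 2 convs
  expect_equal(sum(convs$stream == "s2"), 6)
  expect_equal(sum(pools$stream == "s1"), 3)
  expect_true(all(convs$kernel[convs$stream == "s1"] == 3))
  expect_true(all(convs$kernel[convs$stream == "s2"] == 5))
  expect_true(all(pools$kernel == 2))
  expect_equal(sum(d$kind == "batch_norm"), 6)
  expect_equal(sum(d$kind == "dropout"), 6)
})

test_that("pooling arithmetic gives 16x16 features and concatenated length", {
  cfg <- model_config(input_size = 128, filters = c(16, 32, 64), n_classes = 2)
  m <- build_model(cfg, seed = 1)
  d <- model_descriptor(m)
  final_pool <- d[d$kind == "max_pool" & d$block == 3, ]
  expect_true(all(final_pool$spatial_out == 16)) # 128 / 2^3
  x <- array(runif(128 * 128), c(128, 128, 1, 1))
  fw <- model_forward(m, x)
  expect_equal(ncol(fw$f_s1), 16 * 16 * 64)
  expect_equal(ncol(fw$f_total), ncol(fw$f_s1) + ncol(fw$f_s2))
})

test_that("parameter count follows from the shape arithmetic", {
  cfg <- model_config(input_size = 128, filters = c(16, 32, 64), embedding_len = 8, n_classes = 2)
  m <- build_model(cfg, seed = 1)
  count_stream <- function(k) {
    cin <- 1
    total <- 0
    for (f in c(16, 32, 64)) {
      total <- total + (k * k * cin * f + f) + (k * k * f * f + f) + 2 * f
      cin <- f
    }
    total
  }
  head_len <- 2 * 16 * 16 * 64 * (2 * 8) + 2 * 8
  expect_equal(n_params(m), count_stream(3) + count_stream(5) + head_len)
  expect_equal(n_params(m), 795568) # frozen regression value
})

test_that("inference is deterministic and scores are valid norms", {
  m <- tiny_model()
  x <- array(runif(32 * 32 * 1 * 3), c(32, 32, 1, 3))
  a <- model_forward(m, x)
  b <- model_forward(m, x)
  expect_identical(a$scores, b$scores)
  expect_true(all(a$scores >= 0 & a$scores < 1))
  # scores equal the norms of the squashed embedding vectors
  expect_equal(
    a$scores[2, ],
    apply(a$vectors[, , 2], 2, function(v) sqrt(sum(v^2)))
  )
})

test_that("both streams genuinely feed the head", {
  m <- tiny_model()
  x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  fw <- model_forward(m, x)
  flen <- ncol(fw$f_s1)
  # ablation probe: recompute the head on f_total with stream 2 zeroed
  f_ablate <- fw$f_total
  f_ablate[, flen + seq_len(flen)] <- 0
  z <- f_ablate %*% m$params$head$w +
    matrix(m$params$head$b, 2, length(m$params$head$b), byrow = TRUE)
  v <- array(t(z), c(m$cfg$embedding_len, m$cfg$n_classes, 2))
  u <- sqrt(apply(v^2, c(2, 3), sum))
  scores_ablate <- t(u^2 / (1 + u^2))
  expect_false(isTRUE(all.equal(scores_ablate, fw$scores)))
})

test_that("swapping streams with a correspondingly permuted head preserves scores", {
  m <- tiny_model()
  x <- array(runif(32 * 32 * 1 * 2), c(32, 32, 1, 2))
  ref <- model_forward(m, x)$scores
  flen <- stream_feature_len <- ncol(model_forward(m, x)$f_s1)
  perm <- m
  perm$params$s1 <- m$params$s2
  perm$params$s2 <- m$params$s1
  perm$bn_state <- list(s1 = m$bn_state$s2, s2 = m$bn_state$s1)
  perm$cfg$kernel_s1 <- m$cfg$kernel_s2
  perm$cfg$kernel_s2 <- m$cfg$kernel_s1
  perm$params$head$w <- m$params$head$w[c(flen + seq_len(flen), seq_len(flen)), ]
  expect_equal(model_forward(perm, x)$scores, ref, tolerance = 1e-12)
})

test_that("input shape mismatches name expected and actual shapes", {
  m <- tiny_model()
  expect_error(
    model_forward(m, array(0, c(16, 16, 1, 1))),
    "expected \\[32, 32, 1, N\\].*16"
  )
  expect_error(model_config(input_size = 50), "divisible")
  expect_error(model_config(kernel_s1 = 5, kernel_s2 = 5), "different kernel")
})

test_that("swap_head preserves the backbone bit-exactly and resizes scores", {
  m <- tiny_model()
  before <- model_checksum(m, "backbone")
  head_before <- model_checksum(m, "head")
  m4 <- swap_head(m, 4, "single", seed = 99)
  expect_identical(model_checksum(m4, "backbone"), before)
  expect_false(identical(model_checksum(m4, "head"), head_before))
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_length(model_forward(m4, x)$scores, 4)
  # same class count, fresh seed: head differs, backbone identical
  m2 <- swap_head(m, 2, "single", seed = 123)
  expect_identical(model_checksum(m2, "backbone"), before)
  expect_false(identical(model_checksum(m2, "head"), head_before))
})

test_that("one training step moves parameters in every block of both streams", {
  m <- build_model(tiny_model_cfg(dropout_rate = 0.25), seed = 5)
  x <- array(runif(32 * 32 * 1 * 4), c(32, 32, 1, 4))
  tg <- matrix(c(1, 0, 1, 0, 0, 1, 0, 1), 4, 2)
  set.seed(1)
  fw <- model_forward(m, x, training = TRUE, keep_cache = TRUE)
  ds <- margin_loss_grad(fw$scores, tg)
  bk <- model_backward(m, fw$cache, ds)
  st <- adam_step(m$params, bk$grads, adam_init(m$params), 1e-3)
  for (s in c("s1", "s2")) {
    for (b in paste0("b", 1:3)) {
      expect_false(
        identical(st$params[[s]][[b]]$conv1$w, m$params[[s]][[b]]$conv1$w),
        label = sprintf("%s %s conv1 moved", s, b)
      )
      expect_false(
        identical(st$params[[s]][[b]]$conv2$w, m$params[[s]][[b]]$conv2$w),
        label = sprintf("%s %s conv2 moved", s, b)
      )
    }
  }
})

test_that("analytic gradients agree with finite differences through the whole net", {
  cfg <- model_config(
    input_size = 16, filters = c(2, 2, 3), embedding_len = 3,
    n_classes = 2, dropout_rate = 0
  )
  m <- build_model(cfg, seed = 8)
  x <- array(runif(16 * 16 * 2), c(16, 16, 1, 2))
  tg <- matrix(c(1, 0, 0, 1), 2, 2)
  loss_at <- function(model) {
    fw <- model_forward(model, x, training = TRUE)
    margin_loss(fw$scores, tg)
  }
  fw <- model_forward(m, x, training = TRUE, keep_cache = TRUE)
  g <- model_backward(m, fw$cache, margin_loss_grad(fw$scores, tg))$grads
  eps <- 1e-5
  checks <- list(
    list(c("s1", "b1", "conv1", "w"), 4),
    list(c("s2", "b2", "conv2", "w"), 11),
    list(c("s1", "b3", "bn", "gamma"), 1),
    list(c("s2", "b1", "bn", "beta"), 2),
    list(c("head", "w"), 17)
  )
  for (ch in checks) {
    path <- ch[[1]]
    idx <- ch[[2]]
    bump <- function(model, delta) {
      ref <- model$params
      if (length(path) == 4) {
        ref[[path[1]]][[path[2]]][[path[3]]][[path[4]]][idx] <-
          ref[[path[1]]][[path[2]]][[path[3]]][[path[4]]][idx] + delta
      } else {
        ref[[path[1]]][[path[2]]][idx] <- ref[[path[1]]][[path[2]]][idx] + delta
      }
      model$params <- ref
      model
    }
    fd <- (loss_at(bump(m, eps)) - loss_at(bump(m, -eps))) / (2 * eps)
    analytic <- if (length(path) == 4) {
      g[[path[1]]][[path[2]]][[path[3]]][[path[4]]][idx]
    } else {
      g[[path[1]]][[path[2]]][idx]
    }
    expect_equal(analytic, fd,
      tolerance = 1e-4,
      label = sprintf("grad %s[%d]", paste(path, collapse = "$"), idx)
    )
  }
})

test_that("checkpoints round-trip through disk", {
  m <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, path)
  back <- load_checkpoint(path)
  expect_identical(model_checksum(back, "backbone"), model_checksum(m, "backbone"))
  x <- array(runif(32 * 32), c(32, 32, 1, 1))
  expect_identical(model_forward(back, x)$scores, model_forward(m, x)$scores)
})
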
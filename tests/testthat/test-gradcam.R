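test_that("map combination matches a hand computation on 2x2 feature maps", {
  a <- array(c(
    1, 2, 3, 4, # A^1
    5, 6, 7, 8 # A^2
  ), c(2, 2, 2))
  g <- array(c(
    0.4, 0.4, 0.4, 0.4, # constant gradient: weight = 0.4
    -1, -1, -1, 3 # mean = 0
  ), c(2, 2, 2))
  out <- chestnet:::gradcam_combine(a, g)
  # weights: a_1 = 0.4, a_2 = 0; map = ReLU(0.4 * A^1)
  expect_equal(out, matrix(0.4 * c(1, 2, 3, 4), 2, 2))
  # zero gradients give an identically zero map
  expect_equal(
    chestnet:::gradcam_combine(a, array(0, dim(a))),
    matrix(0, 2, 2)
  )
  # negative combinations are rectified away
  gneg <- array(rep(-1, 8), c(2, 2, 2))
  expect_equal(chestnet:::gradcam_combine(a, gneg), matrix(0, 2, 2))
})

test_that("a constant gradient over a feature map recovers it as its weight", {
  a <- array(runif(9 * 2), c(3, 3, 2))
  g <- array(c(rep(2.5, 9), rep(0, 9)), c(3, 3, 2))
  out <- chestnet:::gradcam_combine(a, g)
  expect_equal(out, pmax(2.5 * a[, , 1], 0))
})

test_that("grad_cam returns a non-negative input-sized map per stream", {
  m <- tiny_model()
  img <- small_records()$pixels[[1]]
  cam <- grad_cam(m, img, 1)
  expect_equal(dim(cam$upsampled), c(32, 32))
  expect_true(all(cam$raw$s1 >= 0))
  expect_true(all(cam$raw$s2 >= 0))
  expect_true(all(cam$upsampled >= 0))
  expect_equal(dim(cam$raw$s1), c(8, 8)) # 32 / 2^2 at the last conv layer
  expect_error(grad_cam(m, img, 7), "out of range")
  # deterministic
  cam2 <- grad_cam(m, img, 1)
  expect_identical(cam$upsampled, cam2$upsampled)
})

test_that("zone partition is a disjoint cover for all sizes 3 to 512", {
  for (s in 3:512) {
    z <- zone_partition(s)
    expect_equal(nrow(z), 9)
    expect_equal(sum(z$n_pixels), s * s)
    # disjointness: row/col bands tile without overlap
    rows <- unique(z[, c("row_start", "row_end")])
    expect_equal(rows$row_start[-1], rows$row_end[-3] + 1)
  }
  expect_error(zone_partition(2), ">= 3")
})

test_that("the 128-pixel grid puts remainder pixels in the last bands", {
  z <- zone_partition(128)
  expect_equal(unique(z$row_end[z$zone %in% c("Z11", "Z12", "Z13")]), 42)
  expect_equal(unique(z$row_end[z$zone %in% c("Z21", "Z22", "Z23")]), 84)
  expect_equal(unique(z$row_end[z$zone %in% c("Z31", "Z32", "Z33")]), 128)
  # last band is 2 pixels taller: 44 vs 42
  expect_equal(z$n_pixels[z$zone == "Z33"], 44 * 44)
  expect_equal(z$n_pixels[z$zone == "Z11"], 42 * 42)
})

test_that("uniform maps give uniform zone fractions that sum to one", {
  zones <- zone_partition(30)
  fr <- chestnet:::zone_fractions(matrix(1, 30, 30), zones)
  expect_equal(fr, rep(1 / 9, 9))
  set.seed(2)
  fr2 <- chestnet:::zone_fractions(matrix(runif(900), 30, 30), zones)
  expect_equal(sum(fr2), 1, tolerance = 1e-9)
  expect_true(all(fr2 >= 0))
})

test_that("zone profiles aggregate only correctly classified images of the class", {
  m <- tiny_model()
  rec <- small_records()[1:10, ]
  prof <- suppressWarnings(zone_profile(m, rec, "gender", "Male"))
  expect_s3_class(prof, "zone_profile")
  expect_equal(nrow(prof), 9)
  if (prof$n_images[1] > 0) {
    expect_equal(sum(prof$fraction), 1, tolerance = 1e-9)
  } else {
    expect_true(all(is.na(prof$fraction)))
  }
  expect_error(zone_profile(m, rec, "gender", "Dragon"), "unknown class")
})

test_that("an untrained-class profile is empty but not an error", {
  m <- tiny_model()
  rec <- small_records()[1:6, ]
  rec$gender <- rep("Male", 6) # force all images to one class
  # find which class the model never predicts correctly by flipping labels
  pred <- predict(m, rec, class_names = c("Male", "Female"))
  wrong <- if (all(pred$predicted == "Male")) "Female" else NA
  if (!is.na(wrong)) {
    rec$gender <- rep(wrong, 6)
    expect_warning(prof <- zone_profile(m, rec, "gender", wrong), "empty profile")
    expect_equal(prof$n_images, rep(0L, 9))
  } else {
    succeed()
  }
})

test_that("overlays blend proportionally to the map", {
  img <- matrix(128, 10, 10)
  zero <- overlay_attention(img, matrix(0, 10, 10))
  expect_equal(dim(zero), c(10, 10, 3))
  for (ch in 1:3) expect_equal(zero[, , ch], img / 255)
  sat <- overlay_attention(img, matrix(1, 10, 10), alpha = 0.45)
  # uniform blend at weight alpha everywhere: each channel is constant and
  # differs from the plain grayscale rendering
  for (ch in 1:3) {
    expect_equal(sd(sat[, , ch]), 0)
    expect_false(isTRUE(all.equal(sat[, , ch], zero[, , ch])))
  }
  expect_error(overlay_attention(img, matrix(0, 5, 5)), "shapes differ")
})

test_that("overlay renders are byte-stable across runs", {
  img <- with_seed_matrix(4, 16, 16)
  map <- matrix(seq(0, 1, length.out = 256), 16, 16)
  a <- overlay_attention(img, map)
  b <- overlay_attention(img, map)
  expect_identical(rlang::hash(a), rlang::hash(b))
})
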
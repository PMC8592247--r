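test_that("empty configuration yields an empty collection and manifest", {
  rec <- generate_phantoms(small_phantom_cfg(n_subjects = 0))
  expect_equal(nrow(rec), 0)
  expect_named(
    rec,
    c("image_id", "pixels", "gender", "age_years", "age_bin", "diseases")
  )
  expect_error(write_manifest(rec, tempfile()), "non-empty")
})

test_that("identical config and seed give byte-identical image sets", {
  cfg <- phantom_config(image_size = 32, n_subjects = 20, seed = 7)
  a <- generate_phantoms(cfg)
  b <- generate_phantoms(cfg)
  expect_identical(
    rlang::hash(do.call(c, a$pixels)),
    rlang::hash(do.call(c, b$pixels))
  )
  # and a different seed changes the pixels
  c2 <- generate_phantoms(phantom_config(image_size = 32, n_subjects = 20, seed = 8))
  expect_false(identical(a$pixels, c2$pixels))
})

test_that("records have 8-bit square pixels and binnable ages", {
  rec <- small_records()
  for (px in rec$pixels) {
    expect_true(is.matrix(px) && nrow(px) == ncol(px))
    expect_true(all(px >= 0 & px <= 255))
  }
  expect_true(all(rec$age_bin %in% c("Age_1-10", "Age_11-20", "Age_21-30", "Age_31-120")))
  expect_identical(rec$age_bin, age_bin(rec$age_years))
})

test_that("each disease blob brightens its disc relative to the disease-free twin", {
  cfg <- phantom_config(
    image_size = 64, n_subjects = 1, disease_blob_intensity = 0.4,
    disease_blob_radius = 8, noise_sd = 0, seed = 1
  )
  bp <- chestnet:::disease_blob_params()
  for (d in c("Atelectasis", "Effusion", "Pneumothorax")) {
    with_disease <- render_phantom("Male", 40, d, cfg)
    twin <- render_phantom("Male", 40, character(0), cfg)
    p <- bp[bp$disease == d, ]
    geo <- chestnet:::phantom_geometry(64, 4, "Male", cfg)
    cx <- geo$lung_cx[p$side] + p$fx * geo$lung_a
    cy <- geo$lung_cy + p$fy * geo$lung_b
    r <- chestnet:::blob_radius_px(cfg) * p$rmult
    rows <- matrix(seq_len(64), 64, 64)
    cols <- matrix(seq_len(64), 64, 64, byrow = TRUE)
    disc <- (cols - cx)^2 + (rows - cy)^2 <= r^2
    # cosine blob profile: mean added intensity over the disc is about half
    # the peak 0.4 * 255 = 102
    diff <- mean(with_disease[disc]) - mean(twin[disc])
    expect_gt(diff, 25)
    # outside all discs the twins agree exactly (noise-free render)
    far <- (cols - cx)^2 + (rows - cy)^2 > (3 * r)^2
    expect_equal(with_disease[far], twin[far])
  }
})

test_that("gender and age alter only their own geometric cue", {
  cfg <- phantom_config(image_size = 64, n_subjects = 1, noise_sd = 0, seed = 1)
  male <- render_phantom("Male", 40, character(0), cfg)
  female <- render_phantom("Female", 40, character(0), cfg)
  young <- render_phantom("Male", 5, character(0), cfg)
  # gender changes the shoulder-band rows only (top fifth of the image)
  diff_rows <- which(rowSums(male != female) > 0)
  expect_true(all(diff_rows <= 64 * 0.2))
  # age changes the lung-field extent, below the shoulder bands
  diff_rows_age <- which(rowSums(male != young) > 0)
  expect_true(all(diff_rows_age > 64 * 0.15))
})

test_that("disease blobs never touch the shoulder bands", {
  cfg <- phantom_config(image_size = 64, n_subjects = 1, noise_sd = 0, seed = 1)
  geo <- chestnet:::phantom_geometry(64, 4, "Male", cfg)
  band_bottom <- geo$band_top + geo$band_h
  bp <- chestnet:::disease_blob_params()
  for (i in seq_len(nrow(bp))) {
    p <- bp[i, ]
    # worst case: oldest bin has the largest lung ellipse
    cy <- geo$lung_cy + p$fy * geo$lung_b
    top <- cy - chestnet:::blob_radius_px(cfg) * p$rmult
    expect_gt(top, band_bottom)
  }
})

test_that("gender is recoverable from the band-width feature alone", {
  cfg <- phantom_config(
    image_size = 64, n_subjects = 120, gender_geometry_effect = 0.2,
    noise_sd = 10, disease_prevalence = 0, seed = 13
  )
  rec <- generate_phantoms(cfg)
  # band-width feature: count of bright pixels in the left shoulder column range
  feature <- vapply(rec$pixels, function(px) {
    sum(px[1:round(0.2 * 64), round(0.05 * 64):round(0.38 * 64)] > 150)
  }, numeric(1))
  fit <- suppressWarnings(glm((rec$gender == "Male") ~ feature, family = binomial()))
  acc <- mean((predict(fit, type = "response") > 0.5) == (rec$gender == "Male"))
  expect_gt(acc, 0.9)
})

test_that("invalid configurations are rejected with the offending field named", {
  expect_error(phantom_config(image_size = 16), "image_size")
  expect_error(phantom_config(noise_sd = -1), "noise_sd")
  expect_error(phantom_config(disease_blob_intensity = 1.5), "disease_blob_intensity")
  expect_error(phantom_config(gender_geometry_effect = Inf), "gender_geometry_effect")
  expect_error(
    phantom_config(image_size = 32, disease_blob_radius = 40),
    "disease_blob_radius"
  )
})
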
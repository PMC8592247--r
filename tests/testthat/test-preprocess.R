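test_that("a balanced input passes through augmentation unchanged", {
  rec <- small_records()[1:8, ]
  rec$gender <- rep(c("Male", "Female"), each = 4)
  out <- augment_balance(rec, by = "gender")
  expect_equal(out$image_id, rec$image_id)
  expect_equal(out$pixels, rec$pixels)
})

test_that("minority classes are oversampled to the majority count", {
  rec <- small_records()[1:14, ]
  rec$gender <- c(rep("Male", 10), rep("Female", 4))
  out <- augment_balance(rec, by = "gender")
  expect_equal(as.integer(table(out$gender)[c("Male", "Female")]), c(10L, 10L))
  # originals retained, copies have derived ids and recorded angles
  expect_true(all(rec$image_id %in% out$image_id))
  copies <- out[!is.na(out$aug_angle), ]
  expect_equal(nrow(copies), 6)
  expect_true(all(grepl("_aug\\d+", copies$image_id)))
})

test_that("all drawn rotation angles lie within the configured range", {
  rec <- small_records()[1:20, ]
  rec$gender <- c(rep("Male", 12), rep("Female", 5), rep("Male", 3))
  set.seed(99)
  out <- augment_balance(rec, max_angle_deg = 30, by = "gender")
  angles <- out$aug_angle[!is.na(out$aug_angle)]
  expect_gt(length(angles), 0)
  expect_true(all(angles >= -30 & angles <= 30))
  # same seed, same angles
  set.seed(99)
  out2 <- augment_balance(rec, max_angle_deg = 30, by = "gender")
  expect_identical(out$aug_angle, out2$aug_angle)
})

test_that("a class listed as required but absent raises an error naming it", {
  rec <- small_records()[1:5, ]
  rec$gender <- rep("Male", 5)
  expect_error(
    augment_balance(rec, by = "gender", classes = c("Male", "Female")),
    "Female"
  )
})

test_that("rotation keeps shape and fills corners with black", {
  img <- matrix(200, 33, 33)
  rot <- rotate_image(img, 25)
  expect_equal(dim(rot), c(33, 33))
  expect_equal(rot[1, 1], 0) # exposed corner
  expect_equal(rotate_image(img, 0), img)
})

test_that("a 1000-record single-class split is exactly 800/100/100", {
  rec <- small_records()[rep(1, 1000), ]
  rec$image_id <- sprintf("r%04d.png", 1:1000)
  rec$diseases <- rep(list(character(0)), 1000)
  out <- split_dataset(rec, seed = 1)
  expect_equal(as.integer(table(out$role)[c("train", "val", "test")]), c(800L, 100L, 100L))
})

test_that("largest-remainder split of two classes of five gives 8/1/1 overall", {
  rec <- small_records()[rep(1, 10), ]
  rec$image_id <- sprintf("r%02d.png", 1:10)
  rec$gender <- rep(c("Male", "Female"), each = 5)
  out <- split_dataset(rec, seed = 2, by = "gender")
  expect_equal(as.integer(table(out$role)[c("train", "val", "test")]), c(8L, 1L, 1L))
  # per class: 4 train plus one of val/test
  for (g in c("Male", "Female")) {
    expect_equal(sum(out$role == "train" & out$gender == g), 4)
  }
})

test_that("splits are deterministic in the seed and stratified", {
  rec <- small_records()
  a <- split_dataset(rec, seed = 1, by = "gender")
  b <- split_dataset(rec, seed = 1, by = "gender")
  expect_identical(a$role, b$role)
  c2 <- split_dataset(rec, seed = 2, by = "gender")
  expect_false(identical(a$role, c2$role))
  expect_error(split_dataset(rec, fractions = c(0.5, 0.2, 0.2)), "sum to 1")
})

test_that("classes with fewer than three members fall back to train with a warning", {
  rec <- small_records()[1:5, ]
  rec$gender <- c(rep("Male", 3), "Female", "Female")
  expect_warning(out <- split_dataset(rec, seed = 1, by = "gender"), "fewer than 3")
  expect_true(all(out$role[out$gender == "Female"] == "train"))
})

test_that("Ver_NMF is label-isomorphic to Ver_ORG with transformed pixels", {
  rec <- small_records()[1:6, ]
  org <- make_version_org(rec)
  nmf <- make_version_nmf(rec, nmf_config(kappa = 6, max_iter = 20), clahe_config(nt = c(4, 4)))
  expect_equal(version_tag(org), "Ver_ORG")
  expect_equal(version_tag(nmf), "Ver_NMF")
  expect_identical(nmf$image_id, org$image_id)
  expect_identical(nmf$diseases, org$diseases)
  expect_identical(nmf$role, org$role)
  for (i in seq_len(nrow(rec))) {
    expect_false(identical(nmf$pixels[[i]], org$pixels[[i]]))
    expect_equal(dim(nmf$pixels[[i]]), dim(org$pixels[[i]]))
  }
})

test_that("per-image preprocessing is independent of batch composition", {
  rec <- small_records()[1:5, ]
  ncfg <- nmf_config(kappa = 6, max_iter = 20)
  ccfg <- clahe_config(nt = c(4, 4))
  batch <- make_version_nmf(rec, ncfg, ccfg)
  solo <- make_version_nmf(rec[3, ], ncfg, ccfg)
  expect_identical(batch$pixels[[3]], solo$pixels[[1]])
})

test_that("empty record sets produce an empty Ver_NMF", {
  rec <- small_records()[0, ]
  out <- make_version_nmf(rec)
  expect_equal(nrow(out), 0)
  expect_equal(version_tag(out), "Ver_NMF")
})
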
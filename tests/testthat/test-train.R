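test_that("task targets encode the three label families", {
  rec <- small_records()[1:4, ]
  rec$gender <- c("Male", "Female", "Male", "Female")
  tg <- task_targets_for_test(rec, "gender")
  expect_equal(tg[, "Male"], c(1, 0, 1, 0))
  rec$diseases <- list(character(0), "Mass", c("Mass", "Edema"), "Hernia")
  td <- task_targets_for_test(rec, "disease")
  expect_equal(dim(td), c(4, 14))
  expect_equal(sum(td[1, ]), 0) # no finding: all-zero row
  expect_equal(sum(td[3, ]), 2)
})

test_that("zero epochs returns the initialization with an empty log", {
  m <- tiny_model()
  rec <- make_version_org(gender_records())
  ph <- run_phase(m, rec, phase_config("gender", "Ver_ORG", epochs = 0))
  expect_identical(model_checksum(ph$model, "backbone"), model_checksum(m, "backbone"))
  expect_equal(nrow(ph$log), 0)
})

test_that("one epoch logs finite loss and accuracy once", {
  m <- tiny_model()
  rec <- make_version_org(gender_records()[1:25, ])
  set.seed(1)
  ph <- run_phase(m, rec, phase_config("gender", "Ver_ORG", epochs = 1, batch_size = 8))
  expect_equal(nrow(ph$log), 1)
  expect_true(is.finite(ph$log$train_loss))
  expect_true(ph$log$train_acc >= 0 && ph$log$train_acc <= 1)
})

test_that("version/task mismatches are rejected with the naming convention", {
  m <- tiny_model()
  rec <- make_version_org(gender_records()[1:10, ])
  expect_error(
    run_phase(m, rec, phase_config("gender", "Ver_NMF", epochs = 1)),
    "GD_NMF"
  )
  m4 <- swap_head(tiny_model(), 4, "single", seed = 1)
  expect_error(
    run_phase(m4, rec, phase_config("gender", "Ver_ORG", epochs = 1)),
    "swap_head"
  )
})

test_that("the gender task is learnable on separable phantoms", {
  rec <- make_version_org(gender_records())
  m <- build_model(model_config(
    input_size = 32, filters = c(4, 8, 16),
    embedding_len = 4, n_classes = 2
  ), seed = 2)
  set.seed(42)
  ph <- run_phase(m, rec, phase_config("gender", "Ver_ORG", epochs = 10, batch_size = 16))
  best_val <- max(ph$log$val_acc)
  expect_gt(best_val, 0.5) # beats the majority baseline
  expect_equal(ph$log$val_acc[ph$best_epoch], max(ph$log$val_acc))
})

test_that("variant names parse to their phase chains and bad names list the nine", {
  ch <- parse_variant("GD_NMF=>AD_NMF=>DD_ORG")
  expect_equal(ch$task, c("gender", "age", "disease"))
  expect_equal(ch$dataset_version, c("Ver_NMF", "Ver_NMF", "Ver_ORG"))
  expect_equal(nrow(parse_variant("DD_ORG")), 1)
  expect_equal(nrow(parse_variant("GD_NMF => DD_ORG")), 2) # whitespace tolerated
  err <- tryCatch(parse_variant("DD_NMF"), error = conditionMessage)
  for (v in c("GD_NMF", "AD_NMF=>DD_ORG", "GD_ORG", "DD_ORG")) {
    expect_match(err, v, fixed = TRUE)
  }
})

test_that("chained protocols pass each phase's backbone to the next", {
  versions <- transfer_versions()
  run <- run_protocol("GD_NMF=>DD_ORG",
    versions = versions, seed = 7,
    model_cfg = tiny_model_cfg(), epochs = c(1, 1), batch_size = 16
  )
  expect_length(run$phases, 2)
  expect_identical(
    run$backbone_chain$backbone_start[2],
    run$backbone_chain$backbone_end[1]
  )
  expect_equal(run$phases[[2]]$cfg$task, "disease")
  # single-phase variant runs exactly one phase
  one <- run_protocol("DD_ORG",
    versions = versions, seed = 7,
    model_cfg = tiny_model_cfg(), epochs = 1, batch_size = 16
  )
  expect_length(one$phases, 1)
})

test_that("identical seeds reproduce identical metric trajectories", {
  versions <- transfer_versions()
  a <- run_protocol("GD_NMF",
    versions = versions, seed = 3,
    model_cfg = tiny_model_cfg(), epochs = 2, batch_size = 16
  )
  b <- run_protocol("GD_NMF",
    versions = versions, seed = 3,
    model_cfg = tiny_model_cfg(), epochs = 2, batch_size = 16
  )
  expect_identical(tidy(a), tidy(b))
  c2 <- run_protocol("GD_NMF",
    versions = versions, seed = 4,
    model_cfg = tiny_model_cfg(), epochs = 2, batch_size = 16
  )
  expect_false(identical(tidy(a)$train_loss, tidy(c2)$train_loss))
})

test_that("test ids never enter any phase's training pool", {
  versions <- transfer_versions()
  run <- run_protocol("GD_NMF=>DD_ORG",
    versions = versions, seed = 5,
    model_cfg = tiny_model_cfg(), epochs = c(1, 1), batch_size = 16
  )
  test_ids <- versions$Ver_ORG$image_id[versions$Ver_ORG$role == "test"]
  for (ph in run$phases) {
    expect_length(intersect(ph$train_ids, test_ids), 0)
  }
})

test_that("tidy and glance summarize runs", {
  versions <- transfer_versions()
  run <- run_protocol("GD_NMF",
    versions = versions, seed = 3,
    model_cfg = tiny_model_cfg(), epochs = 2, batch_size = 16
  )
  td <- tidy(run)
  expect_equal(nrow(td), 2)
  expect_true(all(c("phase", "task", "epoch", "train_loss", "val_acc") %in% names(td)))
  gl <- glance(run)
  expect_equal(gl$variant, "GD_NMF")
  expect_equal(gl$n_phases, 1)
  expect_equal(gl$final_task, "gender")
})

test_that("evaluating a run on the test split yields a bounded report", {
  versions <- transfer_versions()
  run <- run_protocol("GD_NMF",
    versions = versions, seed = 3,
    model_cfg = tiny_model_cfg(), epochs = 1, batch_size = 16
  )
  rep_ <- evaluate_model(run$model, versions$Ver_NMF, "gender")
  expect_true(all(rep_$accuracy >= 0 & rep_$accuracy <= 1, na.rm = TRUE))
  expect_true("macro" %in% rep_$class)
})
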
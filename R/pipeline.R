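#' Assemble a full run configuration
#'
#' Nested configuration for the end-to-end pipeline
#' (phantoms -> versions -> protocol -> metrics -> zone profiles). Any field
#' can be overridden; the resolved configuration is written back verbatim into
#' the run directory as `config.yaml`.
#'
#' @param seed Global seed; every stage derives its randomness from it.
#' @param out_dir Output directory of the run.
#' @param phantom List of [phantom_config()] overrides.
#' @param nmf,clahe,model,loss Lists of overrides for the respective configs.
#' @param split List: `fractions`, `by`.
#' @param augment List: `max_angle_deg`, `by`, `enabled`.
#' @param train List: `variant`, `epochs`, `learning_rates`, `batch_size`.
#' @param attend List: `tasks` (classes are profiled for each), `stream`.
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, out_dir = tempfile("chestnet_run_"),
                       phantom = list(), nmf = list(), clahe = list(),
                       model = list(), loss = list(), split = list(),
                       augment = list(), train = list(), attend = list()) {
  cfg <- list(
    seed = seed, out_dir = out_dir,
    phantom = modifyList(list(
      image_size = 64, n_subjects = 200, gender_geometry_effect = 0.3,
      disease_blob_intensity = 0.4, disease_blob_radius = 8,
      disease_prevalence = 0.07, disease_sampling = "balanced", noise_sd = 8
    ), phantom),
    nmf = modifyList(list(kappa = 6, max_iter = 60, tol = 1e-5, objective = "frobenius"), nmf),
    clahe = modifyList(list(nt = c(8, 8), cl = 2), clahe),
    model = modifyList(list(filters = c(4, 8, 16), embedding_len = 8, dropout_rate = 0.25), model),
    loss = modifyList(list(
      m_plus = 0.9, m_minus = 0.1, lambda = 0.5,
      squared_hinge_variant = FALSE
    ), loss),
    split = modifyList(list(fractions = c(0.80, 0.10, 0.10), by = "disease"), split),
    augment = modifyList(list(max_angle_deg = 30, by = "disease", enabled = TRUE), augment),
    train = modifyList(list(
      variant = "GD_NMF=>AD_NMF=>DD_ORG", epochs = c(2, 2, 5),
      learning_rates = NULL, batch_size = 32, class_weighting = FALSE
    ), train),
    attend = modifyList(list(tasks = "gender", stream = "both"), attend)
  )
  structure(cfg, class = "run_config")
}

stage_done <- function(dir, stage, key) {
  f <- file.path(dir, "stages.json")
  if (!file.exists(f)) {
    return(FALSE)
  }
  st <- jsonlite::read_json(f)
  identical(st[[stage]]$key, key) && all(file.exists(file.path(dir, unlist(st[[stage]]$outputs))))
}

stage_record <- function(dir, stage, key, outputs) {
  f <- file.path(dir, "stages.json")
  st <- if (file.exists(f)) jsonlite::read_json(f) else list()
  st[[stage]] <- list(key = key, outputs = as.list(outputs))
  jsonlite::write_json(st, f, auto_unbox = TRUE, pretty = TRUE)
}

#' Run the full pipeline
#'
#' Stages: phantom generation; role split + rotation balancing of the
#' training pool + Ver_ORG / Ver_NMF construction; protocol training; test
#' metrics; and zone-attention profiles. Every stage writes a start/end record
#' to the run log; with `resume = TRUE`, stages whose configuration key
#' matches a previous run (and whose outputs still exist) are skipped and
#' their cached outputs reloaded, so e.g. deleting only `profiles.csv`
#' re-executes only the attention stage.
#'
#' @param cfg A [run_config()].
#' @param resume Skip completed stages by configuration checksum.
#' @param verbose Log progress to the console as well as the run log.
#' @return Invisibly, a list with the run directory, the trained run, the
#'   metrics and the profiles.
#' @export
run_all <- function(cfg = run_config(), resume = FALSE, verbose = FALSE) {
  dir <- cfg$out_dir
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  if (!resume && file.exists(file.path(dir, "stages.json"))) {
    unlink(file.path(dir, "stages.json"))
  }
  log_file <- file.path(dir, "run.log")
  logmsg <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...))
    cat(line, "\n", file = log_file, append = TRUE)
    if (verbose) message(line)
  }
  run_stage <- function(stage, key_obj, outputs, fn, reload) {
    key <- rlang::hash(key_obj)
    if (resume && stage_done(dir, stage, key)) {
      logmsg("stage %s: skipped (up to date)", stage)
      reload()
      return(invisible(FALSE))
    }
    logmsg("stage %s: start", stage)
    tryCatch(fn(), error = function(e) {
      logmsg("stage %s: FAILED: %s", stage, conditionMessage(e))
      abort(sprintf("pipeline stage '%s' failed: %s", stage, conditionMessage(e)))
    })
    stage_record(dir, stage, key, outputs)
    logmsg("stage %s: end", stage)
    invisible(TRUE)
  }
  yaml::write_yaml(unclass(cfg), file.path(dir, "config.yaml"))

  pc <- phantom_config(
    image_size = cfg$phantom$image_size, n_subjects = cfg$phantom$n_subjects,
    gender_geometry_effect = cfg$phantom$gender_geometry_effect,
    disease_blob_intensity = cfg$phantom$disease_blob_intensity,
    disease_blob_radius = cfg$phantom$disease_blob_radius,
    disease_prevalence = cfg$phantom$disease_prevalence,
    disease_sampling = cfg$phantom$disease_sampling,
    noise_sd = cfg$phantom$noise_sd, seed = cfg$seed
  )
  env <- new.env()
  run_stage(
    "phantom", list(pc), c("manifest.csv", "records.rds"),
    function() {
      env$records <- generate_phantoms(pc)
      write_manifest(env$records, file.path(dir, "manifest.csv"))
      saveRDS(env$records, file.path(dir, "records.rds"))
    },
    function() env$records <- readRDS(file.path(dir, "records.rds"))
  )

  ncfg <- nmf_config(
    kappa = cfg$nmf$kappa, max_iter = cfg$nmf$max_iter,
    tol = cfg$nmf$tol, objective = cfg$nmf$objective, seed = cfg$seed + 3
  )
  ccfg <- clahe_config(nt = cfg$clahe$nt, cl = cfg$clahe$cl)
  run_stage(
    "versions", list(pc, ncfg, ccfg, cfg$split, cfg$augment, cfg$seed),
    c("roles.csv", "versions.rds"),
    function() {
      # split before augmentation so val/test stay un-augmented
      rec <- split_dataset(env$records,
        fractions = cfg$split$fractions,
        seed = cfg$seed + 1, by = cfg$split$by
      )
      if (isTRUE(cfg$augment$enabled)) {
        train_part <- rec[rec$role == "train", ]
        balanced <- with_local_seed(cfg$seed + 2, {
          augment_balance(train_part,
            max_angle_deg = cfg$augment$max_angle_deg, by = cfg$augment$by
          )
        })
        balanced$role <- "train"
        rec <- dplyr::bind_rows(balanced, rec[rec$role != "train", ])
      }
      env$ver_org <- make_version_org(rec)
      env$ver_nmf <- make_version_nmf(rec, ncfg, ccfg)
      readr::write_csv(
        tibble(image_id = rec$image_id, role = rec$role),
        file.path(dir, "roles.csv")
      )
      saveRDS(list(org = env$ver_org, nmf = env$ver_nmf), file.path(dir, "versions.rds"))
    },
    function() {
      v <- readRDS(file.path(dir, "versions.rds"))
      env$ver_org <- v$org
      env$ver_nmf <- v$nmf
    }
  )

  mcfg <- model_config(
    input_size = cfg$phantom$image_size, filters = cfg$model$filters,
    embedding_len = cfg$model$embedding_len, dropout_rate = cfg$model$dropout_rate
  )
  run_stage(
    "train", list(mcfg, cfg$train, cfg$seed),
    c("checkpoint.rds", "training_log.csv"),
    function() {
      env$run <- run_protocol(cfg$train$variant,
        versions = list(Ver_ORG = env$ver_org, Ver_NMF = env$ver_nmf),
        seed = cfg$seed + 4, model_cfg = mcfg, epochs = cfg$train$epochs,
        learning_rates = cfg$train$learning_rates,
        batch_size = cfg$train$batch_size,
        loss_params = margin_loss_params(
          m_plus = cfg$loss$m_plus, m_minus = cfg$loss$m_minus,
          lam = cfg$loss$lambda,
          squared_hinge_variant = isTRUE(cfg$loss$squared_hinge_variant)
        ),
        class_weighting = isTRUE(cfg$train$class_weighting),
        verbose = verbose
      )
      save_checkpoint(env$run$model, file.path(dir, "checkpoint.rds"))
      readr::write_csv(tidy(env$run), file.path(dir, "training_log.csv"))
    },
    function() {
      env$run <- list(model = load_checkpoint(file.path(dir, "checkpoint.rds")))
    }
  )

  final_task <- tail(parse_variant(cfg$train$variant)$task, 1)
  eval_version <- if (final_task == "disease") env$ver_org else env$ver_nmf
  run_stage(
    "eval", list(cfg$train, cfg$seed, "eval"), "metrics.csv",
    function() {
      env$metrics <- evaluate_model(env$run$model, eval_version, final_task)
      readr::write_csv(env$metrics, file.path(dir, "metrics.csv"))
    },
    function() {
      env$metrics <- readr::read_csv(file.path(dir, "metrics.csv"), show_col_types = FALSE)
    }
  )

  run_stage(
    "attend", list(cfg$attend, cfg$train, cfg$seed), "profiles.csv",
    function() {
      test_rec <- eval_version[eval_version$role == "test", ]
      tc <- task_classes(final_task)
      profs <- purrr::map(tc$classes, function(cl) {
        tryCatch(
          suppressWarnings(zone_profile(env$run$model, test_rec, final_task, cl,
            stream = cfg$attend$stream
          )),
          error = function(e) NULL
        )
      })
      env$profiles <- dplyr::bind_rows(profs)
      readr::write_csv(env$profiles, file.path(dir, "profiles.csv"))
    },
    function() {
      env$profiles <- readr::read_csv(file.path(dir, "profiles.csv"), show_col_types = FALSE)
    }
  )

  logmsg("run complete: %s", dir)
  invisible(list(
    dir = dir, run = env$run,
    metrics = env$metrics, profiles = env$profiles
  ))
}
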
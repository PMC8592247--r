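task_classes <- function(task) {
  switch(task,
    gender = list(classes = c("Male", "Female"), kind = "single"),
    age = list(classes = age_bins, kind = "single"),
    disease = list(classes = chest_diseases, kind = "multi"),
    abort(sprintf("unknown task: %s (expected gender, age or disease)", task))
  )
}

# N x K binary target matrix for a task
task_targets <- function(records, task) {
  tc <- task_classes(task)
  k <- length(tc$classes)
  t_mat <- matrix(0, nrow(records), k, dimnames = list(NULL, tc$classes))
  if (task == "gender") {
    t_mat[cbind(seq_len(nrow(records)), match(records$gender, tc$classes))] <- 1
  } else if (task == "age") {
    t_mat[cbind(seq_len(nrow(records)), match(records$age_bin, tc$classes))] <- 1
  } else {
    for (i in seq_len(nrow(records))) {
      t_mat[i, match(records$diseases[[i]], tc$classes)] <- 1
    }
  }
  t_mat
}

#' Configuration of one training phase
#'
#' Defaults follow the sequential protocol: gender and age phases use learning
#' rate 0.001 for 10 epochs; the disease phase uses 0.0001 for 100 epochs.
#' Both are freely scalable down for desk-size runs.
#'
#' @param task `"gender"`, `"age"`, or `"disease"`.
#' @param dataset_version `"Ver_NMF"` or `"Ver_ORG"`; must match the tag of
#'   the records the phase is run on.
#' @param learning_rate Adam learning rate (default by task).
#' @param epochs Training epochs (default by task).
#' @param batch_size Images per batch.
#' @param loss_params A [margin_loss_params()].
#' @param class_weighting Use inverse-frequency class weights in the loss.
#' @return A `phase_config` list.
#' @export
phase_config <- function(task, dataset_version,
                         learning_rate = NULL, epochs = NULL, batch_size = 32,
                         loss_params = margin_loss_params(),
                         class_weighting = FALSE) {
  tc <- task_classes(task)
  if (!dataset_version %in% c("Ver_ORG", "Ver_NMF")) {
    abort("dataset_version must be Ver_ORG or Ver_NMF")
  }
  structure(
    list(
      task = task, dataset_version = dataset_version,
      learning_rate = learning_rate %||% if (task == "disease") 1e-4 else 1e-3,
      epochs = epochs %||% if (task == "disease") 100L else 10L,
      batch_size = batch_size, n_classes = length(tc$classes),
      task_kind = tc$kind, loss_params = loss_params,
      class_weighting = class_weighting
    ),
    class = "phase_config"
  )
}

#' Train the model for one phase
#'
#' Trains with Adam on the margin loss over the `train` role of `records`,
#' evaluating on the `val` role after every epoch, and returns the
#' best-validation checkpoint (highest validation accuracy for single-label
#' tasks, highest validation macro-AUC for the disease task). The model head
#' must already match the phase's task (see [swap_head()]).
#'
#' @param model A `dual_stream_model` whose head matches the task.
#' @param records Record tibble with roles, tagged with its dataset version.
#' @param cfg A [phase_config()].
#' @param verbose Print one line per epoch.
#' @return A `chestnet_phase`: list with `model` (best checkpoint), `log`
#'   (one-row-per-epoch tibble), `cfg`, `best_epoch`, `train_ids`.
#' @export
run_phase <- function(model, records, cfg, verbose = FALSE) {
  tag <- version_tag(records)
  if (!is.na(tag) && tag != cfg$dataset_version) {
    abort(sprintf(
      paste0(
        "dataset version mismatch: a %s phase on %s breaks the variant naming ",
        "convention <TASK>_<VERSION> (GD_NMF, AD_NMF, DD_ORG, GD_ORG, AD_ORG); ",
        "these records are tagged %s"
      ),
      cfg$task, cfg$dataset_version, tag
    ))
  }
  if (model$cfg$n_classes != cfg$n_classes) {
    abort(sprintf(
      "model head has %d classes but task '%s' needs %d; call swap_head() first",
      model$cfg$n_classes, cfg$task, cfg$n_classes
    ))
  }
  train_rec <- records[records$role == "train", ]
  val_rec <- records[records$role == "val", ]
  x_train <- records_to_input(train_rec, model$cfg$input_size)
  t_train <- task_targets(train_rec, cfg$task)
  x_val <- if (nrow(val_rec) > 0) records_to_input(val_rec, model$cfg$input_size)
  t_val <- if (nrow(val_rec) > 0) task_targets(val_rec, cfg$task)
  weights <- if (cfg$class_weighting) inverse_frequency_weights(t_train)
  n <- nrow(train_rec)
  opt <- adam_init(model$params)
  log <- list()
  best <- list(metric = -Inf, loss = Inf, model = model, epoch = 0L)
  if (cfg$epochs == 0) {
    return(structure(
      list(
        model = model, log = tibble(), cfg = cfg, best_epoch = 0L,
        train_ids = character(0)
      ),
      class = "chestnet_phase"
    ))
  }
  for (epoch in seq_len(cfg$epochs)) {
    perm <- sample.int(n)
    epoch_loss <- 0
    epoch_correct <- 0
    for (start in seq(1, n, by = cfg$batch_size)) {
      sel <- perm[start:min(start + cfg$batch_size - 1, n)]
      xb <- x_train[, , , sel, drop = FALSE]
      tb <- t_train[sel, , drop = FALSE]
      fw <- model_forward(model, xb, training = TRUE, keep_cache = TRUE)
      model$bn_state <- fw$bn_state
      loss <- margin_loss(fw$scores, tb, cfg$loss_params, weights)
      dscores <- margin_loss_grad(fw$scores, tb, cfg$loss_params, weights)
      bk <- model_backward(model, fw$cache, dscores)
      step <- adam_step(model$params, bk$grads, opt, cfg$learning_rate)
      model$params <- step$params
      opt <- step$state
      epoch_loss <- epoch_loss + loss * length(sel)
      epoch_correct <- epoch_correct + batch_correct(fw$scores, tb, cfg$task_kind)
    }
    val <- evaluate_split(model, x_val, t_val, cfg)
    metric <- if (cfg$task_kind == "multi") val$macro_auc else val$acc
    # ties on the validation metric are broken by validation loss, so a
    # saturated metric still selects the better-converged model
    if (!is.na(metric) &&
      (metric > best$metric ||
        (metric == best$metric && !is.na(val$loss) && val$loss < best$loss))) {
      best <- list(metric = metric, loss = val$loss, model = model, epoch = epoch)
    }
    log[[epoch]] <- tibble(
      epoch = epoch,
      train_loss = epoch_loss / n,
      train_acc = epoch_correct / n,
      val_loss = val$loss, val_acc = val$acc, val_macro_auc = val$macro_auc
    )
    if (verbose) {
      message(sprintf(
        "  epoch %d/%d: train loss %.4f acc %.3f | val loss %.4f acc %.3f auc %.3f",
        epoch, cfg$epochs, epoch_loss / n, epoch_correct / n,
        val$loss, val$acc, val$macro_auc
      ))
    }
  }
  if (!is.finite(best$metric)) {
    best <- list(metric = NA_real_, model = model, epoch = cfg$epochs)
  }
  structure(
    list(
      model = best$model, log = dplyr::bind_rows(log), cfg = cfg,
      best_epoch = best$epoch, train_ids = unique(train_rec$image_id)
    ),
    class = "chestnet_phase"
  )
}

batch_correct <- function(scores, targets, kind) {
  if (kind == "single") {
    sum(max.col(scores, ties.method = "first") == max.col(targets, ties.method = "first"))
  } else {
    # mean per-class accuracy at the 0.5 threshold, summed over the batch
    sum(rowMeans((scores > 0.5) == (targets == 1)))
  }
}

evaluate_split <- function(model, x, t_mat, cfg, batch_size = 64) {
  if (is.null(x) || dim(x)[4] == 0) {
    return(list(loss = NA_real_, acc = NA_real_, macro_auc = NA_real_))
  }
  n <- dim(x)[4]
  scores <- matrix(NA_real_, n, ncol(t_mat))
  for (start in seq(1, n, by = batch_size)) {
    sel <- start:min(start + batch_size - 1, n)
    scores[sel, ] <- model_forward(model, x[, , , sel, drop = FALSE])$scores
  }
  loss <- margin_loss(scores, t_mat, cfg$loss_params)
  acc <- batch_correct(scores, t_mat, cfg$task_kind) / n
  macro_auc <- if (cfg$task_kind == "multi") {
    aucs <- vapply(seq_len(ncol(t_mat)), function(k) {
      if (length(unique(t_mat[, k])) < 2) {
        return(NA_real_)
      }
      auc_rank(scores[, k], t_mat[, k])
    }, numeric(1))
    mean(aucs, na.rm = TRUE)
  } else {
    NA_real_
  }
  list(loss = loss, acc = acc, macro_auc = macro_auc)
}

protocol_variants <- c(
  "GD_NMF", "GD_NMF=>AD_NMF", "GD_NMF=>AD_NMF=>DD_ORG", "AD_NMF",
  "GD_NMF=>DD_ORG", "AD_NMF=>DD_ORG", "GD_ORG", "AD_ORG", "DD_ORG"
)

#' Parse a protocol variant name into its phase chain
#'
#' Variant names chain `<TASK>_<VERSION>` tokens with `=>`: `GD`/`AD`/`DD` for
#' gender/age/disease detection, `NMF`/`ORG` for the dataset version. The nine
#' valid variants cover single-task baselines and the partial and full
#' transfer chains.
#'
#' @param variant Variant name, e.g. `"GD_NMF=>AD_NMF=>DD_ORG"` (whitespace
#'   around `=>` is ignored).
#' @return Tibble with one row per phase: `task`, `dataset_version`.
#' @export
parse_variant <- function(variant) {
  norm <- gsub("\\s", "", variant)
  if (!norm %in% gsub("\\s", "", protocol_variants)) {
    abort(sprintf(
      "unknown variant '%s'; valid variants: %s",
      variant, paste(protocol_variants, collapse = ", ")
    ))
  }
  tokens <- strsplit(norm, "=>", fixed = TRUE)[[1]]
  tibble(
    task = dplyr::case_match(substr(tokens, 1, 2), "GD" ~ "gender", "AD" ~ "age", "DD" ~ "disease"),
    dataset_version = paste0("Ver_", substr(tokens, 4, 6))
  )
}

#' Run a (possibly chained) training protocol variant
#'
#' Executes the phase chain encoded by the variant name: each phase trains on
#' the dataset version its token names, and each later phase starts from the
#' previous phase's best backbone with a freshly initialized head
#' ([swap_head()]). All randomness (weight init, shuffling, dropout, head
#' re-init) flows from `seed`.
#'
#' @param variant One of the nine variant names (see [parse_variant()]).
#' @param versions Named list with elements `Ver_ORG` and `Ver_NMF`, record
#'   tibbles sharing ids, labels and roles.
#' @param seed Integer seed for the whole run.
#' @param model_cfg Optional base [model_config()]; its head fields are
#'   overridden per phase.
#' @param epochs Optional vector of epoch overrides, one per phase (recycled).
#' @param learning_rates Optional vector of learning-rate overrides per phase.
#' @param batch_size Batch size for all phases.
#' @param loss_params A [margin_loss_params()] shared by all phases.
#' @param class_weighting Use inverse-frequency class weights in the loss.
#' @param verbose Print per-epoch progress.
#' @return A `chestnet_run`: list with `variant`, `phases` (list of
#'   `chestnet_phase`), `model` (final best model), `seed`,
#'   `backbone_chain` (per-phase start/end backbone checksums).
#' @export
run_protocol <- function(variant, versions, seed = 1, model_cfg = NULL,
                         epochs = NULL, learning_rates = NULL,
                         batch_size = 32, loss_params = margin_loss_params(),
                         class_weighting = FALSE, verbose = FALSE) {
  chain <- parse_variant(variant)
  for (v in unique(chain$dataset_version)) {
    if (is.null(versions[[v]])) {
      abort(sprintf("variant %s needs dataset version %s, which was not supplied", variant, v))
    }
  }
  input_size <- nrow(versions[[chain$dataset_version[1]]]$pixels[[1]])
  model_cfg <- model_cfg %||% model_config(input_size = input_size)
  with_local_seed(seed, {
    model <- NULL
    phases <- list()
    checks <- list()
    for (i in seq_len(nrow(chain))) {
      task <- chain$task[i]
      tc <- task_classes(task)
      if (is.null(model)) {
        cfg_i <- model_cfg
        cfg_i$n_classes <- length(tc$classes)
        cfg_i$task <- tc$kind
        model <- build_model(cfg_i)
      } else {
        model <- swap_head(model, length(tc$classes), tc$kind)
      }
      start_checksum <- model_checksum(model, "backbone")
      pcfg <- phase_config(
        task, chain$dataset_version[i],
        learning_rate = if (!is.null(learning_rates)) {
          learning_rates[min(i, length(learning_rates))]
        },
        epochs = if (!is.null(epochs)) as.integer(epochs[min(i, length(epochs))]),
        batch_size = batch_size, loss_params = loss_params,
        class_weighting = class_weighting
      )
      if (verbose) {
        message(sprintf(
          "phase %d/%d: %s on %s (%d epochs, lr %g)",
          i, nrow(chain), task, pcfg$dataset_version, pcfg$epochs, pcfg$learning_rate
        ))
      }
      phase <- run_phase(model, versions[[chain$dataset_version[i]]], pcfg, verbose)
      model <- phase$model
      phases[[i]] <- phase
      checks[[i]] <- tibble(
        phase = i, task = task,
        backbone_start = start_checksum,
        backbone_end = model_checksum(model, "backbone")
      )
    }
    structure(
      list(
        variant = variant, phases = phases, model = model, seed = seed,
        backbone_chain = dplyr::bind_rows(checks)
      ),
      class = "chestnet_run"
    )
  })
}

#' Evaluate a trained model on the test split of a record set
#'
#' @param model A `dual_stream_model`.
#' @param records Record tibble with roles.
#' @param task Task whose labels to evaluate against.
#' @param role Which role to evaluate (default `"test"`).
#' @return A [metrics_report()] tibble.
#' @export
evaluate_model <- function(model, records, task, role = "test") {
  rec <- records[records$role == role, ]
  if (nrow(rec) == 0) abort(sprintf("no records with role '%s'", role))
  tc <- task_classes(task)
  x <- records_to_input(rec, model$cfg$input_size)
  t_mat <- task_targets(rec, task)
  scores <- matrix(NA_real_, nrow(rec), length(tc$classes), dimnames = list(NULL, tc$classes))
  for (start in seq(1, nrow(rec), by = 64)) {
    sel <- start:min(start + 63, nrow(rec))
    scores[sel, ] <- model_forward(model, x[, , , sel, drop = FALSE])$scores
  }
  metrics_report(scores, t_mat, rule = if (tc$kind == "single") "argmax" else "threshold")
}

#' @export
print.chestnet_run <- function(x, ...) {
  cat(sprintf(
    "<chestnet_run> %s (seed %d): %d phase(s)\n", x$variant, x$seed,
    length(x$phases)
  ))
  invisible(x)
}

#' Tidy the per-epoch training log of a protocol run
#'
#' @param x A `chestnet_run`.
#' @param ... Unused.
#' @return Tibble with `phase`, `task`, `epoch`, and the logged metrics.
#' @export
tidy.chestnet_run <- function(x, ...) {
  purrr::imap(x$phases, function(ph, i) {
    if (nrow(ph$log) == 0) {
      return(tibble())
    }
    mutate(ph$log, phase = i, task = ph$cfg$task, .before = 1)
  }) |> dplyr::bind_rows()
}

#' One-row summary of a protocol run
#'
#' @param x A `chestnet_run`.
#' @param ... Unused.
#' @return Tibble with the variant, phase count, final task, its best
#'   validation metric and best epoch.
#' @export
glance.chestnet_run <- function(x, ...) {
  last <- x$phases[[length(x$phases)]]
  metric <- if (last$cfg$task_kind == "multi") "val_macro_auc" else "val_acc"
  tibble(
    variant = x$variant,
    n_phases = length(x$phases),
    final_task = last$cfg$task,
    best_epoch = last$best_epoch,
    best_val_metric = if (nrow(last$log) > 0) last$log[[metric]][last$best_epoch] else NA_real_
  )
}
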
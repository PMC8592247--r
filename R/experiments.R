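#' Desk-scale transfer experiment: sequential chain vs. training from scratch
#'
#' For each seed: generate a class-balanced phantom corpus, split 80/10/10,
#' balance the training pool by rotation, build Ver_ORG and Ver_NMF, then train
#' the full sequential chain (gender on Ver_NMF, age on Ver_NMF, disease on
#' Ver_ORG) and the single-phase disease baseline from scratch, and evaluate
#' both on the shared test split. The comparison measures whether
#' anatomy-first pretraining transfers to disease detection.
#'
#' @param seeds Integer vector of experiment seeds (one replicate per seed).
#' @param n_subjects Phantom corpus size per replicate.
#' @param image_size Phantom/model input side (divisible by 8).
#' @param filters Conv widths per block for the desk-scale model.
#' @param epochs Per-phase epochs of the chain (the baseline uses the final
#'   phase's epochs).
#' @param nmf_kappa,nmf_max_iter NMF settings for Ver_NMF.
#' @param verbose Print progress.
#' @return Tibble with one row per seed: test macro-AUC of the chain and of
#'   the scratch baseline, their difference, and the gender/age test
#'   accuracies of the intermediate phase models.
#' @export
transfer_experiment <- function(seeds = 1:5, n_subjects = 500, image_size = 64,
                                filters = c(4, 8, 16), epochs = c(2, 2, 5),
                                nmf_kappa = 6, nmf_max_iter = 60,
                                verbose = FALSE) {
  purrr::map(seeds, function(seed) {
    pc <- phantom_config(
      image_size = image_size, n_subjects = n_subjects,
      disease_sampling = "balanced", seed = seed
    )
    rec <- generate_phantoms(pc)
    rec <- split_dataset(rec, seed = seed + 1, by = "disease")
    train_part <- rec[rec$role == "train", ]
    bal <- with_local_seed(
      seed + 2,
      augment_balance(train_part, by = "disease")
    )
    bal$role <- "train"
    rec <- dplyr::bind_rows(bal, rec[rec$role != "train", ])
    org <- make_version_org(rec)
    nmf <- make_version_nmf(
      rec,
      nmf_config(kappa = nmf_kappa, max_iter = nmf_max_iter, seed = seed + 3),
      clahe_config()
    )
    versions <- list(Ver_ORG = org, Ver_NMF = nmf)
    mcfg <- model_config(
      input_size = image_size, filters = filters,
      embedding_len = 8
    )
    chain <- run_protocol("GD_NMF=>AD_NMF=>DD_ORG", versions,
      seed = seed + 4,
      model_cfg = mcfg, epochs = epochs, verbose = verbose
    )
    scratch <- run_protocol("DD_ORG", versions,
      seed = seed + 4,
      model_cfg = mcfg, epochs = epochs[length(epochs)], verbose = verbose
    )
    chain_rep <- evaluate_model(chain$model, org, "disease")
    scratch_rep <- evaluate_model(scratch$model, org, "disease")
    gender_rep <- evaluate_model(chain$phases[[1]]$model, nmf, "gender")
    age_rep <- evaluate_model(chain$phases[[2]]$model, nmf, "age")
    macro <- function(rep_, col) rep_[[col]][rep_$class == "macro"]
    tibble(
      seed = seed,
      chain_auc = macro(chain_rep, "auc"),
      scratch_auc = macro(scratch_rep, "auc"),
      auc_gain = macro(chain_rep, "auc") - macro(scratch_rep, "auc"),
      gender_acc = mean(gender_rep$accuracy[gender_rep$class != "macro"]),
      age_acc = mean(age_rep$accuracy[age_rep$class != "macro"])
    )
  }) |> dplyr::bind_rows()
}

#' Synthetic records with a class feature planted in one zone
#'
#' Binary task for attention-localization checks: positive images carry a
#' bright disc centred in `zone` (well inside it, so the disc and its edges
#' stay within the zone); negative images are background only. Labels reuse
#' the gender head (positive = Male).
#'
#' @param n Number of images.
#' @param seed RNG seed.
#' @param zone Target zone name (`"Z11"` ... `"Z33"`).
#' @param image_size Side length (divisible by 8 for model use).
#' @param background,noise_sd Background gray level and noise SD.
#' @param amplitude Added disc brightness (gray levels).
#' @return Record tibble compatible with the training functions.
#' @export
planted_zone_records <- function(n, seed, zone = "Z11", image_size = 64,
                                 background = 5, noise_sd = 3, amplitude = 140) {
  z <- zone_partition(image_size)
  target <- z[z$zone == zone, ]
  if (nrow(target) == 0) abort(sprintf("unknown zone %s", zone))
  with_local_seed(seed, {
    positive <- runif(n) < 0.5
    rows <- matrix(seq_len(image_size), image_size, image_size)
    cols <- matrix(seq_len(image_size), image_size, image_size, byrow = TRUE)
    cy <- (target$row_start + target$row_end) / 2
    cx <- (target$col_start + target$col_end) / 2
    r <- (target$row_end - target$row_start + 1) / 3
    disc <- (rows - cy)^2 + (cols - cx)^2 <= r^2
    pixels <- map(seq_len(n), function(i) {
      img <- matrix(background + abs(rnorm(image_size^2, sd = noise_sd)),
        image_size, image_size
      )
      if (positive[i]) img <- img + amplitude * disc
      clip255(img)
    })
    tibble(
      image_id = sprintf("planted_%04d.png", seq_len(n)),
      pixels = pixels,
      gender = ifelse(positive, "Male", "Female"),
      age_years = 40L, age_bin = "Age_31-120",
      diseases = rep(list(character(0)), n)
    )
  })
}

#' Attention-localization experiment on planted-feature images
#'
#' For each seed: train a small model to detect the planted disc
#' ([planted_zone_records()]), then profile the Grad-CAM attention of the
#' positive class over the nine zones on the test split. The planted zone
#' should dominate the profile.
#'
#' @param seeds Integer vector of experiment seeds.
#' @param zone Planted zone.
#' @param n Images per replicate.
#' @param image_size Side length.
#' @param filters Conv widths.
#' @param epochs,batch_size Training settings.
#' @return Tibble per seed: `top_zone`, `target_fraction`, `max_other`,
#'   `val_acc`, `n_images`.
#' @export
localization_experiment <- function(seeds = 1:5, zone = "Z11", n = 120,
                                    image_size = 64, filters = c(4, 8, 16),
                                    epochs = 12, batch_size = 8) {
  purrr::map(seeds, function(seed) {
    rec <- planted_zone_records(n, seed, zone = zone, image_size = image_size)
    rec <- split_dataset(rec, seed = seed + 10, by = "gender")
    org <- make_version_org(rec)
    m <- build_model(
      model_config(
        input_size = image_size, filters = filters,
        embedding_len = 4
      ),
      seed = seed
    )
    ph <- with_local_seed(seed + 20, {
      run_phase(m, org, phase_config("gender", "Ver_ORG",
        epochs = epochs,
        batch_size = batch_size
      ))
    })
    prof <- suppressWarnings(
      zone_profile(ph$model, rec[rec$role == "test", ], "gender", "Male")
    )
    found <- prof$n_images[1] > 0
    tibble(
      seed = seed,
      top_zone = if (found) prof$zone[which.max(prof$fraction)] else NA_character_,
      target_fraction = if (found) prof$fraction[prof$zone == zone] else NA_real_,
      max_other = if (found) max(prof$fraction[prof$zone != zone]) else NA_real_,
      val_acc = max(ph$log$val_acc),
      n_images = prof$n_images[1]
    )
  }) |> dplyr::bind_rows()
}
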
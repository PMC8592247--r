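#' Configuration for the chest-phantom generator
#'
#' The phantom is a minimal chest geometry on a dark background: two shoulder
#' bands whose thickness depends on gender, two lung-field ellipses whose
#' vertical aspect depends on the age bin, and a central spine column. Each
#' disease label adds one bright blob at a class-specific position inside a
#' lung-field ellipse, so anatomy-driven and disease-driven image structure are
#' spatially separable by construction.
#'
#' @param image_size Pixels per side (square), >= 32.
#' @param n_subjects Number of phantoms to generate.
#' @param gender_geometry_effect Relative difference in shoulder-band thickness
#'   between Male and Female (unitless fraction of the base thickness).
#' @param age_geometry_effect Length-4 vector of relative deltas applied to the
#'   lung ellipse vertical semi-axis, one per age bin; must be monotone so the
#'   age cue is learnable.
#' @param disease_blob_intensity Additive blob brightness as a fraction of the
#'   8-bit range, in `[0, 1]`.
#' @param disease_blob_radius Base blob radius in pixels at `image_size = 128`
#'   (scaled proportionally for other sizes).
#' @param disease_prevalence Per-class probability that a subject carries each
#'   of the 14 disease labels under `disease_sampling = "independent"`.
#' @param disease_sampling `"independent"`: each label is an independent
#'   Bernoulli(`disease_prevalence`) draw, emulating the rarity structure of a
#'   clinical corpus. `"balanced"`: each subject draws one primary label
#'   uniformly from the 14 diseases plus no-finding (with a 15% chance of one
#'   additional label), giving near-equal class counts so rotation balancing
#'   stays cheap at desk scale.
#' @param noise_sd Additive Gaussian pixel noise SD in gray levels (>= 0).
#' @param seed RNG seed; identical (config, seed) pairs give byte-identical
#'   image sets.
#' @return A `phantom_config` list.
#' @export
phantom_config <- function(image_size = 128, n_subjects = 100,
                           gender_geometry_effect = 0.3,
                           age_geometry_effect = c(-0.15, -0.05, 0.05, 0.15),
                           disease_blob_intensity = 0.4,
                           disease_blob_radius = 8,
                           disease_prevalence = 0.07,
                           disease_sampling = c("independent", "balanced"),
                           noise_sd = 8, seed = 1) {
  disease_sampling <- match.arg(disease_sampling)
  cfg <- list(
    image_size = image_size, n_subjects = n_subjects,
    gender_geometry_effect = gender_geometry_effect,
    age_geometry_effect = age_geometry_effect,
    disease_blob_intensity = disease_blob_intensity,
    disease_blob_radius = disease_blob_radius,
    disease_prevalence = disease_prevalence,
    disease_sampling = disease_sampling,
    noise_sd = noise_sd, seed = seed
  )
  class(cfg) <- "phantom_config"
  validate_phantom_config(cfg)
  cfg
}

validate_phantom_config <- function(cfg) {
  if (!is_count(cfg$image_size) || cfg$image_size < 32) {
    abort("phantom_config: image_size must be an integer >= 32")
  }
  if (!is_count(cfg$n_subjects)) abort("phantom_config: n_subjects must be a non-negative integer")
  for (f in c("gender_geometry_effect", "disease_blob_intensity", "disease_blob_radius")) {
    if (!is.numeric(cfg[[f]]) || length(cfg[[f]]) != 1 || !is.finite(cfg[[f]])) {
      abort(sprintf("phantom_config: %s must be a finite scalar", f))
    }
  }
  if (length(cfg$age_geometry_effect) != 4 || any(!is.finite(cfg$age_geometry_effect))) {
    abort("phantom_config: age_geometry_effect must be 4 finite deltas (one per age bin)")
  }
  if (cfg$disease_blob_intensity < 0 || cfg$disease_blob_intensity > 1) {
    abort("phantom_config: disease_blob_intensity must lie in [0, 1]")
  }
  if (!is.finite(cfg$noise_sd) || cfg$noise_sd < 0) {
    abort("phantom_config: noise_sd must be >= 0")
  }
  if (cfg$disease_prevalence < 0 || cfg$disease_prevalence > 1) {
    abort("phantom_config: disease_prevalence must lie in [0, 1]")
  }
  if (!cfg$disease_sampling %in% c("independent", "balanced")) {
    abort("phantom_config: disease_sampling must be independent or balanced")
  }
  # blob must fit inside a lung ellipse at this size
  geo <- phantom_geometry(cfg$image_size, 0, "Male", cfg)
  r <- blob_radius_px(cfg)
  if (r >= min(geo$lung_a, geo$lung_b) * 0.4) {
    abort(paste0(
      "phantom_config: disease_blob_radius too large for image_size ",
      cfg$image_size, " (blobs must fit inside the lung-field ellipses)"
    ))
  }
  invisible(cfg)
}

blob_radius_px <- function(cfg) cfg$disease_blob_radius * cfg$image_size / 128

# geometry of one phantom, all coordinates in pixels (row = y, col = x).
# gender alters only the shoulder-band thickness; the age bin alters only the
# lung-ellipse vertical semi-axis.
phantom_geometry <- function(s, age_bin_index, gender, cfg) {
  band_base <- 0.055 * s
  half <- cfg$gender_geometry_effect / 2
  band_h <- band_base * (1 + if (gender == "Male") half else -half)
  age_delta <- if (age_bin_index >= 1) cfg$age_geometry_effect[age_bin_index] else 0
  list(
    background = 20,
    band_top = 0.05 * s, band_h = band_h,
    band_cols_left = c(0.05, 0.38) * s, band_cols_right = c(0.62, 0.95) * s,
    band_level = 200,
    lung_cx = c(0.30, 0.70) * s, lung_cy = 0.55 * s,
    lung_a = 0.16 * s, lung_b = 0.28 * s * (1 + age_delta),
    lung_level = 90,
    spine_cols = c(0.47, 0.53) * s, spine_rows = c(0.16, 0.92) * s,
    spine_level = 160
  )
}

# class-specific blob placement: (lung side, fractional position within the
# ellipse, radius multiplier); positions lie within the 0.55-radius unit disc so
# blob centres are strictly inside the lung field
disease_blob_params <- function() {
  tibble(
    disease = chest_diseases,
    side = rep(c(1L, 2L), 7),
    fx = c(-0.35, 0.35, 0.0, -0.5, 0.5, -0.2, 0.2, 0.0, -0.4, 0.4, 0.0, -0.25, 0.25, 0.0),
    fy = c(-0.45, -0.45, -0.25, 0.0, 0.0, 0.25, 0.25, -0.5, 0.45, 0.45, 0.0, -0.1, -0.1, 0.5),
    rmult = c(1, 1, 1.3, 0.8, 1.1, 0.9, 1, 1.2, 0.8, 1, 0.7, 1.1, 0.9, 1)
  )
}

#' Render a single chest phantom
#'
#' Deterministic given its arguments; noise is drawn from the current RNG
#' stream (set a seed for reproducibility, or `noise_sd = 0` for a noise-free
#' render). Used by [generate_phantoms()] and directly by paired-render tests
#' (a record and its disease-free twin differ only inside the blob discs).
#'
#' @param gender `"Male"` or `"Female"`.
#' @param age_years Age in years (1-120).
#' @param diseases Character vector of disease labels (possibly empty).
#' @param cfg A [phantom_config()].
#' @return Integer-valued matrix `image_size` x `image_size` in `[0, 255]`.
#' @export
render_phantom <- function(gender, age_years, diseases, cfg) {
  s <- cfg$image_size
  bin_idx <- match(age_bin(age_years), age_bins)
  geo <- phantom_geometry(s, bin_idx, gender, cfg)
  img <- matrix(geo$background, s, s)
  rows <- matrix(seq_len(s), s, s)          # row index (y)
  cols <- matrix(seq_len(s), s, s, byrow = TRUE)  # col index (x)

  # shoulder bands (top left / top right)
  in_band_rows <- rows >= geo$band_top & rows < geo$band_top + geo$band_h
  img[in_band_rows & cols >= geo$band_cols_left[1] & cols <= geo$band_cols_left[2]] <- geo$band_level
  img[in_band_rows & cols >= geo$band_cols_right[1] & cols <= geo$band_cols_right[2]] <- geo$band_level

  # lung-field ellipses
  for (k in 1:2) {
    d2 <- ((cols - geo$lung_cx[k]) / geo$lung_a)^2 + ((rows - geo$lung_cy) / geo$lung_b)^2
    img[d2 <= 1] <- geo$lung_level
  }

  # spine column drawn over the lungs' medial edges
  img[rows >= geo$spine_rows[1] & rows <= geo$spine_rows[2] &
    cols >= geo$spine_cols[1] & cols <= geo$spine_cols[2]] <- geo$spine_level

  # one blob per disease label, centred inside a lung-field ellipse, with a
  # cosine edge profile
  if (length(diseases) > 0) {
    bp <- disease_blob_params()
    for (d in diseases) {
      p <- bp[bp$disease == d, ]
      if (nrow(p) == 0) abort(sprintf("unknown disease label: %s", d))
      cx <- geo$lung_cx[p$side] + p$fx * geo$lung_a
      cy <- geo$lung_cy + p$fy * geo$lung_b
      r <- blob_radius_px(cfg) * p$rmult
      dist <- sqrt((cols - cx)^2 + (rows - cy)^2)
      w <- ifelse(dist <= r, 0.5 * (1 + cos(pi * dist / r)), 0)
      img <- img + cfg$disease_blob_intensity * 255 * w
    }
  }

  if (cfg$noise_sd > 0) img <- img + rnorm(s * s, sd = cfg$noise_sd)
  clip255(img)
}

#' Generate a collection of synthetic chest phantoms
#'
#' Draws subject covariates (gender ~ Bernoulli(0.5); age uniform over the four
#' bins, then uniform within the bin; each disease label an independent
#' Bernoulli with probability `disease_prevalence`), renders each phantom, and
#' returns one record per subject. All randomness flows from `cfg$seed`.
#'
#' @param cfg A [phantom_config()].
#' @return Tibble with columns `image_id`, `pixels` (list of matrices),
#'   `gender`, `age_years`, `age_bin`, `diseases` (list of character vectors).
#' @export
#' @examples
#' rec <- generate_phantoms(phantom_config(image_size = 64, n_subjects = 3))
#' rec$image_id
generate_phantoms <- function(cfg) {
  stopifnot(inherits(cfg, "phantom_config"))
  validate_phantom_config(cfg)
  n <- cfg$n_subjects
  if (n == 0) {
    return(tibble(
      image_id = character(0), pixels = list(), gender = character(0),
      age_years = integer(0), age_bin = character(0), diseases = list()
    ))
  }
  with_local_seed(cfg$seed, {
    gender <- ifelse(runif(n) < 0.5, "Male", "Female")
    bin_idx <- sample.int(4, n, replace = TRUE)
    lo <- c(1, 11, 21, 31)[bin_idx]
    hi <- c(10, 20, 30, 100)[bin_idx]
    age <- as.integer(lo + floor(runif(n) * (hi - lo + 1)))
    diseases <- if (cfg$disease_sampling == "independent") {
      map(seq_len(n), function(i) {
        chest_diseases[runif(length(chest_diseases)) < cfg$disease_prevalence]
      })
    } else {
      # near-equal class counts: one primary label uniform over the 14
      # diseases plus no-finding, with a 15% chance of a second label
      primary <- sample(c(chest_diseases, NA), n, replace = TRUE)
      map(seq_len(n), function(i) {
        d <- primary[i]
        if (is.na(d)) {
          return(character(0))
        }
        if (runif(1) < 0.15) {
          extra <- sample(setdiff(chest_diseases, d), 1)
          sort(c(d, extra))
        } else {
          d
        }
      })
    }
    pixels <- map(seq_len(n), function(i) {
      render_phantom(gender[i], age[i], diseases[[i]], cfg)
    })
    tibble(
      image_id = sprintf("phantom_%05d.png", seq_len(n)),
      pixels = pixels,
      gender = gender,
      age_years = age,
      age_bin = age_bin(age),
      diseases = diseases
    )
  })
}

#' Write phantom images as 8-bit grayscale PNG files
#'
#' @param records Record tibble with `image_id` and `pixels`.
#' @param dir Output directory (created if needed).
#' @return Vector of written paths, invisibly.
#' @export
write_phantom_pngs <- function(records, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- file.path(dir, records$image_id)
  purrr::walk2(records$pixels, paths, function(px, p) {
    png::writePNG(px / 255, p)
  })
  invisible(paths)
}

#' Read grayscale PNG images into a record tibble
#'
#' @param manifest_path Manifest CSV (see [read_manifest()]).
#' @param image_dir Directory holding one PNG per `image_id`.
#' @return Record tibble as from [generate_phantoms()].
#' @export
read_image_records <- function(manifest_path, image_dir) {
  rec <- read_manifest(manifest_path)
  rec$pixels <- map(rec$image_id, function(id) {
    px <- png::readPNG(file.path(image_dir, id))
    if (length(dim(px)) == 3) px <- px[, , 1]
    clip255(px * 255)
  })
  dplyr::relocate(rec, pixels, .after = image_id)
}
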
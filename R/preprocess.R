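#' Rotate an image about its centre, filling exposed corners with black
#'
#' @param image Numeric matrix in `[0, 255]`.
#' @param angle_deg Rotation angle in degrees.
#' @return Rotated image, same shape, 8-bit range.
#' @export
rotate_image <- function(image, angle_deg) {
  assert_pixels(image)
  rot <- EBImage::rotate(EBImage::Image(image / 255), angle_deg,
    output.dim = dim(image), bg.col = 0
  )
  clip255(as.matrix(EBImage::imageData(rot)) * 255)
}

#' Balance class counts by rotation-based oversampling
#'
#' Minority classes are oversampled with copies rotated by angles drawn
#' uniformly from `[-max_angle_deg, max_angle_deg]` until every class count
#' equals the majority count. Originals are retained; rotated copies get ids
#' derived as `<id>_augN` and record their angle in an `aug_angle` column
#' (`NA` for originals). The class of a record is its stratum under `by`:
#' `"disease"` uses the first (alphabetical) disease label or `"No Finding"`.
#'
#' @param records Record tibble.
#' @param max_angle_deg Maximum absolute rotation angle (default 30).
#' @param by Stratum: `"disease"`, `"gender"`, or `"age_bin"`.
#' @param classes Optional vector of class labels that must all be present;
#'   classes with zero records raise an error listing them.
#' @return Record tibble with equal per-class counts and an `aug_angle` column.
#' @export
augment_balance <- function(records, max_angle_deg = 30,
                            by = c("disease", "gender", "age_bin"),
                            classes = NULL) {
  by <- match.arg(by)
  strata <- record_strata(records, by)
  if (!is.null(classes)) {
    missing <- setdiff(classes, unique(strata))
    if (length(missing) > 0) {
      abort(sprintf(
        "cannot balance: class(es) with zero records: %s",
        paste(missing, collapse = ", ")
      ))
    }
  }
  if (nrow(records) == 0) abort("cannot balance an empty record set")
  if (!"aug_angle" %in% names(records)) records$aug_angle <- NA_real_
  counts <- table(strata)
  target <- max(counts)
  extra <- list()
  for (cls in names(counts)) {
    need <- target - counts[[cls]]
    if (need == 0) next
    pool <- which(strata == cls)
    src <- pool[((seq_len(need) - 1) %% length(pool)) + 1]
    angles <- runif(need, -max_angle_deg, max_angle_deg)
    copies <- records[src, ]
    copies$image_id <- sprintf(
      "%s_aug%d", sub("\\.png$", "", copies$image_id),
      seq_len(need)
    )
    copies$image_id <- paste0(copies$image_id, ".png")
    copies$pixels <- map2(records$pixels[src], angles, rotate_image)
    copies$aug_angle <- angles
    extra[[cls]] <- copies
  }
  if (length(extra) == 0) {
    return(records)
  }
  dplyr::bind_rows(records, dplyr::bind_rows(extra))
}

record_strata <- function(records, by) {
  switch(by,
    disease = primary_label(records$diseases),
    gender = records$gender,
    age_bin = records$age_bin
  )
}

#' Assign train/validation/test roles, stratified by class
#'
#' Within each class (stratum under `by`), role counts follow the largest-
#' remainder rule on `fractions`; remainder seats go to the role with the
#' largest fractional remainder, ties broken toward the globally most
#' under-filled role and then in the order train > val > test. Classes with
#' fewer than 3 members cannot fill three roles: they go entirely to `train`
#' with a warning. The same assignment is intended to be shared by all
#' dataset versions.
#'
#' @param records Record tibble.
#' @param fractions Named or positional fractions `c(train, val, test)`
#'   summing to 1.
#' @param seed Seed controlling which members land in which role.
#' @param by Stratum as in [augment_balance()].
#' @return `records` with a `role` column (`train`/`val`/`test`).
#' @export
split_dataset <- function(records, fractions = c(0.80, 0.10, 0.10), seed = 1,
                          by = c("disease", "gender", "age_bin")) {
  by <- match.arg(by)
  if (abs(sum(fractions) - 1) > 1e-8) abort("fractions must sum to 1")
  roles <- c("train", "val", "test")
  strata <- record_strata(records, by)
  n_total <- nrow(records)
  global_target <- n_total * fractions
  global_alloc <- c(0, 0, 0)
  role <- character(n_total)
  small <- character(0)
  with_local_seed(seed, {
    for (cls in sort(unique(strata))) {
      idx <- which(strata == cls)
      n <- length(idx)
      if (n < 3) {
        role[idx] <- "train"
        global_alloc <- global_alloc + c(n, 0, 0)
        small <- c(small, cls)
        next
      }
      base <- floor(n * fractions)
      rem <- n * fractions - base
      seats <- n - sum(base)
      alloc <- base
      if (seats > 0) {
        for (s in seq_len(seats)) {
          # largest remainder; ties toward the globally most under-filled
          # role, then train > val > test
          deficit <- global_target - (global_alloc + alloc)
          ord <- order(-rem, -deficit, seq_along(roles))
          pick <- ord[1]
          alloc[pick] <- alloc[pick] + 1
          rem[pick] <- -Inf
        }
      }
      global_alloc <- global_alloc + alloc
      shuffled <- sample(idx)
      role[shuffled] <- rep(roles, times = alloc)
    }
  })
  if (length(small) > 0) {
    warn(sprintf(
      "class(es) with fewer than 3 members assigned entirely to train: %s",
      paste(small, collapse = ", ")
    ))
  }
  records$role <- role
  records
}

#' Tag a record set as the original (augmented) dataset version
#'
#' @param records Record tibble (with roles assigned).
#' @return The records, tagged `Ver_ORG`.
#' @export
make_version_org <- function(records) {
  attr(records, "version_tag") <- "Ver_ORG"
  records
}

#' Build the NMF + CLAHE dataset version
#'
#' Each image is compressed with [nmf_compress()] and then enhanced with
#' [clahe_enhance()]; labels and roles are untouched, so the result is
#' label-isomorphic to the `Ver_ORG` version of the same records. The NMF
#' initialization seed for each image is derived from `nmf_cfg$seed` and the
#' image id, so per-image output is independent of batch composition.
#'
#' @param records Record tibble.
#' @param nmf_cfg An [nmf_config()].
#' @param clahe_cfg A [clahe_config()].
#' @return The records with transformed `pixels`, tagged `Ver_NMF`.
#' @export
make_version_nmf <- function(records, nmf_cfg = nmf_config(), clahe_cfg = clahe_config()) {
  out <- records
  out$pixels <- map2(records$pixels, records$image_id, function(px, id) {
    tryCatch(
      {
        cfg_i <- nmf_cfg
        cfg_i$seed <- image_seed(nmf_cfg$seed, id)
        compressed <- nmf_compress(px, cfg_i)$reconstruction
        clahe_enhance(compressed, clahe_cfg)
      },
      error = function(e) {
        abort(sprintf("Ver_NMF preprocessing failed for image %s: %s", id, conditionMessage(e)))
      }
    )
  })
  attr(out, "version_tag") <- "Ver_NMF"
  out
}

#' Dataset-version tag of a record set
#'
#' @param records Record tibble.
#' @return `"Ver_ORG"`, `"Ver_NMF"`, or `NA` if untagged.
#' @export
version_tag <- function(records) {
  attr(records, "version_tag") %||% NA_character_
}
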
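# Grad-CAM map combination: weights are the global-average-pooled gradients,
# the map is the ReLU of the weighted sum of feature maps
gradcam_combine <- function(activations, gradients) {
  stopifnot(all(dim(activations) == dim(gradients)))
  k <- dim(activations)[3]
  z <- dim(activations)[1] * dim(activations)[2]
  weights <- vapply(seq_len(k), function(j) sum(gradients[, , j]) / z, numeric(1))
  combined <- matrix(0, dim(activations)[1], dim(activations)[2])
  for (j in seq_len(k)) combined <- combined + weights[j] * activations[, , j]
  pmax(combined, 0)
}

upsample_bilinear <- function(map, size) {
  if (all(dim(map) == size)) {
    return(map)
  }
  as.matrix(EBImage::resize(EBImage::Image(map), w = size, h = size, filter = "bilinear"))
}

#' Grad-CAM saliency map for one image and class
#'
#' The class score \eqn{y^c = \|\nu_c\|} is differentiated with respect to the
#' final convolutional activations \eqn{A^k} of each stream; the
#' global-average-pooled gradients \eqn{a_k^c = \frac{1}{Z}\sum_{ij}
#' \partial y^c / \partial A^k_{ij}} weight the feature maps, and the
#' rectified weighted sum is bilinearly upsampled to the input size. With
#' `stream = "both"` (default) the two per-stream maps are upsampled and
#' averaged.
#'
#' @param model A `dual_stream_model`.
#' @param image `input_size` x `input_size` matrix of gray levels in
#'   `[0, 255]` (or already normalized to `[0, 1]`).
#' @param class_index Class to explain (1-based column of the score matrix).
#' @param stream `"both"`, `"s1"`, or `"s2"`.
#' @return A `gradcam_map`: list with `raw` (per-stream low-resolution maps),
#'   `upsampled` (input-size map), `class_index`, `score`.
#' @export
grad_cam <- function(model, image, class_index, stream = c("both", "s1", "s2")) {
  stream <- match.arg(stream)
  cfg <- model$cfg
  if (class_index < 1 || class_index > cfg$n_classes) {
    abort(sprintf(
      "class_index %d out of range (model has %d classes)",
      class_index, cfg$n_classes
    ))
  }
  if (max(image) > 1) image <- image / 255
  x <- array(image, c(cfg$input_size, cfg$input_size, 1, 1))
  fw <- model_forward(model, x, training = FALSE, keep_cache = TRUE)
  dscores <- matrix(0, 1, cfg$n_classes)
  dscores[1, class_index] <- 1
  bk <- model_backward(model, fw$cache, dscores)
  raws <- list()
  for (s in c("s1", "s2")) {
    a <- bk$last_act[[s]]
    g <- bk$d_last_act[[s]]
    raws[[s]] <- gradcam_combine(
      array(a, dim(a)[1:3]),
      array(g, dim(g)[1:3])
    )
  }
  upsampled <- switch(stream,
    s1 = upsample_bilinear(raws$s1, cfg$input_size),
    s2 = upsample_bilinear(raws$s2, cfg$input_size),
    both = (upsample_bilinear(raws$s1, cfg$input_size) +
      upsample_bilinear(raws$s2, cfg$input_size)) / 2
  )
  structure(
    list(
      raw = raws, upsampled = upsampled, stream = stream,
      class_index = class_index, score = fw$scores[1, class_index]
    ),
    class = "gradcam_map"
  )
}

#' The 3x3 zone grid of an image
#'
#' Nine rectangular zones Z11..Z33 partition the image: three equal row bands
#' by three equal column bands, with remainder pixels (sizes not divisible by
#' 3) assigned to the last band. Z11 is the top-left (right shoulder) zone,
#' Z13 the top-right; the middle row covers the rib cage and spine, the
#' bottom row the lung bases.
#'
#' @param image_size Side length in pixels (>= 3).
#' @return Tibble with `zone`, `row_start`, `row_end`, `col_start`, `col_end`,
#'   `n_pixels`.
#' @export
zone_partition <- function(image_size) {
  if (image_size < 3) abort("zone_partition needs image_size >= 3")
  b <- floor(image_size / 3)
  starts <- c(1, b + 1, 2 * b + 1)
  ends <- c(b, 2 * b, image_size)
  grid <- tidyr::expand_grid(r = 1:3, c = 1:3)
  mutate(grid,
    zone = sprintf("Z%d%d", .data$r, .data$c),
    row_start = starts[.data$r], row_end = ends[.data$r],
    col_start = starts[.data$c], col_end = ends[.data$c],
    n_pixels = (.data$row_end - .data$row_start + 1) *
      (.data$col_end - .data$col_start + 1)
  ) |>
    dplyr::select(zone, row_start, row_end, col_start, col_end, n_pixels)
}

# per-zone mean of a (min-max normalized) map, normalized to sum 1
zone_fractions <- function(map, zones) {
  rng <- range(map)
  norm <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map * 0
  means <- map_dbl(seq_len(nrow(zones)), function(i) {
    z <- zones[i, ]
    mean(norm[z$row_start:z$row_end, z$col_start:z$col_end])
  })
  if (sum(means) == 0) {
    return(rep(1 / nrow(zones), nrow(zones)))
  }
  means / sum(means)
}

#' Zone-wise attention profile of a class
#'
#' For every *correctly classified* test image of the class, the Grad-CAM map
#' is min-max normalized, averaged within each of the nine zones, and the nine
#' zone means are normalized to sum 1; the profile is the mean of these
#' per-image zone vectors. If no image of the class is classified correctly
#' the profile is returned empty (`n_images = 0`, `fraction` all `NA`) with a
#' warning rather than an error.
#'
#' @param model A trained `dual_stream_model`.
#' @param records Record tibble (typically the test role) with labels.
#' @param task `"gender"`, `"age"`, or `"disease"`.
#' @param class_label Class to profile (e.g. `"Male"`, `"Age_1-10"`,
#'   `"Effusion"`).
#' @param stream Stream choice passed to [grad_cam()].
#' @return A `zone_profile` tibble: `class`, `zone`, `fraction`, `n_images`.
#' @export
zone_profile <- function(model, records, task, class_label,
                         stream = c("both", "s1", "s2")) {
  stream <- match.arg(stream)
  tc <- task_classes(task)
  class_index <- match(class_label, tc$classes)
  if (is.na(class_index)) {
    abort(sprintf(
      "unknown class '%s' for task %s (expected one of: %s)",
      class_label, task, paste(tc$classes, collapse = ", ")
    ))
  }
  t_mat <- task_targets(records, task)
  x <- records_to_input(records, model$cfg$input_size)
  n <- nrow(records)
  scores <- matrix(NA_real_, n, model$cfg$n_classes)
  for (start in seq(1, n, by = 64)) {
    sel <- start:min(start + 63, n)
    scores[sel, ] <- model_forward(model, x[, , , sel, drop = FALSE])$scores
  }
  is_class <- t_mat[, class_index] == 1
  correct <- if (tc$kind == "single") {
    max.col(scores, ties.method = "first") == class_index
  } else {
    (scores[, class_index] > 0.5) == (t_mat[, class_index] == 1)
  }
  use <- which(is_class & correct)
  zones <- zone_partition(model$cfg$input_size)
  if (length(use) == 0) {
    warn(sprintf(
      "no correctly classified image of class '%s'; returning an empty profile",
      class_label
    ))
    return(structure(
      tibble(
        class = class_label, zone = zones$zone,
        fraction = NA_real_, n_images = 0L
      ),
      class = c("zone_profile", class(tibble()))
    ))
  }
  fracs <- vapply(use, function(i) {
    cam <- grad_cam(model, records$pixels[[i]], class_index, stream)
    zone_fractions(cam$upsampled, zones)
  }, numeric(nrow(zones)))
  structure(
    tibble(
      class = class_label, zone = zones$zone,
      fraction = rowMeans(fracs), n_images = length(use)
    ),
    class = c("zone_profile", class(tibble()))
  )
}

#' Overlay a saliency map on a grayscale image
#'
#' Alpha-blends a heat colormap of the map over the image: per-pixel blend
#' weight is `alpha` times the map value, so a zero map returns the image
#' rendered as RGB and a saturated map blends at `alpha` everywhere.
#'
#' @param image Gray-level matrix in `[0, 255]`.
#' @param map Saliency map of the same shape (any non-negative range; it is
#'   min-max normalized for display).
#' @param alpha Maximum blend weight in `[0, 1]`.
#' @return H x W x 3 RGB array in `[0, 1]`.
#' @export
overlay_attention <- function(image, map, alpha = 0.45) {
  if (!all(dim(image) == dim(map))) {
    abort(sprintf(
      "image (%s) and map (%s) shapes differ",
      paste(dim(image), collapse = "x"), paste(dim(map), collapse = "x")
    ))
  }
  rng <- range(map)
  m <- if (diff(rng) > 0) (map - rng[1]) / diff(rng) else map
  gray <- image / 255
  ramp <- grDevices::colorRamp(c("navy", "cyan", "yellow", "red"))(as.vector(m)) / 255
  out <- array(0, c(dim(image), 3))
  w <- alpha * m
  for (ch in 1:3) {
    heat <- matrix(ramp[, ch], nrow(image), ncol(image))
    out[, , ch] <- (1 - w) * gray + w * heat
  }
  out
}

#' @export
print.gradcam_map <- function(x, ...) {
  cat(sprintf(
    "<gradcam_map> class %d (%s stream), score %.3f, map %s\n",
    x$class_index, x$stream, x$score, paste(dim(x$upsampled), collapse = " x ")
  ))
  invisible(x)
}
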
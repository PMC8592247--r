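# internal helpers shared across modules

# stable per-image seed: mixes a base seed with the image id so that per-image
# randomness is independent of batch composition and ordering
image_seed <- function(base_seed, image_id) {
  h <- sum(utf8ToInt(image_id) * seq_along(utf8ToInt(image_id)))
  as.integer((base_seed + h * 2654435) %% 2147483647)
}

# run code with a local RNG state so library functions never disturb the
# caller's random stream
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_pixels <- function(px, what = "pixels") {
  if (!is.matrix(px) || !is.numeric(px)) {
    abort(sprintf("%s must be a numeric matrix", what))
  }
  if (any(px < 0) || any(px > 255)) {
    abort(sprintf("%s must lie in the 8-bit range [0, 255]", what))
  }
  invisible(px)
}

clip255 <- function(x) round(pmin(pmax(x, 0), 255))

is_count <- function(x) length(x) == 1 && is.finite(x) && x == round(x) && x >= 0

# checksum of a parameter list (used for backbone-preservation contracts)
param_hash <- function(x) rlang::hash(x)
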
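#' Configuration for contrast-limited adaptive histogram equalization
#'
#' CLAHE equalizes the histogram of each tile of a `nt[1]` x `nt[2]` grid
#' (rows x cols), clipping each tile histogram at a relative clip limit `cl`
#' before equalization, then bilinearly interpolates across tile borders to
#' remove seams. For a 512 x 512 image with `nt = c(8, 8)` the grid has 64
#' non-overlapping 64 x 64 tiles.
#'
#' @param nt Tile grid as `c(rows, cols)`, both >= 1.
#' @param cl Relative clip limit, > 0 (1 = plain tile size / bins slope; larger
#'   values allow more contrast amplification).
#' @return A `clahe_config` list.
#' @export
clahe_config <- function(nt = c(8, 8), cl = 2) {
  if (length(nt) != 2 || !all(nt >= 1) || any(nt != round(nt))) {
    abort("clahe_config: nt must be two integers >= 1 (rows, cols)")
  }
  if (!is.finite(cl) || cl <= 0) abort("clahe_config: cl must be > 0")
  structure(list(nt = as.integer(nt), cl = cl), class = "clahe_config")
}

#' Tile rectangles of the CLAHE grid for a given image size
#'
#' Image sides not divisible by the grid are padded by edge replication to the
#' next multiple before tiling (and cropped back after enhancement), so tiles
#' are always equal-sized; this helper reports the tiles on the padded canvas.
#'
#' @param dim Image dimensions `c(rows, cols)`.
#' @param cfg A [clahe_config()].
#' @return Tibble with one row per tile: `tile_row`, `tile_col`, `row_start`,
#'   `row_end`, `col_start`, `col_end` (padded-canvas coordinates), `height`,
#'   `width`.
#' @export
#' @examples
#' nrow(clahe_tiles(c(512, 512), clahe_config(nt = c(8, 8)))) # 64
clahe_tiles <- function(dim, cfg = clahe_config()) {
  padded <- ceiling(dim / cfg$nt) * cfg$nt
  th <- padded[1] / cfg$nt[1]
  tw <- padded[2] / cfg$nt[2]
  grid <- tidyr::expand_grid(tile_row = seq_len(cfg$nt[1]), tile_col = seq_len(cfg$nt[2]))
  dplyr::mutate(grid,
    row_start = (.data$tile_row - 1) * th + 1, row_end = .data$tile_row * th,
    col_start = (.data$tile_col - 1) * tw + 1, col_end = .data$tile_col * tw,
    height = th, width = tw
  )
}

#' Enhance an 8-bit grayscale image with CLAHE
#'
#' Wraps tile-based contrast-limited equalization with edge-replication
#' padding so any image size works with any grid; output has the input's shape
#' and 8-bit range. A constant image stays constant.
#'
#' @param image Numeric matrix of gray levels in `[0, 255]`.
#' @param cfg A [clahe_config()].
#' @return Enhanced image, same shape, integer gray levels in `[0, 255]`.
#' @export
clahe_enhance <- function(image, cfg = clahe_config()) {
  assert_pixels(image, "image")
  d <- dim(image)
  if (any(cfg$nt > d)) {
    abort(sprintf(
      "clahe_config: tile grid %d x %d exceeds image size %d x %d",
      cfg$nt[1], cfg$nt[2], d[1], d[2]
    ))
  }
  if (diff(range(image)) == 0) {
    # degenerate histogram: equalization leaves a constant image flat
    return(clip255(image))
  }
  padded <- as.integer(ceiling(d / cfg$nt) * cfg$nt)
  x <- image[
    pmin(seq_len(padded[1]), d[1]),
    pmin(seq_len(padded[2]), d[2]),
    drop = FALSE
  ]
  # EBImage works in [0,1]; nx is the tile count along dim 1
  enh <- EBImage::clahe(x / 255,
    nx = cfg$nt[1], ny = cfg$nt[2],
    limit = cfg$cl
  )
  clip255(as.matrix(enh)[seq_len(d[1]), seq_len(d[2]), drop = FALSE] * 255)
}
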
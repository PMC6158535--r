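#' Configuration for procedural bark textures
#'
#' Parameters of the texture recipe used by [generate_synthetic_bark()].
#' The texture is built from three band-limited value-noise layers: broad
#' vertically streaked light/dark bands (ridges and furrows), sparse
#' mid-scale blobs of the opposite tone (lenticels and scars, the features
#' that become prey markings), and low-amplitude fine grain. The blob layer
#' is kept sparse so that a prey-sized patch typically contains a handful of
#' distinct markings, making all three camouflage constraints attainable by
#' rejection sampling. The recipe is a design choice, not a contract: any
#' texture satisfying the luminance-spread floor works as a background.
#'
#' @param band_scale horizontal scale (px) of the light/dark bands.
#' @param band_sharpness steepness of the light/dark tone split.
#' @param blob_scale feature scale (px) of the marking blobs.
#' @param blob_density fraction of pixels covered by blobs.
#' @param fine_scale,fine_amp scale (px) and amplitude (grey levels) of the
#'   fine grain.
#' @param anisotropy vertical elongation factor; > 1 stretches features
#'   vertically, emulating bark ridges and furrows.
#' @param min_spread floor (grey levels) on the 90th minus 10th luminance
#'   percentile of a generated image; guarantees marking segmentation is
#'   non-degenerate.
#' @return A list of class `bark_config`.
#' @export
bark_config <- function(band_scale = 280,
                        band_sharpness = 3,
                        blob_scale = 14,
                        blob_density = 0.02,
                        fine_scale = 5,
                        fine_amp = 10,
                        anisotropy = 4,
                        min_spread = 40) {
  stopifnot(band_scale >= 8, blob_scale >= 2, blob_density > 0,
            blob_density < 0.5, fine_scale >= 1, fine_amp >= 0,
            anisotropy >= 1, min_spread >= 0)
  structure(as.list(environment()), class = "bark_config")
}

# Bilinear upsample of a coarse grid to nr x nc. Control points are placed at
# the corners of the target so every output pixel interpolates, none
# extrapolates.
upsample_bilinear <- function(grid, nr, nc) {
  gr <- nrow(grid); gc <- ncol(grid)
  ri <- if (nr == 1) rep(1, nr) else seq(1, gr, length.out = nr)
  ci <- if (nc == 1) rep(1, nc) else seq(1, gc, length.out = nc)
  r0 <- pmin(floor(ri), gr - 1); rf <- ri - r0
  c0 <- pmin(floor(ci), gc - 1); cf <- ci - c0
  a <- grid[r0, c0, drop = FALSE]; b <- grid[r0 + 1, c0, drop = FALSE]
  cc <- grid[r0, c0 + 1, drop = FALSE]; d <- grid[r0 + 1, c0 + 1, drop = FALSE]
  w1 <- outer(1 - rf, 1 - cf); w2 <- outer(rf, 1 - cf)
  w3 <- outer(1 - rf, cf); w4 <- outer(rf, cf)
  a * w1 + b * w2 + cc * w3 + d * w4
}

#' Generate a synthetic bark-like background texture
#'
#' Procedurally synthesizes a grayscale background standing in for
#' photographs of natural tree bark: broad vertically streaked light and
#' dark bands, sparse mid-scale blobs of the opposite tone, and fine grain
#' (see [bark_config()]). Deterministic for a fixed
#' `(seed, width, height, config)`.
#'
#' @param seed integer RNG seed.
#' @param width,height image dimensions in px (>= 256).
#' @param config a [bark_config()].
#' @param id image identifier; defaults to `"bark_s<seed>"`.
#' @return A `background_image`: list with `id`, `pixels` (height x width
#'   integer matrix, values 0-255), `width`, `height`.
#' @export
generate_synthetic_bark <- function(seed, width = CANVAS_WIDTH,
                                    height = CANVAS_HEIGHT,
                                    config = bark_config(),
                                    id = NULL) {
  if (!is.numeric(width) || !is.numeric(height) || width < 256 || height < 256)
    stop_invalid("background dimensions must be >= 256 px (got %sx%s)",
                 width, height)
  width <- as.integer(width); height <- as.integer(height)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  noise_layer <- function(scale_x, scale_y) {
    gc <- max(2L, as.integer(ceiling(width / scale_x)) + 1L)
    gr <- max(2L, as.integer(ceiling(height / scale_y)) + 1L)
    z <- upsample_bilinear(matrix(stats::rnorm(gr * gc), gr, gc),
                           height, width)
    (z - mean(z)) / stats::sd(z)
  }
  # broad light/dark bands, vertically elongated, tones pushed apart
  bands <- noise_layer(config$band_scale,
                       config$band_scale * config$anisotropy)
  base <- 127.5 + 65 * tanh(config$band_sharpness * bands)
  # sparse mid-scale blobs flip to the opposite tone (the prey markings)
  blobs <- noise_layer(config$blob_scale,
                       config$blob_scale * sqrt(config$anisotropy))
  blob_mask <- blobs > stats::quantile(blobs, 1 - config$blob_density)
  base[blob_mask] <- 255 - base[blob_mask]
  # fine grain
  px <- base + config$fine_amp * noise_layer(config$fine_scale,
                                             config$fine_scale)
  px <- matrix(as.integer(pmin(pmax(round(px), 0), 255)), height, width)
  bg <- structure(list(id = id %||% sprintf("bark_s%d", as.integer(seed)),
                       pixels = px, width = width, height = height),
                  class = "background_image")
  spread <- luminance_spread(bg)
  if (spread < config$min_spread)
    stop_invalid("generated texture spread %.1f below floor %.1f",
                 spread, config$min_spread)
  bg
}

# Save/restore global RNG state so generators are pure in the caller's RNG.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' 90th minus 10th luminance percentile of a background
#' @param bg a `background_image`.
#' @return Spread in grey levels.
#' @export
luminance_spread <- function(bg) {
  q <- stats::quantile(bg$pixels, c(0.1, 0.9), names = FALSE)
  q[2] - q[1]
}

#' Load a raster file as a background image
#'
#' Reads a PNG (or TIFF) raster, converts it to 8-bit luminance (Rec. 709
#' weights for RGB input) and centre-crops it to the canvas. Images smaller
#' than the canvas are rejected under the default crop-only policy.
#'
#' @param path path to a PNG or TIFF file.
#' @param canvas target dimensions `c(width, height)`; `NULL` keeps the native
#'   size.
#' @param id identifier; defaults to the file name without extension.
#' @return A `background_image`.
#' @export
load_background <- function(path, canvas = c(CANVAS_WIDTH, CANVAS_HEIGHT),
                            id = NULL) {
  if (!file.exists(path)) stop_invalid("background file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
    png = png::readPNG(path),
    tif = , tiff = {
      if (!requireNamespace("tiff", quietly = TRUE))
        stop_invalid("reading TIFF requires the 'tiff' package")
      tiff::readTIFF(path)
    },
    stop_invalid("unsupported raster format: .%s (PNG or TIFF)", ext)
  )
  if (length(dim(arr)) == 3) {
    nch <- dim(arr)[3]
    arr <- if (nch >= 3) {
      0.2126 * arr[, , 1] + 0.7152 * arr[, , 2] + 0.0722 * arr[, , 3]
    } else arr[, , 1]
  }
  px <- matrix(as.integer(pmin(pmax(round(arr * 255), 0), 255)),
               nrow(arr), ncol(arr))
  if (!is.null(canvas)) {
    cw <- as.integer(canvas[1]); ch <- as.integer(canvas[2])
    if (ncol(px) < cw || nrow(px) < ch)
      stop_invalid("image %dx%d smaller than canvas %dx%d under crop-only policy",
                   ncol(px), nrow(px), cw, ch)
    r0 <- (nrow(px) - ch) %/% 2L; c0 <- (ncol(px) - cw) %/% 2L
    px <- px[r0 + seq_len(ch), c0 + seq_len(cw), drop = FALSE]
  }
  structure(list(id = id %||% tools::file_path_sans_ext(basename(path)),
                 pixels = px, width = ncol(px), height = nrow(px)),
            class = "background_image")
}

#' Write a background image to PNG
#' @param bg a `background_image`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_background <- function(bg, path) {
  png::writePNG(bg$pixels / 255, path)
  invisible(path)
}

#' Build a pool of synthetic backgrounds
#'
#' Generates `n` distinct bark textures with unique ids. Deterministic for a
#' fixed seed; per-image seeds are derived from the pool seed.
#'
#' @param n pool size (>= 1).
#' @param seed integer pool seed.
#' @param width,height image dimensions in px.
#' @param config a [bark_config()].
#' @return A list of `background_image` of length `n`, named by id.
#' @export
make_background_pool <- function(n, seed = 0L, width = CANVAS_WIDTH,
                                 height = CANVAS_HEIGHT,
                                 config = bark_config()) {
  assert_scalar_count(n, "n")
  pool <- lapply(seq_len(n), function(i) {
    generate_synthetic_bark(derive_seed(seed, "background", i),
                            width, height, config,
                            id = sprintf("bg%02d", i))
  })
  names(pool) <- vapply(pool, `[[`, "", "id")
  pool
}

#' @export
print.background_image <- function(x, ...) {
  cat(sprintf("<background_image '%s'> %dx%d px, luminance spread %.0f\n",
              x$id, x$width, x$height, luminance_spread(x)))
  invisible(x)
}
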
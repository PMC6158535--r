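#' Stimulus-generation configuration
#'
#' Thresholds governing prey-target generation. Defaults operationalize the
#' three camouflage-strategy constraints on 8-bit bark textures.
#'
#' @param min_component_area smallest marking component kept by segmentation
#'   (px).
#' @param ring_width width of the outline boundary ring used to score edge
#'   intersections (px).
#' @param spot_area_min,spot_area_max bounds on the distractive spot's total
#'   area (px).
#' @param spot_margin minimum distance (px) from every spot pixel to the
#'   boundary ring.
#' @param spot_contrast_floor minimum absolute luminance difference between
#'   the spot fill and the mean texture in its 5-px neighbourhood.
#' @param max_attempts rejection-sampling budget per target.
#' @param allow_drup_inversion permit polarity inversion of disruptive prey
#'   (off by default: only background-matching and distractive prey have
#'   light-on-dark / dark-on-light variants).
#' @return A list of class `stimulus_config`.
#' @export
stimulus_config <- function(min_component_area = 20,
                            ring_width = 1,
                            spot_area_min = 100,
                            spot_area_max = 300,
                            spot_margin = 2,
                            spot_contrast_floor = 60,
                            max_attempts = 1000,
                            allow_drup_inversion = FALSE) {
  stopifnot(min_component_area >= 1, ring_width >= 1,
            spot_area_min >= 1, spot_area_max >= spot_area_min,
            spot_margin >= 0, spot_contrast_floor >= 0, max_attempts >= 1)
  structure(as.list(environment()), class = "stimulus_config")
}

#' Rasterize the triangular prey outline
#'
#' Apex-up isosceles triangle filling a `width` x `height` bounding box,
#' left-right symmetric about the vertical midline. The boundary ring is the
#' set of interior pixels within `ring_width` (Chebyshev) of the exterior.
#'
#' @param width,height bounding box in px (>= 8); defaults are the prey
#'   dimensions of the detection task (126 x 64).
#' @param ring_width boundary ring width in px.
#' @return A `triangle_mask`: list with logical matrices `inside` and
#'   `boundary_ring` (height x width), plus `width`, `height`.
#' @export
triangle_mask <- function(width = TARGET_WIDTH, height = TARGET_HEIGHT,
                          ring_width = 1) {
  if (width < 8 || height < 8) stop_invalid("mask dimensions must be >= 8 px")
  width <- as.integer(width); height <- as.integer(height)
  cx <- (width + 1) / 2
  # row i (top = apex) admits columns within half-width (w/2) * i/h of centre
  inside <- outer(seq_len(height), seq_len(width),
                  function(i, j) abs(j - cx) <= (width / 2) * (i / height))
  ring <- inside & !erode_chebyshev(inside, ring_width)
  structure(list(width = width, height = height,
                 inside = inside, boundary_ring = ring),
            class = "triangle_mask")
}

# Erosion by a Chebyshev ball of radius r (box of side 2r+1), treating
# out-of-bounds as FALSE. Thin wrapper over EBImage's morphological erosion.
erode_chebyshev <- function(mask, r) {
  if (r == 0) return(mask)
  m <- matrix(0, nrow(mask) + 2 * r, ncol(mask) + 2 * r)
  m[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] <- mask * 1
  er <- EBImage::erode(m, EBImage::makeBrush(2 * r + 1, shape = "box"))
  er[r + seq_len(nrow(mask)), r + seq_len(ncol(mask))] > 0.5
}

#' Sample a texture patch for a prey target
#'
#' Copies a mask-shaped patch from a uniformly random in-bounds window of the
#' background, so prey patterns are taken from the scene they will be shown
#' against. The binarization threshold used later for marking segmentation is
#' the background's global median, offset to the half-integer grid so that
#' polarity inversion permutes the two phases exactly.
#'
#' @param bg a `background_image`.
#' @param mask a [triangle_mask()].
#' @param seed integer seed; fixed seed gives a fixed source window.
#' @return A `prey_patch`: list with `values` (height x width matrix, NA
#'   outside the mask), `mask`, `origin` (0-based `c(x, y)` of the source
#'   window), `threshold`, `background_id`.
#' @export
sample_patch <- function(bg, mask, seed) {
  if (bg$width < mask$width || bg$height < mask$height)
    stop_invalid("background %dx%d smaller than mask %dx%d",
                 bg$width, bg$height, mask$width, mask$height)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  x0 <- sample.int(bg$width - mask$width + 1L, 1L) - 1L
  y0 <- sample.int(bg$height - mask$height + 1L, 1L) - 1L
  vals <- bg$pixels[y0 + seq_len(mask$height), x0 + seq_len(mask$width),
                    drop = FALSE]
  vals[!mask$inside] <- NA_integer_
  structure(list(values = vals, mask = mask, origin = c(x = x0, y = y0),
                 threshold = floor(stats::median(bg$pixels)) + 0.5,
                 background_id = bg$id),
            class = "prey_patch")
}

#' Segment marking components of a prey patch
#'
#' Binarizes the patch at the source background's global median and labels
#' 8-connected regions of the minority phase as marking components, dropping
#' regions below the minimum area. Each component records its polarity (light
#' or dark relative to threshold) and whether it touches the outline ring.
#'
#' @param patch a `prey_patch`.
#' @param mask a `triangle_mask` (defaults to the patch's own mask).
#' @param min_area minimum component area in px.
#' @param threshold binarization level; defaults to the patch's stored
#'   background median.
#' @return A list of `pattern_component`: each has `pixels` (linear indices
#'   into the mask grid), `area`, `polarity` ("light"/"dark"),
#'   `touches_outline`.
#' @export
segment_markings <- function(patch, mask = patch$mask,
                             min_area = 20, threshold = patch$threshold) {
  light <- !is.na(patch$values) & patch$values > threshold
  dark <- !is.na(patch$values) & patch$values < threshold
  # minority phase = the rarer of the two inside the mask
  minority <- if (sum(light) <= sum(dark)) light else dark
  polarity <- if (sum(light) <= sum(dark)) "light" else "dark"
  if (!any(minority)) return(list())
  lab <- EBImage::bwlabel(minority * 1)
  ids <- seq_len(max(lab))
  comps <- lapply(ids, function(k) {
    pix <- which(lab == k)
    structure(list(pixels = pix, area = length(pix), polarity = polarity,
                   touches_outline = any(mask$boundary_ring[pix])),
              class = "pattern_component")
  })
  comps[vapply(comps, `[[`, 0L, "area") >= min_area]
}

#' Count marking components intersecting the outline
#' @param components output of [segment_markings()].
#' @return Number of components with `touches_outline = TRUE`.
#' @export
count_edge_intersections <- function(components) {
  sum(vapply(components, `[[`, FALSE, "touches_outline"))
}

# Rasterize a union of 1-3 overlapping ellipses near (cy, cx) into the mask
# grid. Returns linear indices (possibly empty).
rasterize_spot <- function(nr, nc, cy, cx, n_ellipse, axes, angles, offsets) {
  acc <- matrix(FALSE, nr, nc)
  jj <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ii <- matrix(rep(seq_len(nr), nc), nr, nc)
  for (e in seq_len(n_ellipse)) {
    ey <- cy + offsets[e, 1]; ex <- cx + offsets[e, 2]
    a <- axes[e, 1]; b <- axes[e, 2]; th <- angles[e]
    dx <- jj - ex; dy <- ii - ey
    u <- dx * cos(th) + dy * sin(th)
    v <- -dx * sin(th) + dy * cos(th)
    acc <- acc | (u^2 / a^2 + v^2 / b^2 <= 1)
  }
  which(acc)
}

# Mean texture level in the 5-px (Chebyshev) neighbourhood of the spot,
# excluding the spot itself, restricted to the mask interior.
spot_local_mean <- function(values, inside, spot_idx, radius = 5) {
  nr <- nrow(values); nc <- ncol(values)
  spot <- matrix(FALSE, nr, nc); spot[spot_idx] <- TRUE
  neigh <- !erode_chebyshev(!spot, radius) # dilation by radius
  sel <- neigh & !spot & inside
  mean(values[sel], na.rm = TRUE)
}

#' Generate a camouflaged prey target
#'
#' Rejection-samples texture patches from the background (a fresh random
#' window per attempt; markings are never translated inward, which would
#' create artificial inside edges) until the requested camouflage constraint
#' holds:
#' \describe{
#'   \item{BM}{background matching: at least one marking component and no
#'     component intersecting the outline.}
#'   \item{D_RUP}{disruptive: at least one component intersects the outline.}
#'   \item{D_RAC}{distractive: a background-matching base patch (no outline
#'     intersections) plus one randomly shaped high-contrast spot (union of
#'     1-3 overlapping ellipses) strictly interior to the outline, filled
#'     solid black or white to maximize contrast with the local texture.}
#' }
#'
#' @param bg a `background_image`.
#' @param treatment one of `"BM"`, `"D_RUP"`, `"D_RAC"`.
#' @param inverted present the prey with polarity inverted
#'   (light-on-dark vs dark-on-light); applied via [invert_polarity()].
#' @param seed integer seed; targets with distinct seeds are individually
#'   unique.
#' @param mask a [triangle_mask()].
#' @param config a [stimulus_config()].
#' @return A `prey_target`: list with `treatment`, `inverted`, `texture`
#'   (height x width matrix, NA outside mask), `mask`, `components`,
#'   `edge_intersection_count`, `threshold`, `source_background_id`, `spot`
#'   (`NULL` unless D_RAC: list with `pixels`, `area`, `fill`), `gen_seed`.
#' @export
make_target <- function(bg, treatment = PREY_TYPES, inverted = FALSE,
                        seed = 1L, mask = triangle_mask(),
                        config = stimulus_config()) {
  treatment <- match.arg(treatment)
  if (inverted && treatment == "D_RUP" && !config$allow_drup_inversion)
    stop_invalid("disruptive prey have no inverted variant (set allow_drup_inversion to override)")
  target <- NULL
  for (attempt in seq_len(config$max_attempts)) {
    patch <- sample_patch(bg, mask, derive_seed(seed, "patch", attempt))
    comps <- segment_markings(patch, mask, config$min_component_area)
    n_int <- count_edge_intersections(comps)
    ok <- switch(treatment,
                 BM = length(comps) >= 1 && n_int == 0,
                 D_RUP = n_int >= 1,
                 D_RAC = n_int == 0)
    if (!ok) next
    texture <- patch$values
    spot <- NULL
    if (treatment == "D_RAC") {
      spot <- draw_spot(texture, mask, derive_seed(seed, "spot", attempt),
                        config)
      if (is.null(spot)) next
      texture[spot$pixels] <- spot$fill
      comps <- segment_markings(
        structure(list(values = texture, mask = mask,
                       threshold = patch$threshold), class = "prey_patch"),
        mask, config$min_component_area)
      n_int <- count_edge_intersections(comps)
    }
    target <- structure(list(treatment = treatment, inverted = FALSE,
                             texture = texture, mask = mask,
                             components = comps,
                             edge_intersection_count = n_int,
                             threshold = patch$threshold,
                             source_background_id = bg$id,
                             spot = spot, gen_seed = as.integer(seed)),
                        class = "prey_target")
    break
  }
  if (is.null(target))
    stop_invalid("could not generate a %s target on background '%s' within %d attempts",
                 treatment, bg$id, config$max_attempts)
  if (inverted) target <- invert_polarity(target, config)
  target
}

# Sample one distractive spot: union of 1-3 overlapping ellipses whose pixels
# all lie >= spot_margin from the boundary ring, total area within bounds,
# filled black or white to maximize contrast with the 5-px local mean.
# Returns NULL when no admissible spot is found in the attempt budget.
draw_spot <- function(texture, mask, seed, config, forced_fill = NULL) {
  # Chebyshev distance to the exterior >= margin + ring width guarantees
  # distance to the ring >= margin.
  allowed <- erode_chebyshev(mask$inside,
                             as.integer(config$spot_margin + config$ring_width))
  allowed_idx <- which(allowed)
  if (!length(allowed_idx)) return(NULL)
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  nr <- nrow(texture); nc <- ncol(texture)
  for (try in seq_len(200)) {
    centre <- allowed_idx[sample.int(length(allowed_idx), 1)]
    cy <- (centre - 1) %% nr + 1; cx <- (centre - 1) %/% nr + 1
    k <- sample.int(3, 1)
    axes <- cbind(stats::runif(k, 3.5, 8.5), stats::runif(k, 3.5, 8.5))
    angles <- stats::runif(k, 0, pi)
    offsets <- cbind(stats::runif(k, -4, 4), stats::runif(k, -4, 4))
    offsets[1, ] <- 0
    idx <- rasterize_spot(nr, nc, cy, cx, k, axes, angles, offsets)
    if (length(idx) < config$spot_area_min ||
        length(idx) > config$spot_area_max) next
    if (!all(allowed[idx])) next
    local_mean <- spot_local_mean(texture, mask$inside, idx)
    fill <- forced_fill %||% (if (local_mean > 127.5) 0L else 255L)
    if (abs(fill - local_mean) < config$spot_contrast_floor) next
    return(list(pixels = idx, area = length(idx), fill = as.integer(fill),
                local_mean = local_mean))
  }
  NULL
}

#' Invert the luminance polarity of a prey target
#'
#' Maps every texture value v to 255 - v (light-on-dark to dark-on-light and
#' vice versa). The distractive spot's fill flips black/white, the
#' segmentation threshold is mirrored so marking geometry is preserved, and
#' components are re-segmented. Applying the operation twice restores the
#' original target bitwise.
#'
#' @param target a `prey_target`.
#' @param config a [stimulus_config()]; controls whether disruptive prey may
#'   be inverted.
#' @return The inverted `prey_target`.
#' @export
invert_polarity <- function(target, config = stimulus_config()) {
  if (target$treatment == "D_RUP" && !config$allow_drup_inversion)
    stop_invalid("disruptive prey have no inverted variant (set allow_drup_inversion to override)")
  target$texture <- 255L - target$texture
  target$threshold <- 255 - target$threshold
  if (!is.null(target$spot)) {
    target$spot$fill <- 255L - target$spot$fill
    target$spot$local_mean <- 255 - target$spot$local_mean
  }
  target$inverted <- !target$inverted
  target$components <- segment_markings(
    structure(list(values = target$texture, mask = target$mask,
                   threshold = target$threshold), class = "prey_patch"),
    target$mask, config$min_component_area)
  target$edge_intersection_count <-
    count_edge_intersections(target$components)
  target
}

#' Composite a prey target onto a background slide
#'
#' Renders one experimental slide: the background cropped to the canvas with
#' the target's texture composited under the triangle mask, centred at
#' `(x, y)` (0-based pixel coordinates, origin top-left). Pixels outside the
#' mask are untouched.
#'
#' @param bg a `background_image` at least canvas-sized.
#' @param target a `prey_target`.
#' @param x,y target-centre coordinates (0-based px).
#' @param canvas `c(width, height)` of the rendered slide.
#' @return Integer matrix (canvas height x width) of luminance values.
#' @export
render_slide <- function(bg, target, x, y,
                         canvas = c(CANVAS_WIDTH, CANVAS_HEIGHT)) {
  cw <- as.integer(canvas[1]); ch <- as.integer(canvas[2])
  if (bg$width < cw || bg$height < ch)
    stop_invalid("background smaller than canvas")
  w <- target$mask$width; h <- target$mask$height
  x0 <- as.integer(x) - (w %/% 2L); y0 <- as.integer(y) - (h %/% 2L)
  if (x0 < 0 || y0 < 0 || x0 + w > cw || y0 + h > ch)
    stop_invalid("placement (%d, %d) puts the %dx%d target outside the %dx%d canvas",
                 x, y, w, h, cw, ch)
  slide <- bg$pixels[seq_len(ch), seq_len(cw), drop = FALSE]
  sub <- slide[y0 + seq_len(h), x0 + seq_len(w), drop = FALSE]
  sub[target$mask$inside] <- target$texture[target$mask$inside]
  slide[y0 + seq_len(h), x0 + seq_len(w)] <- sub
  slide
}

#' Re-verify a prey target against its treatment constraint
#'
#' Independent re-check used in constraint sweeps: re-segments the stored
#' texture and tests the treatment's invariant (BM: >= 1 component, 0 outline
#' intersections; D_RUP: >= 1 intersection; D_RAC: spot present, interior by
#' the configured margin, contrast above the floor).
#'
#' @param target a `prey_target`.
#' @param config a [stimulus_config()].
#' @return `TRUE` if the target satisfies its constraint.
#' @export
verify_target <- function(target, config = stimulus_config()) {
  comps <- segment_markings(
    structure(list(values = target$texture, mask = target$mask,
                   threshold = target$threshold), class = "prey_patch"),
    target$mask, config$min_component_area)
  n_int <- count_edge_intersections(comps)
  if (n_int != target$edge_intersection_count) return(FALSE)
  switch(target$treatment,
    BM = length(comps) >= 1 && n_int == 0,
    D_RUP = n_int >= 1,
    D_RAC = {
      if (is.null(target$spot)) return(FALSE)
      allowed <- erode_chebyshev(target$mask$inside,
                                 as.integer(config$spot_margin + config$ring_width))
      lm <- spot_local_mean(target$texture, target$mask$inside,
                            target$spot$pixels)
      all(allowed[target$spot$pixels]) &&
        target$spot$fill %in% c(0L, 255L) &&
        abs(target$spot$fill - lm) >= config$spot_contrast_floor
    })
}

#' @export
print.prey_target <- function(x, ...) {
  cat(sprintf("<prey_target %s%s> %dx%d px, %d component(s), %d outline intersection(s), bg '%s'\n",
              x$treatment, if (x$inverted) " (inverted)" else "",
              x$mask$width, x$mask$height, length(x$components),
              x$edge_intersection_count, x$source_background_id))
  invisible(x)
}
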
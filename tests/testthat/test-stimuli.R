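test_that("triangle mask fills its bounding box, matches an independent rasterizer and is symmetric", {
  m <- triangle_mask(126, 64)
  expect_equal(range(which(apply(m$inside, 2, any))), c(1, 126))
  expect_equal(range(which(apply(m$inside, 1, any))), c(1, 64))
  # area within 3% of the ideal half-box, against a half-plane oracle
  expect_lt(abs(sum(m$inside) - 126 * 64 / 2) / (126 * 64 / 2), 0.03)
  expect_lt(abs(sum(m$inside) - triangle_oracle_area(126, 64)) /
              triangle_oracle_area(126, 64), 0.01)
  # mirror symmetry about the vertical midline, for several sizes
  for (wh in list(c(126, 64), c(40, 20), c(9, 15))) {
    mm <- triangle_mask(wh[1], wh[2])
    expect_identical(mm$inside, mm$inside[, rev(seq_len(wh[1]))])
  }
  expect_gt(sum(m$boundary_ring), 0)
  expect_true(all(m$inside[m$boundary_ring]))
  expect_error(triangle_mask(4, 64), ">= 8")
})

test_that("patch sampling copies background values and is deterministic", {
  m <- triangle_mask()
  p1 <- sample_patch(const_background(77L), m, seed = 9)
  expect_true(all(p1$values[m$inside] == 77L))
  expect_true(all(is.na(p1$values[!m$inside])))
  bg <- small_pool()[[1]]
  p2 <- sample_patch(bg, m, seed = 4)
  p3 <- sample_patch(bg, m, seed = 4)
  expect_identical(p2$origin, p3$origin)
  expect_identical(p2$values, p3$values)
  # values equal a direct window extraction at the recorded origin
  win <- bg$pixels[p2$origin[["y"]] + seq_len(m$height),
                   p2$origin[["x"]] + seq_len(m$width)]
  expect_identical(p2$values[m$inside], win[m$inside])
  tiny <- const_background(0L, width = 100, height = 100)
  expect_error(sample_patch(tiny, m, 1), "smaller than mask")
})

test_that("marking segmentation finds constructed components with correct polarity and outline flags", {
  m <- triangle_mask()
  # constant patch: no pattern
  expect_length(segment_markings(as_patch(matrix(200L, 64, 126), m, 127.5)), 0)
  # one dark disc strictly interior on a light ground
  vals <- matrix(230L, 64, 126)
  ii <- matrix(rep(1:64, 126), 64); jj <- matrix(rep(1:126, each = 64), 64)
  disc <- (ii - 40)^2 + (jj - 63)^2 <= 16
  vals[disc] <- 20L
  comps <- segment_markings(as_patch(vals, m, 127.5), m, min_area = 20)
  expect_length(comps, 1)
  expect_equal(comps[[1]]$polarity, "dark")
  expect_false(comps[[1]]$touches_outline)
  expect_equal(comps[[1]]$area, sum(disc & m$inside))
  expect_equal(count_edge_intersections(comps), 0)
  # a horizontal band crossing the outline is counted once
  vals2 <- matrix(230L, 64, 126)
  vals2[30:36, ] <- 20L
  comps2 <- segment_markings(as_patch(vals2, m, 127.5), m, min_area = 20)
  expect_length(comps2, 1)
  expect_true(comps2[[1]]$touches_outline)
  expect_equal(count_edge_intersections(comps2), 1)
  # single-pixel overlap with the ring counts
  ring_px <- which(m$boundary_ring)[100]
  vals3 <- matrix(230L, 64, 126)
  r <- (ring_px - 1) %% 64 + 1; cc <- (ring_px - 1) %/% 64 + 1
  block <- as.matrix(expand.grid(r = r + (-10:0), c = cc + (0:3)))
  block <- block[block[, 1] >= 1, , drop = FALSE]
  vals3[block] <- 20L
  comps3 <- segment_markings(as_patch(vals3, m, 127.5), m, min_area = 20)
  expect_gte(count_edge_intersections(comps3), 1)
})

test_that("segmentation agrees with an independent flood-fill labelling", {
  m <- triangle_mask()
  bg <- small_pool()[[2]]
  p <- sample_patch(bg, m, seed = 21)
  comps <- segment_markings(p, m, min_area = 1)
  # rebuild the binarized minority phase exactly as documented
  light <- !is.na(p$values) & p$values > p$threshold
  dark <- !is.na(p$values) & p$values < p$threshold
  minority <- if (sum(light) <= sum(dark)) light else dark
  oracle <- flood_fill_components(minority)
  expect_equal(length(comps), length(oracle))
  expect_equal(sort(vapply(comps, `[[`, 0L, "area")),
               sort(lengths(oracle)))
  expect_setequal(unlist(lapply(comps, `[[`, "pixels")), unlist(oracle))
})

test_that("generated targets satisfy their treatment constraints", {
  pool <- small_pool()
  bm <- make_target(pool[[1]], "BM", seed = 101)
  expect_equal(bm$edge_intersection_count, 0)
  expect_gte(length(bm$components), 1)
  dr <- make_target(pool[[2]], "D_RUP", seed = 102)
  expect_gte(dr$edge_intersection_count, 1)
  da <- make_target(pool[[3]], "D_RAC", seed = 103)
  expect_false(is.null(da$spot))
  expect_true(da$spot$fill %in% c(0L, 255L))
  expect_gte(da$spot$area, 100)
  expect_lte(da$spot$area, 300)
  for (tg in list(bm, dr, da)) expect_true(verify_target(tg))
})

test_that("degenerate constant backgrounds fail BM/D_RUP generation but admit D_RAC", {
  bg <- const_background(128L)
  cfg <- stimulus_config(max_attempts = 25)
  expect_error(make_target(bg, "BM", seed = 1, config = cfg),
               "could not generate")
  expect_error(make_target(bg, "D_RUP", seed = 1, config = cfg),
               "could not generate")
  da <- make_target(bg, "D_RAC", seed = 1, config = cfg)
  expect_false(is.null(da$spot))
  expect_true(verify_target(da))
})

test_that("polarity inversion is an involution preserving marking geometry", {
  pool <- small_pool()
  bm <- make_target(pool[[1]], "BM", seed = 55)
  inv <- invert_polarity(bm)
  expect_true(inv$inverted)
  expect_equal(inv$edge_intersection_count, 0)
  expect_equal(mean(inv$texture[inv$mask$inside]),
               255 - mean(bm$texture[bm$mask$inside]))
  back <- invert_polarity(inv)
  expect_identical(back$texture, bm$texture)
  expect_false(back$inverted)
  # component geometry is unchanged by the value flip
  expect_equal(sort(vapply(inv$components, `[[`, 0L, "area")),
               sort(vapply(bm$components, `[[`, 0L, "area")))
  # distractive spots flip black/white and keep their contrast
  da <- make_target(pool[[2]], "D_RAC", seed = 56)
  dinv <- invert_polarity(da)
  expect_equal(dinv$spot$fill, 255L - da$spot$fill)
  expect_true(verify_target(dinv))
  # disruptive prey have no inverted variant unless overridden
  dr <- make_target(pool[[3]], "D_RUP", seed = 57)
  expect_error(invert_polarity(dr), "no inverted variant")
  cfg <- stimulus_config(allow_drup_inversion = TRUE)
  expect_s3_class(invert_polarity(dr, cfg), "prey_target")
})

test_that("slide rendering composites only under the mask and round-trips the texture", {
  bg <- canvas_pool()[[1]]
  tg <- make_target(bg, "D_RUP", seed = 77)
  slide <- render_slide(bg, tg, x = 400, y = 300)
  expect_equal(dim(slide), c(1080, 1920))
  base <- bg$pixels[1:1080, 1:1920]
  expect_lte(sum(slide != base), sum(tg$mask$inside))
  crop <- slide[300 - 32 + seq_len(64), 400 - 63 + seq_len(126)]
  expect_identical(crop[tg$mask$inside], tg$texture[tg$mask$inside])
  expect_error(render_slide(bg, tg, x = 10, y = 300), "outside")
  expect_error(render_slide(bg, tg, x = 1900, y = 300), "outside")
})
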
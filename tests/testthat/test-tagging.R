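layout <- tag_layout()

test_that("the circular layout has the family's structure", {
  expect_equal(layout$n, 10L)
  expect_equal(sum(layout$grid == "d"), 44L)
  expect_equal(layout$n_data, 44L)
  # bit_order is a permutation of exactly the data-cell positions
  expect_equal(nrow(layout$bit_order), 44L)
  key <- paste(layout$bit_order[, 1], layout$bit_order[, 2])
  expect_equal(anyDuplicated(key), 0L)
  dpos <- which(layout$grid == "d", arr.ind = TRUE)
  expect_setequal(key, paste(dpos[, 1], dpos[, 2]))
  # ignored cells occur only near the corners
  xpos <- which(layout$grid == "x", arr.ind = TRUE)
  ctr <- (layout$n + 1) / 2
  expect_true(all(sqrt((xpos[, 1] - ctr)^2 + (xpos[, 2] - ctr)^2) > 4.5))
  # the border ring is made of the fixed black/white cells
  expect_gt(sum(layout$grid == "b"), 0L)
  expect_gt(sum(layout$grid == "w"), 0L)
})

test_that("rendering honors cell roles and codeword bits", {
  cp <- 4L
  all_on <- render_tag(2^44 - 1, layout, cp)
  for (k in seq_len(layout$n_data)) {
    r <- layout$bit_order[k, 1]; c <- layout$bit_order[k, 2]
    expect_equal(all_on[(r - 1) * cp + 1, (c - 1) * cp + 1], 1)
  }
  all_off <- render_tag(0, layout, cp)
  expect_equal(sum(all_off == 0),
               (sum(layout$grid == "b") + 44L) * cp^2)
  expect_error(render_tag(2^44, layout), "range")
  expect_error(render_tag(-1, layout), "range")
})

test_that("render and decode are mutually inverse", {
  withr::with_seed(5, {
    for (rep in 1:25) {
      code <- bits_to_codeword(rbinom(44, 1, 0.5))
      img <- render_tag(code, layout, cell_pixels = 3L)
      expect_equal(decode_raster(img, layout), code)
    }
  })
  # flipping one data cell flips exactly that bit
  code <- bits_to_codeword(rep(c(1L, 0L), 22))
  img <- render_tag(code, layout, 3L)
  k <- 7L
  r <- layout$bit_order[k, 1]; c <- layout$bit_order[k, 2]
  img[((r - 1) * 3 + 1):(r * 3), ((c - 1) * 3 + 1):(c * 3)] <-
    1 - img[((r - 1) * 3 + 1):(r * 3), ((c - 1) * 3 + 1):(c * 3)]
  flipped <- decode_raster(img, layout)
  bits <- codeword_bits(code, 44)
  bits[k] <- 1L - bits[k]
  expect_equal(flipped, bits_to_codeword(bits))
  # all-black data field decodes to zero
  expect_equal(decode_raster(render_tag(0, layout, 3L), layout), 0)
})

test_that("ambiguous cells raise instead of guessing", {
  img <- render_tag(0, layout, 4L)
  r <- layout$bit_order[1, 1]; c <- layout$bit_order[1, 2]
  img[((r - 1) * 4 + 1):(r * 4), ((c - 1) * 4 + 1):(c * 4)] <- 0.5
  expect_error(decode_raster(img, layout), "ambiguous")
})

test_that("white dilation grows bright regions and never darkens", {
  blk <- matrix(0, 9, 9)
  expect_equal(dilate_white(blk), blk)
  one <- matrix(0, 9, 9); one[5, 5] <- 1
  d <- dilate_white(one, 3L)
  expect_equal(sum(d), 9)
  expect_true(all(d[4:6, 4:6] == 1))
  expect_true(all(d >= one))
  expect_error(dilate_white(one, 4L), "odd")
  expect_identical(dilate_white(one, 1L), one)
})

test_that("ink-bleed degradation breaks decoding and dilation repairs it", {
  withr::with_seed(12, {
    for (rep in 1:5) {
      code <- bits_to_codeword(rbinom(44, 1, 0.5))
      img <- render_tag(code, layout, cell_pixels = 3L)
      # ink bleed: black creeps one pixel into every white region
      bled <- 1 - dilate_white(1 - img, 3L)
      misread <- tryCatch(decode_raster(bled, layout) != code,
                          error = function(e) TRUE)
      expect_true(misread)
      repaired <- dilate_white(bled, 3L)
      expect_equal(decode_raster(repaired, layout), code)
    }
  })
})

test_that("the reference detector finds rendered tags in frames", {
  cp <- 8L
  det_fun <- naive_tag_detector(layout, cp)
  blank <- matrix(1, 320, 800)
  expect_equal(nrow(detect_tags(blank, det_fun)), 0L)
  # one tag at a known position
  code <- 314159265358
  img <- render_tag(code, layout, cp)
  frame <- blank
  r0 <- 101L; c0 <- 301L
  frame[r0:(r0 + 10 * cp - 1), c0:(c0 + 10 * cp - 1)] <- img
  found <- detect_tags(frame, det_fun)
  expect_equal(nrow(found), 1L)
  expect_equal(found$id, code)
  truth_x <- (c0 - 1) + 5 * cp - 0.5
  truth_y <- (r0 - 1) + 5 * cp - 0.5
  expect_lt(abs(found$x - truth_x), cp / 2)
  expect_lt(abs(found$y - truth_y), cp / 2)
  # two non-overlapping tags are both recovered
  code2 <- 271828182845
  frame[201:(200 + 10 * cp), 601:(600 + 10 * cp)] <-
    render_tag(code2, layout, cp)
  found2 <- detect_tags(frame, det_fun)
  expect_equal(nrow(found2), 2L)
  expect_setequal(found2$id, c(code, code2))
})

test_that("printable sheets carry the physical geometry", {
  sheet <- make_sheet(c(5000, 5001, 5002, 5003, 5004))
  expect_equal(nrow(sheet$geometry), 5L)
  expect_equal(unique(sheet$geometry$cut_diameter_mm /
                        sheet$geometry$side_mm), 1.3)
  # 2 mm at 1200 dpi is between 94 and 95 dots
  expect_true(all(sheet$geometry$side_dots > 94 &
                    sheet$geometry$side_dots < 95))
  # empty sheet
  expect_equal(nrow(make_sheet(numeric(0))$geometry), 0L)
  # SVG file output
  svg <- withr::local_tempfile(fileext = ".svg")
  write_sheet(sheet, svg)
  txt <- readLines(svg)
  expect_match(txt[1], "<svg")
  expect_equal(sum(grepl("circle", txt)), 5L)
  # 100 tags keep their dot size
  big <- make_sheet(seq(0, 99))
  expect_true(all(round(big$geometry$side_dots) %in% c(94L, 95L)))
})

test_that("impossible sheet geometry is rejected", {
  expect_error(make_sheet(c(1, 2), clearance_mm = 0.01), "overlap")
  expect_error(make_sheet(1, dpi = 150), "dpi")
  expect_error(tag_spec(1, tag_side_mm = 2, cut_diameter_mm = 1.5), "clip")
})
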
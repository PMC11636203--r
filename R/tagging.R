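#' Circular tag layout
#'
#' Loads the 10 x 10 cell-role grid defining the circular 44-bit tag family
#' used on bee thoraxes. Each cell is `w` (fixed white), `b` (fixed black),
#' `d` (data bit) or `x` (ignored; the cells trimmed from the corners to
#' approximate a circle). The `b`/`w` cells form the detection border ring.
#' Data-bit significance (`bit_order`) follows raster scan of the `d` cells,
#' top-left to bottom-right, most significant bit first.
#'
#' The grid shipped with the package is a synthetic reconstruction from the
#' family's published description (see the file header in
#' `extdata/circle44_layout_synthetic.txt`).
#'
#' @param path Path to a layout file (lines of cell-role characters; `#`
#'   comment lines ignored). Defaults to the shipped layout.
#' @return An object of class `tag_layout`: list with `grid` (character
#'   matrix), `n` (grid side), `bit_order` (two-column matrix of the
#'   row/column of each data cell, most significant first), `n_data`.
#' @export
tag_layout <- function(path = system.file("extdata",
                                          "circle44_layout_synthetic.txt",
                                          package = "beegate")) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines[!startsWith(trimws(lines), "#")])
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  if (any(nchar(lines) != n)) abort("layout grid must be square.")
  grid <- do.call(rbind, strsplit(lines, ""))
  if (!all(grid %in% c("w", "b", "d", "x"))) {
    abort("layout cells must be one of w, b, d, x.")
  }
  dcells <- which(t(grid) == "d")  # t(): raster scan = row-major order
  bit_order <- cbind(row = (dcells - 1L) %/% n + 1L,
                     col = (dcells - 1L) %% n + 1L)
  structure(list(grid = grid, n = n, bit_order = bit_order,
                 n_data = nrow(bit_order)),
            class = "tag_layout")
}

#' @export
print.tag_layout <- function(x, ...) {
  cat(sprintf("<tag_layout> %d x %d cells, %d data bits\n",
              x$n, x$n, x$n_data))
  cat(apply(x$grid, 1, paste, collapse = ""), sep = "\n")
  invisible(x)
}

max_codeword <- function(layout) 2^layout$n_data - 1

#' Codeword bit helpers
#'
#' Convert between integer codewords (held exactly as doubles, up to 2^53)
#' and bit vectors ordered most significant bit first.
#'
#' @param codeword Non-negative integer codeword.
#' @param nbits Number of bits.
#' @return `codeword_bits()`: integer vector of 0/1, length `nbits`.
#' @export
codeword_bits <- function(codeword, nbits) {
  if (codeword < 0 || codeword > 2^nbits - 1) {
    abort(sprintf("codeword out of range [0, 2^%d).", nbits))
  }
  bits <- integer(nbits)
  for (i in nbits:1) {
    bits[i] <- codeword %% 2
    codeword <- codeword %/% 2
  }
  bits
}

#' @rdname codeword_bits
#' @param bits Integer vector of 0/1, most significant first.
#' @return `bits_to_codeword()`: the numeric codeword.
#' @export
bits_to_codeword <- function(bits) {
  sum(bits * 2^(rev(seq_along(bits)) - 1))
}

#' Render a tag codeword to a grayscale raster
#'
#' Draws the layout at `cell_pixels` pixels per cell: fixed white and ignored
#' cells render white (1), fixed black cells render black (0), and each data
#' cell renders white when its codeword bit is 1. The output is a plain
#' numeric matrix in `[0, 1]`, rows indexing image y.
#'
#' @param codeword Codeword in `[0, 2^44)` for the default layout.
#' @param layout A [tag_layout()].
#' @param cell_pixels Pixels per cell (positive integer).
#' @return A square numeric matrix of side `layout$n * cell_pixels`.
#' @seealso [decode_raster()], its exact inverse on clean renders.
#' @export
render_tag <- function(codeword, layout = tag_layout(), cell_pixels = 8L) {
  cell_pixels <- as.integer(cell_pixels)
  if (is.na(cell_pixels) || cell_pixels < 1L) {
    abort("`cell_pixels` must be a positive integer.")
  }
  bits <- codeword_bits(codeword, layout$n_data)
  vals <- matrix(1, layout$n, layout$n)
  vals[layout$grid == "b"] <- 0
  for (k in seq_len(layout$n_data)) {
    vals[layout$bit_order[k, 1], layout$bit_order[k, 2]] <- bits[k]
  }
  vals[rep(seq_len(layout$n), each = cell_pixels),
       rep(seq_len(layout$n), each = cell_pixels)]
}

#' Decode an axis-aligned tag raster
#'
#' Inverse of [render_tag()] for unrotated rasters at a whole number of
#' pixels per cell: each data cell is read as the mean intensity over the
#' cell, thresholded at mid-gray. Reading the whole cell rather than a
#' single centre pixel makes the decoder sensitive to ink-bleed-style
#' degradation (shrunken white regions) in the same way a real detector is,
#' which is exactly what [dilate_white()] repairs.
#'
#' @param img Square numeric matrix whose side is a multiple of the layout
#'   side.
#' @param layout A [tag_layout()].
#' @return The decoded numeric codeword.
#' @section Errors: a data cell whose mean lies within 10% of the mid-gray
#'   threshold is ambiguous and raises an error rather than guessing.
#' @export
decode_raster <- function(img, layout = tag_layout()) {
  if (nrow(img) != ncol(img) || nrow(img) %% layout$n != 0L) {
    abort("image side must be a multiple of the layout side.")
  }
  cp <- nrow(img) %/% layout$n
  bits <- integer(layout$n_data)
  for (k in seq_len(layout$n_data)) {
    r <- layout$bit_order[k, 1]
    c <- layout$bit_order[k, 2]
    cell <- img[((r - 1) * cp + 1):(r * cp), ((c - 1) * cp + 1):(c * cp)]
    m <- mean(cell)
    if (abs(m - 0.5) <= 0.05) {
      abort(sprintf("ambiguous data cell at (%d, %d): mean %.3f", r, c, m))
    }
    bits[k] <- as.integer(m > 0.5)
  }
  bits_to_codeword(bits)
}

#' Dilate the white (bright) regions of an image
#'
#' Grayscale morphological dilation with a square structuring element.
#' Printed tags whose black ink bleeds into neighbouring white cells become
#' undetectable; dilating the white pixels before detection restores them.
#' The operation never decreases a pixel value.
#'
#' @param img Single-channel numeric matrix.
#' @param kernel_px Side of the square kernel; positive odd integer
#'   (default 3).
#' @return A matrix of the same dimensions.
#' @export
dilate_white <- function(img, kernel_px = 3L) {
  kernel_px <- as.integer(kernel_px)
  if (is.na(kernel_px) || kernel_px < 1L || kernel_px %% 2L == 0L) {
    abort("`kernel_px` must be a positive odd integer.")
  }
  if (kernel_px == 1L) return(img)
  out <- EBImage::dilate(img, EBImage::makeBrush(kernel_px, "box"))
  out <- as.matrix(out)
  dimnames(out) <- NULL
  out
}

#' Reference detector for axis-aligned rendered tags
#'
#' Builds a detector function conforming to the detector-adapter contract:
#' given a grayscale frame, return one row per found tag with `id`, centre
#' `x`/`y` (0-based pixel coordinates) and `theta`. This reference
#' implementation finds dark connected regions (after closing the gaps
#' between a tag's black cells), takes each region's bounding box as a tag
#' candidate, and decodes it with [decode_raster()]; candidates that fail to
#' decode are discarded. It assumes unrotated tags rendered at a known
#' integer `cell_pixels`, which is what the simulator and tests produce; any
#' real tag-family detector binding can be plugged into [detect_tags()] in
#' its place.
#'
#' @param layout A [tag_layout()].
#' @param cell_pixels Pixels per cell the frames were rendered at.
#' @return A `function(frame)` returning a tibble `id`, `x`, `y`, `theta`.
#' @export
naive_tag_detector <- function(layout = tag_layout(), cell_pixels = 8L) {
  cp <- as.integer(cell_pixels)
  side <- layout$n * cp
  function(frame) {
    empty <- tibble(id = numeric(0), x = numeric(0), y = numeric(0),
                    theta = numeric(0))
    if (!any(frame < 0.5)) return(empty)
    mask <- (frame < 0.5) * 1
    # close intra-tag gaps (at most two cells wide between black cells)
    closed <- EBImage::dilate(mask, EBImage::makeBrush(2L * cp + 1L, "box"))
    lab <- EBImage::bwlabel(closed)
    out <- list()
    for (l in seq_len(max(lab))) {
      idx <- which(lab == l, arr.ind = TRUE)
      r0 <- min(idx[, 1]); r1 <- max(idx[, 1])
      c0 <- min(idx[, 2]); c1 <- max(idx[, 2])
      if ((r1 - r0 + 1L) != side || (c1 - c0 + 1L) != side) next
      sub <- frame[r0:r1, c0:c1]
      code <- tryCatch(decode_raster(sub, layout), error = function(e) NULL)
      if (is.null(code)) next
      out[[length(out) + 1L]] <- tibble(
        id = code,
        x = (c0 + c1) / 2 - 0.5,   # 0-based continuous centre
        y = (r0 + r1) / 2 - 0.5,
        theta = 0)
    }
    if (!length(out)) return(empty)
    bind_rows(out)
  }
}

#' Detect tags in a frame through a pluggable detector
#'
#' Applies an optional white-pixel dilation pre-pass (the ink-bleed fix;
#' disabled by default because clean synthetic renders do not need it) and
#' then the injected detector. Detections outside the frame bounds are
#' dropped with a warning.
#'
#' @param frame Grayscale numeric matrix.
#' @param detector A detector function (`function(frame)` returning a tibble
#'   with `id`, `x`, `y`, `theta`); defaults to [naive_tag_detector()].
#' @param dilate If `TRUE`, run [dilate_white()] on the frame first.
#' @param kernel_px Kernel for the dilation pre-pass.
#' @return Tibble of detections with `id`, `x`, `y`, `theta` in frame
#'   coordinates (no timestamp; timestamps are the logger's job).
#' @export
detect_tags <- function(frame, detector = naive_tag_detector(),
                        dilate = FALSE, kernel_px = 3L) {
  if (dilate) frame <- dilate_white(frame, kernel_px)
  det <- detector(frame)
  inb <- det$x >= 0 & det$x < ncol(frame) & det$y >= 0 & det$y < nrow(frame)
  if (any(!inb)) {
    warn(sprintf("%d detection(s) outside frame bounds dropped", sum(!inb)))
  }
  det[inb, , drop = FALSE]
}

#' Printable tag specification
#'
#' Physical print geometry for one tag: the codeword, the printed square's
#' side, the cut-circle diameter, and whether the forward-orientation stripe
#' is drawn. The defaults (2 mm square, 2.6 mm cut circle) fit a worker
#' bee's thorax without obstructing wings or head. The cut circle must cover
#' every black-border and data cell of the layout; only the ignored corner
#' cells may be clipped.
#'
#' @param codeword Codeword in range for `layout`.
#' @param tag_side_mm Printed side of the tag square, mm.
#' @param cut_diameter_mm Diameter of the cut circle, mm.
#' @param orientation_stripe Draw the forward stripe marking tag orientation
#'   (placed on the edge that faces the bee's head)?
#' @param layout A [tag_layout()] used for the geometric check.
#' @return An object of class `tag_spec`.
#' @export
tag_spec <- function(codeword, tag_side_mm = 2.0, cut_diameter_mm = 2.6,
                     orientation_stripe = TRUE, layout = tag_layout()) {
  if (codeword < 0 || codeword > max_codeword(layout)) {
    abort(sprintf("codeword out of range [0, 2^%d).", layout$n_data))
  }
  if (tag_side_mm <= 0 || cut_diameter_mm <= 0) {
    abort("physical dimensions must be positive.")
  }
  cell_mm <- tag_side_mm / layout$n
  essential <- which(matrix(layout$grid %in% c("b", "d"),
                            nrow(layout$grid)), arr.ind = TRUE)
  ctr <- layout$n / 2
  corner_r <- max(sqrt(pmax(abs(essential[, 1] - 1 - ctr),
                            abs(essential[, 1] - ctr))^2 +
                       pmax(abs(essential[, 2] - 1 - ctr),
                            abs(essential[, 2] - ctr))^2))
  need_mm <- 2 * corner_r * cell_mm
  if (cut_diameter_mm < need_mm) {
    abort(sprintf(
      "cut circle (%.2f mm) would clip data/border cells; need >= %.2f mm.",
      cut_diameter_mm, need_mm))
  }
  structure(list(codeword = codeword, tag_side_mm = tag_side_mm,
                 cut_diameter_mm = cut_diameter_mm,
                 orientation_stripe = orientation_stripe),
            class = "tag_spec")
}

#' Lay out a printable sheet of tags
#'
#' Places each tag at its physical size on a grid with concentric cut
#' circles and orientation stripes, and renders the sheet to SVG (and
#' optionally PDF). Tag pitch is the cut diameter plus `clearance_mm`;
#' clearance below 0.1 mm (typical plotter precision) is rejected because
#' the cut circles would effectively overlap.
#'
#' @param specs A list of [tag_spec()] objects, or a numeric vector of
#'   codewords (converted with default geometry).
#' @param layout A [tag_layout()].
#' @param dpi Print resolution used for the reported dot geometry
#'   (minimum 300).
#' @param columns Tags per row.
#' @param clearance_mm Gap between neighbouring cut circles.
#' @param margin_mm Sheet margin.
#' @return An object of class `tag_sheet`: list with `geometry` (a tibble of
#'   per-tag placements: `codeword`, `row`, `col`, `cx_mm`, `cy_mm`,
#'   `side_mm`, `cut_diameter_mm`, `side_dots`), `width_mm`, `height_mm`,
#'   `dpi`, and `svg` (the SVG document lines). Write it with
#'   [write_sheet()].
#' @export
make_sheet <- function(specs, layout = tag_layout(), dpi = 1200,
                       columns = 10L, clearance_mm = 0.4, margin_mm = 5) {
  if (dpi < 300) abort("`dpi` must be at least 300 for printable tags.")
  if (is.numeric(specs)) {
    specs <- lapply(specs, tag_spec, layout = layout)
  }
  if (clearance_mm < 0.1) {
    abort("cut circles would overlap: clearance below the 0.1 mm cutting precision.")
  }
  n <- length(specs)
  columns <- max(1L, as.integer(columns))
  geom <- if (n) {
    cut_d <- vapply(specs, function(s) s$cut_diameter_mm, 0)
    pitch <- max(cut_d) + clearance_mm
    idx <- seq_len(n) - 1L
    tibble(
      codeword = vapply(specs, function(s) s$codeword, 0),
      row = idx %/% columns + 1L,
      col = idx %% columns + 1L,
      cx_mm = margin_mm + (idx %% columns + 0.5) * pitch,
      cy_mm = margin_mm + (idx %/% columns + 0.5) * pitch,
      side_mm = vapply(specs, function(s) s$tag_side_mm, 0),
      cut_diameter_mm = cut_d,
      side_dots = vapply(specs, function(s) s$tag_side_mm, 0) * dpi / 25.4
    )
  } else {
    tibble(codeword = numeric(0), row = integer(0), col = integer(0),
           cx_mm = numeric(0), cy_mm = numeric(0), side_mm = numeric(0),
           cut_diameter_mm = numeric(0), side_dots = numeric(0))
  }
  width_mm <- if (n) max(geom$cx_mm + geom$cut_diameter_mm / 2) + margin_mm
    else 2 * margin_mm
  height_mm <- if (n) max(geom$cy_mm + geom$cut_diameter_mm / 2) + margin_mm
    else 2 * margin_mm
  svg <- sheet_svg(specs, geom, layout, width_mm, height_mm)
  structure(list(geometry = geom, width_mm = width_mm, height_mm = height_mm,
                 dpi = dpi, svg = svg, specs = specs, layout = layout),
            class = "tag_sheet")
}

sheet_svg <- function(specs, geom, layout, width_mm, height_mm) {
  el <- c(sprintf(
    paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%.3fmm" ',
           'height="%.3fmm" viewBox="0 0 %.3f %.3f">'),
    width_mm, height_mm, width_mm, height_mm),
    sprintf('<rect x="0" y="0" width="%.3f" height="%.3f" fill="white"/>',
            width_mm, height_mm))
  for (i in seq_along(specs)) {
    s <- specs[[i]]
    cell <- s$tag_side_mm / layout$n
    x0 <- geom$cx_mm[i] - s$tag_side_mm / 2
    y0 <- geom$cy_mm[i] - s$tag_side_mm / 2
    bits <- codeword_bits(s$codeword, layout$n_data)
    k <- 0L
    for (r in seq_len(layout$n)) {
      for (c in seq_len(layout$n)) {
        role <- layout$grid[r, c]
        black <- switch(role, b = TRUE, w = , x = FALSE,
                        d = { k <- k + 1L; bits[match_bit(layout, r, c)] == 0 })
        if (isTRUE(black)) {
          el <- c(el, sprintf(
            '<rect x="%.4f" y="%.4f" width="%.4f" height="%.4f" fill="black"/>',
            x0 + (c - 1) * cell, y0 + (r - 1) * cell, cell, cell))
        }
      }
    }
    el <- c(el, sprintf(
      '<circle cx="%.4f" cy="%.4f" r="%.4f" fill="none" stroke="magenta" stroke-width="0.05"/>',
      geom$cx_mm[i], geom$cy_mm[i], s$cut_diameter_mm / 2))
    if (isTRUE(s$orientation_stripe)) {
      el <- c(el, sprintf(
        '<rect x="%.4f" y="%.4f" width="%.4f" height="%.4f" fill="gold"/>',
        x0, y0 - 0.15 * cell - 0.05, s$tag_side_mm, 0.15 * cell))
    }
  }
  c(el, "</svg>")
}

match_bit <- function(layout, r, c) {
  which(layout$bit_order[, 1] == r & layout$bit_order[, 2] == c)
}

#' @export
print.tag_sheet <- function(x, ...) {
  cat(sprintf("<tag_sheet> %d tag(s), %.1f x %.1f mm at %d dpi\n",
              nrow(x$geometry), x$width_mm, x$height_mm, x$dpi))
  invisible(x)
}

#' Write a tag sheet to SVG or PDF
#'
#' @param sheet A [make_sheet()] result.
#' @param path Output path; format chosen by extension (`.svg` or `.pdf`).
#' @return `path`, invisibly.
#' @export
write_sheet <- function(sheet, path) {
  if (grepl("\\.svg$", path, ignore.case = TRUE)) {
    writeLines(sheet$svg, path, useBytes = TRUE)
  } else if (grepl("\\.pdf$", path, ignore.case = TRUE)) {
    mm_in <- 1 / 25.4
    grDevices::pdf(path, width = sheet$width_mm * mm_in,
                   height = sheet$height_mm * mm_in)
    on.exit(grDevices::dev.off())
    graphics::par(mar = c(0, 0, 0, 0))
    graphics::plot.new()
    graphics::plot.window(xlim = c(0, sheet$width_mm),
                          ylim = c(sheet$height_mm, 0), asp = 1)
    for (i in seq_along(sheet$specs)) {
      s <- sheet$specs[[i]]
      g <- sheet$geometry[i, ]
      cell <- s$tag_side_mm / sheet$layout$n
      x0 <- g$cx_mm - s$tag_side_mm / 2
      y0 <- g$cy_mm - s$tag_side_mm / 2
      bits <- codeword_bits(s$codeword, sheet$layout$n_data)
      for (r in seq_len(sheet$layout$n)) {
        for (c in seq_len(sheet$layout$n)) {
          role <- sheet$layout$grid[r, c]
          black <- role == "b" ||
            (role == "d" && bits[match_bit(sheet$layout, r, c)] == 0)
          if (black) {
            graphics::rect(x0 + (c - 1) * cell, y0 + r * cell,
                           x0 + c * cell, y0 + (r - 1) * cell,
                           col = "black", border = NA)
          }
        }
      }
      th <- seq(0, 2 * pi, length.out = 120)
      graphics::lines(g$cx_mm + g$cut_diameter_mm / 2 * cos(th),
                      g$cy_mm + g$cut_diameter_mm / 2 * sin(th),
                      col = "magenta", lwd = 0.5)
      if (isTRUE(s$orientation_stripe)) {
        graphics::rect(x0, y0 - 0.2 * cell, x0 + s$tag_side_mm, y0,
                       col = "gold", border = NA)
      }
    }
  } else {
    abort("unsupported sheet format; use .svg or .pdf.")
  }
  invisible(path)
}
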
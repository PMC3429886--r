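#' Render a CGR trail as an SVG document
#'
#' One circle marker per trail point inside a unit-square viewport, with the
#' vertex labels C (top left), G (top right), A (bottom left), T (bottom
#' right) outside the square.
#'
#' @param trail A non-empty `CGRTrail`.
#' @param point_size Marker radius in user units of the 1x1 square
#'   (default 0.004).
#' @param size Rendered width/height in pixels (default 512).
#' @return Character scalar holding a standalone SVG document.
#' @export
render_cgr_svg <- function(trail, point_size = 0.004, size = 512) {
  stopifnot(inherits(trail, "CGRTrail"))
  if (nrow(trail$points) == 0L) stop("cannot render an empty CGR trail")
  pts <- trail$points
  circles <- sprintf('<circle cx="%.8f" cy="%.8f" r="%g" fill="black"/>',
                     pts[, "x"], pts[, "y"], point_size)
  labels <- c(
    '<text x="-0.01" y="-0.01" font-size="0.05" text-anchor="end">C</text>',
    '<text x="1.01" y="-0.01" font-size="0.05" text-anchor="start">G</text>',
    '<text x="-0.01" y="1.04" font-size="0.05" text-anchor="end">A</text>',
    '<text x="1.01" y="1.04" font-size="0.05" text-anchor="start">T</text>'
  )
  paste(c(
    '<?xml version="1.0" encoding="UTF-8"?>',
    sprintf(paste0('<svg xmlns="http://www.w3.org/2000/svg" width="%d" ',
                   'height="%d" viewBox="-0.1 -0.1 1.2 1.2">'),
            as.integer(size), as.integer(size)),
    '<rect x="0" y="0" width="1" height="1" fill="white" stroke="black" stroke-width="0.002"/>',
    labels,
    circles,
    '</svg>'
  ), collapse = "\n")
}

#' Render an FCGR as an 8-bit grayscale raster
#'
#' Maps cell values to pixel intensities monotonically: by default the
#' maximum count is black (0) and zero counts are white (255), matching the
#' usual presentation where dense CGR regions appear dark. Values are
#' normalized by the matrix maximum, so scaling all counts by a constant
#' leaves the image unchanged.
#'
#' @param f An `FCGR`.
#' @param gamma Exponent applied to the normalized values (default 1).
#' @param invert If `TRUE`, maximum count maps to white instead of black.
#' @return Integer matrix (`2^k` x `2^k`) of gray levels 0..255; row 1 is the
#'   top row of the image.
#' @export
render_fcgr_image <- function(f, gamma = 1.0, invert = FALSE) {
  stopifnot(inherits(f, "FCGR"), gamma > 0)
  v <- f$cells
  mx <- max(v)
  norm <- if (mx > 0) (v / mx)^gamma else v
  gray <- if (invert) norm else 1 - norm
  img <- matrix(as.integer(round(gray * 255)), nrow = nrow(v))
  img
}

#' Write a grayscale raster as plain PGM (P2) or PNG
#'
#' @param img Integer matrix of gray levels 0..255 as from
#'   [render_fcgr_image()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pgm <- function(img, path) {
  stopifnot(is.matrix(img), all(img >= 0L), all(img <= 255L))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(img), nrow(img)), "255"), con)
  writeLines(apply(img, 1L, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_pgm
#' @export
write_png <- function(img, path) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG output; use write_pgm()")
  }
  png::writePNG(img / 255, path)
  invisible(path)
}
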
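#' Design for a synthetic fiber-network image
#'
#' Describes the random fiber raster the renderer draws: straight
#' constant-width segments (white = fiber, black = background, the standard
#' binary convention for segmented fibrin micrographs) whose endpoints and
#' widths are recorded as ground truth. Widths are restricted to odd pixel
#' counts so the hard-thresholded rasterization is width-exact.
#'
#' @param n_fibers Number of fiber segments to draw.
#' @param widths Candidate fiber widths in pixels (odd integers >= 1).
#' @param image_shape Image size `c(rows, cols)` in pixels (each >= 32).
#' @param pixel_size Physical pixel size (nm/px), or `NA` for unscaled.
#' @param segments Optional explicit segment table with columns
#'   `x0, y0, x1, y1, width` (pixel coordinates); overrides random
#'   placement.
#' @return An object of class `network_design`.
#' @export
network_design <- function(n_fibers = 12, widths = c(3, 5, 7),
                           image_shape = c(128, 128), pixel_size = NA,
                           segments = NULL) {
  if (is.null(segments)) {
    if (n_fibers < 0) stop("`n_fibers` must be >= 0", call. = FALSE)
    if (any(widths < 1) || any(widths %% 2 != 1))
      stop("`widths` must be odd integers >= 1", call. = FALSE)
  }
  if (length(image_shape) != 2 || any(image_shape < 32))
    stop("`image_shape` must be two dimensions >= 32 px", call. = FALSE)
  structure(list(n_fibers = n_fibers, widths = widths,
                 image_shape = as.integer(image_shape),
                 pixel_size = pixel_size, segments = segments),
            class = "network_design")
}

# rasterize one constant-width segment onto a logical matrix:
# foreground where the pixel-center distance to the segment is < width/2
rasterize_segment <- function(mask, x0, y0, x1, y1, width) {
  nr <- nrow(mask); nc <- ncol(mask)
  half <- width / 2
  cx <- pmin(pmax(c(x0, x1), 1 - half), nc + half)
  cy <- pmin(pmax(c(y0, y1), 1 - half), nr + half)
  x0 <- cx[1]; x1 <- cx[2]; y0 <- cy[1]; y1 <- cy[2]
  xlo <- max(1L, floor(min(x0, x1) - half)); xhi <- min(nc, ceiling(max(x0, x1) + half))
  ylo <- max(1L, floor(min(y0, y1) - half)); yhi <- min(nr, ceiling(max(y0, y1) + half))
  if (xlo > xhi || ylo > yhi) return(mask)
  xs <- xlo:xhi; ys <- ylo:yhi
  px <- matrix(rep(xs, each = length(ys)), nrow = length(ys))
  py <- matrix(rep(ys, times = length(xs)), nrow = length(ys))
  dx <- x1 - x0; dy <- y1 - y0
  len2 <- dx^2 + dy^2
  if (len2 == 0) {
    d2 <- (px - x0)^2 + (py - y0)^2
  } else {
    t <- pmin(pmax(((px - x0) * dx + (py - y0) * dy) / len2, 0), 1)
    d2 <- (px - (x0 + t * dx))^2 + (py - (y0 + t * dy))^2
  }
  hit <- d2 < half^2
  sub <- mask[ys, xs, drop = FALSE]
  mask[ys, xs] <- sub | hit
  mask
}

#' Render a synthetic binary fiber-network image
#'
#' Draws every segment of a [network_design()] as a hard-thresholded
#' (anti-aliasing-free) constant-width bar, so that fiber widths are exact
#' in pixels. Returns the binary image together with the full segment list
#' as ground truth, enabling recovery tests of the image morphometry.
#'
#' @param design A [network_design()].
#' @param seed Optional integer seed for random segment placement.
#' @return A [fiber_image()] (foreground = fibers) with attribute `truth`,
#'   a list holding the rendered `segments` table and the design.
#' @export
render_fiber_network <- function(design = network_design(), seed = NULL) {
  stopifnot(inherits(design, "network_design"))
  nr <- design$image_shape[1]; nc <- design$image_shape[2]
  if (nr * nc == 0) stop("zero-area image", call. = FALSE)
  segs <- design$segments
  if (is.null(segs)) {
    segs <- with_seed_or_not(seed, {
      if (design$n_fibers == 0)
        data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                   y1 = numeric(0), width = numeric(0))
      else
        data.frame(
          x0 = runif(design$n_fibers, 1, nc),
          y0 = runif(design$n_fibers, 1, nr),
          x1 = runif(design$n_fibers, 1, nc),
          y1 = runif(design$n_fibers, 1, nr),
          width = sample(rep(design$widths, length.out = design$n_fibers)))
    })
  }
  mask <- matrix(FALSE, nr, nc)
  if (nrow(segs) > 0)
    for (i in seq_len(nrow(segs)))
      mask <- rasterize_segment(mask, segs$x0[i], segs$y0[i],
                                segs$x1[i], segs$y1[i], segs$width[i])
  img <- fiber_image(mask, pixel_size = design$pixel_size,
                     provenance = "rendered")
  attr(img, "truth") <- list(segments = segs, design = design)
  img
}
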
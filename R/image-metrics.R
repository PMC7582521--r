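#' Binary fiber-network image
#'
#' Container for a segmented fiber-network micrograph using the standard
#' convention: foreground (white, `TRUE`) pixels are fibrin fibers,
#' background (black, `FALSE`) pixels are pore space.
#'
#' @param pixels Logical or 0/1 numeric matrix.
#' @param pixel_size Physical pixel size in nm/px, or `NA` for unscaled
#'   output in pixel units.
#' @param provenance `"raw"`, `"preprocessed"` or `"rendered"`.
#' @return An object of class `fiber_image` (a logical matrix with
#'   attributes).
#' @export
fiber_image <- function(pixels, pixel_size = NA, provenance = "raw") {
  if (!is.matrix(pixels)) stop("`pixels` must be a matrix", call. = FALSE)
  m <- matrix(as.logical(pixels), nrow(pixels), ncol(pixels))
  if (anyNA(m)) stop("`pixels` must be binary without NA", call. = FALSE)
  structure(m, pixel_size = pixel_size, provenance = provenance,
            class = c("fiber_image", "matrix", "array"))
}

as_mask <- function(img) {
  if (inherits(img, "fiber_image"))
    matrix(as.logical(img), nrow(img), ncol(img))
  else matrix(as.logical(img), nrow(img), ncol(img))
}

# separable Gaussian smoothing with first-moment-corrected (local-linear)
# weights at the image border, so constants AND linear ramps are
# reproduced exactly everywhere — truncated kernels otherwise drag edge
# values toward the interior
gaussian_smooth <- function(m, sigma) {
  if (sigma <= 0) return(m)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(-r:r)^2 / (2 * sigma^2))
  smooth_dim <- function(x) {   # smooth along rows of x
    n <- nrow(x)
    W <- matrix(0, n, n)
    for (i in seq_len(n)) {
      lo <- max(1L, i - r); hi <- min(n, i + r)
      off <- (lo:hi) - i
      kk <- k[off + r + 1]
      s0 <- sum(kk); s1 <- sum(kk * off); s2 <- sum(kk * off^2)
      W[i, lo:hi] <- kk * (s2 - off * s1) / (s0 * s2 - s1^2)
    }
    W %*% x
  }
  t(smooth_dim(t(smooth_dim(m))))
}

#' Bandpass-filter a grayscale image before segmentation
#'
#' Difference-of-Gaussians bandpass that removes large-scale intensity
#' variations (illumination, charging gradients) above `large_cutoff`
#' pixels and small structures below `small_cutoff` pixels — the standard
#' preprocessing applied to electron micrographs of fibrin networks before
#' binarization. Cutoffs are mapped to Gaussian sigmas as `cutoff / 2`.
#' The filtered image is re-centered on the input mean and clipped to the
#' input range (no contrast stretching, so suppressed features stay
#' suppressed).
#'
#' @param gray Numeric matrix (any intensity scale).
#' @param large_cutoff Remove variations larger than this (px, default 20).
#' @param small_cutoff Remove structures smaller than this (px, default 3).
#' @return Numeric matrix on the input intensity scale.
#' @export
bandpass_preprocess <- function(gray, large_cutoff = 20, small_cutoff = 3) {
  if (!is.matrix(gray) || !is.numeric(gray))
    stop("`gray` must be a numeric matrix", call. = FALSE)
  if (small_cutoff >= large_cutoff)
    stop("`small_cutoff` must be below `large_cutoff`", call. = FALSE)
  lo <- min(gray); hi <- max(gray)
  if (lo == hi) return(gray)
  bp <- gaussian_smooth(gray, small_cutoff / 2) -
        gaussian_smooth(gray, large_cutoff / 2)
  out <- bp + mean(gray)
  pmin(pmax(out, lo), hi)
}

# Otsu threshold on a 256-bin histogram: maximize between-class variance
otsu_threshold <- function(gray) {
  lo <- min(gray); hi <- max(gray)
  breaks <- seq(lo, hi, length.out = 257)
  h <- tabulate(findInterval(gray, breaks, all.inside = TRUE), nbins = 256)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-257]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[256]
  bcv <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  bcv[!is.finite(bcv)] <- -Inf
  mids[which.max(bcv)]
}

#' Binarize a (filtered) grayscale image into a fiber mask
#'
#' Global-threshold segmentation with an Otsu-style criterion (the
#' threshold maximizing between-class intensity variance); the brighter
#' class becomes foreground, matching the convention that fibers image
#' bright. For inverted-contrast inputs set `invert = TRUE` so foreground
#' still maps to fibers.
#'
#' @param gray Numeric matrix.
#' @param pixel_size Optional nm/px carried onto the result.
#' @param invert Set when fibers are the darker class.
#' @return A [fiber_image()].
#' @export
binarize <- function(gray, pixel_size = NA, invert = FALSE) {
  if (!is.matrix(gray) || !is.numeric(gray))
    stop("`gray` must be a numeric matrix", call. = FALSE)
  if (min(gray) == max(gray)) {
    warning("constant image: returning all-background mask")
    return(fiber_image(matrix(FALSE, nrow(gray), ncol(gray)),
                       pixel_size = pixel_size, provenance = "preprocessed"))
  }
  thr <- otsu_threshold(gray)
  mask <- if (invert) gray <= thr else gray > thr
  fiber_image(mask, pixel_size = pixel_size, provenance = "preprocessed")
}

shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0L, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

#' Topology-preserving skeletonization (Zhang-Suen thinning)
#'
#' Iteratively peels boundary pixels from the foreground while preserving
#' connectivity, leaving a one-pixel-wide, 8-connected medial skeleton.
#'
#' @param img A [fiber_image()] or binary matrix.
#' @return Logical matrix of skeleton pixels.
#' @export
skeletonize <- function(img) {
  p <- as_mask(img) * 1L
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      n  <- shift_mat(p,  1, 0); s  <- shift_mat(p, -1, 0)
      e  <- shift_mat(p, 0, -1); w  <- shift_mat(p, 0,  1)
      ne <- shift_mat(p, 1, -1); se <- shift_mat(p, -1, -1)
      sw <- shift_mat(p, -1, 1); nw <- shift_mat(p, 1,  1)
      # neighbor ring in Zhang-Suen order P2..P9 = N, NE, E, SE, S, SW, W, NW
      B <- n + ne + e + se + s + sw + w + nw
      ring <- list(n, ne, e, se, s, sw, w, nw, n)
      A <- 0L
      for (i in 1:8) A <- A + (ring[[i]] == 0L & ring[[i + 1]] == 1L)
      cond <- p == 1L & B >= 2 & B <= 6 & A == 1L
      if (sub == 1) cond <- cond & (n * e * s == 0L) & (e * s * w == 0L)
      else          cond <- cond & (n * e * w == 0L) & (n * s * w == 0L)
      if (any(cond)) { p[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  p == 1L
}

#' Per-pixel fiber diameter along the skeleton
#'
#' Skeletonizes the foreground and, at every skeleton pixel, measures the
#' local fiber diameter as `2 * d - 1` where `d` is the Euclidean distance
#' to the nearest background pixel (so a bar exactly `w` pixels wide reads
#' `w`). The mean over all skeleton pixels is the per-image diameter; the
#' full per-pixel sample is returned for diameter histograms.
#'
#' @param img A [fiber_image()] with at least one foreground pixel.
#' @return List with `mean_diameter` (px, or nm when the image carries a
#'   `pixel_size`), `diameters` (per skeleton pixel, same units),
#'   `n_skeleton` and `flags` (contains `"degenerate"` when the image has
#'   no background, in which case the diameter is bounded by the smaller
#'   image dimension).
#' @export
fiber_diameter <- function(img) {
  mask <- as_mask(img)
  if (!any(mask)) stop("empty foreground: no fibers to measure",
                       call. = FALSE)
  px <- attr(img, "pixel_size") %||% NA
  scale <- if (is.na(px)) 1 else px
  if (all(mask)) {
    d <- min(dim(mask)) * scale
    return(list(mean_diameter = d, diameters = d, n_skeleton = 0L,
                flags = "degenerate"))
  }
  skel <- skeletonize(mask)
  dist <- EBImage::distmap(mask * 1)
  dia <- (2 * dist[skel] - 1) * scale
  list(mean_diameter = mean(dia), diameters = as.numeric(dia),
       n_skeleton = sum(skel), flags = character(0))
}

# connected components of a logical mask; EBImage::bwlabel is 4-connected,
# which is the background connectivity convention used for pores
label_components_4 <- function(mask) {
  EBImage::bwlabel(mask * 1)
}

#' Porosity and pore statistics of a fiber-network image
#'
#' Porosity is the background-pixel fraction of the image. Pores are
#' discrete clusters of background pixels enclosed by fibers: 4-connected
#' background components that do not touch the image border (a
#' border-touching component is open pore space, not an enclosed pore).
#'
#' @param img A [fiber_image()].
#' @return List with `porosity` (fraction), `mean_pore_area` (px^2, or
#'   nm^2 with a `pixel_size`; `NA` when there are no enclosed pores) and
#'   `n_pores`.
#' @export
pore_metrics <- function(img) {
  mask <- as_mask(img)
  px <- attr(img, "pixel_size") %||% NA
  area_scale <- if (is.na(px)) 1 else px^2
  bg <- !mask
  porosity <- mean(bg)
  lab <- label_components_4(bg)
  border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border <- border[border != 0]
  sizes <- tabulate(lab[lab != 0])
  enclosed <- setdiff(seq_along(sizes)[sizes > 0], border)
  list(porosity = porosity,
       mean_pore_area = if (length(enclosed))
         mean(sizes[enclosed]) * area_scale else NA_real_,
       n_pores = length(enclosed))
}

# 8-connected neighbor count on a logical matrix
neighbor_count_8 <- function(m) {
  mi <- m * 1L
  shift_mat(mi, 1, 0) + shift_mat(mi, -1, 0) + shift_mat(mi, 0, 1) +
    shift_mat(mi, 0, -1) + shift_mat(mi, 1, 1) + shift_mat(mi, 1, -1) +
    shift_mat(mi, -1, 1) + shift_mat(mi, -1, -1)
}

# single-linkage grouping of points within `radius`; returns cluster count
merge_points <- function(pts, radius) {
  n <- nrow(pts)
  if (n == 0) return(0L)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (i in seq_len(n - 1)) {
    d2 <- (pts[(i + 1):n, 1] - pts[i, 1])^2 + (pts[(i + 1):n, 2] - pts[i, 2])^2
    for (j in which(d2 <= radius^2)) {
      ri <- find(i); rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(n), find, integer(1))))
}

#' Fiber intersection density
#'
#' Counts fiber overlaps as branch points of the skeleton (skeleton pixels
#' with at least 3 skeleton neighbors, 8-connected). Branch points closer
#' than `merge_radius` are merged into a single intersection, since
#' thinning renders one crossing as a small cluster of branch pixels. The
#' density is the merged count divided by the image area (per um^2 when
#' the image carries a `pixel_size` in nm/px, else per px^2).
#'
#' @param img A [fiber_image()].
#' @param merge_radius Merge distance in pixels (default 5).
#' @return List with `n_intersections`, `intersection_density` and
#'   `branch_points` (matrix of row/col coordinates before merging).
#' @export
intersection_density <- function(img, merge_radius = 5) {
  mask <- as_mask(img)
  px <- attr(img, "pixel_size") %||% NA
  area <- prod(dim(mask)) * (if (is.na(px)) 1 else (px / 1000)^2)
  if (!any(mask))
    return(list(n_intersections = 0L, intersection_density = 0,
                branch_points = matrix(numeric(0), 0, 2)))
  skel <- skeletonize(mask)
  nb <- neighbor_count_8(skel)
  bp <- which(skel & nb >= 3, arr.ind = TRUE)
  k <- merge_points(bp, merge_radius)
  list(n_intersections = as.integer(k),
       intersection_density = k / area,
       branch_points = bp)
}

#' All structural metrics of a fiber-network image
#'
#' Composes [fiber_diameter()], [pore_metrics()] and
#' [intersection_density()] into the standard five-metric description of a
#' fibrin network: mean fiber diameter, porosity, mean pore area, pore
#' count and intersection density. Physical units are used when the image
#' carries a `pixel_size` (nm/px); otherwise pixel units.
#'
#' @param img A [fiber_image()].
#' @param merge_radius Passed to [intersection_density()].
#' @return A `structural_metrics` list with fields `mean_diameter`,
#'   `porosity`, `mean_pore_area`, `n_pores`, `intersection_density`,
#'   `foreground_fraction` and `flags`.
#' @export
measure_image <- function(img, merge_radius = 5) {
  stopifnot(inherits(img, "fiber_image"))
  mask <- as_mask(img)
  pores <- pore_metrics(img)
  inter <- intersection_density(img, merge_radius)
  if (any(mask)) {
    dia <- fiber_diameter(img)
  } else {
    dia <- list(mean_diameter = NA_real_, diameters = numeric(0),
                flags = "empty_foreground")
  }
  structure(list(mean_diameter = dia$mean_diameter,
                 porosity = pores$porosity,
                 # derived as the exact complement so that
                 # porosity + foreground_fraction == 1 holds identically
                 mean_pore_area = pores$mean_pore_area,
                 n_pores = pores$n_pores,
                 intersection_density = inter$intersection_density,
                 foreground_fraction = 1 - pores$porosity,
                 diameters = dia$diameters,
                 flags = dia$flags),
            class = "structural_metrics")
}

#' @export
print.structural_metrics <- function(x, ...) {
  cat("<structural_metrics>\n")
  cat(sprintf("  mean diameter        %.3g\n", x$mean_diameter))
  cat(sprintf("  porosity             %.4f\n", x$porosity))
  cat(sprintf("  mean pore area       %.4g\n", x$mean_pore_area))
  cat(sprintf("  n pores              %d\n", x$n_pores))
  cat(sprintf("  intersection density %.4g\n", x$intersection_density))
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
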
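# readers/writers for the delimited and image formats used by the pipeline

#' Read a stress-ramp curve from CSV
#'
#' Expects columns `sigma` (Pa) and `gamma` (strain).
#' @param path CSV file path.
#' @return A [stress_ramp()].
#' @export
read_ramp_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("sigma", "gamma") %in% names(d)))
    stop("expected columns sigma, gamma in ", path, call. = FALSE)
  stress_ramp(d$sigma, d$gamma)
}

#' Read a polymerization time series from CSV
#'
#' Expects columns `time` (s), `Gp`, `Gpp` (Pa).
#' @param path CSV file path.
#' @return A `rheology_ts` data frame.
#' @export
read_rheology_csv <- function(path) {
  d <- read.csv(path)
  if (!all(c("time", "Gp", "Gpp") %in% names(d)))
    stop("expected columns time, Gp, Gpp in ", path, call. = FALSE)
  class(d) <- c("rheology_ts", "data.frame")
  d
}

#' Read a fibrinolysis time course from CSV
#'
#' Expects columns `time_min` and `fluorescence`.
#' @param path CSV file path.
#' @param dilution_factor Fold dilution applied to the samples.
#' @return A [lysis_series()].
#' @export
read_lysis_csv <- function(path, dilution_factor = 12) {
  d <- read.csv(path)
  if (!all(c("time_min", "fluorescence") %in% names(d)))
    stop("expected columns time_min, fluorescence in ", path, call. = FALSE)
  lysis_series(d$time_min, d$fluorescence, dilution_factor)
}

#' Read a fiber-network image from PNG or TIFF
#'
#' Grayscale images are returned as a numeric matrix in `[0, 1]`; RGB(A)
#' images are averaged to gray. Use [binarize()] to obtain a
#' [fiber_image()].
#'
#' @param path Image file (.png, .tif/.tiff).
#' @return Numeric matrix.
#' @export
read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  a <- switch(ext,
              png = png::readPNG(path),
              tif = , tiff = {
                if (!requireNamespace("tiff", quietly = TRUE))
                  stop("the tiff package is required for TIFF input",
                       call. = FALSE)
                tiff::readTIFF(path)
              },
              stop("unsupported image format: .", ext, call. = FALSE))
  if (length(dim(a)) == 3) a <- apply(a[, , 1:min(3, dim(a)[3])], c(1, 2), mean)
  a
}

#' Write a binary fiber image as 8-bit PNG
#'
#' @param img A [fiber_image()] or numeric matrix in `[0, 1]`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  m <- if (inherits(img, "fiber_image")) as_mask(img) * 1 else img
  png::writePNG(m, path)
  invisible(path)
}

#' Write nonlinear features as a one-row CSV and JSON sidecar
#'
#' @param features A `nonlinear_features`.
#' @param csv_path,json_path Output paths (either may be `NULL`).
#' @return The feature row as a data frame, invisibly.
#' @export
write_features <- function(features, csv_path = NULL, json_path = NULL) {
  num <- features[c("K0", "sigma0", "gamma0", "Kmax", "sigma_max",
                    "gamma_max", "sigmaR", "gammaR")]
  row <- as.data.frame(num)
  row$flags <- paste(features$flags, collapse = ";")
  if (!is.null(csv_path)) write.csv(row, csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(c(num, list(flags = features$flags)), json_path,
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(row)
}
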
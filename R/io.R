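#' Read a grayscale image as a density field
#'
#' Reads single-channel TIFF or PNG (8- or 16-bit, or float TIFF);
#' multi-channel images are averaged to one channel. Values are optionally
#' min-max normalized to \[0, 1\] (the default, since persistence is
#' shift-invariant but thresholds are specified on likelihoods).
#'
#' @param path image file (.tif/.tiff/.png).
#' @param pixel_size_um pixel size to attach.
#' @param normalize min-max normalize to \[0, 1\] (default TRUE).
#' @return a \code{\link{density_field}}.
#' @export
read_density_image <- function(path, pixel_size_um = 1, normalize = TRUE) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                tif = , tiff = tiff::readTIFF(path),
                png = png::readPNG(path),
                stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3L) img <- apply(img, c(1, 2), mean)
  f <- density_field(img, pixel_size_um)
  if (normalize) f <- normalize_field(f)
  f
}

#' Write a density field or matrix as an image
#'
#' TIFF output is 32-bit float (values written as-is); PNG output clamps
#' to \[0, 1\].
#'
#' @param values a \code{density_field}, matrix, or logical mask.
#' @param path output path (.tif/.tiff/.png).
#' @return \code{path}, invisibly.
#' @export
write_density_image <- function(values, path) {
  if (inherits(values, "density_field")) values <- values$values
  if (is.logical(values)) values <- matrix(as.numeric(values),
                                           nrow(values), ncol(values))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(values, path, bits.per.sample = 32L)
  } else if (ext == "png") {
    png::writePNG(pmin(pmax(values, 0), 1), path)
  } else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Pipeline configuration
#'
#' All tunable parameters of the skeletonization and summarization
#' workflow, with the field's printed defaults where they exist: matching
#' radius 3 px (two-photon setting), optical thickness 2.5 um, section
#' spacing 40 um, analysis voxel 100 um, haircut 10 px. The persistence
#' threshold \code{delta} has no universal default and must be chosen per
#' dataset (see \code{\link{sweep_delta}}).
#'
#' @param pixel_size_um pixel size of the input images.
#' @param delta persistence threshold for Morse simplification.
#' @param floor minimum retained saddle edge value.
#' @param smooth_sigma Gaussian pre-smoothing sigma in pixels.
#' @param mask mask mode: "otsu", "none", or a file path to a binary image.
#' @param haircut_len_px spur pruning threshold.
#' @param optical_thickness_um effective optical slab thickness.
#' @param section_spacing_um distance between imaged sections.
#' @param voxel_um analysis voxel for projection densities.
#' @param Dr evaluation matching radius in pixels.
#' @param normalize min-max normalize input images.
#' @param seed RNG seed recorded in the manifest.
#' @return object of class \code{pipeline_config} (a list).
#' @export
pipeline_config <- function(pixel_size_um = 1, delta = 0, floor = 0,
                            smooth_sigma = 1, mask = "otsu",
                            haircut_len_px = 10L,
                            optical_thickness_um = 2.5,
                            section_spacing_um = 40, voxel_um = 100,
                            Dr = 3, normalize = TRUE, seed = 0L) {
  cfg <- list(pixel_size_um = pixel_size_um, delta = delta, floor = floor,
              smooth_sigma = smooth_sigma, mask = mask,
              haircut_len_px = as.integer(haircut_len_px),
              optical_thickness_um = optical_thickness_um,
              section_spacing_um = section_spacing_um, voxel_um = voxel_um,
              Dr = Dr, normalize = normalize, seed = as.integer(seed))
  for (nm in c("pixel_size_um", "optical_thickness_um",
               "section_spacing_um", "voxel_um"))
    if (cfg[[nm]] <= 0) stop(nm, " must be positive")
  if (cfg$delta < 0 || cfg$floor < 0 || cfg$smooth_sigma < 0 || cfg$Dr < 0)
    stop("delta, floor, smooth_sigma and Dr must be non-negative")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration (plain-text JSON)
#' @param config a \code{\link{pipeline_config}}.
#' @param path file path.
#' @return \code{path} invisibly / the restored \code{pipeline_config}.
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, x)
}
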
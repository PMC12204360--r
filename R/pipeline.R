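#' Skeletonize a likelihood image by persistence-guided discrete Morse
#' extraction
#'
#' The full skeletonization workflow on one image: Gaussian smoothing of
#' the likelihood into a density field; extraction of the
#' persistence-simplified Morse graph (ridges of the density landscape,
#' bridging through low-density gaps); masking of low-likelihood false
#' detections; per-component maximal spanning trees; haircut pruning of
#' short spurs; and decomposition into skeletal fragments between critical
#' points.
#'
#' @param x a \code{\link{density_field}}, numeric matrix, or image file
#'   path.
#' @param delta persistence threshold; ridges of lower importance are
#'   treated as noise. Choose per dataset (see \code{\link{sweep_delta}}).
#' @param floor minimum retained saddle edge value (default 0).
#' @param smooth_sigma pre-smoothing Gaussian sigma in pixels (default 1;
#'   0 disables).
#' @param mask "otsu" (threshold the smoothed field), "none", or a logical
#'   matrix.
#' @param haircut_len_px spur pruning threshold in pixels (default 10).
#' @param pixel_size_um pixel size when \code{x} is a matrix or path.
#' @param normalize min-max normalize the input first (default TRUE for
#'   file input, FALSE otherwise).
#' @return object of class \code{dm_skeleton}: the input and smoothed
#'   fields, the raw Morse graph, the masked/spanning/pruned skeleton
#'   graph, the fragment set, critical points, per-stage counts and the
#'   parameters used.
#' @examples
#' ph <- generate_phantom(phantom_spec(seed = 1, shape = c(64, 64)))
#' sk <- dm_skeletonize(ph$field, delta = 0.3)
#' print(sk)
#' @export
dm_skeletonize <- function(x, delta, floor = 0, smooth_sigma = 1,
                           mask = "otsu", haircut_len_px = 10L,
                           pixel_size_um = 1, normalize = NULL) {
  if (is.character(x)) {
    field <- read_density_image(x, pixel_size_um,
                                normalize = isTRUE(normalize %||% TRUE))
  } else {
    field <- as_density_field(x, pixel_size_um)
    if (isTRUE(normalize)) field <- normalize_field(field)
  }
  sm <- smooth_density(field, smooth_sigma)
  counts <- list()
  empty_input <- all(sm$values == 0) || length(unique(as.vector(sm$values))) == 1L
  if (empty_input) {
    warning("constant input field: empty skeleton returned")
    gs <- skeleton_graph(integer(0), matrix(integer(0), 0, 2),
                         dim(field$values), numeric(0), field$pixel_size_um)
    frags <- extract_fragments(gs)
    return(structure(list(field = field, smoothed = sm, morse = NULL,
                          skeleton = gs, fragments = frags,
                          critical = find_critical_points(gs),
                          counts = list(), params = list(delta = delta)),
                     class = "dm_skeleton"))
  }
  g <- extract_morse_graph(sm, delta = delta, floor = floor)
  counts$morse_nodes <- length(g$nodes)
  counts$morse_edges <- nrow(g$edges)
  gm <- if (identical(mask, "none")) as_skeleton_graph(g) else {
    mk <- if (is.matrix(mask)) mask else otsu_mask(sm)
    mask_graph(g, mk)
  }
  counts$masked_nodes <- length(gm$nodes)
  counts$masked_edges <- nrow(gm$edges)
  gf <- max_spanning_forest(gm)
  counts$forest_edges <- nrow(gf$edges)
  gs <- haircut(gf, haircut_len_px)
  counts$pruned_nodes <- length(gs$nodes)
  counts$pruned_edges <- nrow(gs$edges)
  frags <- extract_fragments(gs)
  counts$fragments <- length(frags)
  counts$total_length_um <- sum(fragment_lengths(frags))
  structure(list(field = field, smoothed = sm, morse = g, skeleton = gs,
                 fragments = frags, critical = find_critical_points(gs),
                 counts = counts,
                 params = list(delta = delta, floor = floor,
                               smooth_sigma = smooth_sigma,
                               haircut_len_px = haircut_len_px,
                               mask = if (is.matrix(mask)) "matrix" else mask)),
            class = "dm_skeleton")
}

#' @export
print.dm_skeleton <- function(x, ...) {
  cat("dm_skeleton\n")
  cat(sprintf("  grid: %d x %d px (%.3g um/px)\n",
              nrow(x$field$values), ncol(x$field$values),
              x$field$pixel_size_um))
  cat(sprintf("  fragments: %d, total length %.4g um\n",
              length(x$fragments), sum(fragment_lengths(x$fragments))))
  cat(sprintf("  critical points: %d branch, %d end\n",
              length(x$critical$branch), length(x$critical$ends)))
  invisible(x)
}

#' @export
summary.dm_skeleton <- function(object, ...) {
  lens <- fragment_lengths(object$fragments)
  out <- list(params = object$params, counts = object$counts,
              n_fragments = length(lens),
              total_length_um = sum(lens),
              fragment_length_summary = if (length(lens)) summary(lens)
              else NULL)
  class(out) <- "summary.dm_skeleton"
  out
}

#' @export
print.summary.dm_skeleton <- function(x, ...) {
  cat("dm_skeleton summary\n")
  cat("  parameters:", paste(names(x$params),
                             unlist(lapply(x$params, format)),
                             sep = "=", collapse = ", "), "\n")
  for (nm in names(x$counts))
    cat(sprintf("  %s: %s\n", nm, format(x$counts[[nm]])))
  if (!is.null(x$fragment_length_summary)) {
    cat("  fragment lengths (um):\n")
    print(x$fragment_length_summary)
  }
  invisible(x)
}

#' @export
plot.dm_skeleton <- function(x, ...) {
  v <- x$field$values
  graphics::image(t(v)[, nrow(v):1], col = grDevices::gray.colors(256),
                  axes = FALSE, asp = nrow(v) / ncol(v), ...)
  nr <- nrow(v); nc <- ncol(v)
  for (m in x$fragments$coords) {
    graphics::lines((m[, "col"]) / (nc - 1), 1 - (m[, "row"]) / (nr - 1),
                    col = "red", lwd = 1)
  }
  invisible(x)
}

#' Binary skeleton image of a skeletonization result
#' @param x a \code{dm_skeleton}.
#' @return logical matrix with TRUE at skeleton pixels.
#' @export
skeleton_mask <- function(x) {
  stopifnot(inherits(x, "dm_skeleton"))
  fragments_to_mask(x$fragments, dim(x$field$values))
}

#' Sweep the persistence threshold
#'
#' Runs the Morse extraction over a grid of \code{delta} values and reports
#' the retained saddle count and graph size for each, to guide the choice
#' of threshold (run with a low threshold first, then raise it until noise
#' ridges disappear).
#'
#' @param field a \code{\link{density_field}} or matrix.
#' @param deltas numeric vector of thresholds; default 10 values from 0 to
#'   the maximum finite persistence.
#' @param floor minimum saddle edge value.
#' @return data.frame with columns \code{delta}, \code{n_saddles},
#'   \code{n_nodes}, \code{n_edges}.
#' @export
sweep_delta <- function(field, deltas = NULL, floor = 0) {
  field <- as_density_field(field)
  if (is.null(deltas)) {
    pers <- compute_persistence_0d(field)
    pmax_ <- if (nrow(pers)) max(pers$persistence) else 0
    deltas <- seq(0, pmax_, length.out = 10)
  }
  rows <- lapply(deltas, function(d) {
    g <- extract_morse_graph(field, delta = d, floor = floor)
    data.frame(delta = d, n_saddles = nrow(g$saddles),
               n_nodes = length(g$nodes), n_edges = nrow(g$edges))
  })
  do.call(rbind, rows)
}

resolve_mask <- function(mask) {
  if (is.matrix(mask) || identical(mask, "otsu") || identical(mask, "none"))
    return(mask)
  if (is.character(mask) && file.exists(mask))
    return(read_density_image(mask, normalize = FALSE)$values > 0.5)
  stop("mask must be 'otsu', 'none', a matrix, or an existing image path")
}

#' Run the full skeletonization workflow over images
#'
#' Executes smoothing, Morse extraction, masking, spanning forests,
#' haircut, fragment decomposition and GeoJSON vectorization for each
#' input image, writing per-image fragment documents and a run manifest
#' (configuration, its hash, package version, per-stage counts). Any stage
#' error aborts with a stage-tagged message and removes partial outputs of
#' the failing image.
#'
#' @param config a \code{\link{pipeline_config}}.
#' @param images character vector of image paths, or a named list of
#'   \code{density_field} objects.
#' @param out_dir output directory (created if missing).
#' @return the manifest (invisibly), also written to
#'   \code{out_dir/manifest.json}.
#' @export
run_pipeline <- function(config, images, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.json")
  write_config(config, cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  entries <- list()
  nms <- if (is.character(images)) images else names(images)
  if (is.null(nms) || any(!nzchar(nms)))
    nms <- paste0("image", seq_along(images))
  for (i in seq_along(images)) {
    nm <- if (is.character(images)) basename(images[[i]]) else nms[[i]]
    out_geo <- file.path(out_dir,
                         paste0(tools::file_path_sans_ext(nm), ".geojson"))
    res <- tryCatch({
      sk <- dm_skeletonize(
        if (is.character(images)) images[[i]] else images[[i]],
        delta = config$delta, floor = config$floor,
        smooth_sigma = config$smooth_sigma, mask = resolve_mask(config$mask),
        haircut_len_px = config$haircut_len_px,
        pixel_size_um = config$pixel_size_um,
        normalize = config$normalize)
      doc <- to_vector_document(sk$fragments,
                                pixel_size_um = config$pixel_size_um)
      write_vector_document(doc, out_geo)
      list(image = nm, output = basename(out_geo), counts = sk$counts,
           stages = c("smooth", "morse", "mask", "spanning_forest",
                      "haircut", "fragments"))
    }, error = function(e) {
      if (file.exists(out_geo)) unlink(out_geo)
      stop("pipeline stage failed for ", nm, ": ", conditionMessage(e),
           call. = FALSE)
    })
    entries[[length(entries) + 1L]] <- res
  }
  manifest <- list(
    package = "dmskel",
    version = as.character(utils::packageVersion("dmskel")),
    config = unclass(config),
    config_md5 = cfg_hash,
    images = entries)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
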
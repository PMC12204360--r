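#' Read a single-neuron morphology in SWC format
#'
#' Standard 7-column SWC: id, type, x, y, z, radius, parent (-1 for roots).
#' Comment lines start with '#'. Parent pointers must form a forest (no
#' cycles, no orphan references).
#'
#' @param path path to an SWC file.
#' @return data.frame with columns \code{id}, \code{type}, \code{x},
#'   \code{y}, \code{z}, \code{radius}, \code{parent} (coordinates in the
#'   file's units, conventionally micrometers).
#' @export
read_swc <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (length(lines) == 0L) stop("empty SWC file: ", path)
  tok <- strsplit(trimws(lines), "\\s+")
  if (any(vapply(tok, length, 0L) != 7L))
    stop("malformed SWC record (expected 7 columns): ", path)
  m <- matrix(as.numeric(unlist(tok)), ncol = 7, byrow = TRUE)
  swc <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                    x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                    parent = as.integer(m[, 7]))
  validate_swc(swc)
}

#' Validate (and return) an SWC morphology table
#' @param swc data.frame with SWC columns.
#' @return the validated data.frame.
#' @export
validate_swc <- function(swc) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(swc))) stop("missing SWC columns")
  if (anyDuplicated(swc$id)) stop("duplicate SWC ids")
  refs <- swc$parent[swc$parent != -1L]
  if (!all(refs %in% swc$id)) stop("orphaned SWC parent references")
  # cycle check: follow parents with a visit bound
  pmap <- stats::setNames(swc$parent, swc$id)
  for (start in swc$id) {
    cur <- start; steps <- 0L
    while (cur != -1L) {
      cur <- pmap[[as.character(cur)]]
      steps <- steps + 1L
      if (steps > length(pmap)) stop("cycle in SWC parent pointers")
    }
  }
  swc
}

#' Voxelize a neuron morphology to a per-voxel length raster
#'
#' Each child-to-parent segment is subdivided into sub-segments no longer
#' than a quarter voxel; each sub-segment's length accrues to the voxel
#' containing its midpoint. Voxel indices are absolute:
#' \code{floor(coordinate / voxel_size)}, so rasters of different neurons
#' on the same voxel size share a common grid. The raster sums to the total
#' cable length of the neuron exactly (sub-segment lengths partition each
#' segment).
#'
#' @param swc SWC data.frame (see \code{\link{read_swc}}); coordinates in
#'   micrometers.
#' @param voxel_size_um voxel edge length in micrometers (e.g. 100).
#' @return data.frame of occupied voxels with integer columns \code{i},
#'   \code{j}, \code{k} (voxel indices of x, y, z) and \code{length_um};
#'   attribute \code{voxel_size_um}. Zero rows for a soma-only neuron.
#' @export
voxelize_swc <- function(swc, voxel_size_um) {
  swc <- validate_swc(swc)
  stopifnot(voxel_size_um > 0)
  child <- swc[swc$parent != -1L, , drop = FALSE]
  if (nrow(child) == 0L) {
    out <- data.frame(i = integer(0), j = integer(0), k = integer(0),
                      length_um = numeric(0))
    attr(out, "voxel_size_um") <- voxel_size_um
    return(out)
  }
  pi_ <- match(child$parent, swc$id)
  p0 <- cbind(child$x, child$y, child$z)
  p1 <- cbind(swc$x[pi_], swc$y[pi_], swc$z[pi_])
  seg_len <- sqrt(rowSums((p1 - p0)^2))
  keep <- seg_len > 0
  p0 <- p0[keep, , drop = FALSE]; p1 <- p1[keep, , drop = FALSE]
  seg_len <- seg_len[keep]
  key <- character(0); wlen <- numeric(0)
  acc <- new.env(hash = TRUE, parent = emptyenv())
  for (s in seq_along(seg_len)) {
    nsub <- max(1L, ceiling(seg_len[s] / (voxel_size_um / 4)))
    t0 <- (seq_len(nsub) - 1) / nsub
    t1 <- seq_len(nsub) / nsub
    tm <- (t0 + t1) / 2
    mids <- matrix(p0[s, ], nsub, 3, byrow = TRUE) +
      outer(tm, p1[s, ] - p0[s, ])
    vox <- floor(mids / voxel_size_um)
    k <- paste(vox[, 1], vox[, 2], vox[, 3], sep = ",")
    sub_len <- seg_len[s] / nsub
    for (kk in k) {
      prev <- if (!is.null(acc[[kk]])) acc[[kk]] else 0
      acc[[kk]] <- prev + sub_len
    }
  }
  keys <- ls(acc)
  parts <- do.call(rbind, strsplit(keys, ","))
  out <- data.frame(i = as.integer(parts[, 1]), j = as.integer(parts[, 2]),
                    k = as.integer(parts[, 3]),
                    length_um = vapply(keys, function(kk) acc[[kk]], 0))
  rownames(out) <- NULL
  out <- out[order(out$i, out$j, out$k), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "voxel_size_um") <- voxel_size_um
  out
}

#' Total cable length of an SWC morphology
#' @param swc SWC data.frame.
#' @return total length in the coordinate units (sum of child-to-parent
#'   segment lengths).
#' @export
swc_total_length <- function(swc) {
  swc <- validate_swc(swc)
  child <- swc[swc$parent != -1L, , drop = FALSE]
  if (nrow(child) == 0L) return(0)
  pi_ <- match(child$parent, swc$id)
  sum(sqrt((child$x - swc$x[pi_])^2 + (child$y - swc$y[pi_])^2 +
             (child$z - swc$z[pi_])^2))
}
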
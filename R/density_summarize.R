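#' Rasterize fragments to an areal line density
#'
#' Each segment between consecutive fragment vertices contributes its
#' physical length, divided by the pixel area, to the pixel containing the
#' segment midpoint. Midpoints falling exactly on a pixel border are
#' assigned to the lower-index pixel, so the accounting is deterministic and
#' total length is conserved exactly:
#' \code{sum(density * pixel_area) == sum(fragment_lengths(frags))}.
#'
#' @param frags a \code{\link{fragment_set}} with coordinates in pixel units.
#' @param dim target grid dimensions c(nr, nc).
#' @param pixel_size_um pixel size (defaults to the fragment set's).
#' @return object of class \code{areal_density}: list with \code{values}
#'   (matrix, um of length per um^2) and \code{pixel_size_um}.
#' @export
rasterize_density <- function(frags, dim, pixel_size_um = frags$pixel_size_um) {
  stopifnot(inherits(frags, "fragment_set"))
  nr <- dim[1]; nc <- dim[2]
  vals <- matrix(0, nr, nc)
  bad <- integer(0)
  for (i in seq_along(frags$coords)) {
    m <- frags$coords[[i]]
    if (any(m[, "row"] < -0.5 | m[, "row"] > nr - 0.5 |
            m[, "col"] < -0.5 | m[, "col"] > nc - 0.5)) {
      bad <- c(bad, i); next
    }
    if (nrow(m) < 2) next
    d <- diff(m)
    seg_len <- sqrt(d[, 1L]^2 + d[, 2L]^2) * pixel_size_um
    mid <- (m[-nrow(m), , drop = FALSE] + m[-1L, , drop = FALSE]) / 2
    # pixel containing the midpoint; exact borders go to the lower index
    pr <- pmax(0, pmin(nr - 1L, ceiling(mid[, "row"] - 0.5)))
    pc <- pmax(0, pmin(nc - 1L, ceiling(mid[, "col"] - 0.5)))
    idx <- cbind(pr + 1L, pc + 1L)
    for (s in seq_along(seg_len))
      vals[idx[s, 1L], idx[s, 2L]] <- vals[idx[s, 1L], idx[s, 2L]] +
        seg_len[s]
  }
  if (length(bad))
    stop("fragments with out-of-bounds vertices: ",
         paste(bad, collapse = ", "))
  vals <- vals / pixel_size_um^2
  structure(list(values = vals, pixel_size_um = pixel_size_um),
            class = "areal_density")
}

#' Convert an areal density to a volumetric slab density
#'
#' Divides a planar line density (length per area) by the effective optical
#' thickness of the imaged slab, giving length per volume. The effective
#' thickness is the axial extent of tissue a single 2D image represents:
#' 2.5 um for the whole-slide fluorescence setting (PSF FWHM plus average
#' axonal diameter), 3 um for serial two-photon optical sections.
#'
#' @param areal an \code{areal_density}.
#' @param optical_thickness_um slab thickness in micrometers (> 0).
#' @return object of class \code{slab_density}: list with \code{values}
#'   (um of length per um^3), \code{pixel_size_um},
#'   \code{optical_thickness_um}.
#' @export
to_volumetric <- function(areal, optical_thickness_um) {
  stopifnot(inherits(areal, "areal_density"))
  if (!is.numeric(optical_thickness_um) || length(optical_thickness_um) != 1 ||
      !is.finite(optical_thickness_um) || optical_thickness_um <= 0)
    stop("`optical_thickness_um` must be a single positive number")
  structure(list(values = areal$values / optical_thickness_um,
                 pixel_size_um = areal$pixel_size_um,
                 optical_thickness_um = optical_thickness_um),
            class = "slab_density")
}

#' Interpolate slab densities across intervening optical sections
#'
#' Imaged sections are spaced farther apart than the effective optical
#' thickness; \code{round(spacing / thickness) - 1} intermediate planes are
#' inserted between consecutive slabs by linear interpolation along the
#' section axis (40 um spacing at 2.5 um thickness gives 15 intermediate
#' planes). With \code{extend_last = TRUE} (default) the final slab is
#' extended by the same number of replicated planes so that every imaged
#' section represents a full section-spacing of tissue; the interpolation
#' then multiplies the total integrated length by exactly
#' \code{spacing / thickness}.
#'
#' @param slabs list of \code{slab_density} objects (or plain matrices of
#'   identical shape), in section order; at least 2.
#' @param spacing_um distance between imaged sections (>= thickness).
#' @param thickness_um effective optical thickness of one plane.
#' @param pixel_size_um in-plane pixel size (defaults to the first slab's).
#' @param extend_last replicate the last slab to a full spacing (default
#'   TRUE).
#' @return object of class \code{density_volume}: list with \code{values}
#'   (3D array, planes along the 3rd axis), \code{pixel_size_um},
#'   \code{plane_thickness_um}, \code{n_intermediate}.
#' @export
interpolate_sections <- function(slabs, spacing_um, thickness_um,
                                 pixel_size_um = NULL, extend_last = TRUE) {
  if (length(slabs) < 2L) stop("need at least 2 slabs")
  if (spacing_um < thickness_um)
    stop("section spacing must be at least the optical thickness")
  mats <- lapply(slabs, function(s) {
    if (inherits(s, "slab_density")) s$values else as.matrix(s)
  })
  if (is.null(pixel_size_um))
    pixel_size_um <- if (inherits(slabs[[1]], "slab_density"))
      slabs[[1]]$pixel_size_um else 1
  shp <- dim(mats[[1]])
  if (!all(vapply(mats, function(m) all(dim(m) == shp), TRUE)))
    stop("all slabs must have the same shape")
  m <- as.integer(round(spacing_um / thickness_um)) - 1L
  n <- length(mats)
  planes <- list()
  for (i in seq_len(n - 1L)) {
    planes[[length(planes) + 1L]] <- mats[[i]]
    if (m > 0L) for (j in seq_len(m)) {
      a <- j / (m + 1)
      planes[[length(planes) + 1L]] <- (1 - a) * mats[[i]] + a * mats[[i + 1L]]
    }
  }
  planes[[length(planes) + 1L]] <- mats[[n]]
  if (extend_last && m > 0L)
    for (j in seq_len(m)) planes[[length(planes) + 1L]] <- mats[[n]]
  vol <- array(unlist(planes), dim = c(shp, length(planes)))
  structure(list(values = vol, pixel_size_um = pixel_size_um,
                 plane_thickness_um = thickness_um, n_intermediate = m),
            class = "density_volume")
}

#' Total integrated length of a density volume or image
#'
#' @param x an \code{areal_density}, \code{slab_density} or
#'   \code{density_volume}.
#' @return total length in micrometers (sum of density times pixel area or
#'   voxel volume).
#' @export
integrated_length <- function(x) {
  if (inherits(x, "areal_density"))
    return(sum(x$values) * x$pixel_size_um^2)
  if (inherits(x, "slab_density"))
    return(sum(x$values) * x$pixel_size_um^2 * x$optical_thickness_um)
  if (inherits(x, "density_volume"))
    return(sum(x$values) * x$pixel_size_um^2 * x$plane_thickness_um)
  stop("unsupported type")
}

#' Displacement-field coordinate transform
#'
#' A dense displacement lookup: at grid position (row, col) the stored
#' displacements are added to a vertex's coordinates. Lookups between grid
#' points use bilinear (\code{interp = "linear"}) or nearest-neighbor
#' interpolation. The grid must cover the bounding box of the coordinates
#' it is applied to.
#'
#' @param d_row,d_col numeric matrices of displacements (in pixels of the
#'   target space) sampled at integer grid positions.
#' @param origin (row, col) coordinate of the first grid sample (default
#'   c(0, 0)).
#' @param spacing spacing of the displacement grid in coordinate units
#'   (default 1).
#' @param interp "linear" or "nearest".
#' @return object of class \code{displacement_transform}.
#' @export
displacement_transform <- function(d_row, d_col, origin = c(0, 0),
                                   spacing = 1, interp = c("linear",
                                                           "nearest")) {
  interp <- match.arg(interp)
  stopifnot(all(dim(d_row) == dim(d_col)))
  structure(list(d_row = d_row, d_col = d_col, origin = origin,
                 spacing = spacing, interp = interp),
            class = "displacement_transform")
}

apply_transform <- function(transform, coords) {
  if (is.function(transform)) return(transform(coords))
  stopifnot(inherits(transform, "displacement_transform"))
  gr <- transform$origin[1] + (seq_len(nrow(transform$d_row)) - 1L) *
    transform$spacing
  gc <- transform$origin[2] + (seq_len(ncol(transform$d_row)) - 1L) *
    transform$spacing
  r <- coords[, 1L]; cc <- coords[, 2L]
  if (any(r < gr[1] | r > gr[length(gr)] | cc < gc[1] | cc > gc[length(gc)]))
    stop("vertex outside the transform's domain")
  if (transform$interp == "nearest") {
    ir <- pmax(1L, pmin(length(gr), round((r - gr[1]) / transform$spacing) + 1L))
    ic <- pmax(1L, pmin(length(gc), round((cc - gc[1]) / transform$spacing) + 1L))
    dr <- transform$d_row[cbind(ir, ic)]
    dc <- transform$d_col[cbind(ir, ic)]
  } else {
    # pracma::interp2 works on (x = columns, y = rows)
    dr <- pracma::interp2(gc, gr, transform$d_row, cc, r, method = "linear")
    dc <- pracma::interp2(gc, gr, transform$d_col, cc, r, method = "linear")
  }
  cbind(row = r + dr, col = cc + dc)
}

#' Map fragment coordinates through a coordinate transform
#'
#' Applies a supplied transform (a \code{\link{displacement_transform}} or a
#' plain function taking and returning an n x 2 coordinate matrix) to every
#' fragment vertex, leaving connectivity unchanged. Lengths are recomputed
#' in the target space on demand by \code{\link{fragment_lengths}}.
#'
#' @param frags a \code{\link{fragment_set}}.
#' @param transform transform to apply.
#' @return the transformed \code{fragment_set}.
#' @export
map_fragments <- function(frags, transform) {
  stopifnot(inherits(frags, "fragment_set"))
  coords <- lapply(frags$coords, function(m) {
    out <- apply_transform(transform, m)
    colnames(out) <- c("row", "col")
    out
  })
  fragment_set(coords, frags$pixel_size_um, frags$end_types, frags$closed)
}

#' Integrate a density volume over labeled compartments
#'
#' Sums density times voxel volume per compartment label, reporting total
#' line length per compartment in meters together with its log10 (the scale
#' on which whole-brain compartment lengths are usually compared).
#'
#' @param vol a \code{density_volume} (or 3D array with attributes supplied
#'   via \code{voxel_volume_um3}).
#' @param labels integer array of the same shape; 0 may be used for
#'   background (it is reported too, as label 0).
#' @param names optional named character vector mapping label to
#'   compartment name.
#' @param voxel_volume_um3 voxel volume, required if \code{vol} is a plain
#'   array.
#' @return data.frame with columns \code{label}, \code{name},
#'   \code{length_m}, \code{log10_length_m} (NA where length is 0).
#' @export
integrate_compartments <- function(vol, labels, names = NULL,
                                   voxel_volume_um3 = NULL) {
  if (inherits(vol, "density_volume")) {
    vv <- vol$pixel_size_um^2 * vol$plane_thickness_um
    values <- vol$values
  } else {
    if (is.null(voxel_volume_um3))
      stop("voxel_volume_um3 required for a plain array")
    vv <- voxel_volume_um3
    values <- vol
  }
  if (!all(dim(values) == dim(labels)))
    stop("label volume shape does not match the density volume")
  sums <- tapply(as.vector(values), as.vector(labels), sum)
  lab <- as.integer(names(sums))
  len_um <- as.numeric(sums) * vv
  len_m <- len_um * 1e-6
  nm <- if (is.null(names)) as.character(lab) else
    ifelse(as.character(lab) %in% base::names(names),
           names[as.character(lab)], as.character(lab))
  data.frame(label = lab, name = unname(nm), length_m = len_m,
             log10_length_m = ifelse(len_m > 0, log10(len_m), NA_real_))
}
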
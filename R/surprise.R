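#' Projection densities
#'
#' A normalized per-voxel length distribution: the voxelized line density of
#' a single axon (q) or of a tracer injection (p), normalized by total
#' length so the values are non-negative and sum to 1. Voxel center
#' coordinates may be attached so that support-filling interpolation can
#' measure distances.
#'
#' @param values non-negative numeric vector (or array, flattened) of
#'   per-voxel lengths or probabilities.
#' @param coords optional numeric matrix (one row per voxel) of voxel
#'   center coordinates; defaults to 1D positions \code{seq_along(values)}.
#' @param normalized logical: are the values already a distribution?
#' @return object of class \code{projection_density}.
#' @export
projection_density <- function(values, coords = NULL, normalized = FALSE) {
  values <- as.numeric(values)
  if (any(!is.finite(values)) || any(values < 0))
    stop("projection density values must be finite and non-negative")
  if (is.null(coords)) coords <- matrix(seq_along(values), ncol = 1)
  coords <- as.matrix(coords)
  if (nrow(coords) != length(values))
    stop("coords must have one row per voxel")
  if (normalized && abs(sum(values) - 1) > 1e-9)
    stop("values flagged normalized but do not sum to 1")
  structure(list(values = values, coords = coords,
                 normalized = normalized),
            class = "projection_density")
}

#' Normalize per-voxel lengths to a projection density
#'
#' @param raw numeric vector/array of per-voxel lengths, or a
#'   \code{projection_density}.
#' @param coords optional voxel center coordinates (see
#'   \code{\link{projection_density}}).
#' @return a normalized \code{projection_density} (values sum to 1).
#' @export
normalize_density <- function(raw, coords = NULL) {
  if (inherits(raw, "projection_density")) {
    coords <- if (is.null(coords)) raw$coords else coords
    raw <- raw$values
  }
  raw <- as.numeric(raw)
  s <- sum(raw)
  if (s <= 0) stop("cannot normalize an all-zero density")
  projection_density(raw / s, coords, normalized = TRUE)
}

#' Surprise of a single-neuron density over a tracer density
#'
#' The relative entropy (Kullback-Leibler divergence) in bits of the
#' neuron's normalized voxel-wise length distribution q from the tracer
#' injection distribution p:
#' \deqn{S = \sum_{i : q_i > 0} q_i \log_2(q_i / p_i)}
#' with 0 log(0/.) = 0 by continuity. S = 0 iff q = p on the union support;
#' for p uniform over n voxels a point-mass q gives log2(n); the most
#' surprising neuron concentrates on the weakest projection voxel and
#' scores -log2(min p). If q has mass where p is zero the divergence is
#' infinite; an explicit error directs to \code{\link{fill_support}}.
#'
#' @param q,p normalized \code{\link{projection_density}} objects on the
#'   same voxel enumeration (equal lengths).
#' @return object of class \code{surprise_score}: list with \code{S}
#'   (bits), \code{n_voxels}, \code{n_support_q}.
#' @export
surprise <- function(q, p) {
  stopifnot(inherits(q, "projection_density"),
            inherits(p, "projection_density"))
  if (length(q$values) != length(p$values))
    stop("q and p must live on the same voxel grid")
  for (d in list(q, p)) if (abs(sum(d$values) - 1) > 1e-9)
    stop("densities must be normalized (call normalize_density)")
  sup <- q$values > 0
  if (any(p$values[sup] == 0))
    stop("q has support where p is zero; interpolate p with fill_support() first")
  S <- sum(q$values[sup] * log2(q$values[sup] / p$values[sup]))
  structure(list(S = S, n_voxels = length(q$values),
                 n_support_q = sum(sup)),
            class = "surprise_score")
}

#' @export
print.surprise_score <- function(x, ...) {
  cat(sprintf("surprise: %.4f bits over %d voxels (%d in q's support)\n",
              x$S, x$n_voxels, x$n_support_q))
  invisible(x)
}

#' Fill zero-support voxels of a tracer density by weighted nearest neighbors
#'
#' Single-neuron reconstructions occasionally occupy voxels where the
#' tracer-injection estimate is zero (the neuron was traced in a different
#' brain); the tracer density is interpolated into those voxels so the
#' surprise stays finite. Each zero voxel of \code{support} receives the
#' inverse-distance-power weighted mean of its \code{k} nearest positive-p
#' voxels (distances between voxel centers); the result is renormalized to
#' sum 1, so previously positive voxels keep their relative proportions.
#'
#' @param p a \code{\link{projection_density}} with at least one positive
#'   voxel.
#' @param support integer indices (into \code{p$values}) of voxels that
#'   must end up positive — typically the union support of the neuron
#'   densities.
#' @param k number of nearest positive voxels to average (default 6).
#' @param power inverse-distance weighting exponent (default 1).
#' @return a normalized \code{projection_density}; attribute
#'   \code{n_filled} counts the voxels that were filled.
#' @export
fill_support <- function(p, support, k = 6L, power = 1) {
  stopifnot(inherits(p, "projection_density"))
  if (all(p$values == 0)) stop("p has no positive voxels")
  if (k < 1L) stop("k must be at least 1")
  v <- p$values
  pos <- which(v > 0)
  fill <- intersect(as.integer(support), which(v == 0))
  for (i in fill) {
    d <- sqrt(rowSums((p$coords[pos, , drop = FALSE] -
                         matrix(p$coords[i, ], length(pos),
                                ncol(p$coords), byrow = TRUE))^2))
    ord <- order(d, pos)
    use <- ord[seq_len(min(k, length(pos)))]
    w <- 1 / pmax(d[use], .Machine$double.eps)^power
    v[i] <- sum(w * v[pos[use]]) / sum(w)
  }
  out <- normalize_density(v, p$coords)
  attr(out, "n_filled") <- length(fill)
  out
}

#' Summarize surprise scores: histogram and length correlation
#'
#' @param scores data.frame with columns \code{S} (bits) and
#'   \code{total_length_um}; an optional \code{id} column is carried
#'   through.
#' @param breaks histogram breaks (passed to \code{hist}; default
#'   \code{"Sturges"}).
#' @return list with \code{histogram} (counts and bin edges),
#'   \code{pearson} and \code{spearman} correlations between
#'   log10(total length) and S (NA with a warning when undefined), and the
#'   input \code{table}.
#' @export
surprise_report <- function(scores, breaks = "Sturges") {
  stopifnot(is.data.frame(scores), nrow(scores) >= 1,
            all(c("S", "total_length_um") %in% names(scores)))
  h <- graphics::hist(scores$S, breaks = breaks, plot = FALSE)
  logl <- log10(scores$total_length_um)
  if (nrow(scores) < 2 || stats::sd(scores$S) == 0 || stats::sd(logl) == 0) {
    warning("correlation undefined (constant scores or lengths)")
    pe <- NA_real_; sp <- NA_real_
  } else {
    pe <- stats::cor(logl, scores$S, method = "pearson")
    sp <- stats::cor(logl, scores$S, method = "spearman")
  }
  list(histogram = list(counts = h$counts, breaks = h$breaks),
       pearson = pe, spearman = sp, table = scores)
}

#' Align sparse voxel rasters onto a common enumeration
#'
#' Takes voxel tables as produced by \code{\link{voxelize_swc}} (integer
#' columns i, j, k and length_um) and returns dense vectors over the union
#' of occupied voxels, plus the voxel center coordinates, so that
#' projection densities of different neurons and of the tracer can be
#' compared voxel by voxel.
#'
#' @param tables named list of voxel data.frames.
#' @param voxel_size_um voxel edge length (for center coordinates).
#' @return list with \code{matrix} (voxels x tables), \code{coords}
#'   (voxel centers, micrometers), \code{keys} (voxel index strings).
#' @export
align_voxel_tables <- function(tables, voxel_size_um) {
  keyify <- function(tb) paste(tb$i, tb$j, tb$k, sep = ",")
  all_keys <- sort(unique(unlist(lapply(tables, keyify))))
  m <- sapply(tables, function(tb) {
    v <- numeric(length(all_keys))
    v[match(keyify(tb), all_keys)] <- tb$length_um
    v
  })
  m <- matrix(m, nrow = length(all_keys),
              dimnames = list(NULL, names(tables)))
  parts <- do.call(rbind, strsplit(all_keys, ","))
  coords <- (apply(parts, 2, as.numeric) + 0.5) * voxel_size_um
  list(matrix = m, coords = coords, keys = all_keys)
}
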
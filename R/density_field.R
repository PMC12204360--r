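#' Density fields on the pixel grid
#'
#' A density field is a non-negative scalar function defined at pixel centers
#' of a 2D grid, together with the physical pixel size. It is the scalar
#' landscape whose mountain ridges the Morse skeletonization traces: values
#' are typically likelihoods in \[0, 1\] produced by an axon-detection stage,
#' but any finite non-negative grid is accepted.
#'
#' Pixels are indexed 0-based as (row, col) in user-facing coordinates;
#' internally R's column-major 1-based linear indices are used and all
#' deterministic tie-breaks refer to that linear index.
#'
#' @param values numeric matrix (>= 2 rows and >= 2 columns) of finite,
#'   non-negative values.
#' @param pixel_size_um physical edge length of one pixel in micrometers.
#' @return An object of class \code{density_field}: a list with elements
#'   \code{values} and \code{pixel_size_um}.
#' @examples
#' f <- density_field(matrix(runif(64), 8, 8), pixel_size_um = 0.46)
#' dim(f$values)
#' @export
density_field <- function(values, pixel_size_um = 1) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (nrow(values) < 2 || ncol(values) < 2)
    stop("density field needs at least 2 rows and 2 columns")
  if (any(!is.finite(values)))
    stop("density field values must all be finite")
  if (any(values < 0))
    stop("density field values must be non-negative")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0)
    stop("`pixel_size_um` must be a single positive number")
  structure(list(values = values, pixel_size_um = as.numeric(pixel_size_um)),
            class = "density_field")
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("density_field: %d x %d pixels, %.4g um/px, range [%.4g, %.4g]\n",
              nrow(x$values), ncol(x$values), x$pixel_size_um,
              min(x$values), max(x$values)))
  invisible(x)
}

as_density_field <- function(x, pixel_size_um = 1) {
  if (inherits(x, "density_field")) return(x)
  density_field(x, pixel_size_um)
}

# Reflect-pad a 1D index range: symmetric reflection including the edge
# sample (1,2,...  ->  2,1 | 1,2,... ). Preserves constants by construction.
reflect_index <- function(idx, n) {
  period <- 2L * n
  m <- ((idx - 1L) %% period + period) %% period
  ifelse(m < n, m + 1L, period - m)
}

#' Gaussian smoothing of a density field
#'
#' Separable Gaussian convolution with reflect boundary handling, so that
#' constant fields pass through unchanged and no values are invented at the
#' image border. The kernel is truncated at \code{radius} standard deviations
#' and renormalized to unit sum, so interior mass is conserved.
#'
#' @param field a \code{\link{density_field}} (or plain matrix).
#' @param sigma Gaussian standard deviation in pixels; \code{sigma = 0}
#'   returns the input unchanged.
#' @param radius kernel truncation radius in standard deviations (default 4).
#' @return a smoothed \code{density_field} of the same shape.
#' @export
smooth_density <- function(field, sigma, radius = 4) {
  field <- as_density_field(field)
  if (!is.numeric(sigma) || length(sigma) != 1 || !is.finite(sigma))
    stop("`sigma` must be a single finite number")
  if (sigma < 0) stop("`sigma` must be non-negative")
  if (sigma == 0) return(field)
  r <- max(1L, as.integer(ceiling(radius * sigma)))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k <- k / sum(k)
  v <- field$values
  v <- convolve_axis(v, k, margin = 1L)
  v <- convolve_axis(v, k, margin = 2L)
  v[v < 0] <- 0  # clamp tiny negative round-off
  density_field(v, field$pixel_size_um)
}

# 1D convolution of a matrix along rows (margin = 1) or columns (margin = 2)
# with reflect padding, vectorized over shifts.
convolve_axis <- function(v, k, margin) {
  r <- (length(k) - 1L) %/% 2L
  n <- if (margin == 1L) nrow(v) else ncol(v)
  out <- matrix(0, nrow(v), ncol(v))
  for (j in seq_along(k)) {
    off <- j - r - 1L
    idx <- reflect_index(seq_len(n) + off, n)
    out <- out + k[j] * (if (margin == 1L) v[idx, , drop = FALSE]
                         else v[, idx, drop = FALSE])
  }
  out
}

#' Min-max normalize a density field to \[0, 1\]
#'
#' @param field a \code{\link{density_field}} or matrix.
#' @return a \code{density_field} with values rescaled to \[0, 1\];
#'   a constant field maps to all zeros.
#' @export
normalize_field <- function(field) {
  field <- as_density_field(field)
  v <- field$values
  rng <- range(v)
  if (rng[2] > rng[1]) v <- (v - rng[1]) / (rng[2] - rng[1]) else v[] <- 0
  density_field(v, field$pixel_size_um)
}
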
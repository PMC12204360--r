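#' Edges of the grid cubical complex
#'
#' The 1-skeleton of the cubical complex built on an \code{nr x nc} pixel
#' grid: every pixel is a vertex and every 4-neighbor (axial) pair is an
#' edge. Vertices are R's column-major 1-based linear indices. Edges are
#' returned with the smaller linear index first, vertical edges (within a
#' column) before horizontal ones, each block in linear-index order; this
#' fixed enumeration is what deterministic tie-breaks refer to.
#'
#' @param nr,nc grid dimensions (each >= 2).
#' @return integer matrix with 2 columns \code{a}, \code{b} (a < b) and
#'   \code{nr * (nc - 1) + (nr - 1) * nc} rows.
#' @export
grid_edges <- function(nr, nc) {
  nr <- as.integer(nr); nc <- as.integer(nc)
  stopifnot(nr >= 2, nc >= 2)
  # vertical: (r, c)-(r + 1, c) for r < nr
  a_v <- as.vector(outer(seq_len(nr - 1L), (seq_len(nc) - 1L) * nr, `+`))
  # horizontal: (r, c)-(r, c + 1) for c < nc
  a_h <- seq_len(nr * (nc - 1L))
  cbind(a = c(a_v, a_h), b = c(a_v + 1L, a_h + nr))
}

# Edge filtration values for superlevel sets: an edge enters when both its
# endpoints are present, i.e. at the min of the endpoint values.
edge_values <- function(values, edges) {
  pmin(values[edges[, 1L]], values[edges[, 2L]])
}

# Total order on vertices used everywhere for tie-breaking: vertex a is
# "higher" than b iff value(a) > value(b), or equal values and a has the
# smaller linear index (lower index is older in the superlevel filtration).
# Returns ranks: 1 = highest/oldest.
vertex_ranks <- function(values) {
  n <- length(values)
  ord <- order(-as.vector(values), seq_len(n))
  rk <- integer(n)
  rk[ord] <- seq_len(n)
  rk
}

# 4-neighbors of linear index i on an nr x nc grid, in increasing linear
# index order: left, up, down, right (NA where off-grid).
neighbor_matrix <- function(nr, nc) {
  n <- nr * nc
  i <- seq_len(n)
  r <- (i - 1L) %% nr + 1L
  cc <- (i - 1L) %/% nr + 1L
  left  <- ifelse(cc > 1L,  i - nr, NA_integer_)
  up    <- ifelse(r  > 1L,  i - 1L, NA_integer_)
  down  <- ifelse(r  < nr,  i + 1L, NA_integer_)
  right <- ifelse(cc < nc,  i + nr, NA_integer_)
  cbind(left, up, down, right)
}
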
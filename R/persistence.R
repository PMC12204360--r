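#' 0-dimensional persistence of the superlevel filtration
#'
#' Computes the vertex-edge persistence pairs of the superlevel-set
#' filtration of a density field on the grid cubical complex, by a
#' union-find sweep with the elder rule. Components of the superlevel set
#' are born at local maxima as the level drops; when an edge first joins two
#' components, the component whose maximum is lower dies there, giving the
#' pair (birth = maximum value, death = edge value, persistence = birth -
#' death). Equal values are ordered by linear pixel index (lower index is
#' older), making the pairing fully deterministic.
#'
#' @param field a \code{\link{density_field}} or numeric matrix.
#' @return A data frame of finite pairs sorted by decreasing persistence,
#'   with columns \code{birth_vertex}, \code{death_edge} (row index into
#'   \code{\link{grid_edges}}), \code{birth_value}, \code{death_value},
#'   \code{persistence}. Attributes: \code{essential} (linear indices of the
#'   unpaired maxima, one per connected grid region — a single one for a
#'   full rectangular grid) and \code{n_vertices}.
#' @examples
#' f <- density_field(rbind(c(2, 1, 3), c(0, 0, 0)))
#' compute_persistence_0d(f)
#' @export
compute_persistence_0d <- function(field) {
  st <- persistence_state(field)
  p <- st$pairs
  p <- p[order(-p$persistence, p$birth_vertex), , drop = FALSE]
  rownames(p) <- NULL
  attr(p, "essential") <- st$essential
  attr(p, "n_vertices") <- st$n
  p
}

# Full union-find sweep; also records, for every edge, whether it merged two
# distinct components (a "merging saddle") and the persistence assigned to
# that merge. Used by both compute_persistence_0d and extract_morse_graph.
persistence_state <- function(field) {
  field <- as_density_field(field)
  v <- as.vector(field$values)
  nr <- nrow(field$values); nc <- ncol(field$values)
  n <- length(v)
  edges <- grid_edges(nr, nc)
  ev <- edge_values(v, edges)
  rk <- vertex_ranks(v)

  # Filtration order for edges: an edge enters with its younger endpoint.
  young <- ifelse(rk[edges[, 1L]] > rk[edges[, 2L]], edges[, 1L], edges[, 2L])
  old   <- ifelse(rk[edges[, 1L]] > rk[edges[, 2L]], edges[, 2L], edges[, 1L])
  eord <- order(rk[young], rk[old])

  parent <- seq_len(n)
  comp_max <- seq_len(n)        # highest vertex (by total order) in each root
  m <- length(eord)
  pr_birth <- integer(m); pr_edge <- integer(m); npairs <- 0L
  merging <- logical(nrow(edges))
  merge_pers <- rep(NA_real_, nrow(edges))

  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }

  for (ei in eord) {
    ra <- find(edges[ei, 1L]); rb <- find(edges[ei, 2L])
    if (ra == rb) next
    ma <- comp_max[ra]; mb <- comp_max[rb]
    if (rk[ma] < rk[mb]) { elder <- ma; dying <- mb } else { elder <- mb; dying <- ma }
    npairs <- npairs + 1L
    pr_birth[npairs] <- dying
    pr_edge[npairs] <- ei
    merging[ei] <- TRUE
    merge_pers[ei] <- v[dying] - ev[ei]
    # union by attaching either way; keep elder as the surviving maximum
    parent[ra] <- rb
    comp_max[rb] <- elder
  }

  essential <- unique(vapply(seq_len(n), function(i) comp_max[find(i)], 1L))
  pairs <- data.frame(
    birth_vertex = pr_birth[seq_len(npairs)],
    death_edge = pr_edge[seq_len(npairs)],
    birth_value = v[pr_birth[seq_len(npairs)]],
    death_value = ev[pr_edge[seq_len(npairs)]]
  )
  pairs$persistence <- pairs$birth_value - pairs$death_value
  list(pairs = pairs, essential = sort(essential), n = n,
       edges = edges, edge_value = ev, merging = merging,
       merge_persistence = merge_pers, values = v, nr = nr, nc = nc, rk = rk)
}
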
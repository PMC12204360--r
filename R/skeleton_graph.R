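#' Skeleton graphs on the pixel grid
#'
#' An undirected simple graph whose vertices are pixels (column-major
#' 1-based linear indices) and whose edges are axial grid edges; a subgraph
#' of the grid adjacency. Carries per-node density values so that edge
#' weights (mean of endpoint densities) can be formed for spanning-forest
#' extraction.
#'
#' @param nodes integer vector of linear pixel indices.
#' @param edges 2-column integer matrix of linear indices (each row one
#'   axial edge; stored with the smaller index first).
#' @param dim grid dimensions c(nr, nc).
#' @param node_value densities at \code{nodes} (same order).
#' @param pixel_size_um pixel size in micrometers.
#' @return object of class \code{skeleton_graph}.
#' @export
skeleton_graph <- function(nodes, edges, dim, node_value = NULL,
                           pixel_size_um = 1) {
  nodes <- sort(unique(as.integer(nodes)))
  if (length(edges)) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    storage.mode(edges) <- "integer"
    if (!all(edges %in% nodes))
      nodes <- sort(unique(c(nodes, as.vector(edges))))
    # axial check
    d <- abs(edges[, 1L] - edges[, 2L])
    if (!all(d == 1L | d == dim[1]))
      stop("skeleton_graph edges must be axial grid edges")
  } else {
    edges <- matrix(integer(0), 0, 2)
  }
  if (is.null(node_value)) node_value <- rep(NA_real_, length(nodes))
  structure(list(nodes = nodes, edges = edges, dim = as.integer(dim),
                 node_value = node_value,
                 pixel_size_um = as.numeric(pixel_size_um)),
            class = "skeleton_graph")
}

#' Convert a Morse graph to a skeleton graph
#' @param g a \code{morse_graph}.
#' @return a \code{skeleton_graph} with the same nodes, edges and values.
#' @export
as_skeleton_graph <- function(g) {
  if (inherits(g, "skeleton_graph")) return(g)
  stopifnot(inherits(g, "morse_graph"))
  skeleton_graph(g$nodes, g$edges, g$dim, g$node_value, g$pixel_size_um)
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("skeleton_graph: %d nodes, %d edges on a %d x %d grid\n",
              length(x$nodes), nrow(x$edges), x$dim[1], x$dim[2]))
  invisible(x)
}

node_degrees <- function(g) {
  deg <- integer(length(g$nodes))
  if (nrow(g$edges)) {
    tab <- tabulate(match(as.vector(g$edges), g$nodes), length(g$nodes))
    deg <- tab
  }
  names(deg) <- g$nodes
  deg
}

value_at <- function(g, idx) g$node_value[match(idx, g$nodes)]

#' Otsu threshold mask of a density field
#'
#' Binarizes a field by the threshold that maximizes the between-class
#' variance over a 256-bin histogram of the values; the mask keeps pixels
#' with value greater than or equal to the threshold.
#'
#' @param likelihood a \code{\link{density_field}} or numeric matrix.
#' @param levels number of histogram bins (default 256).
#' @return logical matrix of the field's shape; the chosen threshold is
#'   attached as attribute \code{threshold}.
#' @export
otsu_mask <- function(likelihood, levels = 256L) {
  likelihood <- as_density_field(likelihood)
  v <- as.vector(likelihood$values)
  rng <- range(v)
  if (rng[1] == rng[2])
    stop("otsu_mask: constant field has no separable classes")
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  h <- tabulate(pmin(findInterval(v, breaks, rightmost.closed = TRUE),
                     levels), levels)
  p <- h / sum(h)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[levels]
  # between-class variance when splitting after bin k
  valid <- w0 > 0 & w0 < 1
  sb <- rep(-Inf, levels)
  sb[valid] <- (mu_t * w0[valid] - mu[valid])^2 / (w0[valid] * (1 - w0[valid]))
  k <- which.max(sb)
  thr <- breaks[k + 1L]
  mask <- likelihood$values >= thr
  attr(mask, "threshold") <- thr
  mask
}

#' Intersect a graph with a binary mask
#'
#' Removes every node at a mask-false pixel, together with its incident
#' edges. The result may be disconnected; that is expected and handled by
#' the downstream per-component spanning forests.
#'
#' @param g a \code{morse_graph} or \code{skeleton_graph}.
#' @param mask logical matrix matching the graph's grid shape.
#' @return a \code{skeleton_graph}.
#' @export
mask_graph <- function(g, mask) {
  g <- as_skeleton_graph(g)
  if (!is.logical(mask) || !all(dim(mask) == g$dim))
    stop("mask shape does not match the graph grid")
  keep_node <- mask[g$nodes]
  nodes <- g$nodes[keep_node]
  if (nrow(g$edges)) {
    ke <- mask[g$edges[, 1L]] & mask[g$edges[, 2L]]
    edges <- g$edges[ke, , drop = FALSE]
  } else edges <- g$edges
  skeleton_graph(nodes, edges, g$dim, g$node_value[keep_node],
                 g$pixel_size_um)
}

#' Maximal spanning forest of a skeleton graph
#'
#' Per connected component, extracts the spanning tree that maximizes the
#' total edge weight, where an edge's weight is the mean of its endpoint
#' densities; high-likelihood ridges are thereby preserved when cycles are
#' broken. The node set is preserved (isolated nodes stay).
#'
#' @param g a \code{skeleton_graph} (or \code{morse_graph}).
#' @return a \code{skeleton_graph} that is a forest.
#' @export
max_spanning_forest <- function(g) {
  g <- as_skeleton_graph(g)
  if (nrow(g$edges) == 0L) return(g)
  w <- (value_at(g, g$edges[, 1L]) + value_at(g, g$edges[, 2L])) / 2
  if (any(is.na(w))) w[is.na(w)] <- 0
  ig <- igraph::graph_from_edgelist(
    cbind(match(g$edges[, 1L], g$nodes), match(g$edges[, 2L], g$nodes)),
    directed = FALSE)
  ig <- igraph::add_vertices(ig, max(0L, length(g$nodes) -
                                       igraph::vcount(ig)))
  mst <- igraph::mst(ig, weights = -w)
  el <- igraph::as_edgelist(mst, names = FALSE)
  edges <- cbind(g$nodes[el[, 1L]], g$nodes[el[, 2L]])
  skeleton_graph(g$nodes, edges, g$dim, g$node_value, g$pixel_size_um)
}

#' Haircut pruning of short low-curvature spurs
#'
#' Removes every branch-node-to-endpoint path (interior vertices of degree
#' 2) of at most \code{max_len_px} edges whose sequence of axial unit steps
#' changes direction at most once; these short straight or L-shaped "hairs"
#' typically connect real signal to a nearby noise maximum. A single pass is
#' made over the spurs present in the input forest (no iteration to a
#' fixpoint). The branch node itself is retained.
#'
#' @param g a \code{skeleton_graph} that is a forest (run after
#'   \code{\link{max_spanning_forest}}).
#' @param max_len_px spur length threshold in edges (default 10);
#'   \code{0} disables pruning.
#' @return the pruned \code{skeleton_graph}.
#' @export
haircut <- function(g, max_len_px = 10L) {
  g <- as_skeleton_graph(g)
  ncomp <- n_components(g)
  if (nrow(g$edges) != length(g$nodes) - ncomp)
    stop("haircut requires a forest (run max_spanning_forest first)")
  if (max_len_px <= 0L || nrow(g$edges) == 0L) return(g)
  deg <- node_degrees(g)
  adj <- adjacency_list(g)
  leaves <- g$nodes[deg == 1L]
  drop_nodes <- integer(0)
  for (leaf in leaves) {
    path <- leaf
    prev <- NA_integer_
    cur <- leaf
    repeat {
      nxt <- setdiff(adj[[as.character(cur)]], prev)
      if (length(nxt) == 0L) { term <- NA_integer_; break }  # isolated path end
      if (length(nxt) > 1L) { term <- cur; break }           # reached non-deg-2
      prev <- cur; cur <- nxt
      path <- c(path, cur)
      dcur <- deg[[as.character(cur)]]
      if (dcur != 2L) { term <- cur; break }
      if (length(path) > max_len_px + 1L) { term <- NA_integer_; break }
    }
    if (is.na(term)) next
    term_deg <- deg[[as.character(term)]]
    if (term_deg <= 2L) next                 # other end is a leaf, not a spur
    n_edges <- length(path) - 1L
    if (n_edges > max_len_px) next
    steps <- step_vectors(path, g$dim[1])
    changes <- if (nrow(steps) < 2L) 0L else
      sum(steps[-1L, 1L] != steps[-nrow(steps), 1L] |
            steps[-1L, 2L] != steps[-nrow(steps), 2L])
    if (changes > 1L) next
    drop_nodes <- c(drop_nodes, path[-length(path)])  # keep the branch node
  }
  if (length(drop_nodes) == 0L) return(g)
  keep <- !(g$nodes %in% drop_nodes)
  ke <- !(g$edges[, 1L] %in% drop_nodes) & !(g$edges[, 2L] %in% drop_nodes)
  skeleton_graph(g$nodes[keep], g$edges[ke, , drop = FALSE], g$dim,
                 g$node_value[keep], g$pixel_size_um)
}

step_vectors <- function(path, nr) {
  if (length(path) < 2L) return(matrix(integer(0), 0, 2))
  r <- (path - 1L) %% nr
  cc <- (path - 1L) %/% nr
  cbind(diff(r), diff(cc))
}

adjacency_list <- function(g) {
  adj <- vector("list", length(g$nodes))
  names(adj) <- g$nodes
  if (nrow(g$edges)) {
    sp1 <- split(g$edges[, 2L], g$edges[, 1L])
    sp2 <- split(g$edges[, 1L], g$edges[, 2L])
    for (k in names(sp1)) adj[[k]] <- c(adj[[k]], sp1[[k]])
    for (k in names(sp2)) adj[[k]] <- c(adj[[k]], sp2[[k]])
    adj <- lapply(adj, function(x) sort(unique(x)))
  }
  adj
}

n_components <- function(g) {
  if (length(g$nodes) == 0L) return(0L)
  ig <- igraph::graph_from_edgelist(
    cbind(match(g$edges[, 1L], g$nodes), match(g$edges[, 2L], g$nodes)),
    directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g$nodes) - igraph::vcount(ig))
  igraph::components(ig)$no
}

#' Critical points of a skeleton graph
#'
#' Branch points are nodes of degree greater than 2, endpoints are nodes of
#' degree 1; together they are the critical points between which skeletal
#' fragments run. Isolated nodes (degree 0) are reported separately.
#'
#' @param g a \code{skeleton_graph}.
#' @return list with integer vectors \code{branch}, \code{ends},
#'   \code{isolated} (linear pixel indices).
#' @export
find_critical_points <- function(g) {
  g <- as_skeleton_graph(g)
  deg <- node_degrees(g)
  list(branch = g$nodes[deg > 2L],
       ends = g$nodes[deg == 1L],
       isolated = g$nodes[deg == 0L])
}
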
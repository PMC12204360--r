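# Independent oracles used to freeze expected values. Each one recomputes
# the quantity by a different route than the implementation under test.

# Boundary-matrix reduction for 0-dim persistence of the superlevel
# filtration on the grid 1-skeleton. Cells: vertices then edges, ordered by
# the same total order as the implementation (value desc, linear index asc;
# edges enter with their younger endpoint). Standard column reduction:
# an edge column with pivot row i pairs vertex i with that edge.
oracle_persistence_pairs <- function(values) {
  v <- as.vector(values)
  nr <- nrow(values); nc <- ncol(values)
  n <- length(v)
  edges <- dmskel::grid_edges(nr, nc)
  rk <- integer(n)
  rk[order(-v, seq_len(n))] <- seq_len(n)
  er_a <- rk[edges[, 1]]; er_b <- rk[edges[, 2]]
  eord <- order(pmax(er_a, er_b), pmin(er_a, er_b))
  cols <- lapply(eord, function(i) sort(c(er_a[i], er_b[i])))
  low_owner <- integer(n)  # row rank -> column index (0 = free)
  pairs <- NULL
  for (j in seq_along(cols)) {
    col <- cols[[j]]
    repeat {
      if (length(col) == 0L) break
      lowj <- max(col)
      k <- low_owner[lowj]
      if (k == 0L) break
      col <- sort(symdiff_int(col, cols[[k]]))
    }
    cols[[j]] <- col
    if (length(col)) {
      lowj <- max(col)
      low_owner[lowj] <- j
      birth_vertex <- which(rk == lowj)
      death_edge <- eord[j]
      ev <- min(v[edges[death_edge, 1]], v[edges[death_edge, 2]])
      pairs <- rbind(pairs, c(birth_value = v[birth_vertex],
                              death_value = ev))
    }
  }
  as.data.frame(pairs)
}

symdiff_int <- function(a, b) c(setdiff(a, b), setdiff(b, a))

# Exhaustive Otsu: try every candidate bin-edge threshold, recompute the
# between-class variance from the raw values via group means.
oracle_otsu_threshold <- function(values, levels = 256L) {
  v <- as.vector(values)
  rng <- range(v)
  breaks <- seq(rng[1], rng[2], length.out = levels + 1L)
  cand <- breaks[2:(levels)]
  best <- -Inf; best_thr <- NA_real_
  for (thr in cand) {
    lo <- v[v < thr]; hi <- v[v >= thr]
    if (!length(lo) || !length(hi)) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-15) { best <- sb; best_thr <- thr }
  }
  best_thr
}

# Exhaustive maximal spanning forest weight by subset enumeration
# (for graphs with <= 8 nodes). Returns the maximum total weight of a
# spanning forest (n - n_components edges, acyclic, spanning).
oracle_max_forest_weight <- function(nodes, edges, weights) {
  n <- length(nodes)
  if (nrow(edges) == 0L) return(0)
  comp <- components_count(nodes, edges)
  k <- n - comp
  if (k == 0L) return(0)
  best <- -Inf
  idx <- utils::combn(nrow(edges), k)
  for (j in seq_len(ncol(idx))) {
    sel <- idx[, j]
    sub <- edges[sel, , drop = FALSE]
    if (is_acyclic(nodes, sub) &&
        components_count(nodes, sub) == comp)
      best <- max(best, sum(weights[sel]))
  }
  best
}

components_count <- function(nodes, edges) {
  p <- seq_along(nodes)
  find <- function(x) { while (p[x] != x) { p[x] <<- p[p[x]]; x <- p[x] }; x }
  if (nrow(edges)) for (i in seq_len(nrow(edges))) {
    a <- find(match(edges[i, 1], nodes)); b <- find(match(edges[i, 2], nodes))
    if (a != b) p[a] <- b
  }
  length(unique(vapply(seq_along(nodes), find, 1L)))
}

is_acyclic <- function(nodes, edges) {
  if (nrow(edges) == 0L) return(TRUE)
  length(nodes) - components_count(nodes, edges) == nrow(edges)
}

# Per-voxel loop for compartment integration.
oracle_compartment_lengths <- function(values, labels, voxel_volume) {
  out <- list()
  for (i in seq_along(values)) {
    key <- as.character(labels[i])
    out[[key]] <- (out[[key]] %||% 0) + values[i] * voxel_volume
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Direct dense convolution of an image with a normalized 2D Gaussian
# kernel, reflect padding, for cross-checking the separable implementation.
oracle_gauss_conv <- function(values, sigma, radius = 4) {
  r <- max(1L, as.integer(ceiling(radius * sigma)))
  g <- stats::dnorm(seq(-r, r), sd = sigma); g <- g / sum(g)
  k2 <- outer(g, g)
  nr <- nrow(values); nc <- ncol(values)
  refl <- function(i, n) { p <- 2L * n
    m <- ((i - 1L) %% p + p) %% p; ifelse(m < n, m + 1L, p - m) }
  out <- matrix(0, nr, nc)
  for (a in seq_len(nr)) for (b in seq_len(nc)) {
    acc <- 0
    for (da in -r:r) for (db in -r:r)
      acc <- acc + k2[da + r + 1, db + r + 1] *
        values[refl(a + da, nr), refl(b + db, nc)]
    out[a, b] <- acc
  }
  out
}

# Deterministic Y-junction test field: three constant-intensity arms
# meeting at one pixel, with a low-intensity (but nonzero) run on one arm.
# Arms: up from the junction, and left/right along the junction row.
make_y_junction <- function(nr = 32, nc = 32, hi = 1, gap_value = 0.3,
                            gap_cols = c(24, 25)) {
  v <- matrix(0, nr, nc)
  jr <- 16L; jc <- 16L
  v[2:jr, jc] <- hi          # vertical arm
  v[jr, 3:29] <- hi          # horizontal arms through the junction
  v[jr, gap_cols] <- gap_value
  attr(v, "junction") <- c(jr, jc)
  attr(v, "arm_tips") <- rbind(c(2, jc), c(jr, 3), c(jr, 29))
  v
}

# 1-based (row, col) -> column-major linear index
lin <- function(r, c, nr) (c - 1L) * nr + r

# connected components of a skeleton/morse graph via igraph
graph_components <- function(g) {
  g <- dmskel::as_skeleton_graph(g)
  ig <- igraph::graph_from_edgelist(
    cbind(match(g$edges[, 1], g$nodes), match(g$edges[, 2], g$nodes)),
    directed = FALSE)
  ig <- igraph::add_vertices(ig, length(g$nodes) - igraph::vcount(ig))
  igraph::components(ig)
}
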
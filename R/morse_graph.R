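#' Steepest-ascent forest of a density field
#'
#' Discretization of the gradient flow toward local maxima: every
#' non-maximum pixel points to its strictly higher 4-neighbor of maximal
#' value (ties between equally high neighbors broken by the smallest linear
#' index). Plateaus (4-connected regions of equal value) are resolved
#' deterministically: pixels of a plateau with an exit to a strictly higher
#' neighbor drain breadth-first toward those exits; a maximal plateau (a
#' flat summit) drains to a single root, its minimum-linear-index pixel,
#' which is the one self-parent of that region. Following parent pointers
#' from any pixel therefore terminates at a maximum.
#'
#' @param field a \code{\link{density_field}} or numeric matrix.
#' @return integer vector of length \code{nr * nc}: \code{parent[i]} is the
#'   linear index of the pixel \code{i} flows to (\code{parent[i] == i}
#'   exactly for maxima).
#' @export
steepest_ascent_forest <- function(field) {
  field <- as_density_field(field)
  v <- as.vector(field$values)
  nr <- nrow(field$values); nc <- ncol(field$values)
  n <- length(v)
  nb <- neighbor_matrix(nr, nc)

  parent <- rep(NA_integer_, n)
  # Pass 1: strictly higher neighbor of maximal value, tie -> smallest index.
  # Columns of nb are already in increasing linear-index order, so scanning
  # them left to right and keeping the first strict improvement implements
  # the tie-break.
  best_val <- rep(-Inf, n)
  best_idx <- rep(NA_integer_, n)
  for (j in seq_len(ncol(nb))) {
    nbj <- nb[, j]
    ok <- !is.na(nbj)
    w <- rep(-Inf, n)
    w[ok] <- v[nbj[ok]]
    better <- w > best_val          # strict: earlier (smaller) index wins ties
    best_val[better] <- w[better]
    best_idx[better] <- nbj[better]
  }
  higher <- best_val > v
  parent[higher] <- best_idx[higher]
  has_equal <- rep(FALSE, n)
  for (j in seq_len(ncol(nb))) {
    nbj <- nb[, j]
    ok <- !is.na(nbj)
    eq <- ok
    eq[ok] <- v[nbj[ok]] == v[ok]
    has_equal <- has_equal | eq
  }
  # strict local maxima (no higher, no equal neighbor)
  strict_max <- !higher & !has_equal
  parent[strict_max] <- which(strict_max)

  # Pass 2: plateau drainage toward resolved exits, wave by wave.
  resolved <- !is.na(parent)
  drain_waves <- function() {
    repeat {
      frontier_parent <- rep(NA_integer_, n)
      for (j in seq_len(ncol(nb))) {
        nbj <- nb[, j]
        ok <- !is.na(nbj) & !resolved
        ok[ok] <- v[nbj[ok]] == v[which(ok)] & resolved[nbj[ok]]
        take <- ok & is.na(frontier_parent)   # smallest-index neighbor wins
        frontier_parent[take] <- nbj[take]
      }
      hit <- which(!is.na(frontier_parent))
      if (length(hit) == 0L) return(invisible())
      parent[hit] <<- frontier_parent[hit]
      resolved[hit] <<- TRUE
    }
  }
  drain_waves()
  # Pass 3: maximal plateaus left unresolved; root each at its min index.
  while (any(!resolved)) {
    root <- which(!resolved)[1L]
    parent[root] <- root
    resolved[root] <- TRUE
    drain_waves()
  }
  parent
}

#' Extract the persistence-simplified Morse graph skeleton
#'
#' Builds the 1-unstable-manifold skeleton of a density field: for every
#' merging saddle edge whose persistence is at least \code{delta} and whose
#' edge value (min of endpoint densities) is at least \code{floor}, the
#' graph contains the saddle edge itself together with the two ascending
#' V-paths from its endpoints to their maxima, traced along the
#' \code{\link{steepest_ascent_forest}}. Maxima are treated as (possibly
#' flat) critical sets: the full drainage tree of a flat summit reached by a
#' V-path is included, as is the drainage tree of each essential (undying)
#' maximum, so a noiseless constant-height ridge is recovered as exactly its
#' own polyline. For generic fields without ties this reduces to the
#' standard saddles-plus-V-paths construction.
#'
#' @param field a \code{\link{density_field}} or numeric matrix.
#' @param delta persistence threshold (>= 0): saddles of lower persistence
#'   are treated as noise and dropped.
#' @param floor minimum edge value for a retained saddle (default 0);
#'   saddles lying below it (pure-background merges) are dropped.
#' @return An object of class \code{morse_graph}: list with \code{dim},
#'   \code{nodes} (linear indices), \code{edges} (2-column matrix of linear
#'   indices, axial grid edges only), \code{node_value}, \code{saddles}
#'   (2-column matrix of retained saddle edges), \code{maxima} (roots
#'   reached), \code{pixel_size_um}.
#' @export
extract_morse_graph <- function(field, delta, floor = 0) {
  field <- as_density_field(field)
  if (!is.numeric(delta) || length(delta) != 1 || !is.finite(delta))
    stop("`delta` must be a single finite number")
  if (delta < 0) stop("`delta` must be non-negative")
  if (!is.numeric(floor) || length(floor) != 1 || floor < 0)
    stop("`floor` must be a single non-negative number")

  st <- persistence_state(field)
  par <- steepest_ascent_forest(field)
  v <- st$values
  n <- st$n
  nb <- neighbor_matrix(st$nr, st$nc)

  keep <- which(st$merging & st$merge_persistence >= delta &
                  st$edge_value >= floor)
  ea <- integer(0); eb <- integer(0)
  add_edge <- function(a, b) {
    ea[[length(ea) + 1L]] <<- a
    eb[[length(eb) + 1L]] <<- b
  }

  on_path <- rep(FALSE, n)       # vertices whose ascent edge is emitted
  roots_hit <- integer(0)
  trace_up <- function(u) {
    while (!on_path[u]) {
      on_path[u] <- TRUE
      p <- par[u]
      if (p == u) { roots_hit[[length(roots_hit) + 1L]] <<- u; return() }
      add_edge(u, p)
      u <- p
    }
  }
  environment(trace_up) <- environment()

  for (ei in keep) {
    a <- st$edges[ei, 1L]; b <- st$edges[ei, 2L]
    add_edge(a, b)
    trace_up(a)
    trace_up(b)
  }

  # flat-summit realizations: drainage trees of reached + essential maxima
  roots <- unique(c(roots_hit, st$essential))
  summit_done <- rep(FALSE, n)
  for (r in roots) {
    if (summit_done[r]) next
    queue <- r; summit_done[r] <- TRUE
    while (length(queue)) {
      u <- queue[[1L]]; queue <- queue[-1L]
      for (w in nb[u, ]) {
        if (!is.na(w) && !summit_done[w] && v[w] == v[r]) {
          # member of the flat summit iff it drains (transitively) into it;
          # maximal-plateau members always do, boundary plateaus may not
          if (drains_to(w, r, par)) {
            summit_done[w] <- TRUE
            add_edge(w, par[w])
            queue[[length(queue) + 1L]] <- w
          }
        }
      }
    }
  }

  if (length(ea)) {
    em <- cbind(pmin(ea, eb), pmax(ea, eb))
    em <- unique(em)
    em <- em[order(em[, 1L], em[, 2L]), , drop = FALSE]
  } else {
    em <- matrix(integer(0), 0, 2)
  }
  nodes <- sort(unique(as.vector(em)))
  structure(list(
    dim = c(st$nr, st$nc),
    nodes = nodes,
    edges = em,
    node_value = v[nodes],
    saddles = st$edges[keep, , drop = FALSE],
    saddle_persistence = st$merge_persistence[keep],
    maxima = sort(roots),
    pixel_size_um = field$pixel_size_um
  ), class = "morse_graph")
}

drains_to <- function(u, r, par) {
  repeat {
    if (u == r) return(TRUE)
    p <- par[u]
    if (p == u) return(FALSE)
    u <- p
  }
}

#' @export
print.morse_graph <- function(x, ...) {
  cat(sprintf(
    "morse_graph: %d nodes, %d edges, %d retained saddles on a %d x %d grid\n",
    length(x$nodes), nrow(x$edges), nrow(x$saddles), x$dim[1], x$dim[2]))
  invisible(x)
}
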
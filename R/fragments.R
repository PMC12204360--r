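#' Fragment sets
#'
#' A fragment is an ordered polyline of pixel coordinates between two
#' critical points (or a closed loop); a fragment set is the decomposition
#' of a skeleton graph into such polylines, each with its length in
#' micrometers. Coordinates are 0-based (row, col) pixel-center positions;
#' after coordinate mapping they may be non-integer.
#'
#' @param coords list of numeric matrices, each n x 2 with columns
#'   (row, col).
#' @param pixel_size_um pixel size in micrometers (1 unit of coordinate
#'   distance corresponds to this physical length).
#' @param end_types optional character vector pairs per fragment, e.g.
#'   \code{c("endpoint-branchpoint")}.
#' @param closed logical per fragment: TRUE for loop fragments (first and
#'   last vertex coincide).
#' @return object of class \code{fragment_set}.
#' @export
fragment_set <- function(coords, pixel_size_um = 1, end_types = NULL,
                         closed = NULL) {
  stopifnot(is.list(coords))
  coords <- lapply(coords, function(m) {
    m <- as.matrix(m)
    stopifnot(ncol(m) == 2, nrow(m) >= 2)
    storage.mode(m) <- "double"
    colnames(m) <- c("row", "col")
    m
  })
  n <- length(coords)
  if (is.null(end_types)) end_types <- rep("unknown", n)
  if (is.null(closed)) closed <- vapply(coords, function(m)
    all(m[1, ] == m[nrow(m), ]), TRUE)
  structure(list(coords = coords, pixel_size_um = as.numeric(pixel_size_um),
                 end_types = end_types, closed = closed),
            class = "fragment_set")
}

#' @export
length.fragment_set <- function(x) length(x$coords)

#' Fragment lengths in micrometers
#' @param frags a \code{\link{fragment_set}}.
#' @return numeric vector: per-fragment polyline length (sum of segment
#'   Euclidean lengths times the pixel size).
#' @export
fragment_lengths <- function(frags) {
  stopifnot(inherits(frags, "fragment_set"))
  vapply(frags$coords, function(m) {
    d <- diff(m)
    sum(sqrt(d[, 1L]^2 + d[, 2L]^2))
  }, 0) * frags$pixel_size_um
}

#' @export
print.fragment_set <- function(x, ...) {
  cat(sprintf("fragment_set: %d fragments, total length %.4g um\n",
              length(x$coords), sum(fragment_lengths(x))))
  invisible(x)
}

#' Decompose a skeleton graph into skeletal fragments
#'
#' Walks all edges of the graph (a deterministic depth-first edge walk) and
#' emits every maximal path whose interior vertices have degree 2 and whose
#' ends are critical points (branch points, endpoints). Pure cycles without
#' any critical point are emitted as one closed fragment anchored at their
#' minimum-linear-index node. Every edge belongs to exactly one fragment.
#'
#' @param g a \code{skeleton_graph}.
#' @return a \code{\link{fragment_set}}.
#' @export
extract_fragments <- function(g) {
  g <- as_skeleton_graph(g)
  nr <- g$dim[1]
  if (nrow(g$edges) == 0L)
    return(fragment_set(list(), g$pixel_size_um, character(0), logical(0)))
  deg <- node_degrees(g)
  adj <- adjacency_list(g)
  used <- new.env(hash = TRUE, parent = emptyenv())
  ekey <- function(a, b) paste0(min(a, b), "_", max(a, b))
  is_crit <- deg != 2L
  names(is_crit) <- g$nodes

  node_type <- function(nd) {
    d <- deg[[as.character(nd)]]
    if (d == 1L) "endpoint" else if (d > 2L) "branchpoint" else "loop"
  }
  coords_of <- function(path) {
    cbind(row = (path - 1L) %% nr, col = (path - 1L) %/% nr)
  }

  frag_coords <- list(); frag_types <- character(0); frag_closed <- logical(0)
  walk_from <- function(start, first) {
    path <- c(start, first)
    assign(ekey(start, first), TRUE, envir = used)
    prev <- start; cur <- first
    while (deg[[as.character(cur)]] == 2L && cur != start) {
      nxt <- setdiff(adj[[as.character(cur)]], prev)
      if (length(nxt) != 1L) break
      assign(ekey(cur, nxt), TRUE, envir = used)
      path <- c(path, nxt)
      prev <- cur; cur <- nxt
    }
    path
  }

  crit_nodes <- g$nodes[is_crit]
  for (cp in crit_nodes) {
    for (nb in adj[[as.character(cp)]]) {
      if (exists(ekey(cp, nb), envir = used)) next
      path <- walk_from(cp, nb)
      frag_coords[[length(frag_coords) + 1L]] <- coords_of(path)
      frag_types <- c(frag_types, paste(node_type(path[1]),
                                        node_type(path[length(path)]),
                                        sep = "-"))
      frag_closed <- c(frag_closed, path[1] == path[length(path)])
    }
  }
  # remaining edges lie on pure cycles: anchor at min-index node with an
  # unused edge and walk around
  repeat {
    unused <- which(!vapply(seq_len(nrow(g$edges)), function(i)
      exists(ekey(g$edges[i, 1L], g$edges[i, 2L]), envir = used), TRUE))
    if (length(unused) == 0L) break
    anchors <- pmin(g$edges[unused, 1L], g$edges[unused, 2L])
    a <- min(anchors)
    nbs <- Filter(function(x) !exists(ekey(a, x), envir = used),
                  adj[[as.character(a)]])
    path <- walk_from(a, nbs[[1L]])
    # close the loop back to the anchor if the walk stopped next to it
    if (path[length(path)] != a) {
      assign(ekey(path[length(path)], a), TRUE, envir = used)
      path <- c(path, a)
    }
    frag_coords[[length(frag_coords) + 1L]] <- coords_of(path)
    frag_types <- c(frag_types, "loop-loop")
    frag_closed <- c(frag_closed, TRUE)
  }
  fragment_set(frag_coords, g$pixel_size_um, frag_types, frag_closed)
}

#' Vectorize fragments as a GeoJSON-style feature document
#'
#' One LineString feature per fragment, coordinates in (x = col, y = row)
#' order scaled to micrometers; properties record length, vertex count and
#' endpoint types. The document is an RFC 7946-shaped FeatureCollection
#' (planar micrometer coordinates, noted in a top-level \code{crs_note}
#' property) and round-trips losslessly through
#' \code{\link{read_vector_document}}.
#'
#' @param frags a \code{\link{fragment_set}}.
#' @param pixel_size_um pixel size used for the coordinate scaling
#'   (defaults to the fragment set's own).
#' @return a list representing the FeatureCollection (serialize with
#'   \code{\link{write_vector_document}}).
#' @export
to_vector_document <- function(frags, pixel_size_um = frags$pixel_size_um) {
  stopifnot(inherits(frags, "fragment_set"))
  lens <- fragment_lengths(frags) / frags$pixel_size_um * pixel_size_um
  features <- lapply(seq_along(frags$coords), function(i) {
    m <- frags$coords[[i]]
    xy <- cbind(m[, "col"], m[, "row"]) * pixel_size_um
    list(
      type = "Feature",
      geometry = list(type = "LineString",
                      coordinates = lapply(seq_len(nrow(xy)),
                                           function(j) unname(xy[j, ]))),
      properties = list(length_um = lens[i],
                        n_vertices = nrow(m),
                        end_types = frags$end_types[i],
                        closed = frags$closed[i])
    )
  })
  list(type = "FeatureCollection",
       crs_note = "planar coordinates in micrometers, (x, y) = (col, row) * pixel_size",
       pixel_size_um = pixel_size_um,
       features = features)
}

#' Write a vector feature document to a GeoJSON file
#' @param doc document from \code{\link{to_vector_document}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_vector_document <- function(doc, path) {
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

#' Read a GeoJSON fragment document back into a fragment set
#' @param path GeoJSON file written by \code{\link{write_vector_document}}.
#' @return a \code{\link{fragment_set}} (coordinates restored to pixel
#'   units using the stored pixel size).
#' @export
read_vector_document <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  ps <- as.numeric(doc$pixel_size_um %||% 1)
  coords <- lapply(doc$features, function(f) {
    xy <- do.call(rbind, lapply(f$geometry$coordinates, function(p)
      c(as.numeric(p[[1]]), as.numeric(p[[2]]))))
    cbind(row = xy[, 2] / ps, col = xy[, 1] / ps)
  })
  end_types <- vapply(doc$features, function(f)
    as.character(f$properties$end_types %||% "unknown"), "")
  closed <- vapply(doc$features, function(f)
    isTRUE(f$properties$closed), TRUE)
  fragment_set(coords, ps, end_types, closed)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Rasterize a fragment set to a binary skeleton image
#' @param frags a \code{\link{fragment_set}}.
#' @param dim grid dimensions c(nr, nc).
#' @return logical matrix with TRUE at every pixel a fragment vertex
#'   rounds to.
#' @export
fragments_to_mask <- function(frags, dim) {
  m <- matrix(FALSE, dim[1], dim[2])
  for (fc in frags$coords) {
    r <- round(fc[, "row"]) + 1L
    cc <- round(fc[, "col"]) + 1L
    ok <- r >= 1L & r <= dim[1] & cc >= 1L & cc <= dim[2]
    m[cbind(r[ok], cc[ok])] <- TRUE
  }
  m
}
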
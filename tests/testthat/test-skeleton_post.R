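make_path_graph <- function(cols, row = 2L, nr = 5L, nc = 20L, value = 1) {
  idx <- lin(rep(row, length(cols)), cols, nr)
  edges <- cbind(idx[-length(idx)], idx[-1])
  skeleton_graph(idx, edges, c(nr, nc), rep(value, length(idx)), 1)
}

test_that("Otsu masking separates well-separated classes and matches exhaustive search", {
  strip <- function(m) { attributes(m) <- list(dim = dim(m)); m }

  v <- matrix(c(rep(0.1, 50), rep(0.9, 50)), 10, 10)
  mk <- otsu_mask(v)
  expect_identical(strip(mk), v == 0.9)

  v01 <- matrix(rep(c(0, 1), 32), 8, 8)
  mk01 <- otsu_mask(v01)
  expect_identical(strip(mk01), v01 == 1)
  expect_true(attr(mk01, "threshold") > 0 && attr(mk01, "threshold") <= 1)

  set.seed(5)
  v2 <- matrix(pmin(pmax(c(rnorm(50, 0.2, 0.05), rnorm(50, 0.8, 0.05)), 0), 1),
               10, 10)
  mk2 <- otsu_mask(v2)
  thr_oracle <- oracle_otsu_threshold(v2)
  expect_identical(strip(mk2), v2 >= thr_oracle)
  expect_equal(attr(mk2, "threshold"), thr_oracle, tolerance = 1e-12)

  expect_error(otsu_mask(matrix(0.5, 4, 4)), "constant")
})

test_that("mask intersection removes nodes and can split components", {
  g <- make_path_graph(3:12)
  all_true <- matrix(TRUE, 5, 20)
  gm <- mask_graph(g, all_true)
  expect_identical(gm$edges, g$edges)
  expect_identical(gm$nodes, g$nodes)

  gm0 <- mask_graph(g, matrix(FALSE, 5, 20))
  expect_equal(length(gm0$nodes), 0L)
  expect_equal(nrow(gm0$edges), 0L)

  cut <- all_true; cut[2, 7] <- FALSE    # knock out one interior pixel
  gm2 <- mask_graph(g, cut)
  expect_equal(graph_components(gm2)$no, 2L)

  expect_error(mask_graph(g, matrix(TRUE, 4, 20)), "shape")
})

test_that("maximal spanning forest keeps trees, breaks cycles at the weakest edge", {
  g <- make_path_graph(3:10)
  expect_identical(max_spanning_forest(g)$edges, g$edges)

  # 2x2 pixel cycle with distinct node values; the lowest-weight edge goes
  nr <- 4L
  nd <- c(lin(1L, 1L, nr), lin(2L, 1L, nr), lin(1L, 2L, nr), lin(2L, 2L, nr))
  ed <- rbind(c(nd[1], nd[2]), c(nd[1], nd[3]), c(nd[2], nd[4]),
              c(nd[3], nd[4]))
  vals <- c(1, 0.8, 0.6, 0.1)
  g4 <- skeleton_graph(nd, ed, c(4L, 4L), vals, 1)
  mst <- max_spanning_forest(g4)
  expect_equal(nrow(mst$edges), 3L)
  dropped <- setdiff(paste(ed[, 1], ed[, 2]),
                     paste(mst$edges[, 1], mst$edges[, 2]))
  expect_identical(dropped, paste(lin(1L, 2L, nr), lin(2L, 2L, nr)))  # w = 0.35

  # forest property: edges = nodes - components
  comp <- graph_components(mst)
  expect_equal(nrow(mst$edges), length(mst$nodes) - comp$no)
})

test_that("spanning forest weight matches exhaustive enumeration on small graphs", {
  set.seed(9)
  for (i in 1:20) {
    nr <- 3L
    sub <- matrix(runif(9) < 0.75, 3, 3)
    if (sum(sub) < 2) next
    g <- mask_to_graph(sub, 1)
    g$node_value <- runif(length(g$nodes))
    if (nrow(g$edges) == 0) next
    msf <- max_spanning_forest(g)
    w <- function(e, gg) (gg$node_value[match(e[, 1], gg$nodes)] +
                            gg$node_value[match(e[, 2], gg$nodes)]) / 2
    got <- sum(w(msf$edges, g))
    want <- oracle_max_forest_weight(g$nodes, g$edges, w(g$edges, g))
    expect_equal(got, want, tolerance = 1e-12)
    expect_equal(nrow(msf$edges),
                 length(g$nodes) - graph_components(g)$no)
  }
})

test_that("haircut removes short low-curvature spurs and nothing else", {
  nr <- 30L; nc <- 40L
  spine_cols <- 2:35
  spine <- lin(rep(15L, length(spine_cols)), spine_cols, nr)
  mk <- matrix(FALSE, nr, nc); mk[15, spine_cols] <- TRUE

  # spurs attach at column 20 so the spine runs > 10 edges on both sides
  # (a terminal run at or below the haircut length is itself a "hair")

  # straight 5-px spur: removed, spine untouched
  mk5 <- mk; mk5[10:14, 20] <- TRUE
  g5 <- max_spanning_forest(mask_to_graph(mk5, 1))
  h5 <- haircut(g5, 10)
  expect_identical(sort(h5$nodes), sort(spine))

  # 14-edge spur exceeds the threshold and is retained
  mk15 <- mk; mk15[1:14, 20] <- TRUE
  g15 <- max_spanning_forest(mask_to_graph(mk15, 1))
  h15 <- haircut(g15, 10)
  expect_identical(sort(h15$nodes), sort(g15$nodes))

  # L-shaped 5-edge spur (one direction change): removed
  mkL <- mk; mkL[12:14, 20] <- TRUE; mkL[12, 18:19] <- TRUE
  gL <- max_spanning_forest(mask_to_graph(mkL, 1))
  hL <- haircut(gL, 10)
  expect_identical(sort(hL$nodes), sort(spine))

  # staircase 6-edge spur with 3+ direction changes: retained
  mkS <- mk
  stairs <- rbind(c(14, 20), c(13, 20), c(13, 21), c(12, 21), c(12, 22),
                  c(11, 22))
  mkS[stairs] <- TRUE
  gS <- max_spanning_forest(mask_to_graph(mkS, 1))
  hS <- haircut(gS, 10)
  expect_identical(sort(hS$nodes), sort(gS$nodes))

  # max_len_px = 0 is the identity
  expect_identical(haircut(g5, 0)$nodes, g5$nodes)

  # non-forest input errors
  sq <- matrix(FALSE, 4, 4); sq[2:3, 2:3] <- TRUE
  expect_error(haircut(mask_to_graph(sq, 1)), "forest")
})

test_that("haircut never raises degrees and removes only whole spurs", {
  set.seed(31)
  for (i in 1:10) {
    mk <- matrix(runif(20 * 20) < 0.35, 20, 20)
    g <- max_spanning_forest(mask_to_graph(mk, 1))
    h <- haircut(g, 4)
    din <- table(factor(c(g$edges), levels = g$nodes))
    dout <- table(factor(c(h$edges), levels = g$nodes))
    expect_true(all(dout <= din))
    # pruning a forest leaves a forest
    expect_equal(nrow(h$edges), length(h$nodes) - graph_components(h)$no)
  }
})

test_that("critical points follow the degree rules", {
  p <- make_path_graph(3:12)
  cp <- find_critical_points(p)
  expect_identical(cp$branch, integer(0))
  expect_identical(sort(cp$ends), sort(p$nodes[c(1, length(p$nodes))]))

  # Y: three arms meeting at (10, 10)
  nr <- 20L
  mk <- matrix(FALSE, 20, 20)
  mk[10, 5:10] <- TRUE; mk[10, 10:15] <- TRUE; mk[4:10, 10] <- TRUE
  y <- mask_to_graph(mk, 1)
  cpy <- find_critical_points(y)
  expect_identical(cpy$branch, lin(10L, 10L, nr))
  expect_equal(length(cpy$ends), 3L)

  # 4-cycle: no critical points at all
  sq <- matrix(FALSE, 4, 4); sq[2:3, 2:3] <- TRUE
  cps <- find_critical_points(mask_to_graph(sq, 1))
  expect_identical(cps$branch, integer(0))
  expect_identical(cps$ends, integer(0))
})

test_that("fragment decomposition conserves edges and lengths", {
  p <- make_path_graph(3:13)           # 11 nodes, 10 edges
  fr <- extract_fragments(p)
  expect_equal(length(fr), 1L)
  expect_equal(fragment_lengths(fr), 10)

  # Y with arms of 5, 5, 5 edges: 3 fragments, 15 edges conserved
  nr <- 20L
  mk <- matrix(FALSE, 20, 20)
  mk[10, 5:10] <- TRUE; mk[10, 10:15] <- TRUE; mk[5:10, 10] <- TRUE
  y <- mask_to_graph(mk, 1)
  fry <- extract_fragments(y)
  expect_equal(length(fry), 3L)
  expect_equal(sum(vapply(fry$coords, nrow, 0L) - 1L), nrow(y$edges))
  expect_equal(sum(fragment_lengths(fry)), 15)

  # two disjoint paths: per-component accounting
  g2 <- make_path_graph(2:6)
  g2b <- make_path_graph(10:14, row = 4L)
  both <- skeleton_graph(c(g2$nodes, g2b$nodes),
                         rbind(g2$edges, g2b$edges), g2$dim,
                         c(g2$node_value, g2b$node_value), 1)
  fr2 <- extract_fragments(both)
  expect_equal(length(fr2), 2L)

  # pure cycle: one closed fragment, all edges covered
  sq <- matrix(FALSE, 5, 5); sq[2:3, 2:3] <- TRUE
  frc <- extract_fragments(mask_to_graph(sq, 1))
  expect_equal(length(frc), 1L)
  expect_true(frc$closed[1])
  expect_equal(nrow(frc$coords[[1]]) - 1L, 4L)

  # random graphs: every edge in exactly one fragment
  set.seed(17)
  for (i in 1:8) {
    mk <- matrix(runif(15 * 15) < 0.4, 15, 15)
    g <- mask_to_graph(mk, 1)
    fr <- extract_fragments(g)
    expect_equal(sum(vapply(fr$coords, nrow, 0L) - 1L), nrow(g$edges))
    if (length(fr)) expect_true(all(fragment_lengths(fr) > 0))
  }
})

test_that("GeoJSON vectorization scales to micrometers and round-trips", {
  p <- make_path_graph(3:13)           # 10 edges
  fr <- extract_fragments(p)
  fr$pixel_size_um <- 0.46
  doc <- to_vector_document(fr, pixel_size_um = 0.46)
  expect_equal(length(doc$features), 1L)
  expect_equal(doc$features[[1]]$properties$length_um, 4.6, tolerance = 1e-12)
  expect_equal(doc$features[[1]]$properties$n_vertices, 11L)

  empty <- fragment_set(list(), 1)
  doc0 <- to_vector_document(empty)
  expect_equal(length(doc0$features), 0L)
  expect_identical(doc0$type, "FeatureCollection")

  f1 <- withr::local_tempfile(fileext = ".geojson")
  f2 <- withr::local_tempfile(fileext = ".geojson")
  write_vector_document(doc, f1)
  rt <- read_vector_document(f1)
  write_vector_document(to_vector_document(rt, 0.46), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
  expect_equal(rt$coords[[1]], fr$coords[[1]], tolerance = 1e-12)
})
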
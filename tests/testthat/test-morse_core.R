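test_that("Gaussian smoothing is identity at sigma 0, preserves constants and mass", {
  f <- density_field(matrix(runif(48, 0, 2), 6, 8))
  expect_identical(smooth_density(f, 0), f)

  const <- density_field(matrix(0.7, 5, 5))
  expect_equal(smooth_density(const, 2)$values, const$values, tolerance = 1e-12)

  # single impulse of mass m: output sums to m (reflect padding, unit kernel)
  imp <- matrix(0, 11, 11); imp[6, 6] <- 3.5
  sm <- smooth_density(density_field(imp), 1)
  expect_equal(sum(sm$values), 3.5, tolerance = 1e-6)

  expect_error(smooth_density(f, -1), "non-negative")
})

test_that("separable smoothing matches a direct dense convolution oracle", {
  set.seed(11)
  v <- matrix(runif(9 * 7), 9, 7)
  sm <- smooth_density(density_field(v), 1.3)
  expect_equal(sm$values, oracle_gauss_conv(v, 1.3), tolerance = 1e-10)
})

test_that("0-dim persistence pairs the two-peak profile by the elder rule", {
  # peaks 2 and 3 along a path; the ridge between them bottoms out at 1
  v <- rbind(c(2, 1, 3), c(0, 0, 0))
  p <- compute_persistence_0d(density_field(v))
  finite_pos <- p[p$persistence > 0, ]
  expect_equal(nrow(finite_pos), 1L)
  expect_equal(finite_pos$birth_value, 2)
  expect_equal(finite_pos$death_value, 1)
  expect_equal(finite_pos$persistence, 1)
  ess <- attr(p, "essential")
  expect_equal(length(ess), 1L)
  expect_equal(as.vector(v)[ess], 3)   # the global maximum never dies
})

test_that("a constant field has no positive-persistence pairs and one essential class", {
  p <- compute_persistence_0d(density_field(matrix(1, 6, 6)))
  expect_true(all(p$persistence == 0))
  expect_equal(length(attr(p, "essential")), 1L)
})

test_that("union-find persistence matches boundary-matrix reduction on random fields", {
  set.seed(42)
  for (i in 1:100) {
    v <- matrix(runif(64), 8, 8)
    p <- compute_persistence_0d(density_field(v))
    o <- oracle_persistence_pairs(v)
    got <- sort(paste(round(p$birth_value, 12), round(p$death_value, 12)))
    want <- sort(paste(round(o$birth_value, 12), round(o$death_value, 12)))
    expect_identical(got, want)
  }
})

test_that("persistence is invariant to adding a constant and stable under perturbation", {
  set.seed(7)
  v <- matrix(runif(100), 10, 10)
  p1 <- compute_persistence_0d(density_field(v))
  p2 <- compute_persistence_0d(density_field(v + 5))
  expect_equal(p1$persistence, p2$persistence, tolerance = 1e-12)

  g1 <- extract_morse_graph(density_field(v), 0.1)
  g2 <- extract_morse_graph(density_field(v + 5), 0.1)
  expect_identical(g1$edges, g2$edges)

  # sup-norm eps perturbation moves sorted persistences by at most 2 eps
  for (i in 1:20) {
    eps <- 0.02
    w <- v + matrix(runif(100, -eps, eps), 10, 10)
    w <- pmax(w, 0)
    q <- compute_persistence_0d(density_field(w))
    a <- sort(p1$persistence, decreasing = TRUE)
    b <- sort(q$persistence, decreasing = TRUE)
    n <- max(length(a), length(b))
    a <- c(a, rep(0, n - length(a))); b <- c(b, rep(0, n - length(b)))
    expect_lt(max(abs(a - b)), 2 * eps + 1e-12)
  }
})

test_that("steepest ascent points to the highest strict neighbor and terminates", {
  # strictly monotone ramp: every pixel points right, one maximum
  ramp <- density_field(rbind(c(0.1, 1.1, 2.1, 3.1), c(0, 1, 2, 3)))
  par <- steepest_ascent_forest(ramp)
  nr <- 2
  expect_equal(par[lin(1, 1, nr)], lin(1, 2, nr))
  expect_equal(par[lin(1, 3, nr)], lin(1, 4, nr))
  expect_equal(par[lin(1, 4, nr)], lin(1, 4, nr))   # self-parent at the max
  expect_equal(sum(par == seq_along(par)), 1L)

  # two-peak profile: the valley flows toward the higher peak
  v <- rbind(c(2, 1, 3), c(0, 0, 0))
  par <- steepest_ascent_forest(density_field(v))
  expect_equal(par[lin(1, 2, 2)], lin(1, 3, 2))

  # termination from every start on random fields
  set.seed(3)
  for (i in 1:10) {
    f <- density_field(matrix(runif(36), 6, 6))
    par <- steepest_ascent_forest(f)
    for (s in seq_along(par)) {
      cur <- s
      for (step in 1:37) { if (par[cur] == cur) break; cur <- par[cur] }
      expect_equal(par[cur], cur)
    }
    # parents never point downhill
    expect_true(all(f$values[par] >= f$values[seq_along(par)]))
  }
})

test_that("plateaus resolve deterministically with one root per flat summit", {
  # exhaustive over all 3x3 binary fields: every value-1 plateau region
  # that is maximal must contain exactly one self-parent
  for (code in 0:511) {
    v <- matrix(as.numeric(bitwAnd(bitwShiftR(code, 0:8), 1L)), 3, 3)
    par <- steepest_ascent_forest(density_field(v))
    expect_true(all(v[par] >= v[seq_len(9)]))
    # roots: self-parents; group pixels by their terminal root
    root_of <- vapply(1:9, function(s) {
      cur <- s
      for (k in 1:10) { if (par[cur] == cur) break; cur <- par[cur] }
      cur
    }, 1L)
    # every maximal plateau region of the top value has exactly one root
    if (any(v == 1)) {
      g <- mask_to_graph(v == 1, 1)
      comp <- graph_components(g)
      for (cid in seq_len(comp$no)) {
        members <- g$nodes[comp$membership == cid]
        # maximal region: no member has a strictly higher neighbor (top value)
        expect_equal(sum(par[members] == members), 1L)
        expect_equal(length(unique(root_of[members])), 1L)
      }
    }
  }
})

test_that("a noiseless straight ridge is recovered exactly", {
  v <- matrix(0, 5, 9); v[3, ] <- 1
  g <- extract_morse_graph(density_field(v), delta = 0.1, floor = 0)
  want_nodes <- sort(lin(3L, 1:9, 5L))
  expect_identical(g$nodes, want_nodes)
  expect_equal(nrow(g$edges), 8L)
  # all edges run along the ridge row
  expect_true(all((g$edges[, 1] - 1) %% 5 + 1 == 3))
  expect_true(all((g$edges[, 2] - 1) %% 5 + 1 == 3))
})

test_that("the Morse graph bridges a low-intensity gap and keeps the junction", {
  v <- make_y_junction(gap_value = 0.3)
  g <- extract_morse_graph(density_field(matrix(v, 32, 32)), delta = 0.1)
  sg <- as_skeleton_graph(g)
  comp <- graph_components(sg)
  jr <- 16L; jc <- 16L
  tips <- c(lin(2, jc, 32), lin(jr, 3, 32), lin(jr, 29, 32))
  expect_true(all(tips %in% sg$nodes))
  tip_comp <- comp$membership[match(tips, sg$nodes)]
  expect_equal(length(unique(tip_comp)), 1L)    # connected across the gap
  deg <- table(c(sg$edges))
  expect_gte(max(deg), 3)                       # a degree-3 node exists
  expect_gte(unname(deg[as.character(lin(jr, jc, 32))]), 3)
})

test_that("saddle retention is nested and monotone in the persistence threshold", {
  set.seed(19)
  v <- matrix(runif(256), 16, 16)
  f <- density_field(v)
  pers <- compute_persistence_0d(f)
  deltas <- c(0, sort(unique(pers$persistence)) + 1e-12)
  prev_edges <- NULL
  prev_saddles <- Inf
  for (d in deltas) {
    g <- extract_morse_graph(f, d)
    key <- paste(g$edges[, 1], g$edges[, 2])
    if (!is.null(prev_edges)) expect_true(all(key %in% prev_edges))
    prev_edges <- key
    expect_lte(nrow(g$saddles), prev_saddles)
    prev_saddles <- nrow(g$saddles)
    # brute-force count of merging edges at or above this threshold
    expect_equal(nrow(g$saddles), sum(pers$persistence >= d))
  }
})

test_that("Morse graph edges are axial and no node is isolated", {
  set.seed(23)
  for (i in 1:5) {
    v <- matrix(runif(144), 12, 12)
    g <- extract_morse_graph(density_field(v), delta = runif(1, 0, 0.3))
    if (nrow(g$edges) == 0) { expect_equal(length(g$nodes), 0L); next }
    d <- abs(g$edges[, 1] - g$edges[, 2])
    expect_true(all(d == 1L | d == 12L))
    expect_true(all(g$nodes %in% as.vector(g$edges)))
  }
})

test_that("invalid parameters are rejected", {
  f <- density_field(matrix(runif(16), 4, 4))
  expect_error(extract_morse_graph(f, -0.1), "non-negative")
  expect_error(density_field(matrix(-1, 3, 3)), "non-negative")
  expect_error(density_field(matrix(1, 1, 5)), "at least 2")
  expect_error(density_field(matrix(c(1, NA, 1, 1), 2, 2)), "finite")
})
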
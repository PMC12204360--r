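#' Specification of a synthetic axon phantom
#'
#' Parameters of the generator that emulates tracer-labeled axon
#' likelihood images: thin bright curvilinear trees with a Gaussian
#' cross-section, per-branch intensity variation, short signal gaps
#' (reduced, not zeroed, intensity) and background noise. Defaults are
#' chosen to resemble sparse tracer label at about 1 um/px: a few trees per
#' tile, gentle tortuosity, a 1 px profile, and gaps of up to 3 px covering
#' a small fraction of the centerline.
#'
#' @param seed integer RNG seed; the phantom is a pure function of the spec.
#' @param shape image dimensions c(nr, nc), at least 64 x 64.
#' @param n_trees number of axon trees (>= 0).
#' @param branch_prob probability per growth step of spawning a side branch.
#' @param step_px growth step length in pixels.
#' @param max_turn_deg maximum direction change per step (tortuosity).
#' @param max_steps maximum growth steps per branch.
#' @param min_branch_px minimum rasterized branch length in pixels; shorter
#'   side branches are discarded (a true branch below the haircut scale is
#'   indistinguishable from a hair by construction).
#' @param profile_sigma_px Gaussian cross-section standard deviation.
#' @param gap_rate expected fraction of centerline pixels inside gaps
#'   (in \[0, 1\]).
#' @param gap_len_px maximum gap run length in pixels.
#' @param gap_floor gap intensity as a fraction of the branch intensity
#'   (default 0.1: faint, not absent).
#' @param noise_sigma background Gaussian noise standard deviation.
#' @param peak peak centerline intensity.
#' @param intensity_range per-branch intensity factor range (fractions of
#'   \code{peak}).
#' @param pixel_size_um physical pixel size.
#' @return object of class \code{phantom_spec}.
#' @export
phantom_spec <- function(seed = 0L, shape = c(192L, 192L), n_trees = 3L,
                         branch_prob = 0.03, step_px = 2, max_turn_deg = 15,
                         max_steps = 120L, min_branch_px = 12L,
                         profile_sigma_px = 1,
                         gap_rate = 0.08, gap_len_px = 3L, gap_floor = 0.1,
                         noise_sigma = 0.05, peak = 1,
                         intensity_range = c(0.8, 1),
                         pixel_size_um = 1) {
  stopifnot(length(shape) == 2, all(shape >= 64))
  for (r in c(branch_prob, gap_rate, gap_floor))
    if (r < 0 || r > 1) stop("rates must lie in [0, 1]")
  if (n_trees < 0 || step_px <= 0 || profile_sigma_px < 0 ||
      noise_sigma < 0 || peak <= 0 || gap_len_px < 0)
    stop("degenerate phantom spec")
  structure(list(seed = as.integer(seed), shape = as.integer(shape),
                 n_trees = as.integer(n_trees), branch_prob = branch_prob,
                 step_px = step_px, max_turn_deg = max_turn_deg,
                 max_steps = as.integer(max_steps),
                 min_branch_px = as.integer(min_branch_px),
                 profile_sigma_px = profile_sigma_px, gap_rate = gap_rate,
                 gap_len_px = as.integer(gap_len_px), gap_floor = gap_floor,
                 noise_sigma = noise_sigma, peak = peak,
                 intensity_range = intensity_range,
                 pixel_size_um = pixel_size_um),
            class = "phantom_spec")
}

with_preserved_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# 4-connected rasterization of a polyline given in (row, col) continuous
# coordinates: per-segment Bresenham between rounded endpoints, diagonal
# steps split through the nearer corner, consecutive duplicates dropped.
# Produces a minimal-thickness digital curve (no rounding zigzag).
raster_polyline_4c <- function(pts) {
  pts_i <- round(pts)
  if (nrow(pts) < 2) return(pts_i)
  out <- pts_i[1, , drop = FALSE]
  for (s in seq_len(nrow(pts) - 1L)) {
    a <- pts_i[s, ]; b <- pts_i[s + 1L, ]
    seg <- bresenham_4c(a, b)
    if (nrow(seg) > 1L) out <- rbind(out, seg[-1L, , drop = FALSE])
  }
  keep <- c(TRUE, rowSums(abs(diff(out))) > 0)
  out[keep, , drop = FALSE]
}

bresenham_4c <- function(a, b) {
  d <- b - a
  n <- max(abs(d))
  if (n == 0) return(matrix(a, 1, 2))
  tt <- seq_len(n) / n
  px <- round(cbind(a[1] + tt * d[1], a[2] + tt * d[2]))
  px <- rbind(matrix(a, 1, 2), px)
  keep <- c(TRUE, rowSums(abs(diff(px))) > 0)
  px <- px[keep, , drop = FALSE]
  out <- px[1, , drop = FALSE]
  for (i in seq_len(nrow(px) - 1L)) {
    p <- px[i, ]; q <- px[i + 1L, ]
    if (all(abs(q - p) == 1)) {
      # split the diagonal through the corner nearer the ideal line
      corner <- if (abs(d[1]) >= abs(d[2])) c(q[1], p[2]) else c(p[1], q[2])
      out <- rbind(out, corner)
    }
    out <- rbind(out, q)
  }
  out
}

#' Generate a synthetic axon phantom
#'
#' Grows random trees by correlated random walks with stochastic
#' Y-branching, rasterizes their centerlines as the ground-truth skeleton,
#' and renders the likelihood image by convolving the centerline amplitude
#' with a Gaussian cross-section profile, attenuating gap runs to a faint
#' floor and adding clipped Gaussian background noise. Fully reproducible
#' from the spec's seed; the caller's RNG state is preserved.
#'
#' @param spec a \code{\link{phantom_spec}}.
#' @return list with \code{field} (the likelihood \code{density_field}),
#'   \code{gt_skeleton} (logical matrix), \code{gt_fragments} (a
#'   \code{\link{fragment_set}} extracted from the rasterized centerline
#'   graph) and \code{spec}.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  with_preserved_seed(spec$seed, {
    nr <- spec$shape[1]; nc <- spec$shape[2]
    margin <- 4
    branches <- list()   # each: matrix of continuous (row, col) points
    for (t in seq_len(spec$n_trees)) {
      # a tree whose trunk dies at the border before reaching a usable
      # length is redrawn (bounded retries, still seed-deterministic)
      for (attempt in 1:20) {
        start <- c(stats::runif(1, margin, nr - 1 - margin),
                   stats::runif(1, margin, nc - 1 - margin))
        dir0 <- stats::runif(1, 0, 2 * pi)
        walkers <- list(list(pos = start, dir = dir0))
        n_spawned <- 1L
        tree_branches <- list()
        while (length(walkers)) {
          w <- walkers[[1L]]; walkers <- walkers[-1L]
          pts <- matrix(w$pos, 1, 2)
          dir <- w$dir
          for (s in seq_len(spec$max_steps)) {
            dir <- dir + stats::runif(1, -1, 1) * spec$max_turn_deg * pi / 180
            nxt <- pts[nrow(pts), ] + spec$step_px * c(sin(dir), cos(dir))
            if (nxt[1] < margin || nxt[1] > nr - 1 - margin ||
                nxt[2] < margin || nxt[2] > nc - 1 - margin) break
            pts <- rbind(pts, nxt)
            if (n_spawned < 6L &&
                stats::runif(1) < spec$branch_prob && nrow(pts) > 3L) {
              side <- sample(c(-1, 1), 1)
              walkers[[length(walkers) + 1L]] <-
                list(pos = nxt,
                     dir = dir + side * stats::runif(1, pi / 6, pi / 3))
              n_spawned <- n_spawned + 1L
            }
          }
          if (nrow(pts) >= 2) tree_branches[[length(tree_branches) + 1L]] <- pts
        }
        trunk_len <- if (length(tree_branches))
          (nrow(tree_branches[[1L]]) - 1L) * spec$step_px else 0
        if (trunk_len >= spec$min_branch_px) break
      }
      branches <- c(branches, tree_branches)
    }

    amp <- matrix(0, nr, nc)
    gt <- matrix(FALSE, nr, nc)
    for (b in branches) {
      px <- raster_polyline_4c(b)
      if (nrow(px) < spec$min_branch_px) next
      inten <- spec$peak * stats::runif(1, spec$intensity_range[1],
                                        spec$intensity_range[2])
      a <- rep(inten, nrow(px))
      # gap runs: expected gap_rate fraction of centerline pixels
      if (spec$gap_rate > 0 && spec$gap_len_px > 0 && nrow(px) > 4) {
        n_gap_px <- round(spec$gap_rate * nrow(px))
        placed <- 0L
        while (placed < n_gap_px) {
          len <- min(sample(spec$gap_len_px, 1), n_gap_px - placed)
          at <- sample(nrow(px) - len + 1L, 1)
          a[at:(at + len - 1L)] <- inten * spec$gap_floor
          placed <- placed + len
        }
      }
      ii <- cbind(px[, 1] + 1, px[, 2] + 1)
      amp[ii] <- pmax(amp[ii], a)
      gt[ii] <- TRUE
    }

    img <- render_profile(amp, spec$profile_sigma_px)
    img <- pmin(img, spec$peak)
    if (spec$noise_sigma > 0)
      img <- img + stats::rnorm(length(img), 0, spec$noise_sigma)
    img <- pmin(pmax(img, 0), spec$peak)

    gt_graph <- mask_to_graph(gt, spec$pixel_size_um)
    gt_frags <- extract_fragments(gt_graph)
    list(field = density_field(matrix(img, nr, nc), spec$pixel_size_um),
         gt_skeleton = gt, gt_fragments = gt_frags, spec = spec)
  })
}

# Convolve a centerline amplitude image with an unnormalized Gaussian
# profile, then rescale so that the interior of a straight axial line of
# amplitude a reads a (its ends read about a(s+1)/(2s), s the 1D kernel
# sum, hence above half the branch intensity).
render_profile <- function(amp, sigma) {
  if (sigma == 0) return(amp)
  r <- max(1L, as.integer(ceiling(4 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  s <- sum(k)
  v <- convolve_axis(amp, k, 1L)
  v <- convolve_axis(v, k, 2L)
  v / s
}

#' Build a skeleton graph from a binary skeleton mask
#'
#' Nodes are the TRUE pixels, edges every axial pair of TRUE pixels; used
#' to derive ground-truth fragments from a rasterized centerline and to
#' turn thinned baselines into graphs.
#'
#' @param mask logical matrix.
#' @param pixel_size_um pixel size.
#' @return a \code{\link{skeleton_graph}}.
#' @export
mask_to_graph <- function(mask, pixel_size_um = 1) {
  nr <- nrow(mask); nc <- ncol(mask)
  idx <- which(mask)
  e1 <- idx[(idx %% nr) != 0 & mask[pmin(idx + 1L, nr * nc)]]
  ev <- cbind(e1, e1 + 1L)
  h1 <- idx[idx + nr <= nr * nc]
  h1 <- h1[mask[h1 + nr]]
  eh <- cbind(h1, h1 + nr)
  skeleton_graph(idx, rbind(ev, eh), c(nr, nc),
                 rep(1, length(idx)), pixel_size_um)
}
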
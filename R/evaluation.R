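#' Distance-tolerant matching of skeleton pixels
#'
#' Matches predicted skeleton pixels to ground-truth pixels one-to-one
#' within Euclidean radius \code{Dr} (pixel centers), greedily in
#' increasing distance order with ties broken by (predicted, ground-truth)
#' linear pixel index, so each ground-truth pixel contributes at most once.
#' Counts follow the stated clauses literally: TP = matched predicted
#' pixels; FP = predicted pixels neither matched nor lying on a
#' ground-truth pixel; FN = ground-truth pixels neither matched nor lying
#' on a predicted pixel.
#'
#' @param pred,gt logical matrices of identical shape (TRUE = skeleton
#'   pixel).
#' @param Dr matching radius in pixels (>= 0); typical values are 5 for
#'   whole-slide and 3 for two-photon data.
#' @return object of class \code{match_result}: list with \code{TP},
#'   \code{FP}, \code{FN} and \code{pairs} (matrix of matched predicted /
#'   ground-truth linear indices).
#' @export
match_pixels <- function(pred, gt, Dr) {
  if (!is.logical(pred)) pred <- pred > 0
  if (!is.logical(gt)) gt <- gt > 0
  if (!all(dim(pred) == dim(gt))) stop("pred and gt shapes differ")
  if (!is.numeric(Dr) || length(Dr) != 1 || Dr < 0)
    stop("Dr must be a single non-negative number")
  nr <- nrow(pred); nc <- ncol(pred)
  p_idx <- which(pred); g_set <- which(gt)
  if (length(p_idx) && length(g_set)) {
    rmax <- floor(Dr)
    offs <- expand.grid(dr = -rmax:rmax, dc = -rmax:rmax)
    offs <- offs[offs$dr^2 + offs$dc^2 <= Dr^2, , drop = FALSE]
    gt_pad <- gt
    cand_p <- integer(0); cand_g <- integer(0); cand_d2 <- numeric(0)
    pr <- (p_idx - 1L) %% nr + 1L
    pc <- (p_idx - 1L) %/% nr + 1L
    for (o in seq_len(nrow(offs))) {
      tr <- pr + offs$dr[o]; tc <- pc + offs$dc[o]
      ok <- tr >= 1L & tr <= nr & tc >= 1L & tc <= nc
      if (!any(ok)) next
      tg <- (tc[ok] - 1L) * nr + tr[ok]
      hit <- gt_pad[tg]
      if (!any(hit)) next
      cand_p <- c(cand_p, p_idx[ok][hit])
      cand_g <- c(cand_g, tg[hit])
      cand_d2 <- c(cand_d2, rep(offs$dr[o]^2 + offs$dc[o]^2, sum(hit)))
    }
    ord <- order(cand_d2, cand_p, cand_g)
    used_p <- logical(nr * nc); used_g <- logical(nr * nc)
    mp <- integer(0); mg <- integer(0)
    for (t in ord) {
      a <- cand_p[t]; b <- cand_g[t]
      if (used_p[a] || used_g[b]) next
      used_p[a] <- TRUE; used_g[b] <- TRUE
      mp <- c(mp, a); mg <- c(mg, b)
    }
  } else {
    mp <- integer(0); mg <- integer(0)
    used_p <- logical(nr * nc); used_g <- logical(nr * nc)
  }
  TP <- length(mp)
  FP <- sum(!used_p[p_idx] & !gt[p_idx])
  FN <- sum(!used_g[g_set] & !pred[g_set])
  structure(list(TP = TP, FP = FP, FN = FN,
                 pairs = cbind(pred = mp, gt = mg)),
            class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: TP=%d FP=%d FN=%d\n", x$TP, x$FP, x$FN))
  invisible(x)
}

metric_counts <- function(m) {
  if (inherits(m, "match_result")) m else as.list(m)
}

#' Skeleton evaluation metrics
#'
#' Precision TP/(TP+FP), recall TP/(TP+FN), their harmonic mean F1, and
#' IoU = TP/(TP+FP+FN). Degenerate denominators return 0 with a warning.
#'
#' @param m a \code{\link{match_pixels}} result (or list with TP, FP, FN).
#' @return a single number in \[0, 1\].
#' @name skeleton_metrics
NULL

#' @rdname skeleton_metrics
#' @export
precision <- function(m) {
  m <- metric_counts(m)
  if (m$TP + m$FP == 0) { warning("no predicted pixels; precision set to 0"); return(0) }
  m$TP / (m$TP + m$FP)
}

#' @rdname skeleton_metrics
#' @export
recall <- function(m) {
  m <- metric_counts(m)
  if (m$TP + m$FN == 0) { warning("no ground-truth pixels; recall set to 0"); return(0) }
  m$TP / (m$TP + m$FN)
}

#' @rdname skeleton_metrics
#' @export
f1_score <- function(m) {
  if (is.numeric(m) && length(m) == 2) {
    p <- m[1]; r <- m[2]           # direct (precision, recall) arithmetic
  } else {
    mm <- metric_counts(m)
    if (mm$TP == 0) { warning("TP = 0; F1 set to 0"); return(0) }
    p <- precision(mm); r <- recall(mm)
  }
  if (p + r == 0) { warning("P + R = 0; F1 set to 0"); return(0) }
  2 * p * r / (p + r)
}

#' @rdname skeleton_metrics
#' @export
iou_score <- function(m) {
  m <- metric_counts(m)
  den <- m$TP + m$FP + m$FN
  if (den == 0) { warning("empty counts; IoU set to 0"); return(0) }
  m$TP / den
}

#' Evaluate a predicted skeleton against ground truth
#' @param pred,gt binary skeleton images (same shape).
#' @param Dr matching radius in pixels.
#' @return data.frame with TP, FP, FN, precision, recall, f1, iou.
#' @export
evaluate_skeleton <- function(pred, gt, Dr) {
  m <- match_pixels(pred, gt, Dr)
  suppressWarnings(data.frame(
    TP = m$TP, FP = m$FP, FN = m$FN,
    precision = precision(m), recall = recall(m),
    f1 = f1_score(m), iou = iou_score(m)))
}

#' Morphological thinning (Zhang-Suen) of a binary mask
#'
#' Iterative two-subpass thinning to a 1-pixel-wide skeleton; the standard
#' medial-axis-style baseline against which ridge-following skeletonization
#' is compared. Operates on a binarized image and therefore cannot follow
#' faint signal through gaps.
#'
#' @param mask logical matrix.
#' @param max_iter iteration cap (default 500).
#' @return logical matrix of the thinned skeleton.
#' @export
thin_skeleton <- function(mask, max_iter = 500L) {
  stopifnot(is.logical(mask) || all(mask %in% c(0, 1)))
  img <- matrix(as.integer(mask), nrow(mask), ncol(mask))
  nr <- nrow(img); nc <- ncol(img)
  shift <- function(m, dr, dc) {
    out <- matrix(0L, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr)
    cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  for (iter in seq_len(max_iter)) {
    changed <- FALSE
    for (pass in 1:2) {
      # neighbors P2..P9 clockwise from north
      P2 <- shift(img, 1, 0);  P3 <- shift(img, 1, -1)
      P4 <- shift(img, 0, -1); P5 <- shift(img, -1, -1)
      P6 <- shift(img, -1, 0); P7 <- shift(img, -1, 1)
      P8 <- shift(img, 0, 1);  P9 <- shift(img, 1, 1)
      B <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
      A <- (P2 == 0 & P3 == 1) + (P3 == 0 & P4 == 1) + (P4 == 0 & P5 == 1) +
        (P5 == 0 & P6 == 1) + (P6 == 0 & P7 == 1) + (P7 == 0 & P8 == 1) +
        (P8 == 0 & P9 == 1) + (P9 == 0 & P2 == 1)
      if (pass == 1) {
        cond <- img == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P6 == 0) & (P4 * P6 * P8 == 0)
      } else {
        cond <- img == 1 & B >= 2 & B <= 6 & A == 1 &
          (P2 * P4 * P8 == 0) & (P2 * P6 * P8 == 0)
      }
      if (any(cond)) { img[cond] <- 0L; changed <- TRUE }
    }
    if (!changed) break
  }
  img == 1L
}
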
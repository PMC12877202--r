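#' Fit a 2-D affine transform from control-point pairs
#'
#' Least-squares fit of `p' = A p + b` from manually selected coordinate
#' pairs (e.g. chip coordinates vs stained-image coordinates). With
#' `similarity = TRUE` the linear part is constrained to rotation + uniform
#' scale (4 degrees of freedom) instead of the full 6.
#'
#' @param src,dst two-column matrices of matched points (n >= 3,
#'   non-collinear).
#' @param similarity constrain to a similarity transform.
#' @return an `affine2d` list with 2x2 matrix `A` and length-2 vector `b`;
#'   apply it with [predict.affine2d()].
#' @export
fit_affine <- function(src, dst, similarity = FALSE) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  if (nrow(src) < 3L || nrow(src) != nrow(dst)) {
    stop("need at least 3 control-point pairs of equal count")
  }
  if (qr(cbind(1, src))$rank < 3L) stop("control points are collinear")
  if (!similarity) {
    X <- cbind(1, src)
    beta <- qr.solve(X, dst)          # 3x2: [b; t(A)]
    A <- t(beta[2:3, , drop = FALSE])
    b <- beta[1, ]
  } else {
    # p' = [a -c; c a] p + b, linear in (a, c, bx, by)
    n <- nrow(src)
    X <- rbind(cbind(src[, 1], -src[, 2], 1, 0),
               cbind(src[, 2],  src[, 1], 0, 1))
    yv <- c(dst[, 1], dst[, 2])
    beta <- qr.solve(X, yv)
    A <- matrix(c(beta[1], beta[2], -beta[2], beta[1]), 2, 2)
    b <- beta[3:4]
  }
  structure(list(A = A, b = as.numeric(b), similarity = similarity),
            class = "affine2d")
}

#' Apply a fitted 2-D affine transform
#' @param object an [fit_affine()] result.
#' @param newdata two-column matrix of points.
#' @param ... unused.
#' @return transformed two-column matrix.
#' @export
predict.affine2d <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  t(object$A %*% t(newdata) + object$b)
}

#' One-to-one nearest matching of predicted to true nucleus positions
#'
#' Greedy globally-shortest-first assignment: all predicted-truth distances
#' are sorted ascending and pairs are accepted whenever both members are
#' still unused, guaranteeing unique one cell-to-one cell correspondences.
#'
#' @param pred data.frame with columns `id`, `x`, `y` (um).
#' @param truth data.frame with columns `id`, `x`, `y` (um).
#' @param max_dist optional cap; pairs farther apart are not formed.
#' @return a `match_result` list: `pairs` (pred_id, truth_id, offset_um),
#'   `unmatched_pred`, `unmatched_truth`.
#' @export
match_nearest <- function(pred, truth, max_dist = Inf) {
  stopifnot(nrow(pred) > 0L, nrow(truth) > 0L)
  d <- outer(seq_len(nrow(pred)), seq_len(nrow(truth)), function(i, j) {
    sqrt((pred$x[i] - truth$x[j])^2 + (pred$y[i] - truth$y[j])^2)
  })
  ord <- order(d)
  used_p <- rep(FALSE, nrow(pred))
  used_t <- rep(FALSE, nrow(truth))
  pi_ <- integer(0); ti_ <- integer(0)
  for (k in ord) {
    if (d[k] > max_dist) break
    i <- (k - 1L) %% nrow(pred) + 1L
    j <- (k - 1L) %/% nrow(pred) + 1L
    if (!used_p[i] && !used_t[j]) {
      used_p[i] <- TRUE; used_t[j] <- TRUE
      pi_ <- c(pi_, i); ti_ <- c(ti_, j)
      if (all(used_p) || all(used_t)) break
    }
  }
  structure(list(
    pairs = data.frame(pred_id = pred$id[pi_], truth_id = truth$id[ti_],
                       offset_um = d[cbind(pi_, ti_)],
                       stringsAsFactors = FALSE),
    unmatched_pred = pred$id[!used_p],
    unmatched_truth = truth$id[!used_t]), class = "match_result")
}

#' Random-placement baseline for localization offsets
#'
#' Samples `n` uniform positions in the region and matches them one-to-one
#' to the true nucleus positions, yielding the offset distribution a random
#' assignment would achieve.
#'
#' @param n number of random nuclei.
#' @param bounds named numeric c(xmin, xmax, ymin, ymax) in um.
#' @param truth data.frame with `id`, `x`, `y` (um).
#' @param seed integer RNG seed.
#' @return numeric vector of matched offsets (um).
#' @export
random_baseline <- function(n, bounds, truth, seed = 1L) {
  set.seed(seed)
  pred <- data.frame(id = paste0("rand", seq_len(n)),
                     x = runif(n, bounds["xmin"], bounds["xmax"]),
                     y = runif(n, bounds["ymin"], bounds["ymax"]))
  match_nearest(pred, truth)$pairs$offset_um
}

#' Overlap ratio of two cell sets
#'
#' `|A intersect B| / max(|A|, |B|)`; 0 when both sets are empty. Used to
#' quantify co-expression of two markers (the sets being the cells
#' expressing each).
#'
#' @param cells_a,cells_b vectors of cell identifiers.
#' @return a number in [0, 1].
#' @export
overlap_ratio <- function(cells_a, cells_b) {
  cells_a <- unique(cells_a); cells_b <- unique(cells_b)
  m <- max(length(cells_a), length(cells_b))
  if (m == 0L) return(0)
  length(intersect(cells_a, cells_b)) / m
}

#' Marker-overlap concordance between two expression matrices
#'
#' For every unordered marker pair, computes the overlap ratio of expressing
#' cells (raw count > 0) in each matrix, then the Pearson correlation of
#' the two overlap-ratio vectors — a platform-agnostic measure of how
#' similarly the two matrices mix cell-type markers.
#'
#' @param matrix_1,matrix_2 gene x cell matrices containing all `markers`.
#' @param markers character vector of marker gene names (>= 2).
#' @return list with `r` (Pearson correlation, NA when a vector is
#'   constant), `overlap_1`, `overlap_2` (named vectors per marker pair).
#' @export
marker_concordance <- function(matrix_1, matrix_2, markers) {
  miss <- setdiff(markers, intersect(rownames(matrix_1), rownames(matrix_2)))
  if (length(miss)) stop("marker(s) absent from a matrix: ", paste(miss, collapse = ", "))
  if (length(markers) < 2L) stop("need at least 2 markers")
  pair_overlaps <- function(m) {
    expressing <- lapply(markers, function(g) colnames(m)[m[g, ] > 0])
    names(expressing) <- markers
    pairs <- combn_pairs(markers)
    v <- vapply(seq_len(nrow(pairs)), function(i) {
      overlap_ratio(expressing[[pairs[i, 1]]], expressing[[pairs[i, 2]]])
    }, 0)
    names(v) <- paste(pairs[, 1], pairs[, 2], sep = "|")
    v
  }
  v1 <- pair_overlaps(matrix_1)
  v2 <- pair_overlaps(matrix_2)
  r <- if (sd(v1) == 0 || sd(v2) == 0) NA_real_ else cor(v1, v2)
  list(r = r, overlap_1 = v1, overlap_2 = v2)
}
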
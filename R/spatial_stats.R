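#' Observed/expected tissue preference (Ro/e)
#'
#' For a cluster x group contingency table of cell counts, expected counts
#' are the chi-square expectations `row_i * col_j / total` and
#' `Ro/e = observed / expected`. A cluster is called enriched in a group
#' when Ro/e > 1. Cells with zero expected count are reported as `NaN`.
#'
#' @param contingency non-negative integer matrix or table with a positive
#'   grand total.
#' @return numeric matrix of Ro/e values, same dimnames as the input.
#' @export
roe <- function(contingency) {
  m <- as.matrix(contingency)
  if (any(m < 0)) stop("contingency counts must be non-negative")
  if (sum(m) == 0) stop("all-zero contingency table")
  expected <- outer(rowSums(m), colSums(m)) / sum(m)
  out <- m / expected            # 0/0 -> NaN where expected is 0
  dimnames(out) <- dimnames(m)
  out
}

#' Pairwise cross-correlation function (PCCF) for cell-type colocalization
#'
#' Observed colocalization events are the (type_a, type_b) cell pairs lying
#' within `radius_um` of each other; the expected count is the mean over
#' `n_perm` random permutations of the type labels across all cells
#' (positions fixed, preserving the tissue's point pattern).
#' `PCCF = observed / expected`; a two-sided empirical permutation p-value
#' is reported alongside.
#'
#' @param cells data.frame with columns `x`, `y` (um) and `cell_type`.
#' @param type_a,type_b cell-type labels (may be equal; same-type pairs are
#'   unordered and exclude self-pairs).
#' @param radius_um colocalization distance (inclusive).
#' @param n_perm number of label permutations.
#' @param seed integer RNG seed.
#' @return a `pccf_result` list: type_a, type_b, observed_pairs,
#'   expected_pairs, pccf, p_value, null (permutation counts), n_perm,
#'   radius_um, seed. `pccf` is `NaN` (flagged degenerate) when the
#'   expected count is 0 over all permutations.
#' @export
pccf <- function(cells, type_a, type_b, radius_um = 30, n_perm = 100, seed = 1L) {
  stopifnot_cols(cells, c("x", "y", "cell_type"))
  if (anyNA(cells$x) || anyNA(cells$y) || anyNA(cells$cell_type)) {
    stop("cells table must not contain missing coordinates or types")
  }
  labels <- as.character(cells$cell_type)
  if (!type_a %in% labels || !type_b %in% labels) {
    stop("both cell types must be present in the table")
  }
  prs <- pairs_within(cells$x, cells$y, radius_um)
  count_pairs <- function(lab) {
    if (nrow(prs) == 0L) return(0L)
    la <- lab[prs[, 1L]]; lb <- lab[prs[, 2L]]
    if (type_a == type_b) {
      sum(la == type_a & lb == type_a)
    } else {
      sum((la == type_a & lb == type_b) | (la == type_b & lb == type_a))
    }
  }
  observed <- count_pairs(labels)
  set.seed(seed)
  null <- vapply(seq_len(n_perm), function(i) count_pairs(sample(labels)), 0L)
  expected <- mean(null)
  val <- if (expected == 0) NaN else observed / expected
  p_up <- (1 + sum(null >= observed)) / (1 + n_perm)
  p_dn <- (1 + sum(null <= observed)) / (1 + n_perm)
  structure(list(type_a = type_a, type_b = type_b,
                 observed_pairs = observed, expected_pairs = expected,
                 pccf = val, p_value = min(1, 2 * min(p_up, p_dn)),
                 null = null, n_perm = n_perm, radius_um = radius_um,
                 seed = seed, degenerate = expected == 0),
            class = "pccf_result")
}

#' @export
print.pccf_result <- function(x, ...) {
  cat(sprintf("PCCF(%s, %s) = %.3f  [observed %d, expected %.2f, p = %.3g, r = %g um, %d perms]\n",
              x$type_a, x$type_b, x$pccf, x$observed_pairs, x$expected_pairs,
              x$p_value, x$radius_um, x$n_perm))
  invisible(x)
}

#' Radial distance profile of cell types around a point
#'
#' Euclidean distance (um) of every cell to a centroid (e.g. the core of a
#' tertiary lymphoid structure), averaged per cell type.
#'
#' @param cells data.frame with `x`, `y` (um) and `cell_type`.
#' @param centroid numeric c(x, y) in um.
#' @return list with `per_type` (data.frame cell_type, mean_dist_um, n) and
#'   `per_cell` (data.frame cell_type, dist_um).
#' @export
radial_profile <- function(cells, centroid) {
  stopifnot(all(is.finite(centroid)))
  d <- sqrt((cells$x - centroid[1])^2 + (cells$y - centroid[2])^2)
  per_cell <- data.frame(cell_type = cells$cell_type, dist_um = d,
                         stringsAsFactors = FALSE)
  agg <- aggregate(dist_um ~ cell_type, per_cell, mean)
  names(agg)[2] <- "mean_dist_um"
  agg$n <- as.integer(table(per_cell$cell_type)[agg$cell_type])
  list(per_type = agg, per_cell = per_cell)
}

#' Centroid of a cell set
#'
#' Arithmetic mean of member coordinates; used e.g. as the core of a niche
#' or district before computing a [radial_profile()].
#'
#' @param cells data.frame with `x` and `y` (um).
#' @return numeric c(x, y).
#' @export
niche_centroid <- function(cells) {
  c(x = mean(cells$x), y = mean(cells$y))
}
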
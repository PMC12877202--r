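#' @importFrom stats rbinom rnbinom rnorm runif rpois sd quantile cor
#'   pchisq p.adjust ks.test setNames aggregate dist chisq.test median
#'   wilcox.test complete.cases
#' @importFrom utils head read.delim write.table read.csv write.csv
#' @import data.table
NULL

#' Chip pixel pitch in micrometres
#'
#' A single constant converts between chip pixels and micrometres:
#' 0.265 um per pixel (100 px = 26.5 um). All um<->px conversions in the
#' package go through [px_to_um()] / [um_to_px()] using this value unless a
#' chip map carries its own `pixel_pitch_um` metadata.
#' @export
PIXEL_PITCH_UM <- 0.265

#' Convert chip pixels to micrometres
#' @param px numeric vector of pixel values.
#' @param pitch micrometres per pixel.
#' @return numeric vector in micrometres.
#' @export
px_to_um <- function(px, pitch = PIXEL_PITCH_UM) px * pitch

#' Convert micrometres to chip pixels
#' @param um numeric vector of micrometre values.
#' @param pitch micrometres per pixel.
#' @return numeric vector in pixels.
#' @export
um_to_px <- function(um, pitch = PIXEL_PITCH_UM) um / pitch

DNA_ALPHABET <- c("A", "C", "G", "T")

# n random barcodes of length len, unique within the returned set
random_barcodes <- function(n, len) {
  if (log(n) > len * log(4)) {
    stop("barcode space 4^", len, " is smaller than the number requested (", n, ")")
  }
  out <- character(0)
  while (length(out) < n) {
    need <- n - length(out)
    mat <- matrix(sample(DNA_ALPHABET, need * len, replace = TRUE), nrow = need)
    out <- unique(c(out, apply(mat, 1, paste0, collapse = "")))
  }
  out[seq_len(n)]
}

is_valid_barcode <- function(x) {
  grepl("^[ACGT]+$", x)
}

# all Hamming-distance-1 neighbours of one barcode (3 * nchar of them)
hamming1_neighbors <- function(barcode) {
  chars <- strsplit(barcode, "", fixed = TRUE)[[1]]
  L <- length(chars)
  out <- character(3L * L)
  k <- 0L
  for (i in seq_len(L)) {
    for (sub in DNA_ALPHABET) {
      if (sub != chars[i]) {
        k <- k + 1L
        tmp <- chars
        tmp[i] <- sub
        out[k] <- paste0(tmp, collapse = "")
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_cols <- function(df, cols, what = deparse(substitute(df))) {
  miss <- setdiff(cols, names(df))
  if (length(miss)) {
    stop(what, " is missing required column(s): ", paste(miss, collapse = ", "))
  }
  invisible(df)
}

# all unordered point pairs within `radius` of each other, found with a
# grid-bucket index; returns a two-column integer matrix (i < j). Exactness
# versus the all-pairs computation is part of the contract (and tested).
pairs_within <- function(x, y, radius) {
  n <- length(x)
  if (n < 2L) return(matrix(integer(0), ncol = 2L))
  cs <- max(radius, 1e-9)
  gx <- floor(x / cs)
  gy <- floor(y / cs)
  key <- paste(gx, gy)
  cells <- split(seq_len(n), key)
  cell_xy <- do.call(rbind, lapply(strsplit(names(cells), " "), as.numeric))
  res_i <- list()
  k <- 0L
  r2 <- radius^2
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_along(cells)) assign(names(cells)[ci], ci, envir = lookup)
  for (ci in seq_along(cells)) {
    a <- cells[[ci]]
    cxy <- cell_xy[ci, ]
    # within-cell pairs
    if (length(a) > 1L) {
      cmb <- combn_pairs(a)
      d2 <- (x[cmb[, 1L]] - x[cmb[, 2L]])^2 + (y[cmb[, 1L]] - y[cmb[, 2L]])^2
      keep <- cmb[d2 <= r2, , drop = FALSE]
      if (nrow(keep)) { k <- k + 1L; res_i[[k]] <- keep }
    }
    # neighbouring cells, visited once (lexicographic order on the offset)
    for (off in list(c(1, 0), c(-1, 1), c(0, 1), c(1, 1))) {
      nb <- mget(paste(cxy[1] + off[1], cxy[2] + off[2]),
                 envir = lookup, ifnotfound = list(NULL))[[1]]
      if (is.null(nb)) next
      b <- cells[[nb]]
      ij <- cbind(rep(a, each = length(b)), rep(b, times = length(a)))
      d2 <- (x[ij[, 1L]] - x[ij[, 2L]])^2 + (y[ij[, 1L]] - y[ij[, 2L]])^2
      keep <- ij[d2 <= r2, , drop = FALSE]
      if (nrow(keep)) {
        swap <- keep[, 1L] > keep[, 2L]
        keep[swap, ] <- keep[swap, c(2L, 1L), drop = FALSE]
        k <- k + 1L
        res_i[[k]] <- keep
      }
    }
  }
  if (k == 0L) return(matrix(integer(0), ncol = 2L))
  out <- do.call(rbind, res_i)
  out[order(out[, 1L], out[, 2L]), , drop = FALSE]
}

combn_pairs <- function(v) {
  n <- length(v)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  cbind(v[i], v[j])
}
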
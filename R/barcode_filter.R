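#' Remove prevalent (detached) spatial barcodes by bin thresholding
#'
#' Spatial barcodes that detach from the chip and get encapsulated by many
#' droplets show anomalously high UMI support concentrated in their home
#' bin; cells carrying them would be mislocalized. The chip is partitioned
#' into `bin_px` x `bin_px` bins, each bin's total UMI support over all
#' spatial barcodes is computed, and any bin whose total *exceeds*
#' `k` times the mean per-bin total (over non-empty bins) is flagged. For
#' each flagged bin the cell with the highest spatial-barcode UMI support in
#' that bin is removed together with all its spatial barcodes everywhere,
#' and the procedure repeats until no bin exceeds the threshold (or
#' `max_iter` / a single pass, if requested).
#'
#' @param pos_counts a positioned count table (see [attach_coordinates()]).
#' @param bin_px bin side length in pixels.
#' @param k threshold multiplier over the mean per-bin UMI total.
#' @param max_iter iteration cap.
#' @param single_pass apply one flag-and-remove pass only.
#' @param mean_mode "bin_total" takes the mean of per-bin UMI totals over
#'   non-empty bins; "per_barcode" divides each bin's total by its number of
#'   distinct barcodes before averaging.
#' @return list with `counts` (filtered table) and `report`, a
#'   `filter_report` list: threshold_value (last computed), bins_flagged
#'   (cumulative), cells_removed, barcodes_removed, iterations.
#' @export
filter_prevalent_barcodes <- function(pos_counts, bin_px = 30, k = 20,
                                      max_iter = 100, single_pass = FALSE,
                                      mean_mode = c("bin_total", "per_barcode")) {
  mean_mode <- match.arg(mean_mode)
  stopifnot_cols(pos_counts, c("cell_id", "spatial_barcode", "umi_count", "x", "y"))
  report <- list(threshold_value = NA_real_, bins_flagged = 0L,
                 cells_removed = character(0), barcodes_removed = 0L,
                 iterations = 0L)
  class(report) <- "filter_report"
  if (nrow(pos_counts) == 0L) {
    report$iterations <- 1L
    return(list(counts = pos_counts, report = report))
  }
  dt <- as.data.table(pos_counts)
  dt[, `:=`(bx = floor(x / bin_px), by_ = floor(y / bin_px))]
  repeat {
    report$iterations <- report$iterations + 1L
    bins <- dt[, list(total = sum(umi_count), n_bc = uniqueN(spatial_barcode)),
               by = c("bx", "by_")]
    thr <- if (mean_mode == "bin_total") {
      k * mean(bins$total)
    } else {
      k * mean(bins$total / bins$n_bc)
    }
    report$threshold_value <- thr
    flagged <- bins[bins$total > thr, ]  # strictly "exceeded"
    if (nrow(flagged) == 0L || nrow(dt) == 0L) break
    report$bins_flagged <- report$bins_flagged + nrow(flagged)
    # per flagged bin: the cell with the highest UMI support inside that bin
    victims <- unique(vapply(seq_len(nrow(flagged)), function(i) {
      sub <- dt[dt$bx == flagged$bx[i] & dt$by_ == flagged$by_[i], ]
      sup <- sub[, list(s = sum(umi_count)), by = "cell_id"]
      sup$cell_id[which.max(sup$s)]
    }, character(1)))
    doomed_bc <- unique(dt$spatial_barcode[dt$cell_id %in% victims])
    report$cells_removed <- c(report$cells_removed, victims)
    report$barcodes_removed <- report$barcodes_removed + length(doomed_bc)
    dt <- dt[!(dt$cell_id %in% victims), ]
    if (single_pass || report$iterations >= max_iter) break
  }
  out <- as.data.frame(dt[, c("cell_id", "spatial_barcode", "umi_count", "x", "y"),
                          with = FALSE])
  attr(out, "pixel_pitch_um") <- attr(pos_counts, "pixel_pitch_um")
  class(out) <- class(pos_counts)
  list(counts = out, report = report)
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf(
    "prevalent-barcode filter: %d iteration(s), %d bin(s) flagged,\n  %d cell(s) removed, %d barcode(s) removed (last threshold %.2f)\n",
    x$iterations, x$bins_flagged, length(x$cells_removed),
    x$barcodes_removed, x$threshold_value))
  invisible(x)
}

#' Restrict a count table to a set of biologically meaningful cells
#'
#' Keeps only rows whose `cell_id` belongs to `valid_cells` (e.g. the cell
#' barcodes retained by expression-based cell calling).
#'
#' @param counts a count table with a `cell_id` column.
#' @param valid_cells character vector of cell ids to keep.
#' @return the subset, same class and attributes as `counts`.
#' @export
restrict_to_cells <- function(counts, valid_cells) {
  keep <- counts$cell_id %in% valid_cells
  out <- counts[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pixel_pitch_um") <- attr(counts, "pixel_pitch_um")
  class(out) <- class(counts)
  out
}
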
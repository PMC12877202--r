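#' Bin one nucleus's spatial-barcode UMIs
#'
#' The chip is partitioned into `bin_px` x `bin_px` bins (default 100 px,
#' i.e. 26.5 um at 0.265 um/px) and the nucleus's UMIs are summed per bin.
#' Nuclei with fewer than 2 spatial-barcode UMIs carry too little signal to
#' classify and are flagged instead of binned.
#'
#' @param rows positioned count rows of a single cell (columns
#'   spatial_barcode, umi_count, x, y).
#' @param bin_px bin side length in pixels.
#' @return a `bin_grid`: data.frame (row, col, umi) of non-empty bins, or
#'   `NULL` when the cell has fewer than 2 UMIs.
#' @export
bin_cell_umis <- function(rows, bin_px = 100) {
  if (sum(rows$umi_count) < 2) return(NULL)
  dt <- data.table(row = floor(rows$y / bin_px), col = floor(rows$x / bin_px),
                   umi = rows$umi_count)
  out <- as.data.frame(dt[, list(umi = sum(umi)), by = c("row", "col")])
  attr(out, "bin_px") <- bin_px
  class(out) <- c("bin_grid", "data.frame")
  out
}

#' Classify a nucleus footprint as unique / major / multiple center
#'
#' The core center is the bin with the maximum UMI count; the core is the
#' 5x5 block around it (24 immediately adjacent bins plus the center). The
#' secondary center is the highest-UMI bin outside the core, with its own
#' 5x5 block. The ratio of core UMI sum to secondary-block UMI sum
#' classifies the nucleus: >= 10 unique center, >= 2 major center,
#' < 2 multiple centers. With no bin outside the core the ratio is infinite
#' (unique). Ties on the maximum bin break to the lexicographically
#' smallest (row, col) for determinism.
#'
#' @param grid a [bin_cell_umis()] grid.
#' @param unique_ratio,major_ratio classification thresholds.
#' @return a `center_class` list: class ("unique", "major" or "multiple"),
#'   ratio, core_bin (row, col), secondary_bin (row, col or NULL),
#'   core_umi, secondary_umi.
#' @export
classify_center <- function(grid, unique_ratio = 10, major_ratio = 2) {
  stopifnot(nrow(grid) >= 1L)
  ord <- order(-grid$umi, grid$row, grid$col)
  core_bin <- c(grid$row[ord[1]], grid$col[ord[1]])
  in_core <- abs(grid$row - core_bin[1]) <= 2 & abs(grid$col - core_bin[2]) <= 2
  core_umi <- sum(grid$umi[in_core])
  outside <- grid[!in_core, , drop = FALSE]
  if (nrow(outside) == 0L) {
    res <- list(class = "unique", ratio = Inf, core_bin = core_bin,
                secondary_bin = NULL, core_umi = core_umi, secondary_umi = 0)
    class(res) <- "center_class"
    return(res)
  }
  ord2 <- order(-outside$umi, outside$row, outside$col)
  sec_bin <- c(outside$row[ord2[1]], outside$col[ord2[1]])
  # the secondary 5x5 block is defined by its own center; it may overlap the core
  in_sec <- abs(grid$row - sec_bin[1]) <= 2 & abs(grid$col - sec_bin[2]) <= 2
  sec_umi <- sum(grid$umi[in_sec])
  ratio <- core_umi / sec_umi
  cls <- if (ratio >= unique_ratio) "unique"
         else if (ratio >= major_ratio) "major"
         else "multiple"
  res <- list(class = cls, ratio = ratio, core_bin = core_bin,
              secondary_bin = sec_bin, core_umi = core_umi,
              secondary_umi = sec_umi)
  class(res) <- "center_class"
  res
}

#' Assign a nucleus position by UMI-weighted minimal combined distance
#'
#' Over candidate positions (by default the spatial-barcode cluster
#' coordinates inside the 25-bin core), returns the candidate minimizing the
#' UMI-weighted sum of Euclidean distances to all core barcodes — the
#' weighted geometric median restricted to observed spatial points. Ties
#' break to the lexicographically smaller (x, y).
#'
#' @param core_rows positioned count rows inside the core (columns
#'   spatial_barcode, umi_count, x, y).
#' @param candidates optional two-column matrix of candidate positions
#'   (defaults to the core barcode coordinates themselves).
#' @return named numeric vector c(x, y) in pixels.
#' @export
assign_position <- function(core_rows, candidates = NULL) {
  if (nrow(core_rows) == 0L) stop("empty core: no barcodes to position against")
  if (is.null(candidates)) {
    candidates <- unique(cbind(core_rows$x, core_rows$y))
  }
  cost <- vapply(seq_len(nrow(candidates)), function(i) {
    sum(core_rows$umi_count *
          sqrt((core_rows$x - candidates[i, 1])^2 +
               (core_rows$y - candidates[i, 2])^2))
  }, 0)
  best <- which(cost == min(cost))
  if (length(best) > 1L) {
    best <- best[order(candidates[best, 1], candidates[best, 2])[1]]
  }
  c(x = candidates[best, 1], y = candidates[best, 2])
}

#' Diffusion quantiles of a localized nucleus
#'
#' UMI-weighted empirical quantiles (closest 50\%, 75\% and 95\%) of the
#' Euclidean distance, in micrometres, from each detected spatial barcode to
#' the assigned nucleus position. Each UMI counts as one observation; the
#' q-quantile is the distance of the first barcode at which the cumulative
#' UMI fraction reaches q.
#'
#' @param rows positioned count rows used for the assignment (core rows by
#'   default in [localize_all()]).
#' @param position assigned c(x, y) in pixels.
#' @param pixel_pitch_um micrometres per pixel.
#' @param probs quantile levels.
#' @return named numeric vector of distances in micrometres.
#' @export
diffusion_quantiles <- function(rows, position, pixel_pitch_um = PIXEL_PITCH_UM,
                                probs = c(0.5, 0.75, 0.95)) {
  d_um <- px_to_um(sqrt((rows$x - position[1])^2 + (rows$y - position[2])^2),
                   pixel_pitch_um)
  ord <- order(d_um)
  d_um <- d_um[ord]
  w <- rows$umi_count[ord]
  cw <- cumsum(w) / sum(w)
  out <- vapply(probs, function(p) d_um[which(cw >= p - 1e-12)[1]], 0)
  names(out) <- paste0("d", round(probs * 100))
  out
}

#' Localize all nuclei in a positioned count table
#'
#' Runs binning, center classification, position assignment and diffusion
#' QC for every cell. Cells classified unique or major center receive
#' coordinates; multiple-center cells and cells with fewer than 2 UMIs are
#' reported unassigned.
#'
#' @param pos_counts a positioned count table (see [attach_coordinates()]).
#' @param bin_px localization bin side (pixels).
#' @param unique_ratio,major_ratio classification thresholds.
#' @param pixel_pitch_um micrometres per pixel (defaults to the table's
#'   metadata).
#' @param quantile_scope "core" computes diffusion quantiles over core
#'   barcodes only, "all" over every detected barcode of the cell.
#' @param mask optional polygon (list with numeric `x`, `y` in um) —
#'   assigned nuclei outside it are dropped from the output.
#' @return data.frame of class `localized_nuclei`: cell_id, x_px, y_px,
#'   x_um, y_um, class, ratio, total_umi, d50, d75, d95. The `summary`
#'   attribute counts cells per class.
#' @export
localize_all <- function(pos_counts, bin_px = 100, unique_ratio = 10,
                         major_ratio = 2, pixel_pitch_um = NULL,
                         quantile_scope = c("core", "all"), mask = NULL) {
  quantile_scope <- match.arg(quantile_scope)
  pitch <- pixel_pitch_um %||% attr(pos_counts, "pixel_pitch_um") %||% PIXEL_PITCH_UM
  dt <- as.data.table(pos_counts)
  cells <- split(dt, by = "cell_id", keep.by = TRUE)
  res <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    rows <- cells[[i]]
    cid <- rows$cell_id[1]
    total <- sum(rows$umi_count)
    grid <- bin_cell_umis(rows, bin_px)
    if (is.null(grid)) {
      res[[i]] <- data.frame(cell_id = cid, x_px = NA_real_, y_px = NA_real_,
                             x_um = NA_real_, y_um = NA_real_,
                             class = "unclassifiable", ratio = NA_real_,
                             total_umi = total, d50 = NA_real_, d75 = NA_real_,
                             d95 = NA_real_, stringsAsFactors = FALSE)
      next
    }
    cc <- classify_center(grid, unique_ratio, major_ratio)
    if (cc$class == "multiple") {
      res[[i]] <- data.frame(cell_id = cid, x_px = NA_real_, y_px = NA_real_,
                             x_um = NA_real_, y_um = NA_real_,
                             class = "multiple", ratio = cc$ratio,
                             total_umi = total, d50 = NA_real_, d75 = NA_real_,
                             d95 = NA_real_, stringsAsFactors = FALSE)
      next
    }
    in_core <- floor(rows$y / bin_px) >= cc$core_bin[1] - 2 &
               floor(rows$y / bin_px) <= cc$core_bin[1] + 2 &
               floor(rows$x / bin_px) >= cc$core_bin[2] - 2 &
               floor(rows$x / bin_px) <= cc$core_bin[2] + 2
    core_rows <- rows[in_core, ]
    pos <- assign_position(core_rows)
    qrows <- if (quantile_scope == "core") core_rows else rows
    dq <- diffusion_quantiles(qrows, pos, pitch)
    res[[i]] <- data.frame(cell_id = cid, x_px = pos[["x"]], y_px = pos[["y"]],
                           x_um = px_to_um(pos[["x"]], pitch),
                           y_um = px_to_um(pos[["y"]], pitch),
                           class = cc$class, ratio = cc$ratio,
                           total_umi = total, d50 = dq[["d50"]],
                           d75 = dq[["d75"]], d95 = dq[["d95"]],
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (!is.null(mask)) {
    assigned <- !is.na(out$x_um)
    inside <- rep(TRUE, nrow(out))
    inside[assigned] <- point_in_polygon(out$x_um[assigned], out$y_um[assigned],
                                         mask$x, mask$y)
    out <- out[!assigned | inside, , drop = FALSE]
    rownames(out) <- NULL
  }
  cls <- factor(out$class, levels = c("unique", "major", "multiple", "unclassifiable"))
  attr(out, "summary") <- table(cls)
  attr(out, "pixel_pitch_um") <- pitch
  class(out) <- c("localized_nuclei", "data.frame")
  out
}

# even-odd ray casting; boundary points on the lower/left edges count inside
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xin <- px < (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & xin)
    j <- i
  }
  inside
}

#' Nucleus recovery as a function of the number of multiplex tubes
#'
#' Collapses the 8 multiplex tubes into k contiguous groups (k in
#' 1, 2, 4, 8), merges cells that share (group, droplet), re-runs
#' localization, and counts cells with a unique or major center. Emulating
#' fewer tubes merges co-encapsulated nuclei back together, so recovery
#' is expected to grow with k.
#'
#' @param pos_counts positioned counts whose `cell_id` is `tube-droplet`.
#' @param ks multiplex group counts to evaluate (must divide 8).
#' @param n_tubes number of tubes in the input ids.
#' @param ... passed to [localize_all()].
#' @return named integer vector of localized-cell counts per k.
#' @export
demux_recovery <- function(pos_counts, ks = c(1L, 2L, 4L, 8L), n_tubes = 8L, ...) {
  if (any(n_tubes %% ks != 0)) stop("every k must divide ", n_tubes)
  parts <- strsplit(pos_counts$cell_id, "-", fixed = TRUE)
  tube <- as.integer(vapply(parts, `[`, "", 1L))
  droplet <- vapply(parts, function(p) paste(p[-1], collapse = "-"), "")
  if (anyNA(tube)) stop("cell_id is not decomposable as tube-droplet")
  out <- integer(length(ks))
  names(out) <- paste0("k", ks)
  for (i in seq_along(ks)) {
    k <- ks[i]
    group <- ceiling(tube / (n_tubes / k))
    merged <- pos_counts
    merged$cell_id <- paste(group, droplet, sep = "-")
    dt <- as.data.table(merged)[, list(umi_count = sum(umi_count)),
                                by = c("cell_id", "spatial_barcode", "x", "y")]
    merged <- as.data.frame(dt[, c("cell_id", "spatial_barcode", "umi_count",
                                   "x", "y"), with = FALSE])
    attr(merged, "pixel_pitch_um") <- attr(pos_counts, "pixel_pitch_um")
    loc <- localize_all(merged, ...)
    out[i] <- sum(loc$class %in% c("unique", "major"))
  }
  out
}
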
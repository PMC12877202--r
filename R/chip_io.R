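#' Construct a chip map
#'
#' A chip map links each spatial barcode on the sequencing chip to the pixel
#' coordinate of its oligo cluster. Region bounds and the pixel pitch are
#' carried as metadata so that downstream stages agree on the um<->px
#' conversion.
#'
#' @param barcode character vector of A/C/G/T barcodes (one length).
#' @param x,y numeric pixel coordinates of the cluster centroids.
#' @param pixel_pitch_um micrometres per pixel.
#' @param bounds optional named numeric vector `c(xmin, xmax, ymin, ymax)`
#'   (pixels); derived from the data when omitted.
#' @return a `chip_map`: a data.frame with columns `barcode`, `x`, `y` and
#'   attributes `pixel_pitch_um` and `bounds`.
#' @export
chip_map <- function(barcode, x, y, pixel_pitch_um = PIXEL_PITCH_UM,
                     bounds = NULL) {
  barcode <- as.character(barcode)
  bad <- !is_valid_barcode(barcode)
  if (any(bad)) {
    stop("non-ACGT barcode(s) in chip map, e.g. ", barcode[which(bad)[1]])
  }
  if (length(unique(nchar(barcode))) > 1L) {
    stop("chip barcodes must all have the same length")
  }
  if (is.null(bounds)) {
    bounds <- c(xmin = min(x), xmax = max(x), ymin = min(y), ymax = max(y))
  }
  out <- data.frame(barcode = barcode, x = as.numeric(x), y = as.numeric(y),
                    stringsAsFactors = FALSE)
  attr(out, "pixel_pitch_um") <- pixel_pitch_um
  attr(out, "bounds") <- bounds
  class(out) <- c("chip_map", "data.frame")
  out
}

#' @export
print.chip_map <- function(x, ...) {
  b <- attr(x, "bounds")
  cat(sprintf("chip_map: %d clusters, %d-mer barcodes, pitch %.3f um/px\n",
              nrow(x), nchar(x$barcode[1]), attr(x, "pixel_pitch_um")))
  cat(sprintf("  bounds (px): x [%.1f, %.1f], y [%.1f, %.1f]\n",
              b["xmin"], b["xmax"], b["ymin"], b["ymax"]))
  invisible(x)
}

#' Read a chip map from a TSV file
#'
#' Expects a tab-separated file whose first three columns are barcode, x, y
#' (a header line is detected and skipped). Malformed rows raise an error
#' naming the offending line.
#'
#' @param path file path.
#' @param pixel_pitch_um micrometres per pixel recorded in the result.
#' @return a [chip_map()].
#' @export
load_chip_map <- function(path, pixel_pitch_um = PIXEL_PITCH_UM) {
  raw <- readLines(path)
  if (!length(raw)) stop("empty chip map file: ", path)
  start <- 1L
  first <- strsplit(raw[1], "\t", fixed = TRUE)[[1]]
  if (length(first) >= 3L && !is_valid_barcode(first[1])) start <- 2L
  if (start > length(raw)) stop("chip map file has a header but no rows: ", path)
  fields <- strsplit(raw[start:length(raw)], "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    line <- start + i - 1L
    if (length(f) < 3L) {
      stop("malformed chip map row at line ", line, ": fewer than 3 fields")
    }
    if (!is_valid_barcode(f[1])) {
      stop("malformed chip map row at line ", line, ": non-ACGT barcode ", f[1])
    }
    if (is.na(suppressWarnings(as.numeric(f[2]))) ||
        is.na(suppressWarnings(as.numeric(f[3])))) {
      stop("malformed chip map row at line ", line, ": non-numeric coordinate")
    }
  }
  chip_map(vapply(fields, `[`, "", 1L),
           as.numeric(vapply(fields, `[`, "", 2L)),
           as.numeric(vapply(fields, `[`, "", 3L)),
           pixel_pitch_um = pixel_pitch_um)
}

#' Write a chip map to a TSV file
#' @param map a [chip_map()].
#' @param path file path.
#' @param header write a `barcode\\tx\\ty` header line.
#' @return `path`, invisibly.
#' @export
write_chip_map <- function(map, path, header = TRUE) {
  write.table(as.data.frame(map)[, c("barcode", "x", "y")], path,
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = header)
  invisible(path)
}

#' Remove chip barcodes observed at more than one coordinate
#'
#' Rare oligo synthesis duplications put the same barcode at two distinct
#' cluster positions; since such a barcode cannot be localized, every entry
#' of it is removed from the whitelist.
#'
#' @param map a [chip_map()].
#' @return list with `map` (deduplicated chip map) and `n_removed`
#'   (number of distinct barcodes removed).
#' @export
dedup_chip_barcodes <- function(map) {
  coord_key <- paste(map$barcode, map$x, map$y)
  map <- map[!duplicated(coord_key), , drop = FALSE]  # exact replicates are harmless
  dup <- unique(map$barcode[duplicated(map$barcode)])
  keep <- !(map$barcode %in% dup)
  out <- map[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "pixel_pitch_um") <- attr(map, "pixel_pitch_um")
  attr(out, "bounds") <- attr(map, "bounds")
  class(out) <- c("chip_map", "data.frame")
  list(map = out, n_removed = length(dup))
}

#' Build a barcode count table
#'
#' Rows of (cell_id, spatial_barcode, umi_count) linking nuclei to chip
#' positions. Rows with the same (cell_id, spatial_barcode) are aggregated by
#' summing their UMI counts.
#'
#' @param cell_id character vector; combination of multiplex and droplet
#'   barcode identifying one captured nucleus.
#' @param spatial_barcode character vector of chip barcodes.
#' @param umi_count positive integer UMI counts.
#' @return data.frame with class `barcode_counts`.
#' @export
barcode_counts <- function(cell_id, spatial_barcode, umi_count) {
  if (any(umi_count < 1)) stop("umi_count must be >= 1")
  dt <- data.table(cell_id = as.character(cell_id),
                   spatial_barcode = as.character(spatial_barcode),
                   umi_count = as.integer(umi_count))
  dt <- dt[, list(umi_count = sum(umi_count)),
           by = c("cell_id", "spatial_barcode")]
  out <- as.data.frame(dt)
  class(out) <- c("barcode_counts", "data.frame")
  out
}

#' Read a barcode count table from a TSV file
#' @param path tab-separated file with columns cell_id, spatial_barcode,
#'   umi_count (header optional).
#' @return a [barcode_counts()] table.
#' @export
load_barcode_counts <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!is.numeric(df[[3]]) && !is.na(suppressWarnings(as.numeric(df[2, 3])))) {
    df <- df[-1, , drop = FALSE]  # header line
    df[[3]] <- as.numeric(df[[3]])
  }
  barcode_counts(df[[1]], df[[2]], df[[3]])
}

#' Correct observed barcodes against a whitelist
#'
#' An observed barcode is kept if it matches the whitelist exactly;
#' otherwise, if exactly one whitelist barcode lies at Hamming distance 1 it
#' is corrected to that barcode; if several do, the whitelist barcode with
#' the highest read count wins (ties are dropped, so correction stays
#' deterministic); if none do, the barcode is reported as unmatched (`NA`).
#' Only substitutions are considered.
#'
#' @param queries character vector of observed barcodes.
#' @param whitelist character vector of valid barcodes (all one length).
#' @param read_counts numeric vector of read support per whitelist barcode,
#'   used to rank multiple distance-1 candidates. Defaults to zero
#'   (all ties, so ambiguous queries are dropped).
#' @return character vector parallel to `queries`; `NA` marks no-match.
#' @export
correct_barcodes <- function(queries, whitelist,
                             read_counts = rep(0, length(whitelist))) {
  L <- unique(nchar(whitelist))
  if (length(L) != 1L) stop("whitelist barcodes must all have one length")
  if (any(nchar(queries) != L)) {
    stop("query barcode length differs from whitelist length ", L)
  }
  wl_counts <- setNames(as.numeric(read_counts), whitelist)
  exact <- queries %in% whitelist
  out <- ifelse(exact, queries, NA_character_)
  todo <- unique(queries[!exact])
  if (length(todo)) {
    fix <- vapply(todo, function(q) {
      nb <- hamming1_neighbors(q)
      hits <- nb[nb %in% whitelist]
      if (length(hits) == 0L) return(NA_character_)
      if (length(hits) == 1L) return(hits)
      cts <- wl_counts[hits]
      best <- cts == max(cts)
      if (sum(best) > 1L) return(NA_character_)  # ambiguous: drop
      hits[best]
    }, character(1))
    out[!exact] <- fix[queries[!exact]]
  }
  out
}

#' Correct a single barcode (scalar convenience wrapper)
#' @inheritParams correct_barcodes
#' @param query one observed barcode.
#' @return the corrected barcode, or `NA` when no match within one mismatch.
#' @export
correct_barcode <- function(query, whitelist,
                            read_counts = rep(0, length(whitelist))) {
  correct_barcodes(query, whitelist, read_counts)
}

#' Attach chip coordinates to a barcode count table
#'
#' Each count row is annotated with the (x, y) pixel position of its spatial
#' barcode on the (deduplicated) chip. Rows whose barcode is absent from the
#' chip are invalid and dropped; optionally they are first run through
#' single-mismatch correction, using the summed UMI support observed in the
#' table as the whitelist read counts.
#'
#' @param counts a [barcode_counts()] table.
#' @param map a deduplicated [chip_map()].
#' @param correct apply [correct_barcodes()] to off-whitelist barcodes first.
#' @return data.frame (class `positioned_counts`) with columns cell_id,
#'   spatial_barcode, umi_count, x, y; attributes `n_dropped` / `umi_dropped`
#'   count removed rows and their UMI mass, and `pixel_pitch_um` is carried
#'   over from the map.
#' @export
attach_coordinates <- function(counts, map, correct = FALSE) {
  stopifnot_cols(counts, c("cell_id", "spatial_barcode", "umi_count"))
  if (anyDuplicated(map$barcode)) {
    stop("chip map contains duplicated barcodes; run dedup_chip_barcodes() first")
  }
  bc <- counts$spatial_barcode
  if (correct) {
    support <- tapply(counts$umi_count, counts$spatial_barcode, sum)
    wl_support <- support[map$barcode]
    wl_support[is.na(wl_support)] <- 0
    bc <- correct_barcodes(bc, map$barcode, wl_support)
  }
  idx <- match(bc, map$barcode)
  keep <- !is.na(idx)
  out <- data.frame(cell_id = counts$cell_id[keep],
                    spatial_barcode = bc[keep],
                    umi_count = counts$umi_count[keep],
                    x = map$x[idx[keep]],
                    y = map$y[idx[keep]],
                    stringsAsFactors = FALSE)
  # correction can merge rows onto the same whitelist barcode
  dt <- as.data.table(out)[, list(umi_count = sum(umi_count), x = x[1], y = y[1]),
                           by = c("cell_id", "spatial_barcode")]
  out <- as.data.frame(dt[, c("cell_id", "spatial_barcode", "umi_count", "x", "y"),
                          with = FALSE])
  attr(out, "n_dropped") <- sum(!keep)
  attr(out, "umi_dropped") <- sum(counts$umi_count[!keep])
  attr(out, "pixel_pitch_um") <- attr(map, "pixel_pitch_um") %||% PIXEL_PITCH_UM
  class(out) <- c("positioned_counts", "data.frame")
  out
}
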
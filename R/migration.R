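#' Infer directed district-to-district movements from shared clonotypes
#'
#' For each clonotype, its mean pseudotime is computed per district; for
#' each unordered district pair in which the clonotype occurs, one movement
#' is recorded from the earlier-mean district to the later-mean district
#' (a clonotype spanning three or more districts contributes one movement
#' per pair). Exactly tied means record no movement: the direction is
#' indeterminate. Directions are invariant to any monotone increasing
#' re-parameterization of pseudotime.
#'
#' @param records data.frame with columns `clonotype`, `district`,
#'   `pseudotime` (one row per cell).
#' @param districts optional full district vocabulary; defaults to the
#'   districts present.
#' @return a `migration_graph` list: `counts` (data.frame from, to, count
#'   over all ordered pairs, zeros included), `totals` (data.frame district,
#'   n_in, n_out), `n_movements`, `districts`.
#' @export
infer_movements <- function(records, districts = NULL) {
  stopifnot_cols(records, c("clonotype", "district", "pseudotime"))
  stopifnot(all(is.finite(records$pseudotime)))
  districts <- districts %||% sort(unique(records$district))
  grid <- expand.grid(from = districts, to = districts,
                      stringsAsFactors = FALSE)
  grid <- grid[grid$from != grid$to, ]
  key <- paste(grid$from, grid$to, sep = "->")
  counts <- setNames(integer(length(key)), key)
  dt <- as.data.table(records)
  means <- dt[, list(mean_pt = mean(pseudotime)), by = c("clonotype", "district")]
  for (cl in unique(means$clonotype)) {
    sub <- means[means$clonotype == cl, ]
    if (nrow(sub) < 2L) next
    prs <- combn_pairs(seq_len(nrow(sub)))
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1L]; j <- prs[r, 2L]
      if (sub$mean_pt[i] == sub$mean_pt[j]) next   # direction indeterminate
      from <- if (sub$mean_pt[i] < sub$mean_pt[j]) sub$district[i] else sub$district[j]
      to <- if (sub$mean_pt[i] < sub$mean_pt[j]) sub$district[j] else sub$district[i]
      k <- paste(from, to, sep = "->")
      counts[k] <- counts[k] + 1L
    }
  }
  cdf <- data.frame(from = grid$from, to = grid$to, count = as.integer(counts),
                    stringsAsFactors = FALSE)
  totals <- data.frame(
    district = districts,
    n_in = vapply(districts, function(d) sum(cdf$count[cdf$to == d]), 0L),
    n_out = vapply(districts, function(d) sum(cdf$count[cdf$from == d]), 0L),
    stringsAsFactors = FALSE)
  structure(list(counts = cdf, totals = totals,
                 n_movements = sum(cdf$count), districts = districts),
            class = "migration_graph")
}

#' @export
print.migration_graph <- function(x, ...) {
  cat(sprintf("migration graph: %d movement(s) over %d districts\n",
              x$n_movements, length(x$districts)))
  nz <- x$counts[x$counts$count > 0, ]
  if (nrow(nz)) {
    for (i in order(-nz$count)) {
      cat(sprintf("  %s -> %s : %d\n", nz$from[i], nz$to[i], nz$count[i]))
    }
  }
  invisible(x)
}

#' Chi-square survival function
#'
#' Upper-tail probability of the chi-square distribution, the p-value of a
#' goodness-of-fit statistic.
#'
#' @param chi2 statistic value (>= 0).
#' @param df degrees of freedom (>= 1).
#' @return upper-tail probability.
#' @export
chisq_sf <- function(chi2, df) {
  stopifnot(chi2 >= 0, df >= 1)
  pchisq(chi2, df, lower.tail = FALSE)
}

#' Chi-square test of migration counts against a uniform expectation
#'
#' Tests whether movements are spread uniformly over the
#' `n_districts * (n_districts - 1)` ordered district pairs (zeros
#' included): expected count = total / number of categories,
#' `chi2 = sum (O - E)^2 / E`, df = number of categories - 1. With 5
#' districts there are 20 ordered transition categories and df = 19.
#'
#' @param graph a [infer_movements()] result (or a data.frame from, to,
#'   count).
#' @param n_districts number of districts; defaults to the graph's.
#' @param expected optional user-supplied expected counts per ordered pair
#'   (same order as `graph$counts`); defaults to uniform.
#' @return list with `chi2`, `df`, `p_value`, `n_categories`.
#' @export
chisq_uniform <- function(graph, n_districts = NULL, expected = NULL) {
  cdf <- if (inherits(graph, "migration_graph")) graph$counts else graph
  n_districts <- n_districts %||%
    length(unique(c(cdf$from, cdf$to)))
  n_cat <- n_districts * (n_districts - 1L)
  obs <- cdf$count
  if (length(obs) != n_cat) {
    stop("expected counts over ", n_cat, " ordered district pairs, got ",
         length(obs))
  }
  total <- sum(obs)
  if (total == 0) stop("no movements: chi-square test undefined")
  e <- expected %||% rep(total / n_cat, n_cat)
  chi2 <- sum((obs - e)^2 / e)
  df <- n_cat - 1L
  list(chi2 = chi2, df = df, p_value = chisq_sf(chi2, df), n_categories = n_cat)
}

#' Isotype ratio per group
#'
#' Count ratio of `IGHG1`-positive to `IGHA1`-positive plasma cells within
#' each group (e.g. district). A zero denominator yields `NA` with the
#' counts still reported.
#'
#' @param cells data.frame with an `isotype` column.
#' @param group name of the grouping column, or a vector of group labels.
#' @param numerator,denominator isotype labels.
#' @return data.frame: group, n_numerator, n_denominator, ratio.
#' @export
isotype_ratio <- function(cells, group, numerator = "IGHG1",
                          denominator = "IGHA1") {
  stopifnot_cols(cells, "isotype")
  g <- if (length(group) == 1L && is.character(group) && group %in% names(cells)) {
    cells[[group]]
  } else group
  groups <- sort(unique(g))
  n_num <- vapply(groups, function(gr) sum(g == gr & cells$isotype == numerator), 0L)
  n_den <- vapply(groups, function(gr) sum(g == gr & cells$isotype == denominator), 0L)
  data.frame(group = groups, n_numerator = n_num, n_denominator = n_den,
             ratio = ifelse(n_den == 0, NA_real_, n_num / n_den),
             stringsAsFactors = FALSE)
}

#' Isotype ratios along a migration route, banded by boundary distance
#'
#' For each consecutive transition in `route`, cells of the current district
#' are banded by their distance to the nearest cell of the next district
#' (band "0" is distance within `tol_um`; further bands are the half-open
#' intervals between consecutive `bands_um` values), and the isotype ratio
#' is computed per band. Empty bands report `NA`.
#'
#' @param cells data.frame with `x`, `y` (um), `district`, `isotype`.
#' @param route ordered character vector of district labels.
#' @param bands_um increasing numeric band edges, starting at 0.
#' @param tol_um tolerance defining the discrete "0" band.
#' @param numerator,denominator isotype labels.
#' @return data.frame: transition, band, n_numerator, n_denominator, ratio.
#' @export
ratio_along_route <- function(cells, route, bands_um = c(0, 50, 100, 150),
                              tol_um = 1, numerator = "IGHG1",
                              denominator = "IGHA1") {
  stopifnot_cols(cells, c("x", "y", "district", "isotype"))
  missing_d <- setdiff(route, unique(cells$district))
  if (length(missing_d)) {
    stop("route district(s) absent: ", paste(missing_d, collapse = ", "))
  }
  band_labels <- c("0", paste0(head(bands_um, -1), "-", bands_um[-1]))
  out <- list()
  for (s in seq_len(length(route) - 1L)) {
    cur <- cells[cells$district == route[s], , drop = FALSE]
    nxt <- cells[cells$district == route[s + 1L], , drop = FALSE]
    dmin <- vapply(seq_len(nrow(cur)), function(i) {
      sqrt(min((nxt$x - cur$x[i])^2 + (nxt$y - cur$y[i])^2))
    }, 0)
    band <- rep(NA_character_, nrow(cur))
    band[dmin <= tol_um] <- "0"
    for (bi in seq_len(length(bands_um) - 1L)) {
      sel <- is.na(band) & dmin > bands_um[bi] & dmin <= bands_um[bi + 1L]
      band[sel] <- band_labels[bi + 1L]
    }
    transition <- paste(route[s], route[s + 1L], sep = "->")
    for (bl in band_labels) {
      sub <- cur[!is.na(band) & band == bl, , drop = FALSE]
      n_num <- sum(sub$isotype == numerator)
      n_den <- sum(sub$isotype == denominator)
      out[[length(out) + 1L]] <- data.frame(
        transition = transition, band = bl,
        n_numerator = n_num, n_denominator = n_den,
        ratio = if (nrow(sub) == 0L || n_den == 0L) NA_real_ else n_num / n_den,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
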
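#' Specification of a synthetic barcode chip
#'
#' Defaults reproduce the fabricated chip geometry: oligo clusters on a
#' jittered grid at a 6.2 px pitch (1.64 um at 0.265 um/px), 32-mer random
#' barcodes, and a 0.03\% barcode duplication rate.
#'
#' @param width_px,height_px chip extent in pixels.
#' @param pitch_px cluster spacing in pixels (> 0).
#' @param barcode_length barcode length in nucleotides.
#' @param duplication_rate probability in [0, 1) that a barcode occupies two
#'   distinct cluster positions.
#' @param jitter_frac uniform grid jitter as a fraction of the pitch.
#' @param seed integer RNG seed.
#' @return a `chip_spec` list.
#' @export
chip_spec <- function(width_px = 600, height_px = 600, pitch_px = 6.2,
                      barcode_length = 32, duplication_rate = 3e-4,
                      jitter_frac = 0.25, seed = 1L) {
  stopifnot(pitch_px > 0, duplication_rate >= 0, duplication_rate < 1,
            barcode_length >= 1, width_px > 0, height_px > 0)
  structure(list(width_px = width_px, height_px = height_px,
                 pitch_px = pitch_px, barcode_length = barcode_length,
                 duplication_rate = duplication_rate,
                 jitter_frac = jitter_frac, seed = as.integer(seed)),
            class = "chip_spec")
}

#' Generate a synthetic barcode chip
#'
#' Cluster centroids sit on a square grid at `pitch_px` with uniform jitter;
#' a `duplication_rate` fraction of barcodes is assigned to two distinct
#' coordinates (the duplication failure mode the whitelist dedup must
#' handle). Deterministic under the spec seed.
#'
#' @param spec a [chip_spec()].
#' @return a [chip_map()] whose attribute `n_duplicated` records how many
#'   barcodes were planted at two positions.
#' @export
make_chip <- function(spec) {
  stopifnot(inherits(spec, "chip_spec"))
  set.seed(spec$seed)
  gx <- seq(spec$pitch_px / 2, spec$width_px - spec$pitch_px / 2, by = spec$pitch_px)
  gy <- seq(spec$pitch_px / 2, spec$height_px - spec$pitch_px / 2, by = spec$pitch_px)
  centers <- expand.grid(x = gx, y = gy)
  n <- nrow(centers)
  if (n < 1L) stop("chip extent too small for the requested pitch")
  jit <- spec$jitter_frac * spec$pitch_px
  x <- pmin(pmax(centers$x + runif(n, -jit, jit), 0), spec$width_px)
  y <- pmin(pmax(centers$y + runif(n, -jit, jit), 0), spec$height_px)
  n_dup <- rbinom(1L, n, spec$duplication_rate)
  n_dup <- as.integer(min(n_dup, n %/% 2L))
  n_bc <- n - n_dup
  barcodes <- random_barcodes(n_bc, spec$barcode_length)  # errors if 4^L < n_bc
  # the first n_dup barcodes each occupy two cluster positions
  assign_bc <- c(barcodes, barcodes[seq_len(n_dup)])
  assign_bc <- assign_bc[sample.int(n)]
  out <- chip_map(assign_bc, x, y,
                  bounds = c(xmin = 0, xmax = spec$width_px,
                             ymin = 0, ymax = spec$height_px))
  attr(out, "n_duplicated") <- n_dup
  out
}

#' Specification of a synthetic tissue on a chip
#'
#' Emulates the capture process: nuclei scattered inside labelled niche
#' regions, isotropic Gaussian diffusion of cleaved barcodes around each
#' nucleus, negative-binomial UMI yield, droplet co-encapsulation, debris,
#' and 8-way multiplex splitting.
#'
#' @param n_nuclei number of nuclei.
#' @param niches list of regions, each a list with `label`, `shape`
#'   ("disc" or "rect"), geometry in um (`cx`, `cy`, `r` for discs;
#'   `xmin`, `xmax`, `ymin`, `ymax` for rects) and `props`, a named vector of
#'   cell-type mixing proportions summing to 1.
#' @param diffusion_sigma_um isotropic diffusion scale (um) of the barcode
#'   cloud around each nucleus.
#' @param umi_mean,umi_dispersion negative-binomial parameters of the
#'   spatial-barcode UMI yield per nucleus (size = `umi_dispersion`).
#' @param debris_rate expected debris items per nucleus.
#' @param co_droplet_rate probability that a nucleus pair shares a droplet.
#' @param n_multiplex number of multiplex tubes (1, 2, 4 or 8).
#' @param seed integer RNG seed.
#' @return a `tissue_spec` list.
#' @export
tissue_spec <- function(n_nuclei = 500,
                        niches = default_niches(),
                        diffusion_sigma_um = 2,
                        umi_mean = 30, umi_dispersion = 4,
                        debris_rate = 0.02,
                        co_droplet_rate = 0,
                        n_multiplex = 8,
                        seed = 1L) {
  stopifnot(diffusion_sigma_um > 0, n_nuclei >= 1,
            n_multiplex %in% c(1L, 2L, 4L, 8L),
            co_droplet_rate >= 0, co_droplet_rate < 1)
  for (nf in niches) {
    if (abs(sum(nf$props) - 1) > 1e-8) {
      stop("mixing proportions of niche '", nf$label, "' must sum to 1")
    }
  }
  structure(list(n_nuclei = n_nuclei, niches = niches,
                 diffusion_sigma_um = diffusion_sigma_um,
                 umi_mean = umi_mean, umi_dispersion = umi_dispersion,
                 debris_rate = debris_rate, co_droplet_rate = co_droplet_rate,
                 n_multiplex = as.integer(n_multiplex), seed = as.integer(seed)),
            class = "tissue_spec")
}

#' Default two-niche layout used in examples
#'
#' Two rectangular niches with complementary cell-type mixes on a
#' 150 x 150 um tissue.
#' @return list of niche definitions for [tissue_spec()].
#' @export
default_niches <- function() {
  list(
    list(label = "N1", shape = "rect", xmin = 5, xmax = 75, ymin = 5, ymax = 145,
         props = c(TypeA = 0.7, TypeB = 0.2, TypeC = 0.1)),
    list(label = "N2", shape = "rect", xmin = 75, xmax = 145, ymin = 5, ymax = 145,
         props = c(TypeA = 0.1, TypeB = 0.2, TypeC = 0.7))
  )
}

#' Evenly spaced disc niches on a square tissue
#'
#' Helper for planted-niche benchmarks: `n` discs of radius `r_um` laid out
#' on a grid inside a `side_um` square, each with its own dominant cell
#' type (`purity` for the focal type, remainder spread over the others).
#'
#' @param n number of niches.
#' @param side_um tissue side length (um).
#' @param r_um disc radius (um).
#' @param purity proportion of the niche's focal cell type.
#' @return list of niche definitions for [tissue_spec()].
#' @export
disc_niches <- function(n = 5, side_um = 400, r_um = 55, purity = 0.85) {
  ncol_ <- ceiling(sqrt(n))
  nrow_ <- ceiling(n / ncol_)
  cx <- seq(side_um / (2 * ncol_), side_um - side_um / (2 * ncol_), length.out = ncol_)
  cy <- seq(side_um / (2 * nrow_), side_um - side_um / (2 * nrow_), length.out = nrow_)
  grid <- expand.grid(cx = cx, cy = cy)[seq_len(n), ]
  types <- paste0("Type", LETTERS[seq_len(n)])
  lapply(seq_len(n), function(i) {
    props <- setNames(rep((1 - purity) / (n - 1), n), types)
    props[types[i]] <- purity
    list(label = paste0("N", i), shape = "disc",
         cx = grid$cx[i], cy = grid$cy[i], r = r_um, props = props)
  })
}

niche_area <- function(nf) {
  if (nf$shape == "disc") pi * nf$r^2
  else (nf$xmax - nf$xmin) * (nf$ymax - nf$ymin)
}

sample_in_niche <- function(nf, n) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  if (nf$shape == "disc") {
    r <- nf$r * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cbind(x = nf$cx + r * cos(th), y = nf$cy + r * sin(th))
  } else {
    cbind(x = runif(n, nf$xmin, nf$xmax), y = runif(n, nf$ymin, nf$ymax))
  }
}

#' Simulate barcode capture of nuclei on a chip
#'
#' Each nucleus yields a negative-binomial number of barcode UMIs; every UMI
#' lands at a Gaussian displacement (scale `diffusion_sigma_um`) from the
#' nucleus and is captured by the nearest chip cluster, so clusters are hit
#' with probability proportional to the isotropic diffusion kernel. Nuclei
#' are split over multiplex tubes; colliding nuclei (probability
#' `co_droplet_rate`) share a droplet id, and debris contributes small
#' barcode sets at random positions inside existing droplets. The emitted
#' `cell_id` is `tube-droplet`.
#'
#' @param chip a [chip_map()] (deduplicated or not).
#' @param tissue a [tissue_spec()]; all niche regions must fit on the chip.
#' @return list with `counts` (a [barcode_counts()] table), `truth`
#'   (data.frame: nucleus_id, cell_id, x_um, y_um, cell_type, niche, tube,
#'   droplet) and `n_capture_events` (total simulated UMIs).
#' @export
simulate_capture <- function(chip, tissue) {
  stopifnot(inherits(tissue, "tissue_spec"))
  if (nrow(chip) == 0L) stop("empty chip")
  pitch_um <- attr(chip, "pixel_pitch_um") %||% PIXEL_PITCH_UM
  bounds <- attr(chip, "bounds")
  chip_w_um <- px_to_um(bounds["xmax"] - bounds["xmin"], pitch_um)
  chip_h_um <- px_to_um(bounds["ymax"] - bounds["ymin"], pitch_um)
  for (nf in tissue$niches) {
    ext <- if (nf$shape == "disc") {
      c(nf$cx - nf$r, nf$cx + nf$r, nf$cy - nf$r, nf$cy + nf$r)
    } else c(nf$xmin, nf$xmax, nf$ymin, nf$ymax)
    if (ext[1] < 0 || ext[2] > chip_w_um || ext[3] < 0 || ext[4] > chip_h_um) {
      stop("niche '", nf$label, "' extends beyond the chip extent")
    }
  }
  set.seed(tissue$seed)
  n <- tissue$n_nuclei
  areas <- vapply(tissue$niches, niche_area, 0)
  niche_of <- sample(seq_along(tissue$niches), n, replace = TRUE,
                     prob = areas / sum(areas))
  xy <- matrix(0, n, 2)
  type <- character(n)
  for (i in seq_along(tissue$niches)) {
    sel <- which(niche_of == i)
    xy[sel, ] <- sample_in_niche(tissue$niches[[i]], length(sel))
    type[sel] <- sample(names(tissue$niches[[i]]$props), length(sel),
                        replace = TRUE, prob = tissue$niches[[i]]$props)
  }
  tube <- sample.int(tissue$n_multiplex, n, replace = TRUE)
  droplet <- seq_len(n)
  # droplet collisions: disjoint nucleus pairs share one droplet id
  n_pairs <- rbinom(1L, floor(n / 2), tissue$co_droplet_rate)
  if (n_pairs > 0L) {
    pick <- sample.int(n, 2L * n_pairs)
    a <- pick[seq_len(n_pairs)]
    b <- pick[n_pairs + seq_len(n_pairs)]
    droplet[b] <- droplet[a]
  }
  umis <- pmax(2L, rnbinom(n, size = tissue$umi_dispersion, mu = tissue$umi_mean))
  # debris: small barcode clouds at random tissue positions, co-encapsulated
  # into an existing droplet with their own tube draw
  n_debris <- rbinom(1L, n, min(tissue$debris_rate, 1))
  if (n_debris > 0L) {
    dx <- runif(n_debris, 0, chip_w_um)
    dy <- runif(n_debris, 0, chip_h_um)
    d_tube <- sample.int(tissue$n_multiplex, n_debris, replace = TRUE)
    d_drop <- droplet[sample.int(n, n_debris, replace = TRUE)]
    d_umis <- 2L + rpois(n_debris, 3)
  }
  src_x <- c(xy[, 1], if (n_debris > 0L) dx)
  src_y <- c(xy[, 2], if (n_debris > 0L) dy)
  src_tube <- c(tube, if (n_debris > 0L) d_tube)
  src_drop <- c(droplet, if (n_debris > 0L) d_drop)
  src_umis <- c(umis, if (n_debris > 0L) d_umis)
  n_src <- length(src_x)

  total <- sum(src_umis)
  src_of <- rep.int(seq_len(n_src), src_umis)
  px <- um_to_px(src_x[src_of] + rnorm(total, 0, tissue$diffusion_sigma_um), pitch_um)
  py <- um_to_px(src_y[src_of] + rnorm(total, 0, tissue$diffusion_sigma_um), pitch_um)
  hit <- nearest_cluster(chip$x, chip$y, px, py)
  counts <- barcode_counts(
    cell_id = paste(src_tube[src_of], src_drop[src_of], sep = "-"),
    spatial_barcode = chip$barcode[hit],
    umi_count = rep(1L, total))
  truth <- data.frame(
    nucleus_id = seq_len(n),
    cell_id = paste(tube, droplet, sep = "-"),
    x_um = xy[, 1], y_um = xy[, 2],
    cell_type = type,
    niche = vapply(tissue$niches, `[[`, "", "label")[niche_of],
    tube = tube, droplet = droplet,
    stringsAsFactors = FALSE)
  list(counts = counts, truth = truth, n_capture_events = total)
}

# nearest chip cluster per query point, via a grid-bucket index over clusters;
# exact: expands the bucket search ring until no closer point can exist
nearest_cluster <- function(cx, cy, qx, qy) {
  nq <- length(qx)
  if (length(cx) <= 2000L || nq <= 50L) {
    return(vapply(seq_len(nq), function(i) {
      which.min((cx - qx[i])^2 + (cy - qy[i])^2)
    }, integer(1)))
  }
  cs <- max((max(cx) - min(cx)) / sqrt(length(cx)) * 2, 1e-6)
  buckets <- split(seq_along(cx), paste(floor(cx / cs), floor(cy / cs)))
  out <- integer(nq)
  for (i in seq_len(nq)) {
    gx <- floor(qx[i] / cs)
    gy <- floor(qy[i] / cs)
    bestd2 <- Inf
    best <- NA_integer_
    ring <- 0L
    repeat {
      if (ring == 0L) {
        keys <- paste(gx, gy)
      } else {
        side <- (gx - ring):(gx + ring)
        keys <- c(paste(side, gy - ring), paste(side, gy + ring),
                  paste(gx - ring, (gy - ring + 1L):(gy + ring - 1L)),
                  paste(gx + ring, (gy - ring + 1L):(gy + ring - 1L)))
      }
      cand <- unlist(buckets[keys], use.names = FALSE)
      if (length(cand)) {
        d2 <- (cx[cand] - qx[i])^2 + (cy[cand] - qy[i])^2
        j <- which.min(d2)
        if (d2[j] < bestd2) { bestd2 <- d2[j]; best <- cand[j] }
      }
      # points in rings beyond `ring` are at least ring*cs away
      if (!is.na(best) && sqrt(bestd2) <= ring * cs) break
      ring <- ring + 1L
      if (ring * cs > 2 * (max(cx) - min(cx) + max(cy) - min(cy)) + 10 * cs) {
        best <- which.min((cx - qx[i])^2 + (cy - qy[i])^2)
        break
      }
    }
    out[i] <- best
  }
  out
}

#' Simulate a cell-type-structured expression matrix
#'
#' Negative-binomial counts with `markers_per_type` marker genes per cell
#' type elevated `fold`-fold in their own type, plus unstructured background
#' genes. Cells follow the ground-truth table of [simulate_capture()].
#'
#' @param truth ground-truth data.frame with `cell_id` and `cell_type`.
#' @param markers_per_type marker genes per cell type.
#' @param n_background unstructured background genes.
#' @param fold marker elevation fold (1 = no differential structure).
#' @param base_mean baseline NB mean per gene.
#' @param dispersion NB size parameter.
#' @param seed integer RNG seed.
#' @return sparse gene x cell `Matrix::dgCMatrix`; marker genes are named
#'   `<type>_marker_<i>`.
#' @export
simulate_expression <- function(truth, markers_per_type = 5, n_background = 50,
                                fold = 4, base_mean = 1, dispersion = 2,
                                seed = 1L) {
  set.seed(seed)
  types <- unique(truth$cell_type)
  genes <- c(unlist(lapply(types, function(tp) {
    paste0(tp, "_marker_", seq_len(markers_per_type))
  })), if (n_background > 0) paste0("bg_", seq_len(n_background)))
  n_genes <- length(genes)
  n_cells <- nrow(truth)
  mu <- matrix(base_mean, n_genes, n_cells)
  for (ti in seq_along(types)) {
    rows <- (ti - 1L) * markers_per_type + seq_len(markers_per_type)
    mu[rows, truth$cell_type == types[ti]] <- base_mean * fold
  }
  counts <- matrix(rnbinom(n_genes * n_cells, size = dispersion, mu = mu),
                   n_genes, n_cells,
                   dimnames = list(genes, truth$cell_id))
  Matrix::Matrix(counts, sparse = TRUE)
}

#' Simulate clonotypes migrating along a district route
#'
#' Each clonotype occupies cells in consecutive districts along `route`;
#' pseudotime increases by `drift` per route step plus Gaussian noise, so a
#' positive drift plants the route direction and `drift = 0` leaves the
#' direction undetermined.
#'
#' @param truth ground-truth data.frame with `cell_id` and a district column.
#' @param route character vector of district labels in migration order.
#' @param n_clonotypes number of clonotypes to plant.
#' @param cells_per_district cells per clonotype in each visited district.
#' @param drift pseudotime increment per route step.
#' @param noise_sd pseudotime noise standard deviation.
#' @param district_col name of the district column in `truth`.
#' @param isotype_probs optional named per-district probability of the
#'   IGHG1 isotype (else IGHA1); `NULL` skips isotype labels.
#' @param seed integer RNG seed.
#' @return data.frame: cell_id, clonotype, district, pseudotime
#'   (and isotype when requested).
#' @export
simulate_clonotypes <- function(truth, route, n_clonotypes = 20,
                                cells_per_district = 2, drift = 1,
                                noise_sd = 0.1, district_col = "niche",
                                isotype_probs = NULL, seed = 1L) {
  set.seed(seed)
  stopifnot_cols(truth, c("cell_id", district_col))
  missing_d <- setdiff(route, unique(truth[[district_col]]))
  if (length(missing_d)) {
    stop("route district(s) absent from truth: ", paste(missing_d, collapse = ", "))
  }
  rows <- list()
  for (cl in seq_len(n_clonotypes)) {
    for (step in seq_along(route)) {
      pool <- truth$cell_id[truth[[district_col]] == route[step]]
      ids <- sample(pool, min(cells_per_district, length(pool)))
      rows[[length(rows) + 1L]] <- data.frame(
        cell_id = ids,
        clonotype = sprintf("CT%03d", cl),
        district = route[step],
        pseudotime = (step - 1) * drift + rnorm(length(ids), 0, noise_sd),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (!is.null(isotype_probs)) {
    p <- isotype_probs[out$district]
    out$isotype <- ifelse(runif(nrow(out)) < p, "IGHG1", "IGHA1")
  }
  rownames(out) <- NULL
  out
}
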
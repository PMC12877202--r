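# fixtures built in code; no data files

# tiny chip with known coordinates for hand-checkable examples
toy_chip <- function(barcodes, x = seq_along(barcodes), y = rep(0, length(barcodes))) {
  chip_map(barcodes, x, y)
}

# positioned count table straight from vectors
toy_positioned <- function(cell_id, x, y, umi = 1L,
                           barcode = sprintf("BC%04d", seq_along(x))) {
  out <- data.frame(cell_id = cell_id, spatial_barcode = barcode,
                    umi_count = as.integer(rep_len(umi, length(x))),
                    x = x, y = y, stringsAsFactors = FALSE)
  attr(out, "pixel_pitch_um") <- PIXEL_PITCH_UM
  class(out) <- c("positioned_counts", "data.frame")
  out
}

# uniform random cell table over a rectangle with random type labels (CSR)
csr_cells <- function(n, types = c("A", "B"), side = 300, probs = NULL,
                      seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  data.frame(cell_id = paste0("c", seq_len(n)),
             x = runif(n, 0, side), y = runif(n, 0, side),
             cell_type = sample(types, n, replace = TRUE,
                                prob = probs %||% rep(1, length(types))),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# simulated tissue on a chip: returns positioned, filtered counts plus truth
simulated_dataset <- function(n_nuclei = 100, seed = 1, chip_px = 900,
                              co_droplet_rate = 0, diffusion_sigma_um = 2,
                              umi_mean = 30, debris_rate = 0.02,
                              niches = NULL, correct = FALSE) {
  side_um <- px_to_um(chip_px) - 10
  niches <- niches %||% list(list(
    label = "N1", shape = "rect", xmin = 5, xmax = side_um,
    ymin = 5, ymax = side_um, props = c(TypeA = 0.5, TypeB = 0.5)))
  chip <- make_chip(chip_spec(width_px = chip_px, height_px = chip_px,
                              seed = seed))
  tis <- tissue_spec(n_nuclei = n_nuclei, niches = niches,
                     diffusion_sigma_um = diffusion_sigma_um,
                     umi_mean = umi_mean, debris_rate = debris_rate,
                     co_droplet_rate = co_droplet_rate, seed = seed + 1)
  cap <- simulate_capture(chip, tis)
  dd <- dedup_chip_barcodes(chip)
  pos <- attach_coordinates(cap$counts, dd$map, correct = correct)
  list(chip = chip, truth = cap$truth, positioned = pos,
       n_capture_events = cap$n_capture_events)
}

# brute-force weighted-geometric-median restricted to candidate points
brute_force_position <- function(rows, candidates = NULL) {
  if (is.null(candidates)) candidates <- unique(cbind(rows$x, rows$y))
  costs <- numeric(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    s <- 0
    for (r in seq_len(nrow(rows))) {
      s <- s + rows$umi_count[r] *
        sqrt((rows$x[r] - candidates[i, 1])^2 + (rows$y[r] - candidates[i, 2])^2)
    }
    costs[i] <- s
  }
  best <- which(costs == min(costs))
  if (length(best) > 1L) {
    best <- best[order(candidates[best, 1], candidates[best, 2])[1]]
  }
  c(x = candidates[best, 1], y = candidates[best, 2])
}
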
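test_that("make_chip honours the duplication rate and is deterministic", {
  # zero rate: all barcodes unique
  cm0 <- make_chip(chip_spec(width_px = 120, height_px = 120,
                             duplication_rate = 0, seed = 5))
  expect_equal(anyDuplicated(cm0$barcode), 0L)
  expect_identical(attr(cm0, "n_duplicated"), 0L)

  # same spec, same seed: byte-identical output
  spec <- chip_spec(width_px = 200, height_px = 200, seed = 42)
  expect_identical(make_chip(spec), make_chip(spec))

  # ~10,000 clusters at rate 0.01: duplicated-barcode count within 3 binomial SDs
  spec2 <- chip_spec(width_px = 620, height_px = 620, pitch_px = 6.2,
                     duplication_rate = 0.01, seed = 9)
  cm <- make_chip(spec2)
  n <- nrow(cm)
  n_dup <- sum(table(cm$barcode) == 2L)
  expect_equal(n_dup, attr(cm, "n_duplicated"))
  expect_lt(abs(n_dup - n * 0.01), 3 * sqrt(n * 0.01 * 0.99))
})

test_that("make_chip rejects a barcode space smaller than the cluster count", {
  # 4^2 = 16 barcodes cannot cover ~100 clusters
  expect_error(make_chip(chip_spec(width_px = 62, height_px = 62,
                                   barcode_length = 2, seed = 1)),
               "barcode space")
})

test_that("capture in the vanishing-diffusion limit hits the nearest cluster", {
  chip <- make_chip(chip_spec(width_px = 100, height_px = 100, seed = 2))
  tis <- tissue_spec(
    n_nuclei = 1,
    niches = list(list(label = "N", shape = "rect", xmin = 10, xmax = 11,
                       ymin = 10, ymax = 11, props = c(T1 = 1))),
    diffusion_sigma_um = 1e-9, umi_mean = 40, debris_rate = 0,
    co_droplet_rate = 0, seed = 3)
  cap <- simulate_capture(chip, tis)
  # all UMIs on a single barcode: the cluster nearest the nucleus
  expect_equal(nrow(cap$counts), 1L)
  nuc_px <- um_to_px(c(cap$truth$x_um, cap$truth$y_um))
  nearest <- which.min((chip$x - nuc_px[1])^2 + (chip$y - nuc_px[2])^2)
  expect_equal(cap$counts$spatial_barcode, chip$barcode[nearest])
})

test_that("capture conserves UMI mass and cell ids map to nuclei without collisions", {
  d <- simulated_dataset(n_nuclei = 40, seed = 11, debris_rate = 0)
  expect_equal(sum(d$positioned$umi_count) + attr(d$positioned, "umi_dropped"),
               d$n_capture_events)
  # co_droplet_rate = 0: every cell_id in the counts belongs to exactly one nucleus
  expect_equal(anyDuplicated(d$truth$cell_id), 0L)
  expect_true(all(unique(d$positioned$cell_id) %in% d$truth$cell_id))
})

test_that("barcode displacement follows the Rayleigh law of the diffusion kernel", {
  # fine-pitch chip so Voronoi snapping does not confound the kernel check
  sigma <- 2
  chip <- make_chip(chip_spec(width_px = 400, height_px = 400, pitch_px = 1.5,
                              barcode_length = 16, seed = 21))
  tis <- tissue_spec(
    n_nuclei = 40,
    niches = list(list(label = "N", shape = "rect", xmin = 30, xmax = 75,
                       ymin = 30, ymax = 75, props = c(T1 = 1))),
    diffusion_sigma_um = sigma, umi_mean = 260, debris_rate = 0,
    co_droplet_rate = 0, seed = 22)
  cap <- simulate_capture(chip, tis)
  pos <- attach_coordinates(cap$counts, dedup_chip_barcodes(chip)$map)
  idx <- match(pos$cell_id, cap$truth$cell_id)
  dists <- px_to_um(sqrt((pos$x - um_to_px(cap$truth$x_um[idx]))^2 +
                         (pos$y - um_to_px(cap$truth$y_um[idx]))^2))
  dists <- rep(dists, pos$umi_count)
  expect_gt(length(dists), 9000)
  # mean within 3 SE of the Rayleigh mean sigma * sqrt(pi/2)
  ray_mean <- sigma * sqrt(pi / 2)
  ray_sd <- sigma * sqrt(2 - pi / 2)
  expect_lt(abs(mean(dists) - ray_mean), 3 * ray_sd / sqrt(length(dists)))
  # full-distribution check at n = 10,000
  ks <- suppressWarnings(ks.test(dists, function(q) 1 - exp(-q^2 / (2 * sigma^2))))
  expect_gt(ks$p.value, 0.01)
})

test_that("simulate_expression plants marker structure at the stated fold", {
  truth <- data.frame(cell_id = paste0("c", 1:400),
                      cell_type = rep(c("A", "B"), each = 200))
  m <- simulate_expression(truth, markers_per_type = 4, n_background = 10,
                           fold = 4, base_mean = 2, dispersion = 5, seed = 3)
  expect_identical(m, simulate_expression(truth, markers_per_type = 4,
                                          n_background = 10, fold = 4,
                                          base_mean = 2, dispersion = 5,
                                          seed = 3))
  a_cells <- truth$cell_id[truth$cell_type == "A"]
  b_cells <- truth$cell_id[truth$cell_type == "B"]
  ratio <- mean(m["A_marker_1", a_cells]) / mean(m["A_marker_1", b_cells])
  expect_gt(ratio, 2.5)  # sampling noise around the planted fold of 4
  expect_lt(ratio, 6)
  # fold = 1: no differential structure
  m1 <- simulate_expression(truth, markers_per_type = 4, n_background = 0,
                            fold = 1, base_mean = 2, dispersion = 5, seed = 4)
  r1 <- mean(m1["A_marker_1", a_cells]) / mean(m1["A_marker_1", b_cells])
  expect_lt(abs(r1 - 1), 0.3)
})

test_that("simulate_clonotypes plants the route direction when drift is large", {
  truth <- data.frame(cell_id = paste0("c", 1:300),
                      niche = rep(c("D5", "D4", "D2"), each = 100))
  ct <- simulate_clonotypes(truth, route = c("D5", "D4", "D2"),
                            n_clonotypes = 15, drift = 5, noise_sd = 0.1,
                            seed = 6)
  expect_identical(ct, simulate_clonotypes(truth, route = c("D5", "D4", "D2"),
                                           n_clonotypes = 15, drift = 5,
                                           noise_sd = 0.1, seed = 6))
  mg <- infer_movements(ct)
  fwd <- c("D5->D4", "D5->D2", "D4->D2")
  key <- paste(mg$counts$from, mg$counts$to, sep = "->")
  expect_equal(sum(mg$counts$count[key %in% fwd]), mg$n_movements)
})
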
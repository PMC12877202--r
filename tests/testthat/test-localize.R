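test_that("binning conserves UMIs and flags under-supported cells", {
  rows <- toy_positioned("c1", x = c(10, 10, 160), y = c(10, 12, 10),
                         umi = c(3L, 2L, 1L))
  g <- bin_cell_umis(rows, bin_px = 100)
  expect_equal(sum(g$umi), sum(rows$umi_count))
  expect_equal(nrow(g), 2L)  # two points 150 px apart on one axis -> two bins
  one_point <- toy_positioned("c1", x = c(10, 11), y = c(10, 11), umi = 1L)
  expect_equal(nrow(bin_cell_umis(one_point, 100)), 1L)
  # fewer than 2 UMIs: unclassifiable
  expect_null(bin_cell_umis(toy_positioned("c1", 1, 1, 1L), 100))
})

test_that("center classification applies the 10/2 ratio rule on 5x5 cores", {
  # all UMIs inside one 5x5 block: infinite ratio, unique
  g1 <- data.frame(row = c(0, 1), col = c(0, 2), umi = c(5, 7))
  c1 <- classify_center(g1)
  expect_equal(c1$class, "unique")
  expect_equal(c1$ratio, Inf)

  # two far-apart equal blobs: ratio 1 -> multiple
  g2 <- data.frame(row = c(0, 20), col = c(0, 0), umi = c(100, 100))
  c2 <- classify_center(g2)
  expect_equal(c2$class, "multiple")
  expect_equal(c2$ratio, 1)

  # blobs 100 vs 10 far apart: ratio exactly 10 -> unique (boundary inclusive)
  g3 <- data.frame(row = c(0, 20), col = c(0, 0), umi = c(100, 10))
  c3 <- classify_center(g3)
  expect_equal(c3$ratio, 10)
  expect_equal(c3$class, "unique")
  # and 100 vs 11 falls to major
  g4 <- data.frame(row = c(0, 20), col = c(0, 0), umi = c(100, 11))
  expect_equal(classify_center(g4)$class, "major")

  # classification is invariant to uniform UMI scaling
  g5 <- data.frame(row = c(0, 9, 15), col = c(0, 2, 1), umi = c(60, 22, 8))
  c5a <- classify_center(g5)
  g5$umi <- g5$umi * 17
  c5b <- classify_center(g5)
  expect_equal(c5a$class, c5b$class)
  expect_equal(c5a$ratio, c5b$ratio)

  # core-center tie breaks to lexicographically smallest (row, col)
  g6 <- data.frame(row = c(5, 1), col = c(9, 2), umi = c(50, 50))
  expect_equal(classify_center(g6)$core_bin, c(1, 2))
})

test_that("assign_position matches exhaustive brute force and documented ties", {
  # single barcode: its own coordinate
  r1 <- toy_positioned("c", 7, 9, 5L)
  expect_equal(assign_position(r1), c(x = 7, y = 9))

  # two equal weights: lexicographically smaller endpoint
  r2 <- toy_positioned(c("c", "c"), x = c(4, 2), y = c(1, 3), umi = 1L)
  expect_equal(assign_position(r2), c(x = 2, y = 3))

  # 4 barcodes with weights (5,1,1,1): brute force gives the argmin
  r3 <- toy_positioned(rep("c", 4), x = c(0, 10, 10, 0), y = c(0, 0, 10, 10),
                       umi = c(5L, 1L, 1L, 1L))
  expect_equal(assign_position(r3), brute_force_position(r3))

  # random fuzz against the oracle
  set.seed(31)
  for (i in 1:20) {
    n <- sample(3:12, 1)
    r <- toy_positioned(rep("c", n), x = round(runif(n, 0, 50), 1),
                        y = round(runif(n, 0, 50), 1),
                        umi = sample(1:20, n, replace = TRUE))
    expect_equal(assign_position(r), brute_force_position(r))
  }
})

test_that("diffusion quantiles equal a direct sorted-distance computation", {
  r1 <- toy_positioned("c", 3, 4, 7L)
  expect_equal(unname(diffusion_quantiles(r1, c(3, 4))), c(0, 0, 0))

  # constructed 10-point set: quantiles from the UMI-expanded sorted distances
  set.seed(12)
  r <- toy_positioned(rep("c", 10), x = runif(10, 0, 100), y = runif(10, 0, 100),
                      umi = sample(1:5, 10, replace = TRUE))
  pos <- c(50, 50)
  dq <- diffusion_quantiles(r, pos)
  d_um <- px_to_um(sqrt((r$x - pos[1])^2 + (r$y - pos[2])^2))
  expanded <- sort(rep(d_um, r$umi_count))
  W <- length(expanded)
  oracle <- vapply(c(0.5, 0.75, 0.95), function(p) expanded[ceiling(p * W)], 0)
  expect_equal(unname(dq), oracle)
  expect_true(dq[["d50"]] <= dq[["d75"]] && dq[["d75"]] <= dq[["d95"]])
})

test_that("localize_all recovers single-nucleus droplets and flags merged ones", {
  d <- simulated_dataset(n_nuclei = 60, seed = 41, debris_rate = 0)
  loc <- localize_all(d$positioned)
  expect_equal(nrow(loc), length(unique(d$positioned$cell_id)))
  expect_gt(mean(loc$class == "unique"), 0.9)
  expect_identical(loc, localize_all(d$positioned))  # deterministic
  assigned <- loc[!is.na(loc$x_um), ]
  expect_true(all(assigned$class %in% c("unique", "major")))

  # two far-apart blobs merged under one cell_id: multiple centers
  blob <- function(cx, cy) toy_positioned(rep("m", 8), x = cx + (0:7) %% 3,
                                          y = cy + (0:7) %/% 3, umi = 3L,
                                          barcode = sprintf("B%s%02d", cx, 0:7))
  merged <- rbind(blob(10, 10), blob(900, 900))
  class(merged) <- c("positioned_counts", "data.frame")
  locm <- localize_all(merged)
  expect_equal(locm$class, "multiple")
})

test_that("tissue mask drops nuclei assigned outside the polygon", {
  pos <- rbind(toy_positioned(c("in", "in"), x = c(10, 11), y = c(10, 11),
                              umi = 2L, barcode = c("AAAA", "AAAC")),
               toy_positioned(c("out", "out"), x = c(900, 901), y = c(900, 901),
                              umi = 2L, barcode = c("GGGG", "GGGT")))
  class(pos) <- c("positioned_counts", "data.frame")
  mask <- list(x = c(0, 50, 50, 0), y = c(0, 0, 50, 50))  # um
  loc <- localize_all(pos, mask = mask)
  expect_equal(loc$cell_id, "in")
})

test_that("demux recovery collapses tubes and recovers split collisions", {
  # two co-droplet nuclei in tubes 1 and 2, far apart
  blob <- function(id, cx, cy, tag) {
    toy_positioned(rep(id, 6), x = cx + (0:5) %% 3, y = cy + (0:5) %/% 3,
                   umi = 4L, barcode = sprintf("B%s%02d", tag, 0:5))
  }
  pos <- rbind(blob("1-7", 20, 20, "A"), blob("2-7", 1500, 1500, "C"))
  class(pos) <- c("positioned_counts", "data.frame")
  rec <- demux_recovery(pos, ks = c(1L, 8L))
  expect_equal(unname(rec["k8"]), 2L)   # identity collapse keeps both
  expect_equal(unname(rec["k1"]), 0L)   # merged cell has multiple centers
  expect_error(demux_recovery(pos, ks = 3L), "divide")

  # k = 8 equals the baseline localization count on simulated data
  d <- simulated_dataset(n_nuclei = 50, seed = 51, co_droplet_rate = 0.1)
  base <- sum(localize_all(d$positioned)$class %in% c("unique", "major"))
  rec2 <- demux_recovery(d$positioned, ks = c(1L, 2L, 4L, 8L))
  expect_equal(unname(rec2["k8"]), base)
  expect_true(all(diff(rec2) >= 0))     # non-decreasing in k
})
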
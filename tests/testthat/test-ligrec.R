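# small sender/receiver geometry shared by several blocks
lr_geometry <- function(n_s = 40, n_r = 40, side = 150, seed = 19) {
  set.seed(seed)
  cells <- data.frame(
    cell_id = c(paste0("s", 1:n_s), paste0("r", 1:n_r)),
    x = runif(n_s + n_r, 0, side), y = runif(n_s + n_r, 0, side),
    cell_type = rep(c("S", "R"), c(n_s, n_r)),
    stringsAsFactors = FALSE)
  cells
}

test_that("candidate filtering applies the 10-cell / 10 percent rule", {
  cells <- lr_geometry(20, 30)
  expr <- matrix(0, 2, 50, dimnames = list(c("L1", "R1"), cells$cell_id))
  pairs <- data.frame(ligand = "L1", receptor = "R1",
                      sender = "S", receiver = "R")
  types <- setNames(cells$cell_type, cells$cell_id)

  # ligand in 10 senders, receptor in 1 receiver: kept by the >= 10 branch
  e1 <- expr
  e1["L1", paste0("s", 1:10)] <- 1
  e1["R1", "r1"] <- 1
  expect_equal(nrow(candidate_interactions(e1, types, pairs)), 1L)

  # ligand in 3 of 20 senders (15%) but receptor in 2 of 30 (6.7%): dropped
  e2 <- expr
  e2["L1", paste0("s", 1:3)] <- 1
  e2["R1", paste0("r", 1:2)] <- 1
  expect_equal(nrow(candidate_interactions(e2, types, pairs)), 0L)

  # 15% senders and 10% receivers: kept by the fraction branch
  e3 <- e2
  e3["R1", paste0("r", 1:3)] <- 1
  expect_equal(nrow(candidate_interactions(e3, types, pairs)), 1L)

  expect_equal(nrow(candidate_interactions(expr, types, pairs)), 0L)
})

test_that("weight matrix equals brute-force distance thresholding", {
  snd <- data.frame(x = c(0, 50, 200), y = c(0, 0, 0))
  rcv <- data.frame(x = c(0, 120), y = c(0, 0))
  W <- build_weight_matrix(snd, rcv, radius_um = 100)
  # distances: (0,120), (50,70), (200,80) against the 100 um radius
  expect_equal(as.matrix(W),
               matrix(c(1, 0, 1, 1, 0, 1), 3, 2, byrow = TRUE),
               ignore_attr = TRUE)
  # coincident points are linked; all pairs beyond the radius give a zero matrix
  expect_equal(as.numeric(build_weight_matrix(data.frame(x = 1, y = 1),
                                              data.frame(x = 1, y = 1), 100)), 1)
  far <- build_weight_matrix(data.frame(x = 0, y = 0),
                             data.frame(x = 500, y = 0), 100)
  expect_equal(sum(far), 0)

  set.seed(3)
  s2 <- data.frame(x = runif(25, 0, 300), y = runif(25, 0, 300))
  r2 <- data.frame(x = runif(35, 0, 300), y = runif(35, 0, 300))
  W2 <- build_weight_matrix(s2, r2, 100)
  d <- outer(seq_len(25), seq_len(35), function(i, j) {
    sqrt((s2$x[i] - r2$x[j])^2 + (s2$y[i] - r2$y[j])^2)
  })
  expect_equal(as.matrix(W2), (d <= 100) * 1, ignore_attr = TRUE)
})

test_that("SCI matches hand computation and standardization properties", {
  # 2 senders, 2 receivers; only s1-r1 adjacent
  W <- Matrix::Matrix(matrix(c(1, 0, 0, 0), 2, 2), sparse = TRUE)
  lig <- c(3, 1); rec <- c(5, 2)
  lz <- (lig - mean(lig)) / sd(lig)
  rz <- (rec - mean(rec)) / sd(rec)
  expect_equal(sci(lig, rec, W), lz[1] * rz[1])
  # affine rescaling of raw expression leaves SCI unchanged
  expect_equal(sci(10 + 4 * lig, -2 + 0.5 * rec, W), sci(lig, rec, W))
  # zero total weight -> flagged undefined
  expect_true(is.nan(sci(lig, rec, W * 0)))
  # zero-variance expression -> 0, flagged
  z <- sci(c(2, 2), rec, W)
  expect_equal(as.numeric(z), 0)
  expect_match(attr(z, "degenerate"), "variance")
  # symmetry under transpose + role swap
  set.seed(4)
  W2 <- Matrix::Matrix((matrix(runif(12), 3, 4) < 0.5) * 1, sparse = TRUE)
  l2 <- rnorm(3); r2 <- rnorm(4)
  expect_equal(sci(l2, r2, W2), sci(r2, l2, Matrix::t(W2)))
})

test_that("permutation test ranks extremes correctly and stops early", {
  cells <- lr_geometry()
  snd <- cells[cells$cell_type == "S", ]
  rcv <- cells[cells$cell_type == "R", ]
  W <- build_weight_matrix(snd, rcv, 60)
  set.seed(5)
  lig <- rnorm(nrow(snd)); rec <- rnorm(nrow(rcv))
  # anti-colocalized construction (high-degree senders get low ligand,
  # high-degree receivers high receptor): observed SCI far below the null
  lig_cold <- -as.numeric(Matrix::rowSums(W)) + rnorm(nrow(snd), 0, 0.05)
  rec_hot <- as.numeric(Matrix::colSums(W)) + rnorm(nrow(rcv), 0, 0.05)
  pt <- permutation_test(lig_cold, rec_hot, W,
                         n_perm = 100, adaptive = FALSE, seed = 6)
  expect_gt(pt$p_raw, 0.9)
  expect_equal(pt$n_perm_used, 100L)

  # unstructured data with adaptive stopping: stops well before the budget
  pt2 <- permutation_test(lig, rec, W, n_perm = 1000, adaptive = TRUE, seed = 7)
  expect_true(pt2$stopped_early)
  expect_lt(pt2$n_perm_used, 1000L)
  expect_gt(pt2$p_raw, 0.005)

  # early-stopped decision agrees with the full-permutation decision
  for (s in 1:10) {
    set.seed(100 + s)
    l <- rnorm(nrow(snd)); r <- rnorm(nrow(rcv))
    a <- permutation_test(l, r, W, n_perm = 400, adaptive = TRUE, seed = s)
    b <- permutation_test(l, r, W, n_perm = 400, adaptive = FALSE, seed = s)
    expect_equal(a$p_raw < 0.005, b$p_raw < 0.005)
  }
})

test_that("BH adjustment follows the hand step-up", {
  expect_equal(bh_adjust(0.04), 0.04)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  set.seed(8)
  p <- sort(runif(20))
  expect_equal(bh_adjust(p), sort(bh_adjust(p)))  # monotone on sorted input
})

test_that("the screen flags a constructed colocalized hotspot", {
  set.seed(33)
  n_s <- 40; n_r <- 40
  hot_s <- 1:12; hot_r <- 1:12
  cells <- data.frame(
    cell_id = c(paste0("s", 1:n_s), paste0("r", 1:n_r)),
    x = c(runif(12, 0, 30), runif(28, 200, 600),
          runif(12, 0, 30), runif(28, 200, 600)),
    y = c(runif(12, 0, 30), runif(28, 200, 600),
          runif(12, 0, 30), runif(28, 200, 600)),
    cell_type = rep(c("S", "R"), c(n_s, n_r)))
  expr <- matrix(rpois(2 * 80, 0.5), 2, 80,
                 dimnames = list(c("LIG", "REC"), cells$cell_id))
  expr["LIG", paste0("s", hot_s)] <- 10 + rpois(12, 3)
  expr["REC", paste0("r", hot_r)] <- 10 + rpois(12, 3)
  pairs <- data.frame(ligand = "LIG", receptor = "REC",
                      sender = "S", receiver = "R")
  res <- ligrec_screen(cells, expr, pairs, radius_um = 100, n_perm = 1000,
                       seed = 9)
  expect_equal(nrow(res), 1L)
  expect_gt(res$sci, 0)
  expect_lt(res$q_bh, 0.005)
  expect_true(res$significant)
  expect_gt(res$log_fc, 0)
})
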
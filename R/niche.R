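#' Neighborhood cell-type composition features
#'
#' For every cell, the proportion vector of cell types among its neighbors
#' within `radius_um` (self excluded). Cells with no neighbor inside the
#' radius carry no compositional information and are excluded (reported in
#' the `excluded` attribute).
#'
#' @param cells data.frame with `cell_id`, `x`, `y` (um), `cell_type`.
#' @param radius_um neighborhood radius.
#' @param types optional type vocabulary ordering the columns.
#' @return numeric matrix (featured cells x types), rows on the simplex,
#'   rownames = cell ids; attribute `excluded` lists dropped cell ids and
#'   `coords` their positions.
#' @export
neighborhood_features <- function(cells, radius_um = 30, types = NULL) {
  stopifnot_cols(cells, c("cell_id", "x", "y", "cell_type"))
  stopifnot(nrow(cells) >= 1L)
  types <- types %||% sort(unique(as.character(cells$cell_type)))
  n <- nrow(cells)
  counts <- matrix(0, n, length(types), dimnames = list(cells$cell_id, types))
  prs <- pairs_within(cells$x, cells$y, radius_um)
  if (nrow(prs)) {
    ti <- match(as.character(cells$cell_type), types)
    for (r in seq_len(nrow(prs))) {
      i <- prs[r, 1L]; j <- prs[r, 2L]
      counts[i, ti[j]] <- counts[i, ti[j]] + 1
      counts[j, ti[i]] <- counts[j, ti[i]] + 1
    }
  }
  deg <- rowSums(counts)
  keep <- deg > 0
  feat <- counts[keep, , drop = FALSE] / deg[keep]
  attr(feat, "excluded") <- cells$cell_id[!keep]
  attr(feat, "coords") <- cbind(x = cells$x[keep], y = cells$y[keep])
  feat
}

#' Delaunay triangulation graph of cell positions
#'
#' Undirected graph whose edges are the Delaunay triangulation of the cell
#' positions; optionally edges longer than `prune_um` are removed.
#' Degenerate (collinear) inputs fall back to a k-nearest-neighbor graph,
#' reported via the graph attribute `method`.
#'
#' @param cells data.frame with `cell_id`, `x`, `y` (um); at least 3 cells.
#' @param prune_um optional maximum edge length.
#' @param fallback_k neighbors used by the degenerate-input fallback.
#' @return an `igraph` graph with vertex names = cell ids and vertex
#'   attributes `x`, `y`.
#' @export
build_delaunay <- function(cells, prune_um = NULL, fallback_k = 2) {
  stopifnot_cols(cells, c("cell_id", "x", "y"))
  n <- nrow(cells)
  if (n < 3L) stop("need at least 3 points for a triangulation")
  tri <- tryCatch(
    deldir::deldir(cells$x, cells$y, suppressMsge = TRUE),
    error = function(e) NULL)
  if (!is.null(tri) && nrow(tri$delsgs) > 0L) {
    edges <- cbind(tri$delsgs$ind1, tri$delsgs$ind2)
    method <- "delaunay"
  } else {
    # collinear or otherwise degenerate layout: k-nearest-neighbor graph
    k <- min(fallback_k, n - 1L)
    d <- as.matrix(dist(cbind(cells$x, cells$y)))
    diag(d) <- Inf
    nb <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
    edges <- cbind(rep(seq_len(n), each = k), as.integer(t(nb)))
    swap <- edges[, 1] > edges[, 2]
    edges[swap, ] <- edges[swap, c(2, 1)]
    edges <- unique(edges)
    method <- "knn_fallback"
  }
  if (!is.null(prune_um)) {
    len <- sqrt((cells$x[edges[, 1]] - cells$x[edges[, 2]])^2 +
                (cells$y[edges[, 1]] - cells$y[edges[, 2]])^2)
    edges <- edges[len <= prune_um, , drop = FALSE]
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n) {
    g <- igraph::add_vertices(g, n - igraph::vcount(g))
  }
  igraph::V(g)$name <- as.character(cells$cell_id)
  igraph::V(g)$x <- cells$x
  igraph::V(g)$y <- cells$y
  g <- igraph::set_graph_attr(g, "method", method)
  g
}

#' Embedding configuration
#'
#' Defaults follow the training recipe used for districting: Adam with
#' learning rate 0.001 for 150 epochs, contrastive temperature 0.3 with
#' weight 0.3, dropout 0.25 on hidden activations.
#'
#' @param hidden_dim,out_dim layer widths.
#' @param n_layers number of aggregation layers.
#' @param lr Adam learning rate.
#' @param epochs training epochs (0 returns the untrained forward pass).
#' @param tau contrastive (InfoNCE) temperature (> 0).
#' @param lam weight of the contrastive term.
#' @param dropout_p hidden-layer dropout probability in [0, 1).
#' @param n_negatives negative samples per node per epoch.
#' @param seed integer RNG seed covering init, sampling and dropout.
#' @return an `embed_config` list.
#' @export
embed_config <- function(hidden_dim = 64, out_dim = 32, n_layers = 2,
                         lr = 0.001, epochs = 150, tau = 0.3, lam = 0.3,
                         dropout_p = 0.25, n_negatives = 5, seed = 1L) {
  stopifnot(tau > 0, dropout_p >= 0, dropout_p < 1, n_layers >= 1)
  structure(list(hidden_dim = hidden_dim, out_dim = out_dim,
                 n_layers = n_layers, lr = lr, epochs = epochs, tau = tau,
                 lam = lam, dropout_p = dropout_p, n_negatives = n_negatives,
                 seed = as.integer(seed)), class = "embed_config")
}

relu <- function(x) { x[x < 0] <- 0; x }
sigmoid <- function(x) 1 / (1 + exp(-x))

# scatter-add rows of V into G at indices idx
scatter_add <- function(G, idx, V) {
  S <- rowsum(V, idx)
  rows <- as.integer(rownames(S))
  G[rows, ] <- G[rows, , drop = FALSE] + S
  G
}

#' Unsupervised graph embedding of neighborhood features
#'
#' Mean-aggregation graph network in the GraphSAGE family: each layer
#' combines a node's own representation with the mean of its neighbors'
#' (`H_l = relu(M H W_n + H W_s + b)`, with `M` the row-normalized
#' adjacency; the final layer is linear). Training is unsupervised: per
#' epoch each node draws one positive (a graph neighbor) and
#' `n_negatives` random nodes, and minimizes a negative-sampling proximity
#' loss plus `lam` times an InfoNCE contrastive term with temperature
#' `tau` (dot-product similarity). Optimized with Adam; all randomness
#' (init, sampling, dropout) flows from the config seed, so runs are
#' reproducible.
#'
#' @param graph an [build_delaunay()] graph (or any igraph whose vertex
#'   names align with `features` rownames).
#' @param features numeric matrix of node features, rownames = vertex names.
#' @param config an [embed_config()].
#' @return numeric matrix (nodes x out_dim) of embeddings, rownames
#'   preserved; attribute `loss` holds the per-epoch training loss.
#' @export
embed_graphsage <- function(graph, features, config = embed_config()) {
  if (igraph::vcount(graph) == 0L) stop("empty graph")
  vn <- igraph::V(graph)$name
  if (!setequal(vn, rownames(features))) {
    stop("feature rownames must match the graph's vertex names")
  }
  X <- features[vn, , drop = FALSE]
  n <- nrow(X)
  A <- igraph::as_adjacency_matrix(graph, sparse = TRUE)
  deg <- Matrix::rowSums(A)
  Minv <- Matrix::Diagonal(x = ifelse(deg > 0, 1 / deg, 0))
  M <- Minv %*% A                       # mean aggregator
  nbrs <- igraph::adjacent_vertices(graph, igraph::V(graph))
  nbrs <- lapply(nbrs, as.integer)

  set.seed(config$seed)
  dims <- c(ncol(X), rep(config$hidden_dim, config$n_layers - 1L), config$out_dim)
  init_w <- function(fi, fo) {
    lim <- sqrt(6 / (fi + fo))
    matrix(runif(fi * fo, -lim, lim), fi, fo)
  }
  L <- config$n_layers
  Wn <- Ws <- bs <- vector("list", L)
  for (l in seq_len(L)) {
    Wn[[l]] <- init_w(dims[l], dims[l + 1L])
    Ws[[l]] <- init_w(dims[l], dims[l + 1L])
    bs[[l]] <- rep(0, dims[l + 1L])
  }
  params <- function() c(Wn, Ws, bs)
  # Adam state
  mom1 <- lapply(params(), function(p) p * 0)
  mom2 <- lapply(params(), function(p) p * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8; t_adam <- 0L

  forward <- function(train) {
    H <- X
    Ps <- Hs <- pres <- masks <- vector("list", L)
    for (l in seq_len(L)) {
      Hs[[l]] <- H
      P <- as.matrix(M %*% H)
      Ps[[l]] <- P
      pre <- P %*% Wn[[l]] + H %*% Ws[[l]] +
        matrix(bs[[l]], n, dims[l + 1L], byrow = TRUE)
      if (l < L) {
        pres[[l]] <- pre
        H <- relu(pre)
        if (train && config$dropout_p > 0) {
          mask <- matrix(runif(length(H)) >= config$dropout_p, n)
          masks[[l]] <- mask
          H <- H * mask / (1 - config$dropout_p)
        }
      } else H <- pre
    }
    list(Z = H, Ps = Ps, Hs = Hs, pres = pres, masks = masks)
  }

  loss_hist <- numeric(config$epochs)
  if (config$epochs > 0) {
    k_neg <- config$n_negatives
    for (ep in seq_len(config$epochs)) {
      pos <- vapply(seq_len(n), function(u) {
        nb <- nbrs[[u]]
        if (length(nb)) nb[sample.int(length(nb), 1L)] else u
      }, integer(1))
      negs <- matrix(sample.int(n, n * k_neg, replace = TRUE), n, k_neg)
      fw <- forward(train = TRUE)
      Z <- fw$Z
      s_pos <- rowSums(Z * Z[pos, , drop = FALSE])
      s_neg <- vapply(seq_len(k_neg), function(k) {
        rowSums(Z * Z[negs[, k], , drop = FALSE])
      }, numeric(n))
      if (k_neg == 1L) s_neg <- matrix(s_neg, ncol = 1L)

      l_nbr <- mean(-log(sigmoid(s_pos) + 1e-12)) +
        mean(rowSums(-log(sigmoid(-s_neg) + 1e-12)))
      logits <- cbind(s_pos, s_neg) / config$tau
      mx <- apply(logits, 1, max)
      lse <- mx + log(rowSums(exp(logits - mx)))
      l_con <- mean(lse - logits[, 1])
      loss_hist[ep] <- l_nbr + config$lam * l_con

      # dL/dZ
      G <- matrix(0, n, ncol(Z))
      a_pos <- (sigmoid(s_pos) - 1) / n
      G <- G + a_pos * Z[pos, , drop = FALSE]
      G <- scatter_add(G, pos, a_pos * Z)
      for (k in seq_len(k_neg)) {
        a_k <- sigmoid(s_neg[, k]) / n
        G <- G + a_k * Z[negs[, k], , drop = FALSE]
        G <- scatter_add(G, negs[, k], a_k * Z)
      }
      p_soft <- exp(logits - lse)        # n x (1 + k_neg)
      w_con <- config$lam / (n * config$tau)
      mix <- p_soft[, 1] * Z[pos, , drop = FALSE]
      for (k in seq_len(k_neg)) {
        mix <- mix + p_soft[, k + 1L] * Z[negs[, k], , drop = FALSE]
      }
      G <- G + w_con * (mix - Z[pos, , drop = FALSE])
      G <- scatter_add(G, pos, w_con * (p_soft[, 1] - 1) * Z)
      for (k in seq_len(k_neg)) {
        G <- scatter_add(G, negs[, k], w_con * p_soft[, k + 1L] * Z)
      }

      # backprop through the layers
      gWn <- gWs <- gbs <- vector("list", L)
      Gcur <- G
      for (l in rev(seq_len(L))) {
        gWn[[l]] <- t(fw$Ps[[l]]) %*% Gcur
        gWs[[l]] <- t(fw$Hs[[l]]) %*% Gcur
        gbs[[l]] <- colSums(Gcur)
        if (l > 1L) {
          Gh <- as.matrix(Matrix::t(M) %*% Gcur) %*% t(Wn[[l]]) +
            Gcur %*% t(Ws[[l]])
          if (config$dropout_p > 0) {
            Gh <- Gh * fw$masks[[l - 1L]] / (1 - config$dropout_p)
          }
          Gcur <- Gh * (fw$pres[[l - 1L]] > 0)
        }
      }
      grads <- c(gWn, gWs, gbs)
      plist <- c(Wn, Ws, bs)
      t_adam <- t_adam + 1L
      for (pi in seq_along(plist)) {
        mom1[[pi]] <- beta1 * mom1[[pi]] + (1 - beta1) * grads[[pi]]
        mom2[[pi]] <- beta2 * mom2[[pi]] + (1 - beta2) * grads[[pi]]^2
        mhat <- mom1[[pi]] / (1 - beta1^t_adam)
        vhat <- mom2[[pi]] / (1 - beta2^t_adam)
        plist[[pi]] <- plist[[pi]] - config$lr * mhat / (sqrt(vhat) + eps)
      }
      Wn <- plist[seq_len(L)]
      Ws <- plist[L + seq_len(L)]
      bs <- plist[2L * L + seq_len(L)]
    }
  }
  Z <- forward(train = FALSE)$Z
  rownames(Z) <- vn
  attr(Z, "loss") <- loss_hist
  attr(Z, "config") <- config
  Z
}

#' Cluster embeddings into spatial districts with Leiden
#'
#' Builds a k-nearest-neighbor graph of the embedding vectors and applies
#' Leiden community detection (modularity objective). Deterministic under
#' the seed. On sparse kNN graphs, modularity at resolution near 1 resolves
#' micro-communities; the default resolution of 0.1 targets district-scale
#' structure (a handful of communities per tissue).
#'
#' @param embeddings numeric matrix (cells x dims), rownames = cell ids.
#' @param resolution Leiden resolution parameter.
#' @param k neighbors in the kNN graph.
#' @param seed integer RNG seed.
#' @return data.frame `cell_id`, `district` (factor "D1", "D2", ... ordered
#'   by decreasing size); attribute `resolution` records the value used.
#' @export
cluster_districts <- function(embeddings, resolution = 0.1, k = 30, seed = 1L) {
  stopifnot(all(is.finite(embeddings)))
  n <- nrow(embeddings)
  k <- min(k, n - 1L)
  d <- as.matrix(dist(embeddings))
  diag(d) <- Inf
  nb <- t(apply(d, 1, function(r) order(r)[seq_len(k)]))
  edges <- cbind(rep(seq_len(n), each = k), as.integer(t(nb)))
  g <- igraph::simplify(igraph::graph_from_edgelist(edges, directed = FALSE))
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  memb <- igraph::membership(cl)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(paste0("D", seq_along(sizes)), names(sizes))
  out <- data.frame(cell_id = rownames(embeddings),
                    district = factor(relabel[as.character(memb)],
                                      levels = paste0("D", seq_along(sizes))),
                    stringsAsFactors = FALSE)
  attr(out, "resolution") <- resolution
  out
}

#' Full spatial districting pipeline
#'
#' Neighborhood composition features within `radius_um`, Delaunay graph of
#' the featured cells, unsupervised graph embedding, and Leiden clustering
#' into districts.
#'
#' @param cells data.frame with `cell_id`, `x`, `y` (um), `cell_type`.
#' @param radius_um neighborhood radius for the composition features.
#' @param config an [embed_config()].
#' @param resolution,knn Leiden parameters (see [cluster_districts()]).
#' @return data.frame `cell_id`, `district`; featured-cell embeddings in
#'   the `embeddings` attribute, excluded cell ids in `excluded`.
#' @export
find_districts <- function(cells, radius_um = 30, config = embed_config(),
                           resolution = 0.1, knn = 30) {
  # canonical cell order so that results are invariant to input row order
  cells <- cells[order(cells$cell_id), , drop = FALSE]
  feat <- neighborhood_features(cells, radius_um)
  kept <- cells[match(rownames(feat), cells$cell_id), ]
  g <- build_delaunay(kept)
  emb <- embed_graphsage(g, feat, config)
  out <- cluster_districts(emb, resolution = resolution, k = knn,
                           seed = config$seed)
  attr(out, "embeddings") <- emb
  attr(out, "excluded") <- attr(feat, "excluded")
  out
}
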
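# First/second-order proximity embedding of the regulatory network.
# Order 1 preserves direct-edge affinity via p1(vi, vj) = sigmoid(ui . uj);
# order 2 preserves shared neighborhoods through per-vertex context vectors
# with `negatives` noise draws proportional to degree^0.75. Both objectives
# are minimized by sequential (single-threaded, seeded, deterministic)
# stochastic gradient descent over sampled edges.

network_index <- function(network) {
  ids <- sort(network$vertices$id)
  list(ids = ids,
       from = match(network$edges$from, ids) - 1L,
       to = match(network$edges$to, ids) - 1L,
       weight = network$edges$weight)
}

#' Train one embedding order
#'
#' @param network A `regdom_network`.
#' @param order Proximity order, 1 or 2.
#' @param dim Embedding dimension per order (default 100).
#' @param negatives Negative samples per positive edge draw (default 5).
#' @param rho0 Initial learning rate (default 0.025), decaying linearly.
#' @param samples Total edge draws; default `1000 * |E|`.
#' @param seed RNG seed; fixed seed gives identical vectors.
#' @return Numeric matrix, one row per vertex (rownames = vertex ids).
#' @export
train_line <- function(network, order, dim = 100L, negatives = 5L,
                       rho0 = 0.025, samples = NULL, seed = 1L) {
  if (!order %in% c(1L, 2L)) abort("order must be 1 or 2")
  nx <- network_index(network)
  if (length(nx$from) == 0) abort("network has no edges")
  samples <- samples %||% (1000 * length(nx$from))
  emb <- .line_sgd(nx$from, nx$to, as.numeric(nx$weight),
                   length(nx$ids), as.integer(order), as.integer(dim),
                   as.integer(negatives), rho0, as.double(samples),
                   as.integer(seed))
  rownames(emb) <- nx$ids
  emb
}

# First-order objective value of an embedding on a network (monitoring).
first_order_objective <- function(network, emb) {
  nx <- network_index(network)
  .line_objective(nx$from, nx$to, as.numeric(nx$weight),
                  emb[nx$ids, , drop = FALSE])
}

#' Normalize and concatenate the two embedding orders
#'
#' Each per-order block is L2-normalized per vertex, then the blocks are
#' concatenated (order-1 first), giving `2 * dim` columns. All-zero rows
#' are left untouched with a warning.
#'
#' @param vec_order1,vec_order2 Matrices from [train_line()] with identical
#'   rownames.
#' @return Matrix of concatenated unit-block vectors.
#' @export
concat_normalize <- function(vec_order1, vec_order2) {
  if (!identical(sort(rownames(vec_order1)), sort(rownames(vec_order2)))) {
    abort("the two orders embed different vertex sets")
  }
  vec_order2 <- vec_order2[rownames(vec_order1), , drop = FALSE]
  l2 <- function(m) {
    nrm <- sqrt(rowSums(m^2))
    zero <- nrm == 0
    if (any(zero)) {
      warn(paste0("zero embedding vector(s) left unnormalized: ",
                  paste(rownames(m)[zero], collapse = ", ")))
      nrm[zero] <- 1
    }
    m / nrm
  }
  cbind(l2(vec_order1), l2(vec_order2))
}

#' Embed a network with both proximity orders
#'
#' Convenience wrapper: trains order 1 and order 2, normalizes and
#' concatenates ([concat_normalize()]), and optionally clusters
#' ([cluster_embeddings()]).
#'
#' @inheritParams train_line
#' @param k Cluster count, `"auto"`, or `NULL` to skip clustering.
#' @param tsne_seed,kmeans_seed Seeds for the clustering stage.
#' @return A `regdom_embedding` object (see [cluster_embeddings()]); when
#'   `k` is `NULL`, the vector matrix only.
#' @export
embed_network <- function(network, dim = 100L, negatives = 5L, rho0 = 0.025,
                          samples = NULL, seed = 1L, k = "auto",
                          tsne_seed = seed, kmeans_seed = seed) {
  v1 <- train_line(network, 1L, dim, negatives, rho0, samples, seed)
  v2 <- train_line(network, 2L, dim, negatives, rho0, samples, seed + 1L)
  vectors <- concat_normalize(v1, v2)
  if (is.null(k)) return(vectors)
  res <- cluster_embeddings(vectors, k = k, tsne_seed = tsne_seed,
                            kmeans_seed = kmeans_seed)
  res$network <- network
  res
}

#' t-SNE reduction and K-means clustering of embedding vectors
#'
#' Reduces the vectors to 2D with PCA-initialized t-SNE (Rtsne), then runs
#' K-means on the 2D coordinates (as the clustering is defined on the t-SNE
#' plane, not on the full vectors). `k = "auto"` picks the k in 2..15 with
#' the highest mean silhouette width, lowest k winning ties.
#'
#' @param vectors Embedding matrix (rownames = vertex ids).
#' @param k Integer cluster count or `"auto"`.
#' @param tsne_seed,kmeans_seed RNG seeds for the two stages.
#' @param perplexity t-SNE perplexity; default `min(30, floor((n-1)/3))`.
#' @return A `regdom_embedding`: list with `vectors`, and `coords` tibble
#'   (`vertex`, `x`, `y`, `cluster`).
#' @export
cluster_embeddings <- function(vectors, k = "auto", tsne_seed = 1L,
                               kmeans_seed = 1L, perplexity = NULL) {
  n <- nrow(vectors)
  perplexity <- perplexity %||% max(1, min(30, floor((n - 1) / 3)))
  coords <- withr::with_seed(tsne_seed, {
    Rtsne::Rtsne(vectors, dims = 2, pca = TRUE, perplexity = perplexity,
                 check_duplicates = FALSE,
                 pca_center = TRUE, pca_scale = FALSE)$Y
  })
  rownames(coords) <- rownames(vectors)

  if (identical(k, "auto")) {
    ks <- 2:min(15, n - 1)
    sil <- withr::with_seed(kmeans_seed, vapply(ks, function(kk) {
      cl <- kmeans(coords, centers = kk, nstart = 20)$cluster
      mean(cluster::silhouette(cl, stats::dist(coords))[, "sil_width"])
    }, numeric(1)))
    k <- ks[which.max(sil)] # which.max returns the first (lowest k) tie
  }
  if (k > n) abort("k exceeds the number of vertices")
  cl <- if (k == 1) {
    rep(1L, n)
  } else {
    withr::with_seed(kmeans_seed, kmeans(coords, centers = k, nstart = 20)$cluster)
  }
  structure(
    list(vectors = vectors,
         coords = tibble(vertex = rownames(vectors),
                         x = coords[, 1], y = coords[, 2],
                         cluster = as.integer(cl))),
    class = "regdom_embedding"
  )
}

#' @export
print.regdom_embedding <- function(x, ...) {
  cat(sprintf("<regdom_embedding> %d vertices, %d dims, %d cluster(s)\n",
              nrow(x$vectors), ncol(x$vectors),
              length(unique(x$coords$cluster))))
  invisible(x)
}

#' Similarity of embedded vectors
#'
#' Pearson correlation between a query vertex's full embedding vector and
#' each target's, sorted descending. Similarity queries use the full
#' vectors, not the 2D t-SNE coordinates.
#'
#' @param result A `regdom_embedding` or a vector matrix.
#' @param query_vertex Vertex id to compare from.
#' @param targets Target vertex ids; default all other vertices.
#' @return Tibble `target`, `pcc` (NA for constant vectors, with warning).
#' @export
embedding_similarity <- function(result, query_vertex, targets = NULL) {
  vectors <- if (inherits(result, "regdom_embedding")) result$vectors else result
  if (!query_vertex %in% rownames(vectors)) {
    abort(paste0("query vertex not embedded: ", query_vertex))
  }
  targets <- targets %||% setdiff(rownames(vectors), query_vertex)
  q <- vectors[query_vertex, ]
  pcc <- vapply(targets, function(t) {
    v <- vectors[t, ]
    if (sd(q) == 0 || sd(v) == 0) NA_real_ else cor(q, v)
  }, numeric(1))
  if (anyNA(pcc)) warn("constant embedding vector(s): correlation undefined")
  tibble(target = targets, pcc = unname(pcc)) |>
    arrange(dplyr::desc(.data$pcc))
}
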
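# Normalization, feature selection and the shared latent embedding that
# the blood/tissue classifier measures distances in.

#' Library-size normalize and log-transform counts
#'
#' Each cell is scaled to `scale_factor` total counts and the result is
#' log1p-transformed (the community-standard CP10k/log recipe). Zeros
#' stay zero, so sparsity is preserved.
#'
#' @param x an [expression_matrix()] of raw counts.
#' @param scale_factor target total per cell (default 10000).
#' @return An `expression_matrix` whose `counts` slot holds real values.
#' @export
normalize_counts <- function(x, scale_factor = 1e4) {
  stopifnot(inherits(x, "expression_matrix"))
  totals <- Matrix::rowSums(x$counts)
  if (any(totals == 0))
    stop("all-zero cells cannot be normalized: ",
         paste(x$barcodes[totals == 0], collapse = ", "))
  scaled <- Matrix::Diagonal(x = scale_factor / totals) %*% x$counts
  out <- x
  out$counts <- as(log1p(scaled), "CsparseMatrix")
  dimnames(out$counts) <- list(x$barcodes, x$genes$gene_id)
  out
}

#' Select shared highly variable genes for a joint embedding
#'
#' Intersects the gene namespaces of query and reference and ranks the
#' shared genes by dispersion (variance of normalized expression on the
#' concatenated matrix), returning the top `n_hvg`. If fewer than
#' `n_hvg` genes are shared, all shared genes are returned.
#'
#' @param query,ref normalized [expression_matrix()] objects.
#' @param n_hvg number of highly variable genes to keep (default 2000).
#' @return Character vector of gene ids, most dispersed first.
#' @export
select_features <- function(query, ref, n_hvg = 2000) {
  stopifnot(inherits(query, "expression_matrix"),
            inherits(ref, "expression_matrix"))
  shared <- intersect(query$genes$gene_id, ref$genes$gene_id)
  if (length(shared) == 0)
    stop("query and reference share no gene identifiers")
  m <- rbind(query$counts[, shared, drop = FALSE],
             ref$counts[, shared, drop = FALSE])
  mu <- Matrix::colMeans(m)
  ex2 <- Matrix::colMeans(m^2)
  disp <- ex2 - mu^2               # population variance per gene
  ord <- order(disp, decreasing = TRUE)
  shared[ord][seq_len(min(n_hvg, length(shared)))]
}

#' Embed query and reference cells in one latent space
#'
#' Query and reference cells are concatenated, features are z-scaled on
#' the concatenation, and a d-dimensional PCA is computed. With
#' `method = "umap"` the PCA coordinates are further embedded into a
#' d-dimensional UMAP under a fixed seed. Both datasets pass through the
#' identical transform, so their coordinates are directly comparable.
#' PCA component signs are fixed (largest-magnitude loading positive)
#' for bit-reproducibility.
#'
#' @param query,ref normalized [expression_matrix()] objects restricted
#'   to the same feature list (same columns, same order).
#' @param d latent dimension (default 10).
#' @param method `"umap"` (default) or `"pca"`.
#' @param seed integer seed controlling the UMAP layout.
#' @param n_neighbors,min_dist UMAP hyperparameters; `n_neighbors` is
#'   capped at one less than the number of cells.
#' @return List with elements `query` and `ref`, each of class
#'   `embedding`: a list of `coords` (cells x d), `barcodes`, `d`,
#'   `method`.
#' @export
joint_embed <- function(query, ref, d = 10, method = c("umap", "pca"),
                        seed = 1, n_neighbors = 30, min_dist = 0.3) {
  method <- match.arg(method)
  stopifnot(inherits(query, "expression_matrix"),
            inherits(ref, "expression_matrix"))
  if (!identical(colnames(query$counts), colnames(ref$counts)))
    stop("query and reference must be restricted to the same feature list")
  n_feat <- ncol(query$counts)
  n_q <- nrow(query$counts); n_r <- nrow(ref$counts)
  if (d > n_feat) stop("latent dimension d = ", d, " exceeds ", n_feat, " features")
  if (n_q + n_r < d + 1)
    stop("need at least d + 1 = ", d + 1, " cells, have ", n_q + n_r)
  if (d < 2) stop("latent dimension must be >= 2")

  m <- as.matrix(rbind(query$counts, ref$counts))
  mu <- colMeans(m)
  sd <- apply(m, 2, stats::sd)
  sd[sd == 0] <- 1                 # constant features contribute 0
  z <- sweep(sweep(m, 2, mu), 2, sd, "/")

  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE, rank. = d)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  coords <- sweep(pc$x[, seq_len(d), drop = FALSE], 2, flip, "*")

  if (method == "umap") {
    nn <- min(n_neighbors, n_q + n_r - 1)
    set.seed(seed)
    coords <- uwot::umap(coords, n_components = d, n_neighbors = nn,
                         min_dist = min_dist, n_threads = 1,
                         n_sgd_threads = 0, verbose = FALSE)
  }
  if (any(!is.finite(coords))) stop("non-finite latent coordinates")
  colnames(coords) <- paste0("latent_", seq_len(d))

  mk <- function(rows, barcodes) {
    structure(list(coords = `rownames<-`(coords[rows, , drop = FALSE], barcodes),
                   barcodes = barcodes, d = d, method = method),
              class = "embedding")
  }
  list(query = mk(seq_len(n_q), query$barcodes),
       ref = mk(n_q + seq_len(n_r), ref$barcodes))
}

#' @exportS3Method print embedding
print.embedding <- function(x, ...) {
  cat(sprintf("embedding: %d cells in %d latent dimensions (%s)\n",
              nrow(x$coords), x$d, x$method))
  invisible(x)
}
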
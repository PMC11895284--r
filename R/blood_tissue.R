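# Blood vs. expected tissue-resident classification: per immune cell
# type, k-means (k = 2) on each query cell's Euclidean distance profile
# to the whole-blood reference; the cluster nearer the reference is
# called blood.

#' Immune cell types processed by default
#'
#' The annotated immune cell types the compartment classifier operates
#' on unless told otherwise.
#' @export
DEFAULT_IMMUNE_TYPES <- c("monocytes", "macrophages", "T-cells",
                          "regulatory T-cells", "plasma cells",
                          "NK cells", "B-cells")

#' Pairwise Euclidean distances between query and reference embeddings
#'
#' @param q,r `embedding` objects from [joint_embed()] with the same
#'   latent dimension.
#' @return An object of class `distance_profile`: list with `dist`
#'   (query cells x reference cells), `query_index`, `ref_index`.
#' @export
distance_profiles <- function(q, r) {
  stopifnot(inherits(q, "embedding"), inherits(r, "embedding"))
  if (q$d != r$d)
    stop("latent dimension mismatch: query d = ", q$d, ", reference d = ", r$d)
  a <- q$coords; b <- r$coords
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  d2[d2 < 0] <- 0                  # numeric noise near zero
  structure(list(dist = sqrt(d2), query_index = q$barcodes,
                 ref_index = r$barcodes),
            class = "distance_profile")
}

# canonical row order from data values only, so clustering is invariant
# to cell order and barcode renaming
canonical_order <- function(m) {
  keys <- c(list(rowMeans(m)), as.list(as.data.frame(m)))
  do.call(order, keys)
}

#' Cluster query cells on their distance profiles
#'
#' k-means on the rows of the distance matrix: each query cell's full
#' vector of distances to the reference is its feature vector. Rows are
#' visited in a canonical data-derived order so the result does not
#' depend on cell order or barcode names.
#'
#' @param p a [distance_profiles()] object.
#' @param k number of clusters (default 2).
#' @param seed integer seed for the k-means restarts.
#' @param nstart number of random restarts (default 10).
#' @return Integer vector of cluster labels in `0:(k-1)`, one per query
#'   cell.
#' @export
cluster_profiles <- function(p, k = 2, seed = 1, nstart = 10) {
  stopifnot(inherits(p, "distance_profile"))
  n <- nrow(p$dist)
  if (k < 1) stop("k must be >= 1")
  if (k == 1) return(rep(0L, n))
  n_distinct <- nrow(unique(p$dist))
  if (n < k || n_distinct < k) {
    warning("fewer ", if (n < k) "query cells" else "distinct profiles",
            " (", min(n, n_distinct), ") than k = ", k,
            "; all cells assigned to cluster 0")
    return(rep(0L, n))
  }
  ord <- canonical_order(p$dist)
  set.seed(seed)
  km <- stats::kmeans(p$dist[ord, , drop = FALSE], centers = k,
                      nstart = nstart, iter.max = 50)
  labels <- integer(n)
  labels[ord] <- km$cluster - 1L
  # relabel clusters by ascending mean profile so labels themselves are
  # canonical (0 = closest to reference on average)
  cl_means <- vapply(0:(k - 1), function(c)
    mean(rowMeans(p$dist)[labels == c]), numeric(1))
  rank_map <- order(order(cl_means, 0:(k - 1))) - 1L
  rank_map[labels + 1L]
}

#' Assign blood/tissue compartments to clustered cells
#'
#' Per query cell, `mean_ref_distance` is its average distance to the
#' whole-blood reference. Of the two clusters, the one with the smaller
#' mean of these averages is annotated blood; the other tissue. An exact
#' tie is broken toward cluster 0 = blood with a warning.
#'
#' @param p a [distance_profiles()] object.
#' @param labels cluster labels from [cluster_profiles()] with k = 2.
#' @return data.frame with columns barcode, cluster_id,
#'   mean_ref_distance, compartment.
#' @export
label_compartments <- function(p, labels) {
  stopifnot(inherits(p, "distance_profile"), length(labels) == nrow(p$dist))
  mrd <- rowMeans(p$dist)
  present <- sort(unique(labels))
  if (length(present) == 1) {
    warning("single cluster present; all cells annotated blood")
    compartment <- rep("blood", length(labels))
  } else if (length(present) == 2) {
    cl_means <- vapply(present, function(c) mean(mrd[labels == c]), numeric(1))
    if (cl_means[1] == cl_means[2]) {
      warning("cluster mean distances tie exactly; cluster 0 annotated blood")
      blood_cluster <- present[1]
    } else {
      blood_cluster <- present[which.min(cl_means)]
    }
    compartment <- ifelse(labels == blood_cluster, "blood", "tissue")
  } else {
    stop("expected at most 2 clusters, got ", length(present))
  }
  data.frame(barcode = p$query_index, cluster_id = labels,
             mean_ref_distance = mrd, compartment = compartment,
             stringsAsFactors = FALSE)
}

#' Classify immune cells into blood vs. tissue-resident compartments
#'
#' The full reference-guided classifier. For each listed immune cell
#' type with at least `min_cells` query cells, query and reference cells
#' are normalized, restricted to shared highly variable genes, jointly
#' embedded ([joint_embed()]), and each query cell's Euclidean distance
#' profile to the reference is clustered by k-means (k = 2,
#' [cluster_profiles()]); the cluster nearer the reference becomes
#' blood ([label_compartments()]). Cell types not listed, with too few
#' cells, or absent from an annotated reference stay `unassigned`.
#'
#' @param query an [expression_matrix()] of raw query counts.
#' @param query_ann annotation data.frame ([read_annotations()] layout)
#'   assigning a cell_type to each query barcode.
#' @param ref an [expression_matrix()] of raw whole-blood reference
#'   counts.
#' @param ref_ann optional reference annotation data.frame; when given,
#'   reference cells of the matching cell type are used, and types the
#'   reference lacks are skipped with a warning. When `NULL`, the whole
#'   reference is used for every type.
#' @param cell_types immune cell types to process (default
#'   [DEFAULT_IMMUNE_TYPES]).
#' @param latent_dim latent dimension (default 10 — the top 10 latent
#'   variables are used for the distance matrix).
#' @param embed_method `"umap"` (default) or `"pca"`.
#' @param k number of k-means clusters (default 2).
#' @param seed top-level seed, fanned out deterministically per type.
#' @param min_cells minimum query cells per type (default 20).
#' @param n_hvg highly variable genes for the joint embedding.
#' @return Object of class `compartment_fit`: list with `calls` (one row
#'   per query barcode: barcode, cell_type, compartment, cluster_id,
#'   mean_ref_distance), `embeddings` (per processed type), `params`,
#'   `skipped`.
#' @export
classify_compartments <- function(query, query_ann, ref, ref_ann = NULL,
                                  cell_types = DEFAULT_IMMUNE_TYPES,
                                  latent_dim = 10,
                                  embed_method = c("umap", "pca"),
                                  k = 2, seed = 1, min_cells = 20,
                                  n_hvg = 2000) {
  embed_method <- match.arg(embed_method)
  stopifnot(inherits(query, "expression_matrix"),
            inherits(ref, "expression_matrix"))
  query_ann <- query_ann[match(query$barcodes, query_ann$barcode), , drop = FALSE]
  if (any(is.na(query_ann$barcode)))
    stop("query annotation lacks some query barcodes")
  present <- intersect(cell_types, unique(query_ann$cell_type))
  if (length(present) == 0)
    stop("none of the requested cell types are present in the query: ",
         paste(cell_types, collapse = ", "))

  calls <- data.frame(barcode = query$barcodes,
                      cell_type = query_ann$cell_type,
                      compartment = "unassigned",
                      cluster_id = NA_integer_,
                      mean_ref_distance = NA_real_,
                      stringsAsFactors = FALSE)
  embeddings <- list(); skipped <- character(0)

  for (ct in present) {
    type_seed <- seed + 1000L * match(ct, cell_types)
    q_idx <- which(query_ann$cell_type == ct)
    if (length(q_idx) < min_cells) {
      warning("cell type '", ct, "' has ", length(q_idx),
              " query cells (< min_cells = ", min_cells, "); left unassigned")
      skipped <- c(skipped, ct)
      next
    }
    if (!is.null(ref_ann)) {
      r_idx <- which(ref_ann$cell_type[match(ref$barcodes, ref_ann$barcode)] == ct)
      if (length(r_idx) == 0) {
        warning("reference lacks cell type '", ct, "'; skipped")
        skipped <- c(skipped, ct)
        next
      }
    } else {
      r_idx <- seq_along(ref$barcodes)
    }

    q_sub <- subset_cells(query, q_idx)
    r_sub <- subset_cells(ref, r_idx)
    # drop zero-count cells: they cannot be normalized, stay unassigned
    qz <- Matrix::rowSums(q_sub$counts) == 0
    rz <- Matrix::rowSums(r_sub$counts) == 0
    if (any(qz)) q_sub <- subset_cells(q_sub, which(!qz))
    if (any(rz)) r_sub <- subset_cells(r_sub, which(!rz))
    if (nrow(q_sub$counts) < min_cells || nrow(r_sub$counts) == 0) {
      skipped <- c(skipped, ct)
      next
    }

    qn <- normalize_counts(q_sub)
    rn <- normalize_counts(r_sub)
    feats <- select_features(qn, rn, n_hvg = n_hvg)
    qn <- subset_genes(qn, feats)
    rn <- subset_genes(rn, feats)
    emb <- joint_embed(qn, rn, d = latent_dim, method = embed_method,
                       seed = type_seed)
    prof <- distance_profiles(emb$query, emb$ref)
    labels <- cluster_profiles(prof, k = k, seed = type_seed)
    lab <- label_compartments(prof, labels)
    rows <- match(lab$barcode, calls$barcode)
    calls$compartment[rows] <- lab$compartment
    calls$cluster_id[rows] <- lab$cluster_id
    calls$mean_ref_distance[rows] <- lab$mean_ref_distance
    embeddings[[ct]] <- emb
  }

  structure(list(calls = calls, embeddings = embeddings,
                 params = list(cell_types = cell_types,
                               latent_dim = latent_dim,
                               embed_method = embed_method, k = k,
                               seed = seed, min_cells = min_cells,
                               n_hvg = n_hvg),
                 skipped = skipped),
            class = "compartment_fit")
}

subset_cells <- function(x, idx) {
  expression_matrix(x$counts[idx, , drop = FALSE], x$barcodes[idx], x$genes)
}

subset_genes <- function(x, gene_ids) {
  j <- match(gene_ids, x$genes$gene_id)
  expression_matrix(x$counts[, j, drop = FALSE], x$barcodes,
                    x$genes[j, , drop = FALSE])
}

#' @exportS3Method print compartment_fit
print.compartment_fit <- function(x, ...) {
  tab <- table(x$calls$compartment)
  cat("Blood/tissue compartment classification\n")
  cat(sprintf("  %d cells: %s\n", nrow(x$calls),
              paste(names(tab), as.integer(tab), sep = " = ", collapse = ", ")))
  cat(sprintf("  embedding: %s, d = %d, k = %d\n",
              x$params$embed_method, x$params$latent_dim, x$params$k))
  if (length(x$skipped))
    cat("  skipped types:", paste(unique(x$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' @exportS3Method summary compartment_fit
summary.compartment_fit <- function(object, ...) {
  agg <- aggregate(barcode ~ cell_type + compartment, object$calls, length)
  names(agg)[3] <- "n_cells"
  agg <- agg[order(agg$cell_type, agg$compartment), ]
  rownames(agg) <- NULL
  agg
}

#' Scatter of the latent embedding colored by compartment
#'
#' @param x a `compartment_fit`.
#' @param cell_type which processed type to plot (default: first).
#' @param dims two latent dimensions to show.
#' @param ... passed to [graphics::plot()].
#' @export
plot.compartment_fit <- function(x, cell_type = NULL, dims = c(1, 2), ...) {
  if (length(x$embeddings) == 0) stop("no processed cell types to plot")
  if (is.null(cell_type)) cell_type <- names(x$embeddings)[1]
  emb <- x$embeddings[[cell_type]]
  if (is.null(emb)) stop("cell type '", cell_type, "' was not processed")
  calls <- x$calls[match(emb$query$barcodes, x$calls$barcode), ]
  col <- c(blood = "#D55E00", tissue = "#0072B2",
           unassigned = "grey70")[calls$compartment]
  graphics::plot(emb$ref$coords[, dims], col = "grey85", pch = 16,
                 cex = 0.5, xlab = paste0("latent_", dims[1]),
                 ylab = paste0("latent_", dims[2]),
                 main = paste0(cell_type, " (ref in grey)"), ...)
  graphics::points(emb$query$coords[, dims], col = col, pch = 16, cex = 0.6)
  graphics::legend("topright", legend = c("blood", "tissue"),
                   col = c("#D55E00", "#0072B2"), pch = 16, bty = "n")
  invisible(x)
}
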
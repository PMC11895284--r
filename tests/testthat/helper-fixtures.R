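# Fixtures are built in code: a hand-written MatrixMarket writer (kept
# independent of the package's own writer so read tests have an
# external fixture), toy allele-count tables, and tiny containers.

# write a 10x-style directory by hand; entries is a data.frame with
# columns gene, cell, value (1-based, genes x cells orientation)
write_toy_10x <- function(dir, n_genes, n_cells, entries, gzip = FALSE,
                          barcodes = sprintf("c%d", seq_len(n_cells)),
                          gene_ids = sprintf("g%d", seq_len(n_genes))) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  maybe_gz <- function(name) {
    path <- file.path(dir, if (gzip) paste0(name, ".gz") else name)
    if (gzip) gzfile(path, "wt") else file(path, "wt")
  }
  con <- maybe_gz("matrix.mtx")
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               paste(n_genes, n_cells, nrow(entries))), con)
  if (nrow(entries))
    writeLines(paste(entries$gene, entries$cell, entries$value), con)
  close(con)
  con <- maybe_gz("barcodes.tsv")
  writeLines(barcodes, con); close(con)
  con <- maybe_gz("features.tsv")
  writeLines(paste(gene_ids, toupper(gene_ids), "Gene Expression", sep = "\t"),
             con); close(con)
  dir
}

write_toy_allele_tsv <- function(path, df) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

toy_expression <- function(m, barcodes = sprintf("c%d", seq_len(nrow(m))),
                           gene_ids = sprintf("g%d", seq_len(ncol(m)))) {
  expression_matrix(Matrix::Matrix(m, sparse = TRUE), barcodes, gene_ids)
}

toy_embedding <- function(coords, barcodes = sprintf("c%d", seq_len(nrow(coords))),
                          method = "pca") {
  structure(list(coords = `rownames<-`(as.matrix(coords), barcodes),
                 barcodes = barcodes, d = ncol(coords), method = method),
            class = "embedding")
}

toy_profile <- function(dist, query = sprintf("q%d", seq_len(nrow(dist))),
                        ref = sprintf("r%d", seq_len(ncol(dist)))) {
  structure(list(dist = as.matrix(dist), query_index = query,
                 ref_index = ref),
            class = "distance_profile")
}

toy_allele_counts <- function(ref, alt, maf = rep(0.05, ncol(ref)),
                              barcodes = sprintf("c%d", seq_len(nrow(ref)))) {
  variants <- data.frame(chrom = "chr1", pos = seq_len(ncol(ref)),
                         ref = "A", alt = "G", maf = maf,
                         stringsAsFactors = FALSE)
  allele_counts(Matrix::Matrix(ref, sparse = TRUE),
                Matrix::Matrix(alt, sparse = TRUE), variants, barcodes)
}

# build a genotype_mixture object with known parameters (for tests of
# downstream calling that must not depend on the EM fit)
toy_model <- function(dosages, weights = rep(1 / nrow(dosages), nrow(dosages)),
                      error_rate = 0.01, doublet_rate = 0.05) {
  structure(list(dosages = dosages, mix_weights = weights,
                 error_rate = error_rate, doublet_rate = doublet_rate,
                 n_origins = nrow(dosages),
                 loglik = 0, converged = TRUE, n_iter = 0,
                 barcodes = character(0)),
            class = "genotype_mixture")
}

# brute-force oracles -------------------------------------------------

brute_distances <- function(a, b) {
  d <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      d[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  d
}

# pairwise Mann-Whitney AUC with half-credit for ties
brute_auc <- function(scores, labels) {
  pos <- which(labels); neg <- which(!labels)
  total <- 0
  for (i in pos)
    for (j in neg)
      total <- total + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  total / (length(pos) * length(neg))
}

# AUCPR by direct counting at every distinct threshold
brute_aucpr <- function(scores, labels) {
  ts <- sort(unique(scores), decreasing = TRUE)
  prev_r <- 0; area <- 0
  for (t in ts) {
    pred <- scores >= t
    tp <- sum(pred & labels)
    p <- tp / sum(pred)
    r <- tp / sum(labels)
    area <- area + (r - prev_r) * p
    prev_r <- r
  }
  area
}

# per-read product log-likelihood under the binomial read model
brute_cell_loglik <- function(ref, alt, dosage, e) {
  ll <- 0
  for (v in seq_along(ref)) {
    p <- dosage[v] * (1 - e) + (1 - dosage[v]) * e
    if (alt[v] > 0) for (k in seq_len(alt[v])) ll <- ll + log(p)
    if (ref[v] > 0) for (k in seq_len(ref[v])) ll <- ll + log(1 - p)
  }
  ll
}

# best 2-partition by total within-cluster sum of squares, exhaustively
brute_best_bipartition <- function(m) {
  n <- nrow(m)
  best <- NULL; best_sse <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    grp <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)))
    if (!any(grp) || all(grp)) next
    sse <- 0
    for (g in list(which(grp), which(!grp))) {
      ctr <- colMeans(m[g, , drop = FALSE])
      sse <- sse + sum(sweep(m[g, , drop = FALSE], 2, ctr)^2)
    }
    if (sse < best_sse) { best_sse <- sse; best <- grp }
  }
  best
}
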
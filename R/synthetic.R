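# Ground-truthed synthetic data: an artificial tissue/blood expression
# mixture for the compartment classifier, and Hardy-Weinberg allele
# counts for the genotype demultiplexer.

#' Simulate an artificial blood/tissue expression mixture
#'
#' Emulates the artificially mixed tissue-blood validation design with
#' a latent-factor model, so that `delta` and `within_sd` are genuine
#' latent-space quantities. Cells live in an `n_latent`-dimensional
#' latent space: each cell type has a latent center and a fixed random
#' unit shift direction; blood cells of a type sit at the center,
#' tissue cells are displaced by `delta` along the type's direction,
#' and every cell gets isotropic latent noise with sd `within_sd`. The
#' latent coordinates map to per-gene log-expression through a random
#' loading matrix on top of a baseline profile, pass through a softmax,
#' and counts are drawn from a multinomial at `library_size` reads —
#' so the planted separation-to-noise ratio `delta / within_sd` is
#' (approximately) what any faithful low-dimensional embedding of the
#' counts sees. The reference consists of additional, independent
#' blood-compartment cells of every type. Fully deterministic under
#' `seed`.
#'
#' @param n_cell_types number of cell types (default 4).
#' @param cells_per_type_per_compartment query cells per type per
#'   compartment (default 250).
#' @param n_genes number of genes (default 1000).
#' @param delta blood-to-tissue separation in latent units; default
#'   1.5 = 5 * within_sd.
#' @param within_sd within-population latent sd (default 0.3).
#' @param library_size reads per cell (default 5000).
#' @param n_latent dimensionality of the generative latent space
#'   (default 10).
#' @param ref_cells_per_type reference blood cells per type (default:
#'   same as `cells_per_type_per_compartment`).
#' @param seed integer seed.
#' @return List with `query` and `ref` ([expression_matrix()]),
#'   `query_ann` and `ref_ann` (annotation data.frames; `query_ann`'s
#'   `compartment` column is the planted truth).
#' @export
simulate_expression <- function(n_cell_types = 4,
                                cells_per_type_per_compartment = 250,
                                n_genes = 1000, delta = 1.5,
                                within_sd = 0.3, library_size = 5000,
                                n_latent = 10,
                                ref_cells_per_type = cells_per_type_per_compartment,
                                seed = 1) {
  stopifnot(delta >= 0, within_sd >= 0, n_cell_types >= 1,
            cells_per_type_per_compartment >= 1, n_genes >= 2,
            library_size >= 1, ref_cells_per_type >= 1, n_latent >= 2)
  set.seed(seed)
  types <- paste0("type", seq_len(n_cell_types))
  baseline <- rnorm(n_genes)                        # per-gene log baseline
  loadings <- matrix(rnorm(n_latent * n_genes, sd = 1 / sqrt(n_latent)),
                     n_latent, n_genes)             # latent -> gene map
  centers <- matrix(rnorm(n_cell_types * n_latent), n_cell_types, n_latent)
  shift_dir <- matrix(rnorm(n_cell_types * n_latent), n_cell_types, n_latent)
  shift_dir <- shift_dir / sqrt(rowSums(shift_dir^2))

  draw_cells <- function(type_idx, n, shifted) {
    mu <- centers[type_idx, ] + if (shifted) delta * shift_dir[type_idx, ] else 0
    z <- matrix(rnorm(n * n_latent, sd = within_sd), n, n_latent) +
      matrix(mu, n, n_latent, byrow = TRUE)
    eta <- z %*% loadings + matrix(baseline, n, n_genes, byrow = TRUE)
    t(apply(eta, 1, function(e) {
      p <- exp(e - max(e)); p <- p / sum(p)
      rmultinom(1, library_size, p)[, 1]
    }))
  }

  nq <- cells_per_type_per_compartment
  q_counts <- vector("list", 2 * n_cell_types)
  q_type <- q_comp <- character(0)
  for (t in seq_len(n_cell_types)) {
    q_counts[[2 * t - 1]] <- draw_cells(t, nq, shifted = FALSE)
    q_counts[[2 * t]] <- draw_cells(t, nq, shifted = TRUE)
    q_type <- c(q_type, rep(types[t], 2 * nq))
    q_comp <- c(q_comp, rep("blood", nq), rep("tissue", nq))
  }
  q_mat <- do.call(rbind, q_counts)
  q_bc <- sprintf("q%05d", seq_len(nrow(q_mat)))

  r_counts <- lapply(seq_len(n_cell_types), function(t)
    draw_cells(t, ref_cells_per_type, shifted = FALSE))
  r_mat <- do.call(rbind, r_counts)
  r_bc <- sprintf("r%05d", seq_len(nrow(r_mat)))
  r_type <- rep(types, each = ref_cells_per_type)

  genes <- data.frame(gene_id = sprintf("gene%05d", seq_len(n_genes)),
                      gene_symbol = sprintf("GENE%05d", seq_len(n_genes)),
                      stringsAsFactors = FALSE)
  list(query = expression_matrix(q_mat, q_bc, genes),
       ref = expression_matrix(r_mat, r_bc, genes),
       query_ann = data.frame(barcode = q_bc, cell_type = q_type,
                              compartment = q_comp,
                              origin = "unassigned",
                              doublet_flag = FALSE,
                              stringsAsFactors = FALSE),
       ref_ann = data.frame(barcode = r_bc, cell_type = r_type,
                            compartment = "blood",
                            origin = "unassigned", doublet_flag = FALSE,
                            stringsAsFactors = FALSE))
}

#' Simulate allele counts with known genetic origins
#'
#' Per variant, a population minor allele frequency is drawn from a
#' Beta(a, b) truncated to (0, 0.5]; per origin, a diploid dosage in
#' `{0, 0.5, 1}` is drawn from Hardy-Weinberg proportions at that MAF.
#' Each cell is a singlet of a random origin, or — at `doublet_rate` —
#' a mosaic doublet of a random unordered origin pair whose dosage
#' profile is the pair average. Read depth per cell and variant is
#' Poisson(`coverage`); alternate reads are Binomial(depth, p) with
#' p = d(1-e) + (1-d)e.
#'
#' @param n_origins number of genetic origins (default 2).
#' @param n_cells number of cells (default 200).
#' @param n_snps number of variants (default 500).
#' @param coverage Poisson mean reads per variant per cell (default 2).
#' @param doublet_rate fraction of mosaic doublets (default 0.05).
#' @param maf_beta_params shape parameters (a, b) of the MAF Beta
#'   distribution (default c(1, 5)).
#' @param error_rate sequencing error rate (default 0.01).
#' @param seed integer seed.
#' @return List with `counts` ([allele_counts()]), `truth` (data.frame:
#'   barcode, origin — 0-based index, NA for doublets —, doublet,
#'   origin2 — the doublet's second origin), and `dosages` (the true
#'   n_origins x n_snps matrix).
#' @export
simulate_allele_counts <- function(n_origins = 2, n_cells = 200,
                                   n_snps = 500, coverage = 2,
                                   doublet_rate = 0.05,
                                   maf_beta_params = c(1, 5),
                                   error_rate = 0.01, seed = 1) {
  stopifnot(n_origins >= 1, n_cells >= 1, n_snps >= 1, coverage >= 0,
            doublet_rate >= 0, doublet_rate < 1)
  set.seed(seed)

  # MAF ~ Beta(a, b) truncated to (0, 0.5]: resample values > 0.5
  maf <- rbeta(n_snps, maf_beta_params[1], maf_beta_params[2])
  while (any(bad <- maf > 0.5 | maf == 0))
    maf[bad] <- rbeta(sum(bad), maf_beta_params[1], maf_beta_params[2])

  # Hardy-Weinberg dosages per origin
  dosages <- matrix(0, n_origins, n_snps)
  for (k in seq_len(n_origins)) {
    u <- runif(n_snps)
    p0 <- (1 - maf)^2; p1 <- 2 * maf * (1 - maf)
    dosages[k, ] <- ifelse(u < p0, 0, ifelse(u < p0 + p1, 0.5, 1))
  }

  is_doublet <- runif(n_cells) < doublet_rate & n_origins >= 2
  origin <- sample.int(n_origins, n_cells, replace = TRUE)
  origin2 <- rep(NA_integer_, n_cells)
  for (i in which(is_doublet)) {
    others <- setdiff(seq_len(n_origins), origin[i])
    origin2[i] <- others[sample.int(length(others), 1)]
  }

  cell_dos <- dosages[origin, , drop = FALSE]
  if (any(is_doublet))
    cell_dos[is_doublet, ] <- (dosages[origin[is_doublet], , drop = FALSE] +
                               dosages[origin2[is_doublet], , drop = FALSE]) / 2

  depth <- matrix(rpois(n_cells * n_snps, coverage), n_cells, n_snps)
  p_alt <- cell_dos * (1 - error_rate) + (1 - cell_dos) * error_rate
  alt <- matrix(rbinom(n_cells * n_snps, depth, p_alt), n_cells, n_snps)
  ref <- depth - alt

  barcodes <- sprintf("cell%04d", seq_len(n_cells))
  variants <- data.frame(chrom = "chr1", pos = seq_len(n_snps) * 100L,
                         ref = "A", alt = "G", maf = maf,
                         stringsAsFactors = FALSE)
  truth <- data.frame(barcode = barcodes,
                      origin = ifelse(is_doublet, NA_integer_, origin - 1L),
                      doublet = is_doublet,
                      origin2 = origin2 - 1L,
                      stringsAsFactors = FALSE)
  list(counts = allele_counts(Matrix::Matrix(ref, sparse = TRUE),
                              Matrix::Matrix(alt, sparse = TRUE),
                              variants, barcodes),
       truth = truth, dosages = dosages)
}
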
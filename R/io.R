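# Readers/writers for 10x-style matrices, annotation tables, allele counts.

#' Construct an expression matrix container
#'
#' Thin validated container for a cells x genes sparse count matrix with
#' barcode and gene identifiers.
#'
#' @param counts sparse (or dense, coerced) nonnegative matrix, cells in
#'   rows, genes in columns.
#' @param barcodes character vector of unique cell barcodes, one per row.
#' @param genes data.frame with columns `gene_id` and `gene_symbol`, one
#'   row per matrix column.
#' @return An object of class `expression_matrix`: a list with elements
#'   `counts` (dgCMatrix), `barcodes`, `genes`.
#' @export
expression_matrix <- function(counts, barcodes, genes) {
  counts <- as(as(counts, "CsparseMatrix"), "generalMatrix")
  barcodes <- as.character(barcodes)
  if (is.character(genes)) genes <- data.frame(gene_id = genes, gene_symbol = genes)
  stopifnot(is.data.frame(genes), all(c("gene_id", "gene_symbol") %in% names(genes)))
  if (nrow(counts) != length(barcodes))
    stop("row count (", nrow(counts), ") != number of barcodes (", length(barcodes), ")")
  if (ncol(counts) != nrow(genes))
    stop("column count (", ncol(counts), ") != number of genes (", nrow(genes), ")")
  if (anyDuplicated(barcodes))
    stop("duplicate barcodes: ", paste(unique(barcodes[duplicated(barcodes)]), collapse = ", "))
  if (any(counts@x < 0)) stop("negative entries in count matrix")
  dimnames(counts) <- list(barcodes, genes$gene_id)
  structure(list(counts = counts, barcodes = barcodes, genes = genes),
            class = "expression_matrix")
}

#' @exportS3Method print expression_matrix
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression_matrix: %d cells x %d genes (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / max(1, prod(dim(x$counts)))))
  invisible(x)
}

#' @exportS3Method
dim.expression_matrix <- function(x) dim(x$counts)

# transparent gz/plain open for line-oriented reads
open_text <- function(path) {
  if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
}

find_10x_file <- function(directory, stem) {
  for (f in c(stem, paste0(stem, ".gz"))) {
    p <- file.path(directory, f)
    if (file.exists(p)) return(p)
  }
  stop("missing file in ", directory, ": expected ", stem, " or ", stem, ".gz")
}

#' Read a 10x-style MatrixMarket directory
#'
#' Reads the Cell Ranger v3 triplet `matrix.mtx`, `barcodes.tsv`,
#' `features.tsv` (gzipped or plain). Cell Ranger stores the matrix as
#' genes x cells; it is transposed on read so that cells are rows.
#'
#' @param directory path containing the three files.
#' @return An [expression_matrix()] with cells as rows.
#' @export
read_10x_mtx <- function(directory) {
  if (!dir.exists(directory)) stop("not a directory: ", directory)
  mtx_path <- find_10x_file(directory, "matrix.mtx")
  bc_path  <- find_10x_file(directory, "barcodes.tsv")
  ft_path  <- find_10x_file(directory, "features.tsv")

  con <- open_text(mtx_path)
  on.exit(close(con), add = TRUE)
  m <- Matrix::readMM(con)

  bc_con <- open_text(bc_path)
  on.exit(close(bc_con), add = TRUE)
  barcodes <- readLines(bc_con)

  ft_con <- open_text(ft_path)
  on.exit(close(ft_con), add = TRUE)
  feats <- read.delim(ft_con, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(feats) < 2) feats$V2 <- feats$V1
  genes <- data.frame(gene_id = feats[[1]], gene_symbol = feats[[2]],
                      stringsAsFactors = FALSE)

  if (nrow(m) != nrow(genes))
    stop("dimension mismatch: matrix.mtx declares ", nrow(m),
         " genes but features.tsv has ", nrow(genes), " rows")
  if (ncol(m) != length(barcodes))
    stop("dimension mismatch: matrix.mtx declares ", ncol(m),
         " cells but barcodes.tsv has ", length(barcodes), " rows")
  expression_matrix(Matrix::t(m), barcodes, genes)
}

#' Write an expression matrix as a 10x-style directory
#'
#' Inverse of [read_10x_mtx()]: writes `matrix.mtx` (genes x cells, the
#' Cell Ranger orientation), `barcodes.tsv` and `features.tsv`.
#'
#' @param x an [expression_matrix()].
#' @param directory output directory (created if absent).
#' @export
write_10x_mtx <- function(x, directory) {
  stopifnot(inherits(x, "expression_matrix"))
  dir.create(directory, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::t(x$counts), file.path(directory, "matrix.mtx"))
  writeLines(x$barcodes, file.path(directory, "barcodes.tsv"))
  write.table(data.frame(x$genes$gene_id, x$genes$gene_symbol, "Gene Expression"),
              file.path(directory, "features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(directory)
}

ANNOTATION_COLS <- c("barcode", "cell_type", "compartment", "origin", "doublet_flag")

#' Read a per-cell annotation table
#'
#' TSV with mandatory columns `barcode` and `cell_type`; optional
#' `compartment`, `origin` and `doublet_flag` are carried through, other
#' columns are ignored.
#'
#' @param path TSV path (gzip-transparent).
#' @return data.frame with columns barcode, cell_type, compartment,
#'   origin, doublet_flag (defaults: "unassigned", "unassigned", FALSE).
#' @export
read_annotations <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(c("barcode", "cell_type"), names(df))
  if (length(missing))
    stop("annotation table ", path, " lacks mandatory column(s): ",
         paste(missing, collapse = ", "))
  if (is.null(df$compartment)) df$compartment <- "unassigned"
  if (is.null(df$origin)) df$origin <- "unassigned"
  df$doublet_flag <- if (is.null(df$doublet_flag)) FALSE else
    as.logical(df$doublet_flag)
  df[, ANNOTATION_COLS]
}

#' Write pipeline results as a TSV annotation table
#'
#' Emits barcode, cell_type, compartment, origin and doublet_flag;
#' [read_annotations()] round-trips the output exactly.
#'
#' @param annotations data.frame in the [read_annotations()] layout.
#' @param path output TSV path.
#' @export
write_results <- function(annotations, path) {
  stopifnot(is.data.frame(annotations))
  for (col in setdiff(ANNOTATION_COLS, names(annotations))) {
    annotations[[col]] <- if (col == "doublet_flag") logical(nrow(annotations))
                          else rep("unassigned", nrow(annotations))
  }
  annotations$doublet_flag <- annotations$origin == "doublet" | annotations$doublet_flag
  out <- annotations[, ANNOTATION_COLS]
  ok <- tryCatch(
    write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE),
    error = function(e) stop("cannot write results to ", path, ": ",
                             conditionMessage(e)))
  invisible(path)
}

#' Construct an allele-count container
#'
#' @param ref_counts,alt_counts sparse nonnegative integer matrices,
#'   cells x variants, of reference- and alternate-allele read counts.
#' @param variants data.frame with columns chrom, pos (1-based, as in
#'   VCF), ref, alt, maf (population minor allele frequency in
#'   `[0, 0.5]`).
#' @param barcodes character vector of cell barcodes.
#' @return An object of class `allele_counts`.
#' @export
allele_counts <- function(ref_counts, alt_counts, variants, barcodes) {
  ref_counts <- as(as(ref_counts, "CsparseMatrix"), "generalMatrix")
  alt_counts <- as(as(alt_counts, "CsparseMatrix"), "generalMatrix")
  if (!identical(dim(ref_counts), dim(alt_counts)))
    stop("ref and alt count layers differ in shape")
  stopifnot(is.data.frame(variants),
            all(c("chrom", "pos", "ref", "alt", "maf") %in% names(variants)))
  if (nrow(ref_counts) != length(barcodes) || ncol(ref_counts) != nrow(variants))
    stop("count layer shape does not match barcodes x variants")
  if (any(ref_counts@x < 0) || any(alt_counts@x < 0))
    stop("negative allele counts")
  if (any(variants$maf < 0 | variants$maf > 0.5))
    stop("population MAF outside [0, 0.5]")
  vid <- paste0(variants$chrom, ":", variants$pos)
  dimnames(ref_counts) <- dimnames(alt_counts) <- list(barcodes, vid)
  structure(list(ref_counts = ref_counts, alt_counts = alt_counts,
                 variants = variants, barcodes = as.character(barcodes)),
            class = "allele_counts")
}

#' @exportS3Method print allele_counts
print.allele_counts <- function(x, ...) {
  depth <- sum(x$ref_counts@x) + sum(x$alt_counts@x)
  cat(sprintf("allele_counts: %d cells x %d variants, %d reads total\n",
              length(x$barcodes), nrow(x$variants), as.integer(depth)))
  invisible(x)
}

#' @exportS3Method
dim.allele_counts <- function(x) dim(x$ref_counts)

#' Read a long-format allele-count table
#'
#' TSV with columns barcode, chrom, pos, ref, alt, ref_count, alt_count,
#' maf — the landed form of an upstream bcftools/pileup extraction.
#' Rows are pivoted to sparse cells x variants layers; variants are
#' ordered by (chrom, pos); duplicate (barcode, variant) rows have their
#' counts summed.
#'
#' @param path TSV path (gzip-transparent).
#' @return An [allele_counts()] object.
#' @export
read_allele_counts <- function(path) {
  con <- open_text(path)
  on.exit(close(con))
  df <- read.delim(con, header = TRUE, stringsAsFactors = FALSE)
  need <- c("barcode", "chrom", "pos", "ref", "alt", "ref_count", "alt_count", "maf")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("allele-count table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(df$ref_count < 0 | df$alt_count < 0))
    stop("negative read counts in ", path)
  if (any(df$maf < 0 | df$maf > 0.5))
    stop("population MAF outside [0, 0.5] in ", path)

  vkey <- paste(df$chrom, df$pos, df$ref, df$alt, sep = "\t")
  vtab <- unique(data.frame(chrom = df$chrom, pos = df$pos, ref = df$ref,
                            alt = df$alt, maf = df$maf, key = vkey,
                            stringsAsFactors = FALSE))
  vtab <- vtab[order(vtab$chrom, vtab$pos), ]
  barcodes <- sort(unique(df$barcode))
  i <- match(df$barcode, barcodes)
  j <- match(vkey, vtab$key)
  dims <- c(length(barcodes), nrow(vtab))
  ref_m <- Matrix::sparseMatrix(i = i, j = j, x = df$ref_count, dims = dims)
  alt_m <- Matrix::sparseMatrix(i = i, j = j, x = df$alt_count, dims = dims)
  allele_counts(ref_m, alt_m, vtab[, c("chrom", "pos", "ref", "alt", "maf")],
                barcodes)
}

#' Write an allele-count object as a long-format TSV
#'
#' Inverse of [read_allele_counts()]; rows with zero coverage are not
#' written.
#'
#' @param x an [allele_counts()] object.
#' @param path output TSV path.
#' @export
write_allele_counts <- function(x, path) {
  stopifnot(inherits(x, "allele_counts"))
  rs <- Matrix::summary(x$ref_counts)
  al <- Matrix::summary(x$alt_counts)
  all_ij <- unique(rbind(rs[, 1:2], al[, 1:2]))
  ref_v <- x$ref_counts[cbind(all_ij$i, all_ij$j)]
  alt_v <- x$alt_counts[cbind(all_ij$i, all_ij$j)]
  df <- data.frame(barcode = x$barcodes[all_ij$i],
                   chrom = x$variants$chrom[all_ij$j],
                   pos = x$variants$pos[all_ij$j],
                   ref = x$variants$ref[all_ij$j],
                   alt = x$variants$alt[all_ij$j],
                   ref_count = ref_v, alt_count = alt_v,
                   maf = x$variants$maf[all_ij$j])
  df <- df[order(df$barcode, df$chrom, df$pos), ]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
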
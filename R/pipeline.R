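# Top-level orchestration: blood/tissue classification always, genotype
# demultiplexing optionally, merged into one annotation table plus a
# reproducibility manifest.

#' Run the full deconvolution pipeline
#'
#' Executes [classify_compartments()] on the query against the
#' whole-blood reference and, when allele counts are supplied,
#' [filter_snps()] + [fit_genotype_mixture()] + [call_doublets()] (and
#' [label_origins()] when an anchor type is configured). Results are
#' merged into one annotation table written with [write_results()],
#' together with a JSON run manifest recording the configuration and
#' seeds. Progress is logged to stderr; a rerun of the same config is
#' byte-identical.
#'
#' @param config named list (or path to a YAML/JSON file) with elements:
#'   `query`, `reference` (10x-style directories), `annotations` (TSV),
#'   optional `ref_annotations`, optional `allele_counts` (long TSV,
#'   enables the demux stage), `out_dir`, `seed` (default 1), and any
#'   of the stage parameters `cell_types`, `latent_dim`, `embed_method`,
#'   `k`, `min_cells`, `n_hvg`, `n_origins`, `max_maf`, `error_rate`,
#'   `doublet_rate`, `threshold`, `anchor_type`, `anchor_label`,
#'   `other_label`.
#' @param seed optional override of `config$seed`.
#' @return Invisibly, the merged annotation data.frame. Side effects:
#'   `results.tsv` and `manifest.json` in `out_dir`.
#' @export
run_pipeline <- function(config, seed = NULL) {
  if (is.character(config)) config <- read_config(config)
  stopifnot(is.list(config))
  for (key in c("query", "reference", "annotations", "out_dir"))
    if (is.null(config[[key]]))
      stop("config error: missing required key '", key, "'")
  if (!is.null(seed)) config$seed <- seed
  if (is.null(config$seed)) config$seed <- 1
  cfg <- function(key, default) if (is.null(config[[key]])) default else config[[key]]

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_msg <- function(...) message("[scorigins] ", ...)

  log_msg("reading query ", config$query)
  query <- read_10x_mtx(config$query)
  log_msg("reading reference ", config$reference)
  ref <- read_10x_mtx(config$reference)
  ann <- read_annotations(config$annotations)
  ref_ann <- if (!is.null(config$ref_annotations))
    read_annotations(config$ref_annotations) else NULL

  log_msg("blood/tissue classification (", nrow(query$counts), " cells)")
  fit <- withCallingHandlers(
    classify_compartments(
      query, ann, ref, ref_ann = ref_ann,
      cell_types = cfg("cell_types", DEFAULT_IMMUNE_TYPES),
      latent_dim = cfg("latent_dim", 10),
      embed_method = cfg("embed_method", "umap"),
      k = cfg("k", 2), seed = config$seed,
      min_cells = cfg("min_cells", 20), n_hvg = cfg("n_hvg", 2000)),
    warning = function(w) {
      log_msg("warning [blood_tissue]: ", conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  out <- ann[match(query$barcodes, ann$barcode), , drop = FALSE]
  out$compartment <- fit$calls$compartment
  out$origin <- "unassigned"
  out$doublet_flag <- FALSE

  if (!is.null(config$allele_counts)) {
    log_msg("genotype demultiplexing from ", config$allele_counts)
    ac <- read_allele_counts(config$allele_counts)
    ac <- filter_snps(ac, max_maf = cfg("max_maf", 10))
    log_msg(ncol(ac$ref_counts), " variants after MAF/coverage filter")
    model <- fit_genotype_mixture(
      ac, n_origins = cfg("n_origins", 2), seed = config$seed,
      error_rate = cfg("error_rate", 0.01),
      doublet_rate = cfg("doublet_rate", 0.05))
    calls <- call_doublets(ac, model, threshold = cfg("threshold", 0.8))
    if (!is.null(config$anchor_type)) {
      calls <- label_origins(calls, ann, config$anchor_type,
                             anchor_label = cfg("anchor_label", "fetal"),
                             other_label = cfg("other_label", "maternal"))
      origin_col <- calls$origin_label
    } else {
      origin_col <- calls$call
    }
    idx <- match(out$barcode, calls$barcode)
    hit <- !is.na(idx)
    out$origin[hit] <- origin_col[idx[hit]]
    out$doublet_flag[hit] <- calls$call[idx[hit]] == "doublet"
  }

  results_path <- file.path(config$out_dir, "results.tsv")
  write_results(out, results_path)
  manifest <- list(package = "scorigins",
                   version = as.character(packageVersion("scorigins")),
                   seed = config$seed,
                   config = config[order(names(config))])
  writeLines(to_json(manifest), file.path(config$out_dir, "manifest.json"))
  log_msg("wrote ", results_path)
  invisible(out)
}

read_config <- function(path) {
  if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package")
    yaml::read_yaml(path)
  } else if (grepl("\\.json$", path)) {
    if (!requireNamespace("jsonlite", quietly = TRUE))
      stop("reading JSON configs requires the jsonlite package")
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else stop("config must be a .yaml or .json file: ", path)
}

# minimal dependency-free JSON writer for the manifest (scalars, vectors,
# named lists); deterministic output
to_json <- function(x, indent = "") {
  esc <- function(s) gsub('"', '\\\\"', s)
  if (is.list(x)) {
    if (length(x) == 0) return("{}")
    items <- vapply(names(x), function(nm)
      paste0(indent, '  "', esc(nm), '": ',
             to_json(x[[nm]], paste0(indent, "  "))), character(1))
    paste0("{\n", paste(items, collapse = ",\n"), "\n", indent, "}")
  } else if (length(x) == 1) {
    if (is.character(x)) paste0('"', esc(x), '"')
    else if (is.logical(x)) tolower(as.character(x))
    else format(x, digits = 15)
  } else {
    paste0("[", paste(vapply(x, to_json, character(1)), collapse = ", "), "]")
  }
}
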
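# Evaluation metrics (AUC, F1, AUCPR) and the replicated benchmark
# harness used to assess the pipeline on synthetic mixtures.

as_binary <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(labels == 1)
  }
  stop("labels must be logical or 0/1 numeric")
}

#' Rank-based (Mann-Whitney) AUC
#'
#' Area under the ROC curve computed from ranks; tied scores receive
#' midranks.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or 0/1 vector; both classes must be present.
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels) {
  labels <- as_binary(labels)
  stopifnot(length(scores) == length(labels))
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0)
    stop("AUC requires both classes present (", n1, " positives, ",
         n0, " negatives)")
  r <- rank(scores)                # midranks for ties
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' F score of a hard classification
#'
#' F1 = 2PR / (P + R). When there are no predicted positives or no true
#' positives at all (P + R undefined or zero), returns 0 with a
#' warning.
#'
#' @param pred,truth label vectors of equal length.
#' @param positive_class the label counted as positive.
#' @return F1 in `[0, 1]`.
#' @export
f_score <- function(pred, truth, positive_class) {
  stopifnot(length(pred) == length(truth))
  tp <- sum(pred == positive_class & truth == positive_class)
  fp <- sum(pred == positive_class & truth != positive_class)
  fn <- sum(pred != positive_class & truth == positive_class)
  if (tp == 0) {
    warning("precision + recall is zero for class '", positive_class,
            "'; F = 0")
    return(0)
  }
  p <- tp / (tp + fp); r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

#' Macro-averaged F score over all classes in the truth
#'
#' @param pred,truth label vectors.
#' @return Mean of per-class [f_score()] over `unique(truth)`.
#' @export
macro_f1 <- function(pred, truth) {
  classes <- sort(unique(truth))
  mean(vapply(classes, function(cl) f_score(pred, truth, cl), numeric(1)))
}

#' Area under the precision-recall curve
#'
#' Step-wise summation over descending score thresholds (the average
#' precision estimator): sum over thresholds of
#' (recall step) x (precision at that threshold). Tied scores form a
#' single threshold. With all-identical scores this equals the
#' prevalence.
#'
#' @param scores numeric scores, higher = more positive.
#' @param labels logical or 0/1 vector; positives must be present.
#' @return AUCPR in `[0, 1]`.
#' @export
aucpr <- function(scores, labels) {
  labels <- as_binary(labels)
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels)
  if (n_pos == 0) stop("AUCPR requires at least one positive")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  # threshold group ends = last index of each distinct score
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE))
  tp <- cumsum(y)[grp_end]
  n_at <- grp_end
  precision <- tp / n_at
  recall <- tp / n_pos
  sum(diff(c(0, recall)) * precision)
}

#' Run a pipeline over replicated synthetic datasets
#'
#' Mirrors the five-iteration evaluation protocol: the pipeline is run
#' on `n_reps` independently seeded synthetic datasets and per-replicate
#' metrics are collected in a long table.
#'
#' @param pipeline_fn function(seed) returning a named numeric vector
#'   of metrics, or a data.frame with columns metric, value and
#'   optionally cell_type.
#' @param n_reps number of replicates (default 5).
#' @param seeds integer seeds, one per replicate (default `1:n_reps`).
#' @return data.frame with columns rep, seed, metric, cell_type, value;
#'   rows with `rep == 0` hold the across-replicate means.
#' @export
benchmark_pipeline <- function(pipeline_fn, n_reps = 5,
                               seeds = seq_len(n_reps)) {
  stopifnot(length(seeds) == n_reps)
  rows <- vector("list", n_reps)
  for (i in seq_len(n_reps)) {
    res <- tryCatch(pipeline_fn(seeds[i]), error = function(e)
      stop("replicate ", i, " (seed ", seeds[i], ") failed: ",
           conditionMessage(e)))
    if (is.data.frame(res)) {
      if (is.null(res$cell_type)) res$cell_type <- NA_character_
      rows[[i]] <- data.frame(rep = i, seed = seeds[i],
                              metric = res$metric,
                              cell_type = res$cell_type,
                              value = res$value,
                              stringsAsFactors = FALSE)
    } else {
      rows[[i]] <- data.frame(rep = i, seed = seeds[i],
                              metric = names(res),
                              cell_type = NA_character_,
                              value = as.numeric(res),
                              stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  ct <- ifelse(is.na(tab$cell_type), "", tab$cell_type)  # keep NA groups
  means <- aggregate(tab$value, by = list(metric = tab$metric,
                                          cell_type = ct), FUN = mean)
  means <- data.frame(rep = 0L, seed = NA_integer_, metric = means$metric,
                      cell_type = ifelse(means$cell_type == "",
                                         NA_character_, means$cell_type),
                      value = means$x, stringsAsFactors = FALSE)
  rbind(tab, means)
}
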
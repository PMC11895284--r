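# Genotype-based demultiplexing: a freemuxlet-like binomial
# genotype-mixture model fitted by EM on ref/alt allele counts at
# population-rare SNPs, with mosaic-doublet detection.

#' Filter SNPs by population minor allele frequency and coverage
#'
#' Variants informative of genetic origin are the population-rare ones:
#' SNPs with MAF greater than `max_maf` percent are excluded (the
#' boundary is kept: MAF equal to the threshold is retained). Variants
#' with zero read coverage across all cells are also dropped.
#'
#' @param a an [allele_counts()] object.
#' @param max_maf threshold in percent (default 10).
#' @return A filtered `allele_counts` object.
#' @export
filter_snps <- function(a, max_maf = 10) {
  stopifnot(inherits(a, "allele_counts"))
  cover <- Matrix::colSums(a$ref_counts) + Matrix::colSums(a$alt_counts)
  keep <- a$variants$maf <= max_maf / 100 & cover > 0
  if (!any(keep))
    stop("no variants survive MAF <= ", max_maf,
         "% with nonzero coverage; consider raising max_maf")
  allele_counts(a$ref_counts[, keep, drop = FALSE],
                a$alt_counts[, keep, drop = FALSE],
                a$variants[keep, , drop = FALSE], a$barcodes)
}

#' Binomial read-model log-likelihood of one cell under one genotype
#'
#' With alternate-allele dosage d and sequencing error rate e, each read
#' at a variant is alternate with probability p = d(1-e) + (1-d)e. The
#' log-likelihood is the sum over variants of
#' `alt*log(p) + ref*log(1-p)`; uncovered variants contribute 0.
#'
#' @param ref,alt integer read-count vectors over the same variants.
#' @param dosage alternate-allele dosage vector (values in
#'   `{0, 0.25, 0.5, 0.75, 1}` — doublet profiles are pair averages).
#' @param error_rate e in (0, 0.5), default 0.01.
#' @return Scalar log-likelihood.
#' @export
cell_loglik <- function(ref, alt, dosage, error_rate = 0.01) {
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  stopifnot(length(ref) == length(alt), length(ref) == length(dosage))
  p <- dosage * (1 - error_rate) + (1 - dosage) * error_rate
  sum(alt * log(p) + ref * log(1 - p))
}

# cells x genotypes log-likelihood matrix; dosages is genotypes x variants
loglik_matrix <- function(a, dosages, error_rate) {
  p <- dosages * (1 - error_rate) + (1 - dosages) * error_rate
  as.matrix(a$alt_counts %*% t(log(p)) + a$ref_counts %*% t(log(1 - p)))
}

logsumexp <- function(m) {
  mx <- apply(m, 1, max)
  mx + log(rowSums(exp(m - mx)))
}

#' Fit a genotype-mixture model to allele counts by EM
#'
#' Models each cell as drawn from one of `n_origins` diploid genotypes
#' with per-variant alternate-allele dosage in `{0, 0.5, 1}` and a
#' binomial read model with fixed error rate ([cell_loglik()]). EM
#' alternates responsibilities (E) with exhaustive per-variant dosage
#' maximization and mixing-weight updates (M). Initialization is k-means
#' on per-cell alternate-allele-fraction vectors, with uncovered
#' variants imputed at the population MAF. The observed-data
#' log-likelihood is checked to be non-decreasing at every iteration.
#'
#' @param a an [allele_counts()] object (typically after
#'   [filter_snps()]).
#' @param n_origins number of genetic origins N (default 2).
#' @param seed integer seed for the k-means initialization.
#' @param max_iter,tol EM stopping rule: stop when the total
#'   log-likelihood improves by less than `tol` or after `max_iter`
#'   iterations.
#' @param error_rate fixed sequencing error rate (default 0.01).
#' @param doublet_rate prior doublet proportion carried into
#'   [call_doublets()] (default 0.05).
#' @param init optional integer vector in `1:n_origins` (one per cell)
#'   overriding the k-means initialization.
#' @return Object of class `genotype_mixture`: dosages
#'   (n_origins x variants), mix_weights, responsibilities
#'   (cells x origins), loglik trace, converged flag, plus the model
#'   constants. Methods: [print()], [summary()], [coef()] (dosage
#'   matrix), [logLik()], [predict()] (posterior origin/doublet calls).
#' @export
fit_genotype_mixture <- function(a, n_origins = 2, seed = 1, max_iter = 100,
                                 tol = 1e-6, error_rate = 0.01,
                                 doublet_rate = 0.05, init = NULL) {
  stopifnot(inherits(a, "allele_counts"))
  if (n_origins < 1) stop("n_origins must be >= 1")
  if (error_rate <= 0 || error_rate >= 0.5)
    stop("error_rate must lie in (0, 0.5)")
  n_cells <- length(a$barcodes); n_var <- nrow(a$variants)
  dosage_levels <- c(0, 0.5, 1)

  # --- initialization: k-means on alt-fraction vectors ---
  depth <- a$ref_counts + a$alt_counts
  af <- as.matrix(a$alt_counts) / pmax(as.matrix(depth), 1)
  no_cov <- as.matrix(depth) == 0
  af[no_cov] <- matrix(a$variants$maf, n_cells, n_var, byrow = TRUE)[no_cov]
  if (is.null(init)) {
    if (n_origins == 1) {
      init <- rep(1L, n_cells)
    } else {
      set.seed(seed)
      init <- tryCatch(
        stats::kmeans(af, centers = n_origins, nstart = 10,
                      iter.max = 50)$cluster,
        error = function(e) ((seq_len(n_cells) - 1L) %% n_origins) + 1L)
    }
  }
  stopifnot(length(init) == n_cells)
  resp <- matrix(0, n_cells, n_origins)
  resp[cbind(seq_len(n_cells), init)] <- 1

  m_step_dosages <- function(resp) {
    # responsibility-weighted alt/ref totals per origin and variant
    A <- as.matrix(Matrix::crossprod(a$alt_counts, resp))   # var x k
    R <- as.matrix(Matrix::crossprod(a$ref_counts, resp))
    dos <- matrix(0, n_origins, n_var)
    scores <- array(0, c(n_var, n_origins, length(dosage_levels)))
    for (di in seq_along(dosage_levels)) {
      p <- dosage_levels[di] * (1 - error_rate) +
        (1 - dosage_levels[di]) * error_rate
      scores[, , di] <- A * log(p) + R * log(1 - p)
    }
    for (k in seq_len(n_origins)) {
      s <- matrix(scores[, k, ], n_var, length(dosage_levels))
      # ties broken toward the smaller dosage (deterministic)
      dos[k, ] <- dosage_levels[max.col(s, ties.method = "first")]
    }
    dos
  }

  dosages <- m_step_dosages(resp)
  weights <- colMeans(resp)
  weights <- pmax(weights, 1e-12); weights <- weights / sum(weights)

  ll_trace <- numeric(0)
  converged <- FALSE
  ll_prev <- -Inf
  for (iter in seq_len(max_iter)) {
    # E-step
    L <- loglik_matrix(a, dosages, error_rate)
    lw <- sweep(L, 2, log(weights), "+")
    lse <- logsumexp(lw)
    resp <- exp(lw - lse)
    ll <- sum(lse)
    if (ll < ll_prev - 1e-9 * (1 + abs(ll_prev)))
      stop("EM log-likelihood decreased (", ll_prev, " -> ", ll, ")")
    ll_trace <- c(ll_trace, ll)
    if (is.finite(ll_prev) && ll - ll_prev < tol) {
      converged <- TRUE
      break
    }
    ll_prev <- ll
    # M-step
    dosages <- m_step_dosages(resp)
    weights <- colMeans(resp)
    weights <- pmax(weights, 1e-12); weights <- weights / sum(weights)
  }
  if (!converged)
    warning("EM did not converge in ", max_iter, " iterations")

  structure(list(dosages = dosages, mix_weights = weights,
                 error_rate = error_rate, doublet_rate = doublet_rate,
                 responsibilities = `rownames<-`(resp, a$barcodes),
                 loglik = ll_trace, converged = converged,
                 n_iter = length(ll_trace), n_origins = n_origins,
                 variants = a$variants, barcodes = a$barcodes,
                 counts = a, seed = seed),
            class = "genotype_mixture")
}

#' @exportS3Method print genotype_mixture
print.genotype_mixture <- function(x, ...) {
  cat(sprintf("genotype_mixture: %d origins, %d variants, %d cells\n",
              x$n_origins, ncol(x$dosages), length(x$barcodes)))
  cat(sprintf("  mixing weights: %s\n",
              paste(sprintf("%.3f", x$mix_weights), collapse = ", ")))
  cat(sprintf("  log-likelihood %.2f after %d EM iterations (%s)\n",
              x$loglik[length(x$loglik)], x$n_iter,
              if (x$converged) "converged" else "not converged"))
  invisible(x)
}

#' @exportS3Method summary genotype_mixture
summary.genotype_mixture <- function(object, ...) {
  hard <- max.col(object$responsibilities, ties.method = "first") - 1L
  discord <- if (object$n_origins >= 2)
    mean(apply(object$dosages, 2, function(v) length(unique(v)) > 1))
  else 0
  out <- list(n_origins = object$n_origins,
              n_cells = length(object$barcodes),
              n_variants = ncol(object$dosages),
              mix_weights = object$mix_weights,
              assignments = table(origin = hard),
              frac_discriminating_variants = discord,
              logLik = object$loglik[length(object$loglik)],
              converged = object$converged)
  class(out) <- "summary.genotype_mixture"
  out
}

#' @exportS3Method print summary.genotype_mixture
print.summary.genotype_mixture <- function(x, ...) {
  cat("Genotype mixture model fit\n")
  cat(sprintf("  %d cells, %d variants, N = %d origins\n",
              x$n_cells, x$n_variants, x$n_origins))
  cat(sprintf("  mixing weights: %s\n",
              paste(sprintf("%.3f", x$mix_weights), collapse = ", ")))
  cat(sprintf("  discriminating variants: %.1f%%\n",
              100 * x$frac_discriminating_variants))
  cat(sprintf("  log-likelihood: %.2f (%s)\n", x$logLik,
              if (x$converged) "converged" else "not converged"))
  print(x$assignments)
  invisible(x)
}

#' @exportS3Method
coef.genotype_mixture <- function(object, ...) object$dosages

#' @exportS3Method
logLik.genotype_mixture <- function(object, ...) {
  val <- object$loglik[length(object$loglik)]
  # free parameters: dosage per origin x variant + (N - 1) weights
  attr(val, "df") <- length(object$dosages) + object$n_origins - 1
  attr(val, "nobs") <- length(object$barcodes)
  class(val) <- "logLik"
  val
}

#' Posterior origin and doublet calls from a fitted mixture
#'
#' @param object a `genotype_mixture`.
#' @param newdata optional [allele_counts()] over the same variants
#'   (default: the training counts).
#' @param type `"call"` for the call table, `"posterior"` for the full
#'   posterior matrix.
#' @param threshold confidence threshold passed to [call_doublets()].
#' @param ... unused.
#' @export
predict.genotype_mixture <- function(object, newdata = NULL,
                                     type = c("call", "posterior"),
                                     threshold = 0.8, ...) {
  type <- match.arg(type)
  res <- call_doublets(if (is.null(newdata)) object$counts else newdata,
                       object, threshold = threshold)
  if (type == "call") res else attr(res, "posterior")
}

#' Call singlet origins, mosaic doublets and ambiguous cells
#'
#' For each cell, likelihoods are computed under every singlet origin
#' and every unordered origin pair, a pair's dosage profile being the
#' average of its two members (a mosaic doublet is a 50/50 genetic
#' mixture of two individuals). The doublet prior is split evenly over
#' pairs and `1 - doublet_rate` over singlets by mixing weight; the
#' posterior is normalized per cell and the argmax category is called
#' when its posterior reaches `threshold`, otherwise `ambiguous`.
#'
#' @param a an [allele_counts()] object over the model's variants.
#' @param m a fitted `genotype_mixture` with at least 2 origins.
#' @param threshold posterior confidence threshold (default 0.8).
#' @return data.frame of class `demux_calls` with columns barcode, call
#'   (`"0"`..`"N-1"`, `"doublet"`, `"ambiguous"`), posterior_max,
#'   doublet_posterior, log_likelihood; full posterior matrix in
#'   `attr(, "posterior")`.
#' @export
call_doublets <- function(a, m, threshold = 0.8) {
  stopifnot(inherits(a, "allele_counts"), inherits(m, "genotype_mixture"))
  N <- m$n_origins
  if (N < 2) stop("doublet calling requires at least 2 origins")
  if (ncol(a$ref_counts) != ncol(m$dosages))
    stop("allele counts cover ", ncol(a$ref_counts),
         " variants but the model has ", ncol(m$dosages))
  pairs <- utils::combn(N, 2)
  pair_dos <- t(apply(pairs, 2, function(jk)
    colMeans(m$dosages[jk, , drop = FALSE])))
  all_dos <- rbind(m$dosages, pair_dos)
  n_pair <- ncol(pairs)
  log_prior <- c(log1p(-m$doublet_rate) + log(m$mix_weights),
                 rep(log(m$doublet_rate) - log(n_pair), n_pair))

  L <- loglik_matrix(a, all_dos, m$error_rate)
  lp <- sweep(L, 2, log_prior, "+")
  lse <- logsumexp(lp)
  post <- exp(lp - lse)
  colnames(post) <- c(as.character(0:(N - 1)),
                      apply(pairs, 2, function(jk)
                        paste0("doublet_", jk[1] - 1, "_", jk[2] - 1)))

  best <- max.col(post, ties.method = "first")
  best_p <- post[cbind(seq_len(nrow(post)), best)]
  call <- ifelse(best <= N, as.character(best - 1L), "doublet")
  call[best_p < threshold] <- "ambiguous"
  out <- data.frame(barcode = a$barcodes, call = call,
                    posterior_max = best_p,
                    doublet_posterior = rowSums(post[, N + seq_len(n_pair),
                                                     drop = FALSE]),
                    log_likelihood = lse,
                    stringsAsFactors = FALSE)
  attr(out, "posterior") <- post
  class(out) <- c("demux_calls", class(out))
  out
}

#' Map genetic origin indices to biological labels via an anchor type
#'
#' A cell type of known origin (for example trophoblasts, which are
#' fetal) anchors the labelling: the origin index holding the majority
#' of the anchor type's singlet cells receives `anchor_label`, the other
#' receives `other_label`. Doublet and ambiguous cells are untouched.
#' Requires N = 2.
#'
#' @param results a `demux_calls` table from [call_doublets()].
#' @param ann annotation data.frame with barcode and cell_type.
#' @param anchor_type cell type of known origin (e.g. "trophoblast").
#' @param anchor_label label for the anchor's origin (e.g. "fetal").
#' @param other_label label for the other origin (e.g. "maternal").
#' @return `results` with an added `origin_label` column.
#' @export
label_origins <- function(results, ann, anchor_type,
                          anchor_label = "fetal", other_label = "maternal") {
  stopifnot(is.data.frame(results), is.data.frame(ann))
  singlets <- results$call %in% c("0", "1")
  if (any(results$call %in% as.character(2:100)))
    stop("origin labelling via an anchor type requires N = 2")
  ct <- ann$cell_type[match(results$barcode, ann$barcode)]
  anchors <- which(singlets & ct == anchor_type)
  if (length(anchors) == 0)
    stop("anchor cell type '", anchor_type,
         "' absent among confidently assigned singlets")
  n1 <- sum(results$call[anchors] == "1")
  n0 <- length(anchors) - n1
  if (n0 == n1)
    stop("anchor cells split exactly ", n0, "/", n1,
         " between origins; assign labels manually")
  anchor_origin <- if (n1 > n0) "1" else "0"
  lab <- c("0" = other_label, "1" = other_label)
  lab[anchor_origin] <- anchor_label
  results$origin_label <- ifelse(results$call %in% c("0", "1"),
                                 lab[results$call], results$call)
  results
}
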
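test_that("filter_snps keeps the MAF boundary and drops uncovered variants", {
  ref <- rbind(c(1, 1, 1, 1), c(0, 2, 1, 0))
  alt <- rbind(c(0, 1, 0, 1), c(1, 0, 0, 2))
  ac <- toy_allele_counts(ref, alt, maf = c(0.01, 0.09, 0.10, 0.25))
  kept <- filter_snps(ac, max_maf = 10)
  expect_equal(kept$variants$maf, c(0.01, 0.09, 0.10))   # boundary inclusive
  expect_equal(ncol(filter_snps(ac, max_maf = 50)$ref_counts), 4)

  # covered nowhere -> dropped even at low MAF
  ref2 <- rbind(c(1, 0), c(2, 0)); alt2 <- rbind(c(0, 0), c(1, 0))
  ac2 <- toy_allele_counts(ref2, alt2, maf = c(0.05, 0.05))
  expect_equal(ncol(filter_snps(ac2)$ref_counts), 1)

  expect_error(filter_snps(toy_allele_counts(ref, alt,
                                             maf = rep(0.4, 4)), 10),
               "max_maf")
})

test_that("cell_loglik matches closed forms and validates error_rate", {
  expect_equal(cell_loglik(0, 1, 1, error_rate = 0.01), log(0.99))
  expect_equal(cell_loglik(1, 1, 0.5, error_rate = 0.01), 2 * log(0.5))
  expect_equal(cell_loglik(1, 1, 0.5, error_rate = 0.3), 2 * log(0.5))
  expect_equal(cell_loglik(c(0, 2), c(0, 0), c(1, 0), error_rate = 0.01),
               2 * log(0.99))   # zero-coverage variant contributes 0
  expect_error(cell_loglik(1, 1, 0.5, error_rate = 0), "error_rate")
  expect_error(cell_loglik(1, 1, 0.5, error_rate = 0.6), "error_rate")
})

test_that("cell_loglik equals the per-read brute-force product", {
  set.seed(31)
  for (rep in 1:10) {
    v <- sample(1:8, 1)
    ref <- rpois(v, 2); alt <- rpois(v, 2)
    while (sum(ref) + sum(alt) > 50) { ref <- rpois(v, 2); alt <- rpois(v, 2) }
    d <- sample(c(0, 0.5, 1), v, replace = TRUE)
    e <- runif(1, 0.005, 0.4)
    expect_equal(cell_loglik(ref, alt, d, e),
                 brute_cell_loglik(ref, alt, d, e), tolerance = 1e-12)
  }
})

test_that("single-origin fit degenerates to the pooled dosage argmax", {
  set.seed(32)
  sim <- simulate_allele_counts(n_origins = 1, n_cells = 30, n_snps = 40,
                                coverage = 3, doublet_rate = 0, seed = 32)
  fit <- fit_genotype_mixture(sim$counts, n_origins = 1, seed = 1)
  expect_equal(as.numeric(fit$responsibilities), rep(1, 30))
  # oracle: per variant, the dosage maximizing the pooled log-likelihood
  pooled_alt <- Matrix::colSums(sim$counts$alt_counts)
  pooled_ref <- Matrix::colSums(sim$counts$ref_counts)
  oracle <- vapply(seq_along(pooled_alt), function(v) {
    lls <- vapply(c(0, 0.5, 1), function(d) {
      p <- d * 0.99 + (1 - d) * 0.01
      pooled_alt[v] * log(p) + pooled_ref[v] * log(1 - p)
    }, numeric(1))
    c(0, 0.5, 1)[which.max(lls)]
  }, numeric(1))
  expect_equal(as.numeric(fit$dosages), oracle)
})

test_that("EM log-likelihood is monotone and posteriors are normalized", {
  set.seed(33)
  for (rep in 1:5) {
    sim <- simulate_allele_counts(n_origins = 2, n_cells = 25, n_snps = 30,
                                  coverage = 1.5, seed = 33 + rep)
    fit <- fit_genotype_mixture(sim$counts, n_origins = 2, seed = rep)
    expect_true(all(diff(fit$loglik) >= -1e-9 * (1 + abs(fit$loglik[-1]))))
    expect_equal(rowSums(fit$responsibilities), rep(1, 25),
                 tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("the fit is a function of the empirical distribution (sufficiency)", {
  sim <- simulate_allele_counts(n_cells = 40, n_snps = 60, seed = 34)
  ac <- filter_snps(sim$counts)
  doubled <- allele_counts(rbind(ac$ref_counts, ac$ref_counts),
                           rbind(ac$alt_counts, ac$alt_counts),
                           ac$variants,
                           c(ac$barcodes, paste0(ac$barcodes, "_dup")))
  f1 <- fit_genotype_mixture(ac, seed = 1)
  f2 <- fit_genotype_mixture(doubled, seed = 1)
  # same dosage matrix up to origin relabelling
  direct <- identical(f1$dosages, f2$dosages)
  flipped <- identical(f1$dosages, f2$dosages[2:1, , drop = FALSE])
  expect_true(direct || flipped)
})

test_that("permuting the initialization permutes the fitted origins", {
  sim <- simulate_allele_counts(n_cells = 40, n_snps = 60, seed = 35)
  ac <- filter_snps(sim$counts)
  init <- ((seq_len(40) - 1L) %% 2L) + 1L
  f1 <- fit_genotype_mixture(ac, seed = 1, init = init)
  f2 <- fit_genotype_mixture(ac, seed = 1, init = 3L - init)
  expect_equal(f1$dosages, f2$dosages[2:1, , drop = FALSE])
  expect_equal(f1$mix_weights, f2$mix_weights[2:1], tolerance = 1e-12)
  expect_equal(unname(f1$responsibilities),
               unname(f2$responsibilities[, 2:1]), tolerance = 1e-9)
})

test_that("two-origin mixtures are recovered up to label permutation", {
  sim <- simulate_allele_counts(n_cells = 100, n_snps = 200, coverage = 2,
                                doublet_rate = 0, seed = 36)
  ac <- filter_snps(sim$counts)
  fit <- fit_genotype_mixture(ac, seed = 1)
  hard <- max.col(fit$responsibilities, ties.method = "first") - 1L
  acc <- function(perm) mean(hard == perm[sim$truth$origin + 1])
  expect_gte(max(acc(c(0, 1)), acc(c(1, 0))), 0.98)
})

test_that("call_doublets handles no-information and high-coverage cells", {
  dos <- rbind(rep(0, 50), rep(1, 50))
  m <- toy_model(dos, weights = c(0.5, 0.5))
  # zero coverage everywhere: posterior equals the prior, call ambiguous
  z <- matrix(0, 1, 50)
  ac0 <- toy_allele_counts(z, z, maf = rep(0.05, 50), barcodes = "empty")
  res0 <- call_doublets(ac0, m)
  expect_equal(res0$call, "ambiguous")
  post <- attr(res0, "posterior")
  expect_equal(as.numeric(post),
               c(0.95 * 0.5, 0.95 * 0.5, 0.05), tolerance = 1e-12)

  # pure origin-0 cell at high coverage
  ref <- matrix(4, 1, 50); alt <- matrix(0, 1, 50)
  res1 <- call_doublets(toy_allele_counts(ref, alt, rep(0.05, 50)), m)
  expect_equal(res1$call, "0")
  expect_gt(res1$posterior_max, 0.99)

  expect_error(call_doublets(ac0, toy_model(matrix(0, 1, 50))), "2 origins")
})

test_that("a 50/50 mosaic doublet at coverage 4 is called doublet", {
  set.seed(37)
  dos <- rbind(rep(0, 100), rep(1, 100))  # 100 discriminating SNPs
  m <- toy_model(dos, weights = c(0.5, 0.5))
  depth <- rpois(100, 4)
  alt <- rbinom(100, depth, 0.5 * 0.99 + 0.5 * 0.01)
  ac <- toy_allele_counts(matrix(depth - alt, 1), matrix(alt, 1),
                          rep(0.05, 100))
  res <- call_doublets(ac, m)
  expect_equal(res$call, "doublet")
  expect_gt(res$doublet_posterior, 0.99)
})

test_that("posterior rows always sum to one", {
  sim <- simulate_allele_counts(n_cells = 50, n_snps = 80, seed = 38)
  ac <- filter_snps(sim$counts)
  fit <- fit_genotype_mixture(ac, seed = 1)
  res <- call_doublets(ac, fit)
  expect_equal(rowSums(attr(res, "posterior")), rep(1, 50),
               tolerance = 1e-9, ignore_attr = TRUE)
})

test_that("label_origins follows the anchor majority and rejects ties", {
  results <- data.frame(
    barcode = sprintf("c%d", 1:10),
    call = c("1", "1", "1", "1", "0", "0", "1", "doublet", "ambiguous", "0"),
    stringsAsFactors = FALSE)
  ann <- data.frame(
    barcode = sprintf("c%d", 1:10),
    cell_type = c(rep("trophoblast", 4), "T-cell", "trophoblast", "T-cell",
                  "trophoblast", "trophoblast", "T-cell"),
    stringsAsFactors = FALSE)
  lab <- label_origins(results, ann, "trophoblast", "fetal", "maternal")
  # 4 of 5 singlet trophoblasts in origin 1 -> origin 1 = fetal
  expect_equal(lab$origin_label[lab$call == "1"],
               rep("fetal", sum(lab$call == "1")))
  expect_equal(lab$origin_label[lab$call == "0"],
               rep("maternal", sum(lab$call == "0")))
  expect_equal(lab$origin_label[8:9], c("doublet", "ambiguous"))

  expect_error(label_origins(results, ann, "hepatocyte"), "absent")

  tie <- results
  tie$call <- rep(c("0", "1"), 5)
  ann_all <- ann; ann_all$cell_type <- "trophoblast"
  expect_error(label_origins(tie, ann_all, "trophoblast"), "manual")
})
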
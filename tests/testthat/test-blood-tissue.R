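test_that("distance_profiles computes Euclidean distances exactly", {
  q <- toy_embedding(rbind(c(0, 0)))
  r <- toy_embedding(rbind(c(3, 4), c(0, 0)))
  p <- distance_profiles(q, r)
  expect_equal(as.numeric(p$dist), c(5, 0))

  e <- toy_embedding(matrix(rnorm(10), 5, 2))
  self <- distance_profiles(e, e)
  expect_equal(unname(diag(self$dist)), rep(0, 5))

  bad <- toy_embedding(matrix(0, 2, 3))
  expect_error(distance_profiles(q, bad), "dimension mismatch")
})

test_that("distance_profiles matches the brute-force double loop", {
  set.seed(21)
  for (rep in 1:3) {
    a <- matrix(rnorm(10 * 4), 10, 4)
    b <- matrix(rnorm(8 * 4), 8, 4)
    p <- distance_profiles(toy_embedding(a), toy_embedding(b))
    expect_equal(p$dist, brute_distances(a, b), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
})

test_that("cluster_profiles recovers the SSE-optimal 2-partition", {
  rows <- rbind(c(0.1, 0.2), c(0.15, 0.25), c(9, 9.1), c(9.2, 9.0))
  p <- toy_profile(rows)
  labels <- cluster_profiles(p, k = 2, seed = 1)
  expect_setequal(unique(labels), c(0L, 1L))
  # oracle: exhaustive minimization of within-cluster sum of squares
  oracle <- brute_best_bipartition(rows)
  expect_true(all(labels[oracle] == labels[oracle][1]) &&
              all(labels[!oracle] == labels[!oracle][1]) &&
              labels[oracle][1] != labels[!oracle][1])
  expect_equal(sort(table(labels)), sort(c(2, 2)), ignore_attr = TRUE)
})

test_that("cluster_profiles handles degenerate inputs as documented", {
  ident <- toy_profile(matrix(1, 4, 2))
  expect_warning(lab <- cluster_profiles(ident, k = 2, seed = 1), "distinct")
  expect_equal(lab, rep(0L, 4))

  p <- toy_profile(matrix(rnorm(6), 3, 2))
  expect_equal(cluster_profiles(p, k = 1), rep(0L, 3))
  expect_warning(lab2 <- cluster_profiles(toy_profile(matrix(1:2, 1, 2)),
                                          k = 2), "query cells")
  expect_equal(lab2, 0L)
})

test_that("label_compartments assigns blood to the reference-proximal cluster", {
  p <- toy_profile(rbind(c(1, 1), c(1.2, 1.2), c(8, 8), c(9, 9)))
  calls <- label_compartments(p, c(0L, 0L, 1L, 1L))
  expect_equal(calls$compartment, c("blood", "blood", "tissue", "tissue"))
  expect_equal(calls$mean_ref_distance, c(1, 1.2, 8, 9))
  # blood cluster mean <= tissue cluster mean, by construction
  expect_lte(mean(calls$mean_ref_distance[calls$compartment == "blood"]),
             mean(calls$mean_ref_distance[calls$compartment == "tissue"]))
})

test_that("label_compartments ties and single clusters warn as documented", {
  tie <- toy_profile(rbind(c(2, 2), c(4, 4), c(1, 1), c(5, 5)))
  # clusters {1,2} and {3,4} both have mean row-mean 3
  expect_warning(calls <- label_compartments(tie, c(0L, 0L, 1L, 1L)), "tie")
  expect_equal(calls$compartment[1:2], c("blood", "blood"))

  single <- toy_profile(matrix(1, 3, 2))
  expect_warning(calls2 <- label_compartments(single, rep(0L, 3)),
                 "single cluster")
  expect_equal(calls2$compartment, rep("blood", 3))
})

test_that("classify_compartments recovers a planted blood/tissue shift", {
  sim <- simulate_expression(n_cell_types = 2,
                             cells_per_type_per_compartment = 60,
                             n_genes = 300, ref_cells_per_type = 40, seed = 3)
  fit <- classify_compartments(sim$query, sim$query_ann, sim$ref,
                               ref_ann = sim$ref_ann,
                               cell_types = c("type1", "type2"),
                               embed_method = "pca", seed = 3)
  truth <- sim$query_ann$compartment
  pred <- fit$calls$compartment
  sens <- mean(pred[truth == "blood"] == "blood")
  spec <- mean(pred[truth == "tissue"] == "tissue")
  expect_gte((sens + spec) / 2, 0.9)
  # blood cells sit closer to the whole-blood reference on average
  expect_lt(mean(fit$calls$mean_ref_distance[pred == "blood"]),
            mean(fit$calls$mean_ref_distance[pred == "tissue"]))
})

test_that("classify_compartments is invariant to cell order", {
  sim <- simulate_expression(n_cell_types = 1,
                             cells_per_type_per_compartment = 30,
                             n_genes = 200, ref_cells_per_type = 25, seed = 4)
  fit1 <- classify_compartments(sim$query, sim$query_ann, sim$ref,
                                cell_types = "type1", embed_method = "pca",
                                seed = 1)
  set.seed(99)
  perm <- sample(length(sim$query$barcodes))
  qperm <- expression_matrix(sim$query$counts[perm, ],
                             sim$query$barcodes[perm], sim$query$genes)
  fit2 <- classify_compartments(qperm, sim$query_ann[perm, ], sim$ref,
                                cell_types = "type1", embed_method = "pca",
                                seed = 1)
  m <- match(fit1$calls$barcode, fit2$calls$barcode)
  expect_equal(fit1$calls$compartment, fit2$calls$compartment[m])
})

test_that("classify_compartments leaves unlisted and sparse types unassigned", {
  sim <- simulate_expression(n_cell_types = 2,
                             cells_per_type_per_compartment = 30,
                             n_genes = 150, ref_cells_per_type = 25, seed = 5)
  ann <- sim$query_ann
  # bleed 5 cells out of type2 so it falls below min_cells = 60
  ann$cell_type[which(ann$cell_type == "type2")[1:5]] <- "epithelial"
  expect_warning(
    fit <- classify_compartments(sim$query, ann, sim$ref,
                                 cell_types = c("type1", "type2"),
                                 embed_method = "pca", seed = 1,
                                 min_cells = 60),
    "min_cells")
  expect_true(all(fit$calls$compartment[ann$cell_type == "epithelial"] ==
                  "unassigned"))
  expect_true(all(fit$calls$compartment[ann$cell_type == "type2"] ==
                  "unassigned"))
  expect_true(any(fit$calls$compartment[ann$cell_type == "type1"] !=
                  "unassigned"))
})

test_that("classify_compartments errors when no listed type is present", {
  sim <- simulate_expression(n_cell_types = 1,
                             cells_per_type_per_compartment = 25,
                             n_genes = 100, ref_cells_per_type = 20, seed = 6)
  ann <- sim$query_ann
  ann$cell_type <- "epithelial"
  expect_error(classify_compartments(sim$query, ann, sim$ref,
                                     cell_types = c("T-cells", "NK cells")),
               "none of the requested cell types")
})

test_that("annotated references restrict matching and skip missing types", {
  sim <- simulate_expression(n_cell_types = 2,
                             cells_per_type_per_compartment = 30,
                             n_genes = 150, ref_cells_per_type = 25, seed = 8)
  ref_ann <- sim$ref_ann
  ref_ann$cell_type[ref_ann$cell_type == "type2"] <- "somethingelse"
  expect_warning(
    fit <- classify_compartments(sim$query, sim$query_ann, sim$ref,
                                 ref_ann = ref_ann,
                                 cell_types = c("type1", "type2"),
                                 embed_method = "pca", seed = 1),
    "reference lacks")
  expect_true("type2" %in% fit$skipped)
  expect_true(all(fit$calls$compartment[sim$query_ann$cell_type == "type2"] ==
                  "unassigned"))
  expect_true(any(fit$calls$compartment[sim$query_ann$cell_type == "type1"] !=
                  "unassigned"))
})
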
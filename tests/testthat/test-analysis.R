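test_that("normalization rescales columns exactly and is idempotent", {
  counts <- matrix(c(2, 3, 5,
                     0, 4, 4,
                     0, 0, 0), nrow = 3, byrow = FALSE,
                   dimnames = list(c("g1", "g2", "g3"),
                                   c("b1", "b2", "b3")))
  expect_warning(norm <- normalize_counts(counts, scale_n = 1e4),
                 "all-zero")
  expect_equal(unname(norm$prelog[, "b1"]), c(2000, 3000, 5000))
  expect_equal(unname(colSums(norm$prelog)), rep(1e4, 2))
  expect_equal(norm$log2, log2(norm$prelog + 1))
  # already-normalized pre-log columns are a fixed point
  renorm <- normalize_counts(norm$prelog, scale_n = 1e4)
  expect_equal(renorm$prelog, norm$prelog)
  expect_error(normalize_counts(matrix(-1)), "non-negative")
})

test_that("variable-gene selection ranks by CV with deterministic ties", {
  mat <- rbind(flat = rep(5, 8),
               wild = c(0.1, 10, 0.1, 10, 0.1, 10, 0.1, 10),
               mild = c(4, 6, 4, 6, 4, 6, 4, 6))
  expect_identical(select_variable_genes(mat, n = 1L), "wild")
  expect_identical(select_variable_genes(mat, n = 3L),
                   c("wild", "mild", "flat"))
  expect_error(select_variable_genes(mat, n = 9L), "exceeds")
})

test_that("abundance filter is inclusive at the threshold and centres rows", {
  prelog <- matrix(c(6.5, 6.5, 6.5,
                     7.0, 7.1, 6.9,
                     1.0, 2.0, 3.0), nrow = 3, byrow = TRUE,
                   dimnames = list(c("at", "above", "below"),
                                   paste0("b", 1:3)))
  norm <- structure(list(prelog = prelog, log2 = log2(prelog + 1),
                         scale_n = 1e4, pseudocount = 1),
                    class = "masc_norm")
  res <- abundance_filter(norm, min_mean = 6.5)
  expect_setequal(res$genes, c("at", "above"))
  expect_equal(unname(rowMeans(res$centred)), rep(0, 2))
})

test_that("named background genes are removed, mitochondria only on request", {
  genes <- data.frame(gene_id = c("HS_BCYRN1", "HS_MT-G1", "HS_G001"),
                      symbol = c("BCYRN1", "MT-G1", "G001"),
                      is_mito = c(FALSE, TRUE, FALSE))
  mat <- matrix(1, 3, 2, dimnames = list(genes$gene_id, c("b1", "b2")))
  kept <- remove_named_background_genes(mat, genes)
  expect_setequal(rownames(kept), c("HS_MT-G1", "HS_G001"))
  kept2 <- remove_named_background_genes(mat, genes, include_mito = TRUE)
  expect_setequal(rownames(kept2), "HS_G001")
  expect_warning(remove_named_background_genes(mat, genes,
                                               symbols = "NOPE"),
                 "none of the named")
  expect_identical(nrow(remove_named_background_genes(mat, genes,
                                                      symbols = character(0))),
                   3L)
})

test_that("permutation test finds the planted rank and rejects pure noise", {
  lr <- simulate_lowrank_matrix(n_genes = 300L, n_cells = 60L, rank = 2L,
                                n_signal_genes = 100L, seed = 71L)
  res <- significant_pcs(lr$mat, n_perm = 100L, seed = 71L)
  expect_identical(res$n_sig, 2L)
  expect_true(all(res$p_values[1:2] < 0.01))
  expect_identical(dim(res$scores), c(60L, 2L))

  set.seed(72)
  noise <- matrix(rnorm(300 * 60), 300, 60)
  res0 <- significant_pcs(noise, n_perm = 100L, seed = 72L)
  expect_lte(res0$n_sig, 1L)
  expect_error(significant_pcs(lr$mat, n_perm = 10L, alpha = 0.01),
               "n_perm")
})

test_that("t-SNE embeddings have the right shape and are seed-deterministic", {
  lr <- simulate_lowrank_matrix(n_genes = 100L, n_cells = 60L,
                                n_signal_genes = 50L, seed = 73L)
  scores <- significant_pcs(lr$mat, n_perm = 100L, seed = 73L)$scores
  e1 <- tsne_embed(scores, dims = 2L, n_iter = 300L, perplexity = 10,
                   seed = 9L)
  e2 <- tsne_embed(scores, dims = 2L, n_iter = 300L, perplexity = 10,
                   seed = 9L)
  expect_identical(dim(e1), c(60L, 2L))
  expect_identical(e1, e2)
  e3 <- tsne_embed(scores, dims = 3L, n_iter = 300L, perplexity = 10,
                   seed = 9L)
  expect_identical(ncol(e3), 3L)
  expect_error(tsne_embed(scores, perplexity = 30), "perplexity")
})

test_that("correlation-distance clustering matches the naive UPGMA oracle", {
  set.seed(74)
  mat <- matrix(rnorm(8 * 5), 8, 5,
                dimnames = list(paste0("g", 1:8), paste0("c", 1:5)))
  d <- stats::as.dist(1 - stats::cor(mat))
  res <- hcluster(mat, k = 2L)
  expect_equal(sort(res$tree$height), sort(oracle_upgma_heights(d)))

  twin <- cbind(mat, c6 = mat[, "c1"])
  res2 <- hcluster(twin, k = 2L)
  first <- res2$tree$merge[1, ]
  expect_setequal(abs(first), c(1L, 6L))
  expect_equal(res2$tree$height[1], 0, tolerance = 1e-12)
})

test_that("clustering separates two planted expression programs", {
  set.seed(75)
  base <- runif(60, 2, 5)
  shift <- c(rep(0, 30), rep(3, 30))
  mat <- sapply(1:40, function(i) {
    grp <- if (i <= 20) 0 else 1
    base + grp * shift + rnorm(60, sd = 0.5)
  })
  dimnames(mat) <- list(paste0("g", 1:60), paste0("c", 1:40))
  labels <- hcluster(mat, k = 2L)$labels
  expect_identical(length(unique(labels[1:20])), 1L)
  expect_identical(length(unique(labels[21:40])), 1L)
  expect_false(labels[1] == labels[40])
})

test_that("the two-part LRT degenerates to p = 1 on identical clusters", {
  mat <- matrix(rep(c(0, 2, 3, 0, 2, 3), 4), nrow = 2, byrow = TRUE,
                dimnames = list(c("g1", "g2"), paste0("c", 1:12)))
  labels <- rep(1:2, each = 6)
  res <- lrt_de(mat, labels)
  expect_true(all(res$statistic < 1e-8))
  expect_true(all(res$p_value > 0.999))

  allzero <- rbind(mat, g3 = 0)
  expect_false("g3" %in% lrt_de(allzero, labels)$gene_id)
  expect_error(lrt_de(mat, rep(1, 12)), "two clusters")
})

test_that("the LRT is calibrated under the null and powered under shift", {
  null <- simulate_de_matrix(n_genes = 1000L, n_per_cluster = 40L,
                             frac_de = 0, seed = 76L)
  set.seed(76)
  res <- lrt_de(null$mat, sample(null$labels))
  frac <- mean(res$p_value < 0.05)
  expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))

  shifted <- simulate_de_matrix(n_genes = 400L, n_per_cluster = 80L,
                                frac_de = 0.5, effect = 1, seed = 77L)
  resp <- lrt_de(shifted$mat, shifted$labels)
  expect_gt(mean(resp$significant[shifted$is_de]), 0.9)
  # effect monotonicity of power over a 3-point grid
  pw <- vapply(c(0.25, 0.5, 1), function(e) {
    s <- simulate_de_matrix(n_genes = 300L, n_per_cluster = 40L,
                            frac_de = 0.5, effect = e, seed = 78L)
    mean(lrt_de(s$mat, s$labels)$significant[s$is_de])
  }, numeric(1))
  expect_true(all(diff(pw) > 0))
})

test_that("top-abundance overlap reports exclusives and intersections", {
  m1 <- matrix(c(10, 8, 6, 1), 4, 2,
               dimnames = list(paste0("g", 1:4), c("a1", "a2")))
  identical_groups <- list(x = m1, y = m1, z = m1)
  res <- top_abundant_overlap(identical_groups, top_n = 3L)
  expect_identical(res$common, 3L)
  expect_true(all(res$exclusive == 0L))

  m2 <- m1[c(4, 3, 2, 1), ]
  rownames(m2) <- paste0("h", 1:4)
  mats <- list(x = rbind(m1, m2 * 0), y = rbind(m1 * 0, m2))
  res2 <- top_abundant_overlap(mats, top_n = 3L)
  expect_identical(unname(res2$exclusive), c(3L, 3L))
  expect_identical(res2$pairwise$shared, 0L)
  expect_identical(res2$common, 0L)
})
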
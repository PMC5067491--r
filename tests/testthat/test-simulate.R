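test_that("identical config and seed reproduce the experiment exactly", {
  cfg <- simulation_config(seed = 21L, genes_per_species = 40L,
                           mean_meanlog = log(0.6))
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 8L, n_cols = 9L)
  s1 <- simulate_experiment(cfg, wl, layout)
  s2 <- simulate_experiment(cfg, wl, layout)
  expect_identical(s1$r1, s2$r1)
  expect_identical(s1$r2, s2$r2)
  expect_identical(s1$reads, s2$reads)
  expect_identical(s1$true_counts, s2$true_counts)
  expect_identical(s1$cells, s2$cells)
})

test_that("occupancy controls spot groups", {
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 8L, n_cols = 9L)

  empty <- simulate_cells(layout, simulation_config(seed = 1L, occupancy = 0))
  expect_true(all(empty$spots$group == "background"))
  expect_identical(nrow(empty$cells), 0L)

  one <- simulate_cells(layout, simulation_config(seed = 1L, n_cells = 1L))
  expect_identical(sum(one$spots$n_cells), 1L)
  expect_identical(one$spots$group[one$spots$n_cells == 1L], "single")

  # occupancy 0.47 over the full 1007-spot array: binomial 3 SD bound
  full <- simulate_cells(full_layout(),
                         simulation_config(seed = 2L, occupancy = 0.47))
  occupied <- sum(full$spots$n_cells > 0)
  expect_lt(abs(occupied - 0.47 * 1007), 3 * sqrt(1007 * 0.47 * 0.53))
  expect_true(all(c("background", "single", "doublet", "cluster") %in%
                    full$spots$group))
  # group labels consistent with counts
  expect_identical(full$spots$group,
                   ifelse(full$spots$n_cells == 0, "background",
                          ifelse(full$spots$n_cells == 1, "single",
                                 ifelse(full$spots$n_cells == 2, "doublet",
                                        "cluster"))))
})

test_that("cell centroids stay within the jitter radius of their spot", {
  sim <- small_sim()
  sp <- sim$layout[match(sim$cells$spot_id, sim$layout$spot_id), ]
  d <- sqrt((sim$cells$x_um - sp$x_um)^2 + (sim$cells$y_um - sp$y_um)^2)
  expect_true(all(d <= sim$config$jitter_um + 1e-9))
})

test_that("expression model respects dropout and background scaling", {
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 8L, n_cols = 9L)
  cfg_drop <- simulation_config(seed = 3L, dropout = 1,
                                genes_per_species = 40L,
                                background_fraction = 0)
  gm <- simulate_genes(cfg_drop)
  pl <- simulate_cells(layout, cfg_drop)
  ex <- simulate_expression(pl, gm, cfg_drop)
  expect_true(all(ex$true_counts == 0L))

  cfg_nobg <- simulation_config(seed = 4L, background_fraction = 0,
                                genes_per_species = 40L)
  gm <- simulate_genes(cfg_nobg)
  pl <- simulate_cells(layout, cfg_nobg)
  ex <- simulate_expression(pl, gm, cfg_nobg)
  bg <- pl$spots$barcode_id[pl$spots$n_cells == 0L]
  expect_true(all(ex$true_counts[, bg] == 0L))
})

test_that("per-gene CV decreases with expression level at fixed dispersion", {
  # NB closed form: CV^2 = 1/mu + 1/size, monotone decreasing in mu
  cfg <- simulation_config(seed = 5L, occupancy = 0.9, dropout = 0,
                           background_fraction = 0, genes_per_species = 80L)
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 12L, n_cols = 12L)
  gm <- simulate_genes(cfg)
  pl <- simulate_cells(layout, cfg)
  ex <- simulate_expression(pl, gm, cfg)
  cc <- ex$cell_counts
  mu <- rowMeans(cc)
  keep <- mu > 0
  cv <- apply(cc[keep, , drop = FALSE], 1, stats::sd) / mu[keep]
  hi <- mu[keep] >= stats::quantile(mu[keep], 0.75)
  lo <- mu[keep] <= stats::quantile(mu[keep], 0.25)
  expect_lt(mean(cv[hi]), mean(cv[lo]))
  # and the closed form tracks the empirical CV for well-sampled genes
  well <- mu[keep] > 1
  pred <- sqrt(1 / mu[keep][well] + 1 / cfg$dispersion)
  expect_gt(stats::cor(cv[well], pred), 0.9)
})

test_that("reads conserve the true matrix when each molecule is read once", {
  cfg <- simulation_config(seed = 6L, error_rate = 0, swap_rate = 0,
                           reads_per_molecule = 1, genes_per_species = 40L,
                           mean_meanlog = log(0.8))
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 8L, n_cols = 9L)
  sim <- simulate_experiment(cfg, wl, layout)
  agg <- table(factor(sim$reads$gene_id, rownames(sim$true_counts)),
               factor(sim$reads$barcode_id, colnames(sim$true_counts)))
  expect_identical(matrix(as.integer(agg), nrow = nrow(sim$true_counts)),
                   unname(unclass(sim$true_counts)))
})

test_that("read structure matches the declared geometry", {
  sim <- small_sim()
  expect_true(all(nchar(sim$r1) == 31L))
  expect_true(all(nchar(sim$r2) == 121L))
  # zero-error reads carry the true barcode and a valid UMI verbatim
  wl_seq <- sim$whitelist$sequence[match(sim$reads$obs_barcode_id,
                                         sim$whitelist$barcode_id)]
  expect_identical(unname(substr(sim$r1, 1, 18)), wl_seq)
  expect_identical(unname(substr(sim$r1, 19, 27)), sim$reads$umi)
  expect_true(all(umi_is_valid(sim$reads$umi)))
  # R2 is a verbatim transcript substring of the true gene
  idx <- sample(length(sim$r2), 50)
  hits <- mapply(function(rd, g) grepl(rd, sim$transcriptome[[g]],
                                       fixed = TRUE),
                 sim$r2[idx], sim$reads$gene_id[idx])
  expect_true(all(hits))
})

test_that("swap rate marks the expected read fraction and reroutes barcodes", {
  cfg <- simulation_config(seed = 8L, error_rate = 0, swap_rate = 0.02,
                           genes_per_species = 40L, mean_meanlog = log(0.8))
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 8L, n_cols = 9L)
  sim <- simulate_experiment(cfg, wl, layout)
  n <- nrow(sim$reads)
  frac <- mean(sim$reads$is_swapped)
  expect_lt(abs(frac - 0.02), 3 * sqrt(0.02 * 0.98 / n))
  sw <- sim$reads$is_swapped
  expect_true(all(sim$reads$obs_barcode_id[sw] != sim$reads$barcode_id[sw]))
  expect_true(all(sim$reads$obs_barcode_id[!sw] == sim$reads$barcode_id[!sw]))
})

test_that("background molecules land only on empty spots at the set rate", {
  sim <- small_sim()  # background_fraction default 0.05
  bg_spots <- sim$spots$barcode_id[sim$spots$n_cells == 0L]
  expect_true(all(sim$reads$barcode_id[sim$reads$is_background] %in% bg_spots))
  f <- mean(sim$reads$is_background)
  expect_lt(abs(f - 0.05), 0.02)
})

test_that("simulation files round-trip through the writers", {
  cfg <- simulation_config(seed = 9L, genes_per_species = 40L,
                           mean_meanlog = log(0.3))
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 8L, n_cols = 9L)
  sim <- simulate_experiment(cfg, wl, layout)
  dir <- withr::local_tempdir()
  write_simulation(sim, dir)
  fq <- read_fastq_pair(file.path(dir, "reads_R1.fastq.gz"),
                        file.path(dir, "reads_R2.fastq.gz"))
  expect_identical(fq$r1, sim$r1)
  expect_identical(fq$r2, sim$r2)
  back <- read_counts_mtx(file.path(dir, "true_counts"))
  expect_identical(back[rownames(sim$true_counts), colnames(sim$true_counts)],
                   unclass(sim$true_counts)[, ])
})
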
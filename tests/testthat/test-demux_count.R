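test_that("read pairs are sliced positionally and malformed pairs skipped", {
  bc <- strrep("A", 18)
  umi <- "ACGGACGGA"
  r1 <- c(good = paste0(bc, umi, "TTTT"), short = strrep("A", 30))
  r2 <- c(good = strrep("G", 121), short = strrep("G", 121))
  parsed <- parse_read_pairs(r1, r2)
  expect_identical(nrow(parsed), 1L)
  expect_identical(parsed$barcode, bc)
  expect_identical(parsed$umi, umi)
  expect_identical(parsed$transcript, unname(r2[1]))
  expect_identical(attr(parsed, "n_malformed"), 1L)
})

test_that("exact-match gene assignment distinguishes unique/ambiguous/absent", {
  set.seed(31)
  shared <- paste(sample(c("A", "C", "G", "T"), 121, TRUE), collapse = "")
  mk <- function() paste(sample(c("A", "C", "G", "T"), 200, TRUE),
                         collapse = "")
  tx <- c(g1 = paste0(mk(), shared, mk()),
          g2 = paste0(mk(), shared, mk()),
          g3 = paste0(mk(), mk()))
  idx <- build_transcript_index(tx)
  verbatim <- substr(tx[["g3"]], 37, 157)
  random <- paste(sample(c("A", "C", "G", "T"), 121, TRUE), collapse = "")
  got <- assign_genes(c(verbatim, shared, random), idx)
  expect_identical(got[1], "g3")
  expect_identical(got[2], "__ambiguous__")
  expect_true(is.na(got[3]))
  expect_error(build_transcript_index(c(g = "ACGT")), "at least")
})

test_that("UMI collapse counts hamming components", {
  expect_identical(dedup_umis(rep("ACGGACGGA", 3)), 1L)
  # one 1-step neighbour merges, a distance-2 sequence stays separate
  ms <- c(rep("ACGGACGGA", 5), "ACGGACGGC", rep("TCGGTCGGA", 2))
  expect_identical(oracle_umi_components(ms, 1L), 2L)
  expect_identical(dedup_umis(ms, threshold = 1L), 2L)
  expect_identical(dedup_umis(c("ACGGACGGA", "ACGGACGGC", "TCGGTCGGA"),
                              threshold = 0L), 3L)
  expect_identical(dedup_umis(character(0)), 0L)
  # chains merge transitively
  chain <- c("ACGGACGGA", "ACGGACGGC", "ACGGACGCC")
  expect_identical(dedup_umis(chain, threshold = 1L), 1L)
  expect_identical(oracle_umi_components(chain, 1L), 1L)
})

test_that("UMI collapse is permutation- and duplication-invariant and matches
           the component oracle on random multisets", {
  set.seed(32)
  for (i in 1:40) {
    umis <- sample_umis(sample(2:12, 1))
    thr <- sample(0:2, 1)
    base <- dedup_umis(umis, thr)
    expect_identical(base, oracle_umi_components(umis, thr))
    expect_identical(dedup_umis(sample(umis), thr), base)
    expect_identical(dedup_umis(c(umis, sample(umis, 3, TRUE)), thr), base)
  }
})

test_that("read filters drop flagged reads and report counts", {
  genes <- data.frame(gene_id = c("HS_RPL1", "HS_MALAT1", "HS_G001"),
                      symbol = c("RPL1", "MALAT1", "G001"),
                      is_ribosomal = c(TRUE, FALSE, FALSE),
                      stringsAsFactors = FALSE)
  reads <- data.frame(
    read_id = paste0("r", 1:6),
    barcode_id = c("b1", "b1", "b1", NA, "b1", "b1"),
    barcode_distance = c(0L, 0L, 0L, NA, 0L, 0L),
    umi = rep("ACGGACGGA", 6),
    umi_valid = c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE),
    gene_id = c("HS_RPL1", "HS_MALAT1", "HS_G001", "HS_G001", "HS_G001", NA),
    ambiguous_gene = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  kept <- apply_read_filters(reads, genes)
  rep_ <- attr(kept, "filter_report")
  expect_identical(kept$read_id, "r3")
  expect_identical(rep_[["ribosomal"]], 1L)
  expect_identical(rep_[["named_removal"]], 1L)
  expect_identical(rep_[["invalid_umi"]], 1L)
  expect_identical(rep_[["ambiguous_gene"]], 1L)
  expect_identical(rep_[["unassigned_barcode"]], 1L)
  expect_identical(rep_[["retained"]], 1L)

  bad <- reads
  bad$gene_id[3] <- "HS_UNKNOWN"
  expect_error(apply_read_filters(bad, genes), "annotation mismatch")
})

test_that("count matrix collapses UMIs per cell of the matrix", {
  reads <- data.frame(
    read_id = paste0("r", 1:12),
    barcode_id = c(rep("b1", 10), "b2", "b2"),
    umi = c(rep("ACGGACGGA", 10), "ACGGACGGA", "TCGGTCGGA"),
    gene_id = c(rep("g1", 10), "g1", "g1"),
    stringsAsFactors = FALSE)
  m <- build_count_matrix(reads, c("g1", "g2"), c("b1", "b2", "b3"))
  expect_identical(m["g1", "b1"], 1L)   # 10 identical UMIs, one molecule
  expect_identical(m["g1", "b2"], 2L)
  expect_identical(m["g2", "b3"], 0L)
  expect_identical(attr(m, "raw_reads"), c(b1 = 10L, b2 = 2L, b3 = 0L))

  empty <- build_count_matrix(reads[0, ], c("g1", "g2"), c("b1", "b2"))
  expect_true(all(empty == 0L))
  expect_identical(dim(empty), c(2L, 2L))
})

test_that("adding reads never decreases a matrix entry", {
  set.seed(33)
  mk_reads <- function(n) data.frame(
    read_id = sprintf("r%03d", seq_len(n)),
    barcode_id = sample(c("b1", "b2"), n, TRUE),
    umi = sample_umis(n),
    gene_id = sample(c("g1", "g2", "g3"), n, TRUE),
    stringsAsFactors = FALSE)
  base <- mk_reads(40)
  extra <- mk_reads(20)
  extra$read_id <- paste0("x", extra$read_id)
  m1 <- build_count_matrix(base, c("g1", "g2", "g3"), c("b1", "b2"))
  m2 <- build_count_matrix(rbind(base, extra), c("g1", "g2", "g3"),
                           c("b1", "b2"))
  expect_true(all(m2 >= m1))
})

test_that("zero-error reads demultiplex perfectly; errors follow the
           binomial tail", {
  sim <- small_sim()
  pipe <- small_sim_pipeline()
  expect_identical(pipe$reads$barcode_id, sim$reads$obs_barcode_id)
  expect_true(all(pipe$reads$barcode_distance == 0L))

  # with substitutions, the unassigned fraction tracks P(>2 errors in 18)
  e <- 0.05
  cfg <- simulation_config(seed = 41L, error_rate = e, swap_rate = 0,
                           genes_per_species = 40L, mean_meanlog = log(0.8),
                           reads_per_molecule = 1)
  wl <- small_whitelist()
  layout <- array_layout(wl, n_rows = 8L, n_cols = 9L)
  sim_e <- simulate_experiment(cfg, wl, layout)
  bc <- match_barcodes(substr(sim_e$r1, 1, 18), wl)
  p_tail <- 1 - stats::pbinom(2, 18, e)
  n <- length(sim_e$r1)
  frac_un <- mean(is.na(bc$barcode_id))
  expect_lt(abs(frac_un - p_tail), 5 * sqrt(p_tail * (1 - p_tail) / n))
  # every read that is assigned at all is assigned correctly
  ok <- !is.na(bc$barcode_id)
  expect_true(mean(bc$barcode_id[ok] == sim_e$reads$barcode_id[ok]) > 0.999)
})

test_that("the pipeline reproduces ground truth exactly at zero error", {
  sim <- small_sim()
  pipe <- small_sim_pipeline()
  want <- expected_counts(sim, threshold = 1L)
  want[rownames(want) %in% filtered_gene_ids(sim), ] <- 0L
  got <- pipe$counts[rownames(want), colnames(want)]
  expect_identical(unname(got), unname(want))
})

test_that("external gene assignments can replace the exact-match assigner", {
  sim <- small_sim()
  take <- seq_len(200)
  ga <- stats::setNames(sim$reads$gene_id[take], sim$reads$read_id[take])
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(read_id = names(ga), gene_id = ga),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  imported <- read_gene_assignments_tsv(path)
  ann <- demux_reads(sim$r1[take], sim$r2[take], sim$whitelist,
                     gene_assignments = imported)
  expect_identical(ann$gene_id, unname(sim$reads$gene_id[take]))
})
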
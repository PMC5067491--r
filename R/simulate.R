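# Synthetic-data generator: array experiments with known ground truth.
#
# The generator emulates the experimental design the pipeline assumes: cells
# smeared or sorted onto a barcoded spot array (occupancy ~47%, the sorting
# efficiency of the real instrument), negative-binomial per-gene expression
# with Bernoulli dropout, empty-spot background from cell-free RNA, paired
# 31/121 nt reads with substitution errors, semi-randomized UMIs with
# collisions, and optional barcode swapping (crosstalk).

#' Simulation configuration
#'
#' Collects and validates every tunable of the synthetic experiment.
#' Defaults are the package's fixed study conditions; see the methods
#' vignette for the rationale behind each value.
#'
#' @param seed integer seed; a fixed seed makes every simulator output
#'   byte-identical.
#' @param occupancy probability that a non-frame spot receives at least one
#'   cell (default 0.47, the indexed-sorting efficiency). Cell
#'   multiplicities are Poisson conditioned on this, so background,
#'   single, doublet and cluster spots all occur.
#' @param n_cells optional exact number of cells; when set, that many
#'   spots are drawn without replacement and receive one cell each
#'   (sorted-singles mode), and `occupancy` is ignored.
#' @param species_mix named numeric vector of species proportions summing
#'   to 1, e.g. `c(HS = 0.5, MM = 0.5)` for a two-species mixing
#'   experiment. Default single species `c(HS = 1)`.
#' @param genes_per_species number of genes simulated per species
#'   (default 120), including flagged decoys (ribosomal, mitochondrial,
#'   housekeeping, a MALAT1-like and a BCYRN1-like background gene) and
#'   `n_orthologs` ortholog-paired genes.
#' @param n_orthologs number of ortholog pairs shared across species
#'   (default 30; only meaningful with two species).
#' @param mean_meanlog,mean_sdlog lognormal parameters of the per-gene
#'   base mean grid (defaults log(2) and 1.2).
#' @param dispersion negative-binomial size parameter (default 2).
#' @param dropout Bernoulli dropout probability applied per gene and cell
#'   (default 0.1).
#' @param background_fraction expected fraction of all molecules that come
#'   from cell-free background RNA on empty spots (default 0.05).
#' @param error_rate per-base substitution error rate on both mates
#'   (default 0.005).
#' @param reads_per_molecule mean sequenced reads per captured molecule
#'   (>= 1; default 2, i.e. one duplicate on average).
#' @param swap_rate probability that a read is reassigned to a random
#'   other barcode before sequencing (default 0).
#' @param n_clusters number of expression programs (clusters) per species
#'   (default 1).
#' @param cluster_effect log2 fold-change applied to a cluster's program
#'   genes (default 1.5).
#' @param program_size genes per cluster program (default 15).
#' @param transcript_length length of each toy transcript (default 500 nt).
#' @param jitter_um radius of uniform jitter of cell centroids around the
#'   spot centre (default 30 um, within the 50 um assignment radius).
#' @return a validated list of class `masc_sim_config`.
#' @export
simulation_config <- function(seed = 1L,
                              occupancy = 0.47,
                              n_cells = NULL,
                              species_mix = c(HS = 1),
                              genes_per_species = 120L,
                              n_orthologs = 30L,
                              mean_meanlog = log(2),
                              mean_sdlog = 1.2,
                              dispersion = 2,
                              dropout = 0.1,
                              background_fraction = 0.05,
                              error_rate = 0.005,
                              reads_per_molecule = 2,
                              swap_rate = 0,
                              n_clusters = 1L,
                              cluster_effect = 1.5,
                              program_size = 15L,
                              transcript_length = 500L,
                              jitter_um = 30) {
  probs <- c(occupancy, dropout, background_fraction, error_rate, swap_rate,
             species_mix)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0,1]")
  if (abs(sum(species_mix) - 1) > 1e-8) stop("species_mix must sum to 1")
  if (is.null(names(species_mix)) || anyDuplicated(names(species_mix))) {
    stop("species_mix must have unique names")
  }
  if (reads_per_molecule < 1) stop("reads_per_molecule must be >= 1")
  if (transcript_length < 121L) stop("transcripts must be at least 121 nt")
  if (dispersion <= 0 || mean_sdlog < 0) stop("invalid expression parameters")
  cfg <- list(seed = as.integer(seed) %% 2147483647L,
              occupancy = occupancy, n_cells = n_cells,
              species_mix = species_mix,
              genes_per_species = as.integer(genes_per_species),
              n_orthologs = as.integer(n_orthologs),
              mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
              dispersion = dispersion, dropout = dropout,
              background_fraction = background_fraction,
              error_rate = error_rate,
              reads_per_molecule = reads_per_molecule,
              swap_rate = swap_rate,
              n_clusters = as.integer(n_clusters),
              cluster_effect = cluster_effect,
              program_size = as.integer(program_size),
              transcript_length = as.integer(transcript_length),
              jitter_um = jitter_um)
  class(cfg) <- "masc_sim_config"
  cfg
}

#' Simulate the gene catalogue and toy transcriptome
#'
#' Each species gets `genes_per_species` genes: a MALAT1-like and (for the
#' first species) a BCYRN1-like highly expressed background decoy,
#' ribosomal, mitochondrial and housekeeping flagged genes, ortholog-paired
#' genes shared across species, and generic genes. Every gene receives a
#' deterministic seeded random transcript.
#'
#' @param config a [simulation_config()].
#' @return list with `genes` (annotation data.frame: `gene_id`, `symbol`,
#'   `species`, `is_ribosomal`, `is_mito`, `is_housekeeping`,
#'   `base_mean`), `transcriptome` (named character vector) and
#'   `orthologs` (data.frame `gene_a`, `gene_b`, one row per pair).
#' @export
simulate_genes <- function(config) {
  set.seed(config$seed + 101L)
  species <- names(config$species_mix)
  npg <- config$genes_per_species
  n_orth <- if (length(species) >= 2L) config$n_orthologs else 0L
  genes <- list()
  for (si in seq_along(species)) {
    sp <- species[si]
    sym <- c("MALAT1",
             if (si == 1L) "BCYRN1",
             paste0("RPL", 1:5),
             paste0("MT-G", 1:3),
             c("ACTB", "GAPDH", "HK3", "HK4", "HK5"),
             if (n_orth > 0L) sprintf("ORTH%02d", seq_len(n_orth)))
    n_generic <- npg - length(sym)
    if (n_generic < 0L) stop("genes_per_species too small for the decoy set")
    sym <- c(sym, sprintf("G%03d", seq_len(n_generic)))
    base_mean <- stats::rlnorm(length(sym), config$mean_meanlog,
                               config$mean_sdlog)
    # background decoys are strongly expressed so removal filters matter
    base_mean[sym %in% c("MALAT1", "BCYRN1")] <-
      base_mean[sym %in% c("MALAT1", "BCYRN1")] * 25
    base_mean[sym %in% c("ACTB", "GAPDH")] <-
      base_mean[sym %in% c("ACTB", "GAPDH")] * 10
    genes[[sp]] <- data.frame(
      gene_id = paste0(sp, "_", sym), symbol = sym, species = sp,
      is_ribosomal = grepl("^RPL", sym),
      is_mito = grepl("^MT-", sym),
      is_housekeeping = sym %in% c("ACTB", "GAPDH", "HK3", "HK4", "HK5"),
      base_mean = base_mean, stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, genes)
  rownames(genes) <- NULL
  orthologs <- if (n_orth > 0L) {
    data.frame(gene_a = paste0(species[1L], "_", sprintf("ORTH%02d", seq_len(n_orth))),
               gene_b = paste0(species[2L], "_", sprintf("ORTH%02d", seq_len(n_orth))),
               stringsAsFactors = FALSE)
  } else {
    data.frame(gene_a = character(0), gene_b = character(0))
  }
  tx <- vapply(seq_len(nrow(genes)), function(i) {
    paste(sample(BASES, config$transcript_length, replace = TRUE),
          collapse = "")
  }, character(1))
  names(tx) <- genes$gene_id
  list(genes = genes, transcriptome = tx, orthologs = orthologs)
}

#' Simulate cell placement on the array
#'
#' In occupancy mode every non-frame spot receives a Poisson number of
#' cells conditioned so that `P(>=1 cell) = occupancy`; in sorted-singles
#' mode (`n_cells` set) that many distinct spots receive exactly one cell.
#' Cells get species, cluster and centroid coordinates (spot centre plus
#' uniform jitter).
#'
#' @param layout an [array_layout()].
#' @param config a [simulation_config()].
#' @return list with `spots` (spot_id, barcode_id, n_cells, group) and
#'   `cells` (cell_id, spot_id, barcode_id, species, cluster, x_um, y_um).
#' @export
simulate_cells <- function(layout, config) {
  set.seed(config$seed + 202L)
  sp <- layout[!layout$is_frame, , drop = FALSE]
  n_spots <- nrow(sp)
  if (!is.null(config$n_cells)) {
    if (config$n_cells > n_spots) {
      stop("more cells than available spots in sorted-singles mode")
    }
    n_cells_spot <- integer(n_spots)
    n_cells_spot[sample.int(n_spots, config$n_cells)] <- 1L
  } else if (config$occupancy == 0) {
    n_cells_spot <- integer(n_spots)
  } else {
    lambda <- -log(1 - config$occupancy)
    n_cells_spot <- stats::rpois(n_spots, lambda)
    n_cells_spot <- pmin(n_cells_spot, 6L)
    # Poisson gives P(N>=1) = occupancy exactly; cap only trims the far tail
  }
  group <- occupancy_group(n_cells_spot)
  spots <- data.frame(spot_id = sp$spot_id, barcode_id = sp$barcode_id,
                      n_cells = n_cells_spot, group = group,
                      stringsAsFactors = FALSE)
  idx <- rep(seq_len(n_spots), n_cells_spot)
  n_cells <- length(idx)
  if (n_cells > 0L) {
    ang <- stats::runif(n_cells, 0, 2 * pi)
    rad <- config$jitter_um * sqrt(stats::runif(n_cells))
    cells <- data.frame(
      cell_id = sprintf("CELL%05d", seq_len(n_cells)),
      spot_id = sp$spot_id[idx], barcode_id = sp$barcode_id[idx],
      species = sample(names(config$species_mix), n_cells, replace = TRUE,
                       prob = config$species_mix),
      cluster = sample.int(config$n_clusters, n_cells, replace = TRUE),
      x_um = sp$x_um[idx] + rad * cos(ang),
      y_um = sp$y_um[idx] + rad * sin(ang),
      stringsAsFactors = FALSE)
  } else {
    cells <- data.frame(cell_id = character(0), spot_id = character(0),
                        barcode_id = character(0), species = character(0),
                        cluster = integer(0), x_um = numeric(0),
                        y_um = numeric(0), stringsAsFactors = FALSE)
  }
  list(spots = spots, cells = cells)
}

# occupancy group from cell count (vectorized)
occupancy_group <- function(n_cells) {
  ifelse(n_cells == 0L, "background",
         ifelse(n_cells == 1L, "single",
                ifelse(n_cells == 2L, "doublet", "cluster")))
}

#' Simulate true molecule counts
#'
#' Per-cell counts are negative binomial with a lognormal base-mean grid,
#' cluster programs as log2 fold-changes on program genes, and Bernoulli
#' dropout; a cell expresses only its own species' genes. Cell counts are
#' aggregated per spot, and empty spots receive background molecules drawn
#' from a shared cell-free profile whose total is scaled so the expected
#' background share of all molecules equals `background_fraction`.
#'
#' @param placement output of [simulate_cells()].
#' @param gene_model output of [simulate_genes()].
#' @param config a [simulation_config()].
#' @return list with `true_counts` (genes x barcodes integer matrix over
#'   all non-frame spots), `cell_counts` (genes x cells matrix) and
#'   `programs` (data.frame gene_id, species, cluster of program genes).
#' @export
simulate_expression <- function(placement, gene_model, config) {
  set.seed(config$seed + 303L)
  genes <- gene_model$genes
  cells <- placement$cells
  spots <- placement$spots
  G <- nrow(genes)
  # cluster programs: disjoint generic genes per (species, cluster)
  programs <- list()
  for (sp in unique(genes$species)) {
    pool <- genes$gene_id[genes$species == sp & grepl("_G\\d+$", genes$gene_id)]
    need <- config$n_clusters * config$program_size
    if (config$n_clusters > 1L && length(pool) < need) {
      stop("not enough generic genes for the requested cluster programs")
    }
    if (config$n_clusters > 1L) {
      chosen <- sample(pool, need)
      programs[[sp]] <- data.frame(
        gene_id = chosen, species = sp,
        cluster = rep(seq_len(config$n_clusters), each = config$program_size),
        stringsAsFactors = FALSE)
    }
  }
  programs <- if (length(programs)) do.call(rbind, programs) else
    data.frame(gene_id = character(0), species = character(0),
               cluster = integer(0))
  rownames(programs) <- NULL

  n_cells <- nrow(cells)
  cell_counts <- matrix(0L, nrow = G, ncol = n_cells,
                        dimnames = list(genes$gene_id, cells$cell_id))
  if (n_cells > 0L) {
    for (j in seq_len(n_cells)) {
      own <- genes$species == cells$species[j]
      mu <- genes$base_mean[own]
      prog <- programs$gene_id[programs$species == cells$species[j] &
                                 programs$cluster == cells$cluster[j]]
      up <- genes$gene_id[own] %in% prog
      mu[up] <- mu[up] * 2^config$cluster_effect
      cnt <- stats::rnbinom(sum(own), mu = mu, size = config$dispersion)
      if (config$dropout > 0) {
        cnt[stats::runif(sum(own)) < config$dropout] <- 0L
      }
      cell_counts[own, j] <- cnt
    }
  }
  # aggregate per spot
  true_counts <- matrix(0L, nrow = G, ncol = nrow(spots),
                        dimnames = list(genes$gene_id, spots$barcode_id))
  if (n_cells > 0L) {
    spot_of <- match(cells$spot_id, spots$spot_id)
    for (j in seq_len(n_cells)) {
      true_counts[, spot_of[j]] <- true_counts[, spot_of[j]] + cell_counts[, j]
    }
  }
  # cell-free background on empty spots
  f <- config$background_fraction
  empty <- which(spots$n_cells == 0L)
  total_cell <- sum(true_counts)
  if (f > 0 && length(empty) > 0L && total_cell > 0L) {
    n_bg <- stats::rpois(1L, f / (1 - f) * total_cell)
    if (n_bg > 0L) {
      prof <- genes$base_mean *
        config$species_mix[genes$species] / sum(genes$base_mean *
                                                  config$species_mix[genes$species])
      draw_gene <- sample.int(G, n_bg, replace = TRUE, prob = prof)
      draw_spot <- empty[sample.int(length(empty), n_bg, replace = TRUE)]
      inc <- table(factor(draw_gene, levels = seq_len(G)),
                   factor(draw_spot, levels = seq_len(nrow(spots))))
      true_counts <- true_counts + matrix(as.integer(inc), nrow = G,
                                          dimnames = dimnames(true_counts))
    }
  }
  storage.mode(cell_counts) <- "integer"
  storage.mode(true_counts) <- "integer"
  out <- list(true_counts = true_counts, cell_counts = cell_counts,
              programs = programs)
  # consumed by simulate_reads' background flag
  attr(out, "cell_spot_barcode") <- cells$barcode_id
  out
}

# substitute bases at the given per-base rate; substitutions never silently
# reproduce the original base
mutate_seqs <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1L])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), ncol = L, byrow = TRUE)
  hit <- which(matrix(stats::runif(length(chars)) < rate, nrow = nrow(chars)))
  if (length(hit) > 0L) {
    old <- match(chars[hit], BASES)
    shift <- sample.int(3L, length(hit), replace = TRUE)
    chars[hit] <- BASES[((old - 1L + shift) %% 4L) + 1L]
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Simulate paired reads from true molecule counts
#'
#' Every true molecule receives a UMI drawn uniformly from the valid
#' `WSNNWSNNV` space (collisions permitted) and `1 + Poisson` duplicate
#' reads. R1 is barcode (18 nt) + UMI (9 nt) + 4 oligo-dT filler bases
#' ("TTTT", 31 nt total); R2 is a uniform 121 nt substring of the gene's
#' transcript. Substitution errors hit both mates at `error_rate`; with
#' probability `swap_rate` a read is reassigned to a random other barcode
#' before sequencing (truth records `is_swapped`).
#'
#' @param expression output of [simulate_expression()].
#' @param whitelist the [barcode_whitelist()] behind the layout.
#' @param gene_model output of [simulate_genes()].
#' @param config a [simulation_config()].
#' @return list with `r1`, `r2` (named character vectors, names are read
#'   ids) and `reads` (per-read truth: read_id, barcode_id (spot of
#'   origin), obs_barcode_id (after swapping), umi, gene_id,
#'   is_background, is_swapped).
#' @export
simulate_reads <- function(expression, whitelist, gene_model, config) {
  set.seed(config$seed + 404L)
  tc <- expression$true_counts
  nz <- which(tc > 0L, arr.ind = TRUE)
  n_mol <- sum(tc[nz])
  if (n_mol == 0L) {
    empty <- data.frame(read_id = character(0), barcode_id = character(0),
                        obs_barcode_id = character(0), umi = character(0),
                        gene_id = character(0), is_background = logical(0),
                        is_swapped = logical(0), stringsAsFactors = FALSE)
    return(list(r1 = character(0), r2 = character(0), reads = empty))
  }
  mol_gene <- rep(rownames(tc)[nz[, 1L]], tc[nz])
  mol_bc <- rep(colnames(tc)[nz[, 2L]], tc[nz])
  mol_umi <- sample_umis(n_mol)
  dup <- 1L + stats::rpois(n_mol, config$reads_per_molecule - 1)
  n_reads <- sum(dup)
  rd_gene <- rep(mol_gene, dup)
  rd_bc <- rep(mol_bc, dup)
  rd_umi <- rep(mol_umi, dup)
  # a molecule is background iff its spot of origin carries no cell
  spots_with_cells <- unique(attr(expression, "cell_spot_barcode"))
  is_bg <- rep(!(mol_bc %in% spots_with_cells), dup)
  swapped <- stats::runif(n_reads) < config$swap_rate
  obs_bc <- rd_bc
  if (any(swapped)) {
    all_bc <- colnames(tc)
    for (i in which(swapped)) {
      obs_bc[i] <- sample(all_bc[all_bc != rd_bc[i]], 1L)
    }
  }
  bc_seq <- whitelist$sequence[match(obs_bc, whitelist$barcode_id)]
  r1 <- paste0(bc_seq, rd_umi, "TTTT")
  tx <- gene_model$transcriptome[rd_gene]
  start <- sample.int(config$transcript_length - 121L + 1L, n_reads,
                      replace = TRUE)
  r2 <- substr(tx, start, start + 120L)
  r1 <- mutate_seqs(r1, config$error_rate)
  r2 <- mutate_seqs(r2, config$error_rate)
  read_id <- sprintf("READ%07d", seq_len(n_reads))
  names(r1) <- read_id
  names(r2) <- read_id
  reads <- data.frame(read_id = read_id, barcode_id = rd_bc,
                      obs_barcode_id = obs_bc, umi = rd_umi,
                      gene_id = rd_gene, is_background = is_bg,
                      is_swapped = swapped, stringsAsFactors = FALSE)
  list(r1 = r1, r2 = r2, reads = reads)
}

#' Run the full synthetic experiment
#'
#' Generates whitelist, layout, gene catalogue, cell placement, true
#' counts and paired reads under one seed. This object is the ground
#' truth against which the pipeline is verified.
#'
#' @param config a [simulation_config()].
#' @param whitelist optional pregenerated [barcode_whitelist()] (saves the
#'   generation time when simulating repeatedly); must cover the layout.
#' @param layout optional [array_layout()] matching `whitelist`.
#' @return object of class `masc_sim`: list with `config`, `whitelist`,
#'   `layout`, `genes`, `transcriptome`, `orthologs`, `spots`, `cells`,
#'   `true_counts`, `cell_counts`, `programs`, `reads`, `r1`, `r2`.
#' @export
simulate_experiment <- function(config = simulation_config(),
                                whitelist = NULL, layout = NULL) {
  if (is.null(whitelist)) {
    whitelist <- generate_whitelist(seed = config$seed + 1L)
  }
  if (is.null(layout)) layout <- array_layout(whitelist)
  gm <- simulate_genes(config)
  placement <- simulate_cells(layout, config)
  expr <- simulate_expression(placement, gm, config)
  rd <- simulate_reads(expr, whitelist, gm, config)
  structure(list(config = config, whitelist = whitelist, layout = layout,
                 genes = gm$genes, transcriptome = gm$transcriptome,
                 orthologs = gm$orthologs,
                 spots = placement$spots, cells = placement$cells,
                 true_counts = expr$true_counts,
                 cell_counts = expr$cell_counts,
                 programs = expr$programs,
                 reads = rd$reads, r1 = rd$r1, r2 = rd$r2),
            class = "masc_sim")
}

#' Collision-aware expected count matrix
#'
#' Aggregates the simulator's per-read truth to the matrix the pipeline
#' should reproduce at zero error and zero swap rate: for each (gene,
#' barcode), the number of UMI clusters among the true molecule UMIs at
#' the given collapse threshold. With `threshold = 0` and no UMI
#' collisions this equals `true_counts` exactly.
#'
#' @param sim a [simulate_experiment()] result.
#' @param threshold UMI collapse hamming threshold (default 1, the
#'   pipeline default).
#' @return genes x barcodes integer matrix on the same axes as
#'   `sim$true_counts`.
#' @export
expected_counts <- function(sim, threshold = 1L) {
  out <- matrix(0L, nrow = nrow(sim$true_counts),
                ncol = ncol(sim$true_counts),
                dimnames = dimnames(sim$true_counts))
  if (nrow(sim$reads) == 0L) return(out)
  key <- paste(sim$reads$gene_id, sim$reads$barcode_id, sep = "\r")
  grp <- split(sim$reads$umi, key)
  cnt <- vapply(grp, dedup_umis, integer(1), threshold = threshold)
  parts <- matrix(unlist(strsplit(names(cnt), "\r", fixed = TRUE)),
                  ncol = 2L, byrow = TRUE)
  out[cbind(match(parts[, 1L], rownames(out)),
            match(parts[, 2L], colnames(out)))] <- cnt
  out
}

# ---- focused matrix generators for analysis-stage verification ------------

#' Simulate a planted low-rank expression matrix
#'
#' `rank` latent factors, each loading on `n_signal_genes` genes, plus iid
#' Gaussian noise: the canonical fixture for checking that the permutation
#' PC test recovers the planted rank.
#'
#' @param n_genes,n_cells matrix dimensions (defaults 500 x 100).
#' @param rank number of planted factors (default 2).
#' @param n_signal_genes genes loading on the factors (default 150).
#' @param loading_sd standard deviation of the loadings (default 0.7).
#' @param noise_sd iid noise level (default 1).
#' @param seed integer seed.
#' @return list with `mat` (genes x cells), `rank`, and the factor scores.
#' @export
simulate_lowrank_matrix <- function(n_genes = 500L, n_cells = 100L,
                                    rank = 2L, n_signal_genes = 150L,
                                    loading_sd = 0.7, noise_sd = 1,
                                    seed = 1L) {
  if (n_signal_genes > n_genes) stop("n_signal_genes exceeds n_genes")
  set.seed(as.integer(seed))
  scores <- matrix(stats::rnorm(n_cells * rank), n_cells, rank)
  loadings <- matrix(0, n_genes, rank)
  sig <- seq_len(n_signal_genes)
  loadings[sig, ] <- stats::rnorm(n_signal_genes * rank, sd = loading_sd)
  mat <- loadings %*% t(scores) +
    matrix(stats::rnorm(n_genes * n_cells, sd = noise_sd), n_genes, n_cells)
  dimnames(mat) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("c%04d", seq_len(n_cells)))
  list(mat = mat, rank = rank, scores = scores)
}

#' Simulate a log-scale expression matrix with known cluster effects
#'
#' A two-part generative model matching the differential-expression test:
#' each gene is detected with probability `1 - dropout` and, when
#' detected, its log2 value is Normal around a gene-specific baseline. A
#' fraction of genes receives an additive `effect` (log2 fold-change) in
#' every cluster beyond the first.
#'
#' @param n_genes number of genes (default 2000).
#' @param n_per_cluster cells per cluster (default 50).
#' @param n_clusters number of clusters (default 2).
#' @param frac_de fraction of genes with a planted effect (default 0).
#' @param effect log2 fold-change of planted genes (default 1, i.e.
#'   2-fold).
#' @param dropout probability a value is a structural zero (default 0.3).
#' @param sd residual standard deviation of positive log values
#'   (default 1).
#' @param seed integer seed.
#' @return list with `mat` (genes x cells log2 values, 0 = undetected),
#'   `labels` (cluster per cell) and `is_de` (logical per gene).
#' @export
simulate_de_matrix <- function(n_genes = 2000L, n_per_cluster = 50L,
                               n_clusters = 2L, frac_de = 0,
                               effect = 1, dropout = 0.3, sd = 1,
                               seed = 1L) {
  set.seed(as.integer(seed))
  n_cells <- n_per_cluster * n_clusters
  labels <- rep(seq_len(n_clusters), each = n_per_cluster)
  base <- stats::runif(n_genes, 2, 5)
  is_de <- seq_len(n_genes) <= round(frac_de * n_genes)
  mat <- matrix(0, n_genes, n_cells)
  for (k in seq_len(n_clusters)) {
    cols <- which(labels == k)
    mu <- base + ifelse(is_de & k > 1L, effect, 0)
    vals <- matrix(stats::rnorm(n_genes * length(cols), mean = mu, sd = sd),
                   n_genes, length(cols))
    vals[vals < 0.1] <- 0.1  # log-scale floor: detected values stay positive
    drop <- matrix(stats::runif(n_genes * length(cols)) < dropout,
                   n_genes, length(cols))
    vals[drop] <- 0
    mat[, cols] <- vals
  }
  dimnames(mat) <- list(sprintf("g%04d", seq_len(n_genes)),
                        sprintf("c%04d", seq_len(n_cells)))
  list(mat = mat, labels = labels, is_de = is_de)
}

#' Simulate cell-cycle phase programs
#'
#' Five phase gene sets with cells either assigned to one phase (their
#' phase genes shifted up by `effect`) or non-cycling (noise only).
#'
#' @param n_cells number of cells (default 500).
#' @param genes_per_phase genes in each phase set (default 20).
#' @param n_noise_genes additional unstructured genes (default 100).
#' @param effect additive log-scale up-shift of a cycling cell's phase
#'   genes (default 3).
#' @param cycling_fraction fraction of cells that cycle (default 1; use
#'   0.1 to plant a minority of cycling cells).
#' @param sd noise standard deviation (default 1).
#' @param seed integer seed.
#' @return list with `mat` (genes x cells), `phase` (truth per cell, one
#'   of the five phase names or `"none"`), `candidates` (data.frame
#'   gene_id, phase) and `phases` (the five phase names in order).
#' @export
simulate_phase_matrix <- function(n_cells = 500L, genes_per_phase = 20L,
                                  n_noise_genes = 100L, effect = 3,
                                  cycling_fraction = 1, sd = 1,
                                  seed = 1L) {
  set.seed(as.integer(seed))
  phases <- c("G1/S", "S", "G2/M", "M", "M/G1")
  n_phase_genes <- genes_per_phase * length(phases)
  n_genes <- n_phase_genes + n_noise_genes
  gene_id <- sprintf("g%04d", seq_len(n_genes))
  candidates <- data.frame(
    gene_id = gene_id[seq_len(n_phase_genes)],
    phase = rep(phases, each = genes_per_phase),
    stringsAsFactors = FALSE)
  cycling <- stats::runif(n_cells) < cycling_fraction
  phase <- rep("none", n_cells)
  phase[cycling] <- sample(phases, sum(cycling), replace = TRUE)
  base <- stats::runif(n_genes, 2, 5)
  mat <- matrix(stats::rnorm(n_genes * n_cells, mean = base, sd = sd),
                n_genes, n_cells,
                dimnames = list(gene_id, sprintf("c%04d", seq_len(n_cells))))
  for (p in phases) {
    rows <- which(gene_id %in% candidates$gene_id[candidates$phase == p])
    cols <- which(phase == p)
    if (length(cols)) mat[rows, cols] <- mat[rows, cols] + effect
  }
  list(mat = mat, phase = phase, candidates = candidates, phases = phases)
}
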
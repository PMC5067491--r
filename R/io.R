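# File formats: FASTQ pairs, MatrixMarket count matrices with TSV
# sidecars, annotation and report tables.

#' Write paired reads as FASTQ
#'
#' Constant quality is emitted (the simulator does not model quality
#' scores). Files ending in `.gz` are compressed.
#'
#' @param r1,r2 named character vectors (names become read ids).
#' @param path_r1,path_r2 output files.
#' @export
write_fastq_pair <- function(r1, r2, path_r1, path_r2) {
  for (side in list(list(x = r1, p = path_r1), list(x = r2, p = path_r2))) {
    ds <- Biostrings::DNAStringSet(unname(side$x))
    names(ds) <- names(side$x)
    Biostrings::writeXStringSet(ds, side$p, format = "fastq",
                                compress = grepl("\\.gz$", side$p))
  }
  invisible(c(path_r1, path_r2))
}

#' Read paired FASTQ files
#'
#' @param path_r1,path_r2 FASTQ files (optionally gzipped).
#' @return list with named character vectors `r1` and `r2`.
#' @export
read_fastq_pair <- function(path_r1, path_r2) {
  rd <- function(p) {
    ds <- Biostrings::readDNAStringSet(p, format = "fastq")
    stats::setNames(as.character(ds), sub(" .*", "", names(ds)))
  }
  r1 <- rd(path_r1)
  r2 <- rd(path_r2)
  if (length(r1) != length(r2) || !identical(names(r1), names(r2))) {
    stop("R1/R2 are not a consistent pair")
  }
  list(r1 = r1, r2 = r2)
}

#' Write a count matrix as MatrixMarket with TSV sidecars
#'
#' Writes `matrix.mtx`, `genes.tsv` and `barcodes.tsv` into `dir`;
#' raw per-barcode read counts, when attached, go to `raw_reads.tsv`.
#'
#' @param counts genes x barcodes matrix (optionally with a `raw_reads`
#'   attribute).
#' @param dir output directory (created if needed).
#' @export
write_counts_mtx <- function(counts, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(Matrix::Matrix(unclass(counts)[, , drop = FALSE],
                                 sparse = TRUE),
                  file.path(dir, "matrix.mtx"))
  writeLines(rownames(counts), file.path(dir, "genes.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  raw <- attr(counts, "raw_reads")
  if (!is.null(raw)) {
    utils::write.table(data.frame(barcode_id = names(raw),
                                  raw_reads = as.integer(raw)),
                       file.path(dir, "raw_reads.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}

#' Read a count matrix written by [write_counts_mtx()]
#'
#' @param dir directory with `matrix.mtx`, `genes.tsv`, `barcodes.tsv`
#'   (and optionally `raw_reads.tsv`).
#' @return dense integer matrix with dimnames and, when present, the
#'   `raw_reads` attribute.
#' @export
read_counts_mtx <- function(dir) {
  m <- as.matrix(Matrix::readMM(file.path(dir, "matrix.mtx")))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(readLines(file.path(dir, "genes.tsv")),
                      readLines(file.path(dir, "barcodes.tsv")))
  rr_path <- file.path(dir, "raw_reads.tsv")
  if (file.exists(rr_path)) {
    rr <- utils::read.table(rr_path, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE)
    attr(m, "raw_reads") <- stats::setNames(as.integer(rr$raw_reads),
                                            rr$barcode_id)
  }
  m
}

#' Write a full synthetic experiment to disk
#'
#' Emits gzipped FASTQ pairs, the layout/whitelist TSV, gene annotation
#' and ortholog TSVs, truth tables (spots, cells, reads), the true count
#' matrix (MatrixMarket) and a key=value echo of the configuration.
#'
#' @param sim a [simulate_experiment()] result.
#' @param dir output directory.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fastq_pair(sim$r1, sim$r2, file.path(dir, "reads_R1.fastq.gz"),
                   file.path(dir, "reads_R2.fastq.gz"))
  write_layout_tsv(sim$layout, sim$whitelist, file.path(dir, "layout.tsv"))
  tsv <- function(x, f) utils::write.table(x, file.path(dir, f), sep = "\t",
                                           quote = FALSE, row.names = FALSE)
  tsv(sim$genes, "genes_annotation.tsv")
  tsv(sim$orthologs, "orthologs.tsv")
  tsv(sim$spots, "truth_spots.tsv")
  tsv(sim$cells, "truth_cells.tsv")
  tsv(sim$reads, "truth_reads.tsv")
  tsv(data.frame(gene_id = names(sim$transcriptome),
                 sequence = unname(sim$transcriptome)), "transcriptome.tsv")
  write_counts_mtx(sim$true_counts, file.path(dir, "true_counts"))
  cfg <- sim$config
  cfg$species_mix <- paste(names(cfg$species_mix), cfg$species_mix,
                           sep = "=", collapse = ",")
  scal <- vapply(cfg, function(v) if (is.null(v)) "" else paste(v, collapse = ","),
                 character(1))
  writeLines(paste0(names(scal), "=", scal), file.path(dir, "config.txt"))
  invisible(dir)
}

#' Import external read-to-gene assignments
#'
#' TSV with columns `read_id` and `gene_id`, as produced by an external
#' aligner, bypassing the exact-match toy assigner.
#'
#' @param path TSV file.
#' @return named character vector read_id -> gene_id.
#' @export
read_gene_assignments_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("read_id", "gene_id") %in% names(tab))) {
    stop("assignment TSV needs columns read_id and gene_id")
  }
  stats::setNames(tab$gene_id, tab$read_id)
}
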
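# From paired reads to a deduplicated gene x barcode UMI count matrix.

#' Parse paired reads into barcode, UMI and transcript parts
#'
#' R1 carries the 18 nt spot barcode at positions 1-18 and the 9 nt UMI at
#' positions 19-27; the remaining 4 bases (oligo-dT anchor) are ignored.
#' R2 is the transcript mate. Reads shorter than the configured lengths
#' are skipped and counted as malformed.
#'
#' @param r1,r2 character vectors of equal length (the two mates).
#' @param barcode_len,umi_len,r1_len,r2_len read geometry (defaults
#'   18/9/31/121).
#' @return data.frame with columns `read_id` (names of `r1` or the index),
#'   `barcode`, `umi`, `transcript`; attribute `n_malformed` counts
#'   skipped pairs.
#' @export
parse_read_pairs <- function(r1, r2, barcode_len = 18L, umi_len = 9L,
                             r1_len = 31L, r2_len = 121L) {
  stopifnot(length(r1) == length(r2))
  ids <- names(r1)
  if (is.null(ids)) ids <- sprintf("read%d", seq_along(r1))
  ok <- nchar(r1) >= r1_len & nchar(r2) >= r2_len
  out <- data.frame(
    read_id = ids[ok],
    barcode = substr(r1[ok], 1L, barcode_len),
    umi = substr(r1[ok], barcode_len + 1L, barcode_len + umi_len),
    transcript = substr(r2[ok], 1L, r2_len),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "n_malformed") <- sum(!ok)
  out
}

#' Build an exact-match transcript index
#'
#' Indexes every 121-mer of every toy transcript. This stands in for a
#' spliced aligner in synthetic experiments; externally aligned reads can
#' instead be imported with [read_gene_assignments_tsv()].
#'
#' @param transcriptome named character vector of transcript sequences
#'   (one per gene, names are gene ids).
#' @param read_len indexed substring length (default 121).
#' @return object of class `masc_tx_index`.
#' @export
build_transcript_index <- function(transcriptome, read_len = 121L) {
  if (any(nchar(transcriptome) < read_len)) {
    stop("all transcripts must be at least ", read_len, " nt")
  }
  kmer_list <- lapply(seq_along(transcriptome), function(i) {
    s <- transcriptome[[i]]
    n <- nchar(s) - read_len + 1L
    unique(substring(s, seq_len(n), seq_len(n) + read_len - 1L))
  })
  kmers <- unlist(kmer_list, use.names = FALSE)
  gene <- rep(names(transcriptome), lengths(kmer_list))
  dup <- kmers %in% kmers[duplicated(kmers)]
  gene[dup] <- "__ambiguous__"
  keep <- !duplicated(kmers)
  structure(list(kmers = kmers[keep], gene = gene[keep],
                 read_len = read_len),
            class = "masc_tx_index")
}

#' Assign transcript reads to genes by exact match
#'
#' A read maps to a gene iff it occurs verbatim in exactly one gene's
#' transcript; reads occurring in two or more genes are `"__ambiguous__"`,
#' reads occurring nowhere are `NA`.
#'
#' @param transcripts character vector of 121 nt read sequences.
#' @param index a [build_transcript_index()].
#' @return character vector of gene ids / `"__ambiguous__"` / `NA`.
#' @export
assign_genes <- function(transcripts, index) {
  index$gene[match(transcripts, index$kmers)]
}

#' Collapse a UMI multiset into a molecule count
#'
#' Molecules are the connected components of the graph joining UMIs at
#' hamming distance at most `threshold`; duplicate sequences always
#' collapse. Union-find over the pairwise distances of the unique UMIs.
#'
#' @param umis character vector (multiset) of equal-length UMI sequences.
#' @param threshold hamming clustering distance (default 1; 0 counts
#'   distinct sequences).
#' @return integer molecule count.
#' @export
dedup_umis <- function(umis, threshold = 1L) {
  if (length(umis) == 0L) return(0L)
  uniq <- unique(umis)
  m <- length(uniq)
  if (m == 1L || threshold <= 0L) return(m)
  enc <- encode_seqs(uniq)
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (i in seq_len(m - 1L)) {
    d <- hamming_to_all(enc[i, ], enc[(i + 1L):m, , drop = FALSE])
    for (j in which(d <= threshold)) {
      ri <- find(i)
      rj <- find(i + j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  length(unique(vapply(seq_len(m), find, integer(1))))
}

#' Demultiplex and annotate paired reads
#'
#' Runs barcode matching, UMI validation and gene assignment, producing
#' the annotated read table that feeds filtering and counting.
#'
#' @param r1,r2 paired read sequences (named by read id).
#' @param whitelist a [barcode_whitelist()].
#' @param tx_index a [build_transcript_index()], or `NULL` when gene
#'   assignments are supplied externally via `gene_assignments` (a named
#'   character vector read id -> gene id).
#' @param max_mismatches barcode correction budget (default 2).
#' @param kmer_index optional prebuilt [build_kmer_index()].
#' @param gene_assignments optional external read -> gene table replacing
#'   the exact-match assigner.
#' @param umi_pat a [umi_pattern()].
#' @return data.frame of class `masc_reads`: `read_id`, `barcode_id`,
#'   `barcode_distance`, `umi`, `umi_valid`, `gene_id`, `ambiguous_gene`;
#'   attribute `n_malformed`.
#' @export
demux_reads <- function(r1, r2, whitelist, tx_index = NULL,
                        max_mismatches = 2L, kmer_index = NULL,
                        gene_assignments = NULL, umi_pat = umi_pattern()) {
  parsed <- parse_read_pairs(r1, r2)
  bc <- match_barcodes(parsed$barcode, whitelist, kmer_index, max_mismatches)
  if (!is.null(gene_assignments)) {
    gene <- unname(gene_assignments[parsed$read_id])
  } else if (!is.null(tx_index)) {
    gene <- assign_genes(parsed$transcript, tx_index)
  } else {
    stop("either tx_index or gene_assignments must be supplied")
  }
  out <- data.frame(
    read_id = parsed$read_id,
    barcode_id = bc$barcode_id,
    barcode_distance = bc$distance,
    umi = parsed$umi,
    umi_valid = umi_is_valid(parsed$umi, umi_pat),
    gene_id = ifelse(gene == "__ambiguous__", NA_character_, gene),
    ambiguous_gene = !is.na(gene) & gene == "__ambiguous__",
    stringsAsFactors = FALSE)
  attr(out, "n_malformed") <- attr(parsed, "n_malformed")
  class(out) <- c("masc_reads", "data.frame")
  out
}

#' Filter annotated reads before counting
#'
#' Drops reads that are unassigned (no barcode or no gene), ambiguous,
#' carry an invalid-pattern UMI, map to a ribosomal-flagged gene, or map
#' to a gene in the named-removal list (default the MALAT1-like gene,
#' removed because of oligo-dT self-priming artefacts).
#'
#' @param reads a [demux_reads()] table.
#' @param genes gene annotation data.frame with columns `gene_id`,
#'   `symbol`, `is_ribosomal`; must cover every assigned gene.
#' @param remove_symbols gene symbols to remove by name (default
#'   `"MALAT1"`).
#' @return the retained reads; attribute `filter_report` is a named
#'   integer vector with counts per filter reason
#'   (unassigned_barcode, unassigned_gene, ambiguous_gene, invalid_umi,
#'   ribosomal, named_removal, retained).
#' @export
apply_read_filters <- function(reads, genes, remove_symbols = "MALAT1") {
  assigned <- stats::na.omit(unique(reads$gene_id))
  unknown <- setdiff(assigned, genes$gene_id)
  if (length(unknown) > 0L) {
    stop("annotation mismatch: unknown gene ids ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  gi <- match(reads$gene_id, genes$gene_id)
  ribo <- !is.na(gi) & genes$is_ribosomal[gi]
  named <- !is.na(gi) & genes$symbol[gi] %in% remove_symbols
  no_bc <- is.na(reads$barcode_id)
  no_gene <- is.na(reads$gene_id) & !reads$ambiguous_gene
  bad_umi <- !reads$umi_valid
  drop <- no_bc | no_gene | reads$ambiguous_gene | bad_umi | ribo | named
  report <- c(unassigned_barcode = sum(no_bc),
              unassigned_gene = sum(no_gene),
              ambiguous_gene = sum(reads$ambiguous_gene),
              invalid_umi = sum(bad_umi),
              ribosomal = sum(ribo),
              named_removal = sum(named),
              retained = sum(!drop))
  out <- reads[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_report") <- report
  out
}

#' Build the deduplicated gene x barcode count matrix
#'
#' For every (gene, barcode) pair the UMIs of its reads are collapsed
#' with [dedup_umis()]; the matrix value is the molecule count. Raw
#' (pre-collapse) read counts per barcode are recorded in the
#' `raw_reads` attribute.
#'
#' @param reads filtered annotated reads ([apply_read_filters()] output).
#' @param gene_ids,barcode_ids the full matrix axes (rows/columns); both
#'   are sorted deterministically.
#' @param umi_threshold hamming collapse threshold (default 1).
#' @return integer matrix genes x barcodes with attribute `raw_reads`
#'   (named integer vector per barcode, before UMI collapse).
#' @export
build_count_matrix <- function(reads, gene_ids, barcode_ids,
                               umi_threshold = 1L) {
  gene_ids <- sort(unique(gene_ids))
  barcode_ids <- sort(unique(barcode_ids))
  mat <- matrix(0L, nrow = length(gene_ids), ncol = length(barcode_ids),
                dimnames = list(gene_ids, barcode_ids))
  raw <- integer(length(barcode_ids))
  names(raw) <- barcode_ids
  if (nrow(reads) > 0L) {
    bad_g <- setdiff(reads$gene_id, gene_ids)
    bad_b <- setdiff(reads$barcode_id, barcode_ids)
    if (length(bad_g) || length(bad_b)) {
      stop("reads reference genes/barcodes outside the declared axes")
    }
    tb <- table(reads$barcode_id)
    raw[names(tb)] <- as.integer(tb)
    key <- paste(reads$gene_id, reads$barcode_id, sep = "\r")
    grp <- split(reads$umi, key)
    cnt <- vapply(grp, dedup_umis, integer(1), threshold = umi_threshold)
    parts <- matrix(unlist(strsplit(names(cnt), "\r", fixed = TRUE)),
                    ncol = 2L, byrow = TRUE)
    mat[cbind(match(parts[, 1L], gene_ids),
              match(parts[, 2L], barcode_ids))] <- cnt
  }
  attr(mat, "raw_reads") <- raw
  mat
}

#' Run the complete counting pipeline on paired reads
#'
#' Demultiplex, validate, assign, filter and count in one call.
#'
#' @inheritParams demux_reads
#' @param genes gene annotation table (see [apply_read_filters()]).
#' @param barcode_ids matrix columns (default: every whitelist barcode).
#' @param umi_threshold UMI collapse threshold (default 1).
#' @param remove_symbols named-removal list (default `"MALAT1"`).
#' @return list with `counts` (the matrix, see [build_count_matrix()]),
#'   `reads` (annotated reads), `filter_report`, `n_malformed`.
#' @export
run_counting_pipeline <- function(r1, r2, whitelist, genes, tx_index = NULL,
                                  gene_assignments = NULL,
                                  barcode_ids = whitelist$barcode_id,
                                  max_mismatches = 2L, umi_threshold = 1L,
                                  remove_symbols = "MALAT1") {
  ann <- demux_reads(r1, r2, whitelist, tx_index,
                     max_mismatches = max_mismatches,
                     gene_assignments = gene_assignments)
  kept <- apply_read_filters(ann, genes, remove_symbols)
  counts <- build_count_matrix(kept, genes$gene_id, barcode_ids,
                               umi_threshold)
  list(counts = counts, reads = ann,
       filter_report = attr(kept, "filter_report"),
       n_malformed = attr(ann, "n_malformed"))
}
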
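# Two-species mixing (barnyard) analysis: species-specific read counts,
# barcode crosstalk and species calling.

#' Derive species-specific gene sets
#'
#' Species-specific genes are a species' genes minus everything in the
#' ortholog pair table; the resulting sets are disjoint by construction.
#'
#' @param genes annotation data.frame with `gene_id` and `species`.
#' @param orthologs data.frame `gene_a`, `gene_b` of ortholog pairs.
#' @return named list of gene-id vectors, one per species.
#' @export
species_specific_sets <- function(genes, orthologs) {
  orth <- c(orthologs$gene_a, orthologs$gene_b)
  sp <- unique(genes$species)
  sets <- lapply(sp, function(s) {
    setdiff(genes$gene_id[genes$species == s], orth)
  })
  names(sets) <- sp
  sets
}

#' Per-barcode species-specific read counts
#'
#' Sums raw reads over each species' specific (non-orthologous) genes.
#'
#' @param reads filtered annotated reads (columns `barcode_id`,
#'   `gene_id`); raw reads, not UMI-collapsed, following the convention
#'   that crosstalk is measured on read counts.
#' @param sets [species_specific_sets()] output (exactly two species).
#' @param barcode_ids barcodes to report (default: all present).
#' @return data.frame `barcode_id` plus one count column per species.
#' @export
species_specific_counts <- function(reads, sets,
                                    barcode_ids = sort(unique(reads$barcode_id))) {
  if (length(sets) != 2L) stop("exactly two species are required")
  covered <- unlist(sets, use.names = FALSE)
  out <- data.frame(barcode_id = barcode_ids, stringsAsFactors = FALSE)
  for (sp in names(sets)) {
    sub <- reads[reads$gene_id %in% sets[[sp]], , drop = FALSE]
    tb <- table(factor(sub$barcode_id, levels = barcode_ids))
    out[[sp]] <- as.integer(tb)
  }
  out
}

#' Barcode crosstalk (misassignment) rate
#'
#' For barcodes with known true species, the percentage of
#' species-specific reads that belong to the wrong species, per barcode
#' and aggregated per species and overall. Barcodes with zero
#' species-specific reads are excluded with a warning.
#'
#' @param counts [species_specific_counts()] output.
#' @param true_species named character vector barcode_id -> species
#'   (names must cover the barcodes in `counts`).
#' @return list with `per_barcode` (barcode_id, true_species, wrong,
#'   total, pct), `per_species` (named percentages) and `overall`
#'   (percentage over all barcodes).
#' @export
misassignment_rate <- function(counts, true_species) {
  species <- setdiff(names(counts), "barcode_id")
  truth <- true_species[counts$barcode_id]
  if (anyNA(truth)) stop("true species missing for some barcodes")
  if (!all(truth %in% species)) stop("true species outside the count table")
  cm <- as.matrix(counts[species])
  total <- rowSums(cm)
  own <- cm[cbind(seq_len(nrow(cm)), match(truth, species))]
  wrong <- total - own
  keep <- total > 0
  if (any(!keep)) {
    warning(sum(!keep), " barcode(s) without species-specific reads excluded")
  }
  per_barcode <- data.frame(barcode_id = counts$barcode_id[keep],
                            true_species = truth[keep],
                            wrong = wrong[keep], total = total[keep],
                            pct = 100 * wrong[keep] / total[keep],
                            stringsAsFactors = FALSE)
  per_species <- vapply(species, function(s) {
    i <- per_barcode$true_species == s
    if (!any(i)) return(NA_real_)
    100 * sum(per_barcode$wrong[i]) / sum(per_barcode$total[i])
  }, numeric(1))
  overall <- 100 * sum(per_barcode$wrong) / sum(per_barcode$total)
  list(per_barcode = per_barcode, per_species = per_species,
       overall = overall)
}

#' Call species per barcode by hierarchical clustering
#'
#' Barcodes are clustered on their species-specific gene profiles
#' (1 - Pearson correlation distance, average linkage, 2-cluster cut);
#' each cluster is labelled by the species whose specific reads dominate
#' it. Clusters with a majority margin below `margin` are labelled
#' `"UNRESOLVED"` rather than guessed.
#'
#' @param counts genes x barcodes matrix (UMI counts or normalized).
#' @param sets [species_specific_sets()] (two species).
#' @param margin required majority fraction within a cluster
#'   (default 0.6).
#' @return named character vector barcode_id -> species label.
#' @export
call_species <- function(counts, sets, margin = 0.6) {
  if (length(sets) != 2L) stop("exactly two species are required")
  keep_genes <- rownames(counts) %in% unlist(sets, use.names = FALSE)
  sub <- counts[keep_genes, , drop = FALSE]
  if (ncol(sub) < 2L) stop("need at least two barcodes to call species")
  sds <- apply(sub, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("degenerate constant profiles excluded from species calling")
  }
  usable <- sds > 0
  labels <- rep(NA_character_, ncol(sub))
  names(labels) <- colnames(sub)
  if (sum(usable) >= 2L) {
    d <- stats::as.dist(1 - stats::cor(sub[, usable, drop = FALSE]))
    cl <- stats::cutree(stats::hclust(d, method = "average"), k = 2L)
    sums <- vapply(names(sets), function(sp) {
      colSums(sub[rownames(sub) %in% sets[[sp]], usable, drop = FALSE])
    }, numeric(sum(usable)))
    for (k in 1:2) {
      in_k <- cl == k
      tot <- colSums(sums[in_k, , drop = FALSE])
      if (sum(tot) == 0) {
        labels[usable][in_k] <- "UNRESOLVED"
      } else {
        frac <- tot / sum(tot)
        labels[usable][in_k] <-
          if (max(frac) >= margin) names(sets)[which.max(frac)] else "UNRESOLVED"
      }
    }
  }
  labels
}
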
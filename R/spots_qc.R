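# Spot occupancy from imaged cell centroids, and the QC statistics:
# saturation curves, dropout rates, CV-vs-rank, background-gene filtering,
# library-size filtering, background read fraction.

#' Assign imaged cell centroids to array spots
#'
#' A cell is assigned to the unique spot whose centre lies within
#' `radius_um` of its centroid; with `radius_um <= pitch/2` no cell can
#' ever match two spots. Cells farther than the radius from every spot
#' stay unassigned. Spots are then classified into occupancy groups:
#' background (0 cells), single (1), doublet (2), cluster (>2).
#'
#' @param centroids data.frame with columns `cell_id`, `x_um`, `y_um`.
#' @param layout an [array_layout()].
#' @param radius_um assignment radius (default 50 um).
#' @return list with `spots` (spot_id, barcode_id, n_cells, group over all
#'   non-frame spots) and `cells` (cell_id, spot_id or NA).
#' @export
colocalize <- function(centroids, layout, radius_um = 50) {
  pitch <- attr(layout, "pitch_um")
  if (radius_um > pitch / 2) {
    stop("radius_um must be at most pitch/2 (", pitch / 2,
         ") to keep assignments unique")
  }
  sp <- layout[!layout$is_frame, , drop = FALSE]
  assigned <- rep(NA_character_, nrow(centroids))
  if (nrow(centroids) > 0L) {
    for (i in seq_len(nrow(centroids))) {
      d2 <- (sp$x_um - centroids$x_um[i])^2 + (sp$y_um - centroids$y_um[i])^2
      j <- which.min(d2)
      if (d2[j] <= radius_um^2) assigned[i] <- sp$spot_id[j]
    }
  }
  n_cells <- integer(nrow(sp))
  names(n_cells) <- sp$spot_id
  tb <- table(assigned)
  n_cells[names(tb)] <- as.integer(tb)
  spots <- data.frame(spot_id = sp$spot_id, barcode_id = sp$barcode_id,
                      n_cells = unname(n_cells),
                      group = occupancy_group(unname(n_cells)),
                      stringsAsFactors = FALSE)
  cells <- data.frame(cell_id = centroids$cell_id, spot_id = assigned,
                      stringsAsFactors = FALSE)
  list(spots = spots, cells = cells)
}

#' Sequencing saturation by read subsampling
#'
#' Reads are subsampled without replacement to each depth `B` times; the
#' UMI-collapsed unique molecule count and unique gene count are averaged
#' over repeats. At the full depth this reproduces the full-data values
#' exactly.
#'
#' @param reads filtered annotated reads (columns `barcode_id`,
#'   `gene_id`, `umi`).
#' @param depths integer vector of read depths; depths above the
#'   available reads are truncated with a warning.
#' @param B subsample repeats per depth (default 10).
#' @param umi_threshold collapse threshold (default 1).
#' @param seed integer seed.
#' @return data.frame `depth`, `mean_molecules`, `mean_genes`.
#' @export
saturation_curve <- function(reads, depths, B = 10L, umi_threshold = 1L,
                             seed = 1L) {
  set.seed(as.integer(seed))
  n <- nrow(reads)
  if (any(depths > n)) {
    warning("depths above the available ", n, " reads were truncated")
    depths <- pmin(depths, n)
  }
  depths <- sort(unique(as.integer(depths)))
  count_at <- function(idx) {
    sub <- reads[idx, , drop = FALSE]
    if (nrow(sub) == 0L) return(c(0, 0))
    key <- paste(sub$gene_id, sub$barcode_id, sep = "\r")
    mols <- sum(vapply(split(sub$umi, key), dedup_umis, integer(1),
                       threshold = umi_threshold))
    c(mols, length(unique(sub$gene_id)))
  }
  res <- t(vapply(depths, function(d) {
    if (d == n) {
      count_at(seq_len(n))       # exact, no sampling needed
    } else {
      rowMeans(vapply(seq_len(B), function(b) count_at(sample.int(n, d)),
                      numeric(2)))
    }
  }, numeric(2)))
  data.frame(depth = depths, mean_molecules = res[, 1L],
             mean_genes = res[, 2L])
}

#' Dropout rate between two expression profiles
#'
#' Percentage of genes expressed in the reference profile `b` that are
#' absent from profile `a`. Asymmetric by construction:
#' `DOR(a,b) = 100 * |{expressed in b, not in a}| / |{expressed in b}|`.
#'
#' @param a,b numeric vectors over the same gene universe (counts or
#'   normalized values); "expressed" means value > 0.
#' @return percentage in [0, 100].
#' @export
dropout_rate <- function(a, b) {
  stopifnot(length(a) == length(b))
  in_b <- b > 0
  if (!any(in_b)) stop("reference profile has no expressed genes")
  100 * sum(in_b & a <= 0) / sum(in_b)
}

#' Mean coefficient of variation over ranked gene expression
#'
#' Genes are ranked by decreasing mean (pre-log normalized) expression;
#' the per-gene CV (sd/mean) is smoothed with a rolling mean of width
#' `window`. Zero-mean genes are excluded (their CV is undefined).
#'
#' @param mat genes x cells matrix of pre-log normalized values.
#' @param window rolling-mean width (default 25; 1 gives raw CVs).
#' @return data.frame `rank`, `gene_id`, `mean_expr`, `cv`, `smoothed_cv`
#'   (NA at the window edges).
#' @export
cv_vs_rank <- function(mat, window = 25L) {
  mu <- rowMeans(mat)
  keep <- mu > 0
  mat <- mat[keep, , drop = FALSE]
  mu <- mu[keep]
  if (nrow(mat) < window) stop("need at least `window` expressed genes")
  sdv <- apply(mat, 1L, stats::sd)
  ord <- order(mu, decreasing = TRUE)
  cv <- (sdv / mu)[ord]
  smoothed <- as.numeric(stats::filter(cv, rep(1 / window, window),
                                       sides = 2L))
  data.frame(rank = seq_along(cv), gene_id = rownames(mat)[ord],
             mean_expr = mu[ord], cv = cv, smoothed_cv = smoothed)
}

#' Background gene removal list
#'
#' Ranks genes by their total expression over the background (empty-spot)
#' barcodes and returns the `top_n` most expressed that are not
#' recognized housekeeping genes. These dominate cell-free RNA and are
#' removed before downstream analysis.
#'
#' @param counts genes x barcodes matrix.
#' @param background_barcodes barcodes of background-group spots.
#' @param housekeeping gene ids exempt from removal.
#' @param top_n list size (default 50).
#' @return character vector of gene ids to remove.
#' @export
background_gene_filter <- function(counts, background_barcodes,
                                   housekeeping = character(0),
                                   top_n = 50L) {
  if (length(background_barcodes) == 0L) {
    stop("no background barcodes supplied")
  }
  bg <- rowSums(counts[, colnames(counts) %in% background_barcodes,
                       drop = FALSE])
  cand <- setdiff(names(sort(bg, decreasing = TRUE)), housekeeping)
  utils::head(cand, top_n)
}

#' Filter libraries by mean read count
#'
#' The threshold is the arithmetic mean of raw read counts over the
#' single-cell libraries; libraries strictly above it are kept (set
#' `inclusive = TRUE` for >=). With a single library (or all-equal
#' counts) the strict rule keeps nothing; a warning marks the degenerate
#' case.
#'
#' @param raw_reads named numeric vector of raw reads per single-cell
#'   barcode.
#' @param inclusive use >= instead of > (default FALSE).
#' @return character vector of kept barcode ids.
#' @export
filter_libraries_by_mean <- function(raw_reads, inclusive = FALSE) {
  if (length(raw_reads) == 0L) stop("no single-cell libraries supplied")
  thr <- mean(raw_reads)
  keep <- if (inclusive) raw_reads >= thr else raw_reads > thr
  if (!any(keep)) {
    warning("no library exceeds the mean-read threshold (degenerate input)")
  }
  names(raw_reads)[keep]
}

#' Fraction of raw reads on background barcodes
#'
#' @param raw_reads named numeric vector of raw reads per barcode (the
#'   `raw_reads` attribute of [build_count_matrix()]).
#' @param spots spot annotation (columns `barcode_id`, `group`) covering
#'   every barcode in `raw_reads`.
#' @return fraction in [0, 1] (0 when there are no reads).
#' @export
background_read_fraction <- function(raw_reads, spots) {
  miss <- setdiff(names(raw_reads), spots$barcode_id)
  if (length(miss) > 0L) {
    stop("spot annotation does not cover barcodes: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  total <- sum(raw_reads)
  if (total == 0) return(0)
  bg <- spots$barcode_id[spots$group == "background"]
  sum(raw_reads[names(raw_reads) %in% bg]) / total
}
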
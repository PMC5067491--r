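# Normalization, gene selection, permutation-based PC significance, t-SNE,
# hierarchical clustering and the two-part likelihood-ratio test for
# differential expression between clusters.

#' Normalize a count matrix to transcripts-per-scale
#'
#' Each barcode's counts are rescaled so the column total equals
#' `scale_n` (TP200K for cell lines, TP10K for the leukaemia analysis),
#' then a pseudocount is added and the values are log2-transformed.
#' All-zero barcodes cannot be rescaled and are dropped with a warning.
#'
#' @param counts genes x barcodes non-negative matrix.
#' @param scale_n target column sum before log (default 2e5; use 1e4 for
#'   TP10K).
#' @param pseudocount added before the log (default 1).
#' @return object of class `masc_norm`: list with `prelog` (column sums
#'   equal `scale_n` exactly), `log2` (`log2(prelog + pseudocount)`),
#'   `scale_n`, `pseudocount`.
#' @export
normalize_counts <- function(counts, scale_n = 2e5, pseudocount = 1) {
  if (scale_n <= 0) stop("scale_n must be positive")
  if (any(counts < 0)) stop("counts must be non-negative")
  cs <- colSums(counts)
  if (any(cs == 0)) {
    warning("dropping ", sum(cs == 0), " all-zero barcode(s)")
    counts <- counts[, cs > 0, drop = FALSE]
    cs <- cs[cs > 0]
  }
  prelog <- sweep(counts, 2L, cs / scale_n, "/")
  structure(list(prelog = prelog, log2 = log2(prelog + pseudocount),
                 scale_n = scale_n, pseudocount = pseudocount),
            class = "masc_norm")
}

#' Select the most variable genes by CV
#'
#' Ranks genes by coefficient of variation (sd/mean) of the pre-log
#' normalized values; ties break deterministically by gene id.
#'
#' @param norm a [normalize_counts()] object (or a pre-log matrix).
#' @param n number of genes (default 2000).
#' @return character vector of gene ids, highest CV first.
#' @export
select_variable_genes <- function(norm, n = 2000L) {
  mat <- if (inherits(norm, "masc_norm")) norm$prelog else norm
  if (n > nrow(mat)) stop("n exceeds the number of genes")
  mu <- rowMeans(mat)
  cv <- ifelse(mu > 0, apply(mat, 1L, stats::sd) / mu, 0)
  ord <- order(-cv, rownames(mat))
  rownames(mat)[ord][seq_len(n)]
}

#' Abundance filter with mean-centring
#'
#' Keeps genes whose mean pre-log expression is at least `min_mean`
#' (inclusive), then mean-centres each retained gene's log values across
#' cells, the form consumed by PCA.
#'
#' @param norm a [normalize_counts()] object on the TP10K scale.
#' @param min_mean inclusive mean threshold on the pre-log scale
#'   (default 6.5).
#' @return list with `genes` (retained ids) and `centred` (genes x cells
#'   matrix of row-centred log values).
#' @export
abundance_filter <- function(norm, min_mean = 6.5) {
  stopifnot(inherits(norm, "masc_norm"))
  keep <- rowMeans(norm$prelog) >= min_mean
  centred <- norm$log2[keep, , drop = FALSE]
  centred <- centred - rowMeans(centred)
  list(genes = rownames(norm$prelog)[keep], centred = centred)
}

#' Remove named background genes (and optionally mitochondrial genes)
#'
#' Drops genes listed by symbol (default the BCYRN1-like cell-free
#' background gene) from the matrix; mitochondrial-flagged genes are
#' removed too iff `include_mito` is `TRUE`, otherwise they are exempt.
#'
#' @param counts genes x barcodes matrix (rownames are gene ids).
#' @param genes annotation with `gene_id`, `symbol`, `is_mito`.
#' @param symbols symbols to remove (default `"BCYRN1"`).
#' @param include_mito also remove mitochondrial-flagged genes
#'   (default FALSE).
#' @return the matrix without the removed rows.
#' @export
remove_named_background_genes <- function(counts, genes,
                                          symbols = "BCYRN1",
                                          include_mito = FALSE) {
  ids <- genes$gene_id[genes$symbol %in% symbols]
  if (length(symbols) > 0L &&
      !any(genes$symbol %in% symbols)) {
    warning("none of the named genes are present: ",
            paste(symbols, collapse = ", "))
  }
  if (include_mito) ids <- union(ids, genes$gene_id[genes$is_mito])
  counts[!(rownames(counts) %in% ids), , drop = FALSE]
}

#' Significant principal components by gene-wise permutation
#'
#' PCA on the row-centred genes x cells matrix; the null spectrum is
#' obtained by independently permuting every gene's values across cells
#' (destroying gene-gene covariance while keeping per-gene variances) and
#' recomputing the eigenvalues. PC i is significant when
#' `p_i = (1 + #{perm lambda_i >= observed lambda_i}) / (n_perm + 1)` is
#' below `alpha`; the leading run of significant PCs is returned,
#' parallel-analysis style.
#'
#' @param mat genes x cells matrix (log normalized values; rows are
#'   centred internally).
#' @param alpha significance level (default 0.01).
#' @param n_perm number of permutations (default 100; must be at least
#'   `1/alpha - 1` for p-values below `alpha` to be attainable).
#' @param seed integer seed.
#' @param n_max highest PC index examined (default 20).
#' @return list with `n_sig` (length of the leading significant run),
#'   `p_values`, `eigenvalues`, and `scores` (cells x `n_sig` PC scores;
#'   cells x 1 of zeros if none significant).
#' @export
significant_pcs <- function(mat, alpha = 0.01, n_perm = 100L, seed = 1L,
                            n_max = 20L) {
  if (ncol(mat) < 3L) stop("need at least 3 cells")
  if (n_perm < ceiling(1 / alpha) - 1L) {
    stop("n_perm too small to resolve p-values below alpha")
  }
  set.seed(as.integer(seed))
  X <- mat - rowMeans(mat)
  n_max <- min(n_max, nrow(X), ncol(X) - 1L)
  sv <- svd(X, nu = 0L, nv = n_max)
  obs <- sv$d[seq_len(n_max)]^2
  exceed <- integer(n_max)
  for (p in seq_len(n_perm)) {
    P <- X
    for (g in seq_len(nrow(P))) P[g, ] <- P[g, sample.int(ncol(P))]
    d <- svd(P, nu = 0L, nv = 0L)$d[seq_len(n_max)]
    exceed <- exceed + (d^2 >= obs)
  }
  p_values <- (1 + exceed) / (n_perm + 1)
  sig <- p_values < alpha
  n_sig <- if (!sig[1L]) 0L else which.min(c(sig, FALSE)) - 1L
  scores <- if (n_sig > 0L) {
    sweep(sv$v[, seq_len(n_sig), drop = FALSE], 2L, sv$d[seq_len(n_sig)], "*")
  } else {
    matrix(0, ncol(mat), 1L)
  }
  rownames(scores) <- colnames(mat)
  list(n_sig = as.integer(n_sig), p_values = p_values, eigenvalues = obs,
       scores = scores)
}

#' t-SNE embedding of cells
#'
#' Thin wrapper around Rtsne on PC scores (or any cells x features
#' matrix); deterministic under a fixed seed. Defaults follow the
#' pipeline convention of 10,000 iterations and perplexity 30; two- or
#' three-dimensional output.
#'
#' @param scores cells x features numeric matrix.
#' @param dims 2 or 3 (default 2).
#' @param n_iter gradient-descent iterations (default 10000).
#' @param perplexity t-SNE perplexity (default 30; must satisfy
#'   `3 * perplexity < n cells - 1`).
#' @param seed integer seed.
#' @return cells x dims coordinate matrix.
#' @export
tsne_embed <- function(scores, dims = 2L, n_iter = 10000L,
                       perplexity = 30, seed = 1L) {
  if (!dims %in% c(2L, 3L)) stop("dims must be 2 or 3")
  if (3 * perplexity >= nrow(scores) - 1) {
    stop("perplexity too large for ", nrow(scores), " cells")
  }
  set.seed(as.integer(seed))
  fit <- Rtsne::Rtsne(as.matrix(scores), dims = dims, max_iter = n_iter,
                      perplexity = perplexity, pca = FALSE,
                      check_duplicates = FALSE)
  out <- fit$Y
  rownames(out) <- rownames(scores)
  out
}

#' Hierarchical clustering on Pearson correlation distance
#'
#' Cells are clustered on `d = 1 - Pearson r` between their profiles with
#' agglomerative linkage (average by default); zero-variance profiles
#' have no defined correlation and are excluded with a warning (label
#' `NA`).
#'
#' @param mat genes x cells matrix (or cells x PCs with
#'   `cells_in_rows = TRUE`).
#' @param k number of clusters for the cut.
#' @param linkage hclust method (default `"average"`).
#' @param cells_in_rows set when `mat` is cells x features.
#' @return list with `labels` (named integer vector, `NA` for excluded
#'   cells) and `tree` (the hclust dendrogram).
#' @export
hcluster <- function(mat, k, linkage = "average", cells_in_rows = FALSE) {
  if (cells_in_rows) mat <- t(mat)
  if (ncol(mat) < 2L) stop("need at least two cells")
  sds <- apply(mat, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0), " zero-variance cell profile(s)")
  }
  usable <- sds > 0
  d <- stats::as.dist(1 - stats::cor(mat[, usable, drop = FALSE]))
  tree <- stats::hclust(d, method = linkage)
  labels <- rep(NA_integer_, ncol(mat))
  names(labels) <- colnames(mat)
  labels[usable] <- stats::cutree(tree, k = k)
  list(labels = labels, tree = tree)
}

#' Two-part likelihood-ratio test for differential expression
#'
#' Per gene, expression is modelled in two parts: detection as
#' Bernoulli(pi) and the positive log values as Normal(mu, sigma^2) with
#' a shared sigma. The null model shares (pi, mu) across clusters; the
#' alternative gives each cluster its own (pi_k, mu_k). The statistic
#' `Lambda = 2 (l_alt - l_null)` is compared to chi-square with
#' `2 (K - 1)` degrees of freedom. When a gene has no zeros (or no
#' positives) anywhere the Bernoulli part carries no information and is
#' dropped with its K-1 df; the Normal part's df counts only clusters
#' with at least one positive observation. Genes that are all-zero are
#' excluded.
#'
#' @param mat genes x cells matrix of log normalized values, 0 meaning
#'   undetected.
#' @param labels cluster label per cell (>= 2 clusters, each >= 2 cells).
#' @param alpha significance threshold on the raw p-value
#'   (default 0.001, no multiple-testing correction, matching the
#'   pipeline convention).
#' @return data.frame of class `masc_de`: `gene_id`, `statistic`, `df`,
#'   `p_value`, `significant`, plus per-cluster detection fractions
#'   (`pi_<k>`) and positive means (`mu_<k>`).
#' @export
lrt_de <- function(mat, labels, alpha = 0.001) {
  labels <- as.factor(labels)
  K <- nlevels(labels)
  if (K < 2L) stop("need at least two clusters")
  if (any(table(labels) < 2L)) stop("every cluster needs at least two cells")
  if (length(labels) != ncol(mat)) stop("one label per cell required")
  keep <- rowSums(mat > 0) > 0L
  mat <- mat[keep, , drop = FALSE]
  G <- nrow(mat)
  cl_idx <- split(seq_along(labels), labels)
  res <- matrix(NA_real_, G, 3L + 2L * K)
  for (g in seq_len(G)) {
    x <- mat[g, ]
    res[g, ] <- lrt_de_one(x, cl_idx, K)
  }
  out <- data.frame(gene_id = rownames(mat), statistic = res[, 1L],
                    df = as.integer(res[, 2L]), p_value = res[, 3L],
                    stringsAsFactors = FALSE)
  out$significant <- out$p_value < alpha
  for (k in seq_len(K)) {
    out[[paste0("pi_", levels(labels)[k])]] <- res[, 3L + k]
    out[[paste0("mu_", levels(labels)[k])]] <- res[, 3L + K + k]
  }
  class(out) <- c("masc_de", "data.frame")
  out
}

# one gene's two-part LRT; x = log values (0 = undetected),
# cl_idx = list of cell indices per cluster
lrt_de_one <- function(x, cl_idx, K) {
  det <- x > 0
  n <- length(x)
  pos <- x[det]
  pi_k <- vapply(cl_idx, function(i) mean(det[i]), numeric(1))
  mu_k <- vapply(cl_idx, function(i) {
    p <- x[i][det[i]]
    if (length(p)) mean(p) else NA_real_
  }, numeric(1))
  stat <- 0
  df <- 0L
  # Bernoulli part: informative only if the gene has both states overall
  if (any(det) && any(!det)) {
    ll <- function(p, n1, n0) {
      ifelse(n1 > 0, n1 * log(p), 0) + ifelse(n0 > 0, n0 * log(1 - p), 0)
    }
    n1 <- vapply(cl_idx, function(i) sum(det[i]), numeric(1))
    n0 <- vapply(cl_idx, function(i) sum(!det[i]), numeric(1))
    p_hat <- ifelse(n1 + n0 > 0, n1 / (n1 + n0), 0)
    l_alt <- sum(ll(pmin(pmax(p_hat, 1e-12), 1 - 1e-12), n1, n0))
    p0 <- sum(n1) / n
    l_null <- sum(ll(p0, n1, n0))
    stat <- stat + 2 * (l_alt - l_null)
    df <- df + (K - 1L)
  }
  # Normal part on positive values: clusters with >= 1 positive contribute
  m <- sum(!is.na(mu_k))
  n_pos <- length(pos)
  if (m >= 2L && n_pos > m) {
    cl_pos <- lapply(cl_idx, function(i) x[i][det[i]])
    rss_alt <- sum(vapply(cl_pos, function(p) {
      if (length(p)) sum((p - mean(p))^2) else 0
    }, numeric(1)))
    rss_null <- sum((pos - mean(pos))^2)
    if (rss_alt <= 0) {
      stat <- if (rss_null > 0) Inf else stat
    } else {
      stat <- stat + n_pos * log(rss_null / rss_alt)
    }
    df <- df + (m - 1L)
  }
  p <- if (df == 0L || stat <= 0) 1 else
    stats::pchisq(stat, df = df, lower.tail = FALSE)
  c(max(stat, 0), df, p, pi_k, mu_k)
}

#' Overlap of the most abundant genes across groups
#'
#' For each group's normalized matrix, takes the `top_n` genes by mean
#' expression and reports exclusive counts, pairwise intersections and
#' the common intersection.
#'
#' @param mats named list of genes x cells matrices on a shared gene
#'   universe (pre-log normalized values).
#' @param top_n list size per group (default 500).
#' @return list with `top` (named list of gene vectors), `exclusive`
#'   (named counts), `pairwise` (data.frame group_a, group_b, shared) and
#'   `common` (size of the intersection of all groups).
#' @export
top_abundant_overlap <- function(mats, top_n = 500L) {
  if (is.null(names(mats)) || length(mats) < 2L) {
    stop("mats must be a named list of at least two matrices")
  }
  top <- lapply(mats, function(m) {
    if (top_n > nrow(m)) stop("top_n exceeds the gene universe")
    mu <- rowMeans(m)
    rownames(m)[order(-mu, rownames(m))][seq_len(top_n)]
  })
  groups <- names(mats)
  exclusive <- vapply(groups, function(g) {
    others <- unlist(top[setdiff(groups, g)], use.names = FALSE)
    sum(!(top[[g]] %in% others))
  }, integer(1))
  pairs <- utils::combn(groups, 2L)
  pairwise <- data.frame(group_a = pairs[1L, ], group_b = pairs[2L, ],
                         shared = apply(pairs, 2L, function(p) {
                           length(intersect(top[[p[1L]]], top[[p[2L]]]))
                         }), stringsAsFactors = FALSE)
  common <- length(Reduce(intersect, top))
  list(top = top, exclusive = exclusive, pairwise = pairwise,
       common = common)
}
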
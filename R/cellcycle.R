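# Cell-cycle phase scoring: correlation-based gene filtering, double
# z-score phase scores, cycling calls.

PHASES <- c("G1/S", "S", "G2/M", "M", "M/G1")

#' Filter candidate phase genes by correlation to the phase profile
#'
#' For each of the five phases, the mean profile of its candidate genes
#' across cells is computed and only genes with Pearson `r > r_threshold`
#' to that profile are retained. A phase left empty is an error naming
#' the phase.
#'
#' @param mat genes x cells matrix of log normalized values.
#' @param candidates data.frame with columns `gene_id`, `phase` (phases
#'   must be among `"G1/S", "S", "G2/M", "M", "M/G1"`).
#' @param r_threshold correlation threshold (default 0.3, exclusive).
#' @return object of class `masc_phase_sets`: named list of data.frames
#'   (`gene_id`, `r`) per phase, in canonical phase order.
#' @export
filter_phase_genes <- function(mat, candidates, r_threshold = 0.3) {
  if (!all(candidates$phase %in% PHASES)) {
    stop("candidate phases must be among: ", paste(PHASES, collapse = ", "))
  }
  sets <- lapply(PHASES, function(p) {
    ids <- intersect(candidates$gene_id[candidates$phase == p],
                     rownames(mat))
    if (length(ids) == 0L) stop("no candidate genes found for phase ", p)
    sub <- mat[ids, , drop = FALSE]
    profile <- colMeans(sub)
    r <- apply(sub, 1L, function(g) {
      if (stats::sd(g) == 0 || stats::sd(profile) == 0) return(NA_real_)
      stats::cor(g, profile)
    })
    keep <- !is.na(r) & r > r_threshold
    if (!any(keep)) stop("phase ", p, " is empty after the r > ",
                         r_threshold, " filter")
    data.frame(gene_id = ids[keep], r = unname(r[keep]),
               stringsAsFactors = FALSE)
  })
  names(sets) <- PHASES
  class(sets) <- c("masc_phase_sets", class(sets))
  sets
}

#' Per-cell phase scores with two-step normalization
#'
#' (1) each gene is z-scored across cells; (2) the raw phase score is the
#' mean z over the phase's genes; (3) each phase's scores are z-scored
#' across cells; (4) the five scores are centred within each cell, so a
#' cell's scores always average zero and its argmax names the most likely
#' current phase. Zero-variance genes are dropped with a warning.
#'
#' @param mat genes x cells matrix of log normalized values.
#' @param sets a [filter_phase_genes()] result.
#' @return object of class `masc_phase_scores`: list with `scores`
#'   (cells x 5 matrix) and `phase` (per-cell argmax phase).
#' @export
phase_scores <- function(mat, sets) {
  used <- unique(unlist(lapply(sets, `[[`, "gene_id")))
  sub <- mat[used, , drop = FALSE]
  sds <- apply(sub, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping ", sum(sds == 0), " zero-variance gene(s)")
    sub <- sub[sds > 0, , drop = FALSE]
  }
  z <- (sub - rowMeans(sub)) / apply(sub, 1L, stats::sd)
  raw <- vapply(names(sets), function(p) {
    ids <- intersect(sets[[p]]$gene_id, rownames(z))
    if (length(ids) == 0L) stop("phase ", p, " lost all genes")
    colMeans(z[ids, , drop = FALSE])
  }, numeric(ncol(z)))
  step3 <- scale(raw)                      # z across cells, per phase
  scores <- step3 - rowMeans(step3)        # centre within each cell
  attr(scores, "scaled:center") <- NULL
  attr(scores, "scaled:scale") <- NULL
  colnames(scores) <- names(sets)
  rownames(scores) <- colnames(mat)
  phase <- colnames(scores)[max.col(scores, ties.method = "first")]
  names(phase) <- rownames(scores)
  structure(list(scores = scores, phase = phase),
            class = "masc_phase_scores")
}

#' Call cycling cells from phase scores
#'
#' A cell is flagged cycling when its maximum phase score reaches
#' `score_threshold` (on the z scale). When a `group` vector is given the
#' cycling fraction is additionally reported per group.
#'
#' @param ps a [phase_scores()] result.
#' @param score_threshold cycling call threshold (default 1.0).
#' @param group optional per-cell grouping (e.g. patient subset).
#' @return list with `cycling` (named logical), `fraction` (overall) and
#'   `by_group` (named fractions, `NULL` without groups).
#' @export
call_cycling <- function(ps, score_threshold = 1.0, group = NULL) {
  mx <- apply(ps$scores, 1L, max)
  cycling <- mx >= score_threshold
  by_group <- NULL
  if (!is.null(group)) {
    if (length(group) != length(cycling)) stop("one group per cell required")
    by_group <- tapply(cycling, group, mean)
  }
  list(cycling = cycling, fraction = mean(cycling), by_group = by_group)
}

#' Group-wise phase scores
#'
#' Recomputes [phase_scores()] independently within each group of cells
#' (e.g. per patient subset), so scores are normalized against the
#' group's own population.
#'
#' @param mat genes x cells matrix of log normalized values.
#' @param sets a [filter_phase_genes()] result.
#' @param group per-cell grouping vector.
#' @return named list of [phase_scores()] results, one per group.
#' @export
phase_scores_by_group <- function(mat, sets, group) {
  if (length(group) != ncol(mat)) stop("one group per cell required")
  lapply(split(seq_len(ncol(mat)), group), function(i) {
    phase_scores(mat[, i, drop = FALSE], sets)
  })
}
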
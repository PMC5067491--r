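# Barcoded array model: whitelist, layout geometry, UMI pattern and the
# kmer-based approximate barcode matcher.

BASES <- c("A", "C", "G", "T")

# Encode sequences as an integer matrix (A=1,C=2,G=3,T=4, anything else 0).
# Row i is sequence i. 0 (e.g. N) mismatches every base including itself.
encode_seqs <- function(seqs) {
  if (length(seqs) == 0L) {
    return(matrix(integer(0), nrow = 0, ncol = 0))
  }
  L <- unique(nchar(seqs))
  if (length(L) != 1L) {
    stop("sequences must all have equal length")
  }
  chars <- strsplit(seqs, "", fixed = TRUE)
  m <- matrix(match(unlist(chars), BASES, nomatch = 0L),
              nrow = length(seqs), ncol = L, byrow = TRUE)
  m[is.na(m)] <- 0L
  m
}

# Hamming distance of one encoded read (integer vector) to each row of an
# encoded matrix. Code 0 counts as mismatch to everything.
hamming_to_all <- function(read_enc, mat_enc) {
  neq <- mat_enc != rep(read_enc, each = nrow(mat_enc))
  amb <- mat_enc == 0L | rep(read_enc == 0L, each = nrow(mat_enc))
  as.integer(rowSums(neq | amb))
}

#' Pairwise minimum hamming distance of a set of equal-length sequences
#'
#' Brute-force scan over all pairs; used both to certify generated
#' whitelists and as an independent check in tests.
#'
#' @param seqs character vector of equal-length sequences.
#' @return integer, the minimum pairwise hamming distance (`Inf` if fewer
#'   than two sequences).
#' @export
min_pairwise_distance <- function(seqs) {
  n <- length(seqs)
  if (n < 2L) return(Inf)
  enc <- encode_seqs(seqs)
  best <- ncol(enc)
  for (i in seq_len(n - 1L)) {
    d <- hamming_to_all(enc[i, ], enc[(i + 1L):n, , drop = FALSE])
    best <- min(best, d)
    if (best == 0L) break
  }
  as.integer(best)
}

#' Construct a barcode whitelist
#'
#' @param barcode_id character vector of unique barcode identifiers.
#' @param sequence character vector of distinct 18 nt sequences over ACGT.
#' @param check_distance if `TRUE` (default) the true minimum pairwise
#'   hamming distance is computed and recorded.
#' @return an object of class `masc_whitelist`: a data.frame with columns
#'   `barcode_id` and `sequence`, attribute `min_pairwise_distance`.
#' @export
barcode_whitelist <- function(barcode_id, sequence, check_distance = TRUE) {
  stopifnot(length(barcode_id) == length(sequence))
  if (anyDuplicated(barcode_id)) stop("barcode ids must be unique")
  if (anyDuplicated(sequence)) stop("barcode sequences must be distinct")
  if (any(nchar(sequence) != 18L)) stop("barcode sequences must be 18 nt")
  if (any(grepl("[^ACGT]", sequence))) stop("barcode sequences must be over {A,C,G,T}")
  wl <- data.frame(barcode_id = as.character(barcode_id),
                   sequence = as.character(sequence),
                   stringsAsFactors = FALSE)
  attr(wl, "min_pairwise_distance") <-
    if (check_distance) min_pairwise_distance(wl$sequence) else NA_integer_
  class(wl) <- c("masc_whitelist", "data.frame")
  wl
}

#' Generate a random barcode whitelist with a guaranteed minimum distance
#'
#' Rejection sampling: candidate 18-mers are drawn uniformly and accepted
#' only if they keep the minimum pairwise hamming distance at or above
#' `min_distance`. Deterministic under a fixed seed.
#'
#' @param n number of barcodes (the default array carries 1007).
#' @param min_distance required minimum pairwise hamming distance; the
#'   default 5 makes 2-mismatch decoding provably unambiguous (2k+1, k=2).
#' @param seed integer seed.
#' @param max_tries rejection budget.
#' @return a [barcode_whitelist()] object with ids `BC0001`, `BC0002`, ...
#' @export
generate_whitelist <- function(n = 1007L, min_distance = 5L, seed = 1L,
                               max_tries = max(200L * n, 20000L)) {
  stopifnot(n >= 1L, min_distance >= 0L, min_distance <= 18L)
  set.seed(as.integer(seed))
  acc <- matrix(0L, nrow = n, ncol = 18L)
  kept <- 0L
  tries <- 0L
  while (kept < n) {
    tries <- tries + 1L
    if (tries > max_tries) {
      stop("whitelist generation failed: rejection budget exhausted (",
           kept, "/", n, " barcodes at distance >= ", min_distance, ")")
    }
    cand <- sample.int(4L, 18L, replace = TRUE)
    ok <- kept == 0L ||
      min(hamming_to_all(cand, acc[seq_len(kept), , drop = FALSE])) >= min_distance
    if (ok) {
      kept <- kept + 1L
      acc[kept, ] <- cand
    }
  }
  seqs <- apply(acc, 1L, function(r) paste(BASES[r], collapse = ""))
  wl <- barcode_whitelist(sprintf("BC%04d", seq_len(n)), seqs,
                          check_distance = FALSE)
  attr(wl, "min_pairwise_distance") <-
    if (n >= 2L) min_pairwise_distance(seqs) else NA_integer_
  if (n >= 2L && attr(wl, "min_pairwise_distance") < min_distance) {
    stop("internal error: generated whitelist violates requested distance")
  }
  wl
}

#' Build a kmer index over a barcode whitelist
#'
#' The 18 nt barcodes are cut into disjoint segments of `segment_length`
#' nucleotides. A read with at most `max_mismatches` substitutions must
#' match at least one segment exactly (pigeonhole), so looking up every
#' (segment, offset) of the read retrieves a candidate set guaranteed to
#' contain the true source barcode.
#'
#' @param whitelist a [barcode_whitelist()].
#' @param segment_length segment size; must divide 18. The default 6 gives
#'   three disjoint segments, enough for 2-mismatch correction.
#' @return an object of class `masc_kmer_index`.
#' @export
build_kmer_index <- function(whitelist, segment_length = 6L) {
  segment_length <- as.integer(segment_length)
  if (18L %% segment_length != 0L) {
    stop("segment_length must divide 18 (got ", segment_length, ")")
  }
  n_seg <- 18L %/% segment_length
  offsets <- (seq_len(n_seg) - 1L) * segment_length
  tab <- new.env(parent = emptyenv(), hash = TRUE,
                 size = nrow(whitelist) * n_seg)
  for (i in seq_len(nrow(whitelist))) {
    s <- whitelist$sequence[i]
    for (off in offsets) {
      key <- paste0(off, ":", substr(s, off + 1L, off + segment_length))
      tab[[key]] <- c(tab[[key]], i)
    }
  }
  structure(list(table = tab, segment_length = segment_length,
                 offsets = offsets, n_barcodes = nrow(whitelist)),
            class = "masc_kmer_index")
}

# Candidate whitelist row indices for one observed barcode.
kmer_candidates <- function(observed, index) {
  sl <- index$segment_length
  idx <- integer(0)
  for (off in index$offsets) {
    key <- paste0(off, ":", substr(observed, off + 1L, off + sl))
    hit <- index$table[[key]]
    if (!is.null(hit)) idx <- c(idx, hit)
  }
  unique(idx)
}

#' Match observed barcode sequences against a whitelist
#'
#' kmer candidate retrieval followed by exact hamming scoring of the
#' candidates. A read is assigned iff exactly one whitelist entry sits at
#' hamming distance at most `max_mismatches` and strictly below every
#' other entry; ties are returned as unassigned so that decoder choices
#' can never manufacture barcode crosstalk. `N` bases mismatch everything.
#'
#' @param observed character vector of observed 18 nt sequences
#'   (over ACGTN).
#' @param whitelist a [barcode_whitelist()].
#' @param index optional prebuilt [build_kmer_index()]; built on the fly
#'   when `NULL`.
#' @param max_mismatches maximum correctable substitutions (default 2).
#' @return data.frame with columns `barcode_id` (`NA` when unassigned) and
#'   `distance` (`NA` when unassigned).
#' @export
match_barcodes <- function(observed, whitelist, index = NULL,
                           max_mismatches = 2L) {
  if (any(nchar(observed) != 18L)) {
    stop("malformed read: observed barcodes must be 18 nt")
  }
  if (is.null(index)) index <- build_kmer_index(whitelist)
  n_seg <- 18L %/% index$segment_length
  if (n_seg < max_mismatches + 1L) {
    stop("segment count too small for requested max_mismatches (pigeonhole)")
  }
  enc <- encode_seqs(whitelist$sequence)
  obs_enc <- encode_seqs(observed)
  out_id <- rep(NA_character_, length(observed))
  out_d <- rep(NA_integer_, length(observed))
  for (r in seq_along(observed)) {
    cand <- kmer_candidates(observed[r], index)
    if (length(cand) == 0L) next
    d <- hamming_to_all(obs_enc[r, ], enc[cand, , drop = FALSE])
    dmin <- min(d)
    if (dmin > max_mismatches) next
    # any tie at <= max_mismatches is itself within max_mismatches of the
    # read, hence in the candidate set: the restricted scan is exact
    if (sum(d == dmin) > 1L) next
    out_id[r] <- whitelist$barcode_id[cand[which.min(d)]]
    out_d[r] <- dmin
  }
  data.frame(barcode_id = out_id, distance = out_d, stringsAsFactors = FALSE)
}

#' Match a single observed barcode
#'
#' Scalar convenience wrapper around [match_barcodes()].
#'
#' @inheritParams match_barcodes
#' @return list with `barcode_id` and `distance`, both `NA` when the read
#'   is unassigned.
#' @export
match_barcode <- function(observed, whitelist, index = NULL,
                          max_mismatches = 2L) {
  res <- match_barcodes(observed, whitelist, index, max_mismatches)
  list(barcode_id = res$barcode_id[1L], distance = res$distance[1L])
}

# ---- UMI pattern ----------------------------------------------------------

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  W = c("A", "T"), S = c("C", "G"), M = c("A", "C"), K = c("G", "T"),
  R = c("A", "G"), Y = c("C", "T"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

#' The semi-randomized UMI pattern
#'
#' The array UMIs follow the 9 nt IUPAC pattern `WSNNWSNNV`
#' (W = A/T, S = C/G, N = any, V = A/C/G), giving
#' 2*2*4*4*2*2*4*4*3 = 12288 valid UMI sequences.
#'
#' @param code IUPAC string (default `"WSNNWSNNV"`).
#' @return object of class `masc_umi_pattern` with the per-position
#'   allowed base sets and the size of the valid-UMI space.
#' @export
umi_pattern <- function(code = "WSNNWSNNV") {
  chars <- strsplit(code, "", fixed = TRUE)[[1L]]
  if (!all(chars %in% names(IUPAC_SETS))) stop("invalid IUPAC code in pattern")
  sets <- IUPAC_SETS[chars]
  structure(list(code = code, sets = sets,
                 space_size = prod(lengths(sets))),
            class = "masc_umi_pattern")
}

#' Validate UMI sequences against the pattern
#'
#' @param umi character vector of UMI sequences (over ACGTN).
#' @param pattern a [umi_pattern()].
#' @return logical vector; `N` is never allowed, sequences of the wrong
#'   length are invalid.
#' @export
umi_is_valid <- function(umi, pattern = umi_pattern()) {
  L <- length(pattern$sets)
  ok <- nchar(umi) == L
  if (!any(ok)) return(ok)
  idx <- which(ok)
  chars <- matrix(unlist(strsplit(umi[idx], "", fixed = TRUE)),
                  nrow = length(idx), ncol = L, byrow = TRUE)
  valid <- rep(TRUE, length(idx))
  for (p in seq_len(L)) {
    valid <- valid & chars[, p] %in% pattern$sets[[p]]
  }
  ok[idx] <- valid
  ok
}

#' Sample UMIs uniformly from the valid pattern space
#'
#' @param n number of UMIs to draw (collisions permitted).
#' @param pattern a [umi_pattern()].
#' @return character vector of length `n`.
#' @export
sample_umis <- function(n, pattern = umi_pattern()) {
  cols <- lapply(pattern$sets, function(s) {
    s[sample.int(length(s), n, replace = TRUE)]
  })
  do.call(paste0, cols)
}

# ---- Array layout ---------------------------------------------------------

#' Build the default barcoded array layout
#'
#' A 33 x 35 spot grid at 200 um centre-to-centre pitch. The full
#' perimeter (132 spots) is an orientation frame, and the four 2x2 interior
#' blocks adjacent to the corners (16 spots) are reserved, leaving 1007
#' interior spots that each carry one unique whitelist barcode. Row/col
#' indices are 0-based, spot ids row-major, and physical coordinates are
#' `x_um = col * pitch`, `y_um = row * pitch` with the origin at the centre
#' of spot (0,0). Any other geometry can be supplied via
#' [read_layout_tsv()].
#'
#' @param whitelist a [barcode_whitelist()] with at least as many entries
#'   as there are non-frame spots.
#' @param n_rows,n_cols grid dimensions (defaults 33 x 35).
#' @param pitch_um centre-to-centre pitch in micrometres (default 200).
#' @return object of class `masc_layout`: a data.frame with columns
#'   `spot_id`, `row`, `col`, `x_um`, `y_um`, `barcode_id` (`NA` on frame
#'   spots), `is_frame`; attributes `n_rows`, `n_cols`, `pitch_um`.
#' @export
array_layout <- function(whitelist, n_rows = 33L, n_cols = 35L,
                         pitch_um = 200) {
  stopifnot(n_rows >= 3L, n_cols >= 3L, pitch_um > 0)
  row <- rep(seq_len(n_rows) - 1L, each = n_cols)
  col <- rep(seq_len(n_cols) - 1L, times = n_rows)
  frame <- row == 0L | row == n_rows - 1L | col == 0L | col == n_cols - 1L
  # reserved 2x2 interior corner blocks
  near_lo_r <- row %in% c(1L, 2L)
  near_hi_r <- row %in% c(n_rows - 3L, n_rows - 2L)
  near_lo_c <- col %in% c(1L, 2L)
  near_hi_c <- col %in% c(n_cols - 3L, n_cols - 2L)
  reserved <- (near_lo_r | near_hi_r) & (near_lo_c | near_hi_c)
  frame <- frame | reserved
  n_bc <- sum(!frame)
  if (nrow(whitelist) < n_bc) {
    stop("whitelist has ", nrow(whitelist), " barcodes but the layout needs ",
         n_bc)
  }
  barcode_id <- rep(NA_character_, length(row))
  barcode_id[!frame] <- whitelist$barcode_id[seq_len(n_bc)]
  layout <- data.frame(
    spot_id = sprintf("S%04d", seq_along(row)),
    row = row, col = col,
    x_um = col * pitch_um, y_um = row * pitch_um,
    barcode_id = barcode_id, is_frame = frame,
    stringsAsFactors = FALSE
  )
  attr(layout, "n_rows") <- as.integer(n_rows)
  attr(layout, "n_cols") <- as.integer(n_cols)
  attr(layout, "pitch_um") <- pitch_um
  class(layout) <- c("masc_layout", "data.frame")
  layout
}

#' Write a combined layout + whitelist TSV
#'
#' Columns `spot_id`, `row`, `col`, `barcode_id`, `sequence`,
#' `is_frame` (0/1), tab-delimited with header.
#'
#' @param layout a [array_layout()].
#' @param whitelist the matching [barcode_whitelist()].
#' @param path output file.
#' @export
write_layout_tsv <- function(layout, whitelist, path) {
  seq_of <- whitelist$sequence[match(layout$barcode_id, whitelist$barcode_id)]
  out <- data.frame(spot_id = layout$spot_id, row = layout$row,
                    col = layout$col, barcode_id = layout$barcode_id,
                    sequence = seq_of, is_frame = as.integer(layout$is_frame),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a combined layout + whitelist TSV
#'
#' Inverse of [write_layout_tsv()]; grid size is inferred from the
#' row/col indices.
#'
#' @param path TSV file with columns `spot_id`, `row`, `col`,
#'   `barcode_id`, `sequence`, `is_frame`.
#' @param pitch_um centre-to-centre pitch (not stored in the file).
#' @return list with elements `layout` and `whitelist`.
#' @export
read_layout_tsv <- function(path, pitch_um = 200) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           colClasses = c(spot_id = "character",
                                          barcode_id = "character",
                                          sequence = "character"),
                           na.strings = "", stringsAsFactors = FALSE)
  need <- c("spot_id", "row", "col", "barcode_id", "sequence", "is_frame")
  if (!all(need %in% names(tab))) {
    stop("layout TSV must have columns ", paste(need, collapse = ", "))
  }
  bc <- tab[!is.na(tab$barcode_id) & tab$is_frame == 0L, ]
  if (anyDuplicated(bc$barcode_id)) stop("each barcode_id may be used at most once")
  wl <- barcode_whitelist(bc$barcode_id, bc$sequence)
  layout <- data.frame(
    spot_id = tab$spot_id, row = tab$row, col = tab$col,
    x_um = tab$col * pitch_um, y_um = tab$row * pitch_um,
    barcode_id = tab$barcode_id, is_frame = tab$is_frame != 0L,
    stringsAsFactors = FALSE
  )
  attr(layout, "n_rows") <- max(tab$row) + 1L
  attr(layout, "n_cols") <- max(tab$col) + 1L
  attr(layout, "pitch_um") <- pitch_um
  class(layout) <- c("masc_layout", "data.frame")
  list(layout = layout, whitelist = wl)
}
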
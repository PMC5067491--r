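# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: distances by direct character comparison,
# components via igraph, linkage by naive agglomeration.

# hamming distance between two equal-length strings, character by character
oracle_hamming <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  sum(ca != cb | ca == "N" | cb == "N")
}

# exhaustive full-scan barcode matcher: unique strict minimum within
# max_mm, else NA. Vectorized over reads via a character matrix.
oracle_match_scan <- function(observed, whitelist, max_mm = 2L) {
  wl_chars <- do.call(rbind, strsplit(whitelist$sequence, ""))
  out_id <- rep(NA_character_, length(observed))
  out_d <- rep(NA_integer_, length(observed))
  for (i in seq_along(observed)) {
    rc <- strsplit(observed[i], "")[[1]]
    neq <- sweep(wl_chars, 2L, rc, "!=") |
      wl_chars == "N" | matrix(rc == "N", nrow(wl_chars), 18, byrow = TRUE)
    d <- as.integer(rowSums(neq))
    dmin <- min(d)
    if (dmin <= max_mm && sum(d == dmin) == 1L) {
      out_id[i] <- whitelist$barcode_id[which.min(d)]
      out_d[i] <- dmin
    }
  }
  data.frame(barcode_id = out_id, distance = out_d, stringsAsFactors = FALSE)
}

# connected-component count of a UMI multiset via igraph
oracle_umi_components <- function(umis, threshold) {
  uniq <- unique(umis)
  m <- length(uniq)
  if (m == 0L) return(0L)
  if (m == 1L) return(1L)
  adj <- matrix(FALSE, m, m)
  for (i in seq_len(m - 1L)) {
    for (j in (i + 1L):m) {
      adj[i, j] <- adj[j, i] <- oracle_hamming(uniq[i], uniq[j]) <= threshold
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  as.integer(igraph::components(g)$no)
}

# naive UPGMA: average of the pairwise distances between original members
oracle_upgma_heights <- function(d) {
  d <- as.matrix(d)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_h <- Inf
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        h <- mean(d[clusters[[i]], clusters[[j]]])
        if (h < best_h) {
          best_h <- h
          best <- c(i, j)
        }
      }
    }
    heights <- c(heights, best_h)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  heights
}

# substitute k bases of a sequence at given positions (1-based)
substitute_at <- function(seq, positions, shift = 1L) {
  chars <- strsplit(seq, "")[[1]]
  bases <- c("A", "C", "G", "T")
  for (p in positions) {
    chars[p] <- bases[((match(chars[p], bases) - 1L + shift) %% 4L) + 1L]
  }
  paste(chars, collapse = "")
}

# all distinct 1- and 2-substitution neighbours of a sequence
all_neighbours <- function(seq, max_k = 2L) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  out <- character(0)
  for (p in seq_len(L)) {
    for (b in setdiff(bases, chars[p])) {
      v <- chars; v[p] <- b
      out <- c(out, paste(v, collapse = ""))
    }
  }
  if (max_k >= 2L) {
    for (p in seq_len(L - 1L)) {
      for (q in (p + 1L):L) {
        for (b1 in setdiff(bases, chars[p])) {
          for (b2 in setdiff(bases, chars[q])) {
            v <- chars; v[p] <- b1; v[q] <- b2
            out <- c(out, paste(v, collapse = ""))
          }
        }
      }
    }
  }
  unique(out)
}

# phase sets without the correlation filter (for null-model tests)
unfiltered_phase_sets <- function(candidates) {
  phases <- c("G1/S", "S", "G2/M", "M", "M/G1")
  sets <- lapply(phases, function(p) {
    data.frame(gene_id = candidates$gene_id[candidates$phase == p],
               r = NA_real_, stringsAsFactors = FALSE)
  })
  names(sets) <- phases
  class(sets) <- c("masc_phase_sets", class(sets))
  sets
}
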
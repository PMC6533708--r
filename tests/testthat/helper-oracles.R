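# Independent oracles used across the suite.  These deliberately take
# different algorithmic routes from the package implementation (top-down
# enumeration with memoisation, set comprehensions, direct recounts).

# Global alignment score by recursion over suffix positions with an
# explicit gap-state machine; a gap run of length L costs open + L*extend.
bf_global_score <- function(a, b, S, open, ext) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j, prev) {
    key <- paste(i, j, prev)
    if (!is.null(memo[[key]])) return(memo[[key]])
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m)
      best <- max(best, S[av[i], bv[j]] + rec(i + 1L, j + 1L, "M"))
    if (i <= n)
      best <- max(best, -(ext + if (prev != "X") open else 0) +
                    rec(i + 1L, j, "X"))
    if (j <= m)
      best <- max(best, -(ext + if (prev != "Y") open else 0) +
                    rec(i, j + 1L, "Y"))
    memo[[key]] <- best
    best
  }
  rec(1L, 1L, "S")
}

# Local score = best global score over all substring pairs (0 if nothing
# positive exists).
bf_local_score <- function(a, b, S, open, ext) {
  n <- nchar(a); m <- nchar(b)
  best <- 0
  for (i1 in 1:n) for (i2 in i1:n) for (j1 in 1:m) for (j2 in j1:m) {
    s <- bf_global_score(substr(a, i1, i2), substr(b, j1, j2), S, open, ext)
    if (s > best) best <- s
  }
  best
}

# Rand index between two partitions given as label vectors over the same
# elements (names are matched).
rand_index <- function(x, y) {
  stopifnot(!is.null(names(x)), !is.null(names(y)))
  y <- y[names(x)]
  n <- length(x)
  ct <- table(x, y)
  a <- sum(choose(ct, 2))
  b <- sum(choose(rowSums(ct), 2)) - a
  c <- sum(choose(colSums(ct), 2)) - a
  d <- choose(n, 2) - a - b - c
  (a + d) / choose(n, 2)
}

# Independent re-implementation of the bidirectional filter as a plain
# set comprehension.
oracle_bidirectional <- function(hits, min_id = 30, min_cov = 0.80,
                                 max_e = 1e-4) {
  ok <- function(h) {
    h$pct_identity >= min_id & h$query_cov >= min_cov &
      (is.na(h$evalue) | h$evalue <= max_e)
  }
  passing <- hits[ok(hits), , drop = FALSE]
  if (nrow(passing) == 0L) return(character(0))
  dirs <- unique(paste(passing$query_id, passing$subject_id, sep = "->"))
  pairs <- unique(t(apply(cbind(passing$query_id, passing$subject_id), 1,
                          sort)))
  keep <- apply(pairs, 1, function(p)
    paste(p[1], p[2], sep = "->") %in% dirs &&
      paste(p[2], p[1], sep = "->") %in% dirs)
  pairs <- pairs[keep, , drop = FALSE]
  sort(paste(pairs[, 1], pairs[, 2], sep = "|"))
}

# Independent row-wise re-implementation of the niche screen.
oracle_screen <- function(mat, positive, negative, min_pos, max_neg) {
  out <- character(0)
  for (f in rownames(mat)) {
    np <- sum(mat[f, positive] > 0)
    nn <- if (length(negative)) sum(mat[f, negative] > 0) else 0
    if (np >= min_pos && nn <= max_neg) out <- c(out, f)
  }
  sort(out)
}

# Rooting-invariant topology comparison via canonical bipartition sets.
same_topology <- function(t1, t2) {
  setequal(t1$tip.label, t2$tip.label) &&
    setequal(brevipan:::bipartitions(ape::unroot(t1)),
             brevipan:::bipartitions(ape::unroot(t2)))
}

random_aa <- function(len, alphabet = c("A", "C", "D", "E")) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# Minimal annotated records for a set of sequences on one chromosome each.
toy_records <- function(seqs, genome = "G1", replicon_type = "chromosome") {
  n <- length(seqs)
  data.frame(
    gene_id = names(seqs), genome_id = rep_len(genome, n),
    replicon_id = if (replicon_type == "chromosome") "chr" else "pA",
    replicon_type = replicon_type,
    start = seq(1L, by = 1000L, length.out = n),
    end = seq(900L, by = 1000L, length.out = n),
    strand = "+", product = "protein", sequence = unname(seqs),
    stringsAsFactors = FALSE)
}
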
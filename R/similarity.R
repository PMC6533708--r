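# Substitution matrices and sequence encoding for the alignment kernel.

blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      env <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = env)
      cache <<- env$BLOSUM62
    }
    cache
  }
})

#' Build a simple match/mismatch scoring matrix
#'
#' Convenience for tests and toy examples (e.g. identity scoring with
#' match 1, mismatch -1) over an arbitrary alphabet.
#'
#' @param alphabet character vector of single letters.
#' @param match,mismatch scores.
#' @return Square numeric matrix with dimnames.
#' @export
scoring_matrix <- function(alphabet = AA_ALPHABET, match = 1, mismatch = -1) {
  n <- length(alphabet)
  m <- matrix(mismatch, n, n, dimnames = list(alphabet, alphabet))
  diag(m) <- match
  m
}

encode_sequences <- function(seqs, alphabet) {
  fallback <- match("X", alphabet)
  if (is.na(fallback)) fallback <- 1L
  lapply(strsplit(toupper(seqs), "", fixed = TRUE), function(ch) {
    idx <- match(ch, alphabet)
    idx[is.na(idx)] <- fallback
    idx - 1L
  })
}

#' Optimal local alignment of two amino-acid sequences
#'
#' Smith-Waterman with affine gaps (a gap run of length L costs
#' `gap_open + L * gap_extend`, the BLAST convention).  The default scoring
#' is BLOSUM62 with gap open 11 / extend 1 so internally computed hits are
#' comparable to externally supplied BLAST tabular hits.  Identity is
#' `matches / aln_length`; each sequence's coverage is the aligned span over
#' its full length.
#'
#' @param a,b non-empty amino-acid strings.
#' @param scoring square numeric scoring matrix with single-letter dimnames
#'   (default BLOSUM62).
#' @param gap_open,gap_extend non-negative gap penalties.
#' @param keep_strings also return the gapped aligned strings.
#' @return List with `score`, `matches`, `aln_length`, `pct_identity`,
#'   `query_cov`, `subject_cov`, span coordinates, and (optionally)
#'   `query_aln` / `subject_aln`.
#' @export
align_pair <- function(a, b, scoring = blosum62_matrix(), gap_open = 11,
                       gap_extend = 1, keep_strings = FALSE) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence")
  alphabet <- rownames(scoring)
  enc <- encode_sequences(c(a, b), alphabet)
  r <- cpp_local_align(enc[[1L]], enc[[2L]], scoring, gap_open, gap_extend,
                       keep_path = TRUE)
  out <- list(
    score = r$score, matches = r$matches, aln_length = r$aln_length,
    pct_identity = if (r$aln_length > 0) 100 * r$matches / r$aln_length else 0,
    query_cov = if (r$aln_length > 0) (r$qend - r$qstart + 1) / nchar(a) else 0,
    subject_cov = if (r$aln_length > 0) (r$send - r$sstart + 1) / nchar(b) else 0,
    qstart = r$qstart, qend = r$qend, sstart = r$sstart, send = r$send)
  if (keep_strings && r$aln_length > 0) {
    ac <- strsplit(toupper(a), "")[[1L]]
    bc <- strsplit(toupper(b), "")[[1L]]
    out$query_aln <- paste(ifelse(r$qa == 0, "-", ac[pmax(r$qa, 1)]),
                           collapse = "")
    out$subject_aln <- paste(ifelse(r$sa == 0, "-", bc[pmax(r$sa, 1)]),
                             collapse = "")
  }
  out
}

#' All-against-all protein similarity search
#'
#' Computes directed similarity hits for every ordered pair of distinct
#' proteins whose local alignment reaches a permissive raw-score floor.
#' A shared-k-mer prefilter (on by default) skips pairs that cannot be
#' similar: a pair is aligned only when the two sequences share at least
#' `max(prefilter_min_shared, ceil(prefilter_min_frac * min(#kmers)))`
#' distinct k-mers.  Both thresholds sit far below what any pair passing
#' the 30%/80% identity/coverage filter shares at moderate divergence, and
#' both are configurable (set them to 1 to keep every pair sharing any
#' k-mer, or `prefilter = FALSE` to align all pairs).
#'
#' @param records data frame with `gene_id` and `sequence` columns (e.g.
#'   from [simulate_pangenome()] or [read_annotation_table()]).
#' @param config a [run_config()].
#' @param prefilter logical; disable to align every pair.
#' @return Data frame of directed hits: `query_id`, `subject_id`,
#'   `pct_identity`, `aln_length`, `query_cov`, `subject_cov`, `score`,
#'   `evalue` (NA for internally computed hits).
#' @export
all_vs_all <- function(records, config = run_config(), prefilter = TRUE) {
  stopifnot(all(c("gene_id", "sequence") %in% names(records)))
  if (nrow(records) < 2L) stop("need at least two records")
  cfg <- config$similarity
  scoring <- blosum62_matrix()
  alphabet <- rownames(scoring)
  enc <- encode_sequences(records$sequence, alphabet)
  lens <- nchar(records$sequence)

  if (prefilter) {
    pairs <- cpp_candidate_pairs(enc, as.integer(cfg$prefilter_k),
                                 length(alphabet),
                                 as.integer(cfg$prefilter_min_shared),
                                 cfg$prefilter_min_frac)
  } else {
    n <- nrow(records)
    idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pairs <- cbind(idx[, "row"], idx[, "col"])
  }
  if (nrow(pairs) == 0L)
    return(empty_hits())

  aln <- cpp_align_pairs(enc, pairs, scoring, cfg$gap_open, cfg$gap_extend)
  keep <- aln$score >= cfg$min_raw_score & aln$aln_length > 0
  aln <- aln[keep, , drop = FALSE]
  if (nrow(aln) == 0L)
    return(empty_hits())

  ids <- records$gene_id
  pid <- 100 * aln$matches / aln$aln_length
  icov <- (aln$qend - aln$qstart + 1) / lens[aln$i]
  jcov <- (aln$send - aln$sstart + 1) / lens[aln$j]
  fwd <- data.frame(query_id = ids[aln$i], subject_id = ids[aln$j],
                    pct_identity = pid, aln_length = aln$aln_length,
                    query_cov = icov, subject_cov = jcov,
                    score = aln$score, evalue = NA_real_,
                    stringsAsFactors = FALSE)
  rev <- data.frame(query_id = ids[aln$j], subject_id = ids[aln$i],
                    pct_identity = pid, aln_length = aln$aln_length,
                    query_cov = jcov, subject_cov = icov,
                    score = aln$score, evalue = NA_real_,
                    stringsAsFactors = FALSE)
  hits <- rbind(fwd, rev)
  hits[order(hits$query_id, hits$subject_id), , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pct_identity = numeric(), aln_length = integer(),
             query_cov = numeric(), subject_cov = numeric(),
             score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Bidirectional identity/coverage/E-value filter
#'
#' An undirected pair `{a, b}` qualifies when directed hits exist in *both*
#' directions and both satisfy identity >= `min_identity_pct`, query
#' coverage >= `min_coverage_frac`, and (when an E-value is present)
#' E-value <= `max_evalue`.  Each retained pair carries the clustering edge
#' weight: `pct_identity/100 * min(query_cov, subject_cov)`, best hit per
#' direction, averaged over the two directions (bounded in (0, 1]).
#'
#' @param hits data frame of directed hits (see [all_vs_all()] or
#'   [read_similarity_tabular()]).
#' @param config a [run_config()].
#' @return Data frame of qualified undirected pairs: `a`, `b` (with
#'   `a < b`), `weight`.
#' @export
filter_bidirectional <- function(hits, config = run_config()) {
  cfg <- config$similarity
  if (nrow(hits) == 0L)
    return(data.frame(a = character(), b = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  pass <- hits$pct_identity >= cfg$min_identity_pct &
    !is.na(hits$query_cov) & hits$query_cov >= cfg$min_coverage_frac &
    (is.na(hits$evalue) | hits$evalue <= cfg$max_evalue)
  h <- hits[pass, , drop = FALSE]
  if (nrow(h) == 0L)
    return(data.frame(a = character(), b = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  scov <- ifelse(is.na(h$subject_cov), h$query_cov, h$subject_cov)
  w <- (h$pct_identity / 100) * pmin(h$query_cov, scov)
  dir_key <- paste(h$query_id, h$subject_id, sep = "\r")
  best <- tapply(w, dir_key, max)
  qs <- sub("\r.*$", "", names(best))
  ss <- sub("^.*\r", "", names(best))
  a <- pmin(qs, ss)
  b <- pmax(qs, ss)
  und_key <- paste(a, b, sep = "\r")
  cnt <- table(und_key)
  both <- names(cnt)[cnt == 2L]  # hit present in both directions
  if (length(both) == 0L)
    return(data.frame(a = character(), b = character(), weight = numeric(),
                      stringsAsFactors = FALSE))
  keep <- und_key %in% both
  wt <- tapply(as.numeric(best)[keep], und_key[keep], mean)
  out <- data.frame(a = sub("\r.*$", "", names(wt)),
                    b = sub("^.*\r", "", names(wt)),
                    weight = as.numeric(wt), stringsAsFactors = FALSE)
  out <- out[order(out$a, out$b), , drop = FALSE]
  rownames(out) <- NULL
  out
}
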
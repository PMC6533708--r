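#' Per-plasmid gene and family profiles
#'
#' @param records annotated records (only `replicon_type == "plasmid"` rows
#'   are used).
#' @param families long-format family table covering the plasmid genes.
#' @return Named list of profiles; each has `plasmid_id`
#'   (`genome_id:replicon_id`), `genome_id`, `gene_ids`, `family_ids`.
#' @export
plasmid_profiles <- function(records, families) {
  pl <- records[records$replicon_type == "plasmid", , drop = FALSE]
  if (nrow(pl) == 0L) return(list())
  fam_of <- setNames(families$family_id, families$gene_id)
  if (anyNA(fam_of[pl$gene_id]))
    stop("plasmid gene(s) missing from families")
  key <- paste(pl$genome_id, pl$replicon_id, sep = ":")
  lapply(split(seq_len(nrow(pl)), key), function(idx) {
    list(plasmid_id = key[idx[1L]],
         genome_id = pl$genome_id[idx[1L]],
         gene_ids = pl$gene_id[idx],
         family_ids = unname(fam_of[pl$gene_id[idx]]))
  })
}

#' Directional gene-content similarity between two plasmids
#'
#' Fraction of `p`'s genes belonging to a family with at least one member
#' on `q` — a gene-content proxy for whole-plasmid identity, since the
#' pipeline operates on annotated proteins rather than nucleotide
#' alignments.  Directional: `sim(p, q)` and `sim(q, p)` generally differ.
#'
#' @param p,q plasmid profiles ([plasmid_profiles()]).
#' @return Fraction in `[0, 1]`.
#' @export
plasmid_similarity <- function(p, q) {
  if (length(p$gene_ids) == 0L) stop("empty plasmid: ", p$plasmid_id)
  mean(p$family_ids %in% q$family_ids)
}

#' Classify plasmids as shared or unique by gene content
#'
#' A plasmid is *unique* when its best similarity to any other plasmid
#' (either direction, taking the larger) stays below `unique_threshold`;
#' a pair is *similar* when both directions reach `similar_threshold`.
#'
#' @param profiles list from [plasmid_profiles()] (>= 2 plasmids).
#' @param similar_threshold,unique_threshold fractions in `[0, 1]`.
#' @return List with `similarity` (directional matrix), `labels` (data
#'   frame: `plasmid_id`, `genome_id`, `n_genes`, `max_similarity`,
#'   `unique`), and `similar_pairs` (data frame `p`, `q`, `sim_pq`,
#'   `sim_qp`).
#' @export
classify_plasmids <- function(profiles, similar_threshold = 0.90,
                              unique_threshold = 0.10) {
  if (length(profiles) < 2L) stop("need at least two plasmids")
  ids <- vapply(profiles, `[[`, character(1), "plasmid_id")
  n <- length(profiles)
  S <- matrix(NA_real_, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n))
    for (j in seq_len(n))
      if (i != j) S[i, j] <- plasmid_similarity(profiles[[i]], profiles[[j]])
  best <- vapply(seq_len(n), function(i)
    max(S[i, -i], S[-i, i]), numeric(1))
  labels <- data.frame(
    plasmid_id = ids,
    genome_id = vapply(profiles, `[[`, character(1), "genome_id"),
    n_genes = vapply(profiles, function(p) length(p$gene_ids), integer(1)),
    max_similarity = best,
    unique = best < unique_threshold,
    stringsAsFactors = FALSE)
  rownames(labels) <- NULL
  pairs <- list()
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      if (min(S[i, j], S[j, i]) >= similar_threshold)
        pairs[[length(pairs) + 1L]] <- data.frame(
          p = ids[i], q = ids[j], sim_pq = S[i, j], sim_qp = S[j, i],
          stringsAsFactors = FALSE)
  similar_pairs <- if (length(pairs)) do.call(rbind, pairs) else
    data.frame(p = character(), q = character(), sim_pq = numeric(),
               sim_qp = numeric(), stringsAsFactors = FALSE)
  list(similarity = S, labels = labels, similar_pairs = similar_pairs)
}
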
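#' Select universal single-copy families
#'
#' Families with exactly one member in every genome (including the
#' outgroup) — the input set for a concatenated supertree.
#'
#' @param families long-format family table.
#' @param genome_ids full genome set including the outgroup.
#' @return Character vector of family ids.
#' @export
select_single_copy_core <- function(families, genome_ids) {
  tab <- table(factor(families$family_id),
               factor(families$genome_id, levels = genome_ids))
  copies_total <- table(families$family_id)[rownames(tab)]
  present_all <- rowSums(tab > 0) == length(genome_ids)
  single <- apply(tab, 1L, max) == 1L &
    as.integer(copies_total) == length(genome_ids)
  out <- rownames(tab)[present_all & single]
  if (length(out) == 0L)
    stop("no universal single-copy families; consider relaxing the ",
         "similarity thresholds")
  sort(out)
}

#' Center-star multiple alignment with gap-column removal
#'
#' Progressive center-star alignment: the center is the sequence with the
#' greatest summed pairwise global alignment score; every other sequence is
#' merged via its global pairwise alignment to the center under the
#' "once a gap, always a gap" rule.  All columns containing any gap are
#' then removed, yielding the ungapped alignment that can be concatenated
#' across variable-length orthologs.
#'
#' @param seqs named character vector, one sequence per taxon.
#' @param scoring scoring matrix (default BLOSUM62).
#' @param gap_open,gap_extend gap penalties.
#' @return Named character vector of equal-length ungapped rows (class
#'   `multiple_alignment`); zero-width when no column is gap-free (with a
#'   warning).
#' @export
align_family <- function(seqs, scoring = blosum62_matrix(), gap_open = 11,
                         gap_extend = 1) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  if (any(!nzchar(seqs))) stop("empty sequence in family")
  n <- length(seqs)
  if (n == 1L) return(structure(seqs, class = "multiple_alignment"))
  alphabet <- rownames(scoring)
  enc <- encode_sequences(seqs, alphabet)
  chars <- strsplit(toupper(seqs), "", fixed = TRUE)

  if (length(unique(seqs)) == 1L) {
    return(structure(setNames(toupper(seqs), names(seqs)),
                     class = "multiple_alignment"))
  }

  # choose the center: maximal summed global score against all others
  scores <- numeric(n)
  aln_to <- vector("list", n)  # pairwise alignments, filled for the center
  pair_score <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      g <- cpp_global_align(enc[[i]], enc[[j]], scoring, gap_open, gap_extend)
      pair_score[i, j] <- pair_score[j, i] <- g$score
    }
  }
  center <- which.max(rowSums(pair_score))

  # master alignment: rows are index vectors into each original sequence
  # (0 = gap); start with the center alone
  clen <- length(chars[[center]])
  rows <- list()
  rows[[names(seqs)[center]]] <- seq_len(clen)
  center_pos <- seq_len(clen)  # original center position per master column

  for (i in setdiff(seq_len(n), center)) {
    g <- cpp_global_align(enc[[center]], enc[[i]], scoring, gap_open,
                          gap_extend)
    # walk master columns and the new pairwise alignment in lockstep over
    # center positions; "once a gap, always a gap"
    merged_center <- integer(0)
    merged_new <- integer(0)
    patch <- lapply(rows, function(r) integer(0))
    mi <- 1L  # master column index
    for (pc in seq_along(g$qa)) {
      if (g$qa[pc] == 0L) {
        # new sequence inserts a column relative to the center
        merged_new <- c(merged_new, g$sa[pc])
        merged_center <- c(merged_center, 0L)
        patch <- lapply(patch, function(x) c(x, 0L))
      } else {
        # advance master until this center residue, carrying gap columns
        while (mi <= length(center_pos) && center_pos[mi] != g$qa[pc]) {
          merged_new <- c(merged_new, 0L)
          merged_center <- c(merged_center, center_pos[mi])
          for (nm in names(patch))
            patch[[nm]] <- c(patch[[nm]], rows[[nm]][mi])
          mi <- mi + 1L
        }
        merged_new <- c(merged_new, g$sa[pc])
        merged_center <- c(merged_center, center_pos[mi])
        for (nm in names(patch))
          patch[[nm]] <- c(patch[[nm]], rows[[nm]][mi])
        mi <- mi + 1L
      }
    }
    while (mi <= length(center_pos)) {  # trailing master columns
      merged_new <- c(merged_new, 0L)
      merged_center <- c(merged_center, center_pos[mi])
      for (nm in names(patch))
        patch[[nm]] <- c(patch[[nm]], rows[[nm]][mi])
      mi <- mi + 1L
    }
    rows <- patch
    rows[[names(seqs)[i]]] <- merged_new
    center_pos <- merged_center
  }

  # render and strip gap columns
  mat <- do.call(rbind, lapply(names(seqs), function(nm) {
    r <- rows[[nm]]
    ch <- chars[[match(nm, names(seqs))]]
    ifelse(r == 0L, "-", ch[pmax(r, 1L)])
  }))
  rownames(mat) <- names(seqs)
  keep <- colSums(mat == "-") == 0L
  if (!any(keep))
    warning("no gap-free columns; alignment is empty")
  mat <- mat[, keep, drop = FALSE]
  out <- setNames(apply(mat, 1L, paste, collapse = ""), rownames(mat))
  structure(out, class = "multiple_alignment")
}

#' Concatenate per-family alignments into a supermatrix
#'
#' @param alignments list of `multiple_alignment` objects over identical
#'   taxon sets.
#' @return `multiple_alignment` with a `family` attribute recording each
#'   column's source family (for block bootstrapping).
#' @export
concatenate_alignments <- function(alignments) {
  if (length(alignments) == 0L) stop("no alignments to concatenate")
  taxa <- sort(names(alignments[[1L]]))
  for (a in alignments)
    if (!identical(sort(names(a)), taxa))
      stop("taxon sets differ across alignments")
  rows <- vapply(taxa, function(tx)
    paste(vapply(alignments, function(a) unname(a[[tx]]), character(1)),
          collapse = ""), character(1))
  fam_names <- names(alignments)
  if (is.null(fam_names)) fam_names <- as.character(seq_along(alignments))
  fam_col <- rep(fam_names, vapply(alignments, function(a)
    nchar(a[[1L]]), integer(1)))
  structure(setNames(rows, taxa), family = fam_col,
            class = "multiple_alignment")
}

alignment_matrix <- function(alignment) {
  lens <- nchar(alignment)
  stopifnot(length(unique(lens)) == 1L)
  mat <- do.call(rbind, strsplit(unname(alignment), "", fixed = TRUE))
  rownames(mat) <- names(alignment)
  mat
}

#' Pairwise p-distance matrix of an alignment
#'
#' `d(i, j)` is the fraction of columns at which rows i and j differ.
#'
#' @param alignment `multiple_alignment` (equal-length rows, length >= 1).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(alignment) {
  if (nchar(alignment[[1L]]) == 0L) stop("zero-length alignment")
  mat <- alignment_matrix(alignment)
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- mean(mat[i, ] != mat[j, ])
  D
}

#' Neighbor-joining tree with non-negative branch lengths
#'
#' Canonical NJ (via \pkg{ape}); any negative branch length is clamped to
#' zero with the deficit moved to the adjacent (sister) branch so that
#' path lengths are preserved where possible.
#'
#' @param D symmetric distance matrix with zero diagonal (>= 3 taxa).
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3L) stop("need at least three taxa")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix not symmetric")
  if (max(abs(diag(D))) > 1e-12) stop("distance matrix diagonal not zero")
  tree <- ape::nj(as.dist(D))
  neg <- which(tree$edge.length < 0)
  for (e in neg) {
    deficit <- tree$edge.length[e]
    parent <- tree$edge[e, 1L]
    sib <- setdiff(which(tree$edge[, 1L] == parent), e)
    if (length(sib)) {
      sib <- sib[1L]
      tree$edge.length[sib] <- tree$edge.length[sib] + deficit
    }
    tree$edge.length[e] <- 0
  }
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}

bipartitions <- function(tree) {
  # internal-edge splits as canonical strings of sorted tip labels
  tips <- sort(tree$tip.label)
  parts <- ape::prop.part(tree)
  out <- character(0)
  for (p in parts) {
    side <- sort(attr(parts, "labels")[p])
    if (length(side) <= 1L || length(side) >= length(tips) - 1L) next
    comp <- setdiff(tips, side)
    canon <- if (paste(side, collapse = ",") < paste(comp, collapse = ","))
      side else comp
    out <- c(out, paste(canon, collapse = ","))
  }
  unique(out)
}

#' Bootstrap a distance supermatrix into a support-annotated NJ tree
#'
#' Columns are resampled with replacement `reps` times (or whole families,
#' when `block = TRUE` and the alignment carries per-column family
#' provenance), an NJ tree is rebuilt per replicate, and each internal
#' edge's support is the number of replicates containing its bipartition.
#' Supports below `display_min` are flagged in the result, not removed.
#'
#' @param alignment supermatrix ([concatenate_alignments()]).
#' @param reps number of bootstrap replicates (>= 1).
#' @param seed integer seed (resampling is the only randomness).
#' @param block resample per-family blocks instead of single columns.
#' @param display_min display threshold recorded alongside supports.
#' @return List with `tree` (a `phylo` whose `node.label` carries integer
#'   supports), `supports` (per-bipartition counts), `reps`,
#'   `below_display` (bipartitions under the display threshold).
#' @export
bootstrap_supertree <- function(alignment, reps = 1000L, seed = 1L,
                                block = FALSE, display_min = 250L) {
  if (reps < 1L) stop("reps must be >= 1")
  mat <- alignment_matrix(alignment)
  if (ncol(mat) < 1L) stop("alignment has no columns")
  ref <- nj_tree(p_dist_mat(mat))
  set.seed(seed)
  fam <- attr(alignment, "family")
  counts <- setNames(integer(length(bipartitions(ref))), bipartitions(ref))
  for (r in seq_len(reps)) {
    if (block && !is.null(fam)) {
      fams <- unique(fam)
      pick <- sample(fams, length(fams), replace = TRUE)
      cols <- unlist(lapply(pick, function(f) which(fam == f)),
                     use.names = FALSE)
    } else {
      cols <- sample.int(ncol(mat), ncol(mat), replace = TRUE)
    }
    bt <- tryCatch(nj_tree(p_dist_mat(mat[, cols, drop = FALSE])),
                   error = function(e) NULL)
    if (is.null(bt)) next
    hit <- intersect(bipartitions(bt), names(counts))
    counts[hit] <- counts[hit] + 1L
  }
  tree <- annotate_supports(ref, counts)
  list(tree = tree, supports = counts, reps = reps,
       below_display = names(counts)[counts < display_min],
       display_min = display_min)
}

p_dist_mat <- function(mat) {
  n <- nrow(mat)
  D <- matrix(0, n, n, dimnames = list(rownames(mat), rownames(mat)))
  for (i in seq_len(n - 1L))
    for (j in (i + 1L):n)
      D[i, j] <- D[j, i] <- mean(mat[i, ] != mat[j, ])
  D
}

annotate_supports <- function(tree, counts) {
  tips <- sort(tree$tip.label)
  ntip <- length(tree$tip.label)
  labels <- character(tree$Nnode)
  parts <- ape::prop.part(tree)
  for (k in seq_along(parts)) {
    side <- sort(attr(parts, "labels")[parts[[k]]])
    if (length(side) <= 1L || length(side) >= ntip - 1L) {
      labels[k] <- ""
      next
    }
    comp <- setdiff(tips, side)
    canon <- if (paste(side, collapse = ",") < paste(comp, collapse = ","))
      side else comp
    key <- paste(canon, collapse = ",")
    labels[k] <- if (key %in% names(counts)) as.character(counts[[key]]) else ""
  }
  tree$node.label <- labels
  tree
}

#' Root a tree on an outgroup's pendant edge
#'
#' The root is placed at the midpoint of the outgroup's terminal branch,
#' so the outgroup becomes the sister of everything else.
#'
#' @param tree unrooted `phylo`.
#' @param outgroup_id a tip label.
#' @return Rooted `phylo`.
#' @export
root_with_outgroup <- function(tree, outgroup_id) {
  if (!outgroup_id %in% tree$tip.label)
    stop("outgroup not found: ", outgroup_id)
  rooted <- ape::root(tree, outgroup = outgroup_id, resolve.root = TRUE)
  root_node <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1L] == root_node)
  if (length(kids) == 2L && !is.null(rooted$edge.length)) {
    total <- sum(rooted$edge.length[kids])
    # split the original pendant edge at its midpoint
    rooted$edge.length[kids] <- total / 2
  }
  rooted
}

#' Single-copy-core supertree pipeline
#'
#' Convenience wrapper: select universal single-copy families, align each
#' (center-star, gap columns removed), concatenate, compute p-distances,
#' build the NJ tree, bootstrap, and root on the outgroup.
#'
#' @param families long-format family table.
#' @param records annotated records with sequences.
#' @param genome_ids genome set including the outgroup.
#' @param outgroup_id outgroup genome id.
#' @param reps bootstrap replicates.
#' @param seed integer seed.
#' @return List: `family_ids`, `supermatrix`, `distances`, `bootstrap`
#'   (see [bootstrap_supertree()]), `rooted` (rooted support-annotated
#'   tree).
#' @export
build_supertree <- function(families, records, genome_ids, outgroup_id,
                            reps = 100L, seed = 1L) {
  fams <- select_single_copy_core(families, genome_ids)
  alns <- lapply(fams, function(f) {
    genes <- families[families$family_id == f, , drop = FALSE]
    seqs <- setNames(
      records$sequence[match(genes$gene_id, records$gene_id)],
      genes$genome_id)
    align_family(seqs)
  })
  names(alns) <- fams
  alns <- alns[vapply(alns, function(a) nchar(a[[1L]]) > 0L, logical(1))]
  super <- concatenate_alignments(alns)
  D <- p_distance(super)
  bs <- bootstrap_supertree(super, reps = reps, seed = seed)
  rooted <- root_with_outgroup(bs$tree, outgroup_id)
  list(family_ids = fams, supermatrix = super, distances = D,
       bootstrap = bs, rooted = rooted)
}
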
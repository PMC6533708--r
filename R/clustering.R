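#' Build a similarity graph from qualified pairs
#'
#' @param pairs data frame with columns `a`, `b`, `weight` (see
#'   [filter_bidirectional()]).
#' @param nodes character vector of all gene ids (so genes with no
#'   qualifying partner become isolated nodes and, later, singleton
#'   families).  Defaults to the ids appearing in `pairs`.
#' @return Symmetric sparse adjacency matrix (`dgCMatrix`) with nodes in
#'   sorted id order, no self-loops, positive weights.
#' @export
similarity_graph <- function(pairs, nodes = NULL) {
  if (is.null(nodes)) nodes <- union(pairs$a, pairs$b)
  nodes <- sort(unique(nodes))
  if (length(nodes) == 0L) stop("empty graph")
  if (nrow(pairs)) {
    stopifnot(all(pairs$weight > 0), all(pairs$a != pairs$b),
              all(pairs$a %in% nodes), all(pairs$b %in% nodes))
  }
  i <- match(pairs$a, nodes)
  j <- match(pairs$b, nodes)
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i),
                       x = rep(pairs$weight, 2L),
                       dims = c(length(nodes), length(nodes)),
                       dimnames = list(nodes, nodes))
}

col_max_sparse <- function(A) {
  T <- as(A, "TsparseMatrix")
  out <- numeric(ncol(A))
  if (length(T@x)) {
    mx <- tapply(T@x, T@j, max)
    out[as.integer(names(mx)) + 1L] <- mx
  }
  out
}

col_normalize <- function(A) {
  cs <- Matrix::colSums(A)
  zero <- cs == 0
  if (any(zero)) {
    # a column emptied by pruning keeps itself as attractor
    A <- A + Matrix::sparseMatrix(i = which(zero), j = which(zero), x = 1,
                                  dims = dim(A))
    cs <- Matrix::colSums(A)
  }
  A %*% Matrix::Diagonal(x = 1 / cs)
}

#' Markov clustering of a weighted similarity graph
#'
#' Standard MCL: self-loops are added (weight = maximum incident edge
#' weight, floored at `self_loop_min`), the matrix is column-normalized to
#' a stochastic matrix, then expansion (matrix squaring) alternates with
#' inflation (entrywise power followed by re-normalization) and pruning
#' (entries below `prune_threshold` dropped, columns re-normalized) until
#' the maximum entrywise change falls below `epsilon` or `max_iterations`
#' is reached.  Clusters are the connected components of the attractor
#' support of the limit matrix; node order (sorted ids) makes the result
#' deterministic.
#'
#' @param graph adjacency matrix from [similarity_graph()] (any matrix
#'   coercible to sparse, with dimnames).
#' @param inflation inflation exponent (> 1).
#' @param max_iterations,epsilon stopping rule.
#' @param prune_threshold entries below this are dropped each iteration.
#' @param self_loop_min floor for the added self-loop weight.
#' @return List of class `mcl_result`: `membership` (named integer vector),
#'   `clusters` (list of id vectors, ordered by smallest member),
#'   `iterations`, `converged`, `max_col_deviation` (worst deviation of any
#'   column sum from 1 observed after any normalization step).
#' @export
mcl <- function(graph, inflation = 1.5, max_iterations = 100L,
                epsilon = 1e-6, prune_threshold = 1e-5,
                self_loop_min = 1e-3) {
  stopifnot(inflation > 1, nrow(graph) == ncol(graph), nrow(graph) >= 1)
  A <- as(as(graph, "CsparseMatrix"), "generalMatrix")
  nodes <- rownames(A)
  if (is.null(nodes)) nodes <- as.character(seq_len(nrow(A)))
  Matrix::diag(A) <- 0
  A <- Matrix::drop0(A)
  loops <- pmax(col_max_sparse(A), self_loop_min)
  Matrix::diag(A) <- loops
  M <- col_normalize(A)
  max_dev <- max(abs(Matrix::colSums(M) - 1))
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    E <- M %*% M              # expansion
    E@x <- E@x^inflation      # inflation
    E <- col_normalize(E)
    max_dev <- max(max_dev, abs(Matrix::colSums(E) - 1))
    E@x[E@x < prune_threshold] <- 0  # pruning
    E <- Matrix::drop0(E)
    E <- col_normalize(E)
    max_dev <- max(max_dev, abs(Matrix::colSums(E) - 1))
    D <- E - M
    delta <- if (length(D@x)) max(abs(D@x)) else 0
    M <- E
    if (delta < epsilon) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("MCL did not converge in ", max_iterations,
            " iterations; interpreting current matrix")
  # attractor support: nodes sharing any row of the limit matrix cluster
  # together; overlaps resolved by taking connected components, which
  # deterministically merges a node into the cluster of its smallest
  # attractor given the sorted node order
  P <- (M != 0) | (Matrix::t(M) != 0)
  g <- igraph::graph_from_adjacency_matrix(P, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)$membership
  names(comp) <- nodes
  first <- tapply(seq_along(comp), comp, min)
  relabel <- match(comp, as.integer(names(sort(first))))
  membership <- setNames(as.integer(relabel), nodes)
  clusters <- split(nodes, membership)
  names(clusters) <- NULL
  structure(list(membership = membership, clusters = clusters,
                 iterations = it, converged = converged,
                 max_col_deviation = max_dev),
            class = "mcl_result")
}

#' Group a clustering partition into gene families
#'
#' @param partition an `mcl_result` or a named vector mapping gene ids to
#'   cluster labels.
#' @param records annotated records (must contain every clustered gene).
#' @return Data frame (class `gene_families`) in long format: `family_id`,
#'   `gene_id`, `genome_id`.
#' @export
build_families <- function(partition, records) {
  if (inherits(partition, "mcl_result")) partition <- partition$membership
  stopifnot(!is.null(names(partition)))
  missing <- setdiff(names(partition), records$gene_id)
  if (length(missing))
    stop("gene id(s) in partition absent from records: ",
         paste(head(missing, 5L), collapse = ", "))
  idx <- match(names(partition), records$gene_id)
  fam <- data.frame(
    family_id = sprintf("FAM%05d", as.integer(factor(partition))),
    gene_id = names(partition),
    genome_id = records$genome_id[idx],
    stringsAsFactors = FALSE)
  fam <- fam[order(fam$family_id, fam$genome_id, fam$gene_id), , drop = FALSE]
  rownames(fam) <- NULL
  class(fam) <- c("gene_families", "data.frame")
  fam
}

#' Classify gene families as core / dispensable / unique
#'
#' `core_single`: exactly one member in every genome; `core_multi`: at
#' least one member in every genome and two or more in at least one
#' (a paralogous core family); `unique`: members in exactly one genome;
#' `dispensable`: everything else.
#'
#' @param families long-format family table from [build_families()].
#' @param all_genome_ids the full genome set (a family can only be core
#'   with respect to a declared genome universe).
#' @return List with `families` (input plus `class` column), `classes`
#'   (named character vector per family) and `summary` (class counts, plus
#'   `core_total`).
#' @export
classify_families <- function(families, all_genome_ids) {
  if (length(all_genome_ids) == 0L) stop("empty genome list")
  extra <- setdiff(unique(families$genome_id), all_genome_ids)
  if (length(extra))
    stop("genomes in families not in genome list: ",
         paste(extra, collapse = ", "))
  tab <- table(families$family_id, families$genome_id)
  n_genomes <- length(all_genome_ids)
  present <- rowSums(tab > 0)
  maxcopy <- apply(tab, 1L, max)
  cls <- ifelse(present == n_genomes & maxcopy == 1L, "core_single",
         ifelse(present == n_genomes, "core_multi",
         ifelse(present == 1L, "unique", "dispensable")))
  classes <- setNames(as.character(cls), rownames(tab))
  families$class <- unname(classes[families$family_id])
  summary <- c(
    core_single = sum(cls == "core_single"),
    core_multi = sum(cls == "core_multi"),
    dispensable = sum(cls == "dispensable"),
    unique = sum(cls == "unique"))
  summary <- c(summary, core_total = unname(summary["core_single"] +
                                              summary["core_multi"]))
  list(families = families, classes = classes, summary = summary)
}
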
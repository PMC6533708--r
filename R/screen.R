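#' Presence/absence niche-association screen
#'
#' Returns the families present in at least `min_pos` genomes of the
#' positive group and at most `max_neg` genomes of the negative group
#' (default 0, i.e. specifically absent from all negatives).  This is the
#' deterministic set rule behind the published beer-spoiler gene lists:
#' chromosomal genes in >= 4 spoiler strains, plasmid genes in >= 3.
#'
#' @param mat presence/absence matrix (families x genomes).
#' @param positive,negative disjoint character vectors of genome ids; both
#'   must be columns of `mat`.
#' @param min_pos minimum number of positive-group carriers.
#' @param max_neg maximum number of negative-group carriers.
#' @return Data frame `family_id`, `n_pos`, `n_neg`, ordered by descending
#'   positive occupancy then family id.
#' @export
screen_families <- function(mat, positive, negative = character(),
                            min_pos = 4L, max_neg = 0L) {
  stopifnot(min_pos >= 1L, max_neg >= 0L)
  if (length(positive) == 0L) stop("empty positive group")
  if (length(intersect(positive, negative)))
    stop("positive and negative groups overlap")
  missing <- setdiff(c(positive, negative), colnames(mat))
  if (length(missing))
    stop("group genome(s) not in matrix: ", paste(missing, collapse = ", "))
  n_pos <- rowSums(mat[, positive, drop = FALSE] > 0)
  n_neg <- if (length(negative))
    rowSums(mat[, negative, drop = FALSE] > 0) else rep(0L, nrow(mat))
  keep <- n_pos >= min_pos & n_neg <= max_neg
  out <- data.frame(family_id = rownames(mat)[keep],
                    n_pos = unname(n_pos[keep]), n_neg = unname(n_neg[keep]),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$n_pos, out$family_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Share of a gene list carried by one strain
#'
#' @param mat presence/absence matrix.
#' @param family_ids subset of row names (e.g. a screen's output).
#' @param genome_id one column of `mat`.
#' @return List `count` (families with at least one member in the genome)
#'   and `fraction` (`count / length(family_ids)`).
#' @export
strain_share <- function(mat, family_ids, genome_id) {
  if (!genome_id %in% colnames(mat)) stop("unknown genome: ", genome_id)
  missing <- setdiff(family_ids, rownames(mat))
  if (length(missing))
    stop("family id(s) not in matrix: ", paste(missing, collapse = ", "))
  count <- sum(mat[family_ids, genome_id] > 0)
  list(count = count,
       fraction = if (length(family_ids)) count / length(family_ids) else 0)
}

#' Default functional-category keyword rules
#'
#' Ordered product-keyword rules used to bin screened genes into coarse
#' functional categories (oxido-reduction, transcription, membrane
#' transport, membrane/cell surface) in lieu of a COG database search;
#' the first matching rule wins and unmatched products fall through to
#' `hypothetical/unknown`.
#'
#' @return Named list of keyword vectors, in match order.
#' @export
default_category_rules <- function() {
  list(
    oxidoreduction = c("flavodoxin", "reductase", "oxidoreductase",
                       "peroxidase", "dehydrogenase", "oxidase"),
    transcription = c("transcriptional regulator", "sigma", "rna polymerase",
                      "transcription"),
    membrane_transport = c("transporter", "permease", "antiporter",
                           "pts ", "pts2c", "symporter", "efflux"),
    cell_surface = c("membrane protein", "cell surface", "cell wall",
                     "lpxtg", "mucus-binding", "glycosyltransferase",
                     "polygalacturonase", "endopeptidase", "nlp-p60")
  )
}

#' Assign product strings to functional categories
#'
#' Each family is assigned to the first rule whose keyword is a
#' case-insensitive substring of its product; families matching no rule
#' fall into `hypothetical/unknown`.
#'
#' @param products character vector of representative product strings
#'   (one per family; see [family_products()]).
#' @param rules ordered named list of keyword vectors
#'   ([default_category_rules()]).
#' @return List with `assignment` (category per family), `counts` and
#'   `fractions` per category (fractions over all families).
#' @export
categorize_products <- function(products, rules = default_category_rules()) {
  if (length(rules) == 0L) stop("empty category rules")
  low <- tolower(products)
  assignment <- rep("hypothetical/unknown", length(products))
  unset <- rep(TRUE, length(products))
  for (cat in names(rules)) {
    kw <- tolower(rules[[cat]])
    hit <- unset & Reduce(`|`, lapply(kw, function(k) grepl(k, low, fixed = TRUE)))
    assignment[hit] <- cat
    unset <- unset & !hit
  }
  names(assignment) <- names(products)
  lv <- c(names(rules), "hypothetical/unknown")
  counts <- table(factor(assignment, levels = lv))
  list(assignment = assignment,
       counts = as.integer(counts) |> setNames(lv),
       fractions = as.numeric(counts / max(length(products), 1L)) |>
         setNames(lv))
}

#' Representative product string per family
#'
#' The most common member product; ties broken lexicographically.
#'
#' @param families long-format family table.
#' @param records annotated records with `product`.
#' @return Named character vector, one product per family.
#' @export
family_products <- function(families, records) {
  prod <- records$product[match(families$gene_id, records$gene_id)]
  if (anyNA(prod)) stop("family gene(s) absent from records")
  vapply(split(prod, families$family_id), function(p) {
    tt <- sort(table(p), decreasing = TRUE)
    top <- names(tt)[tt == tt[1L]]
    sort(top)[1L]
  }, character(1))
}
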
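#' Read a protein FASTA file
#'
#' Headers are truncated at the first whitespace to form the record id;
#' sequences are uppercased.  Duplicate ids and empty sequences are hard
#' errors because every downstream stage assumes globally unique gene ids.
#'
#' @param path path to a FASTA file of amino-acid sequences.
#' @return Named character vector of sequences, in file order.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L || !startsWith(trimws(first), ">"))
    stop("not FASTA: line 1 of '", path, "' does not start with '>'")
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- toupper(as.character(aa))
  names(seqs) <- ids
  empty <- ids[nchar(seqs) == 0L]
  if (length(empty))
    stop("empty sequence(s): ", paste(empty, collapse = ", "))
  seqs
}

#' Write protein sequences to FASTA
#'
#' @param seqs named character vector of amino-acid sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_protein_fasta <- function(seqs, path) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  aa <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

ANNOT_COLS <- c("gene_id", "genome_id", "replicon_id", "replicon_type",
                "start", "end", "strand", "product")

#' Validate a table of annotated coding sequences
#'
#' Coordinates are 1-based inclusive (GenBank convention); strand is `+`/`-`;
#' `replicon_type` is `chromosome` or `plasmid`.
#'
#' @param records data frame with at least the columns `gene_id`,
#'   `genome_id`, `replicon_id`, `replicon_type`, `start`, `end`, `strand`,
#'   `product` (and optionally `sequence`).
#' @return The validated data frame (row names dropped).
#' @export
validate_records <- function(records) {
  miss <- setdiff(ANNOT_COLS, names(records))
  if (length(miss))
    stop("missing annotation column(s): ", paste(miss, collapse = ", "))
  if (nrow(records) == 0L) stop("no coding sequences in table")
  dup <- records$gene_id[duplicated(records$gene_id)]
  if (length(dup))
    stop("duplicate gene_id(s): ", paste(unique(dup), collapse = ", "))
  bad <- !records$replicon_type %in% c("chromosome", "plasmid")
  if (any(bad))
    stop("unknown replicon_type: ",
         paste(unique(records$replicon_type[bad]), collapse = ", "))
  if (!all(records$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  records$start <- as.integer(records$start)
  records$end <- as.integer(records$end)
  if (any(records$start < 1L)) stop("start coordinates must be >= 1")
  coord <- records$end < records$start
  if (any(coord))
    stop("end < start for gene(s): ",
         paste(records$gene_id[coord], collapse = ", "))
  if ("sequence" %in% names(records)) {
    if (any(!nzchar(records$sequence)))
      stop("empty sequence for gene(s): ",
           paste(records$gene_id[!nzchar(records$sequence)], collapse = ", "))
  }
  rownames(records) <- NULL
  records
}

#' Read an annotation table (TSV) of coding sequences
#'
#' @param path TSV with header and the columns of [validate_records()].
#' @param sequences optional named character vector (e.g. from
#'   [read_protein_fasta()]) attached as a `sequence` column; every gene must
#'   then have a sequence.
#' @return Validated records data frame.
#' @export
read_annotation_table <- function(path, sequences = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  records <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  records <- validate_records(records)
  if (!is.null(sequences)) {
    idx <- match(records$gene_id, names(sequences))
    if (anyNA(idx))
      stop("no sequence for gene(s): ",
           paste(records$gene_id[is.na(idx)], collapse = ", "))
    records$sequence <- unname(sequences[idx])
    records <- validate_records(records)
  }
  records
}

#' Read a genome metadata table (TSV)
#'
#' @param path TSV with header columns `genome_id`, `niche_label`,
#'   `spoiler` (logical or 0/1); extra columns are kept.
#' @param require_spoiler error when the spoiler flag is missing for any
#'   genome (required before running a niche screen).
#' @return Data frame of genome metadata.
#' @export
read_genome_table <- function(path, require_spoiler = TRUE) {
  meta <- read.delim(path, stringsAsFactors = FALSE)
  if (!"genome_id" %in% names(meta)) stop("missing column genome_id")
  if (anyDuplicated(meta$genome_id)) stop("duplicate genome_id rows")
  if ("spoiler" %in% names(meta)) {
    meta$spoiler <- as.logical(meta$spoiler)
    if (require_spoiler && anyNA(meta$spoiler))
      stop("spoiler flag missing for genome(s): ",
           paste(meta$genome_id[is.na(meta$spoiler)], collapse = ", "))
  } else if (require_spoiler) {
    stop("missing column spoiler")
  }
  meta
}

#' Read similarity hits in 12-column BLAST tabular format
#'
#' Columns: query, subject, pct_identity, aln_length, mismatches, gap_opens,
#' qstart, qend, sstart, send, evalue, bitscore.  Self-hits (query ==
#' subject) are dropped with a message stating the count.  When `lengths`
#' is supplied, per-sequence coverage is computed as `aln_length / length`.
#'
#' @param path path to the tabular file (no header).
#' @param lengths optional named integer vector of sequence lengths.
#' @return Data frame of directed hits with columns `query_id`,
#'   `subject_id`, `pct_identity`, `aln_length`, `query_cov`, `subject_cov`,
#'   `score`, `evalue`.
#' @export
read_similarity_tabular <- function(path, lengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 12L)
    stop("expected 12 tab-separated columns, got ", ncol(tab))
  names(tab) <- c("query_id", "subject_id", "pct_identity", "aln_length",
                  "mismatches", "gap_opens", "qstart", "qend", "sstart",
                  "send", "evalue", "bitscore")
  num_cols <- names(tab)[3:12]
  for (cc in num_cols) {
    v <- suppressWarnings(as.numeric(tab[[cc]]))
    if (anyNA(v) && !anyNA(tab[[cc]]))
      stop("non-numeric values in column ", cc)
    tab[[cc]] <- v
  }
  self <- tab$query_id == tab$subject_id
  if (any(self))
    message("dropped ", sum(self), " self-hit(s)")
  tab <- tab[!self, , drop = FALSE]
  qcov <- scov <- rep(NA_real_, nrow(tab))
  if (!is.null(lengths)) {
    unknown <- setdiff(unique(c(tab$query_id, tab$subject_id)),
                       names(lengths))
    if (length(unknown))
      stop("unknown sequence id(s) in hits: ",
           paste(unknown, collapse = ", "))
    qcov <- tab$aln_length / unname(lengths[tab$query_id])
    scov <- tab$aln_length / unname(lengths[tab$subject_id])
  }
  data.frame(query_id = tab$query_id, subject_id = tab$subject_id,
             pct_identity = tab$pct_identity, aln_length = tab$aln_length,
             query_cov = qcov, subject_cov = scov,
             score = tab$bitscore, evalue = tab$evalue,
             stringsAsFactors = FALSE)
}

#' Write / read a families-by-genomes count matrix (TSV)
#'
#' First column holds family ids, remaining columns one genome each, entries
#' are integer member counts.  The round trip is bit-exact.
#'
#' @param mat integer matrix with row and column names.
#' @param path file path.
#' @return `write_matrix`: `path`, invisibly.  `read_matrix`: the matrix.
#' @export
write_matrix <- function(mat, path) {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  df <- data.frame(family_id = rownames(mat), mat, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix
#' @export
read_matrix <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (anyDuplicated(df[[1L]]))
    stop("duplicate row label(s): ",
         paste(unique(df[[1L]][duplicated(df[[1L]])]), collapse = ", "))
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df[[1L]]
  mat
}

#' Write / read a phylogenetic tree in Newick format
#'
#' Thin wrappers over \pkg{ape} that keep internal-node bootstrap labels.
#'
#' @param tree an \pkg{ape} `phylo` object.
#' @param path file path.
#' @return `write_newick`: `path`, invisibly.  `read_newick`: a `phylo`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "phylo"))
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}

#' Path to a shipped fixture file
#'
#' @param name file name under the package's `extdata` directory; with no
#'   argument, lists the available fixtures.
#' @return A file path (or a vector of file names).
#' @export
brevipan_fixture <- function(name = NULL) {
  dir <- system.file("extdata", package = "brevipan")
  if (is.null(name)) return(list.files(dir))
  path <- file.path(dir, name)
  if (!file.exists(path)) stop("no fixture named '", name, "'")
  path
}

#' Read a genome summary fixture table
#'
#' Per-genome chromosome statistics (length, CDS count, annotation shares,
#' GC, plasmid complement) plus the beer-spoiler flag, as transcribed from
#' the published strain table.
#'
#' @param path TSV path; defaults to the shipped transcription.
#' @return Data frame with one row per genome.
#' @export
read_genome_summary <- function(path = brevipan_fixture("table3_summary.tsv")) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("genome_id", "chromosome_length_mbp", "cds_count",
            "hypothetical_pct", "assigned_pct", "gc_pct", "plasmid_count",
            "spoiler")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "))
  df$spoiler <- as.logical(df$spoiler)
  df
}

#' Read a screen fixture (gene-by-strain presence table)
#'
#' The shipped fixtures transcribe the published beer-spoiler gene lists:
#' the chromosomal screen (58 genes, 7 spoiler strains) and the plasmid-only
#' screen (25 genes).  Rows carry a unique id, the product string and the
#' printed functional category alongside the 0/1 presence pattern.
#'
#' @param path TSV path, e.g. `brevipan_fixture("table5_matrix.tsv")`.
#' @return List with `matrix` (integer presence matrix, genes x strains),
#'   `product` and `category` (named character vectors).
#' @export
read_screen_fixture <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(all(c("family_id", "product", "category") %in% names(df)))
  if (anyDuplicated(df$family_id)) stop("duplicate family ids in fixture")
  strain_cols <- setdiff(names(df), c("family_id", "product", "category"))
  mat <- as.matrix(df[, strain_cols, drop = FALSE])
  storage.mode(mat) <- "integer"
  rownames(mat) <- df$family_id
  list(matrix = mat,
       product = setNames(df$product, df$family_id),
       category = setNames(df$category, df$family_id))
}
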
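is_hypothetical <- function(product, pattern = "hypothetical protein",
                            match = c("exact", "substring")) {
  match <- match.arg(match)
  p <- tolower(trimws(product))
  if (match == "exact") p == tolower(pattern)
  else grepl(tolower(pattern), p, fixed = TRUE)
}

#' Summarize annotated genomes
#'
#' One row per genome: chromosomal CDS count, share of products flagged as
#' hypothetical (case-insensitive exact-phrase match by default), share
#' with an assigned function, plasmid count, and metadata columns carried
#' over from `meta` (niche label, spoiler flag, GC when available).
#'
#' @param records annotated records.
#' @param meta genome metadata (needs `genome_id`; `spoiler`, `niche_label`,
#'   `gc_pct` used when present).
#' @param config a [run_config()] (controls the hypothetical-product rule).
#' @return Data frame, one row per genome.
#' @export
summarize_genomes <- function(records, meta = NULL, config = run_config()) {
  genomes <- sort(unique(records$genome_id))
  rows <- lapply(genomes, function(g) {
    rec <- records[records$genome_id == g, , drop = FALSE]
    chr <- rec[rec$replicon_type == "chromosome", , drop = FALSE]
    if (nrow(chr) == 0L)
      stop("genome ", g, " has no chromosomal records")
    hyp <- is_hypothetical(chr$product, config$hypothetical_pattern,
                           config$hypothetical_match)
    data.frame(
      genome_id = g,
      cds_count = nrow(chr),
      hypothetical_pct = 100 * mean(hyp),
      assigned_pct = 100 * mean(!hyp),
      plasmid_count = length(unique(
        rec$replicon_id[rec$replicon_type == "plasmid"])),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!is.null(meta)) {
    idx <- match(out$genome_id, meta$genome_id)
    for (cc in setdiff(names(meta), names(out)))
      out[[cc]] <- meta[[cc]][idx]
  }
  out
}

#' Column mean over a genome subset
#'
#' Arithmetic mean of one summary column, optionally restricted to a
#' subset of genomes, rounded with round-half-to-even.  All fixture
#' averages flow through this single code path.
#'
#' @param rows summary data frame (needs `genome_id`).
#' @param column column name.
#' @param subset optional character vector of genome ids.
#' @param digits decimal places (default: no rounding).
#' @return Numeric scalar.
#' @export
column_mean <- function(rows, column, subset = NULL, digits = NULL) {
  if (!column %in% names(rows)) stop("unknown column: ", column)
  x <- rows[[column]]
  if (!is.null(subset)) {
    keep <- rows$genome_id %in% subset
    if (!any(keep)) stop("empty subset")
    x <- x[keep]
  }
  if (length(x) == 0L) stop("empty subset")
  m <- mean(x)
  if (!is.null(digits)) m <- round(m, digits)
  m
}

#' Association between chromosome size and CDS count
#'
#' Ordinary least squares of CDS count on chromosome length, plus the
#' Pearson correlation.
#'
#' @param rows summary data frame with `chromosome_length_mbp` and
#'   `cds_count`.
#' @return List `slope` (CDS per Mbp), `intercept`, `correlation`.
#' @export
size_cds_association <- function(rows) {
  if (nrow(rows) < 3L) stop("need at least three genomes")
  x <- rows$chromosome_length_mbp
  y <- rows$cds_count
  if (stats::var(x) == 0) stop("zero variance in chromosome length")
  fit <- lm(y ~ x)
  list(slope = unname(coef(fit)[2L]),
       intercept = unname(coef(fit)[1L]),
       correlation = cor(x, y))
}
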
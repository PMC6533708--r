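#' Run configuration
#'
#' Central container for every tunable threshold in the pipeline.  Defaults
#' follow the published analysis protocol where one is stated: the similarity
#' filter keeps reciprocal hits with at least 30% amino-acid identity across
#' 80% of the sequence length and (for ingested BLAST tabular hits) an
#' E-value of at most 1e-4; the niche screens require presence in at least 4
#' beer-spoiler genomes on chromosomes and at least 3 on plasmids with no
#' non-spoiler carriers; plasmids are called similar at >= 90% shared gene
#' content and unique below 10%; supertrees are bootstrapped 1000 times with
#' supports above 250 displayed.  Values without a published counterpart
#' (MCL inflation, prefilter geometry, permutation count) carry standard
#' field defaults and are documented in the methods vignette.
#'
#' @param ... named overrides for any top-level section, e.g.
#'   `similarity = list(min_identity_pct = 50)`.  Overrides are merged into
#'   the defaults section-wise, so partial lists are allowed.
#' @return A named list of sections (class `brevipan_config`):
#'   `similarity`, `mcl`, `pan`, `screen`, `plasmid`, `phylogeny`, plus
#'   `hypothetical_pattern`, `hypothetical_match` and `seed`.
#' @examples
#' cfg <- run_config(similarity = list(min_identity_pct = 50), seed = 7)
#' cfg$similarity$min_identity_pct
#' @export
run_config <- function(...) {
  defaults <- list(
    similarity = list(
      min_identity_pct  = 30,
      min_coverage_frac = 0.80,
      max_evalue        = 1e-4,
      gap_open          = 11,
      gap_extend        = 1,
      min_raw_score     = 30,
      prefilter_k       = 4L,
      prefilter_min_shared = 2L,
      prefilter_min_frac   = 0.02
    ),
    mcl = list(
      inflation       = 1.5,
      max_iterations  = 100L,
      epsilon         = 1e-6,
      prune_threshold = 1e-5
    ),
    pan = list(
      closed_exponent_threshold = 0.5,
      n_permutations            = 100L
    ),
    screen = list(
      min_pos_chromosome = 4L,
      min_pos_plasmid    = 3L,
      max_neg            = 0L
    ),
    plasmid = list(
      similar_threshold = 0.90,
      unique_threshold  = 0.10
    ),
    phylogeny = list(
      bootstrap_reps      = 1000L,
      support_display_min = 250L
    ),
    hypothetical_pattern = "hypothetical protein",
    hypothetical_match   = c("exact", "substring"),
    seed = 1L
  )
  defaults$hypothetical_match <- "exact"
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (!nm %in% names(defaults))
      stop("unknown config section: ", nm)
    if (is.list(defaults[[nm]]) && is.list(overrides[[nm]])) {
      bad <- setdiff(names(overrides[[nm]]), names(defaults[[nm]]))
      if (length(bad))
        stop("unknown config field(s) in '", nm, "': ",
             paste(bad, collapse = ", "))
      defaults[[nm]][names(overrides[[nm]])] <- overrides[[nm]]
    } else {
      defaults[[nm]] <- overrides[[nm]]
    }
  }
  validate_config(defaults)
  structure(defaults, class = "brevipan_config")
}

validate_config <- function(cfg) {
  s <- cfg$similarity
  stopifnot(
    s$min_identity_pct >= 0, s$min_identity_pct <= 100,
    s$min_coverage_frac >= 0, s$min_coverage_frac <= 1,
    s$max_evalue > 0, s$gap_open >= 0, s$gap_extend >= 0,
    s$prefilter_k >= 1,
    cfg$mcl$inflation > 1, cfg$mcl$max_iterations >= 1,
    cfg$mcl$epsilon > 0, cfg$mcl$prune_threshold >= 0,
    cfg$pan$n_permutations >= 1,
    cfg$screen$min_pos_chromosome >= 1, cfg$screen$min_pos_plasmid >= 1,
    cfg$screen$max_neg >= 0,
    cfg$plasmid$similar_threshold >= 0, cfg$plasmid$similar_threshold <= 1,
    cfg$plasmid$unique_threshold >= 0, cfg$plasmid$unique_threshold <= 1,
    cfg$phylogeny$bootstrap_reps >= 1
  )
  invisible(cfg)
}
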
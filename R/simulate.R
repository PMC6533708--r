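#' Specification for a synthetic pan-genome
#'
#' The generator plants a known family structure — core families present in
#' every genome, shell families with a drawn genome-frequency spectrum,
#' strain-unique families, and niche families present only in spoiler
#' genomes — then emits per-genome protein copies mutated independently from
#' a family ancestor (star phylogeny).  Ground truth (gene-to-family map and
#' family class labels) is returned alongside the records so downstream
#' stages can be validated exactly.
#'
#' @param n_genomes number of genomes.
#' @param n_spoilers number of spoiler (niche-positive) genomes; the first
#'   `n_spoilers` genome ids are the spoilers.
#' @param n_core_families families present in every genome.
#' @param n_shell_families families present in 2..(n_genomes-1) genomes;
#'   occupancy is drawn uniformly over that range (or from
#'   `shell_occupancy`, a vector of fractions of `n_genomes`).  Shell genome
#'   sets are redrawn if they would mimic the niche-screen pattern
#'   (>= `niche_min_pos` spoilers and no non-spoiler), keeping planted niche
#'   families identifiable.
#' @param n_unique_per_genome strain-unique families per genome.
#' @param n_niche_families families planted only in spoiler genomes, each in
#'   at least `niche_min_pos` of them.
#' @param niche_min_pos minimum spoiler occupancy of a niche family.
#' @param niche_on_plasmid place niche genes on plasmids (otherwise they are
#'   forced onto the chromosome, mirroring a chromosomal screen).
#' @param shell_occupancy optional vector of occupancy fractions in (0,1)
#'   sampled (with replacement) per shell family.
#' @param paralog_prob per family per genome probability of carrying a
#'   second, independently mutated copy.
#' @param substitution_rate per-site probability that a genome copy differs
#'   from the family ancestor (in `[0, 0.5]`).
#' @param mean_protein_len,sd_protein_len,min_protein_len ancestor length
#'   distribution (clipped normal, amino acids).
#' @param plasmid_frac fraction of (non-niche) genes assigned to plasmids.
#' @param n_plasmids_per_genome inclusive integer range (length 2) of the
#'   per-genome plasmid count.
#' @param seed integer seed; identical specs give byte-identical output.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n_genomes = 12L, n_spoilers = 7L,
                     n_core_families = 800L, n_shell_families = 300L,
                     n_unique_per_genome = 5L, n_niche_families = 20L,
                     niche_min_pos = 4L, niche_on_plasmid = FALSE,
                     shell_occupancy = NULL, paralog_prob = 0.1,
                     substitution_rate = 0.02, mean_protein_len = 300,
                     sd_protein_len = 60, min_protein_len = 50L,
                     plasmid_frac = 0.1, n_plasmids_per_genome = c(2L, 5L),
                     seed = 1L) {
  spec <- as.list(environment())
  stopifnot(
    n_genomes >= 2, n_spoilers <= n_genomes,
    n_core_families >= 0, n_shell_families >= 0,
    n_unique_per_genome >= 0, n_niche_families >= 0,
    substitution_rate >= 0, substitution_rate <= 0.5,
    paralog_prob >= 0, paralog_prob <= 1,
    plasmid_frac >= 0, plasmid_frac <= 1,
    length(n_plasmids_per_genome) == 2,
    mean_protein_len > 0, min_protein_len >= 1
  )
  if (n_niche_families > 0 && niche_min_pos > n_spoilers)
    stop("infeasible spec: niche_min_pos exceeds n_spoilers")
  if (n_shell_families > 0 && n_genomes < 3)
    stop("infeasible spec: shell families need at least 3 genomes")
  if (!is.null(shell_occupancy))
    stopifnot(all(shell_occupancy > 0), all(shell_occupancy < 1))
  structure(spec, class = "sim_spec")
}

#' Mutate an amino-acid sequence at a fixed per-site rate
#'
#' Each site is independently replaced, with probability `rate`, by a
#' uniformly chosen *different* residue from the 20-letter alphabet.
#'
#' @param ancestor amino-acid string.
#' @param rate per-site replacement probability in `[0, 0.5]`.
#' @return Mutated string of the same length.
#' @export
mutate_sequence <- function(ancestor, rate) {
  stopifnot(rate >= 0, rate <= 0.5)
  if (!nzchar(ancestor)) stop("empty ancestor sequence")
  if (rate == 0) return(ancestor)
  chars <- strsplit(ancestor, "", fixed = TRUE)[[1L]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    aa20 <- AA_ALPHABET[1:20]
    cur <- match(chars[hit], aa20)
    cur[is.na(cur)] <- 1L  # non-standard residues treated as 'A'
    step <- sample.int(19L, length(hit), replace = TRUE)
    chars[hit] <- aa20[((cur - 1L + step) %% 20L) + 1L]
  }
  paste(chars, collapse = "")
}

random_protein <- function(len) {
  paste(sample(AA_ALPHABET[1:20], len, replace = TRUE), collapse = "")
}

draw_len <- function(n, mean, sd, min_len) {
  pmax(as.integer(round(rnorm(n, mean, sd))), as.integer(min_len))
}

# uniform integer draw on [lo, hi]; safe for degenerate ranges (sample()
# would otherwise reinterpret a scalar as 1:n)
draw_range <- function(lo, hi, n = 1L) {
  if (lo >= hi) return(rep(as.integer(lo), n))
  as.integer(lo) + sample.int(hi - lo + 1L, n, replace = TRUE) - 1L
}

#' Simulate a multi-genome protein universe with known family structure
#'
#' @param spec a [sim_spec()].
#' @return List with elements
#'   `records` (annotated protein data frame incl. sequences),
#'   `genomes` (metadata with `spoiler` flags and niche labels), and
#'   `truth` (list: `genes` mapping gene_id to family_id, `families` with
#'   class labels core/shell/unique/niche and ancestor sequences).
#' @export
simulate_pangenome <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  n <- spec$n_genomes
  genome_ids <- sprintf("G%02d", seq_len(n))
  spoilers <- genome_ids[seq_len(spec$n_spoilers)]
  is_spoiler <- genome_ids %in% spoilers

  fam_class <- c(
    rep("core", spec$n_core_families),
    rep("shell", spec$n_shell_families),
    rep("niche", spec$n_niche_families),
    rep("unique", spec$n_unique_per_genome * n)
  )
  n_fam <- length(fam_class)
  fam_ids <- sprintf("F%05d", seq_len(n_fam))
  anc_len <- draw_len(n_fam, spec$mean_protein_len, spec$sd_protein_len,
                      spec$min_protein_len)
  ancestors <- vapply(anc_len, random_protein, character(1))

  screen_like <- function(members) {
    sp <- sum(members %in% spoilers)
    sp >= spec$niche_min_pos && sp == length(members)
  }

  # genome membership per family
  membership <- vector("list", n_fam)
  uniq_owner <- rep(genome_ids, each = spec$n_unique_per_genome)
  ui <- 0L
  for (f in seq_len(n_fam)) {
    cls <- fam_class[f]
    if (cls == "core") {
      membership[[f]] <- genome_ids
    } else if (cls == "shell") {
      repeat {
        occ <- if (is.null(spec$shell_occupancy)) {
          draw_range(2L, n - 1L)
        } else {
          frac <- spec$shell_occupancy[draw_range(1L,
                                                  length(spec$shell_occupancy))]
          max(2L, min(n - 1L, as.integer(round(frac * n))))
        }
        mem <- sort(sample(genome_ids, occ))
        if (!screen_like(mem)) break
      }
      membership[[f]] <- mem
    } else if (cls == "niche") {
      occ <- draw_range(spec$niche_min_pos, spec$n_spoilers)
      membership[[f]] <- sort(sample(spoilers, occ))
    } else {
      ui <- ui + 1L
      membership[[f]] <- uniq_owner[ui]
    }
  }

  # plasmid complements
  n_plas <- draw_range(spec$n_plasmids_per_genome[1],
                       spec$n_plasmids_per_genome[2], n)
  plasmid_ids <- lapply(n_plas, function(k) paste0("p", LETTERS[seq_len(k)]))
  names(plasmid_ids) <- genome_ids

  rows <- vector("list", n_fam)
  for (f in seq_len(n_fam)) {
    mem <- membership[[f]]
    copies <- 1L + as.integer(runif(length(mem)) < spec$paralog_prob)
    gmem <- rep(mem, copies)
    seqs <- vapply(gmem, function(g)
      mutate_sequence(ancestors[f], spec$substitution_rate), character(1))
    on_plasmid <- if (fam_class[f] == "niche" && !spec$niche_on_plasmid) {
      rep(FALSE, length(gmem))
    } else if (fam_class[f] == "niche" && spec$niche_on_plasmid) {
      rep(TRUE, length(gmem))
    } else {
      runif(length(gmem)) < spec$plasmid_frac
    }
    repl <- vapply(seq_along(gmem), function(i) {
      g <- gmem[i]
      pl <- plasmid_ids[[g]]
      if (on_plasmid[i] && length(pl)) sample(pl, 1L) else "chr"
    }, character(1))
    rows[[f]] <- data.frame(
      family_id = fam_ids[f], genome_id = gmem, replicon_id = repl,
      sequence = unname(seqs), stringsAsFactors = FALSE)
  }
  genes <- do.call(rbind, rows)

  # gene ids, coordinates (genes laid end to end per replicon, 100 bp gaps)
  ord <- order(genes$genome_id, genes$replicon_id)
  genes <- genes[ord, , drop = FALSE]
  genes$gene_id <- sprintf("%s_%05d", genes$genome_id,
                           stats::ave(seq_len(nrow(genes)), genes$genome_id,
                                      FUN = seq_along))
  nt_len <- nchar(genes$sequence) * 3L + 3L
  key <- paste(genes$genome_id, genes$replicon_id)
  off <- stats::ave(nt_len, key, FUN = function(x) cumsum(c(0L, head(x, -1) + 100L)))
  genes$start <- off + 1L
  genes$end <- off + nt_len
  genes$strand <- ifelse(runif(nrow(genes)) < 0.5, "+", "-")
  genes$replicon_type <- ifelse(genes$replicon_id == "chr",
                                "chromosome", "plasmid")
  cls_of <- setNames(fam_class, fam_ids)
  genes$product <- ifelse(cls_of[genes$family_id] == "unique",
                          "hypothetical protein",
                          paste("conserved protein", genes$family_id))

  records <- validate_records(genes[, c(ANNOT_COLS, "sequence")])
  truth_genes <- data.frame(gene_id = genes$gene_id,
                            family_id = genes$family_id,
                            stringsAsFactors = FALSE)
  truth_families <- data.frame(family_id = fam_ids, class = fam_class,
                               ancestor = unname(ancestors),
                               stringsAsFactors = FALSE)
  genomes <- data.frame(
    genome_id = genome_ids,
    niche_label = ifelse(is_spoiler, "beer", "silage"),
    spoiler = is_spoiler,
    n_plasmids = n_plas,
    stringsAsFactors = FALSE)
  list(records = records, genomes = genomes,
       truth = list(genes = truth_genes, families = truth_families))
}

#' Evolve a family of sequences along a guide tree
#'
#' Alternative to the star-phylogeny generator for phylogeny validation:
#' substitutions accumulate along branches, with each edge length read as a
#' per-site substitution probability (capped at 0.5).
#'
#' @param tree an \pkg{ape} `phylo` with edge lengths.
#' @param n_families number of independent families to evolve.
#' @param mean_len,sd_len,min_len ancestor length distribution.
#' @param seed integer seed.
#' @return List of per-family named character vectors (one sequence per tip).
#' @export
simulate_on_tree <- function(tree, n_families = 10L, mean_len = 200,
                             sd_len = 40, min_len = 50L, seed = 1L) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  set.seed(seed)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  out <- vector("list", n_families)
  for (f in seq_len(n_families)) {
    len <- draw_len(1L, mean_len, sd_len, min_len)
    seqs <- character(max(tree$edge))
    seqs[root] <- random_protein(len)
    # fixed-point pass: an edge is processed once its parent has a sequence
    remaining <- rep(TRUE, nrow(tree$edge))
    while (any(remaining)) {
      for (e in which(remaining)) {
        par <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
        if (nzchar(seqs[par])) {
          seqs[child] <- mutate_sequence(seqs[par],
                                         min(tree$edge.length[e], 0.5))
          remaining[e] <- FALSE
        }
      }
    }
    fam <- seqs[seq_len(ntip)]
    names(fam) <- tree$tip.label
    out[[f]] <- fam
  }
  out
}
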
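test_that("single-copy core selection requires universality and single copies", {
  fam <- data.frame(
    family_id = c("f1", "f1", "f1",
                  "f2", "f2", "f2", "f2",
                  "f3", "f3"),
    gene_id = paste0("g", 1:9),
    genome_id = c("A", "B", "C",
                  "A", "A", "B", "C",
                  "A", "B"))
  expect_identical(select_single_copy_core(fam, c("A", "B", "C")), "f1")
  # outgroup missing one member excludes the family
  expect_error(select_single_copy_core(fam[fam$family_id == "f3", ],
                                       c("A", "B", "C")),
               "no universal")
})

test_that("planted universal single-copy families are recovered from a simulation", {
  spec <- sim_spec(n_genomes = 5, n_spoilers = 2, n_core_families = 50,
                   n_shell_families = 10, n_unique_per_genome = 2,
                   n_niche_families = 0, niche_min_pos = 2,
                   paralog_prob = 0, substitution_rate = 0.05,
                   mean_protein_len = 120, sd_protein_len = 20, seed = 29)
  sim <- simulate_pangenome(spec)
  fam <- data.frame(family_id = sim$truth$genes$family_id,
                    gene_id = sim$truth$genes$gene_id,
                    genome_id = sim$records$genome_id[
                      match(sim$truth$genes$gene_id, sim$records$gene_id)])
  got <- select_single_copy_core(fam, sim$genomes$genome_id)
  want <- sim$truth$families$family_id[sim$truth$families$class == "core"]
  expect_setequal(got, want)
  expect_equal(length(got), 50L)
})

test_that("center-star alignment handles identical and gapped families", {
  same <- align_family(c(A = "MKVL", B = "MKVL", C = "MKVL"))
  expect_identical(unclass(same)[1:3],
                   c(A = "MKVL", B = "MKVL", C = "MKVL"))

  id <- scoring_matrix()
  aln <- align_family(c(A = "MKV", B = "MKV", C = "MV"), scoring = id,
                      gap_open = 0, gap_extend = 1)
  expect_equal(unique(nchar(aln)), 2L)
  expect_identical(unname(aln["C"]), "MV")
  expect_identical(unname(aln["A"]), "MV")

  expect_error(align_family(c(A = "", B = "MK")), "empty")
})

test_that("gap-free output contains no gap symbol", {
  set.seed(61)
  seqs <- c(A = "MKVLLQWERT", B = "MKVLQWERT", C = "MKVLLQWRT",
            D = "MKVLLQWERT")
  aln <- align_family(seqs)
  expect_false(any(grepl("-", aln, fixed = TRUE)))
  expect_equal(length(unique(nchar(aln))), 1L)
})

test_that("concatenation preserves length and taxa and is order-invariant downstream", {
  a1 <- structure(c(A = "MKVLAHGWER", B = "MKVLAHGWDR", C = "MKVLAHGAER"),
                  class = "multiple_alignment")
  a2 <- structure(c(A = "PQRSTVWYAC", B = "PQRSTVWYAC", C = "PQRSTVWFAC"),
                  class = "multiple_alignment")
  sup <- concatenate_alignments(list(f1 = a1, f2 = a2))
  expect_equal(unique(nchar(sup)), 20L)
  expect_equal(length(attr(sup, "family")), 20L)
  expect_error(concatenate_alignments(list()), "no alignments")
  a3 <- structure(c(A = "MK", D = "MK"), class = "multiple_alignment")
  expect_error(concatenate_alignments(list(a1, a3)), "taxon sets")

  sup_rev <- concatenate_alignments(list(f2 = a2, f1 = a1))
  expect_equal(p_distance(sup), p_distance(sup_rev))
})

test_that("p-distances count differing columns", {
  al <- structure(c(A = "AAAA", B = "AAAT"), class = "multiple_alignment")
  D <- p_distance(al)
  expect_equal(D["A", "B"], 0.25)
  expect_true(all(diag(D) == 0))

  ident <- structure(c(A = "MKVL", B = "MKVL"), class = "multiple_alignment")
  expect_true(all(p_distance(ident) == 0))

  set.seed(71)
  rows <- vapply(1:4, function(i) random_aa(40, c("A", "C", "D")),
                 character(1))
  names(rows) <- paste0("T", 1:4)
  al2 <- structure(rows, class = "multiple_alignment")
  D2 <- p_distance(al2)
  for (i in 1:3) for (j in (i + 1):4) {
    x <- strsplit(rows[i], "")[[1]]; y <- strsplit(rows[j], "")[[1]]
    expect_equal(D2[i, j], mean(x != y))
  }
})

test_that("three-taxon NJ matches the closed-form branch lengths", {
  D <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(D)
  pen <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])], tr$tip.label)
  expect_equal(unname(pen["A"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(pen["B"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(pen["C"]), (0.5 + 0.6 - 0.3) / 2)
  expect_error(nj_tree(D[1:2, 1:2]), "three taxa")
  Dbad <- D; Dbad[1, 2] <- 0.9
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("NJ reconstructs additive matrices from random 4-8 taxon trees", {
  set.seed(83)
  for (rep in 1:15) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n, rooted = FALSE,
                     br = function(k) runif(k, 0.05, 1))
    D <- ape::cophenetic.phylo(tr)
    got <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(tr), got), 0,
                 ignore_attr = TRUE)
    expect_equal(ape::cophenetic.phylo(got)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }
})

test_that("all-zero distances give a star with zero branch lengths", {
  D <- matrix(0, 5, 5, dimnames = list(paste0("T", 1:5), paste0("T", 1:5)))
  tr <- nj_tree(D)
  expect_true(all(tr$edge.length == 0))
  expect_setequal(tr$tip.label, paste0("T", 1:5))
})

test_that("bootstrap supports are reproducible and bounded by the replicate count", {
  tree <- ape::read.tree(
    text = "((A:0.02,B:0.02):0.4,((C:0.02,D:0.02):0.4,E:0.3):0.1);")
  fams <- simulate_on_tree(tree, n_families = 4, mean_len = 150,
                           sd_len = 10, seed = 5)
  alns <- lapply(fams, function(f)
    structure(f, class = "multiple_alignment"))
  names(alns) <- paste0("fam", seq_along(alns))
  sup <- concatenate_alignments(alns)

  bs1 <- bootstrap_supertree(sup, reps = 25, seed = 9)
  bs2 <- bootstrap_supertree(sup, reps = 25, seed = 9)
  expect_identical(bs1$supports, bs2$supports)
  expect_true(all(bs1$supports >= 0 & bs1$supports <= 25))
  # deep, long-branch splits are unanimous
  expect_true(all(bs1$supports == 25))

  one <- bootstrap_supertree(sup, reps = 1, seed = 2)
  expect_true(all(one$supports %in% c(0L, 1L)))
})

test_that("block bootstrap resamples whole families", {
  tree <- ape::read.tree(text = "((A:0.05,B:0.05):0.3,(C:0.05,D:0.05):0.3);")
  fams <- simulate_on_tree(tree, n_families = 6, mean_len = 80,
                           sd_len = 5, seed = 15)
  alns <- lapply(fams, structure, class = "multiple_alignment")
  names(alns) <- paste0("fam", seq_along(alns))
  sup <- concatenate_alignments(alns)
  bs <- bootstrap_supertree(sup, reps = 10, seed = 3, block = TRUE)
  expect_true(all(bs$supports <= 10))
})

test_that("outgroup rooting splits the pendant edge and is topology-idempotent", {
  tr <- ape::read.tree(text = "(A:0.1,B:0.2,(C:0.3,D:0.4):0.05);")
  rooted <- root_with_outgroup(tr, "A")
  expect_true(ape::is.rooted(rooted))
  root_node <- length(rooted$tip.label) + 1L
  kids <- which(rooted$edge[, 1] == root_node)
  expect_equal(rooted$edge.length[kids[1]], rooted$edge.length[kids[2]])
  og_clade <- ape::extract.clade(
    rooted, rooted$edge[kids, 2][rooted$edge[kids, 2] > length(tr$tip.label)])
  expect_false("A" %in% og_clade$tip.label)

  again <- root_with_outgroup(ape::unroot(rooted), "A")
  expect_true(same_topology(again, rooted))
  expect_error(root_with_outgroup(tr, "Z"), "not found")
})

test_that("a guide-tree simulation is reconstructed end to end with correct rooting", {
  guide <- ape::read.tree(
    text = "(((A:0.03,B:0.03):0.25,(C:0.03,D:0.03):0.25):0.3,OG:0.5);")
  fams <- simulate_on_tree(guide, n_families = 5, mean_len = 200,
                           sd_len = 20, seed = 33)
  alns <- lapply(fams, structure, class = "multiple_alignment")
  names(alns) <- paste0("fam", seq_along(alns))
  sup <- concatenate_alignments(alns)
  bs <- bootstrap_supertree(sup, reps = 20, seed = 8)
  rooted <- root_with_outgroup(bs$tree, "OG")
  ingroup <- ape::drop.tip(rooted, "OG")
  want <- ape::drop.tip(guide, "OG")
  expect_true(same_topology(ingroup, want))
  # with the outgroup retained, the planted topology is also recovered
  expect_true(same_topology(bs$tree, guide))
})

test_that("the supertree wrapper runs on a small simulated universe", {
  spec <- sim_spec(n_genomes = 4, n_spoilers = 2, n_core_families = 12,
                   n_shell_families = 0, n_unique_per_genome = 1,
                   n_niche_families = 0, niche_min_pos = 2,
                   paralog_prob = 0, substitution_rate = 0.05,
                   mean_protein_len = 100, sd_protein_len = 10, seed = 55)
  sim <- simulate_pangenome(spec)
  fam <- data.frame(family_id = sim$truth$genes$family_id,
                    gene_id = sim$truth$genes$gene_id,
                    genome_id = sim$records$genome_id[
                      match(sim$truth$genes$gene_id, sim$records$gene_id)])
  st <- build_supertree(fam, sim$records, sim$genomes$genome_id,
                        outgroup_id = "G01", reps = 10, seed = 1)
  expect_equal(length(st$family_ids), 12L)
  expect_setequal(names(st$supermatrix), sim$genomes$genome_id)
  expect_true(ape::is.rooted(st$rooted))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(st$rooted, f)
  expect_setequal(read_newick(f)$tip.label, sim$genomes$genome_id)
})
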
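triangle_pairs <- function(nodes, weight = 1) {
  combs <- t(combn(nodes, 2))
  data.frame(a = combs[, 1], b = combs[, 2], weight = weight,
             stringsAsFactors = FALSE)
}

test_that("MCL separates disjoint cliques and isolates singletons", {
  pairs <- rbind(triangle_pairs(c("a1", "a2", "a3")),
                 triangle_pairs(c("b1", "b2", "b3")))
  res <- mcl(similarity_graph(pairs))
  expect_equal(length(res$clusters), 2L)
  expect_setequal(vapply(res$clusters, length, integer(1)), c(3L, 3L))
  expect_lte(res$max_col_deviation, 1e-9)

  lonely <- similarity_graph(
    data.frame(a = character(), b = character(), weight = numeric()),
    nodes = paste0("n", 1:5))
  res5 <- mcl(lonely)
  expect_equal(length(res5$clusters), 5L)
  expect_true(all(vapply(res5$clusters, length, integer(1)) == 1L))
})

test_that("MCL recovers planted dense blocks despite weak cross edges", {
  set.seed(2)
  blocks <- split(sprintf("v%02d", 1:30), rep(1:3, each = 10))
  pairs <- do.call(rbind, lapply(blocks, triangle_pairs, weight = 0.9))
  cross <- data.frame(a = c("v01", "v11"), b = c("v15", "v25"),
                      weight = 0.05)
  res <- mcl(similarity_graph(rbind(pairs, cross)), inflation = 1.5)
  got <- lapply(res$clusters, sort)
  expect_setequal(got, lapply(blocks, sort))
  expect_lte(res$max_col_deviation, 1e-9)
})

test_that("MCL output is a partition and behaves on disjoint unions", {
  set.seed(9)
  p1 <- triangle_pairs(paste0("x", 1:4), 0.8)
  p2 <- triangle_pairs(paste0("y", 1:5), 0.7)
  joint <- mcl(similarity_graph(rbind(p1, p2)))
  expect_equal(sum(vapply(joint$clusters, length, integer(1))),
               length(joint$membership))
  expect_false(anyDuplicated(unlist(joint$clusters)) > 0)

  alone1 <- mcl(similarity_graph(p1))
  alone2 <- mcl(similarity_graph(p2))
  expect_setequal(lapply(joint$clusters, sort),
                  c(lapply(alone1$clusters, sort),
                    lapply(alone2$clusters, sort)))
})

test_that("MCL is stable when re-run on its own clusters", {
  blocks <- split(sprintf("w%02d", 1:30), rep(1:3, each = 10))
  pairs <- do.call(rbind, lapply(blocks, triangle_pairs, weight = 0.9))
  cross <- data.frame(a = c("w01", "w11"), b = c("w15", "w25"),
                      weight = 0.05)
  res <- mcl(similarity_graph(rbind(pairs, cross)))
  all_pairs <- rbind(pairs, cross)
  for (cl in res$clusters) {
    sub <- all_pairs[all_pairs$a %in% cl & all_pairs$b %in% cl, ]
    rerun <- mcl(similarity_graph(sub, nodes = cl))
    expect_equal(length(rerun$clusters), 1L)
  }
})

test_that("families are built per cluster and grouped by genome", {
  recs <- rbind(toy_records(c(g1 = "MKV"), genome = "A"),
                toy_records(c(g2 = "MKV"), genome = "B"))
  fam <- build_families(setNames(c(1L, 1L), c("g1", "g2")), recs)
  expect_equal(length(unique(fam$family_id)), 1L)
  expect_setequal(fam$genome_id, c("A", "B"))

  single <- build_families(setNames(2L, "g1"), recs)
  expect_equal(nrow(single), 1L)

  expect_error(build_families(setNames(1L, "nope"), recs), "absent")
})

test_that("family classes follow the membership rules", {
  fam <- data.frame(
    family_id = c("f1", "f1", "f1", "f2", "f2", "f2", "f2", "f3", "f3", "f3"),
    gene_id = paste0("g", 1:10),
    genome_id = c("A", "B", "C", "A", "A", "B", "C", "A", "A", "A"))
  cl <- classify_families(fam, c("A", "B", "C"))
  expect_equal(unname(cl$classes[c("f1", "f2", "f3")]),
               c("core_single", "core_multi", "unique"))
  expect_equal(unname(cl$summary["core_total"]), 2L)
  expect_error(classify_families(fam, character()), "empty")

  disp <- data.frame(family_id = "f4", gene_id = "g11", genome_id = "B")
  cl2 <- classify_families(rbind(fam, disp), c("A", "B", "C"))
  expect_equal(unname(cl2$classes["f4"]), "unique")
  two <- data.frame(family_id = c("f5", "f5"), gene_id = c("g12", "g13"),
                    genome_id = c("A", "B"))
  cl3 <- classify_families(rbind(fam, two), c("A", "B", "C"))
  expect_equal(unname(cl3$classes["f5"]), "dispensable")
})

test_that("clustering a small simulated universe recovers the planted classes", {
  spec <- sim_spec(n_genomes = 5, n_spoilers = 2, n_core_families = 40,
                   n_shell_families = 10, n_unique_per_genome = 3,
                   n_niche_families = 0, niche_min_pos = 2,
                   paralog_prob = 0.1, substitution_rate = 0.05,
                   mean_protein_len = 150, sd_protein_len = 30, seed = 19)
  sim <- simulate_pangenome(spec)
  pairs <- filter_bidirectional(all_vs_all(sim$records))
  res <- mcl(similarity_graph(pairs, nodes = sim$records$gene_id))
  fam <- build_families(res, sim$records)
  expect_equal(length(unique(fam$family_id)),
               length(unique(sim$truth$genes$family_id)))
  truth <- setNames(sim$truth$genes$family_id, sim$truth$genes$gene_id)
  pred <- setNames(fam$family_id, fam$gene_id)
  expect_equal(rand_index(pred, truth), 1.0)

  cl <- classify_families(fam, sim$genomes$genome_id)
  # expected class counts recomputed from the emitted truth tables
  tg <- merge(sim$truth$genes, sim$records[, c("gene_id", "genome_id")])
  tab <- table(tg$family_id, tg$genome_id)
  want <- ifelse(rowSums(tab > 0) == 5 & apply(tab, 1, max) == 1,
                 "core_single",
          ifelse(rowSums(tab > 0) == 5, "core_multi",
          ifelse(rowSums(tab > 0) == 1, "unique", "dispensable")))
  expect_equal(unname(cl$summary[c("core_single", "core_multi",
                                   "dispensable", "unique")]),
               unname(c(sum(want == "core_single"),
                        sum(want == "core_multi"),
                        sum(want == "dispensable"),
                        sum(want == "unique"))))
})
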
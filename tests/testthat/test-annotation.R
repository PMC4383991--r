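test_that("phyletic profile yields universality, duplicability, class", {
  gms <- c("A", "B", "C", "D")
  p1 <- phyletic_profile(c("A", "B", "C", "D"), gms)
  expect_equal(p1$universality, 1.0)
  expect_equal(p1$duplicability, 0.0)
  expect_equal(p1$copy_number_class, "single_copy_in_all")

  # counts {2,1,1,0}: universality 3/4, duplicability 1/3, patchy
  p2 <- phyletic_profile(c("A", "A", "B", "C"), gms)
  expect_equal(unname(p2$counts), c(2L, 1L, 1L, 0L))
  expect_equal(p2$universality, 0.75)
  expect_equal(p2$duplicability, 1 / 3)
  expect_equal(p2$copy_number_class, "patchy")

  p3 <- phyletic_profile(rep(gms, each = 2), gms)
  expect_equal(p3$copy_number_class, "multi_copy_in_all")
  p4 <- phyletic_profile(c("A", "A", "B", "C", "D"), gms)
  expect_equal(p4$copy_number_class, "present_in_all")
  expect_error(phyletic_profile(character(0), gms), "empty group")

  # always within [0, 1]
  set.seed(8)
  for (k in 1:20) {
    mg <- sample(gms, sample(1:10, 1), TRUE)
    p <- phyletic_profile(mg, gms)
    expect_gte(p$universality, 0); expect_lte(p$universality, 1)
    expect_gte(p$duplicability, 0); expect_lte(p$duplicability, 1)
  }
})

test_that("evolutionary rate normalizes member identities by BRH baselines", {
  gg <- setNames(c("A", "B", "A", "B"), c("a1", "b1", "a2", "b2"))
  brh <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                    genome_a = "A", genome_b = "B", score = 100,
                    identity = c(80, 80))
  base <- brh_baseline(brh)
  expect_equal(base$baseline, 80)
  # member pair at the baseline identity: rate 1
  h <- make_sym_hits("a1", "b1", 100, ident = 80)
  expect_equal(evolutionary_rate(c("a1", "b1"), gg, h, base), 1.0)
  # identity 40 against baseline 80: rate 0.5
  h2 <- make_sym_hits("a1", "b1", 100, ident = 40)
  expect_equal(evolutionary_rate(c("a1", "b1"), gg, h2, base), 0.5)
  # single-genome group: undefined
  h3 <- make_sym_hits("a1", "a2", 100, ident = 90)
  expect_true(is.na(evolutionary_rate(c("a1", "a2"), gg, h3, base)))
})

test_that("gene architecture reports medians, population SD and deviants", {
  a <- gene_architecture(c(100, 100, 100), gene_ids = c("x", "y", "z"))
  expect_equal(a$length_median, 100)
  expect_equal(a$length_sd, 0)
  expect_equal(a$deviants, character(0))

  # a single member: median is its length, sd 0
  a1 <- gene_architecture(42L, gene_ids = "solo")
  expect_equal(a1$length_median, 42)
  expect_equal(a1$length_sd, 0)

  # {100,102,98,400}: the plain-SD rule cannot flag the outlier (it
  # inflates its own threshold), the MAD rule does
  lens <- c(100, 102, 98, 400)
  ids <- c("g1", "g2", "g3", "g4")
  asd <- gene_architecture(lens, gene_ids = ids, method = "sd")
  expect_equal(asd$length_median, 101)
  expect_equal(asd$length_sd, sqrt(mean((lens - mean(lens))^2)))
  expect_equal(asd$deviants, character(0))
  amad <- gene_architecture(lens, gene_ids = ids, method = "mad")
  expect_equal(amad$deviants, "g4")

  # exon stats absent without exon data, population SD with it
  ae <- gene_architecture(c(100, 100), exons = c(NA, NA))
  expect_true(is.na(ae$exon_median))
  ae2 <- gene_architecture(c(100, 100, 100), exons = c(2L, 4L, NA))
  expect_equal(ae2$exon_median, 3)
  expect_equal(ae2$exon_sd, 1)
})

test_that("sibling groups need a shared domain in >= 2 organisms each", {
  cl <- data.frame(
    level_id = "R",
    og_id = c("X", "X", "Y", "Y", "Z", "Z"),
    gene_id = paste0("g", 1:6),
    genome_id = c("A", "B", "C", "E", "A", "A"), stringsAsFactors = FALSE)
  md <- data.frame(gene_id = paste0("g", 1:6), genome_id = cl$genome_id,
                   protein_length = 100L, exon_count = NA_integer_,
                   domains = c("D", "D", "D", "D", "D", "D"),
                   stringsAsFactors = FALSE)
  sib <- sibling_groups(cl, md)
  # X (A,B) and Y (C,E) qualify; Z has D only in genome A (twice): genes
  # are not organisms
  expect_equal(nrow(sib), 1L)
  expect_equal(sib$group_a, "X")
  expect_equal(sib$group_b, "Y")
  expect_equal(sib$shared_domains, "D")

  # one organism in Y: no relation
  md2 <- md
  md2$domains[md2$gene_id == "g4"] <- ""
  expect_equal(nrow(sibling_groups(cl, md2)), 0L)
})

test_that("profile queries return matching groups", {
  cl <- data.frame(
    level_id = "R",
    og_id = rep(c("OG1", "OG2"), c(4, 3)),
    gene_id = paste0("g", 1:7),
    genome_id = c("A", "B", "C", "D", "B", "C", "D"),
    stringsAsFactors = FALSE)
  gms <- c("A", "B", "C", "D")
  expect_equal(query_by_profile(cl, "R", gms, "single_copy_in_all"), "OG1")
  expect_equal(query_by_profile(cl, "R", gms, "patchy"), "OG2")
  expect_equal(query_by_profile(cl, "R", gms, "A=0"), "OG2")
  expect_equal(query_by_profile(cl, "R", gms, "A=1,B>=1"), "OG1")
  expect_equal(query_by_profile(cl, "R", gms, "A>=5"), character(0))
  expect_error(query_by_profile(cl, "R", gms, "no_such_class"), "unknown")
})

test_that("annotate_level combines profile, rate and architecture", {
  cs <- cached_sim("clean20")
  sim <- cs$sim
  cl <- cluster_all_levels(cs$hits, sim$genes, sim$taxonomy, levels = "ROOT")
  gg <- setNames(sim$genes$genome_id, sim$genes$gene_id)
  brh <- brh_edges(cs$hits, gg, sim$taxonomy$genomes)
  ann <- annotate_level(cl, "ROOT", sim$taxonomy$genomes, cs$hits, brh,
                        sim$metadata)
  expect_equal(nrow(ann), length(unique(cl$og_id)))
  expect_true(all(ann$universality == 1))
  expect_true(all(ann$duplicability == 0))
  expect_true(all(ann$copy_number_class == "single_copy_in_all"))
  expect_true(all(is.finite(ann$evol_rate)))
  expect_true(all(ann$length_sd >= 0))
  # simulator assigns shared domains: at least one sibling pair appears
  expect_true(any(nzchar(ann$siblings)))
})
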
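g2g <- function(genes) {
  gm <- substr(genes, 1, 1)
  setNames(toupper(gm), genes)
}

test_that("best reciprocal hits require mutual best hits, keeping ties", {
  genomes <- c("A", "B")
  # mutual unique best: one edge
  h <- make_sym_hits("a1", "b1", 100)
  e <- best_reciprocal_hits(h, g2g(c("a1", "b1")), "A", "B")
  expect_equal(nrow(e), 1L)
  expect_equal(e$gene_a, "a1")
  expect_equal(e$score, 100L)

  # reciprocity fails: b1's best is c... i.e. another A gene scores higher
  h2 <- rbind(make_sym_hits("a1", "b1", 100),
              make_sym_hits("a2", "b1", 120))
  e2 <- best_reciprocal_hits(h2, g2g(c("a1", "a2", "b1")), "A", "B")
  expect_equal(nrow(e2), 1L)
  expect_equal(e2$gene_a, "a2")

  # ties kept: a1 ties to b1 and b2, both reciprocate
  h3 <- rbind(make_sym_hits("a1", "b1", 100),
              make_sym_hits("a1", "b2", 100))
  e3 <- best_reciprocal_hits(h3, g2g(c("a1", "b1", "b2")), "A", "B")
  expect_equal(nrow(e3), 2L)
  expect_setequal(e3$gene_b, c("b1", "b2"))

  # edge identity is the mean of the two directed identities
  h4 <- rbind(make_hits("a1", "b1", 100, ident = 80),
              make_hits("b1", "a1", 100, ident = 90))
  e4 <- best_reciprocal_hits(h4, g2g(c("a1", "b1")), "A", "B")
  expect_equal(e4$identity, 85)
})

test_that("in-paralog rule compares intra score to the weakest per-genome best BRH", {
  gg <- g2g(c("a1", "a2", "b1", "c1"))
  # BRH a1-b1 at 120; intra a1-a2 at 150 > 120: link with a2 as gene
  brh <- brh_edges(make_sym_hits("a1", "b1", 120), gg, c("A", "B", "C"))
  hits <- rbind(make_sym_hits("a1", "b1", 120),
                make_sym_hits("a1", "a2", 150))
  il <- in_paralogs(hits, brh, gg, "A")
  expect_equal(nrow(il), 1L)
  # a1 carries the lower T (its BRH score, 120, vs +Inf for BRH-less a2)
  expect_equal(il$gene, "a1")
  expect_equal(il$anchor, "a2")
  expect_equal(il$score, 150L)

  # strict inequality: intra 100 vs both best BRH 120: no link
  brh2 <- brh_edges(rbind(make_sym_hits("a1", "b1", 120),
                          make_sym_hits("a2", "b2", 120)),
                    g2g(c("a1", "a2", "b1", "b2")), c("A", "B"))
  hits2 <- rbind(make_sym_hits("a1", "a2", 100),
                 make_sym_hits("a1", "b1", 120), make_sym_hits("a2", "b2", 120))
  expect_equal(nrow(in_paralogs(hits2, brh2, g2g(c("a1", "a2", "b1", "b2")),
                                "A")), 0L)

  # neither gene has a BRH edge: T = +Inf, no link however high the score
  empty_brh <- brh_edges(make_sym_hits(character(0), character(0),
                                       integer(0)), gg, c("A", "B"))
  hits3 <- make_sym_hits("a1", "a2", 500)
  expect_equal(nrow(in_paralogs(hits3, empty_brh, gg, "A")), 0L)

  # min over genomes: A-B BRH 200 exceeds intra 150, but A-C BRH 120
  # does not; the link fires (the duplication postdates the A/C split)
  brh4 <- brh_edges(rbind(make_sym_hits("a1", "b1", 200),
                          make_sym_hits("a1", "c1", 120)),
                    gg, c("A", "B", "C"))
  hits4 <- rbind(make_sym_hits("a1", "a2", 150),
                 make_sym_hits("a1", "b1", 200), make_sym_hits("a1", "c1", 120))
  il4 <- in_paralogs(hits4, brh4, gg, "A")
  expect_equal(nrow(il4), 1L)
  # and at the two-genome level {A,B} the same data yields no link
  brh4ab <- brh_edges(hits4, gg, c("A", "B"))
  expect_equal(nrow(in_paralogs(hits4, brh4ab, gg, "A")), 0L)
})

test_that("triangulation clusters match hand-traced stage semantics", {
  gg <- g2g(c("a1", "b1", "c1", "d1"))
  # single triangle across three genomes
  tri <- data.frame(gene_a = c("a1", "a1", "b1"),
                    gene_b = c("b1", "c1", "c1"),
                    genome_a = c("A", "A", "B"), genome_b = c("B", "C", "C"),
                    score = c(100, 90, 95), identity = 80)
  cl <- triangulate_and_cluster(tri, NULL, "R", gg)
  expect_equal(groups_from_table(cl, "R"), list(c("a1", "b1", "c1")))

  # two genomes: no triangles, each BRH edge is a two-gene group
  two <- data.frame(gene_a = c("a1", "a2"), gene_b = c("b1", "b2"),
                    genome_a = "A", genome_b = "B",
                    score = c(100, 90), identity = 80)
  cl2 <- triangulate_and_cluster(two, NULL, "R",
                                 g2g(c("a1", "a2", "b1", "b2")))
  expect_equal(groups_from_table(cl2, "R"),
               list(c("a1", "b1"), c("a2", "b2")))

  # two triangles sharing edge (a1, b1) form one group
  shared <- data.frame(gene_a = c("a1", "a1", "b1", "a1", "b1"),
                       gene_b = c("b1", "c1", "c1", "d1", "d1"),
                       genome_a = c("A", "A", "B", "A", "B"),
                       genome_b = c("B", "C", "C", "D", "D"),
                       score = 100, identity = 80)
  cl3 <- triangulate_and_cluster(shared, NULL, "R", gg)
  expect_equal(groups_from_table(cl3, "R"),
               list(c("a1", "b1", "c1", "d1")))
})

test_that("stage machine equals the brute-force reference on random instances", {
  set.seed(321)
  for (k in 1:60) {
    inst <- random_instance()
    got <- groups_from_table(
      triangulate_and_cluster(inst$brh, inst$il, "R",
                              g2g(unique(c(inst$brh$gene_a, inst$brh$gene_b,
                                           inst$il$gene, inst$il$anchor)))),
      "R")
    want <- oracle_stage_machine(inst$brh, inst$il)
    expect_identical(got, want)
  }
})

test_that("clustering output is a partition and is row-order invariant", {
  cs <- cached_sim("duploss20")
  cl <- cluster_all_levels(cs$hits, cs$sim$genes, cs$sim$taxonomy)
  for (lv in unique(cl$level_id)) {
    genes_lv <- cl$gene_id[cl$level_id == lv]
    expect_false(anyDuplicated(genes_lv) > 0)
  }
  set.seed(5)
  shuffled <- cs$hits[sample(nrow(cs$hits)), ]
  cl2 <- cluster_all_levels(shuffled, cs$sim$genes, cs$sim$taxonomy)
  expect_identical(cl, cl2)
})

test_that("child-level groups nest inside parent-level groups on clean data", {
  cs <- cached_sim("clean20")
  cl <- cluster_all_levels(cs$hits, cs$sim$genes, cs$sim$taxonomy)
  tax <- cs$sim$taxonomy
  n_ok <- 0L; n_tot <- 0L
  for (lv in names(tax$levels)) {
    pa <- tax$parent[[lv]]
    if (is.na(pa)) next
    child <- split(cl$gene_id[cl$level_id == lv], cl$og_id[cl$level_id == lv])
    parent_memb <- setNames(cl$og_id[cl$level_id == pa],
                            cl$gene_id[cl$level_id == pa])
    for (grp in child) {
      n_tot <- n_tot + 1L
      pg <- unique(parent_memb[grp])
      if (length(pg) == 1L && !anyNA(pg)) n_ok <- n_ok + 1L
    }
  }
  expect_gte(n_ok / n_tot, 0.99)
})

test_that("naive closure merges what triangulation keeps apart", {
  gg <- g2g(c("a1", "b1", "c1", "a2", "b2"))
  # a triangle cluster and a pair cluster bridged by one non-triangle
  # edge (c1-b2): triangulation records it unverified, naive merges
  brh <- data.frame(gene_a = c("a1", "a1", "b1", "a2", "b2"),
                    gene_b = c("b1", "c1", "c1", "b2", "c1"),
                    genome_a = c("A", "A", "B", "A", "B"),
                    genome_b = c("B", "C", "C", "B", "C"),
                    score = c(100, 90, 95, 80, 60), identity = 80)
  tri <- groups_from_table(
    triangulate_and_cluster(brh, NULL, "R", gg, closure = "triangulate"), "R")
  nv <- groups_from_table(
    triangulate_and_cluster(brh, NULL, "R", gg, closure = "naive"), "R")
  expect_equal(length(tri), 2L)
  expect_equal(length(nv), 1L)
})
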
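test_that("confusion implements precision/recall/F1 with the zero case", {
  expect_equal(confusion(letters[1:4], letters[1:4]),
               c(precision = 1, recall = 1, f1 = 1))
  expect_equal(confusion(c("a", "b", "c", "d"), c("a", "b", "e")),
               c(precision = 2 / 3, recall = 1 / 2, f1 = 4 / 7))
  expect_equal(confusion(c("a", "b"), c("x", "y")),
               c(precision = 0, recall = 0, f1 = 0))
  expect_error(confusion(c("a"), character(0)), "empty cluster")
})

test_that("restriction to the reference universe drops and singles correctly", {
  pred <- partition(list(c1 = c("a", "b", "x"), c2 = c("q", "r")))
  restr <- restrict_to_universe(pred, c("a", "b", "z"))
  expect_equal(restr$blocks, list(c1 = c("a", "b")))
  expect_equal(restr$universe, c("a", "b", "z"))
  # z is unassigned: it completes to a singleton
  cb <- orthotri:::complete_blocks(restr)
  expect_equal(length(cb), 2L)
  expect_true(any(vapply(cb, identical, logical(1), "z")))
})

test_that("each event class is recognized with correct precedence", {
  ref <- partition(list(R1 = paste0("g", 1:10)))

  # Exact: p = r = 1
  res <- classify_events(ref, partition(list(c1 = paste0("g", 1:10))))
  expect_equal(res$records$event, "Exact")

  # Akin: p = r = 0.9 (9 of 10 right, 1 wrong gene)
  pred_akin <- partition(list(c1 = c(paste0("g", 1:9), "x1"),
                              c2 = c("g10", paste0("x", 2:9))),
                         c(paste0("g", 1:10), paste0("x", 1:9)))
  ref_akin <- partition(list(R1 = paste0("g", 1:10),
                             R2 = paste0("x", 1:9)))
  res_akin <- classify_events(ref_akin, pred_akin)
  r1 <- res_akin$records[res_akin$records$refog_id == "R1", ]
  expect_equal(r1$precision, 0.9)
  expect_equal(r1$recall, 0.9)
  expect_equal(r1$event, "Akin")

  # Fused: two reference groups engulfed by one cluster
  ref_f <- partition(list(R1 = paste0("g", 1:10), R2 = paste0("h", 1:10)))
  pred_f <- partition(list(c1 = c(paste0("g", 1:10), paste0("h", 1:10))))
  res_f <- classify_events(ref_f, pred_f)
  expect_equal(res_f$records$event, c("Fused", "Fused"))
  expect_equal(res_f$n_fuse_total, 1L)   # one fusing event for the pair

  # Split: one reference group scattered over three pure clusters
  ref_s <- partition(list(R1 = paste0("g", 1:9)))
  pred_s <- partition(list(c1 = paste0("g", 1:3), c2 = paste0("g", 4:6),
                           c3 = paste0("g", 7:9)))
  res_s <- classify_events(ref_s, pred_s)
  expect_equal(res_s$records$event, "Split")
  expect_equal(res_s$records$n_split_events, 3L)
  expect_equal(res_s$n_split_total, 3L)
  # precedence: its best-cluster recall is 1/3 < 0.5 yet it is not Missed
  expect_lt(res_s$records$recall, 0.5)

  # Missed: best recall 0.4 with no split/fuse structure
  ref_m <- partition(list(R1 = paste0("g", 1:10)),
                     c(paste0("g", 1:10), paste0("x", 1:10)))
  pred_m <- partition(list(c1 = c(paste0("g", 1:4), paste0("x", 1:10))),
                      ref_m$universe)
  res_m <- classify_events(ref_m, pred_m)
  expect_equal(res_m$records$recall, 0.4)
  expect_equal(res_m$records$event, "Missed")

  # Complex: moderate overlap, nothing else fits
  ref_c <- partition(list(R1 = paste0("g", 1:10)),
                     c(paste0("g", 1:10), paste0("x", 1:5)))
  pred_c <- partition(list(c1 = c(paste0("g", 1:6), paste0("x", 1:5))),
                      ref_c$universe)
  res_c <- classify_events(ref_c, pred_c)
  expect_equal(res_c$records$event, "Complex")

  # counts sum to the number of reference groups
  expect_equal(sum(res_akin$event_counts), 2L)
})

test_that("event totals are invariant under cluster relabeling", {
  set.seed(17)
  u <- paste0("e", 1:40)
  ref <- random_partition_of(u, 6)
  predb <- random_partition_of(u, 6)
  r1 <- classify_events(ref, predb)
  relab <- predb
  names(relab$blocks) <- paste0("zz_", rev(seq_along(relab$blocks)))
  r2 <- classify_events(ref, relab)
  expect_equal(r1$event_counts, r2$event_counts)
  expect_equal(r1$n_split_total, r2$n_split_total)
  expect_equal(r1$n_fuse_total, r2$n_fuse_total)
})

test_that("variation of information matches the cell-sum oracle", {
  u <- c("a", "b", "c", "d")
  x <- partition(list(p = c("a", "b"), q = c("c", "d")), u)
  y <- partition(list(w = u), u)
  expect_equal(variation_of_information(x, y), 1.0)
  expect_equal(variation_of_information(x, x), 0)
  expect_equal(variation_of_information(x, y),
               variation_of_information(y, x))
  # natural-log option scales by log(2)
  expect_equal(variation_of_information(x, y, base = exp(1)), log(2))

  set.seed(23)
  for (k in 1:20) {
    u <- paste0("e", seq_len(sample(5:30, 1)))
    px <- random_partition_of(u)
    py <- random_partition_of(u)
    expect_equal(variation_of_information(px, py), vi_oracle(px, py),
                 tolerance = 1e-12)
  }
  expect_error(variation_of_information(
    partition(list(), character(0)), partition(list(), character(0))),
    "empty universe")
})

test_that("benchmark report ties the pieces together", {
  pred <- data.frame(level_id = "R", og_id = rep(c("o1", "o2"), each = 2),
                     gene_id = paste0("g", 1:4),
                     genome_id = c("A", "B", "A", "B"),
                     stringsAsFactors = FALSE)
  refs <- data.frame(refog_id = rep(c("r1", "r2"), each = 2),
                     gene_id = paste0("g", 1:4), stringsAsFactors = FALSE)
  rep <- benchmark_clustering(pred, refs)
  expect_equal(unname(rep$event_counts["Exact"]), 2L)
  expect_equal(rep$vi, 0)
  expect_equal(rep$n_f1_ge_85, 2L)
})
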
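test_that("bh_adjust reproduces the step-up definition", {
  expect_identical(sum(bh_adjust(c(1, 1))$reject), 0L)
  # ranks 1..3 pass jointly, 0.5 does not
  expect_identical(sum(bh_adjust(c(0.01, 0.02, 0.03, 0.5))$reject), 3L)
  # step-up rescue: 0.04 > 0.05 * 1/2 at rank 1, but rank 2 passes both
  expect_identical(sum(bh_adjust(c(0.04, 0.04))$reject), 2L)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_length(bh_adjust(numeric(0))$q_values, 0)

  set.seed(1)
  for (i in 1:20) {
    p <- round(runif(sample(1:8, 1)), 3)
    got <- bh_adjust(p)
    want <- bh_oracle(p)
    expect_equal(got$q_values, want$q_values)
    expect_identical(got$reject, want$reject)
    expect_equal(got$q_values, stats::p.adjust(p, "BH"))
  }
})

test_that("compute_age_change returns the defined statistics", {
  young <- matrix(10, nrow = 2, ncol = 3)
  old <- matrix(c(15, 15, 15, 10, 10, 10), nrow = 2, byrow = TRUE)
  co <- toy_cohort(young, old)
  res <- compute_age_change(co, young_brackets = "20s",
                            old_brackets = "70s")
  expect_equal(res$absolute_change, c(5, 0))
  expect_equal(res$relative_change, c(0.5, 0))
  # noiseless equal-mean gene: no direction, p = 1
  expect_identical(res$direction[[2]], "none")
  expect_equal(res$p_value[[2]], 1)

  # zero young mean flags relative change as missing
  co0 <- toy_cohort(matrix(0, 1, 3), matrix(4, 1, 3))
  res0 <- compute_age_change(co0, "20s", "70s")
  expect_true(is.na(res0$relative_change))

  expect_error(compute_age_change(co, c("20s"), c("20s", "70s")),
               "overlap")
})

test_that("default bracket split uses the two youngest / two oldest", {
  sim <- simulate_cohort(cohort_config(n_genes = 20, n_matrisome = 8,
                                       tissues = "skin",
                                       donors_per_bracket = 4, seed = 2))
  co <- sim$cohorts$skin
  auto <- compute_age_change(co)
  manual <- compute_age_change(co, young_brackets = c("20s", "30s"),
                               old_brackets = c("60s", "70s"))
  expect_equal(auto, manual)
})

test_that("absolute and relative rankings agree in sign", {
  sim <- simulate_cohort(cohort_config(n_genes = 60, n_matrisome = 20,
                                       tissues = "skin",
                                       donors_per_bracket = 6, seed = 4))
  res <- compute_age_change(sim$cohorts$skin)
  ok <- !is.na(res$relative_change)
  expect_identical(sign(res$absolute_change[ok]),
                   sign(res$relative_change[ok]))
})

test_that("filter_matrisome is an order-preserving set filter", {
  coll <- demo_matrisome_collection(2)
  assocs <- data.frame(gene = c("COL1", "X1", "GP2", "X2", "PG1", "X3",
                                "COL2", "X4", "SF1", "X5"),
                       tissue = "t", stringsAsFactors = FALSE)
  kept <- filter_matrisome(assocs, coll)
  expect_identical(kept$gene, c("COL1", "GP2", "PG1", "COL2", "SF1"))
  expect_identical(nrow(filter_matrisome(assocs[assocs$gene %in%
                                                  paste0("X", 1:5), ], coll)),
                   0L)
  all_mat <- assocs[assocs$gene %in% matrisome_genes(coll), ]
  expect_identical(filter_matrisome(all_mat, coll), all_mat)
})

test_that("build_compendium applies support, majority and tie rules", {
  src <- list(
    s1 = data.frame(gene = c("A", "B", "C", "D"),
                    direction = c("up_with_age", "up_with_age",
                                  "up_with_age", "none")),
    s2 = data.frame(gene = c("A", "B", "C", "D"),
                    direction = c("up_with_age", "down_with_age",
                                  "up_with_age", "up_with_age")),
    s3 = data.frame(gene = c("A", "C", "D"),
                    direction = c("up_with_age", "down_with_age",
                                  "down_with_age")),
    s4 = data.frame(gene = c("C", "E"),
                    direction = c("down_with_age", "up_with_age")))
  sig <- build_compendium(src, min_sources = 3)
  # A: 3 sources, all up -> included
  expect_identical(sig$entries$direction[sig$entries$gene == "A"],
                   "up_with_age")
  expect_identical(sig$entries$support[sig$entries$gene == "A"], 3L)
  # B: only 2 sources -> excluded entirely
  expect_false("B" %in% c(sig$entries$gene, sig$conflicts))
  # C: 2 up vs 2 down -> tie, conflict
  expect_true("C" %in% sig$conflicts)
  # D: 3 sources but direction vote 1 up vs 1 down (none abstains) -> tie
  expect_true("D" %in% sig$conflicts)
  # order invariance
  sig_rev <- build_compendium(rev(src), min_sources = 3)
  expect_equal(sig$entries, sig_rev$entries)
  expect_identical(sig$conflicts, sig_rev$conflicts)
})

test_that("invert_signature is an involution that toggles kind", {
  sig <- matreotype_signature(
    data.frame(gene = c("A", "B"),
               direction = c("up_with_age", "down_with_age"),
               support = c(3L, 4L)),
    conflicts = "C", kind = "aged")
  inv <- invert_signature(sig)
  expect_identical(inv$kind, "youthful")
  expect_identical(inv$entries$direction, c("down_with_age", "up_with_age"))
  expect_identical(inv$conflicts, "C")
  expect_identical(invert_signature(inv), sig)

  empty <- matreotype_signature(
    data.frame(gene = character(0), direction = character(0),
               support = integer(0)), kind = "aged")
  expect_identical(nrow(invert_signature(empty)$entries), 0L)
})

test_that("split_signature partitions the entry set", {
  sig <- matreotype_signature(
    data.frame(gene = sprintf("G%d", 1:7),
               direction = c(rep("up_with_age", 4), rep("down_with_age", 3)),
               support = 3L),
    kind = "aged")
  halves <- split_signature(sig)
  expect_length(intersect(halves$up_with_age, halves$down_with_age), 0)
  expect_setequal(c(halves$up_with_age, halves$down_with_age),
                  sig$entries$gene)

  all_up <- matreotype_signature(
    data.frame(gene = c("A", "B"), direction = "up_with_age", support = 3L),
    kind = "aged")
  expect_identical(split_signature(all_up)$down_with_age, character(0))
})

test_that("signature TSV round-trips including conflicts", {
  sig <- matreotype_signature(
    data.frame(gene = c("A", "B"),
               direction = c("up_with_age", "down_with_age"),
               support = c(3L, 5L)),
    conflicts = c("C", "D"), kind = "youthful")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_signature(sig, path)
  back <- read_signature(path)
  expect_equal(back$entries, sig$entries)
  expect_identical(back$conflicts, sig$conflicts)
  expect_identical(back$kind, "youthful")
})
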
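make_profiles <- function(z) {
  drug_profile_matrix(z, data.frame(compound = rownames(z),
                                    lifespan_reported = FALSE))
}

test_that("regulation score matches the exhaustive enumeration oracle", {
  z <- c(3, 3, rep(0, 8))
  names(z) <- sprintf("g%d", 1:10)
  res <- matrisome_regulation_score(z, c("g1", "g2"))
  expect_identical(res$mode, "exhaustive")   # C(10,2) = 45 subsets
  oracle <- subset_mean_null_oracle(unname(z), 2)
  expect_equal(res$null_mean, oracle$mean)
  expect_equal(res$null_sd, oracle$sd)
  expect_equal(res$score, (3 - oracle$mean) / oracle$sd)

  # all-zero profile: degenerate guard
  z0 <- setNames(rep(0, 10), names(z))
  res0 <- matrisome_regulation_score(z0, c("g1", "g2"))
  expect_identical(res0$score, 0)
  expect_true(res0$degenerate)

  expect_error(matrisome_regulation_score(z, character(0)), "empty")
  expect_error(matrisome_regulation_score(z, "g1"), ">= 2")
})

test_that("vectorised regulation scores agree with the exhaustive null", {
  set.seed(8)
  z <- matrix(rnorm(5 * 12), nrow = 5,
              dimnames = list(sprintf("d%d", 1:5), sprintf("g%d", 1:12)))
  got <- regulation_scores(make_profiles(z), sprintf("g%d", 1:3),
                           n_null = 4000, seed = 1)
  for (i in 1:5) {
    exact <- matrisome_regulation_score(z[i, ], sprintf("g%d", 1:3),
                                        mode = "exhaustive")
    expect_lt(abs(got$score[i] - exact$score), 3 * 3 / sqrt(4000))
  }
})

test_that("classification partitions at the stated threshold", {
  sc <- c(a = 0, b = -2, c = 1.5, d = -1.5, e = 1.49)
  cls <- classify_matrisome_response(sc)
  expect_identical(cls$classification,
                   c("minor", "decreased", "increased", "decreased",
                     "minor"))
  expect_error(classify_matrisome_response(sc, threshold = 0), "> 0")
  set.seed(3)
  for (i in 1:5) {
    x <- rnorm(sample(10:60, 1), sd = 2)
    names(x) <- sprintf("c%d", seq_along(x))
    tab <- table(classify_matrisome_response(x)$classification)
    expect_identical(sum(tab), as.integer(length(x)))
  }
})

test_that("concordance scores respect half and mode sign conventions", {
  genes <- sprintf("g%d", 1:6)
  z <- rbind(inverted = c(-1, -1, -1, 0, 0, 0),
             zero = rep(0, 6),
             noisy = c(0.5, -0.2, 0.1, 0.3, 0, 0))
  colnames(z) <- genes
  pr <- make_profiles(z)
  up_genes <- genes[1:3]

  res <- concordance_scores(pr, up_genes, half = "up_with_age")
  rev <- res[res$mode == "reversed", ]
  pot <- res[res$mode == "potentiated", ]
  # extremal: z = -1 on every up_with_age gene gives the maximal reversed
  # score achievable with |z| <= 1
  expect_equal(rev$score[rev$compound == "inverted"], 1)
  expect_true(all(rev$score[rev$compound == "inverted"] >= rev$score))
  expect_equal(rev$score, -pot$score)
  expect_equal(res$score[res$compound == "zero"], c(0, 0))
  expect_setequal(rev$rank, seq_len(nrow(z)))

  # down_with_age half flips the convention
  res_dn <- concordance_scores(pr, up_genes, half = "down_with_age")
  expect_equal(res_dn$score[res_dn$mode == "reversed"], -rev$score)

  expect_error(concordance_scores(pr, c("absent1", "absent2")), "missing")
  # unmeasured signature genes are dropped with a message
  expect_message(concordance_scores(pr, c(up_genes, "absent")), "dropped")
})

test_that("reversed-on-aged equals potentiated-on-youthful exactly", {
  sig <- matreotype_signature(
    data.frame(gene = sprintf("g%d", 1:8),
               direction = rep(c("up_with_age", "down_with_age"), 4),
               support = 3L),
    kind = "aged")
  set.seed(5)
  z <- matrix(rnorm(20 * 10), nrow = 20,
              dimnames = list(sprintf("d%02d", 1:20), sprintf("g%d", 1:10)))
  pr <- make_profiles(z)
  on_aged <- signature_concordance(pr, sig)
  on_youthful <- signature_concordance(pr, invert_signature(sig))
  expect_identical(on_aged$reversed, on_youthful$potentiated)
  expect_identical(on_aged$potentiated, on_youthful$reversed)
})

test_that("top_k is deterministic, tie-broken and prefix-stable", {
  res <- data.frame(compound = c("b", "a", "c"), score = c(1, 1, 0.5))
  top <- top_k(res, k = 50)
  expect_identical(top$compound, c("a", "b", "c"))   # ties alphabetical
  expect_identical(top$rank, 1:3)
  set.seed(9)
  big <- data.frame(compound = sprintf("c%03d", 1:80),
                    score = sample(rep(rnorm(40), 2)))
  expect_identical(top_k(big, 10)$compound,
                   utils::head(top_k(big, 50)$compound, 10))
  expect_error(top_k(res, k = 0), ">= 1")
})

test_that("compile_hit_sets counts unique compounds and cross-overlap", {
  mk <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
  disjoint <- list("up.reversed" = mk("a", 50),
                   "down.reversed" = mk("b", 50),
                   "up.potentiated" = mk("c", 50),
                   "down.potentiated" = mk("d", 50))
  expect_identical(compile_hit_sets(disjoint)$n_unique, 200L)

  identical_lists <- list("up.reversed" = mk("a", 50),
                          "down.reversed" = mk("a", 50),
                          "up.potentiated" = mk("a", 50),
                          "down.potentiated" = mk("a", 50))
  expect_identical(compile_hit_sets(identical_lists)$n_unique, 50L)

  shared <- mk("s", 15)
  lists <- list("up.reversed" = c(shared, mk("a", 35)),
                "down.reversed" = mk("b", 50),
                "up.potentiated" = c(shared, mk("c", 35)),
                "down.potentiated" = mk("d", 50))
  hits <- compile_hit_sets(lists)
  expect_identical(hits$n_unique, 185L)
  expect_identical(hits$overlap_count, 15L)
  expect_identical(hits$n_total_entries, 200L)
  expect_error(compile_hit_sets(list(x = "a", y = "b")), "mode")
})

test_that("enrichment_stats matches the brute-force hypergeometric", {
  res <- enrichment_stats(2, 3, 4, 10)
  expect_equal(res$p_hypergeometric, hyper_oracle(2, 3, 4, 10))
  # every consistent table with a small library
  for (n_bg in c(8, 10, 12)) {
    for (n_bg_flagged in c(2, 5)) {
      for (n_hits in c(3, 6)) {
        for (k in 0:min(n_hits, n_bg_flagged)) {
          expect_equal(
            enrichment_stats(k, n_hits, n_bg_flagged, n_bg)$p_hypergeometric,
            hyper_oracle(k, n_hits, n_bg_flagged, n_bg))
        }
      }
    }
  }
  zero <- enrichment_stats(0, 10, 5, 100)
  expect_equal(zero$pct_hit, 0)
  expect_equal(zero$fold, 0)
  expect_error(enrichment_stats(5, 0, 5, 100), "denominator")
  expect_error(enrichment_stats(5, 4, 5, 100), "inconsistent")
})

test_that("cluster_for_display is deterministic and recovers structure", {
  set.seed(11)
  base <- rnorm(8)
  m <- rbind(r1 = base, r2 = base, r3 = rnorm(8), r4 = rnorm(8))
  cl <- cluster_for_display(m)
  # identical rows merge first at distance 0
  expect_equal(cl$row_hclust$height[[1]], 0)
  expect_setequal(abs(cl$row_hclust$merge[1, ]), c(1, 2))

  # permutation invariance of the dendrogram (cophenetic distances)
  perm <- c(3, 1, 4, 2)
  cl_p <- cluster_for_display(m[perm, ])
  d1 <- as.matrix(stats::cophenetic(cl$row_hclust))[rownames(m), rownames(m)]
  d2 <- as.matrix(stats::cophenetic(cl_p$row_hclust))[rownames(m),
                                                      rownames(m)]
  expect_equal(d1, d2)

  # planted two-block compound structure recovered at a 2-cut
  block <- rbind(matrix(rep(c(2, -2), each = 4), nrow = 4, ncol = 8,
                        byrow = TRUE),
                 matrix(rep(c(-2, 2), each = 4), nrow = 4, ncol = 8,
                        byrow = TRUE)) + matrix(rnorm(64, sd = 0.1), 8)
  rownames(block) <- sprintf("c%d", 1:8)
  colnames(block) <- sprintf("g%d", 1:8)
  groups <- stats::cutree(cluster_for_display(block)$row_hclust, k = 2)
  expect_identical(length(unique(groups[1:4])), 1L)
  expect_identical(length(unique(groups[5:8])), 1L)
  expect_false(groups[[1]] == groups[[5]])

  # zero-variance row flagged, distance set to maximum
  mz <- rbind(flat = rep(1, 6), a = rnorm(6), b = rnorm(6))
  clz <- cluster_for_display(mz)
  expect_identical(unname(clz$flagged_rows), 1L)
})
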
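# Diversity, lineage-class proportions and enrichment tests.

test_that("nei_diversity matches closed forms and is permutation invariant", {
  expect_equal(nei_diversity(c(10))$D, 0)
  expect_equal(nei_diversity(c(1, 1))$D, 1)          # 2/1 * (1 - 0.5)
  cnt <- c(5, 3, 9, 1, 0, 7)
  expect_equal(nei_diversity(cnt)$D, nei_diversity(sample(cnt))$D)
  # closed form at small counts
  expect_equal(nei_diversity(c(2, 2, 4))$D,
               8 / 7 * (1 - (0.25^2 + 0.25^2 + 0.5^2)))
  expect_error(nei_diversity(c(1)), class = "ystrata_domain_error")
})

test_that("diversity_by reproduces the published per-population values", {
  m <- tn_hg_counts()
  f <- tn_hg_frequencies()
  d <- diversity_by(m)
  # published gene diversities are printed to 3 decimals; reconstruction from
  # rounded percentages reproduces them within a rounding-sized band
  expect_lt(max(abs(d$D - f$gene_diversity)), 0.0015)
  expect_lt(max(abs(d$SD - f$gene_diversity_sd)), 0.0015)
})

test_that("lineage class proportions carry binomial standard errors", {
  m <- tn_hg_counts()
  # closed form: p = 0.5, n = 100 -> SE = 0.05
  toy <- count_matrix(tibble::tibble(population = "a", X = 50L, Y = 50L))
  r <- lineage_class_proportion(toy, "X")
  expect_equal(r$p, 0.5)
  expect_equal(r$SE, 0.05)
  # the binomial SE pairing of the published 13.7 +- 1.03 % at n = 1110
  expect_equal(sqrt(0.137 * (1 - 0.137) / 1110), 0.0103, tolerance = 0.005)
  # whole inventory -> p = 1, SE = 0
  all_r <- lineage_class_proportion(m, hg_cols(m))
  expect_equal(all_r$p, 1)
  expect_equal(all_r$SE, 0)
  expect_error(lineage_class_proportion(m, "NOT-A-HG"),
               class = "ystrata_domain_error")
  expect_error(lineage_class_proportion(m, "C-M130", rows = character(0)),
               class = "ystrata_domain_error")
})

test_that("chromosome-level Fisher tests match exhaustive enumeration", {
  # spec-style toy [[5,5],[5,85]]
  m <- count_matrix(tibble::tibble(population = c("in", "out"),
                                   hg = c(5L, 5L), other = c(5L, 85L)))
  g <- grouping(c("in", "out"), c("G", "rest"))
  r <- hg_enrichment_test(m, g, "hg", "G")
  expect_equal(r$p, oracle_fisher(5, 5, 5, 85), tolerance = 1e-12)
  expect_equal(r$direction, "over")
  # sweep of margins <= 40 against the enumeration oracle
  set.seed(42)
  for (rep in 1:25) {
    a <- sample(0:12, 1); b <- sample(0:12, 1)
    c_ <- sample(0:12, 1); d <- sample(1:12, 1)
    if ((a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0) next
    m2 <- count_matrix(tibble::tibble(population = c("in", "out"),
                                      hg = c(a, c_), other = c(b, d)))
    r2 <- hg_enrichment_test(m2, g, "hg", "G")
    expect_equal(r2$p, oracle_fisher(a, b, c_, d), tolerance = 1e-9)
  }
  # identical composition inside and outside -> p = 1
  m3 <- count_matrix(tibble::tibble(population = c("in", "out"),
                                    hg = c(4L, 4L), other = c(6L, 6L)))
  expect_equal(hg_enrichment_test(m3, g, "hg", "G")$p, 1)
  # zero-margin table flagged degenerate
  m4 <- count_matrix(tibble::tibble(population = c("in", "out"),
                                    hg = c(0L, 0L), other = c(5L, 5L)))
  r4 <- hg_enrichment_test(m4, g, "hg", "G")
  expect_true(r4$degenerate)
  expect_equal(r4$p, 1)
})

test_that("group enrichment directions are antisymmetric under complement", {
  m <- tn_hg_counts()
  g <- tn_groupings()$mpg
  comp <- grouping(g$population,
                   ifelse(g$group == "HTF", "HTF", "rest"))
  over <- hg_enrichment_test(m, comp, "F-M89", "HTF")
  under <- hg_enrichment_test(m, comp, "F-M89", "rest")
  expect_equal(over$direction, "over")
  expect_equal(under$direction, "under")
  expect_equal(over$p, under$p, tolerance = 1e-12)
})

test_that("population-level over-representation test matches hypergeometric counts", {
  # 4 of 4 in-group and 3 of 27 out-group over-represented:
  # one-sided p = C(7,4)/C(31,4) = 35/31465
  pops <- sprintf("p%02d", 1:31)
  over <- c(rep(TRUE, 4), rep(TRUE, 3), rep(FALSE, 24))
  # build counts where "over-represented" = frequency above overall
  cnt <- ifelse(over, 30L, 10L)
  m <- count_matrix(tibble::tibble(population = pops, hg = cnt,
                                   other = 100L - cnt))
  g <- grouping(pops, c(rep("G", 4), rep("rest", 27)))
  r <- population_overrep_test(m, g, "hg", "G")
  expect_equal(r$over_in, 4L)
  expect_equal(r$over_out, 3L)
  expect_equal(r$p_one_sided, 35 / 31465, tolerance = 1e-9)
  # toy [[2,0],[0,2]] -> one-sided 1/6
  pops4 <- c("a", "b", "c", "d")
  cnt4 <- c(30L, 30L, 10L, 10L)
  m4 <- count_matrix(tibble::tibble(population = pops4, hg = cnt4,
                                    other = 100L - cnt4))
  g4 <- grouping(pops4, c("G", "G", "rest", "rest"))
  expect_equal(population_overrep_test(m4, g4, "hg", "G")$p_one_sided, 1 / 6,
               tolerance = 1e-9)
  # every population over-represented -> p = 1 (degenerate margin)
  m5 <- count_matrix(tibble::tibble(population = pops4,
                                    hg = c(30L, 30L, 30L, 31L),
                                    other = c(70L, 70L, 70L, 69L)))
  expect_equal(population_overrep_test(m5, g4, "hg", "G")$p_one_sided, 1)
})
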
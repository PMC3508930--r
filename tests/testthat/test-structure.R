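# AMOVA, R_ST, permutation tests, bootstrap and ordination.

test_that("AMOVA components equal the brute-force nested sums-of-squares oracle", {
  set.seed(7)
  # haplogroup metric, <= 30 individuals, unequal sizes
  pop <- rep(c("a", "b", "c", "d"), c(9, 5, 8, 6))
  grp_map <- c(a = "G1", b = "G1", c = "G2", d = "G2")
  hg <- sample(c("H1", "H2", "H3"), length(pop), replace = TRUE,
               prob = c(.5, .3, .2))
  alle <- full_loci_mat(length(pop))
  alle[, 1] <- sample(12:16, length(pop), replace = TRUE)
  alle[, 5] <- sample(9:12, length(pop), replace = TRUE)
  t0 <- toy_hap(pop, alle, hg = hg, loci = ystr_loci())
  g <- grouping(names(grp_map), unname(grp_map))

  for (metric in c("haplogroup", "str")) {
    fit <- amova(t0, g, metric = metric)
    d2 <- if (metric == "haplogroup") d2_haplogroup(hg) else d2_str(alle)
    orc <- oracle_amova(d2, pop, unname(grp_map[pop]))
    for (f in c("Va", "Vb", "Vc", "FCT", "FSC", "FST")) {
      expect_equal(fit$components[[f]], orc[[f]], tolerance = 1e-10,
                   label = paste(metric, f))
    }
  }
})

test_that("phi statistics recompute from variance components exactly", {
  m <- tn_hg_counts()
  fit <- amova(m, tn_groupings()$mpg)
  comp <- fit$components
  V <- comp$Va + comp$Vb + comp$Vc
  expect_equal(comp$FCT, comp$Va / V, tolerance = 1e-12)
  expect_equal(comp$FSC, comp$Vb / (comp$Vb + comp$Vc), tolerance = 1e-12)
  expect_equal(comp$FST, (comp$Va + comp$Vb) / V, tolerance = 1e-12)
})

test_that("count-matrix AMOVA equals per-individual AMOVA on the expansion", {
  m <- tn_hg_counts()[1:8, ]
  m <- count_matrix(m[, c("population", hg_cols(m))])
  g <- grouping(m$population, rep(c("g1", "g2"), each = 4))
  a1 <- amova(m, g)
  ind <- expand_counts(m)
  d2 <- d2_haplogroup(ind$haplogroup)
  orc <- oracle_amova(d2, ind$population, group_of(g, ind$population))
  expect_equal(a1$components$FCT, orc$FCT, tolerance = 1e-12)
})

test_that("identical population compositions give zero fixation indices", {
  m <- count_matrix(tibble::tibble(population = c("a", "b", "c", "d"),
                                   X = 6L, Y = 4L, Z = 2L))
  g <- grouping(m$population, c("g1", "g1", "g2", "g2"))
  # the unbiased components are slightly negative for identical finite
  # samples; with clamping the fixation indices are exactly zero
  fit <- amova(m, g, clamp_negative = TRUE)
  expect_equal(fit$components$FCT, 0, tolerance = 1e-12)
  expect_equal(fit$components$FSC, 0, tolerance = 1e-12)
  expect_equal(fit$components$FST, 0, tolerance = 1e-12)
  raw <- amova(m, g)
  expect_lte(raw$components$FCT, 0)
  expect_lte(raw$components$FST, 0)
})

test_that("R_ST behaves at the degenerate extremes and matches the oracle", {
  # two monomorphic demes one repeat step apart at one locus -> R_ST = 1
  alle <- full_loci_mat(8)
  alle[5:8, 1] <- 15L
  t0 <- toy_hap(rep(c("a", "b"), each = 4), alle, loci = ystr_loci())
  expect_equal(unname(rst_distance(t0)["a", "b"]), 1)
  # 6-individual toy against the brute-force components
  alle2 <- full_loci_mat(6)
  alle2[, 1] <- c(14L, 15L, 14L, 17L, 16L, 17L)
  alle2[, 2] <- c(10L, 10L, 11L, 12L, 12L, 13L)
  pop2 <- rep(c("a", "b"), each = 3)
  t2 <- toy_hap(pop2, alle2, loci = ystr_loci())
  orc <- oracle_amova(d2_str(alle2), pop2, rep("all", 6))
  # one-level design: FST = Vb/(Vb+Vc) from the two-level formulas collapses
  fit <- amova(t2, NULL, metric = "str")
  expect_equal(unname(rst_distance(t2)["a", "b"]), fit$components$FST,
               tolerance = 1e-12)
  # invariance to adding a constant at a locus
  alle3 <- alle2
  alle3[, 2] <- alle3[, 2] + 7L
  t3 <- toy_hap(pop2, alle3, loci = ystr_loci())
  expect_equal(unname(rst_distance(t2)["a", "b"]),
               unname(rst_distance(t3)["a", "b"]), tolerance = 1e-12)
  # a population of size 1 errors by name
  t4 <- toy_hap(c("a", "a", "solo"), full_loci_mat(3), loci = ystr_loci())
  expect_error(rst_distance(t4), "solo", class = "ystrata_domain_error")
})

test_that("no differentiation at split time zero gives near-zero R_ST", {
  tr <- population_tree("A", Ne = 2000)
  t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 400, seed = 5))
  t0$population <- rep(c("x", "y"), 200)
  t0 <- haplotype_table(tibble::as_tibble(t0))
  expect_lt(abs(rst_distance(t0)["x", "y"]), 0.02)
})

test_that("permutation tests detect designed structure and enumerate exactly", {
  # clearly separated groups
  m <- count_matrix(tibble::tibble(
    population = c("a", "b", "c", "d"),
    X = c(28L, 27L, 2L, 3L), Y = c(2L, 3L, 28L, 27L)))
  g <- grouping(m$population, c("g1", "g1", "g2", "g2"))
  fit <- amova(m, g, n_perm = 999, seed = 1)
  p_fct <- fit$p_values$p[fit$p_values$statistic == "FCT"]
  expect_lte(p_fct, 0.35)  # only 3 distinct reassignments exist
  # 3 populations in 2 groups: 3 distinct assignments -> exact enumeration
  m3 <- count_matrix(tibble::tibble(population = c("a", "b", "c"),
                                    X = c(9L, 8L, 1L), Y = c(1L, 2L, 9L)))
  g3 <- grouping(m3$population, c("g1", "g1", "g2"))
  fit3 <- amova(m3, g3, n_perm = 999, seed = 1)
  row <- fit3$p_values[fit3$p_values$statistic == "FCT", ]
  expect_equal(row$method, "exact enumeration")
  expect_equal(row$n_null, 3L)
  expect_equal(row$p, 1 / 3)   # observed assignment is the unique best
  # FST permutation null is calibrated: under shuffled labels the p-value is
  # valid (super-uniform; ties make it discrete and conservative)
  set.seed(99)
  pvals <- replicate(120, {
    hgl <- sample(c("H1", "H2"), 24, replace = TRUE)
    tt <- toy_hap(sample(rep(c("a", "b", "c"), 8)), full_loci_mat(24),
                  hg = hgl, loci = ystr_loci())
    amova(tt, NULL, n_perm = 59)$p_values$p[1]
  })
  for (alpha in c(0.05, 0.1, 0.25)) {
    slack <- 2 * sqrt(alpha * (1 - alpha) / length(pvals))
    expect_lte(mean(pvals <= alpha), alpha + slack)
  }
  # and it is not degenerate: small p-values do occur at roughly their rate
  expect_gte(mean(pvals <= 0.25), 0.05)
})

test_that("the multinomial bootstrap is reproducible and centred", {
  m <- count_matrix(tibble::tibble(
    population = c("a", "b", "c", "d"),
    X = c(45L, 42L, 5L, 8L), Y = c(5L, 8L, 45L, 42L)))
  g <- grouping(m$population, c("g1", "g1", "g2", "g2"))
  b1 <- bootstrap_fct(m, g, B = 200, seed = 11)
  b2 <- bootstrap_fct(m, g, B = 200, seed = 11)
  expect_identical(b1$median, b2$median)
  expect_identical(b1$lower, b2$lower)
  # median close to the point estimate on well-separated data
  expect_lt(abs(b1$median - b1$point), 0.01)
  expect_true(b1$lower <= b1$median && b1$median <= b1$upper)
  # degenerate single-population input errors
  m1 <- count_matrix(tibble::tibble(population = "a", X = 5L, Y = 5L))
  expect_error(bootstrap_fct(m1, grouping("a", "g"), B = 100),
               class = "ystrata_domain_error")
})

test_that("compare_groupings orders by interval separation", {
  m <- count_matrix(tibble::tibble(
    population = c("a", "b", "c", "d"),
    X = c(45L, 42L, 5L, 8L), Y = c(5L, 8L, 45L, 42L)))
  mk <- function(med, lo, hi) {
    structure(list(statistic = "FCT", median = med, lower = lo, upper = hi,
                   fingerprint = "same"), class = "bootstrap_ci")
  }
  expect_equal(compare_groupings(mk(0.065, 0.052, 0.078),
                                 mk(0.02, 0.01, 0.04)), "a>b")
  expect_equal(compare_groupings(mk(0.02, 0.01, 0.04),
                                 mk(0.065, 0.052, 0.078)), "b>a")
  expect_equal(compare_groupings(mk(0.03, 0.01, 0.05),
                                 mk(0.04, 0.02, 0.06)), "overlap")
  # touching bounds count as overlap
  expect_equal(compare_groupings(mk(0.05, 0.04, 0.06),
                                 mk(0.03, 0.02, 0.04)), "overlap")
  bad <- mk(0.1, 0.05, 0.15); bad$fingerprint <- "other"
  expect_error(compare_groupings(mk(0.1, 0.05, 0.15), bad),
               class = "ystrata_domain_error")
})

test_that("PCA variance fractions behave as covariance PCA must", {
  m <- tn_hg_counts()
  p_pop <- hg_pca(m, mode = "population")
  expect_true(all(diff(p_pop$var_fraction) <= 1e-12))
  expect_equal(sum(p_pop$var_fraction), 1)
  # scale invariance: percent vs proportion input
  f <- as_count_mat(m) / rowSums(as_count_mat(m))
  p_prop <- hg_pca(100 * f, mode = "population")
  p_prop2 <- hg_pca(f, mode = "population")
  expect_equal(p_prop$var_fraction, p_prop2$var_fraction, tolerance = 1e-9)
  # rank-1 matrix: PC1 carries all variance
  r1 <- outer(c(1, 2, 3, 4), c(2, 1, 0.5)) +
    matrix(5, 4, 3)
  p1 <- hg_pca(r1, mode = "population")
  expect_equal(p1$var_fraction[1], 1, tolerance = 1e-9)
  expect_error(hg_pca(matrix(3, 4, 3), mode = "population"),
               class = "ystrata_domain_error")
})

test_that("non-metric MDS embeds exact configurations and orders stress by dims", {
  set.seed(3)
  xy <- matrix(rnorm(20), 10, 2)
  d <- as.matrix(dist(xy))
  fit <- hg_nmds(d, dims = 2, restarts = 10, seed = 1)
  expect_lt(fit$stress_percent, 0.5)
  # all-equal distances: still returns a configuration
  deq <- matrix(1, 6, 6); diag(deq) <- 0
  expect_s3_class(hg_nmds(deq, dims = 2, restarts = 3, seed = 1), "hg_nmds")
  # stress non-increasing in embedding dimension
  set.seed(8)
  x5 <- matrix(rnorm(60), 12, 5)
  d5 <- as.matrix(dist(x5))
  s <- vapply(1:3, function(k)
    hg_nmds(d5, dims = k, restarts = 8, seed = 2)$stress_percent, numeric(1))
  expect_true(s[2] <= s[1] + 1e-6 && s[3] <= s[2] + 1e-6)
  expect_error(hg_nmds(matrix(c(0, NA, NA, 0), 2)),
               class = "ystrata_domain_error")
})
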
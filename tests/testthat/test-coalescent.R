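# Split-time sampler: likelihood oracle, TMRCA estimators, recovery and
# scenario behaviour at reduced scale.

test_that("the SMM pruning likelihood matches brute-force enumeration", {
  # fixed 4-tip genealogy: ((1,2),(3,4)) with known node times
  alleles <- matrix(c(14L, 15L, 14L, 16L,
                      10L, 10L, 11L, 11L,
                      20L, 20L, 20L, 21L), 4, 3)
  parent <- c(4L, 4L, 5L, 5L, 6L, 6L, -1L)
  ch1 <- c(-1L, -1L, -1L, -1L, 0L, 2L, 4L)
  ch2 <- c(-1L, -1L, -1L, -1L, 1L, 3L, 5L)
  times <- c(0, 0, 0, 0, 120, 260, 900)
  for (mu in c(2e-4, 6.9e-4, 5e-3)) {
    ours <- ystrata:::smm_loglik_cpp(alleles, parent, ch1, ch2, times, mu,
                                     pad = 6)
    orc <- oracle_smm_loglik(alleles, parent, ch1, ch2, times, mu, pad = 6)
    expect_equal(ours, orc, tolerance = 1e-8, label = paste("mu =", mu))
  }
  # a 3-tip caterpillar
  alleles3 <- matrix(c(14L, 15L, 17L), 3, 1)
  parent3 <- c(3L, 3L, 4L, 4L, -1L)
  ch13 <- c(-1L, -1L, -1L, 0L, 2L)
  ch23 <- c(-1L, -1L, -1L, 1L, 3L)
  times3 <- c(0, 0, 0, 300, 1500)
  expect_equal(
    ystrata:::smm_loglik_cpp(alleles3, parent3, ch13, ch23, times3, 6.9e-4),
    oracle_smm_loglik(alleles3, parent3, ch13, ch23, times3, 6.9e-4),
    tolerance = 1e-8)
})

test_that("tmrca_cluster closed forms hold", {
  H <- full_loci_mat(4)
  expect_equal(tmrca_cluster(H)$age_years, 0)
  # star: each haplotype one step from the centre at a different locus
  Hs <- full_loci_mat(3)
  Hs[1, 1] <- 15L; Hs[2, 2] <- 15L; Hs[3, 3] <- 15L
  a <- tmrca_cluster(Hs, ancestral = rep(14, 17))
  expect_equal(a$age_years, (1 / 17) / 6.9e-4 * 25, tolerance = 1e-9)
  # linearity: doubling all step distances doubles the asd age
  H2 <- Hs
  H2[1, 1] <- 16L; H2[2, 2] <- 16L; H2[3, 3] <- 16L
  a2 <- tmrca_cluster(H2, ancestral = rep(14, 17))
  expect_equal(a2$age_years, 4 * a$age_years, tolerance = 1e-9)  # squared steps
  r2 <- tmrca_cluster(H2, mode = "rho", ancestral = rep(14, 17))
  r1 <- tmrca_cluster(Hs, mode = "rho", ancestral = rep(14, 17))
  expect_equal(r2$age_years, 2 * r1$age_years, tolerance = 1e-9)
  expect_error(tmrca_cluster(full_loci_mat(2)), class = "ystrata_domain_error")
})

test_that("the sampler is seed-reproducible and rejects bad input", {
  tr <- population_tree("(A:8000,B:8000);", Ne = 1500)
  t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 8, seed = 2))
  ch <- chain_config(samples = 1500, burnin = 300, seed = 4)
  p1 <- sample_split_posterior(t0, chain = ch)
  p2 <- sample_split_posterior(t0, chain = ch)
  expect_identical(p1$samples, p2$samples)
  ch2 <- chain_config(samples = 1500, burnin = 300, seed = 5)
  p3 <- sample_split_posterior(t0, chain = ch2)
  expect_false(identical(p1$samples$split1, p3$samples$split1))
  # fewer than 5 records per deme is rejected
  t_small <- haplotype_table(tibble::as_tibble(t0)[c(1:3, 9:16), ])
  expect_error(sample_split_posterior(t_small),
               class = "ystrata_domain_error")
  # one deme is rejected
  t_one <- haplotype_table(dplyr::mutate(tibble::as_tibble(t0),
                                         population = "A"))
  expect_error(sample_split_posterior(t_one), class = "ystrata_domain_error")
})

test_that("posterior credible intervals cover a true split time", {
  # reduced-scale parameter recovery: 2 demes split 10 Kya
  tr <- population_tree("(A:10000,B:10000);", Ne = 2000)
  covered <- 0L
  n_rep <- 12
  for (r in seq_len(n_rep)) {
    t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 12,
                                             seed = 100 + r))
    p <- sample_split_posterior(
      t0, chain = chain_config(samples = 6000, burnin = 1500, thin = 5,
                               seed = 200 + r))
    if (p$splits$lower <= 10000 && 10000 <= p$splits$upper) {
      covered <- covered + 1L
    }
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("mutation-rate posteriors recover the simulation truth within 2x", {
  tr <- population_tree("(A:10000,B:10000);", Ne = 2000)
  t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 30, seed = 55))
  p <- sample_split_posterior(t0, chain = chain_config(samples = 8000,
                                                       burnin = 2000,
                                                       seed = 56))
  mu_hat <- stats::median(p$samples$mu)
  expect_gt(mu_hat, 6.9e-4 / 2)
  expect_lt(mu_hat, 6.9e-4 * 2)
})

test_that("a duplicated panmictic deme collapses the split-time posterior", {
  tr <- population_tree("A", Ne = 2000)
  t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 40, seed = 71))
  t1 <- apply_scenario(t0, scenario_config("random_split", demes = "A",
                                           seed = 72))
  p <- sample_split_posterior(t1, chain = chain_config(samples = 20000,
                                                       burnin = 5000,
                                                       seed = 73))
  expect_lt(p$splits$median, 500)
})

test_that("modal_tree recovers strong three-deme structure", {
  tr <- population_tree("((A:4000,C:4000):36000,B:40000);", Ne = 2000)
  t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 12, seed = 31))
  p <- sample_split_posterior(t0, chain = chain_config(samples = 9000,
                                                       burnin = 2500,
                                                       seed = 32))
  expect_equal(length(p$splits$split), 2L)
  mt <- modal_tree(p)
  expect_equal(mt$topology, "((A,C),B)")
  expect_gte(mt$frequency, 0.8)
  # two demes: the single topology has frequency 1
  tAC <- haplotype_table(tibble::as_tibble(t0)[t0$population != "B", ])
  p2 <- sample_split_posterior(tAC, chain = chain_config(samples = 2000,
                                                         burnin = 500,
                                                         seed = 33))
  expect_equal(unname(p2$topology_freq[1]), 1)
  expect_equal(modal_tree(p2)$topology, "(A,C)")
})
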
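# Synthetic data: split-tree coalescent with stepwise mutation.

test_that("population trees parse Newick with checks", {
  tr <- population_tree("((A:4000,B:4000):6000,C:10000);", Ne = 1500)
  expect_equal(sort(tr$demes), c("A", "B", "C"))
  expect_equal(tr$merges$time_gen, c(160, 400))
  expect_error(population_tree("(A:5000,B:2000);"), "ultrametric",
               class = "ystrata_format_error")
  tr1 <- population_tree("A")
  expect_equal(tr1$demes, "A")
  expect_equal(nrow(tr1$merges), 0L)
  # Newick round trip preserves the merge schedule
  tr2 <- population_tree(as_newick(tr), Ne = 1500)
  expect_equal(tr2$merges$time_gen, tr$merges$time_gen)
  expect_setequal(tr2$demes, tr$demes)
  expect_equal(as_newick(tr1), "A;")
})

test_that("simulation is seed-reproducible and mutation-free at mu = 0", {
  tr <- population_tree("(A:5000,B:5000);", Ne = 1000)
  cfg <- sim_config(samples_per_deme = 15, seed = 5)
  t1 <- simulate_haplotypes(tr, cfg)
  t2 <- simulate_haplotypes(tr, cfg)
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  cfg2 <- cfg; cfg2$seed <- 6
  t3 <- simulate_haplotypes(tr, cfg2)
  expect_false(identical(tibble::as_tibble(t1), tibble::as_tibble(t3)))
  # mu = 0: everyone carries the ancestral vector
  cfg0 <- sim_config(samples_per_deme = 10, mu = 0, seed = 1)
  t0 <- simulate_haplotypes(tr, cfg0)
  expect_true(all(as.matrix(t0[, loci_of(t0)]) == 15L))
  # single deme census
  tr1 <- population_tree("A")
  tA <- simulate_haplotypes(tr1, sim_config(samples_per_deme = 50, seed = 2))
  expect_equal(census(tA)$n, 50L)
  expect_equal(length(unique(tA$haplogroup)), 1L)
  expect_error(sim_config(mu = 0.5), class = "ystrata_domain_error")
})

test_that("between-deme divergence matches the 2*mu*T stepwise expectation", {
  # E[ASD between] - E[ASD within] = 2 mu T for demes split T generations ago
  mu <- 6.9e-4; Tgen <- 2000
  tr <- population_tree(sprintf("(A:%d,B:%d);", Tgen * 25, Tgen * 25),
                        Ne = 5000)
  diffs <- replicate(60, {
    t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 25, mu = mu))
    al <- as.matrix(t0[, loci_of(t0)])
    a <- al[t0$population == "A", ]; b <- al[t0$population == "B", ]
    rot <- function(m) m[c(2:nrow(m), 1), ]      # no self-pairs
    asd_between <- mean((a - b)^2)
    asd_within <- (mean((rot(a) - a)^2) + mean((rot(b) - b)^2)) / 2
    asd_between - asd_within
  })
  expect_equal(mean(diffs), 2 * mu * Tgen, tolerance = 0.1)
})

test_that("within-deme variance grows with Ne and mu", {
  one_var <- function(Ne, mu, reps = 25) {
    tr <- population_tree("A", Ne = Ne)
    mean(replicate(reps, {
      t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 20, mu = mu))
      mean(apply(as.matrix(t0[, loci_of(t0)]), 2, var))
    }))
  }
  set.seed(17)
  v_ne <- c(one_var(300, 6.9e-4), one_var(1500, 6.9e-4), one_var(6000, 6.9e-4))
  expect_true(all(diff(v_ne) > 0))
  v_mu <- c(one_var(1500, 1e-4), one_var(1500, 6.9e-4), one_var(1500, 3e-3))
  expect_true(all(diff(v_mu) > 0))
})

test_that("scenario perturbations conserve record counts", {
  tr <- population_tree("(A:8000,B:8000);", Ne = 1000)
  t0 <- simulate_haplotypes(tr, sim_config(samples_per_deme = 30, seed = 9))
  # m = 0 mixing leaves the table unchanged
  s0 <- scenario_config("symmetric_mixing", demes = c("A", "B"), m = 0,
                        seed = 1)
  expect_identical(tibble::as_tibble(apply_scenario(t0, s0)),
                   tibble::as_tibble(t0))
  # random split partitions one deme, conserving its size
  sp <- apply_scenario(t0, scenario_config("random_split", demes = "A",
                                           seed = 2))
  cz <- census(sp)
  expect_equal(sum(cz$n[cz$population %in% c("A_A", "A_B")]), 30L)
  expect_equal(cz$n[cz$population == "B"], 30L)
  # m = 0.1 swaps exactly round(m * n) labels each way
  big <- toy_hap(rep(c("A", "B"), each = 100), full_loci_mat(200),
                 loci = ystr_loci())
  big$haplogroup <- rep(c("F-M89", "H1-M52"), each = 100)
  big <- haplotype_table(tibble::as_tibble(big))
  mixed <- apply_scenario(big, scenario_config("symmetric_mixing",
                                               demes = c("A", "B"), m = 0.1,
                                               seed = 3))
  swapped_to_b <- sum(mixed$population == "B" & mixed$haplogroup == "F-M89")
  swapped_to_a <- sum(mixed$population == "A" & mixed$haplogroup == "H1-M52")
  expect_equal(swapped_to_b, 10L)
  expect_equal(swapped_to_a, 10L)
  # in-migration conserves per-deme counts
  tr3 <- population_tree("((A:8000,B:8000):12000,C:20000);", Ne = 1000)
  t3 <- simulate_haplotypes(tr3, sim_config(samples_per_deme = 20, seed = 4))
  mig <- apply_scenario(t3, scenario_config("in_migration",
                                            demes = c("A", "B"), m = 0.25,
                                            source = "C", seed = 5))
  expect_equal(census(mig), census(t3))
  # warnings / errors on invalid configuration
  expect_warning(scenario_config("symmetric_mixing", demes = c("A", "B"),
                                 m = 0.6), "majority")
  expect_error(scenario_config("in_migration", demes = "A", m = 0.2),
               "source", class = "ystrata_domain_error")
  expect_error(apply_scenario(t0, scenario_config("random_split",
                                                  demes = "nope")),
               class = "ystrata_domain_error")
})
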
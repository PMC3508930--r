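# Reduced-median network construction and segregation scoring.

test_that("degenerate networks: identical haplotypes collapse to one node", {
  H <- full_loci_mat(5)
  t0 <- toy_hap(rep("a", 5), H, loci = ystr_loci())
  net <- build_rm_network(t0)
  expect_equal(nrow(net$nodes), 1L)
  expect_equal(igraph::ecount(net$graph), 0)
  expect_equal(net$nodes$multiplicity, 5L)
})

test_that("a perfect star recovers the unobserved median node", {
  H <- full_loci_mat(3)
  H[1, 1] <- 15L; H[2, 2] <- 15L; H[3, 3] <- 15L  # each one step from center
  net <- build_rm_network(H, weights = rep(1, 17))
  expect_equal(sum(net$nodes$inferred), 1L)
  center <- net$haplotypes[net$nodes$inferred, ]
  expect_equal(unname(center), rep(14, 17))   # coordinatewise majority
  expect_equal(igraph::ecount(net$graph), 3)
  expect_true(all(igraph::E(net$graph)$steps == 1))
  expect_true(igraph::is_connected(net$graph))
})

test_that("a pure chain yields the path graph of length 2", {
  H <- full_loci_mat(3)
  H[2, 1] <- 15L; H[3, 1] <- 16L
  net <- build_rm_network(H)
  expect_equal(nrow(net$nodes), 3L)
  expect_equal(sum(net$nodes$inferred), 0L)
  expect_equal(igraph::ecount(net$graph), 2)
  expect_equal(net$total_steps, 2)
  degs <- igraph::degree(net$graph)
  expect_equal(sort(unname(degs)), c(1, 1, 2))
})

test_that("networks are connected, contain the observations, and are no longer than an MST", {
  set.seed(12)
  for (rep in 1:4) {
    n <- 12
    H <- full_loci_mat(n)
    for (l in sample(1:17, 4)) H[, l] <- H[, l] + sample(0:3, n, replace = TRUE)
    t0 <- toy_hap(sample(c("a", "b"), n, TRUE), H, loci = ystr_loci())
    net <- build_rm_network(t0)
    expect_true(igraph::is_connected(net$graph))
    obs_keys <- unique(apply(H, 1, paste, collapse = "-"))
    expect_true(all(obs_keys %in% net$nodes$label))
    w <- net$weights
    # weighted network length <= weighted MST length of the observed set
    Hobs <- unique(H)
    wlen <- sum(vapply(seq_len(igraph::ecount(net$graph)), function(e) {
      ends <- igraph::ends(net$graph, e)
      a <- net$haplotypes[as.integer(ends[1]), ]
      b <- net$haplotypes[as.integer(ends[2]), ]
      sum(w * abs(a - b))
    }, numeric(1)))
    expect_lte(wlen, oracle_mst_total(Hobs, w) + 1e-9)
    # inferred nodes earn their place: each lies on a weighted geodesic
    # between observed haplotypes (degree >= 2 once retained)
    if (any(net$nodes$inferred)) {
      degs <- igraph::degree(net$graph)
      expect_true(all(degs[net$nodes$inferred] >= 2))
    }
  }
})

test_that("the network is invariant to input record order", {
  set.seed(21)
  H <- full_loci_mat(10)
  H[, 3] <- H[, 3] + sample(0:2, 10, replace = TRUE)
  H[, 9] <- H[, 9] + sample(0:2, 10, replace = TRUE)
  t1 <- toy_hap(rep(c("a", "b"), 5), H, loci = ystr_loci())
  perm <- sample(10)
  t2 <- haplotype_table(tibble::as_tibble(t1)[perm, ])
  n1 <- build_rm_network(t1)
  n2 <- build_rm_network(t2)
  expect_equal(n1$nodes$label, n2$nodes$label)
  expect_equal(tidy(n1), tidy(n2))
})

test_that("mixed-haplogroup input and wide loci are rejected", {
  H <- full_loci_mat(4)
  t0 <- toy_hap(rep("a", 4), H, hg = c("F-M89", "F-M89", "H1-M52", "F-M89"),
                loci = ystr_loci())
  expect_error(build_rm_network(t0), class = "ystrata_domain_error")
  H2 <- full_loci_mat(40)
  H2[, 1] <- 5L + (seq_len(40) %% 34)
  expect_error(build_rm_network(H2), class = "ystrata_domain_error")
})

test_that("segregation score separates sorted from shuffled labels", {
  # label-sorted chain: a-a-a-b-b-b along one locus
  H <- full_loci_mat(6)
  H[, 1] <- c(12L, 13L, 14L, 17L, 18L, 19L)
  t0 <- toy_hap(rep(c("a", "b"), each = 3), H, loci = ystr_loci())
  net <- build_rm_network(t0)
  s <- segregation_score(net, n_perm = 499, seed = 2)
  # 4 of the 5 path edges are monochromatic (one boundary edge)
  expect_equal(s$score, 0.8)
  expect_lte(s$p, 0.2)  # only 2 of the 20 label arrangements score this high
  # two-node network: score in {0,1}, p = 1 under enumeration
  H2 <- full_loci_mat(2)
  H2[2, 1] <- 15L
  t2 <- toy_hap(c("a", "b"), H2, loci = ystr_loci())
  s2 <- segregation_score(build_rm_network(t2), n_perm = 99, seed = 1)
  expect_true(s2$score %in% c(0, 1))
  expect_equal(s2$p, 1)
  # calibration: under random labels the permutation p is valid, i.e.
  # super-uniform (ties make it discrete and conservative)
  set.seed(31)
  pv <- replicate(80, {
    Hr <- full_loci_mat(10)
    Hr[, 1] <- 10L + sample(0:5, 10, replace = TRUE)
    tr <- toy_hap(sample(c("a", "b"), 10, TRUE), Hr, loci = ystr_loci())
    segregation_score(build_rm_network(tr), n_perm = 49)$p
  })
  pv <- pv[!is.na(pv)]
  for (alpha in c(0.05, 0.1, 0.25)) {
    slack <- 2 * sqrt(alpha * (1 - alpha) / length(pv))
    expect_lte(mean(pv <= alpha), alpha + slack)
  }
})

test_that("GraphML export writes a readable document", {
  H <- full_loci_mat(3)
  H[2, 1] <- 15L; H[3, 2] <- 15L
  t0 <- toy_hap(c("a", "a", "b"), H, loci = ystr_loci())
  net <- build_rm_network(t0)
  path <- withr::local_tempfile(fileext = ".graphml")
  export_graphml(net, path)
  g2 <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g2), nrow(net$nodes))
  expect_equal(igraph::ecount(g2), igraph::ecount(net$graph))
})
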
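# Shared fixtures and independent oracles for the test suite.

# small haplotype table from explicit pieces
toy_hap <- function(pop, alleles, hg = NULL, loci = NULL) {
  alleles <- as.matrix(alleles)
  if (is.null(loci)) loci <- sprintf("STR%02d", seq_len(ncol(alleles)))
  colnames(alleles) <- loci
  if (is.null(hg)) hg <- rep("F-M89", length(pop))
  haplotype_table(
    tibble::tibble(sample_id = sprintf("s%03d", seq_along(pop)),
                   population = pop, haplogroup = hg) |>
      dplyr::bind_cols(tibble::as_tibble(alleles)),
    loci = loci)
}

# a 17-locus allele matrix centered at 14 with the given per-row offsets at
# locus 1 (handy for monomorphic-like toys)
full_loci_mat <- function(n, base = 14L) {
  matrix(base, n, 17, dimnames = list(NULL, ystr_loci()))
}

# ---- brute-force AMOVA oracle -----------------------------------------------
# Direct nested sums of squared distances over an explicit distance matrix.
oracle_amova <- function(d2, pop, grp) {
  N <- length(pop)
  ssd_pairs <- function(idx) {
    s <- 0
    if (length(idx) < 2) return(0)
    for (i in seq_along(idx)) for (j in seq_along(idx)) {
      if (i < j) s <- s + d2[idx[i], idx[j]]
    }
    s
  }
  pops <- unique(pop)
  gl <- unique(grp[match(pops, pop)])
  grp_of_pop <- grp[match(pops, pop)]
  SSD_T <- ssd_pairs(seq_len(N)) / N
  SSD_WP <- sum(sapply(pops, function(p) {
    idx <- which(pop == p); ssd_pairs(idx) / length(idx)
  }))
  SSD_WG <- sum(sapply(gl, function(g) {
    idx <- which(grp == g); ssd_pairs(idx) / length(idx)
  }))
  P <- length(pops); G <- length(gl)
  n_p <- sapply(pops, function(p) sum(pop == p))
  n_g <- sapply(gl, function(g) sum(grp == g))
  MS_AG <- (SSD_T - SSD_WG) / (G - 1)
  MS_AP <- (SSD_WG - SSD_WP) / (P - G)
  MS_WP <- SSD_WP / (N - P)
  s1 <- sum(sapply(gl, function(g) {
    sel <- grp_of_pop == g
    sum(n_p[sel]^2) / sum(n_p[sel])
  }))
  n1 <- (N - s1) / (P - G)
  n2 <- (s1 - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  Vc <- MS_WP
  Vb <- (MS_AP - Vc) / n1
  Va <- (MS_AG - Vc - n2 * Vb) / n3
  list(Va = Va, Vb = Vb, Vc = Vc,
       FCT = Va / (Va + Vb + Vc), FSC = Vb / (Vb + Vc),
       FST = (Va + Vb) / (Va + Vb + Vc))
}

# squared-distance matrices for the two metrics
d2_haplogroup <- function(hg) outer(hg, hg, FUN = function(a, b) (a != b) * 1)
d2_str <- function(alle) {
  n <- nrow(alle)
  D <- matrix(0, n, n)
  for (l in seq_len(ncol(alle)))
    D <- D + outer(alle[, l], alle[, l], "-")^2
  D
}

# ---- Fisher exact enumeration oracle ---------------------------------------
# All 2x2 tables with the margins of [[a,b],[c,d]]; two-sided p sums the
# probabilities of tables no more probable than the observed one.
oracle_fisher <- function(a, b, c, d, alternative = "two.sided") {
  m <- a + c; n <- b + d; k <- a + b
  lo <- max(0, k - n); hi <- min(k, m)
  probs <- sapply(lo:hi, function(x) dhyper(x, m, n, k))
  names(probs) <- lo:hi
  p_obs <- dhyper(a, m, n, k)
  if (alternative == "two.sided") {
    sum(probs[probs <= p_obs * (1 + 1e-7)])
  } else if (alternative == "greater") {
    sum(probs[as.integer(names(probs)) >= a])
  } else {
    sum(probs[as.integer(names(probs)) <= a])
  }
}

# ---- SMM likelihood oracle --------------------------------------------------
# Displacement kernel from explicit Poisson mutation-path enumeration:
# P(d | theta) = sum_k Pois(k; theta) P(net displacement d | k +-1 steps).
oracle_smm_kernel <- function(d, theta, kmax_paths = 80) {
  if (theta == 0) return(as.numeric(d == 0))
  s <- 0
  for (k in 0:kmax_paths) {
    if ((k + d) %% 2 != 0 || abs(d) > k) next
    s <- s + dpois(k, theta) * choose(k, (k + d) / 2) / 2^k
  }
  s
}

# Brute-force pruning on an explicit genealogy (0-based arrays as the C++
# side uses), summing over all internal lattice states.
oracle_smm_loglik <- function(alleles, parent, ch1, ch2, times, mu, pad = 8) {
  n <- nrow(alleles); L <- ncol(alleles); nn <- 2 * n - 1
  root <- which(parent == -1L) - 1L
  ll <- 0
  for (l in seq_len(L)) {
    lo <- min(alleles[, l]) - pad
    hi <- max(alleles[, l]) + pad
    states <- lo:hi
    S <- length(states)
    cond <- matrix(0, nn, S)
    for (i in seq_len(n)) cond[i, match(alleles[i, l], states)] <- 1
    ord <- order(times)
    for (v in ord) {
      if (v <= n) next
      kids <- c(ch1[v], ch2[v]) + 1L
      for (si in seq_len(S)) {
        val <- 1
        for (u in kids) {
          theta <- mu * (times[v] - times[u])
          acc <- 0
          for (sj in seq_len(S)) {
            dd <- abs(states[sj] - states[si])
            if (dd <= 15) acc <- acc + oracle_smm_kernel(dd, theta) * cond[u, sj]
          }
          val <- val * acc
        }
        cond[v, si] <- val
      }
    }
    ll <- ll + log(mean(cond[root + 1L, ]))
  }
  ll
}

# minimum spanning tree total length over unweighted step distances
oracle_mst_total <- function(H, w = rep(1, ncol(H))) {
  n <- nrow(H)
  if (n <= 1) return(0)
  D <- matrix(0, n, n)
  for (l in seq_len(ncol(H))) D <- D + w[l] * abs(outer(H[, l], H[, l], "-"))
  intree <- 1L; total <- 0
  dmin <- D[1, ]; dmin[1] <- Inf
  for (i in seq_len(n - 1)) {
    j <- which.min(dmin)
    total <- total + dmin[j]
    intree <- c(intree, j)
    dmin <- pmin(dmin, D[j, ]); dmin[intree] <- Inf
  }
  total
}
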
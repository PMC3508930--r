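# Hierarchical analysis of molecular variance (AMOVA), R_ST distances,
# permutation tests and the multinomial bootstrap for comparing groupings.
#
# Variance components follow the standard weighted unequal-sample-size scheme:
# with P populations in G groups, n_p individuals in population p, N total,
#   SSD(T)  = (1/N)   sum_{i<j}      d2_ij
#   SSD(WP) = sum_p (1/n_p) sum_{i<j in p} d2_ij
#   SSD(WG) = sum_g (1/n_g) sum_{i<j in g} d2_ij
#   MS(AG) = [SSD(T) - SSD(WG)] / (G-1)
#   MS(AP) = [SSD(WG) - SSD(WP)] / (P-G)
#   MS(WP) = SSD(WP) / (N-P)
#   n'   = (N - sum_g sum_{p in g} n_p^2 / n_g) / (P-G)
#   n''  = (sum_g sum_{p in g} n_p^2 / n_g - sum_p n_p^2 / N) / (G-1)
#   n''' = (N - sum_g n_g^2 / N) / (G-1)
#   Vc = MS(WP);  Vb = (MS(AP) - Vc)/n';  Va = (MS(AG) - Vc - n'' Vb)/n'''
# and the fixation indices are the defining ratios F_CT = Va/V, F_SC = Vb/(Vb+Vc),
# F_ST = (Va+Vb)/V with V = Va+Vb+Vc.

# ---- sufficient statistics backends -----------------------------------------
# A backend holds, per individual, whatever is needed to compute
# sum_{i<j in S} d2_ij for an arbitrary subset S from additive per-subset
# sufficient statistics.

.be_hg <- function(cls, K) {
  list(type = "hg", cls = as.integer(cls), K = as.integer(K))
}
.be_str <- function(alle) {
  list(type = "str", alle = as.matrix(alle))
}

# per-subset sufficient statistic
.be_stat <- function(be, idx) {
  if (be$type == "hg") {
    tabulate(be$cls[idx], nbins = be$K)
  } else {
    a <- be$alle[idx, , drop = FALSE]
    rbind(n = nrow(a), s1 = colSums(a), s2 = colSums(a^2))
  }
}
.be_combine <- function(be, a, b) a + b
# sum over unordered pairs of squared inter-individual distance
.be_ssd <- function(be, stat) {
  if (be$type == "hg") {
    n <- sum(stat)
    n * (n - 1) / 2 - sum(stat * (stat - 1) / 2)
  } else {
    n <- stat["n", 1]
    sum(n * stat["s2", ] - stat["s1", ]^2)
  }
}
.be_n <- function(be, stat) if (be$type == "hg") sum(stat) else stat["n", 1]

# Three-level variance components from per-population sufficient statistics.
.amova_components <- function(be, pop_stats, pop_groups) {
  P <- length(pop_stats)
  n_p <- vapply(pop_stats, function(s) .be_n(be, s), numeric(1))
  N <- sum(n_p)
  gl <- unique(pop_groups)
  G <- length(gl)
  tot <- Reduce(function(a, b) .be_combine(be, a, b), pop_stats)
  SSD_T <- .be_ssd(be, tot) / N
  SSD_WP <- sum(vapply(seq_len(P),
                       function(i) .be_ssd(be, pop_stats[[i]]) / n_p[i],
                       numeric(1)))
  if (G == 1) {
    # two-level design: populations within the total
    MS_AP <- (SSD_T - SSD_WP) / (P - 1)
    MS_WP <- SSD_WP / (N - P)
    n_c <- (N - sum(n_p^2) / N) / (P - 1)
    Vc <- MS_WP
    Vb <- (MS_AP - Vc) / n_c
    return(list(Va = NA_real_, Vb = Vb, Vc = Vc, n_p = n_p, N = N, P = P,
                G = G, FST = Vb / (Vb + Vc)))
  }
  n_g <- vapply(gl, function(g) sum(n_p[pop_groups == g]), numeric(1))
  SSD_WG <- sum(vapply(gl, function(g) {
    sel <- which(pop_groups == g)
    st <- Reduce(function(a, b) .be_combine(be, a, b), pop_stats[sel])
    .be_ssd(be, st) / sum(n_p[sel])
  }, numeric(1)))
  MS_AG <- (SSD_T - SSD_WG) / (G - 1)
  MS_AP <- (SSD_WG - SSD_WP) / (P - G)
  MS_WP <- SSD_WP / (N - P)
  sum_np2_over_ng <- sum(vapply(gl, function(g) {
    sel <- pop_groups == g
    sum(n_p[sel]^2) / sum(n_p[sel])
  }, numeric(1)))
  n1 <- (N - sum_np2_over_ng) / (P - G)
  n2 <- (sum_np2_over_ng - sum(n_p^2) / N) / (G - 1)
  n3 <- (N - sum(n_g^2) / N) / (G - 1)
  Vc <- MS_WP
  Vb <- (MS_AP - Vc) / n1
  Va <- (MS_AG - Vc - n2 * Vb) / n3
  V <- Va + Vb + Vc
  list(Va = Va, Vb = Vb, Vc = Vc, n_p = n_p, N = N, P = P, G = G,
       FCT = Va / V, FSC = Vb / (Vb + Vc), FST = (Va + Vb) / V)
}

# Build a backend + individual population labels from supported inputs.
.amova_data <- function(x, metric) {
  if (inherits(x, "hg_counts")) {
    ind <- expand_counts(x)
    cls <- match(ind$haplogroup, hg_cols(x))
    list(be = .be_hg(cls, length(hg_cols(x))), pop = ind$population)
  } else if (inherits(x, "hap_tbl")) {
    if (metric == "haplogroup") {
      lev <- sort(unique(x$haplogroup))
      list(be = .be_hg(match(x$haplogroup, lev), length(lev)),
           pop = x$population)
    } else {
      x <- drop_incomplete(x)
      list(be = .be_str(as.matrix(x[, loci_of(x)])), pop = x$population)
    }
  } else {
    abort("amova() needs an 'hg_counts' or 'hap_tbl' input",
          class = "ystrata_format_error")
  }
}

#' Hierarchical AMOVA
#'
#' Partitions squared inter-individual distances into among-group,
#' among-population-within-group and within-population variance components
#' (Excoffier-style weighted coefficients for unequal sample sizes) and reports
#' the fixation indices F_CT, F_SC, F_ST. Two distance metrics are supported:
#' `"haplogroup"` scores 0 for identical haplogroups and 1 otherwise (the SNP
#' mode of the published tables); `"str"` uses squared repeat-count differences
#' summed over the 17 loci (the R_ST convention under stepwise mutation).
#'
#' With `n_perm > 0`, permutation p-values are computed under the standard
#' nulls: whole populations permuted among groups (F_CT), individuals permuted
#' among populations within groups (F_SC), and individuals permuted among all
#' populations (F_ST), with \eqn{p = (\#\{null \ge obs\} + 1)/(n_{perm}+1)}.
#' When the distinct population-to-group reassignments number fewer than
#' `n_perm`, the F_CT null is enumerated exhaustively instead.
#'
#' @param x An `hg_counts` or `hap_tbl` object.
#' @param g A `grouping`, or `NULL` for the two-level design (F_ST only).
#' @param metric `"haplogroup"` or `"str"`.
#' @param n_perm Number of permutations (0 = no test).
#' @param seed Optional integer seed for the permutation test.
#' @param clamp_negative Truncate negative variance components at 0 before
#'   forming ratios (off by default; common AMOVA practice retains them).
#' @return An object of class `amova`: see [tidy.amova()] and
#'   [glance.amova()].
#' @export
amova <- function(x, g = NULL, metric = c("haplogroup", "str"), n_perm = 0,
                  seed = NULL, clamp_negative = FALSE) {
  metric <- match.arg(metric)
  d <- .amova_data(x, metric)
  pops <- unique(d$pop)
  idx <- split(seq_along(d$pop), factor(d$pop, levels = pops))
  pop_stats <- lapply(idx, function(i) .be_stat(d$be, i))
  pop_groups <- if (is.null(g)) rep("all", length(pops)) else group_of(g, pops)
  comp <- .amova_components(d$be, pop_stats, pop_groups)
  if (clamp_negative) {
    for (f in c("Va", "Vb", "Vc")) comp[[f]] <- max(comp[[f]], 0, na.rm = FALSE)
    V <- comp$Va + comp$Vb + comp$Vc
    if (comp$G > 1) {
      comp$FCT <- comp$Va / V
      comp$FSC <- comp$Vb / (comp$Vb + comp$Vc)
      comp$FST <- (comp$Va + comp$Vb) / V
    } else comp$FST <- comp$Vb / (comp$Vb + comp$Vc)
  }
  res <- structure(list(components = comp, metric = metric,
                        grouping = attr(g, "name") %||% "none",
                        n_pops = length(pops), n_groups = comp$G,
                        p_values = NULL,
                        fingerprint = .data_fingerprint(x)),
                   class = "amova")
  if (n_perm > 0) {
    res$p_values <- .amova_perm(d, pop_stats, pops, pop_groups, comp, n_perm,
                                seed)
  }
  res
}

.data_fingerprint <- function(x) {
  if (inherits(x, "hg_counts")) {
    paste0("hg_counts:", nrow(x), "x", length(hg_cols(x)), ":", sum(x$N), ":",
           sum(as_count_mat(x) * seq_along(as_count_mat(x))) %% 1e9)
  } else {
    loci <- intersect(ystr_loci(), names(x))
    paste0("hap_tbl:", nrow(x), ":", length(unique(x$population)))
  }
}

# Permutation p-values. Population-level null for F_CT; individual-level
# nulls for F_SC and F_ST.
.amova_perm <- function(d, pop_stats, pops, pop_groups, comp, n_perm, seed) {
  if (!is.null(seed)) set.seed(seed)
  be <- d$be
  P <- length(pops)
  one_group <- length(unique(pop_groups)) == 1
  pop_f <- factor(d$pop, levels = pops)
  pop_i <- as.integer(pop_f)

  recompute <- function(groups_perm = pop_groups, pop_perm = pop_i) {
    if (identical(pop_perm, pop_i)) {
      st <- pop_stats
    } else {
      st <- lapply(split(seq_along(pop_perm), factor(pop_perm, levels = 1:P)),
                   function(i) .be_stat(be, i))
    }
    .amova_components(be, st, groups_perm)
  }

  out <- list()
  if (!one_group) {
    # F_CT: permute whole populations among groups; enumerate if feasible
    n_distinct <- .n_multiset_perms(pop_groups)
    if (n_distinct <= n_perm) {
      perms <- .all_multiset_perms(pop_groups)
      null_fct <- vapply(perms, function(gp) recompute(groups_perm = gp)$FCT,
                         numeric(1))
      out$FCT <- tibble::tibble(
        statistic = "FCT", observed = comp$FCT,
        p = mean(null_fct >= comp$FCT - 1e-12), method = "exact enumeration",
        n_null = length(null_fct))
    } else {
      null_fct <- vapply(seq_len(n_perm), function(b)
        recompute(groups_perm = sample(pop_groups))$FCT, numeric(1))
      out$FCT <- tibble::tibble(
        statistic = "FCT", observed = comp$FCT,
        p = (sum(null_fct >= comp$FCT - 1e-12) + 1) / (n_perm + 1),
        method = "permutation", n_null = n_perm)
    }
    # F_SC: permute individuals among populations within groups
    g_of_ind <- pop_groups[pop_i]
    null_fsc <- vapply(seq_len(n_perm), function(b) {
      pp <- pop_i
      for (gg in unique(pop_groups)) {
        sel <- which(g_of_ind == gg)
        pp[sel] <- pp[sample(sel)]
      }
      recompute(pop_perm = pp)$FSC
    }, numeric(1))
    out$FSC <- tibble::tibble(
      statistic = "FSC", observed = comp$FSC,
      p = (sum(null_fsc >= comp$FSC - 1e-12) + 1) / (n_perm + 1),
      method = "permutation", n_null = n_perm)
  }
  null_fst <- vapply(seq_len(n_perm), function(b)
    recompute(pop_perm = pop_i[sample.int(length(pop_i))])$FST, numeric(1))
  out$FST <- tibble::tibble(
    statistic = "FST", observed = comp$FST,
    p = (sum(null_fst >= comp$FST - 1e-12) + 1) / (n_perm + 1),
    method = "permutation", n_null = n_perm)
  dplyr::bind_rows(out)
}

.n_multiset_perms <- function(x) {
  tab <- table(x)
  exp(lgamma(length(x) + 1) - sum(lgamma(tab + 1)))
}

.all_multiset_perms <- function(x) {
  rec <- function(items) {
    if (length(items) <= 1) return(list(items))
    out <- list()
    for (u in unique(items)) {
      i <- match(u, items)
      for (tail in rec(items[-i])) out[[length(out) + 1]] <- c(u, tail)
    }
    out
  }
  rec(x)
}

#' @describeIn amova Tidy the fixation indices of an `amova` fit.
#' @param x,object An `amova` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.amova <- function(x, ...) {
  comp <- x$components
  est <- tibble::tibble(
    statistic = c("FCT", "FSC", "FST"),
    estimate = c(comp$FCT %||% NA_real_, comp$FSC %||% NA_real_, comp$FST))
  if (!is.null(x$p_values)) {
    est <- dplyr::left_join(est,
      dplyr::select(x$p_values, "statistic", "p"), by = "statistic")
  }
  est
}

#' @describeIn amova One-row summary of an `amova` fit.
#' @exportS3Method generics::glance
glance.amova <- function(x, ...) {
  comp <- x$components
  tibble::tibble(
    metric = x$metric, grouping = x$grouping, n_groups = comp$G,
    n_populations = comp$P, n = comp$N,
    Va = comp$Va, Vb = comp$Vb, Vc = comp$Vc,
    FCT = comp$FCT %||% NA_real_, FSC = comp$FSC %||% NA_real_,
    FST = comp$FST)
}

#' @export
print.amova <- function(x, ...) {
  comp <- x$components
  cat(sprintf("AMOVA (%s distance), grouping '%s': %d groups / %d populations / %d individuals\n",
              x$metric, x$grouping, comp$G, comp$P, comp$N))
  print(glance.amova(x)[, c("Va", "Vb", "Vc", "FCT", "FSC", "FST")])
  if (!is.null(x$p_values)) print(x$p_values)
  invisible(x)
}

# ---- R_ST -------------------------------------------------------------------

#' Pairwise R_ST distance matrix
#'
#' Slatkin's microsatellite analogue of F_ST: for each population pair, a
#' two-level AMOVA on squared repeat-count differences summed over loci gives
#' \eqn{R_{ST} = \sigma^2_a / (\sigma^2_a + \sigma^2_w)}. Negative estimates
#' are reported as computed unless `clamp = TRUE`.
#'
#' @param t A `hap_tbl` with at least two populations, each of size >= 2.
#' @param clamp Truncate negative estimates at 0.
#' @return A symmetric matrix of class `dist_matrix` with attribute
#'   `metric = "rst"`.
#' @export
rst_distance <- function(t, clamp = FALSE) {
  t <- drop_incomplete(t)
  pops <- unique(t$population)
  if (length(pops) < 2) {
    abort("need at least two populations", class = "ystrata_domain_error")
  }
  sizes <- table(t$population)
  if (any(sizes < 2)) {
    abort(sprintf("population(s) of size < 2: %s",
                  paste(names(sizes)[sizes < 2], collapse = ", ")),
          class = "ystrata_domain_error")
  }
  be <- .be_str(as.matrix(t[, loci_of(t)]))
  idx <- split(seq_len(nrow(t)), factor(t$population, levels = pops))
  stats <- lapply(idx, function(i) .be_stat(be, i))
  P <- length(pops)
  D <- matrix(0, P, P, dimnames = list(pops, pops))
  for (i in seq_len(P - 1)) {
    for (j in (i + 1):P) {
      comp <- .amova_components(be, stats[c(i, j)], c("all", "all"))
      r <- comp$FST
      if (clamp) r <- max(r, 0)
      D[i, j] <- D[j, i] <- r
    }
  }
  structure(D, metric = "rst", class = c("dist_matrix", "matrix", "array"))
}

# ---- bootstrap for comparing groupings --------------------------------------

#' Bootstrap confidence interval for F_CT
#'
#' The multinomial bootstrap used to compare alternative population groupings:
#' each replicate resamples individuals with replacement within each population
#' (a multinomial draw over its haplotypes with the population size preserved),
#' recomputes the among-group fixation index F_CT, and the median and 2.5/97.5
#' percentiles over `B` replicates are reported. Pooled resampling across
#' populations is available with `unit = "pooled"`.
#'
#' @param x An `hg_counts` or `hap_tbl` object with at least two populations.
#' @param g A `grouping`.
#' @param B Number of replicates (default 500).
#' @param seed Optional integer seed.
#' @param metric Distance metric, as in [amova()].
#' @param unit `"within"` (resample within populations, the default) or
#'   `"pooled"` (resample individuals across populations).
#' @return An object of class `bootstrap_ci` with fields `statistic`, `median`,
#'   `lower`, `upper`, `B`, `n_degenerate`, `point`, `fingerprint`.
#' @export
bootstrap_fct <- function(x, g, B = 500, seed = NULL,
                          metric = c("haplogroup", "str"),
                          unit = c("within", "pooled")) {
  metric <- match.arg(metric)
  unit <- match.arg(unit)
  stopifnot(B >= 100)
  if (!is.null(seed)) set.seed(seed)
  d <- .amova_data(x, metric)
  pops <- unique(d$pop)
  if (length(pops) < 2) {
    abort("bootstrap needs at least two populations",
          class = "ystrata_domain_error")
  }
  pop_i <- as.integer(factor(d$pop, levels = pops))
  pop_groups <- group_of(g, pops)
  idx <- split(seq_along(pop_i), pop_i)
  point <- .amova_components(
    d$be, lapply(idx, function(i) .be_stat(d$be, i)), pop_groups)$FCT
  vals <- numeric(0)
  n_degen <- 0L
  for (b in seq_len(B)) {
    res_idx <- if (unit == "within") {
      lapply(idx, function(i) sample(i, length(i), replace = TRUE))
    } else {
      pool <- sample(seq_along(pop_i), length(pop_i), replace = TRUE)
      split(pool, pop_i)
    }
    st <- lapply(res_idx, function(i) .be_stat(d$be, i))
    comp <- .amova_components(d$be, st, pop_groups)
    v <- comp$Va + comp$Vb + comp$Vc
    if (!is.finite(comp$FCT) || v <= 0) {
      n_degen <- n_degen + 1L
    } else {
      vals <- c(vals, comp$FCT)
    }
  }
  structure(list(statistic = "FCT", grouping = attr(g, "name") %||% "grouping",
                 median = stats::median(vals),
                 lower = unname(stats::quantile(vals, 0.025)),
                 upper = unname(stats::quantile(vals, 0.975)),
                 B = B, n_degenerate = n_degen, point = point,
                 fingerprint = .data_fingerprint(x)),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%s bootstrap (%s): point %.4f, median %.4f, 95%% CI [%.4f, %.4f], B = %d (%d degenerate)\n",
              x$statistic, x$grouping, x$point, x$median, x$lower, x$upper,
              x$B, x$n_degenerate))
  invisible(x)
}

#' Compare two bootstrap confidence intervals
#'
#' Orders two groupings by their bootstrap F_CT intervals computed on the same
#' data: `"a>b"` when `a`'s lower bound exceeds `b`'s upper bound, `"b>a"`
#' symmetrically, `"overlap"` otherwise (touching bounds count as overlap).
#'
#' @param a,b `bootstrap_ci` objects from [bootstrap_fct()] on the same data
#'   and statistic.
#' @return `"a>b"`, `"b>a"` or `"overlap"`.
#' @export
compare_groupings <- function(a, b) {
  stopifnot(inherits(a, "bootstrap_ci"), inherits(b, "bootstrap_ci"))
  if (!identical(a$fingerprint, b$fingerprint) ||
      !identical(a$statistic, b$statistic)) {
    abort("intervals were not computed on the same data and statistic",
          class = "ystrata_domain_error")
  }
  if (a$lower > b$upper) "a>b" else if (b$lower > a$upper) "b>a" else "overlap"
}
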
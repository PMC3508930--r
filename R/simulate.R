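# Synthetic Y-STR / haplogroup data: structured coalescent over a dated
# population-split tree with single-step stepwise mutation (SMM) at each locus.

#' Construct a dated population-split tree
#'
#' A rooted binary topology over deme labels with split times in years,
#' per-deme (haploid male) effective sizes and a generation length. The tree
#' is both the simulator input and the object the split-time sampler
#' estimates.
#'
#' @param newick Newick string (or an `ape::phylo` object) with branch lengths
#'   in years; must be ultrametric (all tips at the present).
#' @param Ne Effective size: a single number applied to every branch, or a
#'   named vector over demes (ancestral branches then use the mean).
#' @param growth Per-deme exponential growth rate per generation (default 0 =
#'   constant size; the simulator currently supports 0).
#' @param gen_years Generation length in years (default 25).
#' @return An object of class `pop_tree`: `demes`, `merges` (tibble `left`,
#'   `right`, `time_gen`, ordered oldest last), `Ne`, `growth`, `gen_years`.
#' @export
population_tree <- function(newick, Ne = 2000, growth = 0, gen_years = 25) {
  stopifnot(all(Ne > 0), gen_years > 0)
  if (is.character(newick) && !grepl("(", newick, fixed = TRUE)) {
    # a bare deme label: single panmictic population
    deme <- sub(";\\s*$", "", trimws(newick))
    if (is.null(names(Ne))) Ne <- setNames(Ne[1], deme)
    return(structure(list(
      demes = deme,
      merges = tibble::tibble(left = character(), right = character(),
                              time_gen = numeric()),
      Ne = Ne, growth = growth, gen_years = gen_years), class = "pop_tree"))
  }
  if (is.character(newick)) {
    if (!requireNamespace("ape", quietly = TRUE)) {
      abort("reading Newick strings requires the 'ape' package")
    }
    phy <- ape::read.tree(text = newick)
  } else phy <- newick
  if (is.null(phy) || !inherits(phy, "phylo")) {
    abort("could not parse the population tree", class = "ystrata_format_error")
  }
  demes <- phy$tip.label
  if (anyDuplicated(demes)) abort("deme labels must be unique",
                                  class = "ystrata_format_error")
  n <- length(demes)
  if (n == 1) {
    merges <- tibble::tibble(left = character(), right = character(),
                             time_gen = numeric())
  } else {
    # node depths (years above the present) assuming ultrametric tips
    nn <- n + phy$Nnode
    depth <- numeric(nn)
    # distance from root, then convert to height above tips
    dist_root <- numeric(nn)
    root <- n + 1L
    for (e in order(phy$edge[, 1])) {
      dist_root[phy$edge[e, 2]] <- dist_root[phy$edge[e, 1]] +
        phy$edge.length[e]
    }
    total <- max(dist_root[seq_len(n)])
    if (max(abs(dist_root[seq_len(n)] - total)) > 1e-6 * max(total, 1)) {
      abort("population tree must be ultrametric (tips at the present)",
            class = "ystrata_format_error")
    }
    height <- total - dist_root
    # clade membership per internal node
    clade <- vector("list", nn)
    for (i in seq_len(n)) clade[[i]] <- demes[i]
    for (e in order(dist_root[phy$edge[, 1]], decreasing = TRUE)) {
      p <- phy$edge[e, 1]; ch <- phy$edge[e, 2]
      clade[[p]] <- c(clade[[p]], clade[[ch]])
    }
    internal <- (n + 1L):nn
    internal <- internal[order(height[internal])]
    merges <- dplyr::bind_rows(lapply(internal, function(v) {
      ch <- phy$edge[phy$edge[, 1] == v, 2]
      tibble::tibble(left = paste(sort(clade[[ch[1]]]), collapse = "+"),
                     right = paste(sort(clade[[ch[2]]]), collapse = "+"),
                     time_gen = height[v] / gen_years)
    }))
    if (any(diff(merges$time_gen) < 0)) {
      abort("child split times must precede parent split times",
            class = "ystrata_format_error")
    }
  }
  if (is.null(names(Ne))) Ne <- setNames(rep(Ne[1], n), demes)
  structure(list(demes = demes, merges = merges, Ne = Ne, growth = growth,
                 gen_years = gen_years), class = "pop_tree")
}

#' @export
print.pop_tree <- function(x, ...) {
  cat(sprintf("Population tree: %d deme(s) [%s], %d split(s), g = %g y\n",
              length(x$demes), paste(x$demes, collapse = ", "),
              nrow(x$merges), x$gen_years))
  if (nrow(x$merges) > 0) {
    m <- x$merges
    for (i in seq_len(nrow(m))) {
      cat(sprintf("  (%s, %s) at %.0f generations (%.0f y)\n", m$left[i],
                  m$right[i], m$time_gen[i], m$time_gen[i] * x$gen_years))
    }
  }
  invisible(x)
}

#' Serialize a population tree to Newick
#'
#' Branch lengths are in years; deme parameters (Ne, growth, generation
#' length) are not representable in Newick and travel separately.
#'
#' @param tree A `pop_tree`.
#' @return A Newick string.
#' @export
as_newick <- function(tree) {
  stopifnot(inherits(tree, "pop_tree"))
  if (nrow(tree$merges) == 0) return(paste0(tree$demes[1], ";"))
  frag <- as.list(setNames(tree$demes, tree$demes))
  height <- setNames(rep(0, length(tree$demes)), tree$demes)
  for (j in seq_len(nrow(tree$merges))) {
    l <- tree$merges$left[j]; r <- tree$merges$right[j]
    t_y <- tree$merges$time_gen[j] * tree$gen_years
    key <- paste(sort(unique(c(strsplit(l, "+", fixed = TRUE)[[1]],
                               strsplit(r, "+", fixed = TRUE)[[1]]))),
                 collapse = "+")
    frag[[key]] <- sprintf("(%s:%g,%s:%g)", frag[[l]], t_y - height[l],
                           frag[[r]], t_y - height[r])
    height[key] <- t_y
    frag[[l]] <- NULL; frag[[r]] <- NULL
  }
  paste0(frag[[1]], ";")
}

#' Simulation configuration
#'
#' @param samples_per_deme Integer (recycled) or named vector of sample sizes
#'   (>= 2 per deme).
#' @param n_loci Number of STR loci (default 17).
#' @param mu Per-locus mutation rate per generation; the default 6.9e-4 is the
#'   effective-rate convention of the dating calibration. Must lie in
#'   \[0, 0.1) (0 is allowed for degenerate checks).
#' @param founder_haplogroups Labels assigned to the ancestral lineages extant
#'   at the root split (inherited as perfectly linked markers, no recurrent
#'   mutation).
#' @param ancestral_allele Repeat count of the most recent common ancestor at
#'   every locus (default 15).
#' @param seed Optional integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(samples_per_deme = 50, n_loci = 17, mu = 6.9e-4,
                       founder_haplogroups = c("F-M89", "H1-M52", "R1a1-M17",
                                               "L1-M27"),
                       ancestral_allele = 15, seed = NULL) {
  if (mu < 0 || mu >= 0.1) abort("mu must lie in [0, 0.1)",
                                 class = "ystrata_domain_error")
  if (any(samples_per_deme < 2)) abort("need >= 2 samples per deme",
                                       class = "ystrata_domain_error")
  structure(list(samples_per_deme = samples_per_deme, n_loci = n_loci,
                 mu = mu, founder_haplogroups = founder_haplogroups,
                 ancestral_allele = ancestral_allele, seed = seed),
            class = "sim_config")
}

# Structured coalescent genealogy for a pop_tree.
# Returns parent/child arrays and node times in generations.
.sim_genealogy <- function(tree, n_per_deme) {
  demes <- tree$demes
  n <- sum(n_per_deme)
  n_nodes <- 2L * n - 1L
  parent <- integer(n_nodes)
  child1 <- integer(n_nodes); child2 <- integer(n_nodes)
  time <- numeric(n_nodes)
  tip_deme <- rep(seq_along(demes), n_per_deme)
  # active lineage sets per current population (keyed by sorted deme set)
  pops <- lapply(seq_along(demes), function(i) which(tip_deme == i))
  names(pops) <- demes
  Ne_of <- function(key) {
    ds <- strsplit(key, "+", fixed = TRUE)[[1]]
    mean(tree$Ne[ds])
  }
  merges <- tree$merges
  mi <- 1L
  t_now <- 0
  nxt <- n + 1L
  repeat {
    k <- vapply(pops, length, integer(1))
    if (sum(k) == 1) break
    rates <- vapply(names(pops), function(nm) {
      kk <- length(pops[[nm]])
      if (kk < 2) 0 else kk * (kk - 1) / 2 / Ne_of(nm)
    }, numeric(1))
    total_rate <- sum(rates)
    t_merge <- if (mi <= nrow(merges)) merges$time_gen[mi] else Inf
    t_event <- if (total_rate > 0) t_now + rexp(1, total_rate) else Inf
    if (t_event < t_merge) {
      # coalescence in a population chosen proportionally to its rate
      p <- sample.int(length(pops), 1, prob = rates)
      pair <- sample(pops[[p]], 2)
      node <- nxt; nxt <- nxt + 1L
      time[node] <- t_event
      child1[node] <- pair[1]; child2[node] <- pair[2]
      parent[pair] <- node
      pops[[p]] <- c(setdiff(pops[[p]], pair), node)
      t_now <- t_event
    } else if (is.finite(t_merge)) {
      key <- paste(sort(unique(c(
        strsplit(merges$left[mi], "+", fixed = TRUE)[[1]],
        strsplit(merges$right[mi], "+", fixed = TRUE)[[1]]))), collapse = "+")
      l <- merges$left[mi]; r <- merges$right[mi]
      pops[[key]] <- c(pops[[l]], pops[[r]])
      pops[[l]] <- NULL; pops[[r]] <- NULL
      t_now <- t_merge
      mi <- mi + 1L
    } else {
      abort("coalescent cannot proceed: no rate and no merges left")
    }
  }
  list(parent = parent, child1 = child1, child2 = child2, time = time,
       n_tips = n, tip_deme = tip_deme, root = n_nodes)
}

#' Simulate a haplotype table under the split-tree coalescent with SMM
#'
#' Generates per-individual Y-STR haplotypes: a structured coalescent
#' genealogy is drawn under the dated population tree (lineages coalesce only
#' within their current population; populations merge backwards at the split
#' times), mutations are laid on branches as Poisson(mu * length) events per
#' locus, each a +1/-1 repeat step with equal probability, and haplogroup
#' labels are inherited from founder lineages extant at the root split.
#'
#' @param tree A `pop_tree`.
#' @param cfg A `sim_config`.
#' @return A `hap_tbl` with loci named `STR01`.. (or [ystr_loci()] when
#'   `n_loci == 17`).
#' @export
simulate_haplotypes <- function(tree, cfg = sim_config()) {
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  demes <- tree$demes
  if (length(demes) == 0) abort("tree has no demes",
                                class = "ystrata_domain_error")
  npd <- cfg$samples_per_deme
  if (is.null(names(npd))) npd <- setNames(rep(npd, length.out =
                                                 length(demes)), demes)
  npd <- npd[demes]
  gen <- .sim_genealogy(tree, npd)
  L <- cfg$n_loci
  n_nodes <- 2L * gen$n_tips - 1L
  alle <- matrix(0L, n_nodes, L)
  alle[gen$root, ] <- cfg$ancestral_allele
  # founder labels: lineages extant at the root split time; a single-deme
  # tree has one founder, the root itself
  t_label <- if (nrow(tree$merges) > 0) max(tree$merges$time_gen) else -1
  hg_node <- rep(NA_character_, n_nodes)
  if (t_label < 0) hg_node[gen$root] <- cfg$founder_haplogroups[1]
  order_desc <- order(gen$time, decreasing = TRUE)
  n_founders <- 0L
  # traverse root-down, dropping mutations and propagating labels
  for (node in order_desc) {
    for (ch in c(gen$child1[node], gen$child2[node])) {
      if (ch == 0) next
      b <- gen$time[node] - gen$time[ch]
      if (cfg$mu > 0 && b > 0) {
        k <- rpois(L, cfg$mu * b)
        step <- vapply(k, function(kk)
          if (kk == 0) 0L else sum(sample(c(-1L, 1L), kk, replace = TRUE)),
          integer(1))
      } else step <- integer(L)
      alle[ch, ] <- alle[node, ] + step
      # a lineage crossing t_label founds a haplogroup
      if (is.na(hg_node[node]) && gen$time[ch] <= t_label) {
        n_founders <- n_founders + 1L
        hg_node[ch] <- cfg$founder_haplogroups[
          (n_founders - 1L) %% length(cfg$founder_haplogroups) + 1L]
      } else if (!is.na(hg_node[node])) {
        hg_node[ch] <- hg_node[node]
      }
    }
  }
  loci <- if (L == 17) ystr_loci() else sprintf("STR%02d", seq_len(L))
  tips <- seq_len(gen$n_tips)
  al <- alle[tips, , drop = FALSE]
  al[al < 5L] <- 5L; al[al > 50L] <- 50L  # clamp to the representable range
  colnames(al) <- loci
  haplotype_table(tibble::tibble(
    sample_id = sprintf("sim%04d", tips),
    population = demes[gen$tip_deme],
    haplogroup = hg_node[tips]) |>
      dplyr::bind_cols(tibble::as_tibble(al)),
    loci = loci, inventory = NULL)
}

#' Admixture perturbation scenarios
#'
#' Configuration for the three perturbations used to probe the split-time
#' sampler's sensitivity to unmodelled gene flow: `random_split` relabels one
#' deme's records into two pseudo-demes by fair coin; `symmetric_mixing` swaps
#' the population labels of a fraction `m` of records between two demes
#' (exactly `round(m * n)` each way); `in_migration` replaces a fraction `m`
#' of each target deme's records by records drawn from a source deme.
#'
#' @param kind One of `"random_split"`, `"symmetric_mixing"`, `"in_migration"`.
#' @param demes Target deme(s): one for `random_split`, two for
#'   `symmetric_mixing` and `in_migration` (the two demes receiving migrants).
#' @param m Mixing fraction in \[0, 1\] (required for the mixing kinds).
#' @param source Source deme for `in_migration`.
#' @param seed Optional integer seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(kind = c("random_split", "symmetric_mixing",
                                     "in_migration"),
                            demes, m = NULL, source = NULL, seed = NULL) {
  kind <- match.arg(kind)
  if (kind != "random_split") {
    if (is.null(m) || m < 0 || m > 1) {
      abort("mixing kinds require m in [0, 1]", class = "ystrata_domain_error")
    }
    if (kind == "symmetric_mixing" && m > 0.5) {
      warn("m > 0.5: population labels become majority-swapped")
    }
  }
  if (kind == "in_migration" && is.null(source)) {
    abort("in_migration requires a source deme", class = "ystrata_domain_error")
  }
  structure(list(kind = kind, demes = demes, m = m, source = source,
                 seed = seed), class = "scenario_config")
}

#' Apply an admixture scenario to a haplotype table
#'
#' @param t A `hap_tbl`.
#' @param s A `scenario_config`.
#' @return The perturbed `hap_tbl`; record counts are conserved overall
#'   (split, mixing) or per deme (in-migration).
#' @export
apply_scenario <- function(t, s) {
  stopifnot(inherits(s, "scenario_config"))
  if (!is.null(s$seed)) set.seed(s$seed)
  pops <- unique(t$population)
  missing <- setdiff(c(s$demes, s$source), pops)
  if (length(missing) > 0) {
    abort(sprintf("deme(s) not present: %s", paste(missing, collapse = ", ")),
          class = "ystrata_domain_error")
  }
  loci <- loci_of(t)
  out <- tibble::as_tibble(t)
  if (s$kind == "random_split") {
    sel <- which(out$population == s$demes[1])
    coin <- rbinom(length(sel), 1, 0.5)
    out$population[sel] <- paste0(s$demes[1], ifelse(coin == 1, "_A", "_B"))
  } else if (s$kind == "symmetric_mixing") {
    a <- which(out$population == s$demes[1])
    b <- which(out$population == s$demes[2])
    ka <- round(s$m * length(a)); kb <- round(s$m * length(b))
    swap_a <- sample(a, ka); swap_b <- sample(b, kb)
    out$population[swap_a] <- s$demes[2]
    out$population[swap_b] <- s$demes[1]
  } else {
    src <- which(out$population == s$source)
    for (d in s$demes) {
      tgt <- which(out$population == d)
      k <- round(s$m * length(tgt))
      if (k == 0) next
      replace_rows <- sample(tgt, k)
      draw <- sample(src, k, replace = TRUE)
      out[replace_rows, c("haplogroup", loci)] <- out[draw, c("haplogroup", loci)]
    }
  }
  haplotype_table(out, loci = loci)
}
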
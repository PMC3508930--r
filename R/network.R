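# Reduced-median networks of STR haplotypes within a haplogroup.
#
# Multi-state STR characters are ordered, so the coordinatewise median of
# three integer repeat vectors is exactly the majority consensus of their
# binary "ladder" expansions (one indicator per unit step of each locus); the
# construction therefore works directly on repeat vectors. Median (Steiner)
# nodes are proposed from triples in the neighbourhood of the current minimum
# spanning network and accepted when they shorten the weighted spanning tree;
# the reduction coefficient scales that comparison. The final graph is the
# minimum spanning network (union of all minimum spanning trees) over the
# retained nodes.

# weighted L1 distance between allele vectors
.wl1 <- function(a, b, w) sum(w * abs(a - b))

# all-pairs weighted L1 distances for a matrix of haplotypes
.pairdist <- function(H, w) {
  n <- nrow(H)
  D <- matrix(0, n, n)
  for (l in seq_len(ncol(H))) {
    D <- D + w[l] * abs(outer(H[, l], H[, l], "-"))
  }
  D
}

# minimum spanning network: edges that belong to at least one MST
# (cycle property: (u,v) is in some MST iff u,v are disconnected among
# strictly shorter edges)
.msn_edges <- function(D) {
  n <- nrow(D)
  if (n == 1) return(matrix(numeric(0), 0, 3))
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  wts <- D[pairs]
  ord <- order(wts)
  comp <- seq_len(n)
  find <- function(i) { while (comp[i] != i) i <- comp[i]; i }
  out <- matrix(numeric(0), 0, 3)
  k <- 1
  while (k <= length(ord)) {
    # process ties together: test connectivity before merging any of them
    same <- which(abs(wts[ord] - wts[ord[k]]) < 1e-9 & seq_along(ord) >= k)
    batch <- ord[same]
    keep <- batch[vapply(batch, function(e)
      find(pairs[e, 1]) != find(pairs[e, 2]), logical(1))]
    for (e in keep) {
      out <- rbind(out, c(pairs[e, 1], pairs[e, 2], wts[e]))
      comp[find(pairs[e, 1])] <- find(pairs[e, 2])
    }
    k <- max(same) + 1
  }
  out
}

.mst_total <- function(D) {
  n <- nrow(D)
  if (n <= 1) return(0)
  # Prim
  intree <- c(1L)
  total <- 0
  dmin <- D[1, ]
  dmin[1] <- Inf
  for (i in seq_len(n - 1)) {
    j <- which.min(dmin)
    total <- total + dmin[j]
    intree <- c(intree, j)
    dmin <- pmin(dmin, D[j, ])
    dmin[intree] <- Inf
  }
  total
}

#' Character weights from inverse haplotype variance
#'
#' Locus weights inversely proportional to the repeat-count variance at each
#' locus averaged over the dataset, normalized to mean 10 and rounded to
#' integers >= 1. Monomorphic loci (zero variance) receive the maximum weight.
#'
#' @param H Integer matrix of haplotypes (rows) by loci (columns).
#' @return Integer vector of locus weights.
#' @export
rm_weights <- function(H) {
  v <- apply(H, 2, stats::var)
  inv <- ifelse(v > 0, 1 / v, NA)
  if (all(is.na(inv))) return(rep(10L, ncol(H)))
  inv[is.na(inv)] <- max(inv, na.rm = TRUE)
  w <- inv * 10 / mean(inv)
  pmax(1L, as.integer(round(w)))
}

#' Build a reduced-median network of STR haplotypes
#'
#' @param t A `hap_tbl` whose records all carry the same haplogroup (>= 2
#'   distinct haplotypes), or an integer haplotype matrix.
#' @param r Reduction coefficient (default 1.0): a median node is retained
#'   when the weighted spanning-tree length with it is `< r *` the length
#'   without it.
#' @param weights Per-locus character weights; default [rm_weights()] of the
#'   observed haplotypes.
#' @return An object of class `rm_network`: `graph` (igraph, undirected;
#'   node attributes `multiplicity`, `inferred`, `label`; edge attributes
#'   `steps`, `loci`), `nodes` (tibble), `haplotypes` (matrix over all
#'   retained nodes), `weights`, `total_steps`.
#' @export
build_rm_network <- function(t, r = 1.0, weights = NULL) {
  if (inherits(t, "hap_tbl")) {
    t <- drop_incomplete(t)
    if (length(unique(t$haplogroup)) > 1) {
      abort("haplotypes must come from a single haplogroup",
            class = "ystrata_domain_error")
    }
    H_all <- as.matrix(t[, loci_of(t)])
    pop <- t$population
  } else {
    H_all <- as.matrix(t)
    pop <- rep("all", nrow(H_all))
  }
  if (any(apply(H_all, 2, function(x) length(unique(x))) > 32)) {
    abort("a locus has more than 32 states", class = "ystrata_domain_error")
  }
  key <- apply(H_all, 1, paste, collapse = ",")
  uk <- unique(key)
  H <- H_all[match(uk, key), , drop = FALSE]
  rownames(H) <- NULL
  mult <- as.integer(table(factor(key, levels = uk)))
  compo <- lapply(uk, function(k) table(pop[key == k]))
  if (is.null(weights)) weights <- rm_weights(H_all)
  n_obs <- nrow(H)
  inferred <- rep(FALSE, n_obs)

  if (n_obs >= 2) {
    repeat {
      D <- .pairdist(H, weights)
      total <- .mst_total(D)
      edges <- .msn_edges(D)
      adj <- lapply(seq_len(nrow(H)), function(i) integer(0))
      for (e in seq_len(nrow(edges))) {
        a <- edges[e, 1]; b <- edges[e, 2]
        adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
      }
      # candidate medians from triples with at least two MSN links
      cand <- list()
      for (u in seq_len(nrow(H))) {
        nb <- adj[[u]]
        if (length(nb) < 2) next
        for (i in seq_along(nb)) for (j in seq_along(nb)) {
          if (i >= j) next
          med <- apply(H[c(u, nb[i], nb[j]), , drop = FALSE], 2,
                       function(x) sort(x)[2])
          cand[[length(cand) + 1]] <- med
        }
      }
      if (length(cand) == 0) break
      cand <- unique(do.call(rbind, cand))
      keys <- apply(H, 1, paste, collapse = ",")
      new <- cand[!apply(cand, 1, paste, collapse = ",") %in% keys, ,
                  drop = FALSE]
      if (nrow(new) == 0) break
      # greedily add the single best median this round
      best <- NULL
      for (i in seq_len(nrow(new))) {
        H2 <- rbind(H, new[i, ])
        tot2 <- .mst_total(.pairdist(H2, weights))
        if (tot2 < r * total - 1e-9 && (is.null(best) || tot2 < best$tot)) {
          best <- list(vec = new[i, ], tot = tot2)
        }
      }
      if (is.null(best)) break
      H <- rbind(H, best$vec)
      inferred <- c(inferred, TRUE)
      mult <- c(mult, 0L)
      compo <- c(compo, list(table(character(0))))
    }
    # prune inferred nodes whose removal does not lengthen the spanning tree
    repeat {
      D <- .pairdist(H, weights)
      total <- .mst_total(D)
      drop <- NA
      for (i in which(inferred)) {
        tot2 <- .mst_total(.pairdist(H[-i, , drop = FALSE], weights))
        if (tot2 <= total + 1e-9) { drop <- i; break }
      }
      if (is.na(drop)) break
      H <- H[-drop, , drop = FALSE]
      inferred <- inferred[-drop]
      mult <- mult[-drop]
      compo <- compo[-drop]
    }
  }

  # canonical node order (invariant to input record order)
  ord <- order(apply(H, 1, paste, collapse = ","))
  ord <- ord[order(inferred[ord])]           # observed first, then inferred
  H <- H[ord, , drop = FALSE]
  inferred <- inferred[ord]; mult <- mult[ord]; compo <- compo[ord]

  D <- .pairdist(H, weights)
  edges <- .msn_edges(D)
  steps <- .pairdist(H, rep(1, ncol(H)))     # unweighted step counts
  g <- igraph::make_empty_graph(n = nrow(H), directed = FALSE)
  lab <- apply(H, 1, paste, collapse = "-")
  g <- igraph::set_vertex_attr(g, "label", value = lab)
  g <- igraph::set_vertex_attr(g, "multiplicity", value = mult)
  g <- igraph::set_vertex_attr(g, "inferred", value = inferred)
  if (nrow(edges) > 0) {
    el <- t(apply(edges[, 1:2, drop = FALSE], 1, sort))
    loci_lab <- vapply(seq_len(nrow(el)), function(e) {
      diffs <- which(H[el[e, 1], ] != H[el[e, 2], ])
      paste(colnames(H)[diffs] %||% diffs, collapse = "+")
    }, character(1))
    g <- igraph::add_edges(g, t(el))
    g <- igraph::set_edge_attr(g, "steps",
                               value = steps[el])
    g <- igraph::set_edge_attr(g, "loci", value = loci_lab)
  }
  nodes <- tibble::tibble(
    id = seq_len(nrow(H)), label = lab, multiplicity = mult,
    inferred = inferred, composition = compo)
  total_steps <- if (nrow(edges) > 0) sum(steps[edges[, 1:2, drop = FALSE]])
                 else 0
  structure(list(graph = g, nodes = nodes, haplotypes = H, weights = weights,
                 total_steps = total_steps),
            class = "rm_network")
}

#' @export
print.rm_network <- function(x, ...) {
  cat(sprintf("Reduced-median network: %d observed + %d inferred nodes, %d edges, total length %g steps\n",
              sum(!x$nodes$inferred), sum(x$nodes$inferred),
              igraph::ecount(x$graph), x$total_steps))
  invisible(x)
}

#' @describeIn build_rm_network Edge list of the network as a tibble.
#' @param x An `rm_network`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.rm_network <- function(x, ...) {
  if (igraph::ecount(x$graph) == 0) {
    return(tibble::tibble(from = integer(), to = integer(), steps = numeric(),
                          loci = character()))
  }
  el <- igraph::as_edgelist(x$graph)
  tibble::tibble(from = as.integer(el[, 1]), to = as.integer(el[, 2]),
                 steps = igraph::E(x$graph)$steps,
                 loci = igraph::E(x$graph)$loci)
}

#' Export a reduced-median network to GraphML
#'
#' @param net An `rm_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
export_graphml <- function(net, path) {
  g <- net$graph
  comp_str <- vapply(net$nodes$composition, function(tb)
    paste(sprintf("%s:%d", names(tb), as.integer(tb)), collapse = ";"),
    character(1))
  g <- igraph::set_vertex_attr(g, "composition", value = comp_str)
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Population segregation of a haplotype network
#'
#' Quantifies how strongly adjacent haplotypes share their majority population
#' label: the score is the fraction of edges between observed nodes whose
#' endpoints have the same majority label. Significance is assessed by
#' permuting the node labels (`n_perm` label shuffles over observed nodes);
#' p is the upper permutation tail. This score is a package-defined
#' operationalization of the visual cluster reading of published networks and
#' is flagged as such in reports.
#'
#' @param net An `rm_network` built from a `hap_tbl` (population composition
#'   present).
#' @param n_perm Number of label permutations (default 999).
#' @param seed Optional integer seed.
#' @return One-row tibble with `score`, `p`, `n_edges_scored`, `definition`.
#' @export
segregation_score <- function(net, n_perm = 999, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  obs <- which(!net$nodes$inferred)
  if (length(obs) < 2) {
    return(tibble::tibble(score = NA_real_, p = NA_real_, n_edges_scored = 0L,
                          definition = "majority-label concordance (package-defined)"))
  }
  maj <- vapply(net$nodes$composition, function(tb) {
    if (length(tb) == 0) NA_character_ else names(tb)[which.max(tb)]
  }, character(1))
  el <- igraph::as_edgelist(net$graph)
  el <- el[el[, 1] %in% obs & el[, 2] %in% obs, , drop = FALSE]
  if (nrow(el) == 0) {
    return(tibble::tibble(score = NA_real_, p = NA_real_, n_edges_scored = 0L,
                          definition = "majority-label concordance (package-defined)"))
  }
  score_of <- function(lbl) mean(lbl[el[, 1]] == lbl[el[, 2]])
  score <- score_of(maj)
  null <- vapply(seq_len(n_perm), function(b) {
    lbl <- maj
    lbl[obs] <- sample(maj[obs])
    score_of(lbl)
  }, numeric(1))
  tibble::tibble(score = score,
                 p = (sum(null >= score - 1e-12) + 1) / (n_perm + 1),
                 n_edges_scored = nrow(el),
                 definition = "majority-label concordance (package-defined)")
}
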
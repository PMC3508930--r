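# Ordination: covariance PCA of haplogroup data and non-metric MDS of R_ST.

#' Covariance PCA of haplogroup data
#'
#' Principal component analysis of haplogroup composition, column-centered
#' without variance normalization. Two modes are supported:
#'
#' * `mode = "individual"` (default for an `hg_counts` input): the count
#'   matrix is expanded to the per-individual 0/1 haplogroup indicator matrix
#'   and the PCA is taken over individuals. This is the convention of
#'   individual-level genotype PCA and is the one that reproduces the
#'   published variance fractions for the packaged survey.
#' * `mode = "population"`: the PCA is taken over the population frequency
#'   rows (percent or proportion; the variance fractions are scale-free).
#'
#' Population coordinates in individual mode are the per-population centroids
#' of the individual scores. A skree heuristic (components before the largest
#' successive eigenvalue drop) is reported as advisory output.
#'
#' @param m An `hg_counts` tibble, or a numeric matrix of frequencies with
#'   populations as rows (population mode only).
#' @param mode `"individual"` or `"population"`.
#' @return An object of class `hg_pca` with elements `scores` (tibble),
#'   `loadings`, `var_fraction`, `skree_k`, `mode`.
#' @export
hg_pca <- function(m, mode = c("individual", "population")) {
  mode <- match.arg(mode)
  if (inherits(m, "hg_counts")) {
    cnt <- as_count_mat(m)
  } else {
    cnt <- as.matrix(m)
    if (mode == "individual") {
      abort("individual mode needs an 'hg_counts' input",
            class = "ystrata_format_error")
    }
  }
  if (nrow(cnt) < 3) abort("PCA needs at least 3 rows",
                           class = "ystrata_domain_error")
  if (mode == "individual") {
    X <- matrix(0L, sum(cnt), ncol(cnt), dimnames = list(NULL, colnames(cnt)))
    pop <- character(nrow(X))
    r <- 1L
    for (i in seq_len(nrow(cnt))) {
      for (k in seq_len(ncol(cnt))) {
        if (cnt[i, k] > 0) {
          X[r:(r + cnt[i, k] - 1L), k] <- 1L
          pop[r:(r + cnt[i, k] - 1L)] <- rownames(cnt)[i]
          r <- r + cnt[i, k]
        }
      }
    }
  } else {
    X <- 100 * cnt / rowSums(cnt)
    pop <- rownames(cnt) %||% sprintf("row%02d", seq_len(nrow(cnt)))
  }
  if (all(apply(X, 2, function(v) stats::var(v) == 0))) {
    abort("constant matrix: no principal components",
          class = "ystrata_domain_error")
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  scores <- tibble::as_tibble(pc$x[, seq_len(min(4, ncol(pc$x))), drop = FALSE])
  scores$population <- pop
  if (mode == "individual") {
    scores <- scores |>
      dplyr::group_by(.data$population) |>
      dplyr::summarise(dplyr::across(dplyr::everything(), mean),
                       .groups = "drop")
  } else {
    scores <- dplyr::relocate(scores, "population")
  }
  ev <- pc$sdev^2
  drops <- -diff(ev)
  skree_k <- if (length(drops) > 0) which.max(drops) else 1L
  structure(list(scores = scores, loadings = pc$rotation,
                 var_fraction = vf, skree_k = skree_k, mode = mode),
            class = "hg_pca")
}

#' @export
print.hg_pca <- function(x, ...) {
  cat(sprintf("Covariance PCA (%s mode): PC1 %.2f%%, PC2 %.2f%% (PC1+PC2 %.2f%%), skree k = %d\n",
              x$mode, 100 * x$var_fraction[1], 100 * x$var_fraction[2],
              100 * sum(x$var_fraction[1:2]), x$skree_k))
  invisible(x)
}

#' @describeIn hg_pca Per-component variance fractions as a tibble.
#' @param x An `hg_pca` object.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.hg_pca <- function(x, ...) {
  tibble::tibble(component = seq_along(x$var_fraction),
                 var_fraction = x$var_fraction,
                 cumulative = cumsum(x$var_fraction))
}

#' Non-metric multidimensional scaling of a distance matrix
#'
#' Kruskal stress-1 minimized by iterative majorization with monotone
#' regression (via [vegan::monoMDS()]), taking the best of `restarts` random
#' starts. Stress is reported in percent.
#'
#' @param d A symmetric distance matrix (e.g. from [rst_distance()]).
#'   Negative entries are shifted to 0 (non-metric MDS uses ranks only above
#'   ties, but the engine requires non-negative dissimilarities).
#' @param dims Embedding dimension (default 2).
#' @param restarts Number of random starts (default 20).
#' @param seed Optional integer seed.
#' @return An object of class `hg_nmds` with `coordinates` (tibble),
#'   `stress_percent`, `dims`.
#' @export
hg_nmds <- function(d, dims = 2, restarts = 20, seed = NULL) {
  d <- as.matrix(d)
  if (any(!is.finite(d))) abort("non-finite distances",
                                class = "ystrata_domain_error")
  if (nrow(d) < dims + 1) abort("need at least dims + 1 entities",
                                class = "ystrata_domain_error")
  if (!is.null(seed)) set.seed(seed)
  d2 <- d
  d2[d2 < 0] <- 0
  dd <- stats::as.dist(d2)
  best <- NULL
  for (r in seq_len(restarts)) {
    fit <- vegan::monoMDS(dd, k = dims, model = "global",
                          maxit = 500, smin = 1e-7, sratmax = 1 - 1e-6)
    if (is.null(best) || fit$stress < best$stress) best <- fit
  }
  coords <- tibble::as_tibble(best$points, .name_repair = "minimal")
  names(coords) <- paste0("MDS", seq_len(dims))
  coords$population <- rownames(d) %||% as.character(seq_len(nrow(d)))
  structure(list(coordinates = dplyr::relocate(coords, "population"),
                 stress_percent = 100 * best$stress, dims = dims),
            class = "hg_nmds")
}

#' @export
print.hg_nmds <- function(x, ...) {
  cat(sprintf("Non-metric MDS in %d dimensions: stress-1 = %.2f%%\n",
              x$dims, x$stress_percent))
  invisible(x)
}
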
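# Nei gene diversity and lineage-class proportions.

#' Nei gene diversity
#'
#' Unbiased gene diversity over discrete classes,
#' \eqn{D = \frac{n}{n-1}(1 - \sum_i p_i^2)}, with its sampling standard
#' deviation from Nei's (1987) variance formula
#' \deqn{V(D) = \frac{2}{n(n-1)}\left\{2(n-2)\left[\sum p_i^3 -
#'   (\sum p_i^2)^2\right] + \sum p_i^2 - (\sum p_i^2)^2\right\}.}
#'
#' @param counts Integer class counts (e.g. one row of an `hg_counts` matrix),
#'   total at least 2.
#' @return One-row tibble with `D`, `SD`, `n`.
#' @export
nei_diversity <- function(counts) {
  counts <- counts[counts > 0]
  n <- sum(counts)
  if (n < 2) abort("gene diversity needs n >= 2", class = "ystrata_domain_error")
  p <- counts / n
  s2 <- sum(p^2)
  D <- n / (n - 1) * (1 - s2)
  V <- 2 / (n * (n - 1)) * (2 * (n - 2) * (sum(p^3) - s2^2) + s2 - s2^2)
  tibble::tibble(D = D, SD = sqrt(max(V, 0)), n = n)
}

#' Gene diversity for every row of a count matrix
#'
#' @param m An `hg_counts` tibble.
#' @param g Optional `grouping`; if given, rows are pooled by group first.
#' @return Tibble with `population` (or `group`), `D`, `SD`, `n`.
#' @export
diversity_by <- function(m, g = NULL) {
  if (!is.null(g)) m <- pool_counts(m, g)
  cnt <- as_count_mat(m)
  out <- dplyr::bind_rows(lapply(seq_len(nrow(cnt)),
                                 function(i) nei_diversity(cnt[i, ])))
  dplyr::bind_cols(tibble::tibble(population = m$population), out)
}

#' Pooled proportion of a lineage class
#'
#' Proportion of chromosomes carrying a haplogroup from `class_set` among the
#' pooled `rows` of the count matrix, with its binomial standard error
#' \eqn{SE = \sqrt{p(1-p)/n}}.
#'
#' @param m An `hg_counts` tibble.
#' @param class_set Character vector of haplogroup labels (must be a subset of
#'   the column inventory).
#' @param rows Populations to pool (default: all rows).
#' @param class_name Label for the class in the output.
#' @return One-row tibble with `class`, `p`, `SE`, `n`.
#' @export
lineage_class_proportion <- function(m, class_set, rows = NULL,
                                     class_name = "class") {
  bad <- setdiff(class_set, hg_cols(m))
  if (length(bad) > 0) {
    abort(sprintf("haplogroup(s) not in inventory: %s",
                  paste(bad, collapse = ", ")), class = "ystrata_domain_error")
  }
  if (is.null(rows)) rows <- m$population
  sel <- m$population %in% rows
  if (!any(sel)) abort("empty population subset", class = "ystrata_domain_error")
  cnt <- as_count_mat(m)[sel, , drop = FALSE]
  n <- sum(cnt)
  p <- sum(cnt[, class_set, drop = FALSE]) / n
  tibble::tibble(class = class_name, p = p, SE = sqrt(p * (1 - p) / n), n = n)
}
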
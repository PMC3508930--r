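# Population x haplogroup count matrices and population groupings.

#' Construct a haplogroup count matrix
#'
#' An `hg_counts` object is a tibble with a `population` column, one integer
#' column per haplogroup, and an `N` column equal to the row sum. It is the
#' unit of all frequency-based analyses.
#'
#' @param x Data frame with a `population` column and haplogroup count columns;
#'   an `N` column, if present, is checked against the row sums.
#' @return An `hg_counts` tibble.
#' @export
count_matrix <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"population" %in% names(x)) {
    abort("count matrix needs a 'population' column",
          class = "ystrata_format_error")
  }
  hg <- setdiff(names(x), c("population", "N"))
  cnt <- as.matrix(x[, hg])
  if (any(cnt < 0) || any(abs(cnt - round(cnt)) > 1e-9)) {
    abort("counts must be non-negative integers", class = "ystrata_format_error")
  }
  rs <- as.integer(round(rowSums(cnt)))
  if ("N" %in% names(x) && any(x$N != rs)) {
    bad <- which(x$N != rs)[1]
    abort(sprintf("row '%s' sums to %d but N = %d (residual %d)",
                  x$population[bad], rs[bad], x$N[bad], rs[bad] - x$N[bad]),
          class = "ystrata_checksum_error")
  }
  out <- tibble::tibble(population = as.character(x$population), N = rs)
  out <- dplyr::bind_cols(out, tibble::as_tibble(matrix(
    as.integer(round(cnt)), nrow = nrow(cnt), dimnames = list(NULL, hg))))
  class(out) <- c("hg_counts", class(out))
  out
}

#' Haplogroup column names of a count matrix
#' @param m An `hg_counts` tibble.
#' @return Character vector.
#' @export
hg_cols <- function(m) setdiff(names(m), c("population", "N"))

#' Counts as a plain integer matrix
#' @param m An `hg_counts` tibble.
#' @return Integer matrix with population rownames.
#' @export
as_count_mat <- function(m) {
  cnt <- as.matrix(m[, hg_cols(m)])
  rownames(cnt) <- m$population
  cnt
}

#' @export
print.hg_counts <- function(x, ...) {
  cat(sprintf("# Haplogroup counts: %d populations x %d haplogroups, N = %d\n",
              nrow(x), length(hg_cols(x)), sum(x$N)))
  NextMethod()
}

#' Reconstruct integer counts from printed percentages
#'
#' Published frequency tables print percentages rounded to two decimals; for a
#' known sample size the underlying integer counts are recovered by
#' nearest-integer rounding (ties to even). The row-sum checksum against `n`
#' is mandatory so that curation mistakes surface instead of propagating.
#'
#' @param freq_percent Numeric vector of percentages in \[0, 100\].
#' @param n Sample size (>= 1).
#' @param complete_row Enforce the row-sum checksum (default: on whenever more
#'   than one frequency is given, i.e. the vector purports to be a full row;
#'   single-cell reconstructions skip it).
#' @return Integer vector of counts with attribute `checksum_ok`.
#' @export
counts_from_frequencies <- function(freq_percent, n,
                                    complete_row = length(freq_percent) > 1) {
  stopifnot(n >= 1)
  if (any(freq_percent < 0 | freq_percent > 100)) {
    abort("frequencies must lie in [0, 100]", class = "ystrata_format_error")
  }
  cnt <- as.integer(round(freq_percent * n / 100))
  resid <- sum(cnt) - n
  if (complete_row && resid != 0L) {
    abort(sprintf("reconstructed counts sum to %d, not n = %d (residual %+d)",
                  sum(cnt), n, resid), class = "ystrata_checksum_error")
  }
  structure(cnt, checksum_ok = resid == 0L)
}

#' Construct a population grouping
#'
#' A grouping maps every population to exactly one group label. Groupings are
#' the second level of all hierarchical analyses (AMOVA, enrichment tests,
#' pooled diversities).
#'
#' @param populations Character vector of population labels.
#' @param groups Character vector of group labels, same length.
#' @param name Optional name for the grouping.
#' @return A `grouping` tibble with columns `population` and `group`.
#' @export
grouping <- function(populations, groups, name = NULL) {
  stopifnot(length(populations) == length(groups))
  if (anyDuplicated(populations)) {
    abort("each population must be mapped exactly once",
          class = "ystrata_format_error")
  }
  g <- tibble::tibble(population = as.character(populations),
                      group = as.character(groups))
  attr(g, "name") <- name %||% "grouping"
  class(g) <- c("grouping", class(g))
  g
}

#' Look up group labels for populations
#' @param g A `grouping`.
#' @param populations Populations to map; an unmapped one is an error.
#' @return Character vector of group labels.
#' @export
group_of <- function(g, populations) {
  i <- match(populations, g$population)
  if (anyNA(i)) {
    abort(sprintf("population(s) not mapped in grouping '%s': %s",
                  attr(g, "name"), paste(unique(populations[is.na(i)]),
                                         collapse = ", ")),
          class = "ystrata_grouping_error")
  }
  g$group[i]
}

#' Pool a count matrix by group
#'
#' Group rows are column-wise sums of their member populations; the total N is
#' preserved.
#'
#' @param m An `hg_counts` tibble.
#' @param g A `grouping` covering every row of `m`.
#' @return An `hg_counts` tibble with one row per group.
#' @export
pool_counts <- function(m, g) {
  grp <- group_of(g, m$population)
  cnt <- as_count_mat(m)
  lev <- unique(grp)
  pooled <- t(vapply(lev, function(gg) colSums(cnt[grp == gg, , drop = FALSE]),
                     numeric(ncol(cnt))))
  count_matrix(tibble::tibble(population = lev) |>
                 dplyr::bind_cols(tibble::as_tibble(pooled)))
}

#' Read / write a count matrix as CSV
#'
#' CSV with a leading `population` column and an `N` column; the checksum
#' N == row sum is enforced on read.
#'
#' @param path File path.
#' @return `read_count_matrix()`: an `hg_counts` tibble.
#' @export
read_count_matrix <- function(path) {
  count_matrix(utils::read.csv(path, check.names = FALSE))
}

#' @rdname read_count_matrix
#' @param m An `hg_counts` tibble.
#' @export
write_count_matrix <- function(m, path) {
  utils::write.csv(tibble::as_tibble(m), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Expand a count matrix to per-individual haplogroup assignments
#'
#' @param m An `hg_counts` tibble.
#' @return A tibble with `sample_id`, `population`, `haplogroup` (one row per
#'   chromosome).
#' @export
expand_counts <- function(m) {
  cnt <- as_count_mat(m)
  idx <- which(cnt > 0, arr.ind = TRUE)
  rows <- rep(seq_len(nrow(idx)), cnt[idx])
  out <- tibble::tibble(
    population = rownames(cnt)[idx[rows, 1]],
    haplogroup = colnames(cnt)[idx[rows, 2]])
  out <- dplyr::arrange(out, match(.data$population, rownames(cnt)))
  out$sample_id <- sprintf("ind%04d", seq_len(nrow(out)))
  out[, c("sample_id", "population", "haplogroup")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
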
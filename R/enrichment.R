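# Fisher exact enrichment tests at the chromosome and population level.

#' Haplogroup enrichment of a group (chromosome-level Fisher test)
#'
#' Two-sided Fisher exact test on the 2x2 table
#' \[haplogroup vs other\] x \[inside group vs outside\], counting individual
#' chromosomes. Direction (`over` / `under`) is read off the sample odds ratio.
#'
#' @param m An `hg_counts` tibble.
#' @param g A `grouping` covering the rows of `m`.
#' @param hg Haplogroup label.
#' @param group Group label.
#' @param alternative Passed to [stats::fisher.test()] (default two-sided).
#' @return One-row tibble with `haplogroup`, `group`, `direction`, `p`,
#'   `odds_ratio` and the table cells `a`, `b`, `c`, `d`.
#' @export
hg_enrichment_test <- function(m, g, hg, group,
                               alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  grp <- group_of(g, m$population)
  if (!group %in% grp) {
    abort(sprintf("group '%s' is empty", group), class = "ystrata_domain_error")
  }
  cnt <- as_count_mat(m)
  if (!hg %in% colnames(cnt)) {
    abort(sprintf("haplogroup '%s' not in inventory", hg),
          class = "ystrata_domain_error")
  }
  inside <- grp == group
  a <- sum(cnt[inside, hg])              # hg, in group
  b <- sum(cnt[inside, ]) - a            # other, in group
  cc <- sum(cnt[!inside, hg])            # hg, outside
  d <- sum(cnt[!inside, ]) - cc          # other, outside
  tab <- matrix(c(a, cc, b, d), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    return(tibble::tibble(haplogroup = hg, group = group,
                          direction = NA_character_, p = 1, odds_ratio = NA,
                          a = a, b = b, c = cc, d = d, degenerate = TRUE))
  }
  ft <- stats::fisher.test(tab, alternative = alternative)
  or <- (a * d) / (b * cc)
  tibble::tibble(haplogroup = hg, group = group,
                 direction = if (or > 1) "over" else if (or < 1) "under"
                             else NA_character_,
                 p = ft$p.value, odds_ratio = unname(or),
                 a = a, b = b, c = cc, d = d, degenerate = FALSE)
}

#' Population-level over-representation test
#'
#' Second-level Fisher exact test: classify each population as over-represented
#' for haplogroup `hg` (by default, point-estimate frequency strictly above the
#' pooled overall frequency; alternatively a per-population Fisher test at
#' level `alpha`), then test the 2x2 table
#' \[over vs not-over\] x \[population inside group vs outside\]. Both the
#' two-sided and the one-sided (greater) p-values are reported.
#'
#' @inheritParams hg_enrichment_test
#' @param criterion `"point_estimate_above_overall"` (default) or
#'   `"per_population_fisher"`.
#' @param alpha Significance level for the per-population criterion.
#' @return One-row tibble with counts of over-represented populations inside
#'   and outside the group, `p_two_sided`, `p_one_sided` and the criterion.
#' @export
population_overrep_test <- function(m, g, hg, group,
                                    criterion = c("point_estimate_above_overall",
                                                  "per_population_fisher"),
                                    alpha = 0.05) {
  criterion <- match.arg(criterion)
  grp <- group_of(g, m$population)
  if (!group %in% grp) {
    abort(sprintf("group '%s' is empty", group), class = "ystrata_domain_error")
  }
  cnt <- as_count_mat(m)
  n_p <- rowSums(cnt)
  overall <- sum(cnt[, hg]) / sum(cnt)
  over <- switch(criterion,
    point_estimate_above_overall = cnt[, hg] / n_p > overall,
    per_population_fisher = vapply(seq_len(nrow(cnt)), function(i) {
      tab <- matrix(c(cnt[i, hg], n_p[i] - cnt[i, hg],
                      sum(cnt[-i, hg]), sum(cnt[-i, ]) - sum(cnt[-i, hg])), 2,
                    byrow = TRUE)
      stats::fisher.test(tab, alternative = "greater")$p.value < alpha
    }, logical(1)))
  inside <- grp == group
  a <- sum(over & inside); b <- sum(!over & inside)
  cc <- sum(over & !inside); d <- sum(!over & !inside)
  tab <- matrix(c(a, cc, b, d), 2)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    p2 <- 1; p1 <- 1
  } else {
    p2 <- stats::fisher.test(tab)$p.value
    p1 <- stats::fisher.test(tab, alternative = "greater")$p.value
  }
  tibble::tibble(haplogroup = hg, group = group, criterion = criterion,
                 over_in = a, n_in = a + b, over_out = cc, n_out = cc + d,
                 p_two_sided = p2, p_one_sided = p1)
}
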
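# Haplogroup age estimation from mean across-locus STR repeat variance under
# the effective-mutation-rate calibration.

#' Effective mutation rate and generation length defaults
#'
#' The calibration constants of the evolutionary ("effective") Y-STR mutation
#' rate convention: w = 6.9e-4 mutations per locus per 25-year generation.
#' Under single-step mutation the expected repeat variance accumulated along a
#' lineage of age t years is w * t / g, so `age = Var / w * g`.
#'
#' @name dating_constants
NULL

#' Mean across-locus repeat variance of a haplotype set
#'
#' `Var` is the mean over loci of the per-locus repeat-count sample variance
#' (n-1 denominator); `SE` is the standard deviation of those per-locus
#' variances divided by sqrt(#loci). Sets with fewer than `min_n` records are
#' excluded (the published tables drop cells with fewer than 5 samples).
#'
#' @param t A `hap_tbl`, typically filtered to one haplogroup (and group).
#' @param min_n Minimum number of complete records (default 5).
#' @return One-row tibble with `Var`, `SE`, `n`, `n_loci`; errors with class
#'   `ystrata_excluded` if `n < min_n`.
#' @export
locus_variance <- function(t, min_n = 5) {
  t <- drop_incomplete(t)
  loci <- loci_of(t)
  if (nrow(t) < min_n) {
    abort(sprintf("only %d complete records (< %d): excluded", nrow(t), min_n),
          class = "ystrata_excluded")
  }
  v <- vapply(loci, function(l) stats::var(t[[l]]), numeric(1))
  tibble::tibble(Var = mean(v), SE = stats::sd(v) / sqrt(length(v)),
                 n = nrow(t), n_loci = length(loci))
}

#' Age estimate from STR variance
#'
#' Converts a mean across-locus repeat variance into a lineage age in years:
#' `age = Var / w * g`, `age_sd = SE / w * g`.
#'
#' @param Var Mean across-locus repeat variance (repeat^2 units).
#' @param SE Standard error of `Var` (across loci).
#' @param w Effective mutation rate per locus per generation (default 6.9e-4).
#' @param g Generation length in years (default 25).
#' @return One-row tibble with `Var`, `SE`, `age_years`, `age_sd_years`, `w`,
#'   `g`.
#' @export
age_estimate <- function(Var, SE = NA_real_, w = 6.9e-4, g = 25) {
  if (w <= 0) abort("mutation rate w must be positive",
                    class = "ystrata_domain_error")
  stopifnot(Var >= 0)
  tibble::tibble(Var = Var, SE = SE, age_years = Var / w * g,
                 age_sd_years = SE / w * g, w = w, g = g)
}

#' Haplogroup age table from a haplotype table
#'
#' Applies [locus_variance()] and [age_estimate()] to every haplogroup (x
#' group) cell with at least `min_n` complete records, mirroring the layout of
#' published variance/age tables. Cells below the size threshold are listed
#' with `excluded = TRUE`.
#'
#' @param t A `hap_tbl`.
#' @param g Optional `grouping`; if given, estimates are also computed per
#'   group (the pooled "all" column is always included).
#' @param w,gen_years Calibration constants (see [age_estimate()]).
#' @param min_n Minimum complete records per cell (default 5).
#' @return Tibble with `haplogroup`, `group`, `n`, `Var`, `SE`, `age_years`,
#'   `age_sd_years`, `excluded`.
#' @export
hg_age_table <- function(t, g = NULL, w = 6.9e-4, gen_years = 25, min_n = 5) {
  t <- drop_incomplete(t)
  cells <- list(tibble::tibble(group = "all",
                               haplogroup = unique(t$haplogroup)))
  if (!is.null(g)) {
    t$group <- group_of(g, t$population)
    cells[[2]] <- dplyr::distinct(tibble::as_tibble(t)[, c("group", "haplogroup")])
  }
  cells <- dplyr::bind_rows(cells)
  loci <- loci_of(t)
  out <- purrr::pmap_dfr(cells, function(group, haplogroup) {
    sel <- t$haplogroup == haplogroup
    if (group != "all") sel <- sel & t$group == group
    sub <- t[sel, ]
    attr(sub, "loci") <- loci
    if (nrow(sub) < min_n) {
      return(tibble::tibble(haplogroup = haplogroup, group = group,
                            n = nrow(sub), Var = NA_real_, SE = NA_real_,
                            age_years = NA_real_, age_sd_years = NA_real_,
                            excluded = TRUE))
    }
    lv <- locus_variance(sub, min_n = min_n)
    ae <- age_estimate(lv$Var, lv$SE, w = w, g = gen_years)
    tibble::tibble(haplogroup = haplogroup, group = group, n = lv$n,
                   Var = lv$Var, SE = lv$SE, age_years = ae$age_years,
                   age_sd_years = ae$age_sd_years, excluded = FALSE)
  })
  dplyr::arrange(out, .data$haplogroup, .data$group)
}
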
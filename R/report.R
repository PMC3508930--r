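# JSON result export.

#' Write an analysis report as JSON
#'
#' Serializes a named list of results (tibbles, vectors, scalars) to a JSON
#' document carrying a `schema_version` field, so downstream consumers can
#' detect format changes.
#'
#' @param results Named list.
#' @param path Output file.
#' @param schema_version Schema tag (default "1.0").
#' @return `path`, invisibly.
#' @export
write_results_json <- function(results, path, schema_version = "1.0") {
  stopifnot(is.list(results), !is.null(names(results)))
  out <- c(list(schema_version = schema_version), results)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Summary statistics report for a count matrix
#'
#' Bundles the per-population and per-group gene diversities, the
#' lineage-class proportions and the chromosome-level enrichment tests for
#' every haplogroup x group pair into one list ready for
#' [write_results_json()].
#'
#' @param m An `hg_counts` tibble.
#' @param g A `grouping`.
#' @param classes Lineage-class sets (default [lineage_classes()]).
#' @return Named list of tibbles.
#' @export
stats_report <- function(m, g, classes = lineage_classes()) {
  pooled <- pool_counts(m, g)
  enr <- purrr::pmap_dfr(
    expand.grid(hg = hg_cols(m), group = unique(pooled$population),
                stringsAsFactors = FALSE),
    function(hg, group) hg_enrichment_test(m, g, hg, group))
  cls <- purrr::imap_dfr(classes[c("autochthonous", "non_autochthonous")],
    function(set, nm) lineage_class_proportion(m, set, class_name = nm))
  list(diversity_population = diversity_by(m),
       diversity_group = diversity_by(m, g),
       lineage_classes = cls,
       enrichment = enr)
}
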
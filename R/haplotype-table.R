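# Per-individual Y-STR haplotype tables.

#' Default Y-STR locus names
#'
#' The 17 single-copy loci of the Y-filer / Multiplex II panel after exclusion
#' of the multi-copy markers DYS385a and DYS385b, which cannot be assigned
#' unambiguously to a single locus.
#'
#' @return Character vector of 17 locus names.
#' @export
ystr_loci <- function() {
  c("DYS19", "DYS388", "DYS389I", "DYS389II", "DYS390", "DYS391", "DYS392",
    "DYS393", "DYS426", "DYS437", "DYS438", "DYS439", "DYS448", "DYS456",
    "DYS458", "DYS635", "YGATAH4")
}

#' The 21-haplogroup inventory
#'
#' Y-chromosomal haplogroup labels observed in the packaged Tamil Nadu survey,
#' in the column order of the published frequency table.
#'
#' @return Character vector of 21 haplogroup labels.
#' @export
haplogroup_inventory <- function() {
  c("C-M130", "E-M96", "F-M89", "G-M201", "H-M69", "H1-M52", "H1a-M197",
    "H2-Apt", "J-M304", "J2-M172", "J2a1-M47", "J2a3-M68", "K-M9", "L1-M27",
    "L3-M357", "O-M175", "P-M45", "Q-M242", "R-M207", "R1a1-M17", "R2-M124")
}

# Sentinel for a missing STR allele in files; NA inside R.
.missing_allele <- -9L

#' Construct a haplotype table
#'
#' A haplotype table is a tibble with one row per sampled Y chromosome:
#' `sample_id`, `population`, optional `group`, `haplogroup`, and one integer
#' column of repeat counts per STR locus. It is the unit of all STR-based
#' analyses in the package.
#'
#' @param x Data frame with columns `sample_id`, `population`, `haplogroup`,
#'   optionally `group`, and the locus columns.
#' @param loci Character vector of locus column names (default [ystr_loci()]).
#' @param inventory Allowed haplogroup labels; records outside it are an error.
#'   `NULL` skips the check.
#' @return A `hap_tbl` tibble.
#' @export
haplotype_table <- function(x, loci = ystr_loci(), inventory = NULL) {
  x <- tibble::as_tibble(x)
  need <- c("sample_id", "population", "haplogroup")
  miss <- setdiff(need, names(x))
  if (length(miss) > 0) {
    abort(sprintf("haplotype table is missing column(s): %s",
                  paste(miss, collapse = ", ")), class = "ystrata_format_error")
  }
  miss_loci <- setdiff(loci, names(x))
  if (length(miss_loci) > 0) {
    abort(sprintf("expected %d loci; missing locus column(s): %s",
                  length(loci), paste(miss_loci, collapse = ", ")),
          class = "ystrata_format_error")
  }
  if (!"group" %in% names(x)) x$group <- NA_character_
  x$group <- as.character(x$group)
  for (l in loci) {
    v <- x[[l]]
    if (!is.numeric(v)) {
      abort(sprintf("locus %s is not numeric", l), class = "ystrata_format_error")
    }
    v[v == .missing_allele] <- NA_integer_
    vi <- as.integer(round(v))
    if (any(abs(v - vi) > 1e-9, na.rm = TRUE)) {
      bad <- which(abs(v - vi) > 1e-9)[1]
      abort(sprintf("non-integer allele at locus %s, record %d", l, bad),
            class = "ystrata_record_error")
    }
    out_of_range <- !is.na(vi) & (vi < 5L | vi > 50L)
    if (any(out_of_range)) {
      abort(sprintf("allele out of range [5, 50] at locus %s, record %d",
                    l, which(out_of_range)[1]), class = "ystrata_record_error")
    }
    x[[l]] <- vi
  }
  if (!is.null(inventory)) {
    bad <- setdiff(unique(x$haplogroup), inventory)
    if (length(bad) > 0) {
      abort(sprintf("haplogroup label(s) outside inventory: %s",
                    paste(bad, collapse = ", ")), class = "ystrata_record_error")
    }
  }
  x <- x[, c("sample_id", "population", "group", "haplogroup", loci)]
  attr(x, "loci") <- loci
  class(x) <- c("hap_tbl", class(x))
  x
}

#' @export
print.hap_tbl <- function(x, ...) {
  cat(sprintf("# Haplotype table: %d chromosomes, %d populations, %d loci\n",
              nrow(x), dplyr::n_distinct(x$population), length(loci_of(x))))
  NextMethod()
}

#' Locus names of a haplotype table
#' @param x A `hap_tbl`.
#' @return Character vector of locus column names.
#' @export
loci_of <- function(x) {
  l <- attr(x, "loci")
  if (is.null(l)) l <- intersect(ystr_loci(), names(x))
  l
}

#' Per-population census of a haplotype table
#' @param x A `hap_tbl`.
#' @return Tibble with `population` and `n`.
#' @export
census <- function(x) {
  dplyr::count(tibble::as_tibble(x), .data$population, name = "n")
}

#' Drop records with missing STR alleles
#'
#' All STR-based operations either exclude incomplete records (the default,
#' with the number excluded reported as an attribute) or fail loudly.
#'
#' @param x A `hap_tbl`.
#' @param on_missing `"exclude"` (default) or `"error"`.
#' @return The filtered table; attribute `n_excluded` counts dropped records.
#' @export
drop_incomplete <- function(x, on_missing = c("exclude", "error")) {
  on_missing <- match.arg(on_missing)
  loci <- loci_of(x)
  ok <- stats::complete.cases(x[, loci])
  if (all(ok)) {
    attr(x, "n_excluded") <- 0L
    return(x)
  }
  if (on_missing == "error") {
    abort(sprintf("%d record(s) with missing STR alleles", sum(!ok)),
          class = "ystrata_missing_error")
  }
  out <- x[ok, ]
  attr(out, "loci") <- loci
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Read a haplotype table from tab-delimited text
#'
#' The format is one record per line, UTF-8, `#` comment lines, with a header
#' naming `sample_id`, `population`, optional `group`, `haplogroup`, and the
#' 17 locus columns. Missing alleles may be encoded as `-9` or `NA`; they are
#' flagged, not silently dropped.
#'
#' @param path File path.
#' @param loci Expected locus columns (default [ystr_loci()]).
#' @return A `hap_tbl`.
#' @export
read_haplotype_table <- function(path, loci = ystr_loci()) {
  x <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                         stringsAsFactors = FALSE)
  haplotype_table(x, loci = loci)
}

#' Write a haplotype table to tab-delimited text
#'
#' @param x A `hap_tbl`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(x, path) {
  out <- tibble::as_tibble(x)
  for (l in loci_of(x)) {
    v <- out[[l]]
    v[is.na(v)] <- .missing_allele
    out[[l]] <- v
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' Tabulate a haplotype table into a count matrix
#'
#' @param x A `hap_tbl`.
#' @param haplogroups Column inventory to tabulate against (default: labels
#'   present in the data, sorted).
#' @return An `hg_counts` tibble (see [count_matrix()]).
#' @export
count_haplogroups <- function(x, haplogroups = NULL) {
  if (is.null(haplogroups)) haplogroups <- sort(unique(x$haplogroup))
  tab <- table(factor(x$population, levels = unique(x$population)),
               factor(x$haplogroup, levels = haplogroups))
  m <- matrix(as.integer(tab), nrow = nrow(tab), dimnames = dimnames(tab))
  count_matrix(tibble::tibble(population = rownames(m)) |>
                 dplyr::bind_cols(tibble::as_tibble(m)))
}
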
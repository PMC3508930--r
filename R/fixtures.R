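# Packaged Tamil Nadu survey fixture: 31 populations x 21 haplogroups.

#' Published haplogroup frequencies for 31 Tamil Nadu populations
#'
#' The curated percent-frequency table for the 31 endogamous populations
#' (N = 1680 Y chromosomes, 21 haplogroups), with per-population sample size,
#' major population group (MPG) membership and published Nei gene diversity.
#' See the provenance file shipped next to the CSV
#' (`system.file("extdata", "tn_hg_freq_provenance.md", package = "ystrata")`)
#' for how the transcription was curated and checksummed.
#'
#' @return Tibble with `population`, `group`, `N`, the 21 haplogroup percent
#'   columns, `gene_diversity` and `gene_diversity_sd`.
#' @export
tn_hg_frequencies <- function() {
  path <- system.file("extdata", "tn_hg_freq.csv", package = "ystrata")
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Published pooled group rows of the Tamil Nadu frequency table
#'
#' The seven printed group-total rows, used to validate the per-population
#' curation (pooled member counts must reproduce them).
#'
#' @return Tibble with `group`, `N`, the 21 haplogroup percent columns and the
#'   published pooled gene diversity.
#' @export
tn_hg_group_frequencies <- function() {
  path <- system.file("extdata", "tn_hg_freq_groups.csv", package = "ystrata")
  tibble::as_tibble(utils::read.csv(path, check.names = FALSE))
}

#' Reconstructed haplogroup counts for the 31 Tamil Nadu populations
#'
#' Integer counts recovered from the published percentages and per-population
#' sample sizes via [counts_from_frequencies()]; every row passes its row-sum
#' checksum, and the pooled totals reproduce the printed group and grand-total
#' rows.
#'
#' @return An `hg_counts` tibble (31 rows x 21 haplogroups, total N = 1680).
#' @export
tn_hg_counts <- function() {
  f <- tn_hg_frequencies()
  hg <- haplogroup_inventory()
  cnt <- t(mapply(function(i) counts_from_frequencies(as.numeric(f[i, hg]),
                                                      f$N[i]),
                  seq_len(nrow(f))))
  colnames(cnt) <- hg
  count_matrix(dplyr::bind_cols(tibble::tibble(population = f$population),
                                tibble::as_tibble(cnt)))
}

#' Population groupings of the Tamil Nadu survey
#'
#' The alternative partitions of the 31 populations compared by the structure
#' analyses: the seven subsistence-based major population groups (`mpg`), the
#' tribe / non-tribe dichotomy (`tribe_caste`), the caste-rank hierarchy with
#' tribes kept apart (`rank`), and the sampled district (`district`).
#'
#' @return Named list of `grouping` objects.
#' @export
tn_groupings <- function() {
  f <- tn_hg_frequencies()
  tribal <- c("HTF", "HTC", "HTK")
  rank <- c(
    "Paniya" = "tribe", "Paliyan" = "tribe", "Pulayar" = "tribe",
    "Irula" = "tribe", "Kadar" = "tribe", "Kanikaran" = "tribe",
    "Thoda" = "tribe", "Kota" = "tribe", "Betta Kurumba" = "tribe",
    "Kattunaickan" = "tribe", "Kurumba" = "tribe", "Mullukurumba" = "tribe",
    "Parayar NTN" = "low", "Parayar" = "low", "Pallar" = "low",
    "Paravar" = "low", "Yadhava" = "middle", "Vanniyar" = "middle",
    "Vanniyar NTN" = "middle", "Nadar TNV" = "middle", "Nadar Cape" = "middle",
    "Piramalai Kallar" = "middle", "Maravar" = "middle", "Valayar" = "low",
    "Tamil Jains" = "middle", "Ezhava" = "middle", "Mukkuvar" = "low",
    "Sourashtra" = "middle", "Brahacharanam" = "high", "Iyengar" = "high",
    "Vadama" = "high")
  district <- c(
    "Paniya" = "Nilgiris", "Paliyan" = "Theni", "Pulayar" = "Coimbatore",
    "Irula" = "Nilgiris", "Kadar" = "Coimbatore", "Kanikaran" = "Tirunelveli",
    "Thoda" = "Nilgiris", "Kota" = "Nilgiris", "Betta Kurumba" = "Nilgiris",
    "Kattunaickan" = "Nilgiris", "Kurumba" = "Nilgiris",
    "Mullukurumba" = "Nilgiris", "Parayar NTN" = "N.Arcot",
    "Parayar" = "Madurai", "Pallar" = "Tirunelveli", "Paravar" = "Trichendur",
    "Yadhava" = "Madurai", "Vanniyar" = "Erode", "Vanniyar NTN" = "N.Arcot",
    "Nadar TNV" = "Tirunelveli", "Nadar Cape" = "Kanyakumari",
    "Piramalai Kallar" = "Madurai", "Maravar" = "Ramnad",
    "Valayar" = "Madurai", "Tamil Jains" = "N.Arcot",
    "Ezhava" = "Kanyakumari", "Mukkuvar" = "Kanyakumari",
    "Sourashtra" = "Madurai", "Brahacharanam" = "Tirunelveli",
    "Iyengar" = "Madurai", "Vadama" = "Tirunelveli")
  list(
    mpg = grouping(f$population, f$group, name = "7-MPG"),
    tribe_caste = grouping(
      f$population, ifelse(f$group %in% tribal, "tribe", "caste"),
      name = "tribe-caste"),
    rank = grouping(f$population, unname(rank[f$population]),
                    name = "TR-UP-MID-LOW"),
    district = grouping(f$population, unname(district[f$population]),
                        name = "district"))
}

#' Lineage-class haplogroup sets
#'
#' Default partition of the 21-haplogroup inventory into putatively Indian
#' autochthonous lineages (late-Pleistocene in-situ origin), putatively
#' non-autochthonous lineages (Holocene gene flow from western Eurasia) and an
#' unclassified remainder. The sets are configuration, not constants: the
#' classification is debated, and analyses take the set as an argument so the
#' choice stays auditable.
#'
#' @return Named list of character vectors `autochthonous`,
#'   `non_autochthonous`, `unclassified`.
#' @export
lineage_classes <- function() {
  autoch <- c("C-M130", "F-M89", "H-M69", "H1-M52", "H1a-M197", "H2-Apt",
              "L1-M27", "R1a1-M17", "R2-M124")
  non <- c("E-M96", "G-M201", "J2-M172", "J2a1-M47", "J2a3-M68", "L3-M357")
  list(autochthonous = autoch,
       non_autochthonous = non,
       unclassified = setdiff(haplogroup_inventory(), c(autoch, non)))
}
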
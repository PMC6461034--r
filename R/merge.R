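#' Merge phosphopeptide and phosphosite tables
#'
#' Joins the deconvoluted peptide table (from [read_phosphopeptides()]) with
#' the class I site table (from [read_phosphosites()]) on gene symbol and
#' peptide sequence, producing the non-redundant site-peptide evidence table
#' that all scoring consumes. For each (site, gene) combination with several
#' candidate protein accessions, only the best-annotated accession is
#' retained; input symbols are first normalized through `symbol_map` so that
#' synonymous rows collapse. Sites whose peptide is absent from the peptide
#' table are dropped silently and reported via a message.
#'
#' @param peptides Tidy peptide tibble (`gene_symbol`, `peptide`, `n_phospho`,
#'   `sample`, `quant`).
#' @param sites Site tibble (`accession`, `gene_symbol`, `position`,
#'   `residue`, `localization_prob`, `peptide`).
#' @param accession_priority Optional tibble (`accession`, `priority`) ranking
#'   accessions by annotation quality (smaller is better, e.g. reviewed
#'   canonical entries first). Accessions without a priority rank last; final
#'   ties break to the lexicographically smallest accession.
#' @param symbol_map Optional two-column tibble (`symbol`, `official`) mapping
#'   input symbols to official gene symbols; see [map_symbols()].
#' @return A tibble with one row per (site, gene, peptide, sample): all site
#'   fields plus `n_phospho`, `n_inferred_sites` (distinct class I sites
#'   linked to the peptide) and the per-sample `sample`/`quant` pair.
#' @export
merge_site_peptide <- function(peptides, sites, accession_priority = NULL,
                               symbol_map = NULL) {
  if (!is.null(symbol_map)) {
    peptides <- mutate(peptides,
                       gene_symbol = map_symbols(.data$gene_symbol, symbol_map))
    sites <- mutate(sites,
                    gene_symbol = map_symbols(.data$gene_symbol, symbol_map))
  }

  pep_info <- distinct(peptides, .data$gene_symbol, .data$peptide,
                       .data$n_phospho)
  matched <- inner_join(sites, pep_info,
                        by = c("gene_symbol", "peptide"),
                        relationship = "many-to-many")

  n_dropped <- nrow(anti_join(
    distinct(sites, .data$gene_symbol, .data$position, .data$residue,
             .data$peptide),
    pep_info,
    by = c("gene_symbol", "peptide")
  ))
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " site record(s) without a matching ",
                  "phosphopeptide were dropped"))
  }
  if (nrow(matched) == 0) {
    return(tibble(
      gene_symbol = character(), position = integer(), residue = character(),
      accession = character(), localization_prob = numeric(),
      peptide = character(), n_phospho = integer(),
      n_inferred_sites = integer(), sample = character(), quant = numeric()
    ))
  }

  # Retain one accession per (site, gene): best annotation rank, then
  # lexicographically smallest accession.
  if (is.null(accession_priority)) {
    accession_priority <- tibble(accession = character(), priority = numeric())
  }
  matched <- matched |>
    left_join(accession_priority, by = "accession") |>
    mutate(priority = ifelse(is.na(.data$priority), Inf, .data$priority)) |>
    group_by(.data$gene_symbol, .data$position, .data$residue,
             .data$peptide) |>
    arrange(.data$priority, .data$accession, .by_group = TRUE) |>
    slice_head(n = 1) |>
    ungroup() |>
    select(-"priority") |>
    distinct()

  matched <- matched |>
    group_by(.data$gene_symbol, .data$peptide) |>
    mutate(n_inferred_sites = dplyr::n_distinct(.data$position,
                                                .data$residue)) |>
    ungroup()

  quant <- select(peptides, "gene_symbol", "peptide", "sample", "quant") |>
    distinct()
  matched |>
    inner_join(quant, by = c("gene_symbol", "peptide"),
               relationship = "many-to-many") |>
    select("gene_symbol", "position", "residue", "accession",
           "localization_prob", "peptide", "n_phospho", "n_inferred_sites",
           "sample", "quant") |>
    arrange(.data$gene_symbol, .data$position, .data$peptide, .data$sample)
}

#' Write or re-read a merged site-peptide table
#'
#' Plain tab-separated serialization of the merged evidence table; reading a
#' written table reproduces it exactly.
#'
#' @param merged Merged tibble from [merge_site_peptide()].
#' @param path File path.
#' @return `write_merged_table()` returns `path` invisibly;
#'   `read_merged_table()` returns the tibble.
#' @export
write_merged_table <- function(merged, path) {
  readr::write_tsv(merged, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_merged_table
#' @export
read_merged_table <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_symbol = readr::col_character(),
    position = readr::col_integer(),
    residue = readr::col_character(),
    accession = readr::col_character(),
    localization_prob = readr::col_double(),
    peptide = readr::col_character(),
    n_phospho = readr::col_integer(),
    n_inferred_sites = readr::col_integer(),
    sample = readr::col_character(),
    quant = readr::col_double()
  ), progress = FALSE)
}
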
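#' Column-name maps for the MaxQuant-dialect input tables
#'
#' The readers locate fields by header name through these maps, so any
#' tab-separated file with equivalent content can be used by overriding
#' individual entries. Sample quantification columns are always matched by the
#' exact header strings passed as `sample_ids`; there is no fuzzy matching.
#'
#' @param ... Named overrides, e.g. `genes = "Gene Symbols"`.
#' @return A named list mapping logical field names to header strings.
#' @export
#' @examples
#' peptide_columns(genes = "Gene Symbols")
peptide_columns <- function(...) {
  defaults <- list(
    sequence = "Sequence",
    genes = "Gene names",
    n_phospho = "Phospho (STY)",
    reverse = "Reverse",
    contaminant = "Potential contaminant"
  )
  utils::modifyList(defaults, list(...))
}

#' @rdname peptide_columns
#' @export
site_columns <- function(...) {
  defaults <- list(
    proteins = "Proteins",
    genes = "Gene names",
    position = "Position",
    residue = "Amino acid",
    localization_prob = "Localization prob",
    peptide = "Peptide"
  )
  utils::modifyList(defaults, list(...))
}

#' Read a quantified phosphopeptide table
#'
#' Reads a MaxQuant `modificationSpecificPeptides`-style tab-separated table
#' and returns a tidy (long) tibble with one row per peptide, gene symbol and
#' sample. Rows linked to multiple gene symbols (`;`-separated) are
#' deconvoluted into one row per symbol; rows without any phospho modification
#' are dropped, as are rows flagged as decoy or contaminant when such columns
#' exist.
#'
#' @param path Path to the tab-separated peptide table.
#' @param sample_ids Character vector of quantification column headers, one
#'   per sample; matched exactly.
#' @param quant_mode `"counts"` for spectral counts (integers) or
#'   `"intensity"` for intensity-based quantification. The same downstream
#'   formulas apply in either mode.
#' @param columns Field-name map from [peptide_columns()].
#' @return A tibble with columns `gene_symbol`, `peptide`, `n_phospho`,
#'   `sample`, `quant`.
#' @export
read_phosphopeptides <- function(path, sample_ids,
                                 quant_mode = c("counts", "intensity"),
                                 columns = peptide_columns()) {
  quant_mode <- match.arg(quant_mode)
  tbl <- read_tsv_chr(path)
  required <- columns[c("sequence", "genes", "n_phospho")]
  require_columns(tbl, c(required, as.list(sample_ids)), path)

  n_phospho <- parse_numeric(tbl[[columns$n_phospho]], columns$n_phospho,
                             blank_as = 0)
  keep <- n_phospho >= 1
  for (fld in c("reverse", "contaminant")) {
    col <- columns[[fld]]
    if (!is.null(col) && col %in% names(tbl)) {
      keep <- keep & !is_flagged(tbl[[col]])
    }
  }

  quant <- lapply(sample_ids, function(s) {
    q <- parse_numeric(tbl[[s]], s, blank_as = 0)
    if (any(q < 0, na.rm = TRUE)) {
      abort(paste0("negative quantification value in column '", s, "'"))
    }
    q
  })
  names(quant) <- sample_ids

  genes <- split_multi(tbl[[columns$genes]])
  rows <- purrr::map(which(keep), function(i) {
    gs <- genes[[i]]
    if (length(gs) == 0) {
      return(NULL)
    }
    tidyr::expand_grid(gene_symbol = gs, sample = sample_ids) |>
      mutate(
        peptide = tbl[[columns$sequence]][i],
        n_phospho = as.integer(n_phospho[i]),
        quant = unname(vapply(.data$sample, function(s) quant[[s]][i],
                              numeric(1)))
      )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      gene_symbol = character(), peptide = character(),
      n_phospho = integer(), sample = character(), quant = numeric()
    ))
  }
  out |>
    select("gene_symbol", "peptide", "n_phospho", "sample", "quant") |>
    arrange(.data$gene_symbol, .data$peptide, .data$sample)
}

#' Read a phosphosite table and keep class I sites
#'
#' Reads a MaxQuant `Phospho (STY)Sites`-style tab-separated table. Rows
#' linking one site to multiple protein accessions or multiple peptides are
#' split into separate records, and only class I sites — localization
#' probability strictly greater than 0.75 — are retained.
#'
#' @param path Path to the tab-separated site table.
#' @param columns Field-name map from [site_columns()].
#' @param class1_threshold Localization-probability cutoff; a site is kept iff
#'   its probability exceeds this value. Default 0.75.
#' @return A tibble with columns `accession`, `gene_symbol`, `position`,
#'   `residue`, `localization_prob`, `peptide`.
#' @export
read_phosphosites <- function(path, columns = site_columns(),
                              class1_threshold = 0.75) {
  tbl <- read_tsv_chr(path)
  require_columns(tbl, columns[c("proteins", "genes", "position", "residue",
                                 "localization_prob", "peptide")], path)

  prob <- parse_numeric(tbl[[columns$localization_prob]],
                        columns$localization_prob)
  if (any(prob < 0 | prob > 1, na.rm = TRUE)) {
    abort("localization probability outside [0, 1]")
  }
  pos <- parse_numeric(tbl[[columns$position]], columns$position)
  if (any(pos < 1, na.rm = TRUE)) {
    abort("site position must be a 1-based residue index")
  }
  res <- trimws(tbl[[columns$residue]])
  if (!all(res %in% c("S", "T", "Y"))) {
    abort("site residue must be one of S, T, Y")
  }

  keep <- which(!is.na(prob) & prob > class1_threshold)
  accs <- split_multi(tbl[[columns$proteins]])
  genes <- split_multi(tbl[[columns$genes]])
  peps <- split_multi(tbl[[columns$peptide]])

  rows <- purrr::map(keep, function(i) {
    if (length(accs[[i]]) == 0 || length(genes[[i]]) == 0 ||
        length(peps[[i]]) == 0) {
      return(NULL)
    }
    tidyr::expand_grid(
      accession = accs[[i]],
      gene_symbol = genes[[i]],
      peptide = peps[[i]]
    ) |>
      mutate(
        position = as.integer(pos[i]),
        residue = res[i],
        localization_prob = prob[i]
      )
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    return(tibble(
      accession = character(), gene_symbol = character(),
      position = integer(), residue = character(),
      localization_prob = numeric(), peptide = character()
    ))
  }
  out |>
    select("accession", "gene_symbol", "position", "residue",
           "localization_prob", "peptide") |>
    distinct() |>
    arrange(.data$gene_symbol, .data$position, .data$accession)
}
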
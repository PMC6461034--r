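#' Normalize gene symbols through an official-symbol mapping
#'
#' Many-to-one mapping of input symbols (aliases, outdated names) to official
#' gene symbols. Symbols already present as an official symbol pass through
#' silently; symbols found in neither column pass through unchanged with a
#' single aggregated warning.
#'
#' @param symbols Character vector of gene symbols.
#' @param mapping Two-column tibble (`symbol`, `official`).
#' @return Character vector of normalized symbols, same length as `symbols`.
#' @export
#' @examples
#' map_symbols(c("ERK1", "ABL1"),
#'             tibble::tibble(symbol = "ERK1", official = "MAPK3"))
map_symbols <- function(symbols, mapping) {
  if (is.null(mapping) || nrow(mapping) == 0) {
    return(symbols)
  }
  idx <- match(symbols, mapping$symbol)
  out <- ifelse(is.na(idx), symbols, mapping$official[idx])
  unknown <- unique(symbols[is.na(idx) & !(symbols %in% mapping$official)])
  if (length(unknown) > 0) {
    warn(paste0(length(unknown), " gene symbol(s) not in the mapping were ",
                "passed through unchanged: ",
                paste(head(unknown, 5), collapse = ", "),
                if (length(unknown) > 5) ", ..." else ""))
  }
  out
}

#' @rdname peptide_columns
#' @export
psp_columns <- function(...) {
  defaults <- list(
    kinase = "GENE",
    kin_organism = "KIN_ORGANISM",
    substrate = "SUB_GENE",
    sub_organism = "SUB_ORGANISM",
    site = "SUB_MOD_RSD"
  )
  utils::modifyList(defaults, list(...))
}

#' @rdname peptide_columns
#' @export
networkin_columns <- function(...) {
  defaults <- list(
    substrate = "substrate",
    position = "position",
    residue = "residue",
    kinase = "id",
    score = "networkin_score",
    tree = "tree",
    string_id = "string_identifier"
  )
  utils::modifyList(defaults, list(...))
}

#' Read curated kinase-substrate relations (PhosphoSitePlus dialect)
#'
#' Parses a `Kinase_Substrate_Dataset`-style tab-separated table. When
#' organism columns exist, only human-human relations are kept. The modified
#' residue field (e.g. `Y416`) is split into residue letter and 1-based
#' position.
#'
#' @param path Path to the relations table.
#' @param columns Field-name map from [psp_columns()].
#' @return A relations tibble with columns `kinase_symbol`,
#'   `substrate_symbol`, `position`, `residue`, `source` (`"PSP"`), `score`
#'   (`NA`).
#' @export
read_psp_relations <- function(path, columns = psp_columns()) {
  tbl <- read_tsv_chr(path)
  require_columns(tbl, columns[c("kinase", "substrate", "site")], path)
  for (fld in c("kin_organism", "sub_organism")) {
    col <- columns[[fld]]
    if (!is.null(col) && col %in% names(tbl)) {
      tbl <- tbl[tolower(trimws(tbl[[col]])) == "human", , drop = FALSE]
    }
  }
  site <- trimws(tbl[[columns$site]])
  ok <- grepl("^[STY][0-9]+$", site)
  if (!all(ok)) {
    abort(paste0("unparsable modified-residue field at data row ",
                 which(!ok)[1], ": '", site[which(!ok)[1]], "'"))
  }
  tibble(
    kinase_symbol = toupper(trimws(tbl[[columns$kinase]])),
    substrate_symbol = toupper(trimws(tbl[[columns$substrate]])),
    position = as.integer(sub("^[STY]", "", site)),
    residue = substr(site, 1, 1),
    source = "PSP",
    score = NA_real_
  ) |>
    distinct(.data$kinase_symbol, .data$substrate_symbol, .data$position,
             .data$residue, .keep_all = TRUE)
}

#' Filter kinase predictions to high-confidence relations
#'
#' Applies the prediction filter to a table of per-site kinase predictions: a
#' prediction is kept iff its score is at least `score_floor` (default 2.0)
#' and, in addition, exceeds `rel_fraction` (default 90%) of the maximum score
#' among predictions for that exact substrate site. Predictions whose STRING
#' identifier is `ENSP00000376688` are attributed to LYN (the identifier is
#' mis-assigned to LCA5 upstream).
#'
#' @param predictions Tibble with columns `substrate_symbol`, `position`,
#'   `residue`, `kinase_symbol`, `score` and optionally `string_identifier`.
#' @return A relations tibble (`kinase_symbol`, `substrate_symbol`,
#'   `position`, `residue`, `source` = `"NWK"`, `score`).
#' @export
filter_networkin <- function(predictions, score_floor = 2.0,
                             rel_fraction = 0.9) {
  if (nrow(predictions) == 0) {
    return(tibble(
      kinase_symbol = character(), substrate_symbol = character(),
      position = integer(), residue = character(), source = character(),
      score = numeric()
    ))
  }
  if ("string_identifier" %in% names(predictions)) {
    predictions <- mutate(
      predictions,
      kinase_symbol = if_else(.data$string_identifier == "ENSP00000376688",
                              "LYN", .data$kinase_symbol)
    )
  }
  kept <- predictions |>
    group_by(.data$substrate_symbol, .data$position, .data$residue) |>
    filter(.data$score >= score_floor,
           .data$score > rel_fraction * max(.data$score)) |>
    ungroup()
  if (nrow(kept) == 0) {
    return(tibble(
      kinase_symbol = character(), substrate_symbol = character(),
      position = integer(), residue = character(), source = character(),
      score = numeric()
    ))
  }
  kept |>
    mutate(
      kinase_symbol = toupper(.data$kinase_symbol),
      substrate_symbol = toupper(.data$substrate_symbol),
      source = "NWK"
    ) |>
    group_by(.data$kinase_symbol, .data$substrate_symbol, .data$position,
             .data$residue) |>
    summarise(source = "NWK", score = max(.data$score), .groups = "drop") |>
    select("kinase_symbol", "substrate_symbol", "position", "residue",
           "source", "score") |>
    arrange(.data$substrate_symbol, .data$position, .data$kinase_symbol)
}

#' Read kinase predictions (NetworKIN output dialect)
#'
#' Reads a NetworKIN-style output table, restricts it to kinase predictions
#' (`tree == "KIN"`), and applies [filter_networkin()].
#'
#' @param path Path to the predictions table.
#' @param columns Field-name map from [networkin_columns()].
#' @inheritParams filter_networkin
#' @return A filtered relations tibble, as for [filter_networkin()].
#' @export
read_networkin <- function(path, columns = networkin_columns(),
                           score_floor = 2.0, rel_fraction = 0.9) {
  tbl <- read_tsv_chr(path)
  require_columns(tbl, columns[c("substrate", "position", "kinase", "score",
                                 "tree")], path)
  tbl <- tbl[trimws(tbl[[columns$tree]]) == "KIN", , drop = FALSE]
  residue <- if (columns$residue %in% names(tbl)) {
    trimws(tbl[[columns$residue]])
  } else {
    NA_character_
  }
  preds <- tibble(
    substrate_symbol = trimws(tbl[[columns$substrate]]),
    position = as.integer(parse_numeric(tbl[[columns$position]],
                                        columns$position)),
    residue = residue,
    kinase_symbol = trimws(tbl[[columns$kinase]]),
    score = parse_numeric(tbl[[columns$score]], columns$score),
    string_identifier = if (columns$string_id %in% names(tbl)) {
      trimws(tbl[[columns$string_id]])
    } else {
      NA_character_
    }
  )
  filter_networkin(preds, score_floor = score_floor,
                   rel_fraction = rel_fraction)
}

#' Read activation-loop peptide annotations
#'
#' Plain tab-separated list of tryptic peptides lying in kinase activation
#' segments (one row per gene/peptide pair, including missed-cleavage
#' variants). Matching downstream is by exact (gene symbol, peptide sequence).
#'
#' @param path Path to the annotation table with `gene` and `peptide` columns.
#' @return A tibble (`gene_symbol`, `peptide`).
#' @export
read_activation_loops <- function(path) {
  tbl <- read_tsv_chr(path)
  require_columns(tbl, list("gene", "peptide"), path)
  tibble(
    gene_symbol = toupper(trimws(tbl$gene)),
    peptide = trimws(tbl$peptide)
  ) |>
    filter(nzchar(.data$peptide)) |>
    distinct()
}

#' Read the protein-kinase catalog
#'
#' One established protein-kinase gene symbol per line (KinBase-style).
#'
#' @param path Path to the catalog file.
#' @return A character vector of upper-case kinase gene symbols.
#' @export
read_kinome <- function(path) {
  syms <- toupper(trimws(readLines(path, warn = FALSE)))
  syms <- unique(syms[nzchar(syms)])
  if (length(syms) == 0) {
    abort("kinome catalog is empty")
  }
  sort(syms)
}

#' Bundle the annotation resources into one knowledgebase object
#'
#' Collects the curated (PSP) and predicted (NWK) kinase-substrate relations,
#' the kinase catalog, activation-loop annotations and an optional
#' gene-symbol mapping; all symbols are normalized through the mapping at
#' construction time.
#'
#' @param psp Relations tibble from [read_psp_relations()].
#' @param networkin Relations tibble from [read_networkin()] /
#'   [filter_networkin()].
#' @param kinome Character vector of kinase symbols from [read_kinome()].
#' @param activation_loops Optional tibble from [read_activation_loops()].
#' @param symbol_map Optional (`symbol`, `official`) tibble.
#' @return An object of class `kinase_knowledgebase`: a list with elements
#'   `relations` (both sources stacked), `kinome`, `activation_loops`,
#'   `symbol_map`.
#' @export
kinase_knowledgebase <- function(psp, networkin, kinome,
                                 activation_loops = NULL, symbol_map = NULL) {
  if (length(kinome) == 0) {
    abort("kinome catalog is empty")
  }
  relations <- bind_rows(psp, networkin)
  if (!is.null(symbol_map) && nrow(relations) > 0) {
    relations <- mutate(
      relations,
      kinase_symbol = map_symbols(.data$kinase_symbol, symbol_map),
      substrate_symbol = map_symbols(.data$substrate_symbol, symbol_map)
    )
  }
  if (!is.null(symbol_map)) {
    kinome <- sort(unique(map_symbols(kinome, symbol_map)))
    if (!is.null(activation_loops)) {
      activation_loops <- mutate(
        activation_loops,
        gene_symbol = map_symbols(.data$gene_symbol, symbol_map)
      ) |> distinct()
    }
  }
  if (is.null(activation_loops)) {
    activation_loops <- tibble(gene_symbol = character(),
                               peptide = character())
  }
  structure(
    list(
      relations = relations,
      kinome = kinome,
      activation_loops = activation_loops,
      symbol_map = symbol_map
    ),
    class = "kinase_knowledgebase"
  )
}

#' @export
print.kinase_knowledgebase <- function(x, ...) {
  cat("<kinase_knowledgebase>\n")
  cat("  kinome catalog: ", length(x$kinome), " kinases\n", sep = "")
  cat("  relations:      ", sum(x$relations$source == "PSP"), " curated, ",
      sum(x$relations$source == "NWK"), " predicted\n", sep = "")
  cat("  activation-loop peptides: ", nrow(x$activation_loops), "\n",
      sep = "")
  cat("  out-of-scope kinases:     ", length(out_of_scope_kinases(x)), "\n",
      sep = "")
  invisible(x)
}

#' Kinases absent from both relation resources
#'
#' The catalog kinases with no curated and no predicted substrate relation;
#' these can never receive substrate-centric evidence and are ranked
#' separately on kinase-centric evidence alone.
#'
#' @param kb A [kinase_knowledgebase()].
#' @return Character vector of kinase symbols.
#' @export
out_of_scope_kinases <- function(kb) {
  setdiff(kb$kinome, unique(kb$relations$kinase_symbol))
}
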
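#' Normalize a kinase activity score list
#'
#' Divides every score by the maximum of the list, giving normalized kinase
#' activity scores (KAS) in (0, 1] with the top kinase at 1; ordering is
#' preserved (descending score, ties alphabetical).
#'
#' @param scores Tibble with columns `kinase_symbol` and `score`.
#' @return A tibble (`kinase_symbol`, `kas`) in descending KAS order.
#' @export
#' @examples
#' normalize_kas(tibble::tibble(kinase_symbol = c("A", "B", "C"),
#'                              score = c(10, 5, 1)))
normalize_kas <- function(scores) {
  if (nrow(scores) == 0 || max(scores$score) <= 0) {
    abort("score list must contain at least one positive score")
  }
  scores |>
    mutate(kas = .data$score / max(.data$score)) |>
    arrange(desc(.data$kas), .data$kinase_symbol) |>
    select("kinase_symbol", "kas")
}

#' Normalize drug efficacy values for one cell line
#'
#' Transforms logIC50 values by subtracting the median, multiplying by minus
#' one, and dividing by the maximum absolute value, yielding normalized
#' -logIC50 values `e` in `[-1, 1]`: high-affinity (low IC50) drugs positive,
#' low-affinity drugs negative, the median drug at zero.
#'
#' @param efficacy Tibble with columns `drug` and `log_ic50` for one cell
#'   line.
#' @return A tibble (`drug`, `e`).
#' @export
#' @examples
#' normalize_efficacy(tibble::tibble(drug = c("a", "b", "c"),
#'                                   log_ic50 = c(1, 2, 4)))
normalize_efficacy <- function(efficacy) {
  if (nrow(efficacy) < 2) {
    abort("at least two drugs are required per cell line")
  }
  e <- -(efficacy$log_ic50 - median(efficacy$log_ic50))
  m <- max(abs(e))
  if (m == 0) {
    warn("zero spread in logIC50 values; all normalized efficacies are 0")
  } else {
    e <- e / m
  }
  tibble(drug = efficacy$drug, e = e)
}

#' Kinase impact score of an activity ranking
#'
#' Sums, over the kinases in the top-`top_n` of a normalized activity list
#' and the drugs targeting them, the product of the normalized kinase
#' activity score and the drug's normalized efficacy: high-ranking kinases
#' targeted by high-affinity drugs are rewarded, kinases associated with
#' low-affinity drugs are penalized. Kinases absent from every drug's target
#' set contribute nothing.
#'
#' @param kas Normalized activity tibble from [normalize_kas()].
#' @param efficacy_norm Normalized efficacy tibble from
#'   [normalize_efficacy()] (one cell line).
#' @param targets Binary drug-kinase map as a long tibble (`drug`,
#'   `kinase_symbol`).
#' @param top_n Length of the activity list used (at least 2).
#' @return A single numeric impact score.
#' @export
kinase_impact_score <- function(kas, efficacy_norm, targets, top_n) {
  stopifnot(top_n >= 2)
  top <- slice_head(kas, n = top_n)
  hits <- top |>
    inner_join(targets, by = "kinase_symbol",
               relationship = "many-to-many") |>
    inner_join(efficacy_norm, by = "drug")
  sum(hits$kas * hits$e)
}

#' Impact-score curves over activity-list lengths
#'
#' Computes the kinase impact score for every method, sample and list length
#' in `lengths`, normalizing activity scores per (method, sample) and
#' efficacies per cell line.
#'
#' @param activity Tibble (`method`, `sample`, `cell_line`, `kinase_symbol`,
#'   `score`) of raw activity scores per ranking method.
#' @param efficacy Tibble (`cell_line`, `drug`, `log_ic50`).
#' @param targets Tibble (`drug`, `kinase_symbol`).
#' @param lengths Integer vector of list lengths (default `2:40`).
#' @return A tibble (`method`, `sample`, `cell_line`, `n`, `impact`).
#' @export
impact_curve <- function(activity, efficacy, targets, lengths = 2:40) {
  eff_norm <- efficacy |>
    group_by(.data$cell_line) |>
    dplyr::group_modify(~ normalize_efficacy(.x)) |>
    ungroup()

  groups <- distinct(activity, .data$method, .data$sample, .data$cell_line)
  purrr::pmap(groups, function(method, sample, cell_line) {
    sc <- activity[activity$method == method & activity$sample == sample, ]
    kas <- normalize_kas(sc)
    eff_cl <- eff_norm[eff_norm$cell_line == cell_line, ]
    tibble(
      method = method, sample = sample, cell_line = cell_line, n = lengths,
      impact = vapply(lengths, function(nn) {
        kinase_impact_score(kas, eff_cl, targets, nn)
      }, numeric(1))
    )
  }) |>
    bind_rows()
}

#' Compare two ranking methods by paired tests over list lengths
#'
#' For each activity-list length, performs a paired nonparametric test on
#' per-sample impact scores between two methods, and summarizes the
#' difference by the median of the per-length p-values. The default is the
#' Wilcoxon signed-rank test on per-sample paired differences (pairing over
#' samples is the operative design); an unpaired Mann-Whitney option is
#' provided. When all paired differences are zero the p-value is 1.
#'
#' @param impacts Impact tibble from [impact_curve()] holding exactly two
#'   methods.
#' @param test `"wilcoxon"` (paired signed-rank, default) or
#'   `"mann-whitney"` (unpaired).
#' @return A list with `per_length` (tibble `n`, `p_value`) and `median_p`.
#' @export
compare_methods <- function(impacts, test = c("wilcoxon", "mann-whitney")) {
  test <- match.arg(test)
  methods <- sort(unique(impacts$method))
  if (length(methods) != 2) {
    abort("impact table must contain exactly two methods")
  }
  wide <- impacts |>
    select("method", "sample", "n", "impact") |>
    tidyr::pivot_wider(names_from = "method", values_from = "impact")
  if (any(is.na(wide[[methods[1]]])) || any(is.na(wide[[methods[2]]]))) {
    abort("both methods must be scored on the same samples")
  }
  if (dplyr::n_distinct(wide$sample) < 2) {
    abort("at least two paired samples are required")
  }

  per_length <- wide |>
    group_by(.data$n) |>
    summarise(
      p_value = paired_p(.data[[methods[1]]], .data[[methods[2]]], test),
      .groups = "drop"
    )
  list(per_length = per_length, median_p = median(per_length$p_value))
}

paired_p <- function(a, b, test) {
  if (test == "wilcoxon") {
    if (all(a == b)) {
      return(1)
    }
    suppressWarnings(wilcox.test(a, b, paired = TRUE, exact = FALSE)$p.value)
  } else {
    if (all(a == b)) {
      return(1)
    }
    suppressWarnings(wilcox.test(a, b, paired = FALSE, exact = FALSE)$p.value)
  }
}

#' Read drug-efficacy inputs
#'
#' `read_drug_efficacy()` reads a TSV with columns `cell_line`, `drug`,
#' `log_ic50` (one row per cell line and drug); `read_drug_targets()` reads a
#' long-format TSV with columns `drug`, `kinase` linking each drug to the
#' kinases it targets.
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_drug_efficacy <- function(path) {
  tbl <- read_tsv_chr(path)
  require_columns(tbl, list("cell_line", "drug", "log_ic50"), path)
  out <- tibble(
    cell_line = tbl$cell_line,
    drug = tbl$drug,
    log_ic50 = parse_numeric(tbl$log_ic50, "log_ic50")
  )
  if (anyDuplicated(out[c("cell_line", "drug")]) > 0) {
    abort("each (cell_line, drug) pair must appear once")
  }
  out
}

#' @rdname read_drug_efficacy
#' @export
read_drug_targets <- function(path) {
  tbl <- read_tsv_chr(path)
  require_columns(tbl, list("drug", "kinase"), path)
  distinct(tibble(drug = tbl$drug, kinase_symbol = toupper(tbl$kinase)))
}
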
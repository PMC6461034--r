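#' INKA score and skew from the two evidence sums
#'
#' The INKA score integrates kinase-centric evidence (`c_kin`, phosphosignal
#' on the kinase's own phosphopeptides, kinome plus activation-loop arms) and
#' substrate-centric evidence (`c_sub`, phosphosignal on the kinase's
#' substrate phosphosites, curated plus predicted arms) as their geometric
#' mean: `sqrt(c_kin * c_sub)`. A non-zero score therefore requires both
#' lines of evidence.
#'
#' The skew locates the evidence balance on `[0, 1]` by normalizing the angle
#' of the evidence point onto the first quadrant: 0 when all evidence is
#' kinase-centric, 1 when all is substrate-centric, 0.5 at equal
#' contribution. With `formula = "sqrt"` (default) the angle is that of
#' `(sqrt(c_kin), sqrt(c_sub))`, i.e. `(2/pi) * atan(sqrt(c_sub / c_kin))`;
#' `formula = "ratio"` uses `(2/pi) * atan(c_sub / c_kin)`, which shares the
#' anchor values 0, 0.5 and 1. When both sums are zero the skew is undefined
#' and `NA` is returned.
#'
#' @param c_kin,c_sub Non-negative evidence sums (vectorized).
#' @param formula `"sqrt"` or `"ratio"`; see Details.
#' @return A numeric vector.
#' @export
#' @examples
#' inka_stat(4, 9)
#' skew_stat(10, 10)
inka_stat <- function(c_kin, c_sub) {
  if (any(c_kin < 0, na.rm = TRUE) || any(c_sub < 0, na.rm = TRUE)) {
    abort("evidence sums must be non-negative")
  }
  sqrt(c_kin * c_sub)
}

#' @rdname inka_stat
#' @export
skew_stat <- function(c_kin, c_sub, formula = c("sqrt", "ratio")) {
  formula <- match.arg(formula)
  if (any(c_kin < 0, na.rm = TRUE) || any(c_sub < 0, na.rm = TRUE)) {
    abort("evidence sums must be non-negative")
  }
  ratio <- c_sub / c_kin
  if (formula == "sqrt") {
    ratio <- sqrt(ratio)
  }
  out <- (2 / pi) * atan(ratio)
  out[c_kin == 0 & c_sub > 0] <- 1
  out[c_sub == 0 & c_kin > 0] <- 0
  out[c_kin == 0 & c_sub == 0] <- NA_real_
  out
}

#' Score kinase activity in each sample
#'
#' Computes, per sample and per kinase, the four component phosphosignal sums
#' (kinome, activation loop, curated substrate relations, predicted substrate
#' relations), the kinase-centric and substrate-centric totals, the INKA
#' score and the evidence skew.
#'
#' Phosphosignals follow the spectral-count weighting rules: on the
#' kinase-centric side each peptide contributes `quant * n_phospho`; on the
#' substrate-centric side each peptide's contribution to a site is
#' additionally divided by the number of phosphosites inferred for that
#' peptide, and the per-site phosphosignal (summed over peptides harboring
#' the site) is credited in full to every kinase linked to the site.
#'
#' @param merged Merged site-peptide tibble from [merge_site_peptide()].
#' @param kb A [kinase_knowledgebase()].
#' @param quant_mode `"counts"` or `"intensity"`; identical formulas apply,
#'   the mode only changes the out-of-scope evidence threshold in
#'   [rank_inka()].
#' @param skew_formula Passed to [skew_stat()].
#' @return An object of class `inka` with elements `scores` (tibble: sample,
#'   kinase, component sums, `c_kin`, `c_sub`, `inka`, `skew`, `rank`,
#'   `out_of_scope`, raw-count totals) and `components` (tidy per-evidence
#'   contribution table). Kinases appear if they have at least one observed
#'   phosphopeptide (catalog kinases) or at least one observed substrate
#'   site.
#' @seealso [rank_inka()], [add_significance()], [build_network()]
#' @export
inka <- function(merged, kb, quant_mode = c("counts", "intensity"),
                 skew_formula = c("sqrt", "ratio")) {
  quant_mode <- match.arg(quant_mode)
  skew_formula <- match.arg(skew_formula)
  stopifnot(inherits(kb, "kinase_knowledgebase"))
  if (nrow(merged) == 0) {
    abort("merged site-peptide table is empty")
  }

  engine <- build_engine(merged, kb)
  oos <- out_of_scope_kinases(kb)

  scores <- purrr::map(engine$samples, function(s) {
    counts <- engine$counts[, s]
    comp <- score_components(engine, counts)
    raw_total <- bin_sum(counts[engine$kin_pep], engine$kin_pep_kinase,
                         length(engine$kinases))
    n_nonzero <- bin_sum(as.numeric(counts[engine$kin_pep] > 0),
                         engine$kin_pep_kinase, length(engine$kinases))
    tibble(
      sample = s,
      kinase_symbol = engine$kinases,
      c_kinome = unname(comp[, "kinome"]),
      c_activation_loop = unname(comp[, "activation_loop"]),
      c_psp = unname(comp[, "psp"]),
      c_nwk = unname(comp[, "nwk"]),
      raw_count_total = raw_total,
      n_nonzero_peptides = as.integer(n_nonzero)
    )
  }) |>
    bind_rows() |>
    mutate(
      c_kin = .data$c_kinome + .data$c_activation_loop,
      c_sub = .data$c_psp + .data$c_nwk,
      inka = inka_stat(.data$c_kin, .data$c_sub),
      skew = skew_stat(.data$c_kin, .data$c_sub, skew_formula),
      out_of_scope = .data$kinase_symbol %in% oos
    ) |>
    group_by(.data$sample) |>
    arrange(desc(.data$inka), .data$kinase_symbol, .by_group = TRUE) |>
    mutate(rank = if_else(.data$inka > 0, row_number(), NA_integer_)) |>
    ungroup()

  components <- purrr::map(engine$samples,
                           function(s) component_contributions(engine, s)) |>
    bind_rows()

  structure(
    list(
      scores = scores,
      components = components,
      engine = engine,
      kb = kb,
      quant_mode = quant_mode,
      skew_formula = skew_formula
    ),
    class = "inka"
  )
}

#' @export
print.inka <- function(x, ...) {
  ns <- length(x$engine$samples)
  cat("<inka> kinase activity scores\n")
  cat("  samples: ", ns, " (", paste(head(x$engine$samples, 4),
                                     collapse = ", "),
      if (ns > 4) ", ..." else "", ")\n", sep = "")
  cat("  kinases scored: ", length(x$engine$kinases), "\n", sep = "")
  top <- x$scores |>
    filter(!is.na(.data$rank), .data$rank == 1)
  if (nrow(top) > 0) {
    cat("  top kinase per sample:\n")
    for (i in seq_len(min(nrow(top), 6))) {
      cat(sprintf("    %s: %s (INKA %.1f)\n", top$sample[i],
                  top$kinase_symbol[i], top$inka[i]))
    }
  }
  invisible(x)
}

#' Ranked kinase lists and plot sets for one sample
#'
#' Derives from a fitted [inka()] object, for one sample: the main ranking
#' (kinases with a positive INKA score, descending; ties break
#' alphabetically), membership flags for the scatter-plot set (scores at
#' least `plot_fraction` of the top score) and the top-`top_n` bar-graph set,
#' and the separate out-of-scope ranking — catalog kinases absent from both
#' relation resources, ranked on kinase-centric evidence alone, restricted to
#' a total of at least `min_count` raw spectral counts (in intensity mode: a
#' non-zero quantification in at least `min_count` peptide rows) and capped
#' at `top_n` entries.
#'
#' @param fit An [inka()] object.
#' @param sample Sample id; may be omitted when the fit holds one sample.
#' @param plot_fraction Fraction of the top INKA score below which kinases
#'   are excluded from the scatter-plot set (default 0.1).
#' @param top_n Bar-graph and out-of-scope cap (default 20).
#' @param min_count Minimum raw spectral-count total for the out-of-scope
#'   ranking (default 2).
#' @return A list with tibbles `ranking` (with `rank`, `in_plot_set`,
#'   `in_bar_graph`) and `out_of_scope`.
#' @export
rank_inka <- function(fit, sample = NULL, plot_fraction = 0.1, top_n = 20,
                      min_count = 2) {
  stopifnot(inherits(fit, "inka"))
  sample <- resolve_sample(fit, sample)
  sc <- filter(fit$scores, .data$sample == !!sample)

  ranking <- sc |>
    filter(.data$inka > 0) |>
    arrange(desc(.data$inka), .data$kinase_symbol)
  if (nrow(ranking) > 0) {
    ranking <- mutate(
      ranking,
      rank = row_number(),
      in_plot_set = .data$inka >= plot_fraction * max(.data$inka),
      in_bar_graph = .data$rank <= top_n
    )
  } else {
    ranking <- mutate(ranking, rank = integer(), in_plot_set = logical(),
                      in_bar_graph = logical())
    warn(paste0("no kinase has a positive INKA score in sample ", sample))
  }

  evidence_ok <- if (fit$quant_mode == "counts") {
    sc$raw_count_total >= min_count
  } else {
    sc$n_nonzero_peptides >= min_count
  }
  out_of_scope <- sc[sc$out_of_scope & sc$c_sub == 0 & evidence_ok, ] |>
    filter(.data$c_kin > 0) |>
    arrange(desc(.data$c_kin), .data$kinase_symbol) |>
    mutate(rank = row_number()) |>
    slice_head(n = top_n)

  list(ranking = ranking, out_of_scope = out_of_scope)
}

resolve_sample <- function(fit, sample) {
  if (is.null(sample)) {
    if (length(fit$engine$samples) != 1) {
      abort("fit contains several samples; pass `sample`")
    }
    return(fit$engine$samples)
  }
  if (!sample %in% fit$engine$samples) {
    abort(paste0("unknown sample: ", sample))
  }
  sample
}

#' Write ranked INKA results to a tab-separated file
#'
#' @param fit An [inka()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_inka_table <- function(fit, path) {
  readr::write_tsv(tidy(fit), path, progress = FALSE)
  invisible(path)
}
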
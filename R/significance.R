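#' Permute the quantification values of one sample
#'
#' Randomly reassigns the multiset of non-zero peptide quantification values
#' for a sample among the peptides that originally had a non-zero value;
#' zero-count peptides stay zero. Permutation acts at the distinct
#' (gene, peptide) level and is propagated to every site row of a peptide, so
#' duplicated site rows of one peptide stay consistent.
#'
#' @param merged Merged site-peptide tibble from [merge_site_peptide()].
#' @param sample Sample id to permute.
#' @return A tibble like `merged` with permuted `quant` for that sample.
#' @export
permute_quant <- function(merged, sample) {
  pep <- merged |>
    filter(.data$sample == !!sample) |>
    distinct(.data$gene_symbol, .data$peptide, .data$quant)
  nz <- which(pep$quant > 0)
  pep$quant_new <- pep$quant
  if (length(nz) > 1) {
    pep$quant_new[nz] <- pep$quant[nz][sample.int(length(nz))]
  }
  merged |>
    left_join(select(pep, "gene_symbol", "peptide", "quant_new"),
              by = c("gene_symbol", "peptide")) |>
    mutate(quant = if_else(.data$sample == !!sample, .data$quant_new,
                           .data$quant)) |>
    select(-"quant_new")
}

#' Randomize the kinase side of kinase-substrate relations
#'
#' Every relation keeps its substrate site but receives a kinase drawn
#' uniformly, with replacement, from the pool of distinct kinases present in
#' the pooled relation tables. The relation count is conserved.
#'
#' @param relations Relations tibble (as in a [kinase_knowledgebase()]).
#' @param pool Optional kinase pool; defaults to the distinct kinases of
#'   `relations`.
#' @return A tibble like `relations` with resampled `kinase_symbol`.
#' @export
randomize_relations <- function(relations, pool = NULL) {
  pool <- pool %||% unique(relations$kinase_symbol)
  if (length(pool) == 0) {
    abort("kinase pool is empty")
  }
  mutate(relations,
         kinase_symbol = pool[sample.int(length(pool), n(), replace = TRUE)])
}

#' Permutation p-values for INKA scores
#'
#' Builds sample- and kinase-specific null distributions by jointly (i)
#' permuting the non-zero quantification values of the sample across the
#' peptides that had non-zero values and (ii) replacing the kinase of every
#' kinase-substrate relation by a random draw from the pool of kinases
#' present in the relation tables, then rescoring. The one-sided upper-tail
#' p-value uses the add-one estimator
#' `p = (1 + #(null >= observed)) / (1 + n_iterations)`, which never returns
#' zero.
#'
#' @param fit An [inka()] object.
#' @param n_iterations Number of null iterations (default 100000).
#' @param seed Optional integer seed for reproducibility.
#' @param adjust Also report Benjamini-Hochberg adjusted p-values per sample
#'   (an extension; the raw p-values are the primary output).
#' @return The fit with `p_value` (and optionally `p_adjusted`) columns added
#'   to its score table.
#' @export
add_significance <- function(fit, n_iterations = 100000, seed = NULL,
                             adjust = FALSE) {
  stopifnot(inherits(fit, "inka"), n_iterations >= 1)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  engine <- fit$engine
  pool <- unique(fit$kb$relations$kinase_symbol)
  if (length(pool) == 0) {
    abort("kinase pool is empty: no kinase-substrate relations loaded")
  }
  n_rel <- nrow(engine$relations)
  nk <- length(engine$kinases)

  p_tbl <- purrr::map(engine$samples, function(s) {
    counts <- engine$counts[, s]
    obs_comp <- score_components(engine, counts)
    obs_inka <- inka_stat(
      obs_comp[, "kinome"] + obs_comp[, "activation_loop"],
      obs_comp[, "psp"] + obs_comp[, "nwk"]
    )
    nz <- which(counts > 0)
    exceed <- numeric(nk)
    for (i in seq_len(n_iterations)) {
      perm <- counts
      if (length(nz) > 1) {
        perm[nz] <- counts[nz][sample.int(length(nz))]
      }
      rel_kin <- match(pool[sample.int(length(pool), n_rel, replace = TRUE)],
                       engine$kinases)
      comp <- score_components(engine, perm, rel_kinase = rel_kin)
      null_inka <- inka_stat(
        comp[, "kinome"] + comp[, "activation_loop"],
        comp[, "psp"] + comp[, "nwk"]
      )
      exceed <- exceed + (null_inka >= obs_inka)
    }
    tibble(
      sample = s,
      kinase_symbol = engine$kinases,
      p_value = (1 + exceed) / (1 + n_iterations)
    )
  }) |>
    bind_rows()

  scores <- fit$scores
  scores$p_value <- NULL
  scores$p_adjusted <- NULL
  scores <- left_join(scores, p_tbl, by = c("sample", "kinase_symbol"))
  if (adjust) {
    scores <- scores |>
      group_by(.data$sample) |>
      mutate(p_adjusted = stats::p.adjust(.data$p_value, method = "BH")) |>
      ungroup()
  }
  fit$scores <- scores
  fit$n_iterations <- n_iterations
  fit
}
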
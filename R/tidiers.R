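#' Tidy and summarize fitted INKA objects
#'
#' `tidy()` returns the per-sample, per-kinase score table (one row per
#' kinase and sample, with component sums, INKA score, skew, rank and, after
#' [add_significance()], permutation p-values). `glance()` returns a one-row
#' summary of the fit.
#'
#' @param x An [inka()] object.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy inka
#' @export
tidy.inka <- function(x, ...) {
  x$scores
}

#' @rdname tidy.inka
#' @method glance inka
#' @export
glance.inka <- function(x, ...) {
  sc <- x$scores
  tibble(
    n_samples = length(x$engine$samples),
    n_kinases = length(x$engine$kinases),
    n_relations_matched = nrow(x$engine$relations),
    n_positive_scores = sum(sc$inka > 0),
    max_inka = max(sc$inka),
    quant_mode = x$quant_mode,
    skew_formula = x$skew_formula
  )
}
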
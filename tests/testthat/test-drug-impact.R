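test_that("activity normalization divides by the maximum and keeps order", {
  out <- normalize_kas(tibble::tibble(kinase_symbol = c("A", "B", "C"),
                                      score = c(10, 5, 1)))
  expect_equal(out$kas, c(1.0, 0.5, 0.1))
  expect_equal(out$kinase_symbol, c("A", "B", "C"))
  single <- normalize_kas(tibble::tibble(kinase_symbol = "A", score = 3))
  expect_equal(single$kas, 1.0)
  expect_error(normalize_kas(tibble::tibble(kinase_symbol = "A", score = 0)),
               "positive")
})

test_that("efficacy normalization follows the median-shift/negate/scale steps", {
  out <- normalize_efficacy(tibble::tibble(drug = c("a", "b", "c"),
                                           log_ic50 = c(1, 2, 4)))
  expect_equal(out$e, c(0.5, 0, -1))
  sym <- normalize_efficacy(tibble::tibble(drug = c("a", "b", "c"),
                                           log_ic50 = c(-1, 0, 1)))
  expect_equal(sym$e, c(1, 0, -1))
  # shift invariance
  shifted <- normalize_efficacy(tibble::tibble(drug = c("a", "b", "c"),
                                               log_ic50 = c(1, 2, 4) + 17))
  expect_equal(shifted$e, out$e)
  expect_warning(
    flat <- normalize_efficacy(tibble::tibble(drug = c("a", "b"),
                                              log_ic50 = c(2, 2))),
    "spread")
  expect_equal(flat$e, c(0, 0))
})

test_that("impact score equals the double-loop oracle on random instances", {
  # single-term sanity: one kinase at KAS 1 targeted by one drug at e = 0.5
  kas <- tibble::tibble(kinase_symbol = "K1", kas = 1)
  eff <- tibble::tibble(drug = "d1", e = 0.5)
  tg <- tibble::tibble(drug = "d1", kinase_symbol = "K1")
  expect_equal(kinase_impact_score(kas, eff, tg, 2), 0.5)
  expect_equal(kinase_impact_score(kas, eff, tg[0, ], 2), 0)

  for (seed in 1:40) {
    set.seed(seed)
    nk <- sample(2:5, 1)
    nd <- sample(1:5, 1)
    kas <- tibble::tibble(
      kinase_symbol = sprintf("K%d", seq_len(nk)),
      kas = sort(runif(nk), decreasing = TRUE)
    )
    eff <- tibble::tibble(drug = sprintf("d%d", seq_len(nd)),
                          e = runif(nd, -1, 1))
    tg <- tidyr::expand_grid(drug = eff$drug,
                             kinase_symbol = kas$kinase_symbol) |>
      dplyr::slice_sample(prop = 0.5)
    top_n <- sample(2:5, 1)
    expect_equal(kinase_impact_score(kas, eff, tg, top_n),
                 oracle_impact(kas, eff, tg, top_n))
  }
})

test_that("impact at top-(n+1) differs only by the added kinase's terms", {
  set.seed(99)
  kas <- tibble::tibble(kinase_symbol = sprintf("K%d", 1:6),
                        kas = sort(runif(6), decreasing = TRUE))
  eff <- tibble::tibble(drug = sprintf("d%d", 1:4), e = runif(4, -1, 1))
  tg <- tidyr::expand_grid(drug = eff$drug, kinase_symbol = kas$kinase_symbol) |>
    dplyr::slice_sample(prop = 0.4)
  for (n in 2:5) {
    delta <- kinase_impact_score(kas, eff, tg, n + 1) -
      kinase_impact_score(kas, eff, tg, n)
    added <- kas$kinase_symbol[n + 1]
    own <- sum(kas$kas[n + 1] * eff$e[eff$drug %in%
                                        tg$drug[tg$kinase_symbol == added]])
    expect_equal(delta, own)
  }
})

test_that("impact score is invariant to rescaling raw activity scores", {
  set.seed(5)
  raw <- tibble::tibble(kinase_symbol = sprintf("K%d", 1:5),
                        score = runif(5, 1, 10))
  eff <- tibble::tibble(drug = c("d1", "d2"), e = c(0.8, -0.4))
  tg <- tibble::tibble(drug = c("d1", "d2"), kinase_symbol = c("K1", "K3"))
  a <- kinase_impact_score(normalize_kas(raw), eff, tg, 4)
  b <- kinase_impact_score(
    normalize_kas(dplyr::mutate(raw, score = score * 123)), eff, tg, 4)
  expect_equal(a, b)
})

test_that("method comparison pairs samples and spans lengths 2..40", {
  panel <- simulate_drug_panel(sprintf("K%d", 1:10), drivers = "K1",
                               cell_lines = c("c1", "c2", "c3"), seed = 6)
  set.seed(7)
  act <- tidyr::expand_grid(method = c("A", "B"),
                            cell_line = c("c1", "c2", "c3")) |>
    dplyr::mutate(sample = cell_line) |>
    dplyr::reframe(
      tibble::tibble(kinase_symbol = sprintf("K%d", 1:10),
                     score = runif(10, 1, 10)),
      .by = c(method, sample, cell_line)
    )
  curves <- impact_curve(act, panel$efficacy, panel$targets, lengths = 2:40)
  expect_equal(sort(unique(curves$n)), 2:40)
  cmp <- compare_methods(curves)
  expect_equal(nrow(cmp$per_length), 39)
  expect_true(all(cmp$per_length$p_value > 0 & cmp$per_length$p_value <= 1))
  expect_equal(cmp$median_p, median(cmp$per_length$p_value))
  expect_error(compare_methods(curves[curves$method == "A", ]),
               "two methods")
})
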
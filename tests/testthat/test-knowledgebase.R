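test_that("prediction filter applies floor and relative-maximum rules", {
  preds <- tibble::tibble(
    substrate_symbol = "SUB1", position = 10L, residue = "Y",
    kinase_symbol = c("K1", "K2", "K3"),
    score = c(5.0, 4.6, 3.0)
  )
  out <- filter_networkin(preds)
  # 4.6 > 0.9 * 5.0 = 4.5 survives; 3.0 does not
  expect_setequal(out$kinase_symbol, c("K1", "K2"))

  low <- tibble::tibble(substrate_symbol = "SUB2", position = 5L,
                        residue = "S", kinase_symbol = "K1", score = 1.9)
  expect_equal(nrow(filter_networkin(low)), 0)
})

test_that("prediction filter is idempotent and keeps the per-site maximum", {
  for (seed in 1:25) {
    set.seed(seed)
    n <- sample(5:30, 1)
    preds <- tibble::tibble(
      substrate_symbol = sample(c("A", "B", "C"), n, replace = TRUE),
      position = sample(1:3, n, replace = TRUE) * 10L,
      residue = "Y",
      kinase_symbol = sample(sprintf("K%d", 1:6), n, replace = TRUE),
      score = round(runif(n, 0, 6), 2)
    )
    out <- filter_networkin(preds)
    # idempotence: re-filtering the survivors changes nothing
    back <- filter_networkin(
      dplyr::select(out, substrate_symbol, position, residue, kinase_symbol,
                    score)
    )
    expect_equal(as.data.frame(out), as.data.frame(back))
    # every site whose maximum is >= 2 keeps its maximum-scoring prediction
    per_site <- dplyr::summarise(
      dplyr::group_by(preds, substrate_symbol, position),
      mx = max(score), .groups = "drop"
    )
    for (i in seq_len(nrow(per_site))) {
      if (per_site$mx[i] >= 2) {
        kept <- out[out$substrate_symbol == per_site$substrate_symbol[i] &
                      out$position == per_site$position[i], ]
        expect_true(any(kept$score == per_site$mx[i]))
      }
    }
  }
})

test_that("mis-assigned STRING identifier is remapped to LYN", {
  preds <- tibble::tibble(
    substrate_symbol = "SUB1", position = 10L, residue = "Y",
    kinase_symbol = "LCA5", score = 3.5,
    string_identifier = "ENSP00000376688"
  )
  expect_equal(filter_networkin(preds)$kinase_symbol, "LYN")
})

test_that("curated relations are restricted to human entries", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "GENE\tKIN_ORGANISM\tSUB_GENE\tSUB_ORGANISM\tSUB_MOD_RSD",
    "SRC\thuman\tCTNNB1\thuman\tY86",
    "SRC\tmouse\tCtnnb1\tmouse\tY86",
    "ABL1\thuman\tCRK\thuman\tY221",
    "LCK\thuman\tZAP70\thuman\tY319",
    "FYN\trat\tCtnnb1\trat\tY86",
    "EGFR\thuman\tEGFR\thuman\tY1197"
  ), path)
  out <- read_psp_relations(path)
  expect_equal(nrow(out), 4)
  expect_equal(out$position[out$kinase_symbol == "SRC"], 86L)
  expect_equal(out$residue[out$kinase_symbol == "ABL1"], "Y")
})

test_that("symbol mapping normalizes aliases and passes unknowns through", {
  map <- tibble::tibble(symbol = c("ERK1", "ERK2"),
                        official = c("MAPK3", "MAPK1"))
  expect_equal(map_symbols("ERK1", map), "MAPK3")
  expect_equal(suppressWarnings(map_symbols("FAKE1", map)), "FAKE1")
  expect_warning(map_symbols(c("FAKE1", "MAPK3"), map), "FAKE1")
  expect_silent(map_symbols("MAPK3", map))
})

test_that("knowledgebase assembly validates inputs and finds out-of-scope kinases", {
  psp <- tibble::tibble(
    kinase_symbol = "K1", substrate_symbol = "S1", position = 1L,
    residue = "Y", source = "PSP", score = NA_real_
  )
  kb <- kinase_knowledgebase(psp, psp[0, ], kinome = c("K1", "K2", "K3"))
  expect_setequal(out_of_scope_kinases(kb), c("K2", "K3"))
  expect_error(kinase_knowledgebase(psp, psp[0, ], kinome = character()),
               "empty")
  path <- withr::local_tempfile()
  writeLines(character(), path)
  expect_error(read_kinome(path), "empty")
})
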
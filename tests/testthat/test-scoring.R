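test_that("INKA statistic and skew satisfy their algebraic identities", {
  expect_equal(inka_stat(4, 9), 6)
  expect_equal(inka_stat(0, 100), 0)
  expect_error(inka_stat(-1, 1), "non-negative")
  expect_error(skew_stat(1, -2), "non-negative")
  expect_true(is.na(skew_stat(0, 0)))

  set.seed(1)
  a <- runif(50, 0.01, 100)
  b <- runif(50, 0.01, 100)
  expect_equal(inka_stat(a, a), a)                      # inka(c, c) = c
  expect_equal(inka_stat(a, b), inka_stat(b, a))        # symmetry
  expect_equal(skew_stat(a, b) + skew_stat(b, a),
               rep(1, 50))                              # complementarity
  expect_true(all(skew_stat(a, b) >= 0 & skew_stat(a, b) <= 1))
  # the ratio variant shares the anchor values
  expect_equal(skew_stat(10, 10, formula = "ratio"), 0.5)
  expect_equal(skew_stat(0, 3, formula = "ratio"), 1)
})

test_that("component tables follow the phosphosignal rules on a toy case", {
  # one site harbored by 2 peptides with site-phosphosignals 2.0 and 1.0,
  # linked to one kinase: contribution must be 3.0; the kinase-centric side
  # multiplies count x n_phospho
  peptides <- tibble::tibble(
    gene_symbol = c("K1", "SUB1", "SUB1"),
    peptide = c("OWNK", "SUBAK", "SUBBK"),
    n_phospho = c(2L, 2L, 1L),
    sample = "s1",
    quant = c(3, 3, 1)
  )
  sites <- tibble::tibble(
    accession = "P1",
    gene_symbol = c("K1", "SUB1", "SUB1", "SUB1"),
    position = c(50L, 10L, 11L, 10L),
    residue = "Y",
    localization_prob = 0.9,
    peptide = c("OWNK", "SUBAK", "SUBAK", "SUBBK")
  )
  psp <- tibble::tibble(
    kinase_symbol = "K1", substrate_symbol = "SUB1", position = 10L,
    residue = "Y", source = "PSP", score = NA_real_
  )
  kb <- kinase_knowledgebase(psp, psp[0, ], kinome = "K1",
                             activation_loops = tibble::tibble(
                               gene_symbol = "K1", peptide = "OWNK"))
  merged <- merge_site_peptide(peptides, sites)
  fit <- inka(merged, kb)
  sc <- tidy(fit)
  k1 <- sc[sc$kinase_symbol == "K1", ]
  expect_equal(k1$c_kinome, 3 * 2)              # count x n_phospho
  expect_equal(k1$c_activation_loop, 6)         # same peptide, aloop subset
  # site SUB1:Y10 = SUBAK (3*2/2 = 3) + SUBBK (1*1/1 = 1) = 4
  expect_equal(k1$c_psp, 4)
  expect_equal(k1$c_kin, 12)
  expect_equal(k1$c_sub, 4)
  expect_equal(k1$inka, sqrt(48))
})

test_that("a site linked to two kinases credits each kinase in full", {
  toy <- toy_experiment(n_kinases = 2)
  kb2 <- toy$kb
  # add a second kinase claiming kinase 1's substrate site
  extra <- toy$kb$relations[1, ]
  extra$kinase_symbol <- "K02"
  kb2$relations <- dplyr::bind_rows(toy$kb$relations, extra)
  fit <- inka(toy$merged, kb2)
  sc <- tidy(fit)
  site_ps <- 1  # count 1, 1 phospho, 1 inferred site
  expect_equal(sc$c_psp[sc$kinase_symbol == "K01"], site_ps)
  # K02 keeps its own substrate and gains the shared one undivided
  expect_equal(sc$c_psp[sc$kinase_symbol == "K02"], 2 * site_ps)
})

test_that("kinases outside the catalog contribute no kinase-centric evidence", {
  toy <- toy_experiment(n_kinases = 2)
  comp <- fit <- inka(toy$merged, toy$kb)$components
  expect_false(any(grepl("^SUB", comp$kinase_symbol[comp$component ==
                                                      "Kinome"])))
  # activation-loop contributions are a subset of kinome contributions
  sc <- tidy(fit <- inka(toy$merged, toy$kb))
  expect_true(all(sc$c_activation_loop <= sc$c_kinome))
})

test_that("rankings apply the plot-fraction, top-20 and out-of-scope rules", {
  # 25 kinases, counts chosen so INKA scores are 100, 50, 10, 9.9, ...
  toy <- toy_experiment(n_kinases = 25,
                        quant = c(c(100, 50, 10, 9.9, rep(5, 21)),
                                  rep(1, 25)))
  fit <- inka(toy$merged, toy$kb)
  rk <- rank_inka(fit)
  expect_equal(nrow(rk$ranking), 25)
  expect_equal(sum(rk$ranking$in_bar_graph), 20)

  # INKA scores of exactly {100, 50, 10, 9.9}: the 10%-of-max rule keeps 3
  # (c_kin doubles the own-peptide signal because the activation-loop arm
  # counts it again, so own counts of score^2 / 2 give INKA = score)
  toy4 <- toy_experiment(n_kinases = 4,
                         quant = c(c(100, 50, 10, 9.9)^2 / 2, rep(1, 4)))
  rk4 <- rank_inka(inka(toy4$merged, toy4$kb))
  expect_equal(rk4$ranking$inka, c(100, 50, 10, 9.9))
  expect_equal(sum(rk4$ranking$in_plot_set), 3)

  # out-of-scope: drop one kinase from the relation tables
  kb2 <- toy$kb
  kb2$relations <- kb2$relations[kb2$relations$kinase_symbol != "K05", ]
  fit2 <- inka(toy$merged, kb2)
  rk2 <- rank_inka(fit2)
  expect_true("K05" %in% rk2$out_of_scope$kinase_symbol)
  expect_false("K05" %in% rk2$ranking$kinase_symbol)
  # a raw spectral-count total below 2 excludes an out-of-scope kinase
  kb3 <- kb2
  kb3$relations <- kb3$relations[kb3$relations$kinase_symbol != "K24", ]
  fit3 <- inka(toy$merged, kb3)  # K24 own count is 5 -> kept
  expect_true("K24" %in% rank_inka(fit3)$out_of_scope$kinase_symbol)
  toy_low <- toy_experiment(n_kinases = 25,
                            quant = c(rep(5, 23), 1, 5, rep(1, 25)))
  fit_low <- inka(toy_low$merged, kb3)
  expect_false("K24" %in% rank_inka(fit_low)$out_of_scope$kinase_symbol)
})

test_that("scaling all counts by k scales scores and preserves ranks and skew", {
  sim <- simulate_experiment(n_kinases = 15, seed = 11)
  merged <- merge_site_peptide(sim$tidy$peptides, sim$tidy$sites)
  kb <- kinase_knowledgebase(
    psp = sim$tidy$psp,
    networkin = filter_networkin(sim$tidy$networkin_predictions),
    kinome = sim$tidy$kinome,
    activation_loops = sim$tidy$activation_loops
  )
  fit1 <- inka(merged, kb)
  k <- 3.7
  fit2 <- inka(dplyr::mutate(merged, quant = quant * k), kb)
  a <- tidy(fit1)
  b <- tidy(fit2)
  expect_equal(b$inka, k * a$inka)
  expect_equal(b$c_kin, k * a$c_kin)
  expect_equal(b$c_sub, k * a$c_sub)
  expect_equal(b$skew, a$skew)
  expect_equal(b$rank, a$rank)
})

test_that("component aggregation matches brute-force enumeration", {
  for (seed in 1:30) {
    inst <- random_instance(seed)
    expect_true(oracle_vs_fit(inst$merged, inst$kb),
                label = paste("instance seed", seed))
  }
})
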
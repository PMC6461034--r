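test_that("regeneration with the same seed is byte-identical on disk", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_experiment(simulate_experiment(n_kinases = 8, seed = 21), d1)
  write_experiment(simulate_experiment(n_kinases = 8, seed = 21), d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)),
                     label = f)
  }
  # a different seed changes the data
  d3 <- withr::local_tempdir()
  write_experiment(simulate_experiment(n_kinases = 8, seed = 22), d3)
  expect_false(identical(readLines(file.path(d1, "peptides.tsv")),
                         readLines(file.path(d3, "peptides.tsv"))))
})

test_that("generated files parse through the readers without warnings", {
  sim <- simulate_experiment(n_kinases = 10, seed = 31)
  d <- withr::local_tempdir()
  write_experiment(sim, d)
  expect_no_warning(exp <- read_experiment(d, sim$samples))
  expect_s3_class(exp$kb, "kinase_knowledgebase")
  # the file path and the in-memory tidy path agree on every score
  fit_file <- inka(exp$merged, exp$kb)
  fit_mem <- score_simulation(sim)
  expect_equal(as.data.frame(tidy(fit_file)), as.data.frame(tidy(fit_mem)))
})

test_that("planted reader quirks are filtered out on the file path", {
  sim <- simulate_experiment(n_kinases = 6, seed = 41)
  d <- withr::local_tempdir()
  write_experiment(sim, d)
  peptides <- read_phosphopeptides(file.path(d, "peptides.tsv"),
                                   sim$samples)
  expect_false("DECOYDECOYK" %in% peptides$peptide)
  expect_false("CONTAMINANTK" %in% peptides$peptide)
  expect_false("NOPHOSPHOPEPK" %in% peptides$peptide)
  # the planted alias symbol is normalized away by the symbol map
  exp <- read_experiment(d, sim$samples)
  expect_false(any(grepl("X$", exp$merged$gene_symbol)))
  # non-human curated rows are dropped
  psp <- read_psp_relations(file.path(d, "psp.tsv"))
  expect_false(any(psp$position == 9999L))
})

test_that("zero knowledgebase coverage zeroes every INKA score", {
  sim <- simulate_experiment(n_kinases = 8, coverage = 0, seed = 51)
  fit <- score_simulation(sim)
  expect_true(all(tidy(fit)$inka == 0))
  expect_setequal(out_of_scope_kinases(fit$kb), sim$tidy$kinome)
})

test_that("driver boost inflates the driver's evidence far above typical background", {
  sim <- simulate_experiment(n_kinases = 20, seed = 61)
  fit <- score_simulation(sim)
  sc <- tidy(fit)
  driver <- sim$truth$drivers
  expect_lte(rank_of(sc$inka, sc$kinase_symbol, driver), 5)
  # boosted peptides carry clearly higher counts than the background
  pep <- dplyr::distinct(sim$tidy$peptides, peptide, quant)
  boosted <- pep$peptide %in% sim$truth$boosted_peptides
  expect_gt(mean(pep$quant[boosted]), 3 * mean(pep$quant[!boosted]))
})

test_that("intensity mode produces non-integer-scale quantities that score", {
  sim <- simulate_experiment(n_kinases = 6, quant_mode = "intensity",
                             seed = 71)
  fit <- score_simulation(sim)
  expect_equal(fit$quant_mode, "intensity")
  expect_gt(max(tidy(fit)$c_kin), 1e3)
})

test_that("invalid generator configurations are rejected", {
  expect_error(simulate_experiment(fold_boost = 0.5), "fold_boost")
  expect_error(simulate_experiment(coverage = 1.5), "coverage")
  expect_error(simulate_experiment(n_kinases = 1), "sizes")
  expect_error(simulate_experiment(drivers = "NOT_A_KINASE"), "drivers")
})
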
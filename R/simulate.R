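#' Simulate a self-contained phosphoproteomics experiment
#'
#' Generates toy-scale versions of every pipeline input — a quantified
#' phosphopeptide table, a phosphosite table, curated and predicted
#' kinase-substrate relation tables, an activation-loop peptide list, a
#' kinase catalog and a gene-symbol map — with known ground truth: one or
#' more planted driver kinases whose own peptides and substrate peptides
#' receive `fold_boost`-times higher expected counts than the background.
#'
#' Each kinase carries `peptides_per_kinase` own phosphopeptides (the first
#' annotated as an activation-loop peptide) and `sites_per_kinase` substrate
#' phosphosites on background substrate proteins. A fraction `coverage` of
#' kinases (drivers first) is present in the relation tables; the remainder
#' is deliberately excluded to exercise the out-of-scope path. Background
#' spectral counts are Poisson with mean `bg_mean`; setting
#' `dispersion_sdlog > 0` mixes in a per-peptide lognormal abundance factor
#' for overdispersed counts. In intensity mode counts are scaled by a
#' lognormal factor. Site localization probabilities
#' straddle the class I cutoff. The rendered file dialects additionally
#' plant a decoy row, a contaminant row, a non-phospho row, a multi-gene
#' peptide shared by two kinases, a multi-accession site, non-human curated
#' relations, sub-threshold predictions and a gene alias, so that every
#' reader-side filter is exercised.
#'
#' @param n_kinases,n_substrates Numbers of catalog kinases and background
#'   substrate proteins.
#' @param peptides_per_kinase,sites_per_kinase Own phosphopeptides and
#'   substrate sites per kinase.
#' @param bg_mean Background Poisson mean spectral count per peptide.
#' @param n_drivers,drivers Number of planted drivers, or explicit driver
#'   symbols.
#' @param fold_boost Multiplier (>= 1) on the expected counts of driver
#'   peptides and driver-substrate peptides.
#' @param coverage Fraction of kinases present in the relation tables.
#' @param class1_fraction Fraction of sites with localization probability
#'   above 0.75.
#' @param dispersion_sdlog sdlog of the optional per-peptide lognormal
#'   abundance factor (mean 1); 0 (the default) keeps counts exactly
#'   Poisson.
#' @param samples Character vector of sample ids.
#' @param quant_mode `"counts"` or `"intensity"`.
#' @param seed Integer seed; the same seed reproduces the experiment
#'   exactly.
#' @return An object of class `inka_simulation`: a list with `tidy` (tables
#'   ready for [merge_site_peptide()] / [kinase_knowledgebase()]), `tables`
#'   (file-dialect renderings for [write_experiment()]), `truth` (drivers,
#'   covered kinases, boosted peptides, parameters) and `samples`.
#' @export
simulate_experiment <- function(n_kinases = 50,
                                n_substrates = 2 * n_kinases,
                                peptides_per_kinase = 2,
                                sites_per_kinase = 3,
                                bg_mean = 2,
                                n_drivers = 1,
                                drivers = NULL,
                                fold_boost = 10,
                                coverage = 0.7,
                                class1_fraction = 0.85,
                                dispersion_sdlog = 0,
                                samples = "sample_1",
                                quant_mode = c("counts", "intensity"),
                                seed = 1L) {
  quant_mode <- match.arg(quant_mode)
  if (fold_boost < 1) {
    abort("fold_boost must be >= 1")
  }
  if (coverage < 0 || coverage > 1) {
    abort("coverage must be in [0, 1]")
  }
  if (n_kinases < 2 || n_substrates < 1 || length(samples) < 1) {
    abort("inconsistent simulation sizes")
  }
  local_seed(seed)

  kin <- sprintf("KIN%03d", seq_len(n_kinases))
  subs <- sprintf("SUB%03d", seq_len(n_substrates))
  drivers <- drivers %||% sample(kin, n_drivers)
  if (!all(drivers %in% kin)) {
    abort("drivers must be catalog kinases")
  }

  n_cov <- round(coverage * n_kinases)
  covered <- head(c(drivers, sample(setdiff(kin, drivers))), n_cov)

  pos_env <- new.env(parent = emptyenv())
  next_pos <- function(gene) {
    cur <- get0(gene, envir = pos_env, ifnotfound = 0L)
    nxt <- cur + sample(5:60, 1)
    assign(gene, nxt, envir = pos_env)
    nxt
  }
  rand_pep <- function() {
    aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "L", "M", "N", "P", "Q",
            "S", "T", "V", "W", "Y")
    paste0(paste(sample(aa, sample(9:14, 1), replace = TRUE), collapse = ""),
           sample(c("K", "R"), 1))
  }
  loc_prob <- function() {
    if (runif(1) < class1_fraction) runif(1, 0.76, 1) else runif(1, 0.3, 0.75)
  }

  pep_rows <- list()   # gene_symbol, peptide, n_phospho, boosted
  site_rows <- list()  # gene_symbol, position, residue, peptide, loc, acc
  psp_rows <- list()   # kinase, substrate, position, residue
  nwk_rows <- list()   # substrate, position, residue, kinase, score, tree
  aloop_rows <- list()

  add_pep <- function(gene, pep, nph, boosted) {
    pep_rows[[length(pep_rows) + 1]] <<- tibble(
      gene_symbol = gene, peptide = pep, n_phospho = nph, boosted = boosted
    )
  }
  add_site <- function(gene, pos, res, pep, prob, multi_acc = FALSE) {
    site_rows[[length(site_rows) + 1]] <<- tibble(
      gene_symbol = gene, position = pos, residue = res, peptide = pep,
      localization_prob = prob, multi_acc = multi_acc
    )
  }

  # Own (kinase-centric) phosphopeptides.
  for (k in kin) {
    for (j in seq_len(peptides_per_kinase)) {
      pep <- rand_pep()
      nph <- sample(1:2, 1, prob = c(0.7, 0.3))
      add_pep(k, pep, nph, k %in% drivers)
      res <- sample(c("Y", "S", "T"), 1, prob = c(0.8, 0.1, 0.1))
      add_site(k, next_pos(k), res, pep, loc_prob())
      if (j == 1) {
        aloop_rows[[length(aloop_rows) + 1]] <-
          tibble(gene_symbol = k, peptide = pep)
      }
    }
  }

  # One peptide shared by two homologous background kinases.
  homologs <- head(setdiff(covered, drivers), 2)
  if (length(homologs) == 2) {
    pep <- rand_pep()
    for (g in homologs) {
      add_pep(g, pep, 1L, FALSE)
      add_site(g, next_pos(g), "Y", pep, runif(1, 0.9, 1))
    }
  }

  # Substrate sites, their peptides, and relations for covered kinases.
  first_site <- TRUE
  for (k in kin) {
    for (s in seq_len(sites_per_kinase)) {
      g <- sample(subs, 1)
      pos <- next_pos(g)
      res <- sample(c("Y", "S", "T"), 1, prob = c(0.8, 0.1, 0.1))
      pep <- rand_pep()
      nph <- sample(1:2, 1, prob = c(0.8, 0.2))
      add_pep(g, pep, nph, k %in% drivers)
      add_site(g, pos, res, pep, loc_prob(), multi_acc = first_site)
      first_site <- FALSE

      if (k %in% covered) {
        u <- runif(1)
        in_psp <- u < 0.425 || u >= 0.85
        in_nwk <- u >= 0.425
        if (in_psp) {
          psp_rows[[length(psp_rows) + 1]] <-
            tibble(kinase_symbol = k, substrate_symbol = g, position = pos,
                   residue = res)
        }
        if (in_nwk) {
          score <- runif(1, 2.2, 8)
          nwk_rows[[length(nwk_rows) + 1]] <-
            tibble(substrate_symbol = g, position = pos, residue = res,
                   kinase_symbol = k, score = score, tree = "KIN")
          if (runif(1) < 0.1) {
            # Competing prediction below 90% of the site maximum.
            nwk_rows[[length(nwk_rows) + 1]] <-
              tibble(substrate_symbol = g, position = pos, residue = res,
                     kinase_symbol = sample(covered, 1), score = 0.85 * score,
                     tree = "KIN")
          }
        }
        if (runif(1) < 0.1) {
          # Prediction below the absolute score floor.
          nwk_rows[[length(nwk_rows) + 1]] <-
            tibble(substrate_symbol = g, position = pos, residue = res,
                   kinase_symbol = sample(covered, 1),
                   score = runif(1, 0.5, 1.9), tree = "KIN")
        }
      }
    }
  }

  peps <- bind_rows(pep_rows)
  sites <- bind_rows(site_rows)
  psp <- bind_rows(psp_rows)
  nwk <- bind_rows(nwk_rows)
  aloop <- bind_rows(aloop_rows)

  # Counts are drawn per unique peptide so genes sharing a peptide share its
  # quantification.
  pep_level <- peps |>
    group_by(.data$peptide) |>
    summarise(boosted = any(.data$boosted), .groups = "drop")
  quant <- purrr::map(samples, function(s) {
    factor <- rlnorm(nrow(pep_level), meanlog = -dispersion_sdlog^2 / 2,
                     sdlog = dispersion_sdlog)
    lambda <- bg_mean * factor * ifelse(pep_level$boosted, fold_boost, 1)
    q <- rpois(nrow(pep_level), lambda)
    if (quant_mode == "intensity") {
      q <- q * round(rlnorm(nrow(pep_level), meanlog = 11, sdlog = 0.5))
    }
    tibble(peptide = pep_level$peptide, sample = s, quant = as.numeric(q))
  }) |>
    bind_rows()

  tidy_peptides <- peps |>
    select("gene_symbol", "peptide", "n_phospho") |>
    distinct() |>
    inner_join(quant, by = "peptide", relationship = "many-to-many") |>
    select("gene_symbol", "peptide", "n_phospho", "sample", "quant") |>
    arrange(.data$gene_symbol, .data$peptide, .data$sample)

  tidy_sites <- sites |>
    filter(.data$localization_prob > 0.75) |>
    mutate(accession = paste0(.data$gene_symbol, "_P1")) |>
    select("accession", "gene_symbol", "position", "residue",
           "localization_prob", "peptide") |>
    arrange(.data$gene_symbol, .data$position, .data$accession)

  tidy_psp <- if (nrow(psp) > 0) {
    mutate(psp, source = "PSP", score = NA_real_) |>
      select("kinase_symbol", "substrate_symbol", "position", "residue",
             "source", "score")
  } else {
    tibble(kinase_symbol = character(), substrate_symbol = character(),
           position = integer(), residue = character(), source = character(),
           score = numeric())
  }
  tidy_nwk_pred <- if (nrow(nwk) > 0) {
    nwk |>
      mutate(string_identifier = sprintf("ENSP9%08d", seq_len(n()))) |>
      select("substrate_symbol", "position", "residue", "kinase_symbol",
             "score", "tree", "string_identifier")
  } else {
    tibble(substrate_symbol = character(), position = integer(),
           residue = character(), kinase_symbol = character(),
           score = numeric(), tree = character(),
           string_identifier = character())
  }

  # ---- file-dialect renderings -------------------------------------------
  alias_of <- if (length(homologs) == 2) homologs[1] else kin[2]
  alias <- paste0(alias_of, "X")
  to_alias <- function(x) ifelse(x == alias_of, alias, x)

  pep_wide <- peps |>
    group_by(.data$peptide, .data$n_phospho) |>
    summarise(genes = paste(sort(unique(to_alias(.data$gene_symbol))),
                            collapse = ";"),
              .groups = "drop")
  qwide <- quant |>
    tidyr::pivot_wider(names_from = "sample", values_from = "quant")
  pep_dialect <- pep_wide |>
    inner_join(qwide, by = "peptide") |>
    mutate(Reverse = "", `Potential contaminant` = "") |>
    rename(Sequence = "peptide", `Gene names` = "genes",
           `Phospho (STY)` = "n_phospho") |>
    select("Sequence", "Gene names", "Phospho (STY)", "Reverse",
           "Potential contaminant", all_of(samples)) |>
    arrange(.data$Sequence)
  planted <- tibble(
    Sequence = c("DECOYDECOYK", "CONTAMINANTK", "NOPHOSPHOPEPK"),
    `Gene names` = c(kin[1], kin[1], kin[2]),
    `Phospho (STY)` = c(1L, 1L, 0L),
    Reverse = c("+", "", ""),
    `Potential contaminant` = c("", "+", "")
  )
  for (s in samples) {
    planted[[s]] <- c(3, 3, 5)
  }
  pep_dialect <- bind_rows(pep_dialect, planted)

  site_dialect <- sites |>
    mutate(
      gene_alias = to_alias(.data$gene_symbol),
      Proteins = ifelse(.data$multi_acc,
                        paste0(.data$gene_alias, "_P9;", .data$gene_alias,
                               "_P1"),
                        paste0(.data$gene_alias, "_P1"))
    ) |>
    select("Proteins", `Gene names` = "gene_alias", Position = "position",
           `Amino acid` = "residue",
           `Localization prob` = "localization_prob",
           Peptide = "peptide") |>
    arrange(.data$`Gene names`, .data$Position)

  psp_dialect <- tidy_psp |>
    mutate(KIN_ORGANISM = "human", SUB_ORGANISM = "human") |>
    select(GENE = "kinase_symbol", "KIN_ORGANISM", SUB_GENE =
             "substrate_symbol", "SUB_ORGANISM",
           SUB_MOD_RSD_pos = "position", SUB_MOD_RSD_res = "residue") |>
    mutate(SUB_MOD_RSD = paste0(.data$SUB_MOD_RSD_res,
                                .data$SUB_MOD_RSD_pos)) |>
    select("GENE", "KIN_ORGANISM", "SUB_GENE", "SUB_ORGANISM", "SUB_MOD_RSD")
  psp_dialect <- bind_rows(
    psp_dialect,
    tibble(GENE = kin[1], KIN_ORGANISM = "mouse", SUB_GENE = subs[1],
           SUB_ORGANISM = "mouse", SUB_MOD_RSD = "Y9999")
  )

  nwk_dialect <- tidy_nwk_pred |>
    select(substrate = "substrate_symbol", position = "position",
           residue = "residue", id = "kinase_symbol",
           networkin_score = "score", tree = "tree",
           string_identifier = "string_identifier")
  nwk_dialect <- bind_rows(
    nwk_dialect,
    tibble(substrate = subs[1], position = 9999L, residue = "Y",
           id = "PDZ1", networkin_score = 9.9, tree = "PB",
           string_identifier = "ENSP900000000")
  )

  aloop_dialect <- aloop |>
    mutate(gene = to_alias(.data$gene_symbol)) |>
    select("gene", "peptide")

  all_syms <- sort(unique(c(kin, subs)))
  symbol_map <- bind_rows(
    tibble(symbol = all_syms, official = all_syms),
    tibble(symbol = alias, official = alias_of)
  )

  structure(
    list(
      tidy = list(
        peptides = tidy_peptides,
        sites = tidy_sites,
        psp = tidy_psp,
        networkin_predictions = tidy_nwk_pred,
        activation_loops = aloop,
        kinome = kin,
        symbol_map = symbol_map
      ),
      tables = list(
        peptides = pep_dialect,
        sites = site_dialect,
        psp = psp_dialect,
        networkin = nwk_dialect,
        activation_loops = aloop_dialect,
        kinome = tibble(symbol = kin),
        symbol_map = symbol_map
      ),
      truth = list(
        drivers = sort(drivers),
        covered = sort(covered),
        boosted_peptides = sort(pep_level$peptide[pep_level$boosted]),
        alias = setNames(alias_of, alias),
        params = list(
          n_kinases = n_kinases, n_substrates = n_substrates,
          peptides_per_kinase = peptides_per_kinase,
          sites_per_kinase = sites_per_kinase, bg_mean = bg_mean,
          fold_boost = fold_boost, coverage = coverage,
          class1_fraction = class1_fraction,
          dispersion_sdlog = dispersion_sdlog, quant_mode = quant_mode,
          seed = seed
        )
      ),
      samples = samples
    ),
    class = "inka_simulation"
  )
}

# Set the RNG seed for the calling function's scope, restoring the previous
# state on exit.
local_seed <- function(seed, env = parent.frame()) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  if (is.null(old)) {
    withr_expr <- quote(rm(".Random.seed", envir = globalenv()))
  } else {
    withr_expr <- bquote(assign(".Random.seed", .(old), envir = globalenv()))
  }
  do.call(on.exit, list(withr_expr, add = TRUE), envir = env)
  set.seed(seed)
}

#' @export
print.inka_simulation <- function(x, ...) {
  p <- x$truth$params
  cat("<inka_simulation>\n")
  cat("  kinases: ", p$n_kinases, ", substrates: ", p$n_substrates,
      ", samples: ", length(x$samples), "\n", sep = "")
  cat("  drivers (x", p$fold_boost, " boost): ",
      paste(x$truth$drivers, collapse = ", "), "\n", sep = "")
  cat("  knowledgebase coverage: ", p$coverage, "\n", sep = "")
  invisible(x)
}

#' Write a simulated experiment as pipeline input files
#'
#' Renders the file dialects read by the package: `peptides.tsv`,
#' `sites.tsv`, `psp.tsv`, `networkin.tsv`, `activation_loops.tsv`,
#' `kinome.txt`, `symbol_map.tsv`. Regenerating with the same seed and
#' rewriting produces byte-identical files.
#'
#' @param sim An [simulate_experiment()] object.
#' @param dir Output directory (created if needed).
#' @return Named character vector of file paths, invisibly.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "inka_simulation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    peptides = file.path(dir, "peptides.tsv"),
    sites = file.path(dir, "sites.tsv"),
    psp = file.path(dir, "psp.tsv"),
    networkin = file.path(dir, "networkin.tsv"),
    activation_loops = file.path(dir, "activation_loops.tsv"),
    kinome = file.path(dir, "kinome.txt"),
    symbol_map = file.path(dir, "symbol_map.tsv")
  )
  tb <- sim$tables
  readr::write_tsv(tb$peptides, paths["peptides"], progress = FALSE)
  readr::write_tsv(tb$sites, paths["sites"], progress = FALSE)
  readr::write_tsv(tb$psp, paths["psp"], progress = FALSE)
  readr::write_tsv(tb$networkin, paths["networkin"], progress = FALSE)
  readr::write_tsv(tb$activation_loops, paths["activation_loops"],
                   progress = FALSE)
  writeLines(tb$kinome$symbol, paths["kinome"])
  readr::write_tsv(tb$symbol_map, paths["symbol_map"], progress = FALSE)
  invisible(paths)
}

#' Read a written experiment back through the standard readers
#'
#' @param dir Directory written by [write_experiment()].
#' @param sample_ids Sample column headers in the peptide table.
#' @param quant_mode `"counts"` or `"intensity"`.
#' @return A list with the `merged` site-peptide table and the knowledgebase
#'   `kb`.
#' @export
read_experiment <- function(dir, sample_ids,
                            quant_mode = c("counts", "intensity")) {
  quant_mode <- match.arg(quant_mode)
  symbol_map <- readr::read_tsv(file.path(dir, "symbol_map.tsv"),
                                col_types = "cc", progress = FALSE)
  peptides <- read_phosphopeptides(file.path(dir, "peptides.tsv"),
                                   sample_ids, quant_mode)
  sites <- read_phosphosites(file.path(dir, "sites.tsv"))
  merged <- merge_site_peptide(peptides, sites, symbol_map = symbol_map)
  kb <- kinase_knowledgebase(
    psp = read_psp_relations(file.path(dir, "psp.tsv")),
    networkin = read_networkin(file.path(dir, "networkin.tsv")),
    kinome = read_kinome(file.path(dir, "kinome.txt")),
    activation_loops = read_activation_loops(
      file.path(dir, "activation_loops.tsv")),
    symbol_map = symbol_map
  )
  list(merged = merged, kb = kb)
}

#' Score a simulated experiment in memory
#'
#' Convenience wrapper: merges the simulation's tidy tables, assembles the
#' knowledgebase, and runs [inka()].
#'
#' @param sim An [simulate_experiment()] object.
#' @param ... Passed to [inka()].
#' @return An [inka()] object.
#' @export
score_simulation <- function(sim, ...) {
  stopifnot(inherits(sim, "inka_simulation"))
  kb <- kinase_knowledgebase(
    psp = sim$tidy$psp,
    networkin = filter_networkin(sim$tidy$networkin_predictions |>
                                   filter(.data$tree == "KIN") |>
                                   select(-"tree")),
    kinome = sim$tidy$kinome,
    activation_loops = sim$tidy$activation_loops
  )
  merged <- merge_site_peptide(sim$tidy$peptides, sim$tidy$sites)
  inka(merged, kb, quant_mode = sim$truth$params$quant_mode, ...)
}

#' Simulate a drug-efficacy panel matched to a kinase catalog
#'
#' Generates a per-cell-line drug logIC50 table and a binary drug-kinase
#' target map. Drugs targeting a driver kinase are potent (low logIC50) in
#' every cell line; other drugs draw from the background distribution.
#'
#' @param kinases Character vector of kinase symbols.
#' @param drivers Drivers to make targetable by potent drugs.
#' @param n_drugs Number of drugs.
#' @param cell_lines Character vector of cell-line ids.
#' @param seed Integer seed.
#' @return A list with tibbles `efficacy` (`cell_line`, `drug`, `log_ic50`)
#'   and `targets` (`drug`, `kinase_symbol`).
#' @export
simulate_drug_panel <- function(kinases, drivers = character(),
                                n_drugs = 15, cell_lines = "cell_1",
                                seed = 1L) {
  local_seed(seed)
  drugs <- sprintf("DRUG%02d", seq_len(n_drugs))
  targets <- purrr::map(seq_len(n_drugs), function(i) {
    tibble(drug = drugs[i],
           kinase_symbol = sample(kinases, sample(1:3, 1)))
  }) |>
    bind_rows()
  for (d in drivers) {
    if (!d %in% targets$kinase_symbol) {
      targets <- bind_rows(targets,
                           tibble(drug = sample(drugs, 1), kinase_symbol = d))
    }
  }
  targets <- distinct(targets)
  potent <- unique(targets$drug[targets$kinase_symbol %in% drivers])
  efficacy <- tidyr::expand_grid(cell_line = cell_lines, drug = drugs) |>
    mutate(log_ic50 = stats::rnorm(n(), mean = 3, sd = 1) -
             ifelse(.data$drug %in% potent, 3, 0))
  list(efficacy = efficacy, targets = targets)
}
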
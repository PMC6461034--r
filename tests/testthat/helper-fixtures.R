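# Fixture builders and independent brute-force oracles used across the suite.
# Oracles are deliberately written as plain loops over rows, sharing no code
# with the package's vectorized engine.

`%||%` <- function(x, y) if (is.null(x)) y else x

# --- tiny deterministic experiment built in code ---------------------------

# A merged site-peptide table plus knowledgebase where every quantity is easy
# to track by hand. `n_kinases` kinases each get one own peptide (one class I
# site, activation loop), one substrate site with a PSP relation, and count 1.
toy_experiment <- function(n_kinases = 3, quant = NULL, sample = "s1") {
  kin <- sprintf("K%02d", seq_len(n_kinases))
  quant <- quant %||% rep(1, 2 * n_kinases)
  pep_own <- sprintf("PEPTIDEOWN%02dK", seq_len(n_kinases))
  pep_sub <- sprintf("PEPTIDESUB%02dK", seq_len(n_kinases))
  peptides <- tibble::tibble(
    gene_symbol = c(kin, sprintf("SUB%02d", seq_len(n_kinases))),
    peptide = c(pep_own, pep_sub),
    n_phospho = 1L,
    sample = sample,
    quant = quant
  )
  sites <- tibble::tibble(
    accession = paste0(peptides$gene_symbol, "_P1"),
    gene_symbol = peptides$gene_symbol,
    position = 10L + seq_len(2 * n_kinases),
    residue = "Y",
    localization_prob = 0.95,
    peptide = peptides$peptide
  )
  psp <- tibble::tibble(
    kinase_symbol = kin,
    substrate_symbol = sprintf("SUB%02d", seq_len(n_kinases)),
    position = sites$position[n_kinases + seq_len(n_kinases)],
    residue = "Y",
    source = "PSP",
    score = NA_real_
  )
  kb <- kinase_knowledgebase(
    psp = psp,
    networkin = psp[0, ],
    kinome = kin,
    activation_loops = tibble::tibble(gene_symbol = kin, peptide = pep_own)
  )
  merged <- merge_site_peptide(peptides, sites)
  list(peptides = peptides, sites = sites, kb = kb, merged = merged,
       kinases = kin)
}

# --- random small instances for oracle tests -------------------------------

random_instance <- function(seed) {
  set.seed(seed)
  n_genes <- sample(3:6, 1)
  genes <- sprintf("G%02d", seq_len(n_genes))
  kinome <- genes[seq_len(sample(2:n_genes, 1))]
  pep_rows <- list()
  site_rows <- list()
  pid <- 0
  for (g in genes) {
    for (j in seq_len(sample(1:3, 1))) {
      pid <- pid + 1
      pep <- sprintf("P%03dK", pid)
      nph <- sample(1:3, 1)
      n_sites <- sample(1:2, 1)
      pep_rows[[pid]] <- tibble::tibble(
        gene_symbol = g, peptide = pep, n_phospho = nph,
        n_inferred_sites = n_sites
      )
      for (k in seq_len(n_sites)) {
        site_rows[[length(site_rows) + 1]] <- tibble::tibble(
          gene_symbol = g, peptide = pep,
          position = pid * 10L + k,
          residue = sample(c("S", "T", "Y"), 1)
        )
      }
    }
  }
  peps <- dplyr::bind_rows(pep_rows)
  peps$quant <- as.numeric(rpois(nrow(peps), 3))
  sites <- dplyr::bind_rows(site_rows)
  merged <- dplyr::inner_join(sites, peps,
                              by = c("gene_symbol", "peptide")) |>
    dplyr::mutate(
      accession = paste0(gene_symbol, "_P1"),
      localization_prob = 0.9,
      sample = "s1"
    )
  # random relations; some target positions that are not observed
  n_rel <- sample(3:12, 1)
  relations <- tibble::tibble(
    kinase_symbol = sample(kinome, n_rel, replace = TRUE),
    substrate_symbol = sample(genes, n_rel, replace = TRUE),
    position = sample(c(sites$position, 999L), n_rel, replace = TRUE),
    residue = sample(c("S", "T", "Y"), n_rel, replace = TRUE),
    source = sample(c("PSP", "NWK"), n_rel, replace = TRUE),
    score = NA_real_
  ) |>
    dplyr::distinct(kinase_symbol, substrate_symbol, position, residue,
                    source, .keep_all = TRUE)
  # fix residues of observed targets so some relations match
  key <- paste(relations$substrate_symbol, relations$position)
  obs <- paste(sites$gene_symbol, sites$position)
  idx <- match(key, obs)
  relations$residue[!is.na(idx)] <- sites$residue[idx[!is.na(idx)]]
  aloop_pool <- peps[peps$gene_symbol %in% kinome, ]
  aloop <- aloop_pool[sample(nrow(aloop_pool),
                             min(2, nrow(aloop_pool))), ] |>
    dplyr::select(gene_symbol, peptide)
  kb <- kinase_knowledgebase(
    psp = relations[relations$source == "PSP", ],
    networkin = relations[relations$source == "NWK", ],
    kinome = kinome,
    activation_loops = aloop
  )
  list(merged = merged, kb = kb)
}

# --- brute-force oracles ---------------------------------------------------

# Per-kinase component sums by naive enumeration of evidence rows.
oracle_components <- function(merged, kb, sample_id) {
  m <- merged[merged$sample == sample_id, ]
  res <- list()
  add <- function(kin, comp, v) {
    key <- paste(kin, comp)
    res[[key]] <<- (res[[key]] %||% 0) + v
  }
  al_key <- paste(kb$activation_loops$gene_symbol,
                  kb$activation_loops$peptide)
  peps <- unique(m[c("gene_symbol", "peptide", "n_phospho", "quant")])
  for (i in seq_len(nrow(peps))) {
    g <- peps$gene_symbol[i]
    if (g %in% kb$kinome) {
      ps <- peps$quant[i] * peps$n_phospho[i]
      add(g, "kinome", ps)
      if (paste(g, peps$peptide[i]) %in% al_key) {
        add(g, "activation_loop", ps)
      }
    }
  }
  sites <- unique(m[c("gene_symbol", "position", "residue")])
  for (i in seq_len(nrow(sites))) {
    rows <- m[m$gene_symbol == sites$gene_symbol[i] &
                m$position == sites$position[i] &
                m$residue == sites$residue[i], ]
    rows <- unique(rows[c("peptide", "n_phospho", "n_inferred_sites",
                          "quant")])
    site_ps <- sum(rows$quant * rows$n_phospho / rows$n_inferred_sites)
    rel <- kb$relations[kb$relations$substrate_symbol ==
                          sites$gene_symbol[i] &
                          kb$relations$position == sites$position[i] &
                          (is.na(kb$relations$residue) |
                             kb$relations$residue == sites$residue[i]), ]
    rel <- unique(rel[c("kinase_symbol", "source")])
    for (j in seq_len(nrow(rel))) {
      add(rel$kinase_symbol[j],
          if (rel$source[j] == "PSP") "psp" else "nwk", site_ps)
    }
  }
  res
}

oracle_vs_fit <- function(merged, kb, sample_id = "s1") {
  fit <- inka(merged, kb)
  oracle <- oracle_components(merged, kb, sample_id)
  sc <- fit$scores[fit$scores$sample == sample_id, ]
  comp_cols <- c(kinome = "c_kinome", activation_loop = "c_activation_loop",
                 psp = "c_psp", nwk = "c_nwk")
  ok <- TRUE
  for (i in seq_len(nrow(sc))) {
    for (comp in names(comp_cols)) {
      expected <- oracle[[paste(sc$kinase_symbol[i], comp)]] %||% 0
      got <- sc[[comp_cols[comp]]][i]
      if (!isTRUE(all.equal(expected, got))) {
        ok <- FALSE
      }
    }
  }
  # every oracle kinase must be present in the fit
  oracle_kin <- unique(vapply(strsplit(names(oracle), " "), `[`, "", 1))
  ok && all(oracle_kin %in% sc$kinase_symbol)
}

# NetworKIN filter by naive per-site loops.
oracle_networkin <- function(preds, floor = 2, frac = 0.9) {
  keep <- logical(nrow(preds))
  for (i in seq_len(nrow(preds))) {
    same <- preds$substrate_symbol == preds$substrate_symbol[i] &
      preds$position == preds$position[i] &
      preds$residue == preds$residue[i]
    mx <- max(preds$score[same])
    keep[i] <- preds$score[i] >= floor && preds$score[i] > frac * mx
  }
  preds[keep, ]
}

# Kinase impact score by a double loop over kinases and drugs.
oracle_impact <- function(kas, eff, targets, top_n) {
  total <- 0
  top <- kas[seq_len(min(top_n, nrow(kas))), ]
  for (i in seq_len(nrow(top))) {
    for (j in seq_len(nrow(eff))) {
      linked <- any(targets$kinase_symbol == top$kinase_symbol[i] &
                      targets$drug == eff$drug[j])
      if (linked) {
        total <- total + top$kas[i] * eff$e[j]
      }
    }
  }
  total
}

# Driver rank under a score vector: 1 + number of strictly better kinases.
rank_of <- function(values, names, target) {
  v <- values[match(target, names)]
  if (is.na(v)) v <- 0
  1 + sum(values > v, na.rm = TRUE)
}
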
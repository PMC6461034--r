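# Internal evidence-index engine.
#
# The merged site-peptide table and the knowledgebase are compiled once into
# integer-indexed structures so that observed scores and the permutation null
# (which recomputes all component sums up to 1e5 times) share one code path.

build_engine <- function(merged, kb) {
  peps <- merged |>
    distinct(.data$gene_symbol, .data$peptide, .data$n_phospho,
             .data$n_inferred_sites) |>
    arrange(.data$gene_symbol, .data$peptide)
  peps$pep_id <- seq_len(nrow(peps))
  al_key <- paste(kb$activation_loops$gene_symbol,
                  kb$activation_loops$peptide)
  peps$in_kinome <- peps$gene_symbol %in% kb$kinome
  peps$in_aloop <- peps$in_kinome &
    paste(peps$gene_symbol, peps$peptide) %in% al_key

  sites <- merged |>
    distinct(.data$gene_symbol, .data$position, .data$residue) |>
    arrange(.data$gene_symbol, .data$position, .data$residue)
  sites$site_id <- seq_len(nrow(sites))

  site_pep <- merged |>
    distinct(.data$gene_symbol, .data$position, .data$residue, .data$peptide,
             .data$n_phospho, .data$n_inferred_sites) |>
    inner_join(sites, by = c("gene_symbol", "position", "residue")) |>
    inner_join(select(peps, "gene_symbol", "peptide", "pep_id"),
               by = c("gene_symbol", "peptide")) |>
    mutate(weight = .data$n_phospho / .data$n_inferred_sites)

  rel <- kb$relations
  rel_known <- rel |>
    filter(!is.na(.data$residue)) |>
    inner_join(sites,
               by = c(substrate_symbol = "gene_symbol", "position",
                      "residue"))
  rel_nores <- rel |>
    filter(is.na(.data$residue)) |>
    select(-"residue") |>
    inner_join(sites,
               by = c(substrate_symbol = "gene_symbol", "position"),
               relationship = "many-to-many")
  rels <- bind_rows(rel_known, rel_nores) |>
    distinct(.data$kinase_symbol, .data$site_id, .data$source)

  samples <- sort(unique(merged$sample))
  counts <- matrix(0, nrow = nrow(peps), ncol = length(samples),
                   dimnames = list(NULL, samples))
  obs <- merged |>
    distinct(.data$gene_symbol, .data$peptide, .data$sample, .data$quant) |>
    inner_join(select(peps, "gene_symbol", "peptide", "pep_id"),
               by = c("gene_symbol", "peptide"))
  counts[cbind(obs$pep_id, match(obs$sample, samples))] <- obs$quant

  kinases <- sort(union(peps$gene_symbol[peps$in_kinome],
                        rels$kinase_symbol))

  list(
    peptides = peps,
    sites = sites,
    site_pep = site_pep,
    relations = rels,
    counts = counts,
    samples = samples,
    kinases = kinases,
    kin_pep = which(peps$in_kinome),
    kin_pep_kinase = match(peps$gene_symbol[peps$in_kinome], kinases),
    al_pep = which(peps$in_aloop),
    al_pep_kinase = match(peps$gene_symbol[peps$in_aloop], kinases),
    psp_rows = which(rels$source == "PSP"),
    nwk_rows = which(rels$source == "NWK"),
    rel_site = rels$site_id,
    rel_kinase = match(rels$kinase_symbol, kinases)
  )
}

# Sum a value vector into bins 1..n by integer index (dropping NA bins).
bin_sum <- function(values, bins, n) {
  keep <- !is.na(bins)
  out <- numeric(n)
  if (any(keep)) {
    rs <- rowsum(values[keep], bins[keep])
    out[as.integer(rownames(rs))] <- rs[, 1]
  }
  out
}

# Per-kinase component sums for one vector of peptide-level quantifications.
# `rel_kinase` can be overridden with a randomized kinase assignment.
score_components <- function(engine, counts, rel_kinase = engine$rel_kinase) {
  nk <- length(engine$kinases)
  pep_ps <- counts * engine$peptides$n_phospho
  c_kinome <- bin_sum(pep_ps[engine$kin_pep], engine$kin_pep_kinase, nk)
  c_aloop <- bin_sum(pep_ps[engine$al_pep], engine$al_pep_kinase, nk)
  site_ps <- bin_sum(counts[engine$site_pep$pep_id] * engine$site_pep$weight,
                     engine$site_pep$site_id, nrow(engine$sites))
  c_psp <- bin_sum(site_ps[engine$rel_site[engine$psp_rows]],
                   rel_kinase[engine$psp_rows], nk)
  c_nwk <- bin_sum(site_ps[engine$rel_site[engine$nwk_rows]],
                   rel_kinase[engine$nwk_rows], nk)
  cbind(kinome = c_kinome, activation_loop = c_aloop, psp = c_psp,
        nwk = c_nwk)
}

# Tidy per-contribution component table for one sample (evidence keys are
# peptides on the kinase-centric side, sites on the substrate-centric side).
component_contributions <- function(engine, sample) {
  counts <- engine$counts[, sample]
  peps <- engine$peptides
  pep_ps <- counts * peps$n_phospho

  kin_tbl <- tibble(
    component = "Kinome",
    kinase_symbol = peps$gene_symbol[engine$kin_pep],
    evidence_key = peps$peptide[engine$kin_pep],
    phosphosignal = pep_ps[engine$kin_pep]
  )
  al_tbl <- tibble(
    component = "ActivationLoop",
    kinase_symbol = peps$gene_symbol[engine$al_pep],
    evidence_key = peps$peptide[engine$al_pep],
    phosphosignal = pep_ps[engine$al_pep]
  )
  site_ps <- bin_sum(counts[engine$site_pep$pep_id] * engine$site_pep$weight,
                     engine$site_pep$site_id, nrow(engine$sites))
  site_key <- paste0(engine$sites$gene_symbol, "_", engine$sites$residue,
                     engine$sites$position)
  sub_tbl <- tibble(
    component = if_else(engine$relations$source == "PSP", "PSP", "NWK"),
    kinase_symbol = engine$relations$kinase_symbol,
    evidence_key = site_key[engine$rel_site],
    phosphosignal = site_ps[engine$rel_site]
  )
  bind_rows(kin_tbl, al_tbl, sub_tbl) |>
    mutate(sample = sample, .before = 1) |>
    arrange(.data$component, .data$kinase_symbol, .data$evidence_key)
}
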
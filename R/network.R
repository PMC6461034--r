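#' Build the kinase-substrate network for the top-ranked kinases
#'
#' Constructs, for one sample, the directed kinase-to-substrate network over
#' the top `top_n` kinases by INKA score and their observed substrate sites.
#' One edge is created per (kinase, substrate site) link with a positive
#' site phosphosignal; its `source` attribute is `"PSP"`, `"NWK"`, or
#' `"both"` when the link occurs in both relation tables, and its `weight`
#' is the site phosphosignal. Node kinds follow the plotting legend:
#' `observed_kinase` (catalog kinase identified through at least one
#' phosphopeptide), `inferred_kinase` (kinase with substrate links but no own
#' observed phosphopeptide), `substrate` (everything else). Kinase nodes
#' carry their INKA score and a flag for an observed activation-loop
#' phosphosite. Figure styling used downstream (edge colors coral /
#' cornflowerblue / forestgreen, white-to-red node gradient) is carried as
#' attributes, not hard-coded drawing.
#'
#' @param fit An [inka()] object.
#' @param sample Sample id; optional for single-sample fits.
#' @param top_n Number of top INKA kinases whose edges are included
#'   (default 20).
#' @return An [igraph::igraph] directed graph.
#' @export
build_network <- function(fit, sample = NULL, top_n = 20) {
  stopifnot(inherits(fit, "inka"))
  sample <- resolve_sample(fit, sample)
  rk <- rank_inka(fit, sample, top_n = top_n)
  top <- rk$ranking$kinase_symbol[rk$ranking$rank <= top_n]

  engine <- fit$engine
  counts <- engine$counts[, sample]
  site_ps <- bin_sum(counts[engine$site_pep$pep_id] * engine$site_pep$weight,
                     engine$site_pep$site_id, nrow(engine$sites))

  peps <- engine$peptides
  observed_genes <- unique(peps$gene_symbol[counts[peps$pep_id] > 0])

  rel <- tibble(
    kinase_symbol = engine$relations$kinase_symbol,
    site_id = engine$rel_site,
    source = engine$relations$source,
    weight = site_ps[engine$rel_site]
  ) |>
    filter(.data$weight > 0)
  top_edges <- filter(rel, .data$kinase_symbol %in% top)
  # Inferred kinases (no own observed phosphopeptide) join the network on
  # the substrate sites it already contains.
  inferred_edges <- rel |>
    filter(!(.data$kinase_symbol %in% observed_genes),
           .data$site_id %in% top_edges$site_id)
  edges <- bind_rows(top_edges, inferred_edges) |>
    distinct() |>
    group_by(.data$kinase_symbol, .data$site_id, .data$weight) |>
    summarise(
      source = if (dplyr::n_distinct(.data$source) > 1) "both"
               else first(.data$source),
      .groups = "drop"
    ) |>
    mutate(
      substrate_symbol = engine$sites$gene_symbol[.data$site_id],
      position = engine$sites$position[.data$site_id],
      residue = engine$sites$residue[.data$site_id],
      site = paste0(.data$substrate_symbol, "_", .data$residue,
                    .data$position),
      color = c(PSP = "coral", NWK = "cornflowerblue",
                both = "forestgreen")[.data$source]
    ) |>
    arrange(.data$kinase_symbol, .data$site)

  if (nrow(edges) == 0) {
    g <- igraph::make_empty_graph(directed = TRUE)
    g <- igraph::set_graph_attr(g, "sample", sample)
    return(g)
  }

  node_ids <- union(unique(edges$kinase_symbol),
                    unique(edges$substrate_symbol))
  aloop_genes <- unique(peps$gene_symbol[peps$in_aloop &
                                           counts[peps$pep_id] > 0])
  is_kinase_node <- node_ids %in% fit$kb$kinome |
    node_ids %in% edges$kinase_symbol
  kind <- dplyr::case_when(
    is_kinase_node & node_ids %in% observed_genes ~ "observed_kinase",
    is_kinase_node ~ "inferred_kinase",
    TRUE ~ "substrate"
  )
  sc <- filter(fit$scores, .data$sample == !!sample)
  inka_score <- sc$inka[match(node_ids, sc$kinase_symbol)]

  nodes <- tibble(
    name = node_ids,
    kind = kind,
    shape = c(observed_kinase = "hexagon", inferred_kinase = "pentagon",
              substrate = "circle")[kind],
    inka_score = ifelse(is.na(inka_score), 0, inka_score),
    has_activation_loop_site = node_ids %in% aloop_genes
  )

  g <- igraph::graph_from_data_frame(
    select(edges, from = "kinase_symbol", to = "substrate_symbol",
           "weight", "source", "site", "position", "residue", "color"),
    directed = TRUE, vertices = nodes
  )
  igraph::set_graph_attr(g, "sample", sample) |>
    igraph::set_graph_attr("top_n", top_n)
}

#' Force-directed layout with node-count-scaled parameters
#'
#' Computes Fruchterman-Reingold coordinates with the parameter scalings
#' used for these networks: for `N` nodes, `niter = 100 * N` iterations; the
#' companion grid-variant parameters `area = N^1.8`, `repulse.rad = N^1.5`
#' and `ncell = N^3` are recorded as graph attributes (the igraph backend
#' does not expose them; see the package vignette). Coordinates are stored in
#' vertex attributes `x` and `y` and are deterministic under a fixed seed.
#'
#' @param graph An igraph graph from [build_network()].
#' @param seed Optional integer seed.
#' @return The graph with `x`/`y` vertex attributes and layout parameters as
#'   graph attributes.
#' @export
layout_fr <- function(graph, seed = NULL) {
  if (!is.null(seed)) {
    set.seed(seed)
  }
  n <- igraph::vcount(graph)
  if (n == 0) {
    return(graph)
  }
  if (n == 1) {
    coords <- matrix(0, nrow = 1, ncol = 2)
  } else {
    coords <- igraph::layout_with_fr(graph, niter = 100 * n)
  }
  graph |>
    igraph::set_vertex_attr("x", value = coords[, 1]) |>
    igraph::set_vertex_attr("y", value = coords[, 2]) |>
    igraph::set_graph_attr("layout_niter", 100 * n) |>
    igraph::set_graph_attr("layout_area", n^1.8) |>
    igraph::set_graph_attr("layout_repulse_rad", n^1.5) |>
    igraph::set_graph_attr("layout_ncell", n^3)
}

#' Tidy node and edge tables of a kinase-substrate network
#'
#' @param graph An igraph graph from [build_network()].
#' @return A tibble of nodes or directed edges with all attributes.
#' @export
network_nodes <- function(graph) {
  as_tibble(igraph::as_data_frame(graph, what = "vertices"))
}

#' @rdname network_nodes
#' @export
network_edges <- function(graph) {
  as_tibble(igraph::as_data_frame(graph, what = "edges"))
}

#' Export a kinase-substrate network
#'
#' `write_network_graphml()` writes attribute-preserving GraphML;
#' `write_network_tables()` writes the tidy edge-list and node-attribute
#' tables as TSV.
#'
#' @param graph An igraph graph from [build_network()].
#' @param path Output path (for tables: a path prefix; `_edges.tsv` and
#'   `_nodes.tsv` are appended).
#' @return The path(s), invisibly.
#' @export
write_network_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' @rdname write_network_graphml
#' @export
write_network_tables <- function(graph, path) {
  paths <- paste0(path, c("_edges.tsv", "_nodes.tsv"))
  readr::write_tsv(network_edges(graph), paths[1], progress = FALSE)
  readr::write_tsv(network_nodes(graph), paths[2], progress = FALSE)
  invisible(paths)
}
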
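# A scaled-down study used where a test only needs the structure of the
# inputs, not the full-size study conditions.
small_study_config <- function(seed = 1L, ...) {
  defaults <- list(
    n_compounds = 8,
    targets_per_compound = c(4, 8),
    compound_pool_size = 60,
    n_planted_ingredients = 2,
    planted_degree_boost = 5,
    intersection_size = 30,
    universe_size = 500,
    disease_sources = list(
      GeneCards = list(n_genes = 120, family = "lognormal", meanlog = 1, sdlog = 1),
      DisGeNET = list(n_genes = 80, family = "uniform", min = 0, max = 1),
      TTD = list(n_genes = 2, family = "constant")
    ),
    ppi = list(n_connected = 26, n_edges = 60, n_noise_edges = 40,
               n_planted_hubs = 3, hub_degree_boost = 10, threshold = 0.9),
    annotation = list(
      n_terms = c(BP = 8, CC = 4, MF = 4, KEGG = 8),
      term_size_range = c(5, 20),
      n_planted_terms = c(BP = 1, CC = 1, MF = 1, KEGG = 1),
      planted_overlap_fraction = 0.6,
      enriched_fraction = 0.5,
      enriched_overlap_fraction = 0.25
    )
  )
  do.call(study_config, c(list(seed = seed),
                          utils::modifyList(defaults, list(...))))
}
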
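# Hand-built micro-fixtures shared across the suite; everything here is
# generated in code, nothing is read from disk.

# Four proteins over a five-term DAG with hand-computable information content:
#   t1, t2 under the root; t3, t4 under t1.
#   A: {t3}        -> closed {t3, t1, root}
#   B: {t3, t4}    -> closed {t3, t4, t1, root}
#   C: {t2}        -> closed {t2, root}
#   D: {t1}        -> closed {t1, root}
# counts: t1 -> 3, t2 -> 1, t3 -> 2, t4 -> 1 of 4 proteins
tiny_ontology <- function() {
  dag <- list(
    terms = c("t1", "t2", "t3", "t4"),
    parents = list(t1 = character(), t2 = character(), t3 = "t1", t4 = "t1")
  )
  ann <- tibble::tibble(
    protein = c("A", "B", "B", "C", "D"),
    term = c("t3", "t3", "t4", "t2", "t1")
  )
  build_ontology(ann, dag)
}

# ontology in which every listed protein carries an identical annotation set
# with positive total IC (pairwise simGIC exactly 1); an extra corpus-only
# protein keeps t1 informative
uniform_ontology <- function(proteins) {
  dag <- list(terms = c("t1", "t2"), parents = list(t1 = character(), t2 = character()))
  ann <- dplyr::bind_rows(
    tidyr::expand_grid(protein = proteins, term = c("t1", "t2")),
    tibble::tibble(protein = ".corpus_only", term = "t2")
  )
  build_ontology(ann, dag)
}

# weighted network from an explicit edge tibble with given weights
manual_network <- function(edges, normalized = FALSE) {
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  igraph::E(g)$weight <- edges$weight
  egosig:::new_weighted_network(g, normalized = normalized)
}

# direction-network wrapper around a bare igraph, for ego/supernode tests
manual_dirnet <- function(graph, seeds, direction = "up") {
  structure(
    list(graph = graph, seeds = seeds, direction = direction,
         scores = tibble::tibble(protein = character(), layer = character(),
                                 score = numeric(), p_empirical = numeric()),
         layers = "all"),
    class = "direction_network"
  )
}

# memoized small synthetic study + pipeline run reused by pipeline tests
.test_cache <- new.env(parent = emptyenv())

small_spec <- function(seed = 7) {
  fixture_spec(n_communities = 3, community_size = 12, p_within = 0.4,
               p_between = 0.02, n_terms = 36, depth = 3, terms_per_protein = 5,
               coherence = 0.9, n_seed_sites = 18, noise = 0.1, seed = seed)
}

small_study <- function() {
  if (is.null(.test_cache$study)) .test_cache$study <- synth_study(small_spec())
  .test_cache$study
}

small_result <- function() {
  if (is.null(.test_cache$result)) {
    st <- small_study()
    .test_cache$result <- run_pipeline(
      st$edges, st$ontology, st$phospho, st$tyr_kinases, st$kinases,
      n_randoms = 30, seed = 11
    )
  }
  .test_cache$result
}

# brute-force one-sided hypergeometric tail by binomial coefficients
hypergeom_tail <- function(overlap, fg, set, bg) {
  ks <- overlap:min(fg, set)
  sum(choose(set, ks) * choose(bg - set, fg - ks)) / choose(bg, fg)
}
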
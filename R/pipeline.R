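#' Run the full signature-extraction pipeline
#'
#' Chains every stage: semantic weighting and normalization of the
#' interaction network, degree-preserving random ensemble, direction- and
#' layer-wise seed selection, random walk with restart with empirical
#' filtering, dual-membership resolution, ego decomposition into supernodes,
#' supernode-graph construction, and Leiden module detection.
#'
#' @param edges Edge list: tibble/data frame (`from`, `to`) or file path.
#' @param ontology An `ego_ontology`, or a list with elements `annotations`
#'   (path or data frame) and optionally `obo` (path) to be loaded.
#' @param phospho Phospho table: tibble or TSV path
#'   (see [read_phospho_table()]).
#' @param tyr_kinases,kinases Accession vectors or one-per-line file paths.
#' @param damping Continuation probability of all walks (default 0.85).
#' @param alpha Empirical-filter tail fraction (default 0.05).
#' @param n_randoms Random-network replicates (default 1000; desk-scale runs
#'   use fewer).
#' @param kde_cutoff Joint-CDF supernode threshold (default 0.85).
#' @param kinase_percentile,substrate_percentile Seed percentile thresholds
#'   (defaults 20 and 80).
#' @param top_n Optional top-N seed selection replacing percentiles.
#' @param layers Number of propagation layers (1, 2 or 3).
#' @param keep_dual Keep proteins in both direction networks (default
#'   `FALSE`).
#' @param min_ego_neighbors Ego-decomposition gate (default 5).
#' @param z_cutoff Semantic z-score threshold (default 1.64).
#' @param seed Integer seed governing the ensemble and Leiden refinement.
#' @param directions Directions to run (default both).
#' @return An `ego_signature` with the normalized network, semantic profile,
#'   per-direction networks/supernodes/diagnostics, supernode graphs, module
#'   partitions and a reproducibility manifest.
#' @export
run_pipeline <- function(edges, ontology, phospho,
                         tyr_kinases = character(), kinases = character(),
                         damping = 0.85, alpha = 0.05, n_randoms = 1000,
                         kde_cutoff = 0.85, kinase_percentile = 20,
                         substrate_percentile = 80, top_n = NULL, layers = 3,
                         keep_dual = FALSE, min_ego_neighbors = 5,
                         z_cutoff = 1.64, seed = 1,
                         directions = c("up", "down")) {
  stopifnot(damping >= 0, damping < 1, alpha > 0, alpha <= 1, layers %in% 1:3)
  if (!inherits(ontology, "ego_ontology")) {
    stopifnot(is.list(ontology), !is.null(ontology$annotations))
    dag <- if (!is.null(ontology$obo)) read_obo(ontology$obo) else NULL
    ontology <- build_ontology(ontology$annotations, dag)
  }
  records <- read_phospho_table(phospho)
  tyr_kinases <- read_id_list(tyr_kinases)
  kinases <- read_id_list(kinases)

  raw <- build_weighted_network(edges, ontology)
  norm <- suppressWarnings(laplacian_normalize(raw))
  profile <- semantic_profile(norm, ontology)
  ensemble <- randomize_ensemble(raw, n_random = n_randoms, ontology = ontology,
                                 seed = seed)

  run_direction <- function(direction) {
    sl <- suppressWarnings(build_seed_layers(
      records, direction, tyr_kinases, kinases, layers = layers,
      kinase_percentile = kinase_percentile,
      substrate_percentile = substrate_percentile, top_n = top_n
    ))
    filtered <- list()
    for (nm in names(sl)) {
      restart <- suppressWarnings(build_restart_vector(sl[[nm]], norm))
      if (is.null(restart)) next
      real <- rwr(norm, restart, damping)
      nulls <- null_scores(ensemble, restart, damping)
      filtered[[nm]] <- empirical_filter(real, nulls, alpha)
    }
    if (length(filtered) == 0L) return(NULL)
    seeds <- intersect(seed_proteins(sl), network_nodes(norm))
    build_direction_network(filtered, seeds, raw, direction)
  }
  dirnets <- rlang::set_names(purrr::map(directions, run_direction), directions)
  dirnets <- purrr::compact(dirnets)

  if (all(c("up", "down") %in% names(dirnets))) {
    resolved <- resolve_dual_membership(dirnets$up, dirnets$down, keep_dual)
    dirnets$up <- resolved$up
    dirnets$down <- resolved$down
  }

  decomp <- purrr::map(dirnets, function(dn) {
    suppressWarnings(decompose_direction(
      dn, profile, ontology, kde_cutoff = kde_cutoff, ego_damping = damping,
      min_neighbors = min_ego_neighbors, z_cutoff = z_cutoff
    ))
  })
  sgraphs <- purrr::imap(decomp, function(d, direction) {
    build_supernode_graph(d$supernodes, dirnets[[direction]], damping)
  })
  modules <- purrr::map(sgraphs, function(sg) {
    suppressWarnings(partition_modules(sg, seed = seed))
  })

  manifest <- list(
    parameters = list(damping = damping, alpha = alpha, n_randoms = n_randoms,
                      kde_cutoff = kde_cutoff,
                      kinase_percentile = kinase_percentile,
                      substrate_percentile = substrate_percentile,
                      top_n = top_n, layers = layers, keep_dual = keep_dual,
                      min_ego_neighbors = min_ego_neighbors,
                      z_cutoff = z_cutoff, seed = seed),
    counts = list(
      network_nodes = igraph::vcount(norm$graph),
      network_edges = igraph::ecount(norm$graph),
      seeds = purrr::map_int(dirnets, ~ length(.x$seeds)),
      direction_nodes = purrr::map_int(dirnets, ~ igraph::vcount(.x$graph)),
      supernodes = purrr::map_int(decomp, ~ length(.x$supernodes)),
      modules = purrr::map_int(modules, ~ length(unique(.x$module)))
    )
  )
  structure(
    list(network = norm, raw_network = raw, ontology = ontology,
         profile = profile, directions = dirnets,
         supernodes = purrr::map(decomp, "supernodes"),
         diagnostics = purrr::map(decomp, "diagnostics"),
         supernode_graphs = sgraphs, modules = modules, manifest = manifest),
    class = "ego_signature"
  )
}

#' @export
print.ego_signature <- function(x, ...) {
  cat("<ego_signature>\n")
  cat("  network: ", igraph::vcount(x$network$graph), " nodes / ",
      igraph::ecount(x$network$graph), " edges\n", sep = "")
  for (d in names(x$directions)) {
    cat("  ", d, ": ", igraph::vcount(x$directions[[d]]$graph), " nodes, ",
        length(x$supernodes[[d]]), " supernodes, ",
        length(unique(x$modules[[d]]$module)), " modules\n", sep = "")
  }
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a fitted signature into a module membership table
#'
#' @param x An `ego_signature`.
#' @param ... Unused.
#' @return A tibble with one row per (direction, module, protein), flagging
#'   ego proteins.
#' @export
tidy.ego_signature <- function(x, ...) {
  purrr::imap(x$modules, function(part, direction) {
    mm <- module_members(part)
    if (nrow(mm) == 0L) return(NULL)
    egos <- part$ego
    dplyr::mutate(mm, direction = direction, is_ego = .data$protein %in% egos,
                  .before = 1L)
  }) |>
    dplyr::bind_rows()
}

#' One-row summary of a fitted signature
#'
#' @param x An `ego_signature`.
#' @param ... Unused.
#' @return A one-row tibble with network, seed, supernode and module counts.
#' @export
glance.ego_signature <- function(x, ...) {
  cnt <- x$manifest$counts
  tibble::tibble(
    network_nodes = cnt$network_nodes,
    network_edges = cnt$network_edges,
    seeds_up = cnt$seeds[["up"]] %||% 0L,
    seeds_down = cnt$seeds[["down"]] %||% 0L,
    supernodes_up = cnt$supernodes[["up"]] %||% 0L,
    supernodes_down = cnt$supernodes[["down"]] %||% 0L,
    modules_up = cnt$modules[["up"]] %||% 0L,
    modules_down = cnt$modules[["down"]] %||% 0L
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Plot module sizes of a fitted signature
#'
#' @param object An `ego_signature`.
#' @param ... Unused.
#' @return A ggplot: module sizes split by direction, egos highlighted.
#' @export
autoplot.ego_signature <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0L) stop("signature contains no modules to plot", call. = FALSE)
  counts <- df |>
    dplyr::group_by(.data$direction, .data$module) |>
    dplyr::summarise(proteins = dplyr::n(), egos = sum(.data$is_ego), .groups = "drop") |>
    tidyr::pivot_longer(c("proteins", "egos"), names_to = "kind", values_to = "n")
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$module, y = .data$n, fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~ .data$direction, scales = "free_x") +
    ggplot2::labs(x = "functional module", y = "count", fill = NULL,
                  title = "Module composition of the active signaling signature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot the decomposition cloud of one direction
#'
#' Topological-affinity vs functional-distance coordinates of every ego's
#' candidates, colored by selection.
#'
#' @param x An `ego_signature`.
#' @param direction `"up"` or `"down"`.
#' @return A ggplot.
#' @export
plot_decomposition <- function(x, direction = "up") {
  df <- x$diagnostics[[direction]]
  if (is.null(df) || nrow(df) == 0L) stop("no decomposition diagnostics for direction ",
                                          direction, call. = FALSE)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$topo, y = .data$func,
                                   color = .data$selected)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::facet_wrap(~ .data$ego) +
    ggplot2::labs(x = "topological affinity", y = "functional distance",
                  color = "selected",
                  title = paste0("Ego decomposition (", direction, ")")) +
    ggplot2::theme_minimal()
}

#' Write the artifacts of a fitted signature to a directory
#'
#' Per direction: a GraphML and SIF of the coarse network, node scores with
#' empirical p-values (TSV), supernodes (JSON), the supernode graph
#' (GraphML, with `jsd` and `similarity` edge attributes), the module table
#' (TSV) and decomposition diagnostics (TSV); plus a JSON run manifest.
#'
#' @param x An `ego_signature`.
#' @param dir Output directory.
#' @return Invisibly, the directory.
#' @export
write_signature <- function(x, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in names(x$directions)) {
    dn <- x$directions[[d]]
    igraph::write_graph(dn$graph, file.path(dir, paste0(d, "_network.graphml")),
                        format = "graphml")
    readr::write_tsv(network_edges(dn) |>
                       dplyr::mutate(relation = "pp", .after = "from") |>
                       dplyr::select("from", "relation", "to"),
                     file.path(dir, paste0(d, "_network.sif")), col_names = FALSE)
    readr::write_tsv(dn$scores, file.path(dir, paste0(d, "_scores.tsv")))
    sn <- purrr::map(x$supernodes[[d]], ~ list(ego = .x$ego, members = .x$members,
                                               direction = .x$direction))
    jsonlite::write_json(unname(sn), file.path(dir, paste0(d, "_supernodes.json")),
                         auto_unbox = TRUE)
    igraph::write_graph(x$supernode_graphs[[d]]$graph,
                        file.path(dir, paste0(d, "_supernode_graph.graphml")),
                        format = "graphml")
    mm <- dplyr::left_join(x$modules[[d]], module_members(x$modules[[d]]),
                           by = "module", relationship = "many-to-many")
    readr::write_tsv(mm, file.path(dir, paste0(d, "_modules.tsv")))
    if (nrow(x$diagnostics[[d]]) > 0L) {
      readr::write_tsv(x$diagnostics[[d]], file.path(dir, paste0(d, "_decomposition.tsv")))
    }
  }
  jsonlite::write_json(x$manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
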
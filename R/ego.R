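#' Nodes within two steps of an ego
#'
#' @param dirnet A `direction_network`.
#' @param ego A protein present in the network.
#' @return Character vector of nodes at shortest-path distance <= 2 from the
#'   ego (including the ego).
#' @export
extract_ego <- function(dirnet, ego) {
  g <- dirnet$graph
  if (!ego %in% igraph::V(g)$name) stop("ego not present in direction network: ", ego,
                                        call. = FALSE)
  igraph::ego(g, order = 2, nodes = ego)[[1]]$name
}

#' Semantic z-score filter of ego-network candidates
#'
#' Keeps candidate `j` when
#' `(simGIC(ego, j) - mean_ego) / sd_ego > z_cutoff`, using the ego's
#' precomputed network-wide similarity moments. The default cutoff 1.64 is
#' the one-tailed 95% standard-normal quantile. The ego itself is always
#' kept. When `sd_ego` is zero the filter degenerates to
#' `simGIC(ego, j) > mean_ego`, with a warning.
#'
#' @param candidates Character vector of candidate nodes.
#' @param ego The ego protein.
#' @param profile Tibble from [semantic_profile()].
#' @param ontology An `ego_ontology`.
#' @param z_cutoff Z-score threshold (default 1.64).
#' @return Filtered character vector (ego first).
#' @export
z_filter <- function(candidates, ego, profile, ontology, z_cutoff = 1.64) {
  row <- profile[profile$protein == ego, ]
  if (nrow(row) != 1L) stop("no semantic profile for ego ", ego, call. = FALSE)
  others <- setdiff(candidates, ego)
  if (length(others) == 0L) return(ego)
  sims <- vapply(others, function(j) simgic(ontology, ego, j), numeric(1))
  if (row$sd_sim == 0) {
    warning("zero similarity spread for ego ", ego,
            "; falling back to simGIC > mean", call. = FALSE)
    keep <- others[sims > row$mean_sim]
  } else {
    keep <- others[(sims - row$mean_sim) / row$sd_sim > z_cutoff]
  }
  c(ego, keep)
}

#' Re-weight the edges of a functional ego network
#'
#' Builds the induced subgraph on the filtered members and replaces edge
#' weights: an edge incident to the ego takes `simGIC(ego, other)`; an edge
#' between two first-order neighbors, or any edge involving a second-order
#' node, takes the mean of its endpoints' similarities to the ego. The
#' result is then Laplacian-normalized.
#'
#' @param dirnet A `direction_network`.
#' @param members Filtered member set (from [z_filter()]), containing the ego.
#' @param ego The ego protein.
#' @param ontology An `ego_ontology`.
#' @return An `ego_network`: list with `ego`, `members`, `graph`
#'   (normalized), `first_order`, `second_order`.
#' @export
reweight_ego_edges <- function(dirnet, members, ego, ontology) {
  g <- igraph::induced_subgraph(dirnet$graph, intersect(network_nodes(dirnet), members))
  first <- intersect(igraph::neighbors(dirnet$graph, ego)$name, members)
  second <- setdiff(members, c(ego, first))
  if (igraph::ecount(g) > 0L) {
    el <- igraph::as_edgelist(g)
    sim_to_ego <- vapply(igraph::V(g)$name, function(j) {
      if (j == ego) 1 else simgic(ontology, ego, j)
    }, numeric(1))
    w <- vapply(seq_len(nrow(el)), function(k) {
      i <- el[k, 1L]; j <- el[k, 2L]
      if (i == ego || j == ego) {
        simgic(ontology, ego, if (i == ego) j else i)
      } else {
        (sim_to_ego[[i]] + sim_to_ego[[j]]) / 2
      }
    }, numeric(1))
    igraph::E(g)$weight <- w
  }
  net <- new_weighted_network(g, normalized = FALSE)
  norm <- tryCatch(suppressWarnings(laplacian_normalize(net)),
                   error = function(e) net) # all-zero weights: keep raw
  structure(list(ego = ego, members = members, graph = norm$graph,
                 first_order = first, second_order = second),
            class = "ego_network")
}

#' @export
print.ego_network <- function(x, ...) {
  cat("<ego_network> ego=", x$ego, ": ", length(x$members), " members\n", sep = "")
  invisible(x)
}

# base-2 Jensen-Shannon distance between two probability vectors on the same
# support; lies in [0, 1]
js_distance <- function(p, q) {
  if (length(p) != length(q)) stop("mismatched supports in Jensen-Shannon distance",
                                   call. = FALSE)
  if (!is.null(names(p)) && !is.null(names(q))) {
    if (!identical(sort(names(p)), sort(names(q)))) {
      stop("mismatched supports in Jensen-Shannon distance", call. = FALSE)
    }
    q <- q[names(p)]
  }
  m <- (p + q) / 2
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * log2(a[nz] / b[nz]))
  }
  div <- (kl(p, m) + kl(q, m)) / 2
  sqrt(pmin(pmax(div, 0), 1))
}

#' Topological affinity between two within-ego RWR vectors
#'
#' `1000 * log2(2 - jsd(p_ego, p_j))` with the base-2 Jensen-Shannon
#' distance, mapping identical walk profiles to 1000 and maximally distinct
#' ones to 0.
#'
#' @param p_ego,p_j Probability vectors over the same ego network (one-hot
#'   restart walks from the ego and from node `j`).
#' @return A value in \[0, 1000\].
#' @export
topological_affinity <- function(p_ego, p_j) {
  1000 * log2(2 - js_distance(p_ego, p_j))
}

#' Functional distance of a node from its ego
#'
#' `1000 * log2(1 + simGIC(ego, j))`: 0 for unrelated annotation sets, 1000
#' for identical ones.
#'
#' @param ontology An `ego_ontology`.
#' @param ego,j Protein accessions.
#' @return A value in \[0, 1000\].
#' @export
functional_distance <- function(ontology, ego, j) {
  1000 * log2(1 + simgic(ontology, ego, j))
}

#' Joint KDE selection of supernode members
#'
#' Each candidate is a point in the (topological affinity, functional
#' distance) plane, rescaled to \[0, 1\] by dividing by 1000. A 2-D Gaussian
#' kernel density estimate with per-dimension Silverman bandwidth
#' `h_d = sd_d * n^(-1/6)` is fitted to the cloud and each node is scored by
#' the estimated joint lower-tail CDF at its own coordinates,
#' `P(X <= x_j, Y <= y_j)` — for a Gaussian KDE this is the mean over kernel
#' centers of the product of univariate normal CDFs. Nodes in the joint
#' upper-quantile region (`cdf >= threshold`) are selected. A fully
#' degenerate cloud (all points identical) selects every node, with a
#' warning.
#'
#' @param points A tibble with columns `node`, `topo`, `func` (both in
#'   \[0, 1000\]).
#' @param threshold Probability cutoff in (0, 1); the reference analysis
#'   uses 0.85 or 0.9.
#' @return The input tibble with added columns `cdf` and `selected`.
#' @export
kde_select <- function(points, threshold = 0.85) {
  stopifnot(all(c("node", "topo", "func") %in% names(points)))
  if (threshold <= 0 || threshold >= 1) stop("threshold must lie in (0, 1)", call. = FALSE)
  n <- nrow(points)
  x <- points$topo / 1000
  y <- points$func / 1000
  sx <- stats::sd(x)
  sy <- stats::sd(y)
  if (n < 2L || (sx == 0 && sy == 0)) {
    warning("degenerate decomposition cloud: all candidates selected", call. = FALSE)
    return(dplyr::mutate(points, cdf = 1, selected = TRUE))
  }
  hx <- max(sx, 1e-9) * n^(-1 / 6)
  hy <- max(sy, 1e-9) * n^(-1 / 6)
  cdf <- vapply(seq_len(n), function(j) {
    mean(stats::pnorm((x[j] - x) / hx) * stats::pnorm((y[j] - y) / hy))
  }, numeric(1))
  dplyr::mutate(points, cdf = cdf, selected = cdf >= threshold)
}

#' Build one supernode from an ego network
#'
#' Ego networks with more than `min_neighbors` neighbors are decomposed: the
#' supernode comprises the ego plus the KDE-selected members (just the ego
#' when the selection is empty). Smaller ego networks are kept whole.
#'
#' @param ego_net An `ego_network`.
#' @param selection Tibble from [kde_select()], or `NULL` for undecomposed
#'   egos.
#' @param direction `"up"` or `"down"`.
#' @param min_neighbors Decomposition gate (default 5).
#' @return A `supernode`: list with `ego`, `members`, `direction`,
#'   `decomposed`.
#' @export
build_supernode <- function(ego_net, selection, direction, min_neighbors = 5) {
  n_neighbors <- length(ego_net$members) - 1L
  if (n_neighbors > min_neighbors && !is.null(selection)) {
    members <- union(ego_net$ego, selection$node[selection$selected])
    decomposed <- TRUE
  } else {
    members <- ego_net$members
    decomposed <- FALSE
  }
  structure(list(ego = ego_net$ego, members = members, direction = direction,
                 decomposed = decomposed),
            class = "supernode")
}

#' @export
print.supernode <- function(x, ...) {
  cat("<supernode> ego=", x$ego, " (", x$direction, "): ", length(x$members),
      " members\n", sep = "")
  invisible(x)
}

#' Decompose a direction network into supernodes
#'
#' For every seed (ego) of the direction: collect the 2-step neighborhood,
#' apply the semantic z-filter, re-weight and re-normalize the ego subgraph,
#' and — when more than `min_neighbors` neighbors survive — run a one-hot
#' restart walk from every member, score members by topological affinity and
#' functional distance, and keep the joint KDE upper-quantile set as the
#' supernode.
#'
#' @param dirnet A `direction_network`.
#' @param profile Tibble from [semantic_profile()] on the base network.
#' @param ontology An `ego_ontology`.
#' @param kde_cutoff Joint-CDF selection threshold (default 0.85).
#' @param ego_damping Continuation probability of the within-ego walks
#'   (default 0.85).
#' @param min_neighbors Decomposition gate (default 5).
#' @param z_cutoff Semantic z-score threshold (default 1.64).
#' @return A list with `supernodes` (list of `supernode`) and `diagnostics`
#'   (tibble: ego, node, topo, func, cdf, selected).
#' @export
decompose_direction <- function(dirnet, profile, ontology, kde_cutoff = 0.85,
                                ego_damping = 0.85, min_neighbors = 5,
                                z_cutoff = 1.64) {
  egos <- intersect(dirnet$seeds, network_nodes(dirnet))
  supernodes <- list()
  diagnostics <- list()
  for (ego in egos) {
    cand <- extract_ego(dirnet, ego)
    members <- suppressWarnings(z_filter(cand, ego, profile, ontology, z_cutoff))
    ego_net <- reweight_ego_edges(dirnet, members, ego, ontology)
    selection <- NULL
    if (length(members) - 1L > min_neighbors) {
      g_ego <- ego_net$graph
      nodes <- igraph::V(g_ego)$name
      walks <- purrr::map(nodes, function(v) {
        r <- rlang::set_names(numeric(length(nodes)), nodes)
        r[v] <- 1
        rwr(g_ego, r, ego_damping)
      })
      names(walks) <- nodes
      others <- setdiff(nodes, ego)
      pts <- tibble::tibble(
        node = others,
        topo = vapply(others, function(j) topological_affinity(walks[[ego]], walks[[j]]),
                      numeric(1)),
        func = vapply(others, function(j) functional_distance(ontology, ego, j),
                      numeric(1))
      )
      selection <- suppressWarnings(kde_select(pts, kde_cutoff))
      diagnostics[[ego]] <- dplyr::mutate(selection, ego = ego, .before = 1L)
    }
    supernodes[[ego]] <- build_supernode(ego_net, selection, dirnet$direction,
                                         min_neighbors)
  }
  list(supernodes = supernodes,
       diagnostics = dplyr::bind_rows(diagnostics))
}
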
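#' Random walk with restart
#'
#' Iterates `p <- damping * T p + (1 - damping) * restart` to its fixed
#' point, where `T` is the column-stochastic transition operator obtained by
#' column-normalizing the (Laplacian-normalized) edge weights. `damping` is
#' the continuation probability of the walk; the restart probability is
#' `1 - damping`. Convergence when the L1 change drops below `tol` (default
#' 1e-10) or after 10^4 iterations.
#'
#' @param network A `weighted_network` (normalized weights expected for the
#'   reference analysis, but any nonnegative weights are accepted).
#' @param restart A probability vector named by network nodes (sum 1).
#' @param damping Continuation probability in \[0, 1).
#' @param tol L1 convergence tolerance.
#' @return A named probability vector over network nodes.
#' @export
rwr <- function(network, restart, damping = 0.85, tol = 1e-10) {
  g <- if (inherits(network, "igraph")) network else network$graph
  nodes <- igraph::V(g)$name
  if (is.null(names(restart))) {
    if (length(restart) != length(nodes)) stop("unnamed restart vector of wrong length",
                                               call. = FALSE)
    names(restart) <- nodes
  }
  r <- rlang::set_names(numeric(length(nodes)), nodes)
  r[names(restart)] <- restart
  if (any(r < 0) || abs(sum(r) - 1) > 1e-9) {
    stop("restart must be a probability vector over network nodes", call. = FALSE)
  }
  if (damping < 0 || damping >= 1) stop("damping must lie in [0, 1)", call. = FALSE)
  n <- length(nodes)
  if (n == 1L) return(rlang::set_names(1, nodes))

  cache <- if (inherits(network, "weighted_network")) network$cache
  W <- if (!is.null(cache)) cache$transition
  if (is.null(W)) {
    W <- as.matrix(igraph::as_adjacency_matrix(g, attr = if (igraph::ecount(g)) "weight" else NULL,
                                               sparse = TRUE))
    cs <- colSums(W)
    # dangling (isolated) columns restart immediately: leave them as zero columns
    nz <- cs > 0
    W[, nz] <- sweep(W[, nz, drop = FALSE], 2, cs[nz], "/")
    if (!is.null(cache)) cache$transition <- W
  }
  p <- r
  for (i in seq_len(10000L)) {
    p_new <- damping * as.numeric(W %*% p) + (1 - damping) * r
    # walkers stuck on dangling nodes are re-injected via the restart
    loss <- 1 - sum(p_new)
    if (loss > 1e-14) p_new <- p_new + loss * r
    if (sum(abs(p_new - p)) < tol) {
      p <- p_new
      break
    }
    p <- p_new
  }
  rlang::set_names(as.numeric(p), nodes)
}

#' Null RWR scores against a random-network ensemble
#'
#' Repeats one layer's walk, with the identical restart vector, on every
#' replicate of a degree-preserving ensemble.
#'
#' @param ensemble A `random_ensemble`.
#' @param restart The layer's restart vector (named, sum 1).
#' @param damping Continuation probability.
#' @return A numeric matrix, nodes x replicates.
#' @export
null_scores <- function(ensemble, restart, damping = 0.85) {
  stopifnot(inherits(ensemble, "random_ensemble"))
  cols <- purrr::map(ensemble$networks, function(net) {
    nodes <- network_nodes(net)
    r <- restart[intersect(names(restart), nodes)]
    r <- r / sum(r) # replicates may have dropped zero-weight nodes
    p <- rwr(net, r, damping)
    out <- rlang::set_names(numeric(length(restart)), names(restart))
    out[names(p)] <- p
    out
  })
  m <- do.call(cbind, cols)
  rownames(m) <- names(restart)
  m
}

#' Empirical-significance filter of propagated scores
#'
#' A node is retained when its real score exceeds at least a `1 - alpha`
#' fraction of its null scores, strictly: with the default `alpha = 0.05`
#' and 1000 replicates, more than 950 nulls must lie strictly below the
#' real score. The empirical p-value is the fraction of null scores greater
#' than or equal to the real score; ties count against retention.
#' `alpha >= 1` retains every node.
#'
#' @param real Named numeric RWR vector on the real network.
#' @param null Matrix of null scores (nodes x replicates), rows matching
#'   `real`.
#' @param alpha Tail fraction in (0, 1\].
#' @return A tibble with columns `protein`, `score`, `p_empirical`,
#'   `retained`.
#' @export
empirical_filter <- function(real, null, alpha = 0.05) {
  if (is.null(dim(null)) || ncol(null) < 1L) stop("null score matrix is empty", call. = FALSE)
  if (alpha <= 0) stop("alpha must lie in (0, 1]", call. = FALSE)
  null <- null[names(real), , drop = FALSE]
  p_emp <- rowMeans(null >= real)
  tibble::tibble(
    protein = names(real),
    score = unname(real),
    p_empirical = unname(p_emp),
    retained = if (alpha >= 1) TRUE else unname(p_emp) < alpha
  )
}

#' Assemble the coarse direction network
#'
#' Union of the nodes retained by any layer's empirical filter plus all seed
#' nodes of the direction (seeds are kept regardless of their score), with
#' edges induced from the base network and per-layer scores attached (zero
#' where a node was not scored by a layer).
#'
#' @param filtered Named list of per-layer tibbles from [empirical_filter()].
#' @param seeds Character vector of the direction's seed proteins.
#' @param network The base `weighted_network` (raw simGIC weights; subgraphs
#'   are re-normalized downstream).
#' @param direction `"up"` or `"down"`.
#' @return A `direction_network`: list with `graph` (induced igraph),
#'   `scores` (tibble protein x layer score/retained), `seeds`, `direction`.
#' @export
build_direction_network <- function(filtered, seeds, network, direction) {
  stopifnot(length(filtered) >= 1L)
  g <- if (inherits(network, "igraph")) network else network$graph
  retained <- unique(unlist(purrr::map(filtered, ~ .x$protein[.x$retained]),
                            use.names = FALSE))
  seeds <- intersect(seeds, igraph::V(g)$name)
  keep <- union(retained, seeds)
  sub <- igraph::induced_subgraph(g, keep)
  scores <- purrr::imap(filtered, function(df, nm) {
    tibble::tibble(protein = df$protein, layer = nm, score = df$score,
                   p_empirical = df$p_empirical)
  }) |>
    dplyr::bind_rows() |>
    dplyr::filter(.data$protein %in% keep)
  structure(list(graph = sub, scores = scores, seeds = seeds, direction = direction,
                 layers = names(filtered)),
            class = "direction_network")
}

#' @export
print.direction_network <- function(x, ...) {
  cat("<direction_network> ", x$direction, ": ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges, ", length(x$seeds), " seeds\n", sep = "")
  invisible(x)
}

# mean per-layer score of each protein, zeros for layers where it was unscored
mean_layer_score <- function(dirnet) {
  nodes <- network_nodes(dirnet)
  n_layers <- length(dirnet$layers)
  dirnet$scores |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(total = sum(.data$score), .groups = "drop") |>
    dplyr::right_join(tibble::tibble(protein = nodes), by = "protein") |>
    dplyr::mutate(mean_score = dplyr::coalesce(.data$total, 0) / n_layers) |>
    dplyr::select("protein", "mean_score")
}

#' Resolve proteins shared between the up and down networks
#'
#' A protein appearing in both direction networks is removed from the one
#' where its mean RWR score across the configured layers (zeros included for
#' layers that did not score it) is smaller. Seeds are never removed from a
#' direction in which they are seeds: a protein seeded on one side only stays
#' there and leaves the other, and a protein seeded on both sides stays in
#' both. Exact ties keep the protein in the up network. Edges are re-induced
#' after removal.
#'
#' @param up,down `direction_network`s.
#' @param keep_dual If `TRUE`, return both networks unchanged.
#' @return A list with elements `up` and `down`.
#' @export
resolve_dual_membership <- function(up, down, keep_dual = FALSE) {
  if (keep_dual) return(list(up = up, down = down))
  shared <- intersect(network_nodes(up), network_nodes(down))
  if (length(shared) == 0L) return(list(up = up, down = down))
  mu <- mean_layer_score(up)
  md <- mean_layer_score(down)
  drop_up <- character()
  drop_down <- character()
  for (p in shared) {
    seed_up <- p %in% up$seeds
    seed_down <- p %in% down$seeds
    if (seed_up && seed_down) next
    if (seed_up) { drop_down <- c(drop_down, p); next }
    if (seed_down) { drop_up <- c(drop_up, p); next }
    su <- mu$mean_score[mu$protein == p]
    sd_ <- md$mean_score[md$protein == p]
    if (su >= sd_) drop_down <- c(drop_down, p) else drop_up <- c(drop_up, p) # tie kept in up
  }
  prune <- function(dn, drop) {
    if (length(drop) == 0L) return(dn)
    dn$graph <- igraph::delete_vertices(dn$graph, drop)
    dn$scores <- dplyr::filter(dn$scores, !.data$protein %in% drop)
    dn
  }
  list(up = prune(up, drop_up), down = prune(down, drop_down))
}
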
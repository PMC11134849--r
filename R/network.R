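#' Read a protein interaction edge list
#'
#' Whitespace- or tab-separated node pairs, one interaction per line. SIF
#' rows (`node relation node`) are accepted: the middle token is dropped
#' when three columns are present.
#'
#' @param path Path to the edge-list file.
#' @return A tibble with columns `from` and `to`.
#' @export
read_edge_list <- function(path) {
  if (!file.exists(path)) stop("cannot read edge list: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[stringr::str_trim(lines) != ""]
  if (length(lines) == 0L) stop("empty edge list: ", path, call. = FALSE)
  toks <- stringr::str_split(stringr::str_trim(lines), "\\s+")
  bad <- which(lengths(toks) < 2L)
  if (length(bad) > 0L) stop("malformed edge-list line ", bad[1L], call. = FALSE)
  from <- purrr::map_chr(toks, 1L)
  to <- purrr::map_chr(toks, ~ .x[[if (length(.x) >= 3L) 3L else 2L]])
  tibble::tibble(from = from, to = to)
}

#' Build the semantic-similarity-weighted interaction network
#'
#' Restricts the edge list to proteins carrying at least one ontology term,
#' drops self-loops, collapses duplicate edges, and weights every remaining
#' edge by the simGIC similarity of its endpoints.
#'
#' @param edges A data frame with two columns of protein accessions
#'   (`from`, `to`), or a path readable by [read_edge_list()].
#' @param ontology An `ego_ontology`.
#' @return A `weighted_network`: an undirected simple igraph-backed object
#'   with nonnegative edge weights and a `normalized` flag (initially
#'   `FALSE`).
#' @export
build_weighted_network <- function(edges, ontology) {
  if (is.character(edges) && length(edges) == 1L) edges <- read_edge_list(edges)
  edges <- tibble::as_tibble(edges)
  stopifnot(ncol(edges) >= 2L)
  names(edges)[1:2] <- c("from", "to")
  g <- igraph::graph_from_data_frame(edges[, c("from", "to")], directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  annotated <- names(ontology$annotations)
  drop <- setdiff(igraph::V(g)$name, annotated)
  if (length(drop) > 0L) {
    warning(length(drop), " node(s) dropped: no ontology annotation", call. = FALSE)
    g <- igraph::delete_vertices(g, drop)
  }
  if (igraph::vcount(g) == 0L) stop("empty network after annotation filtering", call. = FALSE)
  if (igraph::ecount(g) > 0L) {
    sim <- simgic_matrix(ontology, igraph::V(g)$name)
    el <- igraph::as_edgelist(g)
    igraph::E(g)$weight <- sim[cbind(el[, 1L], el[, 2L])]
  }
  new_weighted_network(g, normalized = FALSE)
}

new_weighted_network <- function(graph, normalized, raw_degree = NULL) {
  structure(list(graph = graph, normalized = normalized, raw_degree = raw_degree,
                 cache = new.env(parent = emptyenv())),
            class = "weighted_network")
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges",
      if (x$normalized) " (Laplacian-normalized)" else "", "\n", sep = "")
  invisible(x)
}

#' Nodes of a weighted network
#' @param network A `weighted_network` or `direction_network`.
#' @return Character vector of protein accessions.
#' @export
network_nodes <- function(network) {
  g <- if (inherits(network, "igraph")) network else network$graph
  igraph::V(g)$name
}

#' Edge table of a weighted network
#' @param network A `weighted_network` or `direction_network`.
#' @return A tibble with columns `from`, `to`, `weight`.
#' @export
network_edges <- function(network) {
  g <- if (inherits(network, "igraph")) network else network$graph
  el <- igraph::as_edgelist(g)
  tibble::tibble(from = el[, 1L], to = el[, 2L],
                 weight = if (igraph::ecount(g)) igraph::E(g)$weight else numeric())
}

#' Laplacian (square-root degree) normalization
#'
#' Corrects hub bias by dividing each edge weight by the square root of the
#' product of its endpoints' weighted degrees, all degrees taken on the
#' input (raw) weights: `w_ij <- w_ij / sqrt(d_i * d_j)`. Nodes with zero
#' weighted degree are dropped with a warning before normalizing. The raw
#' degrees are stored so the transformation is invertible.
#'
#' @param network A raw (un-normalized) `weighted_network`.
#' @return A `weighted_network` with `normalized = TRUE` and a `raw_degree`
#'   field holding the pre-normalization weighted degrees.
#' @export
laplacian_normalize <- function(network) {
  stopifnot(inherits(network, "weighted_network"))
  if (network$normalized) stop("network is already normalized", call. = FALSE)
  g <- network$graph
  deg <- igraph::strength(g, weights = igraph::E(g)$weight)
  if (any(deg <= 0)) {
    warning(sum(deg <= 0), " node(s) with zero weighted degree dropped before normalization",
            call. = FALSE)
    g <- igraph::delete_vertices(g, which(deg <= 0))
    deg <- igraph::strength(g, weights = igraph::E(g)$weight)
  }
  if (igraph::vcount(g) == 0L) stop("no nodes remain after dropping zero-degree nodes",
                                    call. = FALSE)
  el <- igraph::as_edgelist(g)
  igraph::E(g)$weight <- igraph::E(g)$weight / sqrt(deg[el[, 1L]] * deg[el[, 2L]])
  new_weighted_network(g, normalized = TRUE,
                       raw_degree = rlang::set_names(as.numeric(deg), igraph::V(g)$name))
}

#' Degree-preserving random-network ensemble
#'
#' Generates `n_random` degree-preserving rewirings of the raw network by a
#' double-edge-swap Markov chain (at least `10 * |E|` attempted swaps per
#' replicate, no self-loops or multi-edges). Each rewired edge is re-weighted
#' by the simGIC similarity of its new endpoints and the replicate is
#' Laplacian-normalized. Fully determined by `seed`.
#'
#' @param network A raw `weighted_network` (as from [build_weighted_network()]).
#' @param n_random Number of replicates (the reference analysis uses 1000).
#' @param ontology An `ego_ontology`.
#' @param seed Integer seed controlling the rewiring chain.
#' @return A `random_ensemble`: list with `networks` (list of normalized
#'   `weighted_network`s) and `seed`.
#' @export
randomize_ensemble <- function(network, n_random = 1000, ontology, seed = 1) {
  stopifnot(inherits(network, "weighted_network"))
  if (network$normalized) stop("randomize the raw (un-normalized) network", call. = FALSE)
  if (!is.numeric(n_random) || n_random < 1) stop("n_random must be >= 1", call. = FALSE)
  n_random <- as.integer(n_random)
  g <- network$graph
  sim <- simgic_matrix(ontology, igraph::V(g)$name)
  niter <- 10L * igraph::ecount(g)
  nets <- withr::with_seed(seed, lapply(seq_len(n_random), function(i) {
    gr <- igraph::rewire(g, igraph::keeping_degseq(loops = FALSE, niter = niter))
    el <- igraph::as_edgelist(gr)
    igraph::E(gr)$weight <- sim[cbind(el[, 1L], el[, 2L])]
    suppressWarnings(laplacian_normalize(new_weighted_network(gr, normalized = FALSE)))
  }))
  structure(list(networks = nets, seed = seed, n_random = n_random),
            class = "random_ensemble")
}

#' @export
print.random_ensemble <- function(x, ...) {
  cat("<random_ensemble> ", x$n_random, " degree-preserving replicates (seed ",
      x$seed, ")\n", sep = "")
  invisible(x)
}
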
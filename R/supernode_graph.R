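#' Jensen-Shannon weight between two supernodes
#'
#' Builds the subgraph induced by the union of the two supernodes' members
#' inside the direction network, Laplacian-normalizes it, and — if the two
#' egos are connected within it — runs a one-hot restart walk from each ego
#' and returns the base-2 Jensen-Shannon distance between the two walk
#' vectors (0 = strongest relationship). Returns `NA` when the egos are not
#' connected (no edge).
#'
#' @param a,b `supernode`s of the same direction.
#' @param dirnet The `direction_network` the supernodes came from.
#' @param damping Continuation probability of the walks (default 0.85).
#' @return A JSD weight in \[0, 1\], or `NA_real_` when no edge exists.
#' @export
supernode_edge <- function(a, b, dirnet, damping = 0.85) {
  stopifnot(inherits(a, "supernode"), inherits(b, "supernode"))
  nodes <- intersect(union(a$members, b$members), network_nodes(dirnet))
  sub <- igraph::induced_subgraph(dirnet$graph, nodes)
  net <- new_weighted_network(sub, normalized = FALSE)
  norm <- tryCatch(suppressWarnings(laplacian_normalize(net)), error = function(e) net)
  g <- norm$graph
  vn <- igraph::V(g)$name
  if (!(a$ego %in% vn) || !(b$ego %in% vn)) return(NA_real_)
  comp <- igraph::components(g)$membership
  if (comp[[a$ego]] != comp[[b$ego]]) return(NA_real_)
  one_hot <- function(v) {
    r <- rlang::set_names(numeric(length(vn)), vn)
    r[v] <- 1
    r
  }
  pa <- rwr(g, one_hot(a$ego), damping)
  pb <- rwr(g, one_hot(b$ego), damping)
  js_distance(pa, pb)
}

#' Build the supernode graph of one direction
#'
#' Evaluates [supernode_edge()] for every supernode pair and assembles an
#' undirected graph whose vertices are the egos, with edge attributes `jsd`
#' (distance, 0 = strongest) and `similarity` (`1 - jsd`, the weight used
#' for community detection).
#'
#' @param supernodes List of `supernode`s (one direction).
#' @param dirnet The `direction_network`.
#' @param damping Continuation probability (default 0.85).
#' @return A `supernode_graph`: list with `graph` (igraph), `supernodes`,
#'   `direction`.
#' @export
build_supernode_graph <- function(supernodes, dirnet, damping = 0.85) {
  egos <- purrr::map_chr(supernodes, "ego")
  n <- length(egos)
  edges <- list()
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        w <- supernode_edge(supernodes[[i]], supernodes[[j]], dirnet, damping)
        if (!is.na(w)) {
          edges[[length(edges) + 1L]] <- tibble::tibble(
            from = egos[[i]], to = egos[[j]], jsd = w, similarity = 1 - w
          )
        }
      }
    }
  }
  edge_df <- dplyr::bind_rows(edges)
  g <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices(egos)
  if (nrow(edge_df) > 0L) {
    g <- igraph::add_edges(g, rbind(match(edge_df$from, egos), match(edge_df$to, egos)))
    igraph::E(g)$jsd <- edge_df$jsd
    igraph::E(g)$similarity <- edge_df$similarity
  }
  structure(list(graph = g, supernodes = rlang::set_names(supernodes, egos),
                 direction = dirnet$direction),
            class = "supernode_graph")
}

#' @export
print.supernode_graph <- function(x, ...) {
  cat("<supernode_graph> ", x$direction, ": ", igraph::vcount(x$graph),
      " supernodes, ", igraph::ecount(x$graph), " links\n", sep = "")
  invisible(x)
}

#' Partition a supernode graph into functional modules
#'
#' Isolated supernodes are removed. Connected components with at least 4
#' supernodes are partitioned by the Leiden algorithm (modularity objective,
#' resolution 1, similarity weights `1 - jsd`); components with 3 or fewer
#' supernodes are kept whole as modules. Deterministic under a fixed seed.
#'
#' @param sg A `supernode_graph`.
#' @param seed Integer seed for the Leiden refinement.
#' @param resolution Leiden resolution parameter (default 1).
#' @return A `module_partition`: tibble with columns `module`, `ego`,
#'   `method`, plus attributes `members` (named list module -> union of
#'   member proteins) and `direction`.
#' @export
partition_modules <- function(sg, seed = 1, resolution = 1) {
  stopifnot(inherits(sg, "supernode_graph"))
  g <- sg$graph
  iso <- which(igraph::degree(g) == 0L)
  if (length(iso) > 0L) g <- igraph::delete_vertices(g, iso)
  if (igraph::vcount(g) == 0L) {
    warning("no connected supernodes: empty module partition", call. = FALSE)
    out <- tibble::tibble(module = character(), ego = character(), method = character())
    attr(out, "members") <- list()
    attr(out, "direction") <- sg$direction
    class(out) <- c("module_partition", class(out))
    return(out)
  }
  comp <- igraph::components(g)
  rows <- list()
  idx <- 0L
  for (ci in seq_len(comp$no)) {
    vs <- names(comp$membership)[comp$membership == ci]
    if (length(vs) >= 4L) {
      subg <- igraph::induced_subgraph(g, vs)
      cl <- withr::with_seed(seed, igraph::cluster_leiden(
        subg, objective_function = "modularity",
        weights = igraph::E(subg)$similarity,
        resolution = resolution, n_iterations = 10
      ))
      mem <- igraph::membership(cl)
      for (m in sort(unique(mem))) {
        idx <- idx + 1L
        rows[[idx]] <- tibble::tibble(
          module = sprintf("%s_m%02d", sg$direction, idx),
          ego = names(mem)[mem == m], method = "leiden"
        )
      }
    } else {
      idx <- idx + 1L
      rows[[idx]] <- tibble::tibble(
        module = sprintf("%s_m%02d", sg$direction, idx),
        ego = vs, method = "small-component"
      )
    }
  }
  out <- dplyr::bind_rows(rows)
  members <- out |>
    dplyr::group_by(.data$module) |>
    dplyr::summarise(prot = list(unique(unlist(
      purrr::map(sg$supernodes[.data$ego], "members"), use.names = FALSE
    ))), .groups = "drop")
  attr(out, "members") <- rlang::set_names(members$prot, members$module)
  attr(out, "direction") <- sg$direction
  class(out) <- c("module_partition", class(out))
  out
}

#' Member proteins of each module
#'
#' @param partition A `module_partition`.
#' @return A tibble with columns `module` and `protein` (union of the
#'   module's supernode members).
#' @export
module_members <- function(partition) {
  members <- attr(partition, "members")
  if (length(members) == 0L) return(tibble::tibble(module = character(), protein = character()))
  purrr::imap(members, ~ tibble::tibble(module = .y, protein = .x)) |>
    dplyr::bind_rows()
}
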
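#' Read an OBO 1.2/1.4 ontology file
#'
#' Minimal stanza parser extracting term identifiers and `is_a` parentage.
#' Obsolete terms are skipped. The result is the plain DAG consumed by
#' [build_ontology()].
#'
#' @param path Path to an OBO file.
#' @return A list with `terms` (character vector of term ids) and `parents`
#'   (named list mapping each term to its `is_a` parents).
#' @export
read_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  terms <- character()
  parents <- list()
  cur_id <- NA_character_
  cur_parents <- character()
  cur_obsolete <- FALSE
  in_term <- FALSE
  flush <- function() {
    if (in_term && !is.na(cur_id) && !cur_obsolete) {
      terms[[length(terms) + 1L]] <<- cur_id
      parents[[cur_id]] <<- cur_parents
    }
  }
  for (ln in lines) {
    ln <- stringr::str_trim(ln)
    if (ln == "[Term]" || ln == "[Typedef]") {
      flush()
      in_term <- ln == "[Term]"
      cur_id <- NA_character_
      cur_parents <- character()
      cur_obsolete <- FALSE
    } else if (in_term && stringr::str_starts(ln, "id:")) {
      cur_id <- stringr::str_trim(stringr::str_sub(ln, 4L))
    } else if (in_term && stringr::str_starts(ln, "is_a:")) {
      tgt <- stringr::str_trim(stringr::str_sub(ln, 6L))
      tgt <- stringr::str_trim(stringr::str_split_fixed(tgt, "!", 2L)[, 1L])
      if (nzchar(tgt)) cur_parents <- c(cur_parents, tgt)
    } else if (in_term && stringr::str_starts(ln, "is_obsolete: true")) {
      cur_obsolete <- TRUE
    }
  }
  flush()
  if (length(terms) == 0L) stop("no terms parsed from OBO file: ", path, call. = FALSE)
  list(terms = unique(terms), parents = parents)
}

#' Read protein-to-term annotations
#'
#' Accepts either a two-column TSV (protein, term; header optional) or GAF
#' 2.x, from which columns 2 (accession) and 5 (term) are used.
#'
#' @param path Path to the annotation file.
#' @param format `"tsv"` or `"gaf"`.
#' @return A tibble with columns `protein` and `term`, one row per direct
#'   annotation.
#' @export
read_annotations <- function(path, format = c("tsv", "gaf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read annotation file: ", path, call. = FALSE)
  if (format == "gaf") {
    df <- readr::read_tsv(path, comment = "!", col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (ncol(df) < 5L) stop("GAF file has fewer than 5 columns", call. = FALSE)
    out <- tibble::tibble(protein = df[[2L]], term = df[[5L]])
  } else {
    df <- readr::read_tsv(path, col_names = FALSE,
                          col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
    if (ncol(df) < 2L) stop("annotation TSV needs two columns (protein, term)", call. = FALSE)
    out <- tibble::tibble(protein = df[[1L]], term = df[[2L]])
    # tolerate an optional header row
    if (nrow(out) > 0L && tolower(out$protein[1]) %in% c("protein", "accession", "id")) {
      out <- out[-1L, ]
    }
  }
  dplyr::distinct(out)
}

#' Assemble an annotated ontology with information content
#'
#' Joins the term DAG (all namespaces) under a single virtual root, closes
#' every protein's annotation set over ancestors, and computes the
#' information content of each term in bits:
#' `ic(t) = -log2(n_t / n)` where `n_t` counts proteins annotated (after
#' closure) to `t` and `n` is the total number of annotated proteins. The
#' virtual root is annotated to every protein, so `ic(root) = 0`.
#'
#' @param annotations A data frame with columns `protein` and `term`
#'   (direct annotations), or a path readable by [read_annotations()].
#' @param dag A list with `terms` and `parents` as returned by [read_obo()],
#'   or `NULL` to treat every annotated term as a child of the root.
#' @param root Identifier used for the virtual root joining all namespaces.
#' @return An object of class `ego_ontology` with fields `terms`, `parents`,
#'   `ancestors`, `ic` (named numeric, bits), `annotations` (named list of
#'   ancestor-closed term sets) and `root`.
#' @export
build_ontology <- function(annotations, dag = NULL, root = "VR:0000000") {
  if (is.character(annotations) && length(annotations) == 1L) {
    annotations <- read_annotations(annotations)
  }
  stopifnot(all(c("protein", "term") %in% names(annotations)))
  annotations <- dplyr::distinct(tibble::as_tibble(annotations[, c("protein", "term")]))

  if (is.null(dag)) {
    dag <- list(terms = unique(annotations$term), parents = list())
  }
  missing_terms <- setdiff(unique(annotations$term), dag$terms)
  if (length(missing_terms) > 0L) {
    stop("annotated term(s) absent from ontology DAG: ",
         paste(utils::head(missing_terms, 5L), collapse = ", "), call. = FALSE)
  }

  terms <- union(dag$terms, root)
  parents <- dag$parents
  # every parentless term (other than the root) hangs off the virtual root
  for (t in setdiff(terms, root)) {
    p <- parents[[t]]
    if (is.null(p) || length(p) == 0L) parents[[t]] <- root
  }
  parents[[root]] <- character()

  ancestors <- closure_map(terms, parents, root)

  ann_closed <- annotations |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(terms = list(unique(unlist(ancestors[unique(.data$term)],
                                                use.names = FALSE))),
                     .groups = "drop")
  ann_list <- rlang::set_names(ann_closed$terms, ann_closed$protein)

  n <- length(ann_list)
  counts <- table(unlist(ann_list, use.names = FALSE))
  # terms annotating no protein keep infinite IC; they can never occur inside a
  # closed annotation set, so simGIC sums are unaffected
  ic <- rlang::set_names(rep(Inf, length(terms)), terms)
  ic[names(counts)] <- -log2(as.numeric(counts) / n)
  ic[ic < 0] <- 0 # guard against -0 from counts == n
  ic[root] <- 0

  structure(
    list(terms = terms, parents = parents, ancestors = ancestors,
         ic = ic, annotations = ann_list, root = root,
         cache = new.env(parent = emptyenv())),
    class = "ego_ontology"
  )
}

# ancestor sets (self-inclusive, root-inclusive) by memoized DFS; errors on cycles
closure_map <- function(terms, parents, root) {
  anc <- rlang::set_names(vector("list", length(terms)), terms)
  state <- rlang::set_names(integer(length(terms)), terms) # 0 new, 1 visiting, 2 done
  visit <- function(t) {
    if (state[[t]] == 2L) return(anc[[t]])
    if (state[[t]] == 1L) stop("ontology DAG contains a cycle at term ", t, call. = FALSE)
    state[[t]] <<- 1L
    ps <- parents[[t]]
    up <- if (length(ps)) unique(unlist(lapply(ps, visit), use.names = FALSE)) else character()
    anc[[t]] <<- unique(c(t, up, root))
    state[[t]] <<- 2L
    anc[[t]]
  }
  for (t in terms) visit(t)
  anc
}

#' @export
print.ego_ontology <- function(x, ...) {
  cat("<ego_ontology> ", length(x$terms), " terms, ",
      length(x$annotations), " annotated proteins\n", sep = "")
  invisible(x)
}

#' Term information content as a tibble
#'
#' @param ontology An `ego_ontology`.
#' @return A tibble with columns `term` and `ic` (bits).
#' @export
term_ic <- function(ontology) {
  stopifnot(inherits(ontology, "ego_ontology"))
  tibble::tibble(term = names(ontology$ic), ic = unname(ontology$ic))
}

#' simGIC semantic similarity between two proteins
#'
#' Graph-information-content similarity over ancestor-closed annotation sets:
#' the summed information content of the shared terms divided by that of the
#' union. Bounded in \[0, 1\]; defined as 0 when the union carries no
#' information (e.g. both proteins annotated only to the virtual root).
#'
#' @param ontology An `ego_ontology`.
#' @param a,b Protein accessions present in the ontology's annotation map.
#' @return A similarity in \[0, 1\].
#' @export
simgic <- function(ontology, a, b) {
  sa <- ontology$annotations[[a]]
  sb <- ontology$annotations[[b]]
  if (is.null(sa)) stop("protein not annotated: ", a, call. = FALSE)
  if (is.null(sb)) stop("protein not annotated: ", b, call. = FALSE)
  ic <- ontology$ic
  denom <- sum(ic[union(sa, sb)])
  if (denom <= 0) return(0)
  sum(ic[intersect(sa, sb)]) / denom
}

#' Pairwise simGIC similarity matrix
#'
#' Computes (and caches on the ontology object) the full symmetric simGIC
#' matrix for a set of proteins. All downstream stages — edge weighting,
#' semantic profiles, ego z-filtering, functional distances and random-network
#' reweighting — read from this one matrix, so each pair is evaluated once.
#'
#' @param ontology An `ego_ontology`.
#' @param proteins Character vector of annotated protein accessions.
#' @return A symmetric numeric matrix with unit diagonal (for proteins whose
#'   annotations carry information).
#' @export
simgic_matrix <- function(ontology, proteins) {
  stopifnot(inherits(ontology, "ego_ontology"))
  proteins <- unique(proteins)
  key <- paste0("simgic_", rlang::hash(sort(proteins)))
  cached <- ontology$cache[[key]]
  if (!is.null(cached)) return(cached)

  unannot <- proteins[!proteins %in% names(ontology$annotations)]
  if (length(unannot) > 0L) {
    stop("protein not annotated: ", paste(utils::head(unannot, 5L), collapse = ", "),
         call. = FALSE)
  }
  ic <- ontology$ic
  # incidence of closed sets over the terms actually used keeps this vectorized
  used <- unique(unlist(ontology$annotations[proteins], use.names = FALSE))
  inc <- vapply(proteins, function(p) as.numeric(used %in% ontology$annotations[[p]]),
                numeric(length(used)))
  icv <- ic[used]
  B <- inc * sqrt(icv)
  self <- colSums(inc * icv)              # per-protein total IC
  inter <- crossprod(B)                   # pairwise intersection IC sums, symmetric
  un <- outer(self, self, "+") - inter    # union IC sums
  sim <- ifelse(un > 0, inter / un, 0)
  sim <- pmin(pmax(sim, 0), 1)            # clamp floating-point spill
  dimnames(sim) <- list(proteins, proteins)
  ontology$cache[[key]] <- sim
  sim
}

#' Per-node semantic profile of a network
#'
#' For every node, the mean and population standard deviation of its simGIC
#' similarity against all other network nodes. These moments parameterize the
#' z-score filter applied during ego decomposition.
#'
#' @param network A `weighted_network`.
#' @param ontology An `ego_ontology`.
#' @return A tibble with columns `protein`, `mean_sim` and `sd_sim`.
#' @export
semantic_profile <- function(network, ontology) {
  nodes <- network_nodes(network)
  if (length(nodes) < 2L) stop("semantic profile needs at least 2 nodes", call. = FALSE)
  sim <- simgic_matrix(ontology, nodes)
  n <- length(nodes)
  mu <- (rowSums(sim) - diag(sim)) / (n - 1)
  dev2 <- (sim - mu)^2
  sd_pop <- sqrt(pmax((rowSums(dev2) - diag(dev2)) / (n - 1), 0))
  tibble::tibble(protein = nodes, mean_sim = unname(mu), sd_sim = unname(sd_pop))
}
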
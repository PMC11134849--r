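#' Specification for a synthetic study
#'
#' Defines the toy-scale conditions under which the whole pipeline is
#' exercised without downloads: a random term DAG with community-specific
#' term pools, a stochastic-block-model interaction network with planted
#' communities, and a phospho table whose signal sites concentrate on one
#' designated "active" community.
#'
#' @param n_communities Number of planted communities.
#' @param community_size Proteins per community.
#' @param p_within,p_between Within-/between-community edge probabilities.
#' @param n_terms Ontology terms (excluding the virtual root).
#' @param depth DAG depth (levels below the root).
#' @param terms_per_protein Direct annotations drawn per protein.
#' @param coherence Probability that a protein draws a term from its own
#'   community's pool (1 = perfectly coherent annotation).
#' @param n_seed_sites Signal phosphosites planted on the active community.
#' @param noise Noise fraction: `round(noise * n_seed_sites)` additional
#'   low-functional-score sites drawn uniformly from all proteins.
#' @param seed Integer seed; generators are pure functions of (spec, seed).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(n_communities = 3, community_size = 30, p_within = 0.3,
                         p_between = 0.01, n_terms = 60, depth = 3,
                         terms_per_protein = 6, coherence = 0.9,
                         n_seed_sites = 40, noise = 0.1, seed = 1) {
  stopifnot(n_communities >= 1, community_size >= 2, depth >= 1,
            p_within >= 0, p_within <= 1, p_between >= 0, p_between <= 1,
            coherence >= 0, coherence <= 1, noise >= 0, noise <= 1,
            n_terms >= depth, n_seed_sites >= 1)
  structure(as.list(environment()), class = "fixture_spec")
}

protein_ids <- function(spec) {
  sprintf("P%04d", seq_len(spec$n_communities * spec$community_size))
}

community_table <- function(spec) {
  tibble::tibble(
    protein = protein_ids(spec),
    community = rep(seq_len(spec$n_communities), each = spec$community_size)
  )
}

#' Generate a synthetic ontology with community-specific term pools
#'
#' Builds a random DAG of `n_terms` arranged in `depth` levels (level-1
#' terms attach to the virtual root at load time; deeper terms take one or
#' two parents from the level above). Leaf-level terms are partitioned into
#' one pool per community, and each protein draws `terms_per_protein`
#' annotations from its own pool with probability `coherence`, otherwise
#' from the global leaf pool.
#'
#' @param spec A `fixture_spec`.
#' @param seed Seed (defaults to `spec$seed`).
#' @return A list with `dag` (terms/parents, as [read_obo()] returns),
#'   `annotations` (tibble protein/term), `pools` (list of per-community
#'   term pools), `communities` (tibble protein/community).
#' @export
synth_ontology <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(seed, {
    terms <- sprintf("T%04d", seq_len(spec$n_terms))
    # level sizes grow towards the leaves so pools are term-rich
    raw <- seq_len(spec$depth)
    sizes <- pmax(1L, round(spec$n_terms * raw / sum(raw)))
    while (sum(sizes) > spec$n_terms) sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
    while (sum(sizes) < spec$n_terms) sizes[spec$depth] <- sizes[spec$depth] + 1L
    level <- rep(seq_len(spec$depth), times = sizes)
    parents <- rlang::set_names(vector("list", spec$n_terms), terms)
    for (i in seq_along(terms)) {
      if (level[i] == 1L) {
        parents[[terms[i]]] <- character() # attaches to the virtual root
      } else {
        pool <- terms[level == level[i] - 1L]
        k <- if (length(pool) > 1L && stats::runif(1) < 0.3) 2L else 1L
        parents[[terms[i]]] <- sample(pool, min(k, length(pool)))
      }
    }
    leaves <- terms[level == spec$depth]
    pools <- split(leaves, rep_len(seq_len(spec$n_communities), length(leaves)))
    comm <- community_table(spec)
    ann <- purrr::map2(comm$protein, comm$community, function(p, ci) {
      own <- pools[[ci]]
      drawn <- vapply(seq_len(spec$terms_per_protein), function(k) {
        if (stats::runif(1) < spec$coherence) sample(own, 1L) else sample(leaves, 1L)
      }, character(1))
      tibble::tibble(protein = p, term = unique(drawn))
    }) |>
      dplyr::bind_rows()
    list(dag = list(terms = terms, parents = parents), annotations = ann,
         pools = pools, communities = comm)
  })
}

#' Generate a planted-community interaction network
#'
#' Stochastic-block-model edges (within-community probability `p_within`,
#' between `p_between`) plus one random spanning tree per community so every
#' community is internally connected.
#'
#' @param spec A `fixture_spec`.
#' @param seed Seed (defaults to `spec$seed`).
#' @return A tibble with columns `from`, `to` (deduplicated, no loops).
#' @export
synth_network <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(seed, {
    comm <- community_table(spec)
    prots <- comm$protein
    idx <- utils::combn(length(prots), 2L)
    same <- comm$community[idx[1L, ]] == comm$community[idx[2L, ]]
    p <- ifelse(same, spec$p_within, spec$p_between)
    keep <- stats::runif(ncol(idx)) < p
    edges <- tibble::tibble(from = prots[idx[1L, keep]], to = prots[idx[2L, keep]])
    trees <- purrr::map(split(comm$protein, comm$community), function(ps) {
      ord <- sample(ps)
      if (length(ord) < 2L) return(NULL)
      tibble::tibble(from = ord[-1L],
                     to = vapply(seq(2L, length(ord)),
                                 function(i) sample(ord[seq_len(i - 1L)], 1L),
                                 character(1)))
    })
    out <- dplyr::bind_rows(c(list(edges), unname(trees))) |>
      dplyr::mutate(a = pmin(.data$from, .data$to), b = pmax(.data$from, .data$to)) |>
      dplyr::distinct(.data$a, .data$b) |>
      dplyr::transmute(from = .data$a, to = .data$b)
    out
  })
}

#' Generate a phospho table and kinase lists for the planted signal
#'
#' Plants `n_seed_sites` high-|lfc|, high-functional-score sites (mixed
#' signs, so both directions carry signal) on proteins of the active
#' community (community 1), appoints tyrosine kinases and other kinases
#' within it (each guaranteed one strong site), and adds
#' `round(noise * n_seed_sites)` low-functional-score sites drawn uniformly
#' from all proteins.
#'
#' @param spec A `fixture_spec`.
#' @param seed Seed (defaults to `spec$seed`).
#' @return A list with `phospho` (tibble: protein, position, residue, lfc,
#'   fscore), `tyr_kinases`, `kinases` (accession vectors; tyrosine kinases
#'   included), `active_community` (integer).
#' @export
synth_phospho_table <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "fixture_spec"))
  withr::with_seed(seed, {
    comm <- community_table(spec)
    active <- comm$protein[comm$community == 1L]
    n_tyr <- min(4L, length(active))
    n_kin <- min(6L, length(active) - n_tyr)
    picked <- sample(active, n_tyr + n_kin)
    tyr <- picked[seq_len(n_tyr)]
    kin <- picked[-seq_len(n_tyr)]
    site <- function(p, strong) {
      tibble::tibble(
        protein = p,
        position = sample(20:800, length(p), replace = TRUE),
        residue = sample(c("S", "T", "Y"), length(p), replace = TRUE),
        lfc = sample(c(-1, 1), length(p), replace = TRUE) *
          stats::runif(length(p), if (strong) 2 else 0.2, if (strong) 4 else 1.5),
        fscore = stats::runif(length(p), if (strong) 0.6 else 0, if (strong) 1 else 0.4)
      )
    }
    signal <- site(sample(active, spec$n_seed_sites, replace = TRUE), strong = TRUE)
    # pathway kinases are modulated: one strong site of each sign per kinase
    kin_sites <- dplyr::mutate(
      site(rep(c(tyr, kin), each = 2L), strong = TRUE),
      lfc = abs(.data$lfc) * rep(c(1, -1), times = n_tyr + n_kin)
    )
    n_noise <- round(spec$noise * spec$n_seed_sites)
    noise <- if (n_noise > 0L) site(sample(comm$protein, n_noise, replace = TRUE),
                                    strong = FALSE)
    phospho <- dplyr::bind_rows(signal, kin_sites, noise)
    list(phospho = phospho, tyr_kinases = tyr, kinases = c(tyr, kin),
         active_community = 1L)
  })
}

#' Generate a complete synthetic study
#'
#' @param spec A `fixture_spec`.
#' @return A list bundling the ontology (`ego_ontology` plus the raw pieces),
#'   network edge tibble, phospho table, kinase lists, community table and
#'   the active community id.
#' @export
synth_study <- function(spec = fixture_spec()) {
  onto_parts <- synth_ontology(spec)
  edges <- synth_network(spec, seed = spec$seed + 1000L)
  ph <- synth_phospho_table(spec, seed = spec$seed + 2000L)
  ontology <- build_ontology(onto_parts$annotations, onto_parts$dag)
  list(spec = spec, ontology = ontology, dag = onto_parts$dag,
       annotations = onto_parts$annotations, edges = edges,
       phospho = ph$phospho, tyr_kinases = ph$tyr_kinases, kinases = ph$kinases,
       communities = onto_parts$communities, active_community = ph$active_community)
}

#' Write a term DAG as an OBO 1.2 file
#'
#' @param dag A list with `terms` and `parents`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  lines <- c("format-version: 1.2", "")
  for (t in dag$terms) {
    ps <- dag$parents[[t]]
    lines <- c(lines, "[Term]", paste0("id: ", t), paste0("name: ", t),
               if (length(ps)) paste0("is_a: ", ps), "")
  }
  readr::write_lines(lines, path)
  invisible(path)
}

#' Write all files of a synthetic study to a directory
#'
#' Emits exactly the formats the loaders consume: `ontology.obo`,
#' `annotations.tsv` (two columns), `network.tsv` (edge list),
#' `phospho.tsv`, `tyr_kinases.txt`, `kinases.txt`.
#'
#' @param study A list from [synth_study()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the written paths, invisibly.
#' @export
write_fixture_files <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    obo = file.path(dir, "ontology.obo"),
    annotations = file.path(dir, "annotations.tsv"),
    network = file.path(dir, "network.tsv"),
    phospho = file.path(dir, "phospho.tsv"),
    tyr_kinases = file.path(dir, "tyr_kinases.txt"),
    kinases = file.path(dir, "kinases.txt")
  )
  write_obo(study$dag, paths[["obo"]])
  readr::write_tsv(study$annotations, paths[["annotations"]], col_names = FALSE)
  readr::write_tsv(study$edges, paths[["network"]], col_names = FALSE)
  readr::write_tsv(study$phospho, paths[["phospho"]])
  readr::write_lines(study$tyr_kinases, paths[["tyr_kinases"]])
  readr::write_lines(study$kinases, paths[["kinases"]])
  invisible(paths)
}

#' Planted-signal recovery of a pipeline result
#'
#' Measures how well the extracted signature recovers the fixture's active
#' community: the union of the largest module of each direction (the up and
#' down signatures are two halves of one planted signal) is compared with
#' the active community's proteins present in the network.
#'
#' @param result An `ego_signature` from [run_pipeline()].
#' @param study The `synth_study()` list the pipeline ran on.
#' @return A one-row tibble: `recovered` (fraction of active-community
#'   network proteins in the union), `off_community` (fraction of the union
#'   outside the active community), `union_size`.
#' @export
planted_recovery <- function(result, study) {
  active <- study$communities$protein[study$communities$community == study$active_community]
  active <- intersect(active, network_nodes(result$network))
  largest <- purrr::map(result$modules, function(part) {
    mm <- module_members(part)
    if (nrow(mm) == 0L) return(character())
    sizes <- table(mm$module)
    mm$protein[mm$module == names(sizes)[which.max(sizes)]]
  })
  un <- unique(unlist(largest, use.names = FALSE))
  tibble::tibble(
    recovered = if (length(active)) length(intersect(un, active)) / length(active) else NA_real_,
    off_community = if (length(un)) length(setdiff(un, active)) / length(un) else NA_real_,
    union_size = length(un)
  )
}
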
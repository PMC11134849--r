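#' Read a phosphoproteomics site table
#'
#' Tab-separated with a header; mandatory columns `protein`, `position`,
#' `lfc` (log2 fold change); optional `residue` (S/T/Y) and `fscore`
#' (functional score in \[0, 1\]). Rows whose `lfc` does not parse as a
#' number are reported by row number and skipped.
#'
#' @param path Path to a TSV file, or a data frame with the same columns.
#' @return A tibble with columns `protein`, `position`, `residue`, `lfc`,
#'   `fscore` (missing optional values are `NA`).
#' @export
read_phospho_table <- function(path) {
  if (is.data.frame(path)) {
    df <- tibble::as_tibble(path)
  } else {
    if (!file.exists(path)) stop("cannot read phospho table: ", path, call. = FALSE)
    df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                          progress = FALSE)
  }
  names(df) <- tolower(names(df))
  need <- c("protein", "position", "lfc")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("phospho table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  lfc <- suppressWarnings(as.numeric(df$lfc))
  bad <- which(is.na(lfc) & !(is.na(df$lfc) | df$lfc == ""))
  bad <- union(bad, which(is.na(lfc)))
  if (length(bad) > 0L) {
    warning("skipping ", length(bad), " row(s) with non-numeric lfc (rows ",
            paste(utils::head(bad, 5L), collapse = ", "), ")", call. = FALSE)
  }
  out <- tibble::tibble(
    protein = as.character(df$protein),
    position = suppressWarnings(as.integer(df$position)),
    residue = if ("residue" %in% names(df)) toupper(as.character(df$residue)) else NA_character_,
    lfc = lfc,
    fscore = if ("fscore" %in% names(df)) suppressWarnings(as.numeric(df$fscore)) else NA_real_
  )
  out <- out[!is.na(out$lfc), , drop = FALSE]
  if (any(out$position < 1L, na.rm = TRUE)) stop("site positions must be >= 1", call. = FALSE)
  if (any(out$fscore < 0 | out$fscore > 1, na.rm = TRUE)) {
    stop("functional scores must lie in [0, 1]", call. = FALSE)
  }
  out
}

#' Aggregate phosphosites to direction-specific protein scores
#'
#' Splits sites by sign of the log2 fold change and keeps, per protein and
#' direction, the maximum |lfc| and the maximum functional score among that
#' protein's direction-consistent sites. A protein with sites of both signs
#' appears in both directions.
#'
#' @param records A tibble from [read_phospho_table()].
#' @param direction `"up"` (lfc > 0) or `"down"` (lfc < 0; magnitudes used).
#' @return A tibble with columns `protein`, `lfc` (magnitude) and `fscore`
#'   (`NA` when no site of the protein carries a score).
#' @export
aggregate_protein_scores <- function(records, direction = c("up", "down")) {
  direction <- match.arg(direction)
  sel <- if (direction == "up") records$lfc > 0 else records$lfc < 0
  records[sel, , drop = FALSE] |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      lfc = max(abs(.data$lfc)),
      fscore = if (all(is.na(.data$fscore))) NA_real_ else max(.data$fscore, na.rm = TRUE),
      .groups = "drop"
    )
}

#' Partition proteins into kinase layers
#'
#' Splits a protein set into (i) tyrosine kinases, (ii) other kinases and
#' (iii) non-kinase substrates. Precedence is by set subtraction: a protein
#' on both lists lands in the tyrosine-kinase layer.
#'
#' @param proteins Character vector of protein accessions.
#' @param tyr_kinases,kinases Accession vectors (or paths to one-per-line
#'   files) of tyrosine kinases and of all kinases.
#' @return A tibble with columns `protein` and `layer`
#'   (`"tyr_kinase"`, `"kinase"`, `"substrate"`).
#' @export
partition_layers <- function(proteins, tyr_kinases = character(), kinases = character()) {
  tyr_kinases <- read_id_list(tyr_kinases)
  kinases <- read_id_list(kinases)
  if (length(tyr_kinases) == 0L && length(kinases) == 0L) {
    warning("empty kinase lists: all proteins assigned to the substrate layer",
            call. = FALSE)
  }
  layer <- dplyr::case_when(
    proteins %in% tyr_kinases ~ "tyr_kinase",
    proteins %in% setdiff(kinases, tyr_kinases) ~ "kinase",
    TRUE ~ "substrate"
  )
  tibble::tibble(protein = proteins, layer = layer)
}

read_id_list <- function(x) {
  if (length(x) == 1L && is.character(x) && file.exists(x)) {
    x <- readr::read_lines(x)
  }
  x <- stringr::str_trim(as.character(x))
  unique(x[x != ""])
}

#' Percentile filtering of layered seed candidates
#'
#' Kinase layers (tyrosine and other) keep proteins that carry a functional
#' score and exceed the `kinase_percentile` of both |lfc| and functional
#' score within their own layer; the substrate layer keeps proteins
#' exceeding the `substrate_percentile` of both. Percentiles are
#' linear-interpolation quantiles over the layer's own values and the
#' comparison is strict. Alternatively `top_n` keeps the `top_n`
#' highest-|lfc| proteins of the whole direction, ignoring percentiles.
#'
#' Layers with fewer than 2 scored proteins pass through unfiltered with a
#' warning; a strict filter that would empty a layer whose values are all
#' identical also falls back to keeping the layer, with a warning.
#'
#' @param scored A tibble with columns `protein`, `layer`, `lfc`, `fscore`
#'   (one direction; join of [aggregate_protein_scores()] and
#'   [partition_layers()]).
#' @param kinase_percentile,substrate_percentile Percentile thresholds
#'   (defaults 20 and 80).
#' @param top_n Optional count replacing the percentile rule.
#' @return The filtered tibble, same columns.
#' @export
percentile_filter <- function(scored, kinase_percentile = 20,
                              substrate_percentile = 80, top_n = NULL) {
  stopifnot(all(c("protein", "layer", "lfc", "fscore") %in% names(scored)))
  if (!is.null(top_n)) {
    keep <- scored |>
      dplyr::arrange(dplyr::desc(.data$lfc)) |>
      dplyr::slice_head(n = as.integer(top_n))
    return(dplyr::arrange(keep, .data$protein))
  }
  one_layer <- function(df, pct) {
    cand <- df[!is.na(df$fscore), , drop = FALSE] # score required for filtering
    if (nrow(cand) < 2L) {
      warning("layer '", df$layer[1], "' has <2 scored proteins; passed through unfiltered",
              call. = FALSE)
      return(df)
    }
    q_lfc <- stats::quantile(cand$lfc, pct / 100, names = FALSE, type = 7)
    q_fs <- stats::quantile(cand$fscore, pct / 100, names = FALSE, type = 7)
    keep <- cand[cand$lfc > q_lfc & cand$fscore > q_fs, , drop = FALSE]
    if (nrow(keep) == 0L &&
        length(unique(cand$lfc)) == 1L && length(unique(cand$fscore)) == 1L) {
      warning("layer '", df$layer[1], "': all values identical; strict filter would drop ",
              "everything, layer kept unfiltered", call. = FALSE)
      return(cand)
    }
    keep
  }
  out <- scored |>
    dplyr::group_by(.data$layer) |>
    dplyr::group_split() |>
    purrr::map(function(df) {
      pct <- if (df$layer[1] == "substrate") substrate_percentile else kinase_percentile
      one_layer(df, pct)
    }) |>
    dplyr::bind_rows()
  dplyr::arrange(out, .data$protein)
}

#' Build a restart probability vector for one seed layer
#'
#' Seed |lfc| values are min-max scaled into (0, 1] — the layer minimum maps
#' to a small positive floor so no seed loses all restart mass — and then
#' normalized to sum to one over all network nodes. Seeds absent from the
#' network are dropped with a warning.
#'
#' @param layer A tibble with columns `protein` and `lfc` (magnitudes).
#' @param network A `weighted_network` (any normalization state).
#' @param floor Positive scale floor for the layer's weakest seed.
#' @return A named numeric probability vector over all network nodes, or
#'   `NULL` (with a warning) when no seed maps into the network.
#' @export
build_restart_vector <- function(layer, network, floor = 0.01) {
  nodes <- network_nodes(network)
  missing <- setdiff(layer$protein, nodes)
  if (length(missing) > 0L) {
    warning("seed(s) absent from network dropped: ",
            paste(utils::head(missing, 5L), collapse = ", "), call. = FALSE)
  }
  layer <- layer[layer$protein %in% nodes, , drop = FALSE]
  if (nrow(layer) == 0L) {
    warning("no seeds of this layer map into the network; layer skipped", call. = FALSE)
    return(NULL)
  }
  v <- abs(layer$lfc)
  rng <- range(v)
  scaled <- if (rng[1] == rng[2]) rep(1, length(v)) else {
    floor + (1 - floor) * (v - rng[1]) / (rng[2] - rng[1])
  }
  restart <- rlang::set_names(numeric(length(nodes)), nodes)
  restart[layer$protein] <- scaled / sum(scaled)
  restart
}

#' Assemble direction-specific seed layers from a phospho table
#'
#' Convenience wrapper chaining [aggregate_protein_scores()],
#' [partition_layers()] and [percentile_filter()] for one direction, then
#' collapsing to the requested number of propagation layers: 3 keeps
#' tyrosine kinases, other kinases and substrates separate; 2 merges the two
#' kinase layers; 1 pools all seeds.
#'
#' @param records Tibble from [read_phospho_table()].
#' @param direction `"up"` or `"down"`.
#' @param tyr_kinases,kinases Accession vectors or list-file paths.
#' @param layers Number of propagation layers (1, 2 or 3).
#' @inheritParams percentile_filter
#' @return A `seed_layers` object: named list of per-layer tibbles
#'   (`protein`, `lfc`, `fscore`) with attributes `direction` and `layers`.
#' @export
build_seed_layers <- function(records, direction, tyr_kinases = character(),
                              kinases = character(), layers = 3,
                              kinase_percentile = 20, substrate_percentile = 80,
                              top_n = NULL) {
  stopifnot(layers %in% 1:3)
  scored <- aggregate_protein_scores(records, direction)
  parts <- partition_layers(scored$protein, tyr_kinases, kinases)
  scored <- dplyr::left_join(scored, parts, by = "protein")
  filtered <- percentile_filter(scored, kinase_percentile, substrate_percentile, top_n)
  filtered$layer_group <- switch(as.character(layers),
    "3" = filtered$layer,
    "2" = ifelse(filtered$layer == "substrate", "substrate", "kinase"),
    "1" = "all"
  )
  out <- filtered |>
    dplyr::group_by(.data$layer_group) |>
    dplyr::group_split() |>
    rlang::set_names(purrr::map_chr(
      filtered |> dplyr::group_by(.data$layer_group) |> dplyr::group_split(),
      ~ .x$layer_group[1]
    )) |>
    purrr::map(~ dplyr::select(.x, "protein", "lfc", "fscore"))
  structure(out, direction = direction, layers = layers, class = "seed_layers")
}

#' @export
print.seed_layers <- function(x, ...) {
  cat("<seed_layers> direction=", attr(x, "direction"), ": ",
      paste(names(x), vapply(x, nrow, 1L), sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' All seed proteins of a seed-layer set
#' @param layers A `seed_layers` object.
#' @return Character vector of seed accessions.
#' @export
seed_proteins <- function(layers) {
  unique(unlist(purrr::map(layers, "protein"), use.names = FALSE))
}
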
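#' Read a GMT gene-set collection
#'
#' @param path Path to a GMT file (set name, description, members...).
#' @return A named list of character vectors.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("cannot read GMT file: ", path, call. = FALSE)
  lines <- readr::read_lines(path)
  lines <- lines[stringr::str_trim(lines) != ""]
  toks <- stringr::str_split(lines, "\t")
  sets <- purrr::map(toks, ~ unique(.x[-(1:2)][.x[-(1:2)] != ""]))
  names(sets) <- purrr::map_chr(toks, 1L)
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT", call. = FALSE)
  sets[lengths(sets) > 0L]
}

#' Over-representation analysis by Fisher's exact test
#'
#' One-sided (over-representation) Fisher exact test of a foreground protein
#' set against each gene set, with the supplied background as universe. Sets
#' are intersected with the background before testing; p-values are
#' Bonferroni-corrected over the sets tested.
#'
#' @param foreground Character vector, a subset of `background`.
#' @param sets Named list of character vectors (e.g. from [read_gmt()]).
#' @param background Character vector, the test universe (typically all
#'   network nodes).
#' @return A tibble sorted by adjusted p with columns `set`, `overlap`,
#'   `fg_size`, `set_size`, `bg_size`, `p_value`, `p_adjusted`, `fold`.
#' @export
fisher_enrichment <- function(foreground, sets, background) {
  foreground <- unique(foreground)
  background <- unique(background)
  if (!all(foreground %in% background)) {
    stop("foreground must be a subset of the background", call. = FALSE)
  }
  n_sets <- length(sets)
  res <- purrr::imap(sets, function(members, nm) {
    members <- intersect(unique(members), background)
    k <- length(intersect(foreground, members))
    tibble::tibble(
      set = nm,
      overlap = k,
      fg_size = length(foreground),
      set_size = length(members),
      bg_size = length(background),
      p_value = fisher_overrep_p(k, length(foreground), length(members), length(background)),
      fold = fold_enrichment(k, length(foreground), length(members), length(background))
    )
  }) |>
    dplyr::bind_rows()
  res |>
    dplyr::mutate(p_adjusted = pmin(1, .data$p_value * n_sets), .before = "fold") |>
    dplyr::arrange(.data$p_adjusted, .data$p_value)
}

# one-sided (greater) Fisher exact p for a 2x2 over-representation table
fisher_overrep_p <- function(overlap, fg_size, set_size, bg_size) {
  tab <- matrix(c(overlap,
                  fg_size - overlap,
                  set_size - overlap,
                  bg_size - fg_size - set_size + overlap), nrow = 2L)
  if (any(tab < 0)) stop("inconsistent 2x2 table counts", call. = FALSE)
  stats::fisher.test(tab, alternative = "greater")$p.value
}

#' Fold enrichment of an overlap over chance
#'
#' Observed overlap divided by its expectation under independence,
#' `fg_size * set_size / bg_size`.
#'
#' @param overlap,fg_size,set_size,bg_size 2x2 table counts.
#' @return The ratio, or `NA_real_` when the expectation is zero.
#' @export
fold_enrichment <- function(overlap, fg_size, set_size, bg_size) {
  if (bg_size <= 0 || fg_size <= 0) stop("background and foreground must be non-empty",
                                         call. = FALSE)
  expected <- fg_size * set_size / bg_size
  if (expected == 0) return(NA_real_)
  overlap / expected
}

#' Percentile rank of a set in an enrichment table
#'
#' Position of a named set among all tested sets, ranked by significance:
#' 100 means the set outranks every other set.
#'
#' @param result Tibble from [fisher_enrichment()] (already sorted).
#' @param set Set name.
#' @return Percentile in \[0, 100\].
#' @export
enrichment_percentile <- function(result, set) {
  pos <- which(result$set == set)
  if (length(pos) != 1L) stop("set not found in enrichment result: ", set, call. = FALSE)
  100 * (nrow(result) - pos + 1L) / nrow(result)
}

#' Overlap (Szymkiewicz-Simpson) coefficient
#'
#' `|X intersect Y| / min(|X|, |Y|)`: 1 whenever one set contains the other.
#'
#' @param x,y Non-empty character vectors.
#' @return A value in \[0, 1\].
#' @export
overlap_coefficient <- function(x, y) {
  x <- unique(x)
  y <- unique(y)
  if (length(x) == 0L || length(y) == 0L) stop("overlap coefficient needs non-empty sets",
                                               call. = FALSE)
  length(intersect(x, y)) / min(length(x), length(y))
}

#' Overlap distance
#'
#' `1 - overlap_coefficient(x, y)`; the distance between a set and itself
#' is 0.
#'
#' @inheritParams overlap_coefficient
#' @return A value in \[0, 1\].
#' @export
overlap_distance <- function(x, y) {
  1 - overlap_coefficient(x, y)
}

#' Best-matching module for a reference protein set
#'
#' Among modules with at least `min_size` member proteins (small modules
#' inflate the overlap coefficient artificially), returns the one maximizing
#' the overlap coefficient against the reference; ties are broken by larger
#' module, then lexicographic module id.
#'
#' @param partition A `module_partition`.
#' @param reference Character vector of reference proteins.
#' @param min_size Minimum module size (default 10).
#' @return A one-row tibble (`module`, `size`, `coefficient`), or a zero-row
#'   tibble with a warning when no module passes the size filter.
#' @export
best_module_match <- function(partition, reference, min_size = 10) {
  members <- attr(partition, "members")
  sizes <- lengths(members)
  keep <- names(sizes)[sizes >= min_size]
  if (length(keep) == 0L) {
    warning("no module reaches the minimum size of ", min_size, call. = FALSE)
    return(tibble::tibble(module = character(), size = integer(), coefficient = numeric()))
  }
  tab <- tibble::tibble(
    module = keep,
    size = as.integer(sizes[keep]),
    coefficient = purrr::map_dbl(members[keep], ~ overlap_coefficient(.x, reference))
  )
  tab |>
    dplyr::arrange(dplyr::desc(.data$coefficient), dplyr::desc(.data$size), .data$module) |>
    dplyr::slice_head(n = 1L)
}
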
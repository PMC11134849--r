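path_graph <- function(nodes) {
  g <- igraph::make_ring(length(nodes), circular = FALSE)
  igraph::V(g)$name <- nodes
  igraph::E(g)$weight <- 1
  g
}

test_that("two-step ego extraction follows shortest-path distance", {
  dn <- manual_dirnet(path_graph(c("a", "b", "c", "d")), seeds = "a")
  expect_setequal(extract_ego(dn, "a"), c("a", "b", "c"))
  full <- igraph::make_full_graph(5)
  igraph::V(full)$name <- paste0("v", 1:5)
  igraph::E(full)$weight <- 1
  expect_setequal(extract_ego(manual_dirnet(full, "v1"), "v1"), paste0("v", 1:5))
  iso <- igraph::make_empty_graph(directed = FALSE) + igraph::vertices("x")
  expect_equal(extract_ego(manual_dirnet(iso, "x"), "x"), "x")
  expect_error(extract_ego(dn, "zz"), "not present")
})

test_that("the semantic z-filter keeps candidates beyond the 1.64 cutoff", {
  onto <- tiny_ontology()
  # ego A: simGIC(A,B) high, simGIC(A,C) = 0 (root only), simGIC(A,D) partial
  sims <- c(B = simgic(onto, "A", "B"), C = simgic(onto, "A", "C"),
            D = simgic(onto, "A", "D"))
  # profile constructed so that only B clears mean + 1.64 sd
  prof <- tibble::tibble(protein = "A", mean_sim = 0.2,
                         sd_sim = (sims[["B"]] - 0.2) / 2) # z_B = 2, others lower
  kept <- z_filter(c("A", "B", "C", "D"), "A", prof, onto)
  expect_true("B" %in% kept)
  expect_false("C" %in% kept)
  expect_equal(kept[1], "A") # ego always kept
  # candidate exactly at the mean has z = 0 and is excluded
  prof0 <- tibble::tibble(protein = "A", mean_sim = sims[["D"]], sd_sim = 0.1)
  expect_false("D" %in% z_filter(c("A", "D"), "A", prof0, onto))
  # zero spread degenerates to a mean comparison with a warning
  profz <- tibble::tibble(protein = "A", mean_sim = 0.1, sd_sim = 0)
  expect_warning(keptz <- z_filter(c("A", "B", "C"), "A", profz, onto), "zero similarity")
  expect_true("B" %in% keptz)
  expect_false("C" %in% keptz)
})

test_that("ego edges are re-weighted by ego similarity and re-normalized", {
  onto <- tiny_ontology()
  # triangle A-B, B-D, A-D: A is ego; B, D first-order
  g <- igraph::graph_from_data_frame(
    tibble::tibble(from = c("A", "B", "A"), to = c("B", "D", "D")), directed = FALSE)
  igraph::E(g)$weight <- 1
  dn <- manual_dirnet(g, seeds = "A")
  en <- reweight_ego_edges(dn, c("A", "B", "D"), "A", onto)
  expect_setequal(en$first_order, c("B", "D"))
  expect_length(en$second_order, 0)
  # reconstruct the pre-normalization weights via the stored raw degrees
  sAB <- simgic(onto, "A", "B")
  sAD <- simgic(onto, "A", "D")
  expected_raw <- c(`A|B` = sAB, `A|D` = sAD, `B|D` = (sAB + sAD) / 2)
  ne <- network_edges(en$graph)
  key <- paste(pmin(ne$from, ne$to), pmax(ne$from, ne$to), sep = "|")
  raw <- rlang::set_names(expected_raw[key], key)
  d <- tapply(c(raw, raw), c(pmin(ne$from, ne$to), pmax(ne$from, ne$to)), sum)
  # Eq.-1 identity: normalized weight times sqrt(d_i d_j) recovers the raw weight
  recovered <- ne$weight * sqrt(d[pmin(ne$from, ne$to)] * d[pmax(ne$from, ne$to)])
  expect_equal(as.numeric(recovered), as.numeric(raw), tolerance = 1e-12)
})

test_that("second-order edges take the mean ego-similarity weight", {
  onto <- tiny_ontology()
  # path A - B - D: D is second-order from ego A
  dn <- manual_dirnet(path_graph(c("A", "B", "D")), seeds = "A")
  en <- reweight_ego_edges(dn, c("A", "B", "D"), "A", onto)
  expect_equal(en$second_order, "D")
  sAB <- simgic(onto, "A", "B")
  sAD <- simgic(onto, "A", "D")
  ne <- network_edges(en$graph)
  bd <- ne[(ne$from == "B" & ne$to == "D") | (ne$from == "D" & ne$to == "B"), ]
  d_B <- sAB + (sAB + sAD) / 2
  d_D <- (sAB + sAD) / 2
  expect_equal(bd$weight, ((sAB + sAD) / 2) / sqrt(d_B * d_D), tolerance = 1e-12)
})

test_that("topological affinity matches an entropy-based Jensen-Shannon oracle", {
  # identical distributions: JSD 0 -> 1000
  p <- c(a = 0.3, b = 0.7)
  expect_equal(topological_affinity(p, p), 1000)
  # disjoint one-hot distributions: JSD 1 -> 0
  expect_equal(topological_affinity(c(a = 1, b = 0), c(a = 0, b = 1)), 0,
               tolerance = 1e-9)
  # independent oracle: JS divergence = H(m) - (H(p) + H(q)) / 2 in bits
  H <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  q <- c(a = 0.5, b = 0.5)
  p1 <- c(a = 1, b = 0)
  m <- (p1 + q) / 2
  jsd <- sqrt(H(m) - (H(p1) + H(q)) / 2)
  expect_equal(topological_affinity(p1, q), 1000 * log2(2 - jsd), tolerance = 1e-10)
  expect_error(topological_affinity(c(a = 1, b = 0), c(a = 0.5, c = 0.5)),
               "mismatched supports")
})

test_that("affinity decreases with divergence; functional distance grows with simGIC", {
  p <- c(a = 1, b = 0)
  vals <- vapply(seq(0, 0.5, by = 0.05),
                 function(t) topological_affinity(p, c(a = 1 - t, b = t)), numeric(1))
  expect_true(all(diff(vals) < 0))
  onto <- uniform_ontology(c("X", "Y"))
  expect_equal(functional_distance(onto, "X", "Y"), 1000) # simGIC 1 -> 1000*log2(2)
  tiny <- tiny_ontology()
  expect_equal(functional_distance(tiny, "C", "D"), 0)    # simGIC 0 -> 0
  # simGIC 0.5 -> 1000*log2(1.5), checked against direct arithmetic
  expect_equal(1000 * log2(1.5), 584.962500721156, tolerance = 1e-9)
  s <- simgic(tiny, "A", "B")
  expect_equal(functional_distance(tiny, "A", "B"), 1000 * log2(1 + s), tolerance = 1e-9)
})

test_that("KDE joint-CDF selection matches numerical integration of the density", {
  withr::with_seed(31, {
    pts <- tibble::tibble(node = sprintf("n%02d", 1:12),
                          topo = runif(12, 200, 900), func = runif(12, 100, 800))
  })
  res <- kde_select(pts, threshold = 0.85)
  # numeric oracle: quadrature of each Gaussian kernel's density over the
  # lower-left quadrant of the point, averaged over kernels
  x <- pts$topo / 1000; y <- pts$func / 1000; n <- length(x)
  hx <- sd(x) * n^(-1 / 6); hy <- sd(y) * n^(-1 / 6)
  quad <- function(center, h, upper) {
    stats::integrate(function(u) dnorm((u - center) / h) / h,
                     lower = center - 12 * h, upper = upper,
                     rel.tol = 1e-10)$value
  }
  for (j in c(1, 5, 12)) {
    ix <- vapply(x, quad, numeric(1), h = hx, upper = x[j])
    iy <- vapply(y, quad, numeric(1), h = hy, upper = y[j])
    expect_equal(res$cdf[j], mean(ix * iy), tolerance = 1e-7)
  }
  # a point dominating all others attains the maximum CDF
  dom <- dplyr::bind_rows(pts, tibble::tibble(node = "top", topo = 950, func = 900))
  res_dom <- kde_select(dom, threshold = 0.85)
  expect_equal(res_dom$node[which.max(res_dom$cdf)], "top")
})

test_that("KDE selection shrinks as the threshold rises", {
  withr::with_seed(17, {
    pts <- tibble::tibble(node = sprintf("n%02d", 1:25),
                          topo = runif(25, 0, 1000), func = runif(25, 0, 1000))
  })
  prev <- NULL
  for (thr in c(0.80, 0.85, 0.90, 0.95)) {
    sel <- kde_select(pts, thr)
    sel <- sel$node[sel$selected]
    if (!is.null(prev)) expect_true(all(sel %in% prev))
    prev <- sel
  }
  dup <- tibble::tibble(node = c("a", "b"), topo = 500, func = 500)
  expect_warning(res <- kde_select(dup, 0.85), "degenerate")
  expect_true(all(res$selected))
})

test_that("supernode construction gates on neighbor count", {
  onto <- tiny_ontology()
  en <- list(ego = "A", members = c("A", "B", "D"), graph = NULL,
             first_order = c("B", "D"), second_order = character())
  class(en) <- "ego_network"
  # 2 neighbors <= 5: whole functional ego network, no decomposition
  sn <- build_supernode(en, NULL, "up")
  expect_setequal(sn$members, c("A", "B", "D"))
  expect_false(sn$decomposed)
  # above the gate with an empty selection: supernode collapses to the ego
  en2 <- en
  en2$members <- c("A", paste0("x", 1:7))
  sel <- tibble::tibble(node = paste0("x", 1:7), topo = 0, func = 0,
                        cdf = 0, selected = FALSE)
  sn2 <- build_supernode(en2, sel, "up")
  expect_equal(sn2$members, "A")
  expect_true(sn2$decomposed)
  expect_true("A" %in% sn2$members)
})

test_that("direction decomposition yields supernodes nested in their ego networks", {
  st <- small_study()
  res <- small_result()
  for (d in names(res$directions)) {
    dn <- res$directions[[d]]
    for (sn in res$supernodes[[d]]) {
      expect_true(sn$ego %in% sn$members)
      cand <- extract_ego(dn, sn$ego)
      expect_true(all(sn$members %in% cand))
    }
  }
})
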
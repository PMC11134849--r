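# closed-form oracle: p solves (I - damping * T) p = (1 - damping) * r with T
# the column-stochastic transition operator
rwr_oracle <- function(net, restart, damping) {
  g <- net$graph
  nodes <- igraph::V(g)$name
  W <- as.matrix(igraph::as_adjacency_matrix(g, attr = "weight", sparse = FALSE))
  T_ <- sweep(W, 2, colSums(W), "/")
  p <- solve(diag(length(nodes)) - damping * T_, (1 - damping) * restart[nodes])
  rlang::set_names(as.numeric(p), nodes)
}

random_small_net <- function(n, seed) {
  withr::with_seed(seed, {
    repeat {
      g <- igraph::sample_gnp(n, 0.6)
      if (igraph::is_connected(g)) break
    }
    igraph::V(g)$name <- paste0("n", seq_len(n))
    igraph::E(g)$weight <- runif(igraph::ecount(g), 0.2, 1)
    egosig:::new_weighted_network(g, normalized = FALSE)
  })
}

test_that("the walk matches the direct linear-system solution on small graphs", {
  for (seed in 1:5) {
    n <- sample(3:6, 1)
    net <- random_small_net(n, seed)
    nodes <- network_nodes(net)
    restart <- rlang::set_names(rep(1 / n, n), nodes)
    for (damping in c(0.5, 0.85)) {
      p <- rwr(net, restart, damping)
      expect_equal(unname(p), unname(rwr_oracle(net, restart, damping)[nodes]),
                   tolerance = 1e-8)
    }
  }
})

test_that("walk outputs are probability vectors at every damping tested", {
  net <- random_small_net(6, 99)
  nodes <- network_nodes(net)
  restart <- rlang::set_names(c(1, rep(0, 5)), nodes)
  for (damping in c(0, 0.5, 0.7, 0.85)) {
    p <- rwr(net, restart, damping)
    expect_true(all(p >= 0))
    expect_equal(sum(p), 1, tolerance = 1e-9)
  }
})

test_that("degenerate walks reduce to closed forms", {
  net <- random_small_net(5, 4)
  nodes <- network_nodes(net)
  restart <- rlang::set_names(c(0.4, 0.6, 0, 0, 0), nodes)
  # damping 0: fixed point is the restart vector itself
  expect_equal(unname(rwr(net, restart, 0)), unname(restart))
  # single node
  uo <- uniform_ontology("A")
  single <- build_weighted_network(tibble::tibble(from = "A", to = "A"), uo)
  expect_equal(unname(rwr(single, c(A = 1), 0.85)), 1)
  # two nodes, one edge, symmetric restart: symmetry forces (1/2, 1/2)
  pair <- manual_network(tibble::tibble(from = "a", to = "b", weight = 1))
  p <- rwr(pair, c(a = 0.5, b = 0.5), 0.7)
  expect_equal(unname(p), c(0.5, 0.5), tolerance = 1e-10)
  expect_error(rwr(pair, c(a = 0.9, b = 0.3), 0.85), "probability vector")
  expect_error(rwr(pair, c(a = 0.5, b = 0.5), 1), "damping")
})

test_that("the empirical filter applies the strict 95% rule", {
  real <- c(good = 1, tie = 0.5, bad = 0.1)
  null <- rbind(
    good = c(seq_len(951) / 1000, rep(2, 49)),   # exceeds exactly 951 of 1000
    tie = rep(0.5, 1000),                        # equal to every null
    bad = rep(0.2, 1000)
  )
  res <- empirical_filter(real, null, alpha = 0.05)
  expect_true(res$retained[res$protein == "good"])
  expect_false(res$retained[res$protein == "tie"])
  expect_false(res$retained[res$protein == "bad"])
  expect_equal(res$p_empirical[res$protein == "tie"], 1)
  # alpha = 1 retains everything
  expect_true(all(empirical_filter(real, null, alpha = 1)$retained))
  expect_error(empirical_filter(real, null[, 0], 0.05), "empty")
})

test_that("lowering alpha never adds retained nodes", {
  withr::with_seed(21, {
    real <- rlang::set_names(runif(30), paste0("p", 1:30))
    null <- matrix(runif(30 * 200), nrow = 30, dimnames = list(names(real), NULL))
  })
  prev <- NULL
  for (alpha in c(0.5, 0.2, 0.05, 0.01)) {
    kept <- empirical_filter(real, null, alpha)
    kept <- kept$protein[kept$retained]
    if (!is.null(prev)) expect_true(all(kept %in% prev))
    prev <- kept
  }
})

test_that("direction networks keep seeds regardless of filter outcome", {
  uo <- uniform_ontology(paste0("P", 1:5))
  net <- build_weighted_network(
    tibble::tibble(from = c("P1", "P2", "P3", "P4"), to = c("P2", "P3", "P4", "P5")), uo)
  filtered <- list(
    layer_a = tibble::tibble(protein = paste0("P", 1:5), score = c(5, 4, 3, 2, 1) / 15,
                             p_empirical = c(0.01, 0.01, 0.8, 0.8, 0.8),
                             retained = c(TRUE, TRUE, FALSE, FALSE, FALSE)),
    layer_b = tibble::tibble(protein = paste0("P", 1:5), score = rep(0.2, 5),
                             p_empirical = c(0.8, 0.8, 0.01, 0.8, 0.8),
                             retained = c(FALSE, FALSE, TRUE, FALSE, FALSE))
  )
  dn <- build_direction_network(filtered, seeds = c("P5"), net, "up")
  # P5 failed every filter but is a seed; P3 retained by one layer only
  expect_setequal(network_nodes(dn), c("P1", "P2", "P3", "P5"))
  # no retained nodes at all: seeds-only network
  none <- purrr::map(filtered, ~ dplyr::mutate(.x, retained = FALSE))
  dn0 <- build_direction_network(none, seeds = c("P2", "P4"), net, "down")
  expect_setequal(network_nodes(dn0), c("P2", "P4"))
})

test_that("dual membership resolves by larger mean layer score with up tie-break", {
  uo <- uniform_ontology(paste0("P", 1:4))
  net <- build_weighted_network(
    tibble::tibble(from = c("P1", "P2", "P3"), to = c("P2", "P3", "P4")), uo)
  mk <- function(scores, retained, seeds, direction) {
    build_direction_network(
      list(all = tibble::tibble(protein = names(scores), score = unname(scores),
                                p_empirical = 0.01, retained = retained)),
      seeds, net, direction)
  }
  up <- mk(c(P1 = 0.30, P2 = 0.2), c(TRUE, TRUE), "P2", "up")
  down <- mk(c(P1 = 0.10, P3 = 0.2), c(TRUE, TRUE), "P3", "down")
  res <- resolve_dual_membership(up, down)
  expect_true("P1" %in% network_nodes(res$up))
  expect_false("P1" %in% network_nodes(res$down))
  # keep_dual leaves both untouched
  res2 <- resolve_dual_membership(up, down, keep_dual = TRUE)
  expect_true("P1" %in% network_nodes(res2$down))
  # exact tie stays in up
  up_t <- mk(c(P1 = 0.2, P2 = 0.2), c(TRUE, TRUE), "P2", "up")
  down_t <- mk(c(P1 = 0.2, P3 = 0.2), c(TRUE, TRUE), "P3", "down")
  res3 <- resolve_dual_membership(up_t, down_t)
  expect_true("P1" %in% network_nodes(res3$up))
  expect_false("P1" %in% network_nodes(res3$down))
  # a seed is never removed from its own direction
  up_s <- mk(c(P2 = 0.9), TRUE, "P2", "up")
  down_s <- mk(c(P2 = 0.1), TRUE, "P2", "down")
  res4 <- resolve_dual_membership(up_s, down_s)
  expect_true("P2" %in% network_nodes(res4$down))
})

test_that("null scoring is reproducible and feeds a deterministic filter", {
  st <- small_study()
  raw <- build_weighted_network(st$edges, st$ontology)
  norm <- laplacian_normalize(raw)
  nodes <- network_nodes(norm)
  seeds <- st$communities$protein[st$communities$community == 1][1:4]
  restart <- build_restart_vector(tibble::tibble(protein = seeds, lfc = 1:4), norm)
  run_once <- function() {
    ens <- randomize_ensemble(raw, n_random = 10, ontology = st$ontology, seed = 5)
    real <- rwr(norm, restart, 0.85)
    empirical_filter(real, null_scores(ens, restart, 0.85), 0.05)
  }
  expect_identical(run_once(), run_once())
})

test_that("propagation from planted seeds enriches the seeded community", {
  # pooled over 20 seeded replicates: retained non-seed nodes fall inside the
  # seeds' community far more often than uniform sampling would allow
  spec <- small_spec()
  st <- small_study()
  raw <- build_weighted_network(st$edges, st$ontology)
  norm <- laplacian_normalize(raw)
  nodes <- network_nodes(norm)
  comm1 <- intersect(st$communities$protein[st$communities$community == 1], nodes)
  hits <- 0L
  tot <- 0L
  for (i in 1:20) {
    seeds <- withr::with_seed(100 + i, sample(comm1, 4))
    restart <- build_restart_vector(tibble::tibble(protein = seeds, lfc = rep(1, 4)), norm)
    ens <- randomize_ensemble(raw, n_random = 20, ontology = st$ontology, seed = 200 + i)
    real <- rwr(norm, restart, 0.85)
    flt <- empirical_filter(real, null_scores(ens, restart, 0.85), 0.05)
    kept <- setdiff(flt$protein[flt$retained], seeds)
    hits <- hits + length(intersect(kept, comm1))
    tot <- tot + length(kept)
  }
  expect_gt(tot, 0)
  frac_comm <- length(comm1) / length(nodes)
  p <- stats::pbinom(hits - 1, tot, frac_comm, lower.tail = FALSE)
  expect_lt(p, 0.01)
})
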
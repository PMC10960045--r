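test_that("bipartite representation mirrors the directed link set", {
  bip <- build_bipartite(fig1_toy())
  expect_equal(nrow(bip$links), 4)
  expect_equal(bip$links[, 1], c(1, 2, 2, 4), ignore_attr = TRUE)
  expect_equal(bip$links[, 2], c(2, 3, 4, 5), ignore_attr = TRUE)
  expect_equal(nrow(build_bipartite(binary_network(matrix(0, 3, 3)))$links), 0)
  two <- bidirect(binary_network(matrix(c(0, 1, 0, 0), 2)))
  expect_equal(unname(build_bipartite(two)$links),
               cbind(c(1, 2), c(2, 1)))
})

test_that("maximum matching identifies the minimum driver count", {
  mm <- maximum_matching(fig1_toy())
  expect_equal(nrow(mm$matched_links), 3)
  expect_equal(mm$n_unmatched, 2)
  expect_equal(mm$n_inputs, 2)

  # directed cycle: perfect matching, single input suffices
  n <- 7
  a <- matrix(0, n, n)
  for (i in seq_len(n)) a[i %% n + 1, i] <- 1
  mc <- maximum_matching(binary_network(a))
  expect_equal(mc$n_unmatched, 0)
  expect_equal(mc$n_inputs, 1)

  # edgeless network: every node unmatched
  me <- maximum_matching(binary_network(matrix(0, 4, 4)))
  expect_equal(me$n_unmatched, 4)
  expect_equal(me$n_inputs, 4)
})

test_that("matching size agrees with exhaustive search and igraph", {
  for (s in 1:40) {
    net <- random_digraph(n = 3 + s %% 6, p = 1.6 / (3 + s %% 6), seed = 900 + s)
    bip <- build_bipartite(net)
    got <- nrow(maximum_matching(bip)$matched_links)
    expect_equal(got, brute_matching_size(bip$links), info = paste("seed", s))
    # igraph cross-check on the split-node bipartite graph
    n <- net$n_nodes
    if (nrow(bip$links)) {
      g <- igraph::graph_from_edgelist(
        cbind(bip$links[, 1], n + bip$links[, 2]), directed = FALSE)
      g <- igraph::add_vertices(g, max(0, 2 * n - igraph::vcount(g)))
      types <- c(rep(FALSE, n), rep(TRUE, n))
      expect_equal(got,
                   igraph::max_bipartite_match(g, types = types)$matching_size)
    }
  }
})

test_that("the unmatched-set size is matching-invariant and both toy sets appear", {
  sets <- enumerate_unmatched_sets(fig1_toy())
  expect_equal(attr(sets, "matching_size"), 3)
  sizes <- vapply(sets, length, 1L)
  expect_true(all(sizes == 2))
  expect_true(any(vapply(sets, identical, TRUE, y = c(1L, 3L))))
  expect_true(any(vapply(sets, identical, TRUE, y = c(1L, 4L))))

  for (s in 1:10) {
    net <- random_digraph(5, 0.3, seed = 300 + s)
    sets <- enumerate_unmatched_sets(net)
    expect_true(length(unique(vapply(sets, length, 1L))) == 1)
  }
})

test_that("Gramian matches closed forms and quadrature", {
  # A = 0, all inputs: W = t_f * I
  z <- binary_network(matrix(0, 4, 4))
  g <- gramian(z, 1:4, t_f = 1)
  expect_equal(g$W, diag(4), tolerance = 1e-12)
  expect_equal(g$trace_energy, 4, tolerance = 1e-12)

  # 2-node chain closed form
  chain <- binary_network(matrix(c(0, 1, 0, 0), 2))
  gc <- gramian(chain, 1)
  expect_equal(gc$W, matrix(c(1, 1/2, 1/2, 1/3), 2), tolerance = 1e-10)

  # unreachable node 1 under input {3}: singular Gramian
  expect_lt(abs(gramian(fig1_toy(), 3)$lambda_min), 1e-12)

  # quadrature agreement on random 6-node systems
  for (s in 1:5) {
    net <- random_digraph(6, 0.3, seed = 500 + s)
    W <- gramian(net, c(1, 4))$W
    Wq <- simpson_gramian(net, c(1, 4))
    expect_lt(max(abs(W - Wq)) / max(abs(W)), 1e-8)
  }
})

test_that("Gramian eigenvalues are monotone in the input set", {
  for (s in 1:6) {
    net <- random_digraph(6, 0.35, seed = 600 + s)
    e1 <- eigen(gramian(net, c(1, 2))$W, symmetric = TRUE, only.values = TRUE)$values
    e2 <- eigen(gramian(net, c(1, 2, 5))$W, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(sort(e2) - sort(e1) >= -1e-10))
  }
})

test_that("controllability verdicts: Gramian, Kalman rank and graph test agree", {
  toy <- fig1_toy()
  # full input set always controllable
  expect_true(is_structurally_controllable(toy, 1:5))

  # {1,4} and {1,3} are valid driver sets; {1} leaves the 3/4 dilation
  for (S in list(c(1, 3), c(1, 4))) {
    ok <- is_structurally_controllable(toy, S)
    expect_true(ok)
    expect_equal(attr(ok, "diagnostics")$kalman_rank, 5)
    expect_true(attr(ok, "diagnostics")$graph_test)
  }
  bad <- is_structurally_controllable(toy, 1)
  expect_false(bad)
  expect_equal(attr(bad, "diagnostics")$kalman_rank, 4)
  expect_false(attr(bad, "diagnostics")$graph_test)

  # isolated non-input node: never controllable
  a <- matrix(0, 3, 3); a[2, 1] <- 1
  expect_false(is_structurally_controllable(binary_network(a), c(1, 2)))

  # graph test tracks the Kalman rank of a generic weight assignment
  # (binary weights can be degenerate; structural controllability speaks
  # about almost-every assignment)
  for (s in 1:20) {
    net <- random_digraph(5, 0.35, seed = 700 + s)
    S <- c(1, 3)
    graph_ok <- structurally_controllable_graph(net, S)
    set.seed(s)
    Ar <- net$adjacency * matrix(runif(25, 0.5, 1.5), 5, 5)
    B <- input_matrix(net, S)
    ctrb <- cbind(B, Ar %*% B, Ar %*% Ar %*% B, Ar %*% Ar %*% Ar %*% B,
                  Ar %*% Ar %*% Ar %*% Ar %*% B)
    expect_equal(as.logical(graph_ok), qr(ctrb)$rank == 5,
                 info = paste("seed", s))
  }
})
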
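test_that("matrix-csv round-trips and validates", {
  w <- matrix(c(0, 2.5, 0, 0.3, 0, 0, 7.1, 0, 0), 3, 3)
  net <- weighted_network(w, labels = c("A", "B", "C"))
  f <- withr::local_tempfile(fileext = ".csv")
  write_network(net, f, "matrix-csv")
  back <- read_network(f, "matrix-csv")
  expect_equal(back$weights, net$weights)
  expect_equal(back$labels, net$labels)

  # empty network
  f0 <- withr::local_tempfile(fileext = ".csv")
  write_network(weighted_network(matrix(0, 5, 5)), f0, "matrix-csv")
  expect_equal(sum(read_network(f0, "matrix-csv")$weights > 0), 0)

  # non-square
  fbad <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("1,2,3", "4,5,6"), fbad)
  expect_error(read_network(fbad, "matrix-csv"), "square")
})

test_that("edge lists read with preserved label order and strict validation", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines("A\tB\t2.5", f)
  net <- read_network(f, "edgelist")
  expect_equal(net$n_nodes, 2)
  expect_equal(net$labels, c("A", "B"))
  # link A -> B stored at (target, source)
  expect_equal(net$weights[2, 1], 2.5)
  expect_equal(net$weights[1, 2], 0)

  writeLines(c("A\tB\t1", "A\tB\t2"), f)
  expect_error(read_network(f, "edgelist"), "duplicate edge.*row 2")
  writeLines(c("A\tB\t-1"), f)
  expect_error(read_network(f, "edgelist"), "negative weight")
})

test_that("a written binary network re-reads identically", {
  net <- binarize(generate_brain_like(brain_like_config(seed = 42)))
  f <- withr::local_tempfile(fileext = ".csv")
  write_network(net, f, "matrix-csv")
  expect_equal(binarize(read_network(f, "matrix-csv"))$adjacency, net$adjacency)
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_network(remove_isolated(net)$network, f2, "edgelist")
  back <- binarize(read_network(f2, "edgelist"))
  # edge-list labels follow first appearance; compare up to the label map
  perm <- order(as.integer(back$labels))
  expect_equal(back$adjacency[perm, perm],
               remove_isolated(net)$network$adjacency)
})

test_that("binarize thresholds positive weights and preserves symmetry", {
  expect_equal(binarize(weighted_network(matrix(c(0, 0.3, 7.1, 0), 2)))$adjacency,
               matrix(c(0, 1, 1, 0), 2))
  expect_equal(sum(binarize(weighted_network(matrix(0, 4, 4)))$adjacency), 0)
  w <- matrix(c(0, 2, 2, 0), 2)
  expect_true(isSymmetric(binarize(weighted_network(w))$adjacency))
  expect_warning(weighted_network(diag(3)), "self-loop")
})

test_that("bidirect symmetrizes and is idempotent", {
  a <- matrix(0, 3, 3); a[2, 1] <- 1  # 1 -> 2 only
  sym <- bidirect(binary_network(a))
  expect_equal(sym$adjacency[1, 2], 1)
  expect_equal(sym$adjacency[2, 1], 1)
  expect_equal(bidirect(sym)$adjacency, sym$adjacency)
  empty <- bidirect(binary_network(matrix(0, 3, 3)))
  expect_equal(sum(empty$adjacency), 0)
})

test_that("remove_isolated drops only zero-degree nodes and keeps the submatrix", {
  net <- generate_brain_like(brain_like_config(seed = 7, n_isolated = 2))
  res <- remove_isolated(net)
  expect_equal(res$network$n_nodes, 88)
  expect_length(res$removed, 2)
  expect_equal(res$network$adjacency, net$adjacency[res$kept, res$kept])
  # no-op case and all-isolated case
  clean <- res$network
  expect_equal(remove_isolated(clean)$removed, character(0))
  allzero <- remove_isolated(binary_network(matrix(0, 3, 3)))
  expect_equal(allzero$network$n_nodes, 0)
  expect_length(allzero$removed, 3)
})

test_that("properties: degrees, heterogeneity and distances", {
  # directed 4-cycle is 1-regular: H = 0, mean distance n/2
  n <- 6
  a <- matrix(0, n, n)
  for (i in seq_len(n)) a[i %% n + 1, i] <- 1
  p <- properties(binary_network(a))
  expect_equal(p$heterogeneity, 0)
  expect_equal(p$mean_distance, n / 2)
  expect_equal(p$mean_degree, 1)

  # complete digraph: mean distance exactly 1
  full <- binary_network(1 - diag(5))
  expect_equal(properties(full)$mean_distance, 1)

  # toy: 4 directed links over 5 nodes
  expect_equal(properties(fig1_toy())$mean_degree, 4 / 5)

  # directed star center -> 3 leaves, brute-force double-sum oracle
  a <- matrix(0, 4, 4); a[2:4, 1] <- 1
  star <- binary_network(a)
  for (r in c(1, 2.5)) {
    k_in <- rowSums(a); k_out <- colSums(a)
    h_oracle <- max(sum(abs(outer(k_in, k_in, "-"))),
                    sum(abs(outer(k_out, k_out, "-")))) / (r * 16)
    expect_equal(properties(star, r_const = r)$heterogeneity, h_oracle)
  }

  # symmetric networks have equal in- and out-degree everywhere
  net <- generate_brain_like(brain_like_config(seed = 3))
  expect_equal(rowSums(net$adjacency), colSums(net$adjacency))
  expect_error(properties(binary_network(matrix(0, 0, 0))), "empty")
})
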
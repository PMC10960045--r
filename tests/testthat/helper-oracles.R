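# Independent oracles: deliberately naive routes used only to validate the
# production algorithms on small instances.

# random simple digraph as binary_network (adjacency[j, i] = 1 for i -> j)
random_digraph <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(as.numeric(runif(n * n) < p), n, n)
  diag(a) <- 0
  binary_network(a)
}

random_symmetric_net <- function(n, p, seed) {
  set.seed(seed)
  a <- matrix(0, n, n)
  a[upper.tri(a)] <- as.numeric(runif(n * (n - 1) / 2) < p)
  binary_network(pmax(a, t(a)))
}

# exhaustive (branch and bound) maximum matching size over an edge list
brute_matching_size <- function(links) {
  if (nrow(links) == 0) return(0L)
  best <- 0L
  recurse <- function(i, left, right, size) {
    if (size + (nrow(links) - i + 1L) <= best) return()
    if (i > nrow(links)) {
      if (size > best) best <<- size
      return()
    }
    v <- links[i, 1]; w <- links[i, 2]
    if (!(v %in% left) && !(w %in% right)) {
      recurse(i + 1L, c(left, v), c(right, w), size + 1L)
    }
    recurse(i + 1L, left, right, size)
  }
  recurse(1L, integer(0), integer(0), 0L)
  best
}

# hand-rolled multi-source BFS along link direction (no igraph)
bfs_distances <- function(net, sources) {
  n <- net$n_nodes
  dist <- rep(Inf, n)
  dist[sources] <- 0
  frontier <- sources
  d <- 0
  while (length(frontier)) {
    d <- d + 1
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(net$adjacency[, v] == 1)) {
        if (dist[w] > d) {
          dist[w] <- d
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- unique(nxt)
  }
  dist
}

# brute-force minimum distance-l dominating set size via bitmask enumeration
brute_min_cover_size <- function(net, l) {
  n <- net$n_nodes
  best <- n
  for (mask in seq_len(2^n - 1)) {
    S <- which(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
    if (length(S) >= best) next
    if (max(bfs_distances(net, S)) <= l) best <- length(S)
  }
  best
}

# induced-triple enumeration motif census for symmetric networks
brute_motifs <- function(net) {
  a <- net$adjacency
  n <- net$n_nodes
  id78 <- 0L; id238 <- 0L
  if (n >= 3) {
    trips <- utils::combn(n, 3)
    for (j in seq_len(ncol(trips))) {
      t3 <- trips[, j]
      e <- a[t3, t3][upper.tri(matrix(0, 3, 3))]
      if (sum(e) == 3) id238 <- id238 + 1L
      if (sum(e) == 2) id78 <- id78 + 1L
    }
  }
  list(id78 = id78, id238 = id238, M = id78 + id238)
}

# composite-Simpson quadrature of the Gramian integral
simpson_gramian <- function(net, inputs, t_f = 1, panels = 400L) {
  A <- net$adjacency
  B <- input_matrix(net, inputs)
  h <- t_f / panels
  f <- function(tau) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(A * tau)))
    E %*% B %*% t(B) %*% t(E)
  }
  W <- f(0) + f(t_f)
  for (k in seq_len(panels - 1)) W <- W + (if (k %% 2) 4 else 2) * f(k * h)
  W * h / 3
}

# small degree-l neighborhood check used by placement tests
cover_ok <- function(net, S, l) max(bfs_distances(net, S)) <= l
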
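#' Five-node worked-example network
#'
#' The small directed network used throughout the documentation to illustrate
#' matching, driver placement and the LCC--energy relation: nodes 1--5 with
#' directed links 1→2, 2→3, 2→4, 4→5. Its maximum matching has size 3 and two
#' unmatched in-copies; both \{1, 3\} and \{1, 4\} arise as unmatched sets,
#' giving control schemes with LCC 3 and 2 respectively, and the LCC-2 scheme
#' needs less control energy.
#'
#' @return a [binary_network()] on 5 nodes.
#' @export
fig1_toy <- function() {
  a <- matrix(0, 5, 5)
  # adjacency[j, i] = 1 for link i -> j
  a[2, 1] <- 1
  a[3, 2] <- 1
  a[4, 2] <- 1
  a[5, 4] <- 1
  binary_network(a)
}

#' Configuration for synthetic brain-like networks
#'
#' Targets chosen to emulate 90-region AAL structural connectomes: about
#' 1100--1250 directed links (mean degree 12--14), a right-skewed degree
#' sequence (minimum near 1--6, maximum near 25--43), mean inter-node
#' distance around 2.1--2.3, a small number of isolated regions, and an
#' assortative rich club of densely interconnected hubs.
#'
#' @param n_nodes total node count including isolated nodes (default 90).
#' @param target_links target *directed* link count (default 1150, i.e. 575
#'   undirected edges).
#' @param degree_sdlog log-scale spread of the lognormal degree sequence;
#'   0.5 yields the observed heterogeneity (mean absolute pairwise degree
#'   difference around 0.6 of the mean degree).
#' @param rich_club_density target edge density among the top
#'   `hub_quantile` hubs, reached by degree-preserving hub-ward swaps;
#'   0 leaves the configuration-model wiring untouched.
#' @param hub_quantile fraction of nodes counted as hubs.
#' @param n_isolated isolated nodes appended at the last indices.
#' @param seed integer seed; the generator is a pure function of it.
#' @return object of class `brain_like_config`.
#' @export
brain_like_config <- function(n_nodes = 90L, target_links = 1150L,
                              degree_sdlog = 0.5, rich_club_density = 0.8,
                              hub_quantile = 0.1, n_isolated = 1L, seed = 1L) {
  stopifnot(n_nodes >= 10, target_links > 0, degree_sdlog > 0,
            rich_club_density >= 0, rich_club_density <= 1,
            n_isolated >= 0, n_isolated < n_nodes / 2)
  structure(list(n_nodes = as.integer(n_nodes),
                 target_links = as.integer(target_links),
                 degree_sdlog = degree_sdlog,
                 rich_club_density = rich_club_density,
                 hub_quantile = hub_quantile,
                 n_isolated = as.integer(n_isolated),
                 seed = as.integer(seed)),
            class = "brain_like_config")
}

# lognormal degree sequence with fixed even sum 2m, entries in [1, kmax]
sample_degree_sequence <- function(n, m, sdlog, kmax) {
  meanlog <- log(2 * m / n) - sdlog^2 / 2
  deg <- pmin(kmax, pmax(1L, round(stats::rlnorm(n, meanlog, sdlog))))
  gap <- 2L * m - sum(deg)
  guard <- 0L
  while (gap != 0L && guard < 10000L) {
    guard <- guard + 1L
    i <- sample.int(n, 1L)
    if (gap > 0L && deg[i] < kmax) {
      deg[i] <- deg[i] + 1L; gap <- gap - 1L
    } else if (gap < 0L && deg[i] > 1L) {
      deg[i] <- deg[i] - 1L; gap <- gap + 1L
    }
  }
  if (gap != 0L) stop("could not balance degree sequence")
  deg
}

#' Generate a synthetic brain-like network
#'
#' Builds a symmetric binary network matching the summary statistics of
#' structural connectomes (see [brain_like_config()]): a connected simple
#' graph is sampled from a lognormal degree sequence (Viger--Latapy sampler),
#' then hub--hub assortativity is added by degree-preserving swaps that
#' rewire two hub--periphery links into a hub--hub plus periphery--periphery
#' pair until the rich club reaches the target density (swaps that would
#' disconnect the graph are rejected), and finally isolated nodes are
#' appended. Each undirected edge is stored as a bidirectional link pair.
#'
#' @param cfg a [brain_like_config()].
#' @return a symmetric [binary_network()]; attribute `"config"` keeps `cfg`.
#' @export
generate_brain_like <- function(cfg = brain_like_config()) {
  stopifnot(inherits(cfg, "brain_like_config"))
  n_c <- cfg$n_nodes - cfg$n_isolated
  m <- round(cfg$target_links / 2)
  with_seed(cfg$seed, {
    g <- NULL
    for (attempt in 1:25) {
      deg <- sample_degree_sequence(n_c, m, cfg$degree_sdlog,
                                    kmax = min(n_c - 1L, 45L))
      g <- tryCatch(igraph::sample_degseq(deg, method = "vl"),
                    error = function(e) NULL)
      if (!is.null(g)) break
    }
    if (is.null(g)) stop("failed to realize a connected graphical degree sequence")
    a <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
    a <- pmax(a, t(a))
    if (cfg$rich_club_density > 0) {
      a <- enrich_rich_club(a, cfg$hub_quantile, cfg$rich_club_density)
    }
    n <- cfg$n_nodes
    full <- matrix(0, n, n)
    full[seq_len(n_c), seq_len(n_c)] <- a
    out <- binary_network(full)
    attr(out, "config") <- cfg
    out
  })
}

# Degree-preserving swaps increasing hub-hub density:
# (h1-l1), (h2-l2) -> (h1-h2), (l1-l2). Connectivity-breaking swaps rejected.
enrich_rich_club <- function(a, hub_quantile, target_density, max_attempts = 4000L) {
  n <- nrow(a)
  deg <- colSums(a)
  n_hub <- max(2L, ceiling(hub_quantile * n))
  hubs <- order(-deg, seq_len(n))[seq_len(n_hub)]
  is_hub <- seq_len(n) %in% hubs
  hub_pairs <- utils::combn(sort(hubs), 2)
  density <- function(a) sum(a[hubs, hubs]) / (2 * ncol(hub_pairs))
  attempts <- 0L
  while (density(a) < target_density && attempts < max_attempts) {
    attempts <- attempts + 1L
    open <- hub_pairs[, a[t(hub_pairs)] == 0, drop = FALSE]
    if (ncol(open) == 0) break
    hp <- open[, sample.int(ncol(open), 1L)]
    l1 <- which(a[, hp[1]] == 1 & !is_hub)
    l2 <- which(a[, hp[2]] == 1 & !is_hub)
    if (!length(l1) || !length(l2)) break
    v1 <- l1[sample.int(length(l1), 1L)]
    v2 <- l2[sample.int(length(l2), 1L)]
    if (v1 == v2 || a[v1, v2] == 1) next
    b <- a
    b <- set_und_edge(b, c(hp[1], v1), 0)
    b <- set_und_edge(b, c(hp[2], v2), 0)
    b <- set_und_edge(b, hp, 1)
    b <- set_und_edge(b, c(v1, v2), 1)
    g <- igraph::graph_from_adjacency_matrix(b, mode = "undirected")
    if (igraph::is_connected(g)) a <- b
  }
  a
}

#' Rich-club-with-chains fixture
#'
#' Deterministic 16-node network exposing the weakness of hub-first input
#' placement: a bidirected 4-clique of hubs, each hub carrying a bidirected
#' 3-node chain. For \eqn{\ell = 1} the greedy distance cover takes one hub
#' plus the chain midpoints, while the degree-descending hub prefix must
#' exhaust all four mutually adjacent hubs (which cover little) before
#' descending into the chains, ending up strictly larger.
#'
#' @return a symmetric [binary_network()] on 16 nodes: hubs 1--4, chains
#'   5-6-7 (off hub 1), 8-9-10 (hub 2), 11-12-13 (hub 3), 14-15-16 (hub 4).
#' @export
rich_club_chain_fixture <- function() {
  n <- 16L
  a <- matrix(0, n, n)
  und <- function(i, j) a[cbind(c(i, j), c(j, i))] <<- 1
  for (i in 1:3) for (j in (i + 1):4) und(i, j)     # hub clique
  chains <- list(c(1, 5, 6, 7), c(2, 8, 9, 10), c(3, 11, 12, 13), c(4, 14, 15, 16))
  for (ch in chains) for (k in 1:3) und(ch[k], ch[k + 1])
  binary_network(a)
}
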
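#' Rewiring configuration
#'
#' Parameters of the degree-preserving randomization protocol. The number of
#' rewiring *trials* per replicate is
#' \deqn{T = \lceil (|E|/2) \ln(1/\epsilon) \rceil}
#' with \eqn{|E|} the directed link count; \eqn{\epsilon} between 1e-7 and
#' 1e-6 makes the chance that any given link is never proposed for a swap at
#' most \eqn{\epsilon}. Rejected proposals (would-be self-loops or duplicate
#' links) count toward the budget: the formula prices attempts, not
#' successes.
#'
#' @param epsilon residual probability in \[1e-7, 1e-6\].
#' @param n_replicates number of randomized replicates in ensemble runs.
#' @param hub_quantile top fraction of nodes (by degree) treated as hubs for
#'   rich-club destruction.
#' @param seed integer seed.
#' @return object of class `rewiring_config`.
#' @export
rewiring_config <- function(epsilon = 1e-6, n_replicates = 20L,
                            hub_quantile = 0.1, seed = 1L) {
  stopifnot(epsilon >= 1e-7, epsilon <= 1e-6,
            n_replicates >= 1, hub_quantile > 0, hub_quantile < 1)
  structure(list(epsilon = epsilon, n_replicates = as.integer(n_replicates),
                 hub_quantile = hub_quantile, seed = as.integer(seed)),
            class = "rewiring_config")
}

#' Rewiring trial budget
#'
#' \eqn{\lceil (|E|/2) \ln(1/\epsilon) \rceil} with \eqn{|E|} the directed
#' link count (e.g. 691 trials for 100 links at \eqn{\epsilon = 10^{-6}}).
#'
#' @param n_links directed link count.
#' @param epsilon residual probability.
#' @return integer trial count.
#' @export
rewiring_trials <- function(n_links, epsilon) {
  as.integer(ceiling((n_links / 2) * log(1 / epsilon)))
}

# undirected edge list (a < b) of a symmetric binary network
und_edges <- function(net) {
  idx <- which(net$adjacency == 1 & upper.tri(net$adjacency), arr.ind = TRUE)
  cbind(a = idx[, 1], b = idx[, 2])  # row < col, so a < b
}

set_und_edge <- function(a, e, value) {
  a[e[1], e[2]] <- value
  a[e[2], e[1]] <- value
  a
}

#' Degree-preserving rewiring
#'
#' Classic double-edge-swap randomization: `T` times (see
#' [rewiring_trials()]) two links are drawn and their endpoints exchanged,
#' rejecting proposals that would create self-loops or duplicate links. Every
#' node keeps its exact in- and out-degree while higher-order structure
#' (degree correlations, communities, rich club) is destroyed. Symmetric
#' networks are rewired on their undirected edges, writing both directions,
#' so bidirectionality is preserved; asymmetric digraphs are rewired on
#' directed links.
#'
#' @param net a [binary_network()] with at least 2 links.
#' @param cfg a [rewiring_config()].
#' @return a rewired `binary_network`; attribute `"diagnostics"` records
#'   `trials`, `accepted`, `symmetric`.
#' @export
degree_preserving_rewire <- function(net, cfg = rewiring_config()) {
  stopifnot(inherits(net, "binary_network"), inherits(cfg, "rewiring_config"))
  if (sum(net$adjacency) < 2) stop("need at least 2 links to rewire")
  trials <- rewiring_trials(sum(net$adjacency), cfg$epsilon)
  with_seed(cfg$seed, rewire_trials(net, trials))
}

rewire_trials <- function(net, trials) {
  a <- net$adjacency
  sym <- all(a == t(a))
  accepted <- 0L
  if (sym) {
    E <- und_edges(net)
    m <- nrow(E)
    if (m >= 2) {
      for (t in seq_len(trials)) {
        ij <- sample.int(m, 2L)
        e1 <- E[ij[1], ]; e2 <- E[ij[2], ]
        if (stats::runif(1) < 0.5) e2 <- rev(e2)   # random pairing orientation
        # propose (e1[1]-e2[1]), (e1[2]-e2[2])
        new1 <- sort(c(e1[1], e2[1])); new2 <- sort(c(e1[2], e2[2]))
        if (new1[1] == new1[2] || new2[1] == new2[2]) next
        if (a[new1[1], new1[2]] == 1 || a[new2[1], new2[2]] == 1) next
        a <- set_und_edge(a, e1, 0); a <- set_und_edge(a, e2, 0)
        a <- set_und_edge(a, new1, 1); a <- set_und_edge(a, new2, 1)
        E[ij[1], ] <- new1; E[ij[2], ] <- new2
        accepted <- accepted + 1L
      }
    }
  } else {
    idx <- which(a == 1, arr.ind = TRUE)
    E <- cbind(src = idx[, 2], dst = idx[, 1])
    m <- nrow(E)
    for (t in seq_len(trials)) {
      ij <- sample.int(m, 2L)
      e1 <- E[ij[1], ]; e2 <- E[ij[2], ]
      # propose e1_src -> e2_dst, e2_src -> e1_dst
      if (e1[1] == e2[2] || e2[1] == e1[2]) next
      if (a[e2[2], e1[1]] == 1 || a[e1[2], e2[1]] == 1) next
      a[e1[2], e1[1]] <- 0; a[e2[2], e2[1]] <- 0
      a[e2[2], e1[1]] <- 1; a[e1[2], e2[1]] <- 1
      E[ij[1], ] <- c(e1[1], e2[2]); E[ij[2], ] <- c(e2[1], e1[2])
      accepted <- accepted + 1L
    }
  }
  out <- binary_network(a, net$labels)
  attr(out, "diagnostics") <- list(trials = trials, accepted = accepted,
                                   symmetric = sym)
  out
}

#' Destroy rich-club organization
#'
#' Degree-preserving removal of hub assortativity on symmetric networks: a
#' link between two hubs (top `hub_quantile` of nodes by degree) and a link
#' between two low-degree (non-hub) nodes are repeatedly cross-rewired into
#' two hub--low links, so the hub--hub link count is non-increasing and
#' degrees are untouched. Stops when no swappable hub--hub / low--low pair
#' remains or the trial budget is exhausted.
#'
#' @inheritParams degree_preserving_rewire
#' @return a `binary_network`; attribute `"diagnostics"` records
#'   `hub_nodes`, `hub_links_before`, `hub_links_after`, `trials_used`.
#' @export
break_rich_club <- function(net, cfg = rewiring_config()) {
  stopifnot(inherits(net, "binary_network"), inherits(cfg, "rewiring_config"))
  a <- net$adjacency
  if (!all(a == t(a))) stop("rich-club destruction expects a symmetric network")
  deg <- colSums(a)
  n_hub <- max(1L, ceiling(cfg$hub_quantile * net$n_nodes))
  hubs <- order(-deg, seq_len(net$n_nodes))[seq_len(n_hub)]
  is_hub <- seq_len(net$n_nodes) %in% hubs
  budget <- rewiring_trials(sum(a), cfg$epsilon)
  hh0 <- sum(a[hubs, hubs]) / 2
  used <- 0L
  with_seed(cfg$seed + 1L, {
    repeat {
      E <- und_edges(binary_network(a, net$labels))
      hh <- E[is_hub[E[, 1]] & is_hub[E[, 2]], , drop = FALSE]
      ll <- E[!is_hub[E[, 1]] & !is_hub[E[, 2]], , drop = FALSE]
      if (nrow(hh) == 0 || nrow(ll) == 0 || used >= budget) break
      progressed <- FALSE
      for (t in seq_len(min(budget - used, 4L * (nrow(hh) + nrow(ll))))) {
        used <- used + 1L
        e1 <- hh[sample.int(nrow(hh), 1L), ]
        e2 <- ll[sample.int(nrow(ll), 1L), ]
        if (stats::runif(1) < 0.5) e2 <- rev(e2)
        new1 <- sort(c(e1[1], e2[1])); new2 <- sort(c(e1[2], e2[2]))
        if (a[new1[1], new1[2]] == 1 || a[new2[1], new2[2]] == 1) next
        a <- set_und_edge(a, e1, 0); a <- set_und_edge(a, sort(e2), 0)
        a <- set_und_edge(a, new1, 1); a <- set_und_edge(a, new2, 1)
        progressed <- TRUE
        break
      }
      if (!progressed) break
    }
  })
  out <- binary_network(a, net$labels)
  attr(out, "diagnostics") <- list(
    hub_nodes = hubs, hub_links_before = hh0,
    hub_links_after = sum(a[hubs, hubs]) / 2, trials_used = used)
  out
}

#' Required inputs on a randomized ensemble
#'
#' Compares the input fraction \eqn{n_i(\ell)} of a network with its
#' degree-preserving null: for each replicate the network is rewired (and
#' optionally stripped of its rich club), the greedy placement search is run
#' at the same \eqn{\ell}, and the input fractions are averaged. Agreement
#' between \eqn{n_i(\ell)} and \eqn{n_i^{rand}(\ell)} indicates the degree
#' sequence, not higher-order structure, sets the input requirement.
#'
#' @inheritParams min_inputs_for_lcc
#' @param cfg a [rewiring_config()]; `n_replicates` replicates are generated
#'   from seeds `cfg$seed + 1000 * replicate`.
#' @param destroy_rich_club also apply [break_rich_club()] to each replicate.
#' @return list with `n_i_rand` (mean fraction), `per_replicate` (numeric
#'   vector), `n_i_original`.
#' @export
randomized_ensemble_inputs <- function(net, l, cfg = rewiring_config(),
                                       destroy_rich_club = TRUE) {
  stopifnot(inherits(net, "binary_network"))
  orig <- min_inputs_for_lcc(net, l, mode = "greedy")
  fractions <- vapply(seq_len(cfg$n_replicates), function(r) {
    cfg_r <- cfg
    cfg_r$seed <- cfg$seed + 1000L * r
    rnet <- degree_preserving_rewire(net, cfg_r)
    if (destroy_rich_club) rnet <- break_rich_club(rnet, cfg_r)
    min_inputs_for_lcc(rnet, l, mode = "greedy")$n_i_fraction
  }, numeric(1))
  list(n_i_rand = mean(fractions), per_replicate = fractions,
       n_i_original = orig$n_i_fraction)
}
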
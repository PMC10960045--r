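# Restore RNG state on exit so seeded routines are pure functions of their seed.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# out-degree, the node degree used for hub ordering (equals the undirected
# degree on symmetric networks)
node_degree <- function(net) colSums(net$adjacency)

# full directed distance matrix d(v, w)
dist_matrix <- function(net) igraph::distances(as_igraph(net), mode = "out")

# logical cover matrix: C[v, w] TRUE iff node v covers node w at radius l
cover_matrix <- function(net, l, D = dist_matrix(net)) D <= l

pairwise_input_stats <- function(D, inputs) {
  if (length(inputs) < 2) {
    return(list(mean = NA_real_, sd = NA_real_))
  }
  d <- D[inputs, inputs]
  vals <- d[row(d) != col(d)]  # ordered pairs
  list(mean = mean(vals), sd = stats::sd(vals))
}

new_placement_result <- function(net, inputs, method, l, D) {
  inputs <- sort(as.integer(inputs))
  prof <- input_distances(net, inputs)
  ps <- pairwise_input_stats(D, inputs)
  structure(list(
    inputs = inputs,
    method = method,
    target_lcc = l,
    achieved_lcc = prof$lcc,
    n_i_fraction = length(inputs) / net$n_nodes,
    degrees_of_inputs = sort(node_degree(net)[inputs]),
    mean_pairwise_input_distance = ps$mean,
    d_i_std = ps$sd,
    controllable = as.logical(structurally_controllable_graph(net, inputs))
  ), class = "placement_result")
}

#' @export
print.placement_result <- function(x, ...) {
  cat(sprintf(
    "<placement_result> method %s: %d inputs (n_i = %.3f), target LCC %s, achieved %s, d_i = %s\n",
    x$method, length(x$inputs), x$n_i_fraction, format(x$target_lcc),
    format(x$achieved_lcc),
    if (is.na(x$mean_pairwise_input_distance)) "n/a"
    else sprintf("%.2f +- %.2f", x$mean_pairwise_input_distance, x$d_i_std)))
  invisible(x)
}

# If an l-cover fails the exact structural-controllability test (possible on
# asymmetric digraphs: accessibility holds by construction, but a dilation
# may remain), augment it with unmatched in-copies from a maximum matching.
ensure_controllable <- function(net, inputs) {
  inputs <- sort(unique(as.integer(inputs)))
  if (structurally_controllable_graph(net, inputs)) return(inputs)
  extra <- setdiff(maximum_matching(net)$unmatched_nodes, inputs)
  for (v in extra) {
    inputs <- sort(c(inputs, v))
    if (structurally_controllable_graph(net, inputs)) break
  }
  inputs
}

greedy_cover <- function(net, l, D, randomize = FALSE) {
  n <- net$n_nodes
  C <- cover_matrix(net, l, D)
  deg <- node_degree(net)
  uncovered <- rep(TRUE, n)
  inputs <- integer(0)
  while (any(uncovered)) {
    gain <- rowSums(C[, uncovered, drop = FALSE])
    gain[inputs] <- -1L
    best <- max(gain)
    cand <- which(gain == best)
    if (length(cand) > 1) {
      if (randomize) {
        cand <- cand[sample.int(length(cand), 1L)]
      } else {
        cand <- cand[order(-deg[cand], cand)][1]  # higher degree, then lower label
      }
    }
    inputs <- c(inputs, cand)
    uncovered <- uncovered & !C[cand, ]
  }
  sort(inputs)
}

# smallest l-cover by subset enumeration; optionally restricted to
# structurally controllable covers
exact_cover <- function(net, l, D, check_ctrl = FALSE, max_nodes = 15L) {
  n <- net$n_nodes
  if (n > max_nodes) {
    stop("exact placement search is limited to networks with at most ",
         max_nodes, " nodes; use mode = \"greedy\"")
  }
  C <- cover_matrix(net, l, D)
  for (k in seq_len(n)) {
    subsets <- utils::combn(n, k)
    for (j in seq_len(ncol(subsets))) {
      S <- subsets[, j]
      if (all(colSums(C[S, , drop = FALSE]) > 0) &&
          (!check_ctrl || structurally_controllable_graph(net, S))) {
        return(S)
      }
    }
  }
  seq_len(n)
}

#' Minimum input set for a target LCC
#'
#' Finds an input set whose longest control chain is at most \eqn{\ell}: a
#' directed distance-\eqn{\ell} dominating set (every node within distance
#' \eqn{\ell} of some input). `mode = "exact"` enumerates subsets by
#' increasing cardinality (guaranteed minimum; small networks only); `mode =
#' "greedy"` is the standard max-coverage heuristic: repeatedly add the node
#' whose radius-\eqn{\ell} out-neighborhood covers the most still-uncovered
#' nodes, ties broken by higher degree then lower label.
#'
#' Placement solves the *cover* problem; whether the resulting pair (A, B)
#' is structurally controllable is reported in the `controllable` field. On
#' symmetric connectomes, whose maximum matching leaves no node unmatched,
#' every nonempty cover passes; on general digraphs a cover can leave a
#' dilation, and `ensure_controllability = TRUE` then enforces the
#' structural test — exact mode restricts the enumeration to controllable
#' covers, greedy mode augments the cover with unmatched in-copies from the
#' maximum matching.
#'
#' \eqn{\ell = 0} forces every node to be its own input, so the full node set
#' is returned with a warning.
#'
#' @param net a [binary_network()].
#' @param l target LCC, a non-negative integer.
#' @param mode `"greedy"` (default) or `"exact"`.
#' @param ensure_controllability require structural controllability of the
#'   returned set (see Details); default `FALSE`.
#' @return a `placement_result`: `inputs`, `method`, `target_lcc`,
#'   `achieved_lcc`, `n_i_fraction`, `degrees_of_inputs` (ascending),
#'   `mean_pairwise_input_distance` (`d_i`, over ordered input pairs),
#'   `d_i_std`, `controllable`.
#' @export
min_inputs_for_lcc <- function(net, l, mode = c("greedy", "exact"),
                               ensure_controllability = FALSE) {
  stopifnot(inherits(net, "binary_network"), l >= 0)
  mode <- match.arg(mode)
  l <- as.integer(l)
  D <- dist_matrix(net)
  S <- if (mode == "exact") {
    exact_cover(net, l, D, check_ctrl = ensure_controllability)
  } else {
    S0 <- greedy_cover(net, l, D)
    if (ensure_controllability) ensure_controllable(net, S0) else S0
  }
  if (length(S) == net$n_nodes && net$n_nodes > 1) {
    warning("target LCC ", l, " requires every node as an input")
  }
  new_placement_result(net, S, if (mode == "exact") "exact" else "greedy-cover", l, D)
}

#' Hub-prefix baseline for a target LCC
#'
#' The naive high-degree strategy: sort nodes by degree in descending order
#' (ties by ascending label) and add them to the input set from the top of
#' the list until the LCC drops to \eqn{\ell}. On networks with a rich club
#' (densely interconnected hubs) this wastes inputs on mutually adjacent
#' hubs and can need several times more inputs than a distance cover.
#'
#' @inheritParams min_inputs_for_lcc
#' @return a `placement_result` with `method = "hub-greedy"`.
#' @export
hub_greedy_for_lcc <- function(net, l, ensure_controllability = FALSE) {
  stopifnot(inherits(net, "binary_network"), l >= 0)
  l <- as.integer(l)
  D <- dist_matrix(net)
  deg <- node_degree(net)
  ord <- order(-deg, seq_len(net$n_nodes))
  best <- rep(Inf, net$n_nodes)  # running min distance to the growing prefix
  k <- 0L
  repeat {
    k <- k + 1L
    best <- pmin(best, D[ord[k], ])
    if (max(best) <= l || k == net$n_nodes) break
  }
  S <- ord[seq_len(k)]
  if (ensure_controllability) S <- ensure_controllable(net, S)
  if (length(S) == net$n_nodes && net$n_nodes > 1) {
    warning("target LCC ", l, " requires every node as an input")
  }
  new_placement_result(net, S, "hub-greedy", l, D)
}

#' Hub set matched in size to a reference input set
#'
#' Builds the degree-descending prefix with the same cardinality as a
#' reference placement, for contrasting input-set dispersion: optimal sets
#' spread through the network (mean pairwise distance about \eqn{\ell + 1})
#' while equally sized hub sets sit at distance 1 from each other inside the
#' rich club.
#'
#' @param net a [binary_network()].
#' @param reference a `placement_result` (typically from
#'   [min_inputs_for_lcc()]).
#' @return a `placement_result` with `method = "hub-matched"`; the dispersion
#'   statistics are `NA` for a size-1 reference (no pairs).
#' @export
matched_size_hub_set <- function(net, reference) {
  stopifnot(inherits(net, "binary_network"), inherits(reference, "placement_result"))
  D <- dist_matrix(net)
  deg <- node_degree(net)
  ord <- order(-deg, seq_len(net$n_nodes))
  S <- ord[seq_len(length(reference$inputs))]
  new_placement_result(net, S, "hub-matched", reference$target_lcc, D)
}

#' Census of node participation across near-minimal input sets
#'
#' An \eqn{\ell}-constrained input set is far from unique. This census draws
#' `n_sets` distinct near-minimal covers via seeded randomized greedy search
#' (ties between equally covering candidates broken uniformly at random) and
#' counts how often each node participates. Nodes appearing in every set are
#' the primary contributors: they are structurally forced into any economical
#' placement at this \eqn{\ell}.
#'
#' @inheritParams min_inputs_for_lcc
#' @param n_sets number of distinct input sets requested.
#' @param seed integer seed making the census reproducible.
#' @param max_tries attempts allowed before giving up on finding `n_sets`
#'   distinct sets (a warning reports a shortfall).
#' @return list with `counts` (data.frame: node, label, degree, count,
#'   frequency, primary), `n_sets_found`, `sets` (list of input vectors).
#' @export
input_set_census <- function(net, l, n_sets = 100L, seed = 1L,
                             max_tries = 50L * n_sets) {
  stopifnot(inherits(net, "binary_network"), n_sets >= 1)
  D <- dist_matrix(net)
  sets <- list()
  keys <- character(0)
  with_seed(seed, {
    tries <- 0L
    while (length(sets) < n_sets && tries < max_tries) {
      tries <- tries + 1L
      S <- greedy_cover(net, l, D, randomize = TRUE)
      key <- paste(S, collapse = ",")
      if (!key %in% keys) {
        keys <- c(keys, key)
        sets[[length(sets) + 1L]] <- S
      }
    }
  })
  if (length(sets) < n_sets) {
    warning("found only ", length(sets), " distinct input sets (requested ",
            n_sets, ")")
  }
  cnt <- tabulate(unlist(sets), nbins = net$n_nodes)
  counts <- data.frame(
    node = seq_len(net$n_nodes),
    label = node_names(net),
    degree = node_degree(net),
    count = cnt,
    frequency = cnt / length(sets),
    primary = cnt == length(sets)
  )
  counts <- counts[order(-counts$count, counts$node), ]
  rownames(counts) <- NULL
  list(counts = counts, n_sets_found = length(sets), sets = sets)
}
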
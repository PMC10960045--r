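#' Distances from the nearest input and the longest control chain
#'
#' For input set \eqn{S}, each node's control distance is
#' \eqn{\min_{v \in S} d(v, w)} along link direction (input toward controlled
#' node), computed by multi-source BFS. The longest control chain is
#' \deqn{LCC = \max_{w \in V} \min_{v \in S} d(v, w),}
#' the eccentricity of the input set; small LCC correlates with low control
#' energy. Nodes unreachable from every input get distance `Inf` (and the LCC
#' is then `Inf`), which placement search treats as infeasibility rather than
#' an error.
#'
#' @param net a [binary_network()].
#' @param inputs nonempty integer vector of input node indices.
#' @return object of class `distance_profile`: `distances` (length-n numeric,
#'   0 exactly on inputs), `lcc`, `inputs`.
#' @export
input_distances <- function(net, inputs) {
  stopifnot(inherits(net, "binary_network"))
  inputs <- as.integer(inputs)
  if (length(inputs) == 0) stop("inputs must be nonempty")
  if (any(inputs < 1 | inputs > net$n_nodes)) stop("input index out of range")
  d <- igraph::distances(as_igraph(net), v = inputs, mode = "out")
  dist <- apply(d, 2, min)
  structure(list(distances = unname(dist), lcc = max(dist),
                 inputs = sort(unique(inputs))),
            class = "distance_profile")
}

#' @export
print.distance_profile <- function(x, ...) {
  cat("<distance_profile> inputs {", paste(x$inputs, collapse = ", "),
      "}, LCC = ", x$lcc, "\n", sep = "")
  invisible(x)
}

#' Achievable LCC range under a single input
#'
#' Evaluates every node as the sole input: its LCC is its BFS eccentricity
#' over the whole network (`Inf` when some node is unreachable from it).
#' Returns the attainable extremes over nodes with finite LCC and the node
#' sets attaining them.
#'
#' @param net a [binary_network()].
#' @return list with `per_node` (numeric vector of single-input LCCs),
#'   `lcc_min`, `lcc_max`, `argmin`, `argmax` (node indices attaining the
#'   finite extremes; empty when no node reaches the whole network).
#' @export
lcc_range_single_input <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  d <- igraph::distances(as_igraph(net), mode = "out")
  per_node <- apply(d, 1, max)
  finite <- which(is.finite(per_node))
  if (length(finite) == 0) {
    return(list(per_node = unname(per_node), lcc_min = Inf, lcc_max = Inf,
                argmin = integer(0), argmax = integer(0)))
  }
  lo <- min(per_node[finite]); hi <- max(per_node[finite])
  list(per_node = unname(per_node), lcc_min = lo, lcc_max = hi,
       argmin = finite[per_node[finite] == lo],
       argmax = finite[per_node[finite] == hi])
}
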
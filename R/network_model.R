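#' Weighted network
#'
#' Container for a directed, non-negatively weighted network. The adjacency
#' convention throughout the package follows the linear dynamics
#' \eqn{\dot x = A x + B u}: entry `weights[j, i]` holds the strength of the
#' link \eqn{i \to j} (column = source, row = target). For networks read from
#' symmetric sources the distinction is invisible.
#'
#' @param weights square numeric matrix of non-negative link strengths.
#'   Diagonal entries (self-loops) are discarded with a warning: they do not
#'   occur in structural connectomes and are ignored by every downstream
#'   operation.
#' @param labels optional character vector of unique node names (e.g. AAL
#'   region names), one per node.
#' @return an object of class `weighted_network` with fields `n_nodes`,
#'   `weights` and `labels`.
#' @seealso [binarize()], [read_network()]
#' @export
weighted_network <- function(weights, labels = NULL) {
  weights <- as.matrix(weights)
  if (nrow(weights) != ncol(weights)) {
    stop("weights must be a square matrix, got ", nrow(weights), "x", ncol(weights))
  }
  if (any(!is.finite(weights))) stop("weights must be finite")
  if (any(weights < 0)) {
    bad <- which(weights < 0, arr.ind = TRUE)[1, ]
    stop("negative weight at row ", bad[1], ", column ", bad[2])
  }
  if (any(diag(weights) != 0)) {
    warning("diagonal (self-loop) weights discarded")
    diag(weights) <- 0
  }
  labels <- check_labels(labels, nrow(weights))
  structure(
    list(n_nodes = nrow(weights), weights = unname(weights), labels = labels),
    class = "weighted_network"
  )
}

#' Binary directed network
#'
#' The structural adjacency matrix \eqn{A} of the linear model: entries in
#' \{0, 1\}, `adjacency[j, i] = 1` meaning a directed link \eqn{i \to j},
#' zero diagonal. Networks built from undirected (e.g. DTI) sources are
#' symmetric: every anatomical link is represented by the two directed links
#' \eqn{i \to j} and \eqn{j \to i}.
#'
#' @param adjacency square 0/1 matrix (convention as above).
#' @param labels optional unique node names.
#' @return object of class `binary_network` with fields `n_nodes`,
#'   `adjacency`, `labels`.
#' @export
binary_network <- function(adjacency, labels = NULL) {
  adjacency <- as.matrix(adjacency)
  if (nrow(adjacency) != ncol(adjacency)) stop("adjacency must be square")
  if (!all(adjacency %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  if (any(diag(adjacency) != 0)) stop("adjacency must have a zero diagonal")
  labels <- check_labels(labels, nrow(adjacency))
  structure(
    list(n_nodes = nrow(adjacency), adjacency = unname(adjacency) * 1, labels = labels),
    class = "binary_network"
  )
}

check_labels <- function(labels, n) {
  if (is.null(labels)) return(NULL)
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels must have length ", n)
  if (anyDuplicated(labels)) {
    stop("duplicate labels: ", paste(unique(labels[duplicated(labels)]), collapse = ", "))
  }
  labels
}

#' @export
print.weighted_network <- function(x, ...) {
  cat("<weighted_network> ", x$n_nodes, " nodes, ",
      sum(x$weights > 0), " directed links\n", sep = "")
  invisible(x)
}

#' @export
print.binary_network <- function(x, ...) {
  sym <- isTRUE(all.equal(x$adjacency, t(x$adjacency)))
  cat("<binary_network> ", x$n_nodes, " nodes, ", sum(x$adjacency),
      " directed links", if (sym) " (symmetric)", "\n", sep = "")
  invisible(x)
}

node_names <- function(net) {
  if (!is.null(net$labels)) net$labels else as.character(seq_len(net$n_nodes))
}

# igraph view of a binary network; edge i -> j for adjacency[j, i] = 1.
as_igraph <- function(net) {
  igraph::graph_from_adjacency_matrix(t(net$adjacency), mode = "directed")
}

#' Read a network from disk
#'
#' Two plain-text formats are supported. `matrix-csv` is a square numeric CSV,
#' optionally with a header row of node labels; entry (j, i) is read as the
#' weight of the link \eqn{i \to j}. `edgelist` is a tab-separated file with
#' rows `source<TAB>target<TAB>weight`; node order is the order of first
#' appearance.
#'
#' @param path file to read.
#' @param format `"matrix-csv"` or `"edgelist"`.
#' @return a [weighted_network()].
#' @export
read_network <- function(path, format = c("matrix-csv", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "matrix-csv") {
    raw <- utils::read.csv(path, header = FALSE, check.names = FALSE,
                           colClasses = "character")
    first_numeric <- !any(is.na(suppressWarnings(as.numeric(raw[1, ]))))
    # a non-numeric first row is a header; so is a numeric one that makes an
    # otherwise off-by-one-square table square (numeric node labels)
    has_header <- !first_numeric ||
      (nrow(raw) == ncol(raw) + 1 && first_numeric)
    labels <- if (has_header) as.character(unlist(raw[1, ])) else NULL
    body <- if (has_header) raw[-1, , drop = FALSE] else raw
    m <- suppressWarnings(apply(as.matrix(body), c(1, 2), as.numeric))
    if (any(is.na(m))) stop("non-numeric entry in matrix-csv body")
    if (nrow(m) != ncol(m)) {
      stop("matrix-csv must be square, got ", nrow(m), " rows and ", ncol(m), " columns")
    }
    weighted_network(m, labels)
  } else {
    df <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
    if (ncol(df) != 3) stop("edgelist must have 3 columns (source, target, weight)")
    names(df) <- c("source", "target", "weight")
    df$weight <- as.numeric(df$weight)
    for (i in seq_len(nrow(df))) {
      if (is.na(df$weight[i])) stop("non-numeric weight in edgelist row ", i)
      if (df$weight[i] < 0) stop("negative weight in edgelist row ", i)
    }
    key <- paste(df$source, df$target, sep = "\r")
    if (anyDuplicated(key)) {
      stop("duplicate edge in edgelist row ", which(duplicated(key))[1])
    }
    labels <- unique(c(rbind(as.character(df$source), as.character(df$target))))
    n <- length(labels)
    w <- matrix(0, n, n)
    si <- match(df$source, labels)
    ti <- match(df$target, labels)
    w[cbind(ti, si)] <- df$weight  # i -> j stored at (j, i)
    weighted_network(w, labels)
  }
}

#' Write a network to disk
#'
#' Inverse of [read_network()]; both binary and weighted networks are
#' accepted (binary adjacency is written as 0/1 weights).
#'
#' @param net a `weighted_network` or `binary_network`.
#' @param path output file.
#' @param format `"matrix-csv"` or `"edgelist"`.
#' @export
write_network <- function(net, path, format = c("matrix-csv", "edgelist")) {
  format <- match.arg(format)
  w <- if (inherits(net, "binary_network")) net$adjacency else net$weights
  if (format == "matrix-csv") {
    df <- as.data.frame(w)
    colnames(df) <- node_names(net)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    idx <- which(w > 0, arr.ind = TRUE)
    nm <- node_names(net)
    df <- data.frame(source = nm[idx[, 2]], target = nm[idx[, 1]],
                     weight = w[idx])
    df <- df[order(match(df$source, nm), match(df$target, nm)), ]
    utils::write.table(df, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Binarize a weighted network
#'
#' Produces the structural adjacency matrix: every positive weight becomes 1,
#' the diagonal is forced to zero. Symmetry of the source is preserved.
#'
#' @param net a [weighted_network()] (a `binary_network` passes through).
#' @return a [binary_network()].
#' @export
binarize <- function(net) {
  if (inherits(net, "binary_network")) return(net)
  stopifnot(inherits(net, "weighted_network"))
  a <- (net$weights > 0) * 1
  diag(a) <- 0
  binary_network(a, net$labels)
}

#' Replace undirected links by bidirectional link pairs
#'
#' Structural brain networks are undirected; control theory operates on
#' digraphs, so every undirected link \eqn{(i - j)} is represented by the two
#' directed links \eqn{i \to j} and \eqn{j \to i}. On an adjacency matrix this
#' is symmetrization; a symmetric input is returned unchanged (idempotent).
#'
#' @param net a [binary_network()].
#' @return a symmetric [binary_network()].
#' @export
bidirect <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- pmax(net$adjacency, t(net$adjacency))
  binary_network(a, net$labels)
}

#' Remove isolated nodes
#'
#' Drops nodes with zero total degree. Isolated regions do not affect the LCC
#' or the connected component's control energy, but each would require its own
#' input signal, so they are removed before controllability analysis.
#'
#' @param net a [binary_network()].
#' @return list with `network` (the reduced net), `removed` (labels of dropped
#'   nodes) and `kept` (original indices of surviving nodes, the relabeling
#'   map).
#' @export
remove_isolated <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  deg <- rowSums(net$adjacency) + colSums(net$adjacency)
  keep <- which(deg > 0)
  removed <- setdiff(seq_len(net$n_nodes), keep)
  nm <- node_names(net)
  out <- binary_network(net$adjacency[keep, keep, drop = FALSE],
                        if (!is.null(net$labels)) net$labels[keep] else NULL)
  list(network = out, removed = nm[removed], kept = keep)
}

#' Structural network properties
#'
#' Summary statistics of a binary directed network: node and link counts,
#' isolated nodes, degree extremes and mean, degree heterogeneity and the mean
#' shortest-path distance.
#'
#' Degree heterogeneity is
#' \deqn{H = \max(H^{in}, H^{out}), \quad
#'       H^{in/out} = \frac{1}{r N^2} \sum_i \sum_j |k_i^{in/out} - k_j^{in/out}|,}
#' the normalized mean absolute pairwise degree difference; `r_const` is a
#' free normalization constant (default 1). Dividing instead by the mean
#' degree (`r_const = mean degree`) gives the dimensionless form of order
#' 0.5--0.7 typical of 90-region connectomes.
#'
#' Mean distance averages directed shortest-path lengths over ordered pairs of
#' distinct nodes with a finite distance; unreachable pairs are excluded.
#'
#' @param net a [binary_network()] with at least one node.
#' @param r_const positive normalization constant `r` in the heterogeneity
#'   formula.
#' @return object of class `network_properties`: a list with `n_nodes`,
#'   `n_links` (directed count), `n_links_undirected` (for symmetric nets,
#'   otherwise `NA`), `isolated_nodes`, `heterogeneity`, `mean_degree`
#'   (mean out-degree over all nodes), `k_min`, `k_max` (out-degree extremes
#'   over non-isolated nodes), `mean_distance`.
#' @export
properties <- function(net, r_const = 1) {
  stopifnot(inherits(net, "binary_network"))
  if (net$n_nodes < 1) stop("empty network")
  stopifnot(r_const > 0)
  a <- net$adjacency
  n <- net$n_nodes
  k_in <- rowSums(a)
  k_out <- colSums(a)
  deg_tot <- k_in + k_out
  isolated <- node_names(net)[deg_tot == 0]
  sym <- all(a == t(a))
  het <- function(k) sum(abs(outer(k, k, "-"))) / (r_const * n^2)
  d <- igraph::distances(as_igraph(net), mode = "out")
  diag(d) <- Inf
  finite <- d[is.finite(d)]
  active <- deg_tot > 0
  structure(list(
    n_nodes = n,
    n_links = sum(a),
    n_links_undirected = if (sym) sum(a) / 2 else NA_real_,
    isolated_nodes = isolated,
    heterogeneity = max(het(k_in), het(k_out)),
    mean_degree = mean(k_out),
    k_min = if (any(active)) min(k_out[active]) else 0L,
    k_max = if (any(active)) max(k_out[active]) else 0L,
    mean_distance = if (length(finite)) mean(finite) else NA_real_
  ), class = "network_properties")
}

#' @export
print.network_properties <- function(x, ...) {
  cat(sprintf(
    "<network_properties> N = %d, |E| = %d directed, H = %.3f, c = %.2f, k in [%d, %d], d = %.3f\n",
    x$n_nodes, x$n_links, x$heterogeneity, x$mean_degree,
    x$k_min, x$k_max, x$mean_distance))
  if (length(x$isolated_nodes)) {
    cat("  isolated:", paste(x$isolated_nodes, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Tabulate properties of several networks
#'
#' Convenience wrapper producing one row per network in the style of a
#' connectome summary table.
#'
#' @param nets list of [binary_network()] objects.
#' @param r_const passed to [properties()].
#' @return data.frame with one row per network.
#' @export
properties_table <- function(nets, r_const = 1) {
  rows <- lapply(seq_along(nets), function(i) {
    p <- properties(nets[[i]], r_const = r_const)
    data.frame(network = i, n_nodes = p$n_nodes, n_links = p$n_links,
               n_isolated = length(p$isolated_nodes),
               H = p$heterogeneity, c = p$mean_degree,
               k_min = p$k_min, k_max = p$k_max, d = p$mean_distance)
  })
  do.call(rbind, rows)
}
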
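#' Bipartite representation of a digraph
#'
#' Splits every node \eqn{v} into an out-copy \eqn{v^+} and an in-copy
#' \eqn{v^-}; each directed link \eqn{v \to w} becomes the undirected
#' bipartite link \eqn{(v^+, w^-)}. Maximum matchings on this graph identify
#' the minimum number of independent control signals.
#'
#' @param net a [binary_network()].
#' @return object of class `bipartite_rep`: list with `n_nodes` and `links`,
#'   a 2-column matrix of (out-copy, in-copy) index pairs sorted by out-copy
#'   then in-copy.
#' @export
build_bipartite <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  idx <- which(net$adjacency == 1, arr.ind = TRUE)  # (target j, source i)
  links <- cbind(out_copy = idx[, 2], in_copy = idx[, 1])
  links <- links[order(links[, 1], links[, 2]), , drop = FALSE]
  structure(list(n_nodes = net$n_nodes, links = links), class = "bipartite_rep")
}

# Kuhn's augmenting-path maximum matching. adj: list over left vertices of
# right-neighbor vectors (ascending). Deterministic: left vertices and their
# neighbors are scanned in ascending order.
kuhn_matching <- function(n_left, n_right, adj) {
  match_right <- integer(n_right)  # 0 = free
  match_left <- integer(n_left)
  seen <- logical(n_right)
  try_aug <- function(v) {
    for (w in adj[[v]]) {
      if (!seen[w]) {
        seen[w] <<- TRUE
        if (match_right[w] == 0L || try_aug(match_right[w])) {
          match_right[w] <<- v
          match_left[v] <<- w
          return(TRUE)
        }
      }
    }
    FALSE
  }
  for (v in seq_len(n_left)) {
    if (length(adj[[v]])) {
      seen[] <- FALSE
      try_aug(v)
    }
  }
  list(match_left = match_left, match_right = match_right)
}

#' Maximum matching and minimum input count
#'
#' Finds a maximum matching of the bipartite split-node representation by
#' deterministic augmenting-path search (out-copies and their neighbors
#' scanned in ascending label order, so the result is reproducible).
#' In-copies left unmatched mark nodes that must receive an independent
#' external signal; the number of signals is
#' \eqn{N_i = \max(1, N_u)} with \eqn{N_u} the number of unmatched in-copies.
#' \eqn{N_u} is invariant across maximum matchings even though the unmatched
#' set itself is not unique.
#'
#' @param bip a [build_bipartite()] result (a `binary_network` is accepted and
#'   converted).
#' @return object of class `matching_result`: `matched_links` (2-column
#'   matrix of matched (out-copy, in-copy) pairs), `unmatched_nodes`
#'   (ascending in-copy indices), `n_unmatched`, `n_inputs`.
#' @export
maximum_matching <- function(bip) {
  if (inherits(bip, "binary_network")) bip <- build_bipartite(bip)
  stopifnot(inherits(bip, "bipartite_rep"))
  n <- bip$n_nodes
  adj <- split(bip$links[, 2], factor(bip$links[, 1], levels = seq_len(n)))
  adj <- lapply(adj, function(x) sort(unname(x)))
  m <- kuhn_matching(n, n, adj)
  matched <- which(m$match_left > 0L)
  matched_links <- cbind(out_copy = matched, in_copy = m$match_left[matched])
  unmatched <- which(m$match_right == 0L)
  structure(list(
    matched_links = matched_links,
    unmatched_nodes = unmatched,
    n_unmatched = length(unmatched),
    n_inputs = max(1L, length(unmatched))
  ), class = "matching_result")
}

#' @export
print.matching_result <- function(x, ...) {
  cat("<matching_result> matching size ", nrow(x$matched_links),
      ", unmatched in-copies {", paste(x$unmatched_nodes, collapse = ", "),
      "}, N_i = ", x$n_inputs, "\n", sep = "")
  invisible(x)
}

#' Enumerate unmatched sets over all maximum matchings
#'
#' Maximum matchings are not unique; different matchings yield different
#' (equal-sized) unmatched in-copy sets, i.e. alternative minimal driver-node
#' sets. This exhaustive branch-and-bound enumeration is intended for small
#' graphs (it refuses networks with more than `max_links` bipartite links).
#'
#' @param bip [build_bipartite()] result or `binary_network`.
#' @param max_sets stop after this many distinct unmatched sets.
#' @param max_links guard on problem size.
#' @return list of sorted integer vectors, each a valid unmatched in-copy set;
#'   the attribute `"matching_size"` carries the maximum matching size.
#' @export
enumerate_unmatched_sets <- function(bip, max_sets = 100L, max_links = 30L) {
  if (inherits(bip, "binary_network")) bip <- build_bipartite(bip)
  stopifnot(inherits(bip, "bipartite_rep"))
  links <- bip$links
  if (nrow(links) > max_links) {
    stop("enumeration limited to graphs with at most ", max_links, " links")
  }
  best <- nrow(maximum_matching(bip)$matched_links)
  sets <- new.env()
  n_found <- 0L
  recurse <- function(i, used_left, used_right, size) {
    if (n_found >= max_sets) return()
    if (size + (nrow(links) - i + 1L) < best) return()  # bound
    if (i > nrow(links)) {
      if (size == best) {
        key <- paste0("u", paste(sort(setdiff(seq_len(bip$n_nodes), used_right)),
                                 collapse = ","))
        if (is.null(sets[[key]])) {
          sets[[key]] <- TRUE
          n_found <<- n_found + 1L
        }
      }
      return()
    }
    v <- links[i, 1]; w <- links[i, 2]
    if (!(v %in% used_left) && !(w %in% used_right)) {
      recurse(i + 1L, c(used_left, v), c(used_right, w), size + 1L)
    }
    recurse(i + 1L, used_left, used_right, size)
  }
  recurse(1L, integer(0), integer(0), 0L)
  out <- lapply(ls(sets), function(k) {
    v <- strsplit(substring(k, 2), ",")[[1]]
    if (length(v)) as.integer(v) else integer(0)
  })
  out <- out[order(vapply(out, paste, "", collapse = ","))]
  attr(out, "matching_size") <- best
  out
}

#' Input (driver) matrix B
#'
#' Builds the \eqn{n \times m} selector matrix coupling one independent
#' control signal to each input node: column \eqn{j} is the canonical unit
#' vector of the \eqn{j}-th input node.
#'
#' @param net a [binary_network()] (or an integer node count).
#' @param inputs integer vector of distinct input node indices (nonempty).
#' @return numeric matrix B.
#' @export
input_matrix <- function(net, inputs) {
  n <- if (inherits(net, "binary_network")) net$n_nodes else as.integer(net)
  inputs <- as.integer(inputs)
  if (length(inputs) == 0) stop("inputs must be nonempty")
  if (anyDuplicated(inputs)) stop("inputs must be distinct")
  if (any(inputs < 1 | inputs > n)) stop("input index out of range")
  B <- matrix(0, n, length(inputs))
  B[cbind(inputs, seq_along(inputs))] <- 1
  B
}

expm_dense <- function(m) {
  as.matrix(Matrix::expm(Matrix::Matrix(m)))
}

#' Finite-horizon controllability Gramian
#'
#' Computes \deqn{W_B(t_f) = \int_0^{t_f} e^{A\tau} B B^T e^{A^T\tau}\, d\tau}
#' by the Van Loan block-exponential method: the exponential of the
#' \eqn{2n \times 2n} block matrix \eqn{t_f [[-A, BB^T], [0, A^T]]} yields the
#' integral exactly up to matrix-exponential accuracy, valid for unstable
#' \eqn{A} (a finite horizon, so Lyapunov solvers do not apply). The result is
#' symmetrized to remove roundoff asymmetry.
#'
#' @param net a [binary_network()]; its adjacency is the system matrix A.
#' @param inputs integer vector of input node indices.
#' @param t_f control horizon (> 0); the study convention is `t_f = 1`.
#' @return object of class `gramian_result`: `W`, `lambda_min`, `lambda_max`,
#'   `trace_energy` (\eqn{\varepsilon(t_f) = Trace(W)}), `log10_energy`,
#'   `t_f`, `inputs`.
#' @export
gramian <- function(net, inputs, t_f = 1) {
  stopifnot(inherits(net, "binary_network"), t_f > 0)
  A <- net$adjacency
  B <- input_matrix(net, inputs)
  n <- net$n_nodes
  M <- rbind(cbind(-A, B %*% t(B)), cbind(matrix(0, n, n), t(A))) * t_f
  E <- expm_dense(M)
  if (any(!is.finite(E))) {
    stop("matrix exponential overflowed; use a smaller t_f or rescale A")
  }
  F3 <- E[(n + 1):(2 * n), (n + 1):(2 * n)]
  G <- E[1:n, (n + 1):(2 * n)]
  W <- t(F3) %*% G
  W <- (W + t(W)) / 2
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  structure(list(
    W = W,
    lambda_min = min(ev),
    lambda_max = max(ev),
    trace_energy = sum(diag(W)),
    log10_energy = log10(sum(diag(W))),
    t_f = t_f,
    inputs = sort(as.integer(inputs))
  ), class = "gramian_result")
}

#' @export
print.gramian_result <- function(x, ...) {
  cat(sprintf(
    "<gramian_result> m = %d inputs, t_f = %g: trace = %.6g (log10 = %.3f), lambda_min = %.3g\n",
    length(x$inputs), x$t_f, x$trace_energy, x$log10_energy, x$lambda_min))
  invisible(x)
}

# Kalman controllability matrix rank [B, AB, ..., A^{n-1}B]; columns are
# rescaled per power to keep the QR factorization conditioned.
kalman_rank <- function(A, B, tol = NULL) {
  n <- nrow(A)
  blocks <- vector("list", n)
  cur <- B
  for (k in seq_len(n)) {
    s <- max(abs(cur))
    if (s > 0) cur <- cur / s
    blocks[[k]] <- cur
    cur <- A %*% cur
  }
  C <- do.call(cbind, blocks)
  qr(C, tol = if (is.null(tol)) 1e-9 else tol)$rank
}

#' Graph-theoretic structural controllability test
#'
#' Exact test on the zero pattern alone (no floating point): the pair (A, B)
#' with unit-selector B on the input set is structurally controllable iff
#' (i) every node is accessible from some input along directed links and
#' (ii) the generic rank of \eqn{[A\ B]} is n, i.e. the bipartite graph whose
#' right vertices are the n state rows, with left vertices the state columns
#' (edges per A) plus one signal vertex per input (edge to its input row),
#' admits a matching saturating all rows (no dilation).
#'
#' @param net a [binary_network()].
#' @param inputs integer vector of input node indices.
#' @return logical; attribute `"diagnostics"` lists `accessible` (logical
#'   per-node vector) and `generic_rank`.
#' @export
structurally_controllable_graph <- function(net, inputs) {
  stopifnot(inherits(net, "binary_network"))
  inputs <- as.integer(inputs)
  n <- net$n_nodes
  d <- suppressWarnings(
    igraph::distances(as_igraph(net), v = inputs, mode = "out"))
  reach <- apply(d, 2, min) < Inf
  # generic rank of [A B]: left = n state columns + m signal columns
  m <- length(inputs)
  adj <- vector("list", n + m)
  for (v in seq_len(n)) adj[[v]] <- which(net$adjacency[, v] == 1)
  for (j in seq_len(m)) adj[[n + j]] <- inputs[j]
  mm <- kuhn_matching(n + m, n, adj)
  grank <- sum(mm$match_right > 0L)
  ok <- all(reach) && grank == n
  attr(ok, "diagnostics") <- list(accessible = reach, generic_rank = grank)
  ok
}

#' Gramian-based structural controllability test
#'
#' Declares the system controllable when the smallest eigenvalue of the
#' controllability Gramian exceeds `tol`. The Gramian of a sparse input set is
#' typically severely ill-conditioned, so the default tolerance is the
#' eigenvalue-scale machine floor \eqn{n\,\epsilon_{mach}\,\lambda_{max}(W)};
#' for networks beyond a few tens of nodes prefer
#' [structurally_controllable_graph()], reported here as a diagnostic.
#'
#' @inheritParams gramian
#' @param tol non-negative eigenvalue threshold; `NULL` for the default above.
#' @return logical; attribute `"diagnostics"`: `lambda_min`, `tol`,
#'   `kalman_rank` (for n <= 50, else `NA`), `graph_test` result.
#' @export
is_structurally_controllable <- function(net, inputs, t_f = 1, tol = NULL) {
  g <- gramian(net, inputs, t_f)
  if (is.null(tol)) {
    tol <- net$n_nodes * .Machine$double.eps * max(g$lambda_max, 0)
  }
  stopifnot(tol >= 0)
  krank <- if (net$n_nodes <= 50) {
    kalman_rank(net$adjacency, input_matrix(net, inputs))
  } else NA_integer_
  ok <- g$lambda_min > tol
  attr(ok, "diagnostics") <- list(
    lambda_min = g$lambda_min, tol = tol, kalman_rank = krank,
    graph_test = as.logical(structurally_controllable_graph(net, inputs)))
  ok
}
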
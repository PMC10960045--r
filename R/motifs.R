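#' Census of connected 3-node motifs in bidirectional networks
#'
#' Counts the two connected triads that occur in symmetric (bidirectional)
#' networks, classified on *induced* 3-node subgraphs:
#' \describe{
#'   \item{id78}{the mutual open path \eqn{a \leftrightarrow b
#'     \leftrightarrow c} with no \eqn{a}--\eqn{c} link (two mutual dyads);}
#'   \item{id238}{the fully mutually connected triangle (three mutual
#'     dyads).}
#' }
#' Their sum `M` measures path multiplicity between regions: each id238
#' triple offers a direct link plus a 2-hop detour, so larger `M` means more
#' parallel routes from inputs to targets and hence lower control energy.
#'
#' Counting uses closed forms on the mutual-dyad graph \eqn{U = A \wedge
#' A^T}: id238 equals the triangle count \eqn{T = tr(U^3)/6}, and id78 equals
#' \eqn{\sum_v \binom{k_v}{2} - 3T} with \eqn{k_v} the mutual degree. On an
#' asymmetric digraph only the mutual patterns enter `id78`/`id238`;
#' remaining (weakly) connected triples are tallied in `other` and excluded
#' from `M`.
#'
#' @param net a [binary_network()].
#' @return object of class `motif_census`: `id78`, `id238`, `M = id78 +
#'   id238`, `other`.
#' @export
motif_census <- function(net) {
  stopifnot(inherits(net, "binary_network"))
  a <- net$adjacency
  u <- (a == 1 & t(a) == 1) * 1          # mutual dyads
  tri <- sum(diag(u %*% u %*% u)) / 6
  k <- rowSums(u)
  id78 <- sum(choose(k, 2)) - 3 * tri
  # weakly connected triples on the full skeleton, minus the mutual ones
  skel <- pmax(a, t(a))
  tri_s <- sum(diag(skel %*% skel %*% skel)) / 6
  ks <- rowSums(skel)
  connected_s <- sum(choose(ks, 2)) - 2 * tri_s
  structure(list(
    id78 = as.integer(round(id78)),
    id238 = as.integer(round(tri)),
    M = as.integer(round(id78 + tri)),
    other = as.integer(round(connected_s - id78 - tri))
  ), class = "motif_census")
}

#' @export
print.motif_census <- function(x, ...) {
  cat("<motif_census> id78 =", x$id78, ", id238 =", x$id238, ", M =", x$M,
      if (x$other > 0) paste0(", other = ", x$other), "\n")
  invisible(x)
}
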
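#' Trace control energy
#'
#' The control-energy metric \eqn{\varepsilon(t_f) = Trace(W_B(t_f))}: the sum
#' of the Gramian eigenvalues, with *higher* values meaning *less* energy is
#' needed on average to move the state in all directions. Values are carried
#' both raw and as \eqn{\log_{10}\varepsilon(t_f)}, the reporting scale used
#' throughout.
#'
#' This is a thin wrapper over [gramian()]; it exists so energy computations
#' read as such at call sites.
#'
#' @inheritParams gramian
#' @return a `gramian_result` (see [gramian()]).
#' @export
trace_energy <- function(net, inputs, t_f = 1) {
  gramian(net, inputs, t_f)
}

#' Per-node single-input trace energies
#'
#' The trace is additive over input columns:
#' \eqn{\varepsilon_S = \sum_{v \in S} \varepsilon_{\{v\}}}, because
#' \eqn{W_B = \sum_v W_{e_v}}. All n single-input energies are therefore the
#' diagonal of \eqn{\int_0^{t_f} e^{A^T\tau} e^{A\tau} d\tau}, obtained from a
#' single Van Loan block exponential instead of n separate Gramian
#' integrations.
#'
#' @param net a [binary_network()].
#' @param t_f control horizon (> 0).
#' @return numeric vector of length n: `trace_energy` of each node as sole
#'   input.
#' @export
node_energies <- function(net, t_f = 1) {
  stopifnot(inherits(net, "binary_network"), t_f > 0)
  A <- net$adjacency
  n <- net$n_nodes
  # Gramian of the pair (A^T, I): integral of e^{A^T tau} e^{A tau}
  M <- rbind(cbind(-t(A), diag(n)), cbind(matrix(0, n, n), A)) * t_f
  E <- expm_dense(M)
  if (any(!is.finite(E))) {
    stop("matrix exponential overflowed; use a smaller t_f or rescale A")
  }
  F3 <- E[(n + 1):(2 * n), (n + 1):(2 * n)]
  G <- E[1:n, (n + 1):(2 * n)]
  W <- t(F3) %*% G
  diag((W + t(W)) / 2)
}

#' Trace inverse-proportionality check
#'
#' The average-energy metric \eqn{Trace(W^{-1})} and the trace metric obey
#' \eqn{Trace(W^{-1}) > N^2 / Trace(W)} (a Cauchy--Schwarz consequence, with
#' equality only at \eqn{W \propto I}), which justifies using the
#' numerically benign trace as the energy proxy: the two are inversely
#' related. \eqn{W} is typically near-singular for sparse input sets, so this
#' check is meant for small well-conditioned validation systems.
#'
#' @param W a `gramian_result` or a symmetric positive-definite matrix.
#' @param tol relative singularity threshold on the smallest eigenvalue.
#' @return list with `lhs` (\eqn{Trace(W^{-1})}), `rhs` (\eqn{N^2/Trace(W)})
#'   and `holds` (`lhs >= rhs`).
#' @export
trace_inverse_check <- function(W, tol = 1e-12) {
  if (inherits(W, "gramian_result")) W <- W$W
  W <- as.matrix(W)
  ev <- eigen(W, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= tol * max(ev)) {
    stop("Gramian is singular to tolerance: system not controllable through this input set")
  }
  lhs <- sum(diag(solve(W)))
  rhs <- nrow(W)^2 / sum(diag(W))
  list(lhs = lhs, rhs = rhs, holds = lhs >= rhs)
}
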
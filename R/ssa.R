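#' Diffusion matrix of the system-size conductance model
#'
#' For a kinetic scheme at voltage `V` and deterministic state-fraction
#' vector `x_det`, the diffusion matrix has entries
#' \deqn{D_{kl} = -( r_{k\to l} x_k + r_{l\to k} x_l ) / N \quad (k \ne l),
#'       \qquad D_{kk} = \sum_{l \ne k} ( r_{k\to l} x_k + r_{l\to k} x_l )/N.}
#' Evaluating at the deterministic (simplex) state guarantees positive
#' semidefiniteness, hence the existence of a real matrix square root.
#'
#' @param scheme a [kinetic_scheme()].
#' @param V voltage (mV).
#' @param x_det state-fraction vector on the simplex (e.g. from
#'   [gating_to_statevec()]); entries must sum to 1 within 1e-6.
#' @param N channel count.
#' @return Symmetric matrix `D` (1/ms, fraction^2 scale) with zero row sums.
#' @export
build_diffusion <- function(scheme, V, x_det, N) {
  if (abs(sum(x_det) - 1) > 1e-6 || any(x_det < -1e-6))
    stop("x_det must lie on the probability simplex (within 1e-6)")
  ns <- length(scheme$states)
  D <- matrix(0, ns, ns, dimnames = list(scheme$states, scheme$states))
  for (e in seq_along(scheme$from)) {
    k <- scheme$from[e]; l <- scheme$to[e]
    flux <- scheme$mult[e] * eval_edge_rate(scheme$rate[[e]], V) * x_det[k] / N
    D[k, l] <- D[k, l] - flux
    D[l, k] <- D[l, k] - flux
    D[k, k] <- D[k, k] + flux
    D[l, l] <- D[l, l] + flux
  }
  D
}

#' Symmetric square root of a positive semidefinite matrix
#'
#' Eigendecomposition square root with small negative eigenvalues clamped
#' to zero.  Because the conservation vector (all ones) is in the null
#' space of the diffusion matrix, the symmetric root keeps it there
#' structurally, so fluctuations remain zero-sum.
#'
#' @param D symmetric matrix with eigenvalues >= `-eps_tol * scale` where
#'   `scale` is `max(1, trace magnitude)`.
#' @param eps_tol relative tolerance for negative eigenvalues (default
#'   1e-9).
#' @return Symmetric matrix `S` with `S %*% S` reconstructing `D`.
#' @export
matrix_sqrt_psd <- function(D, eps_tol = 1e-9) {
  if (max(abs(D - t(D))) > 1e-10 * max(1, max(abs(D))))
    stop("D must be symmetric")
  dec <- eigen(D, symmetric = TRUE)
  scale <- max(1e-300, sum(abs(diag(D))))
  if (any(dec$values < -eps_tol * scale))
    stop(sprintf("matrix is not PSD: min eigenvalue %.3e (tolerance %.3e)",
                 min(dec$values), -eps_tol * scale))
  ev <- sqrt(pmax(dec$values, 0))
  S <- dec$vectors %*% (ev * t(dec$vectors))
  dimnames(S) <- dimnames(D)
  (S + t(S)) / 2
}

#' Drift, diffusion and noise matrices of the fluctuation SDE
#'
#' Convenience wrapper returning the generator `A`, diffusion `D` and
#' square root `S` for the classical Na or K scheme at a given voltage and
#' gating state.
#'
#' @param type `"Na"` or `"K"`.
#' @param V voltage (mV).
#' @param gating list with `m`, `h`, `n` giving the deterministic state.
#' @param N channel count.
#' @return List with `A`, `D`, `S` and the deterministic vector `x_det`.
#' @export
ssa_matrices <- function(type = c("Na", "K"), V, gating, N) {
  type <- match.arg(type)
  scheme <- if (type == "Na") hh_na_scheme() else hh_k_scheme()
  x_det <- gating_to_statevec(gating, scheme)
  A <- build_generator(scheme, V)
  D <- build_diffusion(scheme, V, x_det, N)
  list(A = A, D = D, S = matrix_sqrt_psd(D), x_det = x_det)
}

#' One Euler-Maruyama step of the fluctuation SDE
#'
#' Advances the zero-mean fluctuation vector by
#' `x + A x dt + S sqrt(dt) zeta`.  The deterministic companion of the
#' decomposition evolves separately (by the matching Euler step of the
#' linear deterministic equation, or equivalently by the gating ODE mapped
#' through [gating_to_statevec()]).
#'
#' @param x_tilde fluctuation vector.
#' @param A generator (drift) matrix.
#' @param S noise matrix (square root of the diffusion matrix).
#' @param dt time step (ms).
#' @param zeta standard normal vector (one draw per state).
#' @return Updated fluctuation vector.
#' @export
step_fluctuation <- function(x_tilde, A, S, dt, zeta) {
  as.vector(x_tilde + A %*% x_tilde * dt + S %*% zeta * sqrt(dt))
}

#' Stationary covariance of the fluctuation SDE in voltage clamp
#'
#' Solves the continuous Lyapunov equation `A S + S A' + D = 0` for the
#' stationary covariance of the linear fluctuation SDE.  The generator is
#' singular (probability conservation), so the Kronecker system is solved
#' by SVD pseudo-inverse and the free mode along the stationary vector is
#' fixed by requiring zero total-fraction variance (`1' Sigma 1 = 0`).
#'
#' @param A generator matrix (columns sum to zero).
#' @param D symmetric PSD diffusion matrix with zero row sums.
#' @return Symmetric covariance matrix `Sigma`.
#' @export
lyapunov_covariance <- function(A, D) {
  ns <- nrow(A)
  K <- kronecker(diag(ns), A) + kronecker(A, diag(ns))
  b <- -as.vector(D)
  sv <- svd(K)
  tol <- max(dim(K)) * max(sv$d) * .Machine$double.eps
  dinv <- ifelse(sv$d > tol, 1 / sv$d, 0)
  Sig <- matrix(sv$v %*% (dinv * crossprod(sv$u, b)), ns, ns)
  Sig <- (Sig + t(Sig)) / 2
  # fix the homogeneous mode (outer product of the stationary vector) so
  # that the total fraction has zero variance
  dec <- eigen(A)
  w <- Re(dec$vectors[, which.min(abs(dec$values))])
  w <- w / sum(w)
  ones <- rep(1, ns)
  Sig <- Sig - (as.numeric(t(ones) %*% Sig %*% ones)) * (w %o% w)
  dimnames(Sig) <- dimnames(A)
  (Sig + t(Sig)) / 2
}

#' Stationary fluctuation samples of the system-size model in clamp
#'
#' Evolves the fluctuation SDE at a fixed clamp voltage for a burn-in
#' period and returns the final fluctuation vectors across replicates,
#' for comparison with the Lyapunov-equation covariance.
#'
#' @param V clamp voltage (mV).
#' @param N_Na,N_K channel counts.
#' @param reps number of replicates.
#' @param seed integer seed.
#' @param T_burn burn-in duration (ms).
#' @param dt time step (ms).
#' @return List with matrices `fluct_Na` (reps x 8) and `fluct_K`
#'   (reps x 5).
#' @export
ssa_stationary_sample <- function(V, N_Na = 6000, N_K = 1800, reps = 5000,
                                  seed = NULL, T_burn = 50, dt = 0.01) {
  seed <- check_seed(seed)
  cpp_ssa_stationary_sample(V, 1 / N_Na, 1 / N_K, as.integer(reps),
                            T_burn, dt, seed)
}
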
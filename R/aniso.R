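# quadratic-form design row per reflection: h'Uh = V . (U11,...,U23)
quad_basis <- function(indices) {
  h <- as_index_matrix(indices)
  cbind(h[, 1]^2, h[, 2]^2, h[, 3]^2,
        2 * h[, 1] * h[, 2], 2 * h[, 1] * h[, 3], 2 * h[, 2] * h[, 3])
}

#' Exponential anisotropic scale factor
#'
#' Evaluates `exp(-2 pi^2 h' U h)` per reflection, with U a symmetric
#' tensor in the Miller-index basis.
#'
#' @param u Symmetric 6-vector (U11, U22, U33, U12, U13, U23).
#' @param indices Integer matrix (n x 3) of Miller indices.
#' @return Positive numeric vector; equals 1 at (0, 0, 0).
#' @export
k_aniso_exponential <- function(u, indices) {
  exp(-2 * pi^2 * drop(quad_basis(indices) %*% u))
}

#' Polynomial anisotropic scale factor
#'
#' Evaluates `1 + h' V0 h + s^2 (h' V1 h)`, the constant-plus-Taylor-terms
#' form of the exponential factor.  Linear in the 12 tensor coefficients
#' and equal to 1 at (0, 0, 0).
#'
#' @param v0,v1 Symmetric 6-vectors.
#' @param indices Integer matrix (n x 3) of Miller indices.
#' @param s2 Per-reflection s^2 values (Angstrom^-2).
#' @return Numeric vector (not guaranteed positive far from the fitted
#'   resolution range).
#' @export
k_aniso_polynomial <- function(v0, v1, indices, s2) {
  B <- quad_basis(indices)
  1 + drop(B %*% v0) + s2 * drop(B %*% v1)
}

#' Analytic exponential anisotropic fit
#'
#' Fits the symmetry-constrained tensor U of the exponential scale
#' factor by minimizing the log residual
#' `sum((h'Uh + Z)^2)` with `Z = ln(F_obs / m) / (2 pi^2)`, where `m`
#' is the current model amplitude excluding the anisotropic factor.
#' This reduces to a small linear system in the independent tensor
#' coefficients.  Reflections with non-positive `F_obs` or `m` are
#' excluded (their count is reported).
#'
#' @param f_obs Observed amplitudes.
#' @param m Model amplitudes excluding the anisotropic factor
#'   (`k_overall * k_isotropic * |F_calc + k_mask F_mask|`).
#' @param indices Miller indices (n x 3).
#' @param C Constraint matrix from [derive_constraint_matrix()];
#'   defaults to the unconstrained (triclinic) 6x6 identity.
#' @return List with `u` (full 6-vector), `u_ind`, `n_excluded`.
#' @export
fit_exponential_aniso <- function(f_obs, m, indices, C = diag(6)) {
  keep <- is.finite(f_obs) & is.finite(m) & f_obs > 0 & m > 0
  if (sum(keep) < nrow(C))
    stop("too few reflections with positive amplitudes for the exponential fit")
  z <- log(f_obs[keep] / m[keep]) / (2 * pi^2)
  X <- quad_basis(as_index_matrix(indices)[keep, , drop = FALSE]) %*% t(C)
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    null_dir <- qr.Q(qr(t(X)), complete = TRUE)[, ncol(X), drop = TRUE]
    stop(sprintf(
      "rank-deficient anisotropic normal matrix; unconstrained direction (%s)",
      paste(sprintf("%.3g", null_dir), collapse = ", ")))
  }
  # minimize ||X u_ind + z||^2  (model: h'Uh = -Z at the optimum)
  u_ind <- qr.coef(qrx, -z)
  list(u = expand_independent(u_ind, C), u_ind = u_ind,
       n_excluded = sum(!keep))
}

#' Polynomial anisotropic fit
#'
#' Fits (V0, V1) of the polynomial scale factor by minimizing the linear
#' residual `sum((F_obs - k_aniso * m)^2)` directly -- a 12-parameter
#' linear least-squares problem.  No positivity of the amplitudes is
#' required and, following the model's usual practice, no symmetry
#' constraints are applied.
#'
#' @inheritParams fit_exponential_aniso
#' @param s2 Per-reflection s^2 values.
#' @return List with `v0`, `v1` (6-vectors) and `pseudo_inverse`
#'   (logical: TRUE when an ill-conditioned normal matrix forced the
#'   pseudo-inverse path).
#' @export
fit_polynomial_aniso <- function(f_obs, m, indices, s2) {
  B <- quad_basis(indices)
  X <- cbind(B, s2 * B) * m
  y <- f_obs - m
  N <- crossprod(X)
  b <- crossprod(X, y)
  sv <- svd(N)
  used_pinv <- FALSE
  if (sv$d[1] <= 0 || sv$d[length(sv$d)] < sv$d[1] / 1e12) {
    used_pinv <- TRUE
    warning("ill-conditioned 12x12 normal matrix; using pseudo-inverse")
    dinv <- ifelse(sv$d > sv$d[1] * 1e-12, 1 / sv$d, 0)
    theta <- sv$v %*% (dinv * crossprod(sv$u, b))
  } else {
    theta <- solve(N, b)
  }
  theta <- drop(theta)
  list(v0 = theta[1:6], v1 = theta[7:12], pseudo_inverse = used_pinv)
}

#' Exponential anisotropic fit by quasi-Newton minimization
#'
#' Minimizes the linear (amplitude) residual
#' `sum((F_obs - exp(-2 pi^2 h'Uh) * m)^2)` over the constrained tensor
#' by L-BFGS iteration, started from the analytic log-residual solution.
#' The two targets have different minima in general; this variant trades
#' speed for the amplitude-space optimum.  The returned tensor never has
#' a higher amplitude residual than its starting point.
#'
#' @inheritParams fit_exponential_aniso
#' @param start Optional starting 6-vector; defaults to the analytic
#'   fit (zero tensor if that fit fails).
#' @param max_iter Iteration cap for the optimizer.
#' @return List with `u`, `u_ind`, `converged` (logical), `residual`.
#' @export
fit_exponential_aniso_minimized <- function(f_obs, m, indices, C = diag(6),
                                            start = NULL, max_iter = 200) {
  X6 <- quad_basis(indices)
  XC <- X6 %*% t(C)
  # clamp the exponent so wild optimizer steps cannot overflow to Inf
  kfun <- function(u_ind) exp(pmin(-2 * pi^2 * drop(XC %*% u_ind), 200))
  obj <- function(u_ind) {
    r <- f_obs - kfun(u_ind) * m
    sum(r * r)
  }
  grad <- function(u_ind) {
    ka <- kfun(u_ind)
    r <- f_obs - ka * m
    drop(crossprod(XC, 4 * pi^2 * r * ka * m))
  }
  if (is.null(start)) {
    start_ind <- tryCatch(
      fit_exponential_aniso(f_obs, m, indices, C)$u_ind,
      error = function(e) rep(0, nrow(C)))
  } else {
    # least-squares projection of the supplied tensor onto the basis rows
    start_ind <- drop(solve(C %*% t(C), C %*% start))
  }
  f0 <- obj(start_ind)
  fit <- stats::optim(start_ind, obj, grad, method = "L-BFGS-B",
                      control = list(maxit = max_iter, factr = 1e4))
  if (fit$value <= f0) {
    u_ind <- fit$par
    val <- fit$value
  } else {
    u_ind <- start_ind
    val <- f0
  }
  list(u = expand_independent(u_ind, C), u_ind = u_ind,
       converged = fit$convergence == 0, residual = val)
}
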
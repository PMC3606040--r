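#' Per-reflection moments for bin-wise scale determination
#'
#' Precomputes the quadratic-form moments of the two model
#' contributions: `u = |F_calc|^2`, `v = Re(F_calc . conj(F_mask))`,
#' `w = |F_mask|^2` and the observed intensity `I = F_obs^2`, so that
#' `|F_calc + k F_mask|^2 = u + 2 k v + k^2 w`.
#'
#' @param f_calc,f_mask Complex vectors.
#' @param f_obs Observed amplitudes.
#' @return Object of class `bin_moments` (list of numeric vectors `u`,
#'   `v`, `w`, `i_obs`).
#' @export
bin_moments <- function(f_calc, f_mask, f_obs) {
  structure(
    list(u = Mod(f_calc)^2,
         v = Re(f_calc * Conj(f_mask)),
         w = Mod(f_mask)^2,
         i_obs = as.numeric(f_obs)^2),
    class = "bin_moments")
}

# cubic coefficients of the stationarity condition in k_mask, written so
# the leading coefficient is the Cauchy-Schwarz-nonnegative combination
# sum(I^2) sum(w^2) - sum(I w)^2
cubic_coefficients <- function(mom) {
  with(mom, {
    A <- sum(i_obs^2)
    a1 <- sum(i_obs * u); a2 <- sum(i_obs * v); a3 <- sum(i_obs * w)
    Suv <- sum(u * v); Svv <- sum(v * v); Suw <- sum(u * w)
    Svw <- sum(v * w); Sww <- sum(w * w)
    c(t0 = A * Suv - a1 * a2,
      t1 = A * (2 * Svv + Suw) - (a1 * a3 + 2 * a2^2),
      t2 = 3 * (A * Svw - a2 * a3),
      t3 = A * Sww - a3^2)
  })
}

# least-squares value of the bin target at (K, k_mask)
bin_ls <- function(mom, K, k) {
  r <- K * mom$i_obs - (mom$u + 2 * k * mom$v + k^2 * mom$w)
  sum(r * r)
}

# K from the first normal equation at fixed k_mask
k_from_normal <- function(mom, k) {
  A <- sum(mom$i_obs^2)
  sum(mom$i_obs * (mom$u + 2 * k * mom$v + k^2 * mom$w)) / A
}

# real roots of a cubic via eigenvalues of the companion matrix; degrades
# to quadratic/linear when leading coefficients vanish
real_poly_roots <- function(coefs) {   # coefs = c(t0, t1, t2, t3)
  scale <- max(abs(coefs))
  if (scale == 0) return(numeric(0))
  cf <- coefs / scale
  while (length(cf) > 1L && abs(cf[length(cf)]) < 1e-12) cf <- cf[-length(cf)]
  deg <- length(cf) - 1L
  if (deg < 1L) return(numeric(0))
  if (deg == 1L) return(-cf[1] / cf[2])
  comp <- matrix(0, deg, deg)
  comp[cbind(2:deg, 1:(deg - 1L))] <- 1
  comp[, deg] <- -cf[1:deg] / cf[deg + 1L]
  ev <- eigen(comp, only.values = TRUE)$values
  Re(ev[abs(Im(ev)) < 1e-8 * (1 + abs(Re(ev)))])
}

#' Analytic per-bin overall and bulk-solvent scales
#'
#' Determines `(K, k_mask)` for one resolution bin by minimizing
#' `sum((K I - (u + 2 k v + k^2 w))^2)` with `K = k_total^-2`.
#' Eliminating K through its normal equation reduces the stationarity
#' condition in `k_mask` to a cubic whose leading coefficient is
#' non-negative by the Cauchy-Schwarz inequality, so the global
#' constrained optimum is found among the real roots with
#' `k_mask >= 0` plus the `k_mask = 0` boundary -- no iterative search.
#' If several admissible roots exist, the one with the smallest
#' least-squares value is selected; if none, `k_mask = 0` (no solvent
#' contribution) with K from the pure-model normal equation.
#'
#' @param mom A [bin_moments()] object (one bin's reflections).
#' @return List: `K` (> 0), `k_mask` (>= 0), `ls` (least-squares value
#'   at the solution) and `diagnostics` (cubic coefficients, candidate
#'   roots, fallback flag).
#' @export
solve_bin_scales <- function(mom) {
  stopifnot(inherits(mom, "bin_moments"))
  if (length(mom$i_obs) < 1L || all(mom$i_obs == 0))
    stop("undefined scale: bin has no nonzero observed intensities")
  coefs <- cubic_coefficients(mom)
  roots <- real_poly_roots(coefs)
  roots[roots > -1e-12 & roots < 0] <- 0
  cand_k <- unique(c(0, roots[roots >= 0]))
  cand <- lapply(cand_k, function(k) {
    K <- k_from_normal(mom, k)
    list(k = k, K = K, ls = if (K > 0) bin_ls(mom, K, k) else Inf)
  })
  ls_vals <- vapply(cand, `[[`, numeric(1), "ls")
  fallback <- FALSE
  if (all(!is.finite(ls_vals))) {
    # every candidate gave K <= 0; no admissible stationary point
    fallback <- TRUE
    K0 <- k_from_normal(mom, 0)
    if (K0 <= 0)
      stop("undefined scale: non-positive K at every candidate root")
    best <- list(k = 0, K = K0, ls = bin_ls(mom, K0, 0))
  } else {
    best <- cand[[which.min(ls_vals)]]
  }
  # strong model/mask anticorrelation makes (K, k_mask) nearly degenerate
  # at low resolution (Babinet regime): flag it for the caller
  su <- sum(mom$u); sw <- sum(mom$w)
  anticorr <- if (su > 0 && sw > 0) sum(mom$v) / sqrt(su * sw) else 0
  list(K = best$K, k_mask = best$k, ls = best$ls,
       diagnostics = list(coefficients = coefs, roots = roots,
                          candidates = cand_k, fallback = fallback,
                          anticorrelation = anticorr,
                          degenerate = anticorr < -0.95))
}

#' Savitzky-Golay smoothing of a bin-wise scale curve
#'
#' Second-order Savitzky-Golay filtering with a 5-point window, shrunk
#' symmetrically near the edges (3-point linear there, endpoints kept).
#' A curve that is already monotone is returned unchanged -- smoothing
#' must damp oscillations between bins without altering monotone
#' behaviour.  Negative outputs are clamped to zero since the solvent
#' scale is non-negative.
#'
#' @param x Numeric vector of per-bin values (e.g. k_mask).
#' @return Numeric vector of the same length.
#' @export
smooth_kmask <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 3L) return(pmax(x, 0))
  dx <- diff(x)
  if (all(dx <= 0) || all(dx >= 0)) return(pmax(x, 0))
  out <- x
  w5 <- c(-3, 12, 17, 12, -3) / 35   # classical 5-point quadratic weights
  for (i in seq_len(n)) {
    hw <- min(2L, i - 1L, n - i)
    if (hw == 2L) {
      out[i] <- sum(w5 * x[(i - 2L):(i + 2L)])
    } else if (hw == 1L) {
      out[i] <- mean(x[(i - 1L):(i + 1L)])
    }
  }
  pmax(out, 0)
}

#' Interpolate per-bin scales to individual reflections
#'
#' Piecewise-linear interpolation in s^2 between bin centers, constant
#' beyond the outer centers; a single bin yields a constant.
#'
#' @param values Per-bin values.
#' @param centers_s2 Per-bin centers in s^2 (same length, increasing or
#'   decreasing).
#' @param s2 Per-reflection s^2 values.
#' @return Numeric vector, one value per reflection.
#' @export
interpolate_scales <- function(values, centers_s2, s2) {
  stopifnot(length(values) == length(centers_s2), length(values) >= 1L)
  if (length(values) == 1L) return(rep(values, length(s2)))
  o <- order(centers_s2)
  stats::approx(centers_s2[o], values[o], xout = s2, rule = 2)$y
}

#' Optimal per-bin isotropic scale
#'
#' The exact least-squares minimizer of `sum((F_obs - k |F'|)^2)` for a
#' bin: `k = sum(F_obs |F'|) / sum(|F'|^2)`, where `|F'|` is the model
#' amplitude excluding the isotropic scale.
#'
#' @param f_obs Observed amplitudes in the bin.
#' @param f_prime Model amplitudes excluding k_isotropic.
#' @return Scalar scale.
#' @export
update_kisotropic <- function(f_obs, f_prime) {
  denom <- sum(f_prime^2)
  if (denom == 0) stop("undefined isotropic scale: all model amplitudes zero")
  sum(f_obs * f_prime) / denom
}

# exponential curve fit core: minimize sum((ks * exp(-B s2 / 4) - y)^2).
# Log-linearized weighted start (weights y^2) + damped Gauss-Newton.
fit_exp_curve <- function(y, s2) {
  sel <- y > 0
  if (sum(sel) < 2L) return(NULL)
  ys <- y[sel]; xs <- s2[sel]
  wt <- ys^2
  ly <- log(ys)
  xb <- sum(wt * xs) / sum(wt)
  lb <- sum(wt * ly) / sum(wt)
  sxx <- sum(wt * (xs - xb)^2)
  slope <- if (sxx > 0) sum(wt * (xs - xb) * (ly - lb)) / sxx else 0
  B <- -4 * slope
  ks <- exp(lb - slope * xb)
  ssq <- function(p) sum((p[1] * exp(-p[2] * xs / 4) - ys)^2)
  p <- c(ks, B)
  f <- ssq(p)
  for (iter in 1:50) {
    e <- exp(-p[2] * xs / 4)
    r <- p[1] * e - ys
    J <- cbind(e, -p[1] * xs / 4 * e)
    step <- tryCatch(solve(crossprod(J), -crossprod(J, r)),
                     error = function(err) NULL)
    if (is.null(step)) break
    step <- drop(step)
    lambda <- 1
    repeat {
      pn <- p + lambda * step
      if (pn[1] < 0) pn[1] <- 0
      fn <- ssq(pn)
      if (fn <= f || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (fn >= f - 1e-14 * (1 + f)) { if (fn < f) { p <- pn; f <- fn }; break }
    p <- pn; f <- fn
  }
  list(k = max(unname(p[1]), 0), B = unname(p[2]), residual = unname(f),
       n_used = sum(sel))
}

#' Fit the flat-solvent exponential to a bin-wise k_mask curve
#'
#' Fits `k_sol exp(-B_sol s^2 / 4)` to the per-bin `k_mask` values over
#' bins with `k_mask > 0`.  Useful for comparing the bin-wise curve with
#' the classical two-parameter flat bulk-solvent model.
#'
#' @param k_mask Per-bin solvent scales.
#' @param s2 Per-bin centers in s^2.
#' @return List with `k_sol`, `B_sol`, `residual`, `n_used`, or `NULL`
#'   when fewer than two bins have positive k_mask (no solvent model).
#' @export
fit_ksol_bsol <- function(k_mask, s2) {
  fit <- fit_exp_curve(as.numeric(k_mask), as.numeric(s2))
  if (is.null(fit)) return(NULL)
  list(k_sol = fit$k, B_sol = fit$B, residual = fit$residual,
       n_used = fit$n_used)
}

#' Fit an overall exponential to the bin-wise K curve
#'
#' Same as [fit_ksol_bsol()] with `k_overall exp(-B_overall s^2 / 4)`
#' fitted to the per-bin K values.
#'
#' @param K Per-bin K values (K = k_total^-2).
#' @param s2 Per-bin centers in s^2.
#' @return List with `k_overall`, `B_overall`, `residual`, `n_used`, or
#'   `NULL` when fewer than two bins qualify.
#' @export
fit_koverall_boverall <- function(K, s2) {
  fit <- fit_exp_curve(as.numeric(K), as.numeric(s2))
  if (is.null(fit)) return(NULL)
  list(k_overall = fit$k, B_overall = fit$B, residual = fit$residual,
       n_used = fit$n_used)
}

#' R-factor grid refinement of a bin's (k_mask, k_isotropic) pair
#'
#' The least-squares and R-factor surfaces can have minima at
#' significantly different locations.  This scans `k_mask` on a grid
#' around the least-squares optimum (`[0, 2 k_LS]`, or `[0, 1]` when
#' `k_LS = 0`), recomputing the optimal isotropic scale at each trial
#' value, and returns the pair with the lowest bin R factor.  The
#' least-squares pair itself is always a candidate, so the result is
#' never worse in R.
#'
#' @param f_obs Observed amplitudes in the bin.
#' @param f_calc,f_mask Complex model contributions in the bin.
#' @param k_mask_ls,k_iso_ls The least-squares pair to refine around.
#' @param n_grid Number of grid points (default 41).
#' @return List with `k_mask`, `k_iso`, `r`.
#' @export
rfactor_grid_refine <- function(f_obs, f_calc, f_mask, k_mask_ls, k_iso_ls,
                                n_grid = 41) {
  denom <- sum(f_obs)
  if (denom <= 0) stop("zero denominator in bin R factor")
  best <- list(k_mask = k_mask_ls, k_iso = k_iso_ls,
               r = sum(abs(f_obs - k_iso_ls * Mod(f_calc + k_mask_ls * f_mask))) / denom)
  if (n_grid <= 1L) return(best)   # degenerate grid: keep the LS pair
  hi <- if (k_mask_ls > 0) 2 * k_mask_ls else 1
  grid <- unique(c(seq(0, hi, length.out = n_grid), k_mask_ls))
  for (k in grid) {
    amp <- Mod(f_calc + k * f_mask)
    sa <- sum(amp^2)
    if (sa == 0) next
    ki <- sum(f_obs * amp) / sa
    r <- sum(abs(f_obs - ki * amp)) / denom
    if (r < best$r) best <- list(k_mask = k, k_iso = ki, r = r)
  }
  best
}
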
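#' Crystallographic R factor
#'
#' `R = sum(|F_obs - |F_model||) / sum(F_obs)`.
#'
#' @param f_obs Observed amplitudes.
#' @param f_model Model amplitudes.
#' @return Scalar R factor.
#' @examples
#' r_factor(c(10, 20, 30), c(9, 22, 30))
#' @export
r_factor <- function(f_obs, f_model) {
  denom <- sum(f_obs)
  if (denom <= 0) stop("zero denominator in R factor")
  sum(abs(f_obs - f_model)) / denom
}

#' Optimal overall scalar scale
#'
#' Exact least-squares minimizer of `sum((F_obs - k |F'|)^2)`:
#' `k = sum(F_obs |F'|) / sum(|F'|^2)`.
#'
#' @param f_obs Observed amplitudes.
#' @param f_prime Model amplitudes excluding the overall scale.
#' @return Scalar.
#' @export
k_overall_scale <- function(f_obs, f_prime) {
  denom <- sum(f_prime^2)
  if (denom == 0) stop("zero denominator in overall scale")
  sum(f_obs * f_prime) / denom
}

aniso_method_list <- function(method) {
  switch(method,
         "none" = character(0),
         "poly" = "poly",
         "exp_anal" = "exp_anal",
         "exp_min" = "exp_min",
         "poly+exp_anal" = c("poly", "exp_anal"),
         "all" = c("poly", "exp_anal", "exp_min"),
         stop(sprintf("unknown aniso_method '%s'", method)))
}

# floor for dividing by the anisotropic factor (the polynomial form can
# dip below zero outside its fitted range)
clamp_pos <- function(x, floor = 1e-6) pmax(x, floor)

#' Run the full scaling protocol
#'
#' Alternates bin-wise determination of (k_mask, k_isotropic) -- the
#' analytic cubic solve, optional R-factor grid refinement, smoothing
#' and linear interpolation -- with determination of the overall
#' anisotropic scale factor, until the R factor decreases by less than
#' `tol` between cycles (default 0.01%) or `max_cycles` is reached.
#' When several anisotropic methods are requested, each is evaluated
#' independently over the full protocol and the result with the lowest
#' R factor is accepted.  If twin operators are present, twin fractions
#' are re-estimated at the start of every cycle and all scaling sums use
#' fraction-weighted intensities.
#'
#' @param inputs A [scaling_inputs()].
#' @param aniso_method One of `"poly"`, `"exp_anal"`, `"exp_min"`,
#'   `"poly+exp_anal"` (default), `"all"`, `"none"`.
#' @param tol Convergence threshold on the R-factor decrease (absolute;
#'   default 1e-4, i.e. 0.01%).
#' @param max_cycles Cycle cap (default 10; convergence typically takes
#'   1-5 cycles).
#' @param min_count,max_bins Binning parameters (see [log_d_bins()]).
#' @param grid_refine Refine each bin's (k_mask, k_isotropic) by an
#'   R-factor grid search around the least-squares optimum (default
#'   TRUE).
#' @param twin_operators Optional twin operators; defaults to those
#'   stored in `inputs`.
#' @param solvent_first Determine (k_mask, k_isotropic) before
#'   k_anisotropic within each cycle (default TRUE, the empirically
#'   preferred order); FALSE swaps the two stages for experimentation.
#'
#' @return Object of class `scaling_result`: per-reflection `k_total`,
#'   `k_isotropic`, `k_anisotropic`, `k_mask`, scalar `k_overall`,
#'   model amplitudes `f_model`, `r_all`/`r_low`/`r_high`, the accepted
#'   anisotropic method and tensors, per-bin table, solvent-model fits,
#'   twin fractions (if any), `cycles` and the per-cycle R `trace`.
#' @export
run_scaling <- function(inputs, aniso_method = "poly+exp_anal", tol = 1e-4,
                        max_cycles = 10, min_count = 300, max_bins = 30,
                        grid_refine = TRUE, twin_operators = NULL,
                        solvent_first = TRUE) {
  stopifnot(inherits(inputs, "scaling_inputs"))
  methods <- aniso_method_list(aniso_method)
  if (tol <= 0) stop("tol must be positive")
  if (max_cycles < 1) stop("max_cycles must be >= 1")
  if (length(methods) > 1L) {
    # evaluate each anisotropic method independently over the full
    # protocol and accept the result with the lowest R factor
    runs <- lapply(methods, function(m) {
      run_scaling(inputs, aniso_method = m, tol = tol,
                  max_cycles = max_cycles, min_count = min_count,
                  max_bins = max_bins, grid_refine = grid_refine,
                  twin_operators = twin_operators,
                  solvent_first = solvent_first)
    })
    r_each <- vapply(runs, `[[`, numeric(1), "r_all")
    best <- runs[[which.min(r_each)]]
    best$aniso$candidates <- stats::setNames(r_each, methods)
    return(best)
  }
  refl <- inputs$refl
  fo <- inputs$f_obs
  fc <- inputs$f_calc
  fm <- inputs$f_mask
  n <- length(fo)
  if (n < 10) stop("need at least 10 reflections")
  obs <- fo > 0
  n_excluded <- sum(!obs)
  if (sum(obs) < 10) stop("need at least 10 reflections with F_obs > 0")

  ops <- normalize_twin_operators(
    if (is.null(twin_operators)) inputs$twin_operators else twin_operators)
  twinned <- !is.null(ops)
  if (twinned) {
    mates <- twin_mate_table(refl, ops)          # n x N row indices
    complete <- rowSums(is.na(mates)) == 0
    N_dom <- length(ops)
  }

  part <- log_d_bins(refl$d[obs], min_count = min_count, max_bins = max_bins)
  bin_of <- assign_bins(refl$d, part$boundaries)
  nb <- part$n_bins
  centers <- vapply(seq_len(nb), function(b) {
    mean(refl$s2[obs & bin_of == b])
  }, numeric(1))
  bin_rows <- lapply(seq_len(nb), function(b) which(obs & bin_of == b))

  # state
  st <- list(kaniso = rep(1, n), kiso = rep(1, n), kmask = rep(0, n),
             alpha = if (twinned) c(1, rep(0, N_dom - 1L)) else 1,
             aniso = list(method = "none"),
             kmask_bins_raw = rep(0, nb), kmask_bins = rep(0, nb),
             kiso_bins = rep(1, nb), K_bins = rep(1, nb),
             degenerate_bins = rep(FALSE, nb),
             untwinned_fallback = FALSE)

  # model amplitude excluding all scales except k_mask (and twin weights)
  base_amp <- function(kmask_refl, alpha) {
    if (!twinned) return(Mod(fc + kmask_refl * fm))
    wts <- matrix(0, n, N_dom)
    for (j in seq_len(N_dom)) wts[!is.na(mates[, j]), j] <- alpha[j]
    rs <- rowSums(wts)
    rs[rs == 0] <- 1
    wts <- wts / rs
    acc <- numeric(n)
    for (j in seq_len(N_dom)) {
      idx <- mates[, j]
      okj <- !is.na(idx)
      amp2 <- Mod(fc[idx[okj]] + kmask_refl[okj] * fm[idx[okj]])^2
      acc[okj] <- acc[okj] + wts[okj, j] * amp2
    }
    sqrt(acc)
  }

  estimate_alpha <- function(st) {
    ktot <- st$kiso * st$kaniso
    imod <- matrix(NA_real_, n, N_dom)
    for (j in seq_len(N_dom)) {
      idx <- mates[, j]
      okj <- !is.na(idx)
      imod[okj, j] <- (ktot[okj] * Mod(fc[idx[okj]] + st$kmask[okj] * fm[idx[okj]]))^2
    }
    rows <- which(obs & complete)
    if (length(rows) < N_dom + 1L)
      return(list(fractions = c(1, rep(0, N_dom - 1L)), fallback = TRUE))
    active <- seq_len(N_dom)
    for (pass in seq_len(N_dom)) {
      est <- estimate_twin_fractions(fo[rows]^2, imod[rows, active, drop = FALSE])
      a <- est$fractions
      # only the non-identity twin operations can be ignored; the identity
      # domain always participates
      bad <- (a < -1e-9 | a > 1 + 1e-9) & active != 1L
      if (!any(bad)) {
        full <- numeric(N_dom)
        full[active] <- pmin(pmax(a, 0), 1)
        return(list(fractions = full, lambda = est$lambda, fallback = FALSE))
      }
      active <- active[!bad]
      if (length(active) == 0L)
        return(list(fractions = c(1, rep(0, N_dom - 1L)), fallback = TRUE))
      if (length(active) == 1L) {
        full <- numeric(N_dom)
        full[active] <- 1
        return(list(fractions = full, lambda = 0, fallback = FALSE))
      }
    }
    list(fractions = c(1, rep(0, N_dom - 1L)), fallback = TRUE)
  }

  solvent_stage <- function(st) {
    f_work <- fo / clamp_pos(st$kaniso)
    K_b <- numeric(nb); km_raw <- numeric(nb); deg_b <- logical(nb)
    for (b in seq_len(nb)) {
      rows <- bin_rows[[b]]
      if (!twinned) {
        mom <- bin_moments(fc[rows], fm[rows], f_work[rows])
        sol <- solve_bin_scales(mom)
      } else {
        um <- vm <- wm <- matrix(0, length(rows), N_dom)
        wts <- matrix(0, length(rows), N_dom)
        for (j in seq_len(N_dom)) {
          idx <- mates[rows, j]
          okj <- !is.na(idx)
          wts[okj, j] <- st$alpha[j]
          um[okj, j] <- Mod(fc[idx[okj]])^2
          vm[okj, j] <- Re(fc[idx[okj]] * Conj(fm[idx[okj]]))
          wm[okj, j] <- Mod(fm[idx[okj]])^2
        }
        rs <- rowSums(wts); rs[rs == 0] <- 1
        wts <- wts / rs
        mom <- structure(list(u = rowSums(um * wts), v = rowSums(vm * wts),
                              w = rowSums(wm * wts),
                              i_obs = f_work[rows]^2),
                         class = "bin_moments")
        sol <- solve_bin_scales(mom)
      }
      K_b[b] <- sol$K
      km_raw[b] <- sol$k_mask
      deg_b[b] <- isTRUE(sol$diagnostics$degenerate)
      if (grid_refine && !twinned) {
        ref <- rfactor_grid_refine(f_work[rows], fc[rows], fm[rows],
                                   sol$k_mask, 1 / sqrt(sol$K))
        km_raw[b] <- ref$k_mask
      }
    }
    km_b <- smooth_kmask(km_raw)
    st$kmask <- interpolate_scales(km_b, centers, refl$s2)
    st$kmask <- pmax(st$kmask, 0)
    amp <- base_amp(st$kmask, st$alpha)
    ki_b <- vapply(seq_len(nb), function(b) {
      rows <- bin_rows[[b]]
      update_kisotropic(f_work[rows], amp[rows])
    }, numeric(1))
    st$kiso <- interpolate_scales(ki_b, centers, refl$s2)
    st$K_bins <- K_b
    st$kmask_bins_raw <- km_raw
    st$kmask_bins <- km_b
    st$kiso_bins <- ki_b
    st$degenerate_bins <- deg_b
    st
  }

  aniso_stage <- function(st) {
    if (length(methods) == 0L) return(st)
    amp <- base_amp(st$kmask, st$alpha)
    m <- st$kiso * amp
    rows <- which(obs & m > 0)
    C <- derive_constraint_matrix(refl$rotations)
    k0 <- k_overall_scale(fo[rows], m[rows])
    ms <- k0 * m
    best <- NULL
    for (meth in methods) {
      cand <- tryCatch({
        if (meth == "poly") {
          fit <- fit_polynomial_aniso(fo[rows], ms[rows],
                                      refl$indices[rows, , drop = FALSE],
                                      refl$s2[rows])
          ka <- k_aniso_polynomial(fit$v0, fit$v1, refl$indices, refl$s2)
          list(method = meth, fit = fit, ka = ka)
        } else if (meth == "exp_anal") {
          fit <- fit_exponential_aniso(fo[rows], ms[rows],
                                       refl$indices[rows, , drop = FALSE], C)
          list(method = meth, fit = fit,
               ka = k_aniso_exponential(fit$u, refl$indices))
        } else {
          fit <- fit_exponential_aniso_minimized(
            fo[rows], ms[rows], refl$indices[rows, , drop = FALSE], C)
          list(method = meth, fit = fit,
               ka = k_aniso_exponential(fit$u, refl$indices))
        }
      }, error = function(e) NULL)
      if (is.null(cand)) next
      mm <- ms * clamp_pos(cand$ka)
      k1 <- k_overall_scale(fo[rows], mm[rows])
      cand$r <- r_factor(fo[rows], k1 * mm[rows])
      cand$k1 <- k1
      if (is.null(best) || cand$r < best$r) best <- cand
    }
    if (is.null(best)) return(st)
    st$kaniso <- clamp_pos(best$ka)
    st$kiso <- st$kiso * k0 * best$k1
    st$aniso <- best[c("method", "fit")]
    st
  }

  current_r <- function(st) {
    amp <- base_amp(st$kmask, st$alpha)
    fmdl <- st$kiso * st$kaniso * amp
    r_factor(fo[obs], fmdl[obs])
  }

  trace <- numeric(0)
  r_prev <- Inf
  prev_state <- st
  cycles <- 0L
  for (cyc in seq_len(max_cycles)) {
    cand <- st
    if (twinned) {
      est <- estimate_alpha(cand)
      cand$alpha <- est$fractions
      cand$untwinned_fallback <- est$fallback
      if (est$fallback)
        warning("no admissible twin fractions; falling back to untwinned scaling")
    }
    if (solvent_first) {
      cand <- solvent_stage(cand)
      cand <- aniso_stage(cand)
    } else {
      cand <- aniso_stage(cand)
      cand <- solvent_stage(cand)
    }
    r_new <- current_r(cand)
    if (r_new > r_prev) break        # keep the previous cycle's state
    st <- cand
    cycles <- cyc
    trace <- c(trace, r_new)
    if (r_prev - r_new < tol) { r_prev <- r_new; break }
    r_prev <- r_new
  }

  # reporting: fold the scalar overall scale out of the internal
  # isotropic component so the k_total decomposition is unique
  amp <- base_amp(st$kmask, st$alpha)
  ktot <- st$kiso * st$kaniso
  fmdl <- ktot * amp
  a0 <- (st$kaniso * amp)[obs]
  k_over <- k_overall_scale(fo[obs], a0)
  kiso_rep <- st$kiso / k_over
  r_all <- r_factor(fo[obs], fmdl[obs])

  bins_tbl <- data.frame(
    bin = seq_len(nb),
    d_max = part$boundaries[seq_len(nb)],
    d_min = part$boundaries[seq_len(nb) + 1L],
    count = part$counts,
    center_s2 = centers,
    K = st$K_bins,
    k_mask_raw = st$kmask_bins_raw,
    k_mask = st$kmask_bins,
    k_iso = st$kiso_bins,
    r_bin = vapply(seq_len(nb), function(b) {
      rows <- bin_rows[[b]]
      r_factor(fo[rows], fmdl[rows])
    }, numeric(1)))

  aniso_report <- st$aniso
  if (!is.null(aniso_report$fit$u))
    aniso_report$b_cartesian <- u_star_to_b_cartesian(aniso_report$fit$u, refl$cell)

  res <- structure(list(
    k_total = ktot,
    k_overall = k_over,
    k_isotropic = kiso_rep,
    k_anisotropic = st$kaniso,
    k_mask = st$kmask,
    f_model = fmdl,
    f_obs = fo,
    d = refl$d,
    bin_of = bin_of,
    included = obs,
    n_excluded = n_excluded,
    r_all = r_all,
    r_low = NA_real_,
    r_high = NA_real_,
    aniso = aniso_report,
    bins = list(partition = part, table = bins_tbl,
                k_mask_raw = st$kmask_bins_raw,
                k_mask_smoothed = st$kmask_bins,
                k_iso = st$kiso_bins, K = st$K_bins,
                centers_s2 = centers,
                degenerate = st$degenerate_bins),
    solvent_fit = fit_ksol_bsol(st$kmask_bins, centers),
    overall_fit = fit_koverall_boverall(st$K_bins, centers),
    twin = if (twinned) list(operators = ops, fractions = st$alpha,
                             lambda = NA_real_,
                             untwinned_fallback = st$untwinned_fallback)
           else NULL,
    cycles = cycles,
    trace = trace), class = "scaling_result")
  rr <- resolution_partition_report(res)
  res$r_low <- rr["r_low"]
  res$r_high <- rr["r_high"]
  res
}

#' @export
print.scaling_result <- function(x, ...) {
  cat(sprintf("scaling_result: R_all = %.4f (low %.4f, high %.4f), %d cycle(s), aniso = %s\n",
              x$r_all, x$r_low, x$r_high, x$cycles, x$aniso$method))
  cat(sprintf("  k_overall = %.6g, %d bins, %d reflections excluded (F_obs <= 0)\n",
              x$k_overall, length(x$bins$K), x$n_excluded))
  if (!is.null(x$solvent_fit))
    cat(sprintf("  flat-solvent fit: k_sol = %.4f, B_sol = %.2f A^2\n",
                x$solvent_fit$k_sol, x$solvent_fit$B_sol))
  if (!is.null(x$twin))
    cat(sprintf("  twin fractions: %s\n",
                paste(sprintf("%.4f", x$twin$fractions), collapse = ", ")))
  invisible(x)
}

#' R factors for all, low- and high-resolution reflection subsets
#'
#' The low-resolution subset is `d > low_d_cut` but always at least
#' `min_low_count` lowest-resolution reflections (defaults 8 Angstrom /
#' 500); the high-resolution subset is the highest-resolution bin.
#'
#' @param result A `scaling_result` from [run_scaling()].
#' @param low_d_cut Resolution cut in Angstrom for the low set.
#' @param min_low_count Minimum size of the low set.
#' @return Named numeric vector `c(r_all, r_low, r_high)`.
#' @export
resolution_partition_report <- function(result, low_d_cut = 8,
                                        min_low_count = 500) {
  stopifnot(inherits(result, "scaling_result"))
  inc <- which(result$included)
  d <- result$d[inc]
  fo <- result$f_obs[inc]
  fmdl <- result$f_model[inc]
  low <- d > low_d_cut
  if (sum(low) < min_low_count) {
    take <- min(min_low_count, length(d))
    low <- rank(-d, ties.method = "first") <= take
  }
  hi_bin <- max(result$bin_of[inc])
  high <- result$bin_of[inc] == hi_bin
  c(r_all = r_factor(fo, fmdl),
    r_low = r_factor(fo[low], fmdl[low]),
    r_high = r_factor(fo[high], fmdl[high]))
}
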
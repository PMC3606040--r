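#' Simulation specification for synthetic reflection data
#'
#' Describes a synthetic data set with known ground truth for every
#' scaling stage: the solvent scale curve, the anisotropic tensor, the
#' overall scale, optional twinning, and the noise model.  The forward
#' model is `F_obs = k_overall * k_aniso(s) * |F_calc + k_mask(s^2) F_mask| *
#' (1 + noise)` (or the fraction-weighted intensity sum under twinning).
#'
#' @param cell A [unit_cell()] (default tetragonal 60 x 60 x 90).
#' @param symmetry Symbol or rotation list (see [reflection_set()]).
#' @param d_range Resolution range in Angstrom, c(d_min, d_max).
#' @param n Number of reflections to draw.
#' @param k_sol,b_sol Flat-solvent truth: `k_mask(s2) = k_sol *
#'   exp(-b_sol * s2 / 4)`.
#' @param k_mask_curve Optional function of s^2 overriding the
#'   exponential solvent truth.
#' @param u_aniso Symmetric 6-vector of the exponential anisotropic
#'   truth in the Miller-index basis (zero = isotropic).
#' @param k_overall Overall scalar scale.
#' @param b_model,b_mask Falloff of the |F_calc| and |F_mask| envelopes
#'   (Angstrom^2); the much larger mask falloff concentrates the solvent
#'   contribution at low resolution, as in real data.
#' @param noise Relative Gaussian amplitude noise (standard deviation).
#' @param outlier_fraction Fraction of reflections whose amplitude is
#'   multiplied by a heavy-tailed (log-normal, sdlog = 1) factor.
#' @param twin_operators Optional twin operators (strings or matrices).
#' @param twin_fractions Twin fractions summing to 1 (first = identity
#'   domain).
#' @param seed Integer RNG seed; the simulation is fully reproducible.
#' @return Object of class `simulation_spec`.
#' @export
simulation_spec <- function(cell = unit_cell(60, 60, 90, 90, 90, 90),
                            symmetry = "tetragonal",
                            d_range = c(2, 25), n = 10000,
                            k_sol = 0.35, b_sol = 46,
                            k_mask_curve = NULL,
                            u_aniso = rep(0, 6),
                            k_overall = 1,
                            b_model = 20, b_mask = 150,
                            noise = 0, outlier_fraction = 0,
                            twin_operators = NULL, twin_fractions = NULL,
                            seed = 1) {
  d_range <- sort(as.numeric(d_range))
  if (length(d_range) != 2L || any(d_range <= 0))
    stop("d_range must be two positive resolutions")
  if (noise < 0 || outlier_fraction < 0 || outlier_fraction > 1)
    stop("noise must be >= 0 and outlier_fraction in [0, 1]")
  ops <- normalize_twin_operators(twin_operators)
  if (!is.null(ops)) {
    if (is.null(twin_fractions) || length(twin_fractions) != length(ops))
      stop("twin_fractions must match the number of operators (identity first)")
    if (abs(sum(twin_fractions) - 1) > 1e-12)
      stop("twin fractions must sum to 1")
  }
  structure(
    list(cell = cell, symmetry = symmetry, d_range = d_range, n = n,
         k_sol = k_sol, b_sol = b_sol, k_mask_curve = k_mask_curve,
         u_aniso = u_aniso, k_overall = k_overall,
         b_model = b_model, b_mask = b_mask,
         noise = noise, outlier_fraction = outlier_fraction,
         twin_operators = ops, twin_fractions = twin_fractions,
         seed = as.integer(seed)),
    class = "simulation_spec")
}

# all Friedel-unique lattice points in the resolution range
lattice_indices <- function(cell, d_range) {
  gstar <- reciprocal_metric_tensor(cell)
  dmin <- d_range[1]
  lims <- ceiling(c(cell$a, cell$b, cell$c) / dmin) + 1L
  h <- as.matrix(expand.grid(h = -lims[1]:lims[1], k = -lims[2]:lims[2],
                             l = 0:lims[3]))
  # Friedel-unique half space: l > 0, or l == 0 and k > 0, or k == l == 0, h > 0
  keep_half <- h[, 3] > 0 |
    (h[, 3] == 0 & h[, 2] > 0) |
    (h[, 3] == 0 & h[, 2] == 0 & h[, 1] > 0)
  h <- h[keep_half, , drop = FALSE]
  s2 <- s_squared(h, gstar)
  d <- 1 / sqrt(s2)
  h[d >= d_range[1] & d <= d_range[2], , drop = FALSE]
}

#' Generate synthetic scaling inputs with known ground truth
#'
#' Draws complex structure factors with resolution-dependent envelopes,
#' composes the forward model described by the [simulation_spec()] and
#' returns the aligned [scaling_inputs()] plus a ground-truth record
#' sufficient to reconstruct `F_obs` bit-exactly.
#'
#' @param spec A [simulation_spec()].
#' @return List with `inputs` (a [scaling_inputs()]) and `truth`
#'   (per-reflection `k_mask`, `k_aniso`, `noise_factor`, and the
#'   generating scalar parameters).
#' @export
simulate_reflections <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  hall <- lattice_indices(spec$cell, spec$d_range)
  if (nrow(hall) < spec$n)
    stop(sprintf("unsatisfiable spec: only %d lattice points in the d range (need %d)",
                 nrow(hall), spec$n))
  pick <- sort(sample.int(nrow(hall), spec$n))
  h <- hall[pick, , drop = FALSE]

  twinned <- !is.null(spec$twin_operators)
  if (twinned) {
    # close the index set under the twin operators (mapped to the stored
    # Friedel-unique half space) so every twin mate is resolvable
    key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
    friedel_rep <- function(m) {
      flip <- m[, 3] < 0 | (m[, 3] == 0 & m[, 2] < 0) |
        (m[, 3] == 0 & m[, 2] == 0 & m[, 1] < 0)
      m[flip, ] <- -m[flip, , drop = FALSE]
      m
    }
    seen <- new.env(hash = TRUE, parent = emptyenv())
    for (k in key(h)) assign(k, TRUE, envir = seen)
    frontier <- h
    for (iter in 1:8) {
      imgs <- do.call(rbind, lapply(spec$twin_operators[-1], function(Tj) {
        friedel_rep(frontier %*% t(Tj))
      }))
      ks <- key(imgs)
      new_rows <- imgs[!vapply(ks, exists, logical(1), envir = seen), ,
                       drop = FALSE]
      if (nrow(new_rows) == 0L) break
      new_rows <- new_rows[!duplicated(key(new_rows)), , drop = FALSE]
      for (k in key(new_rows)) assign(k, TRUE, envir = seen)
      h <- rbind(h, new_rows)
      frontier <- new_rows
    }
  }
  h <- unname(as.matrix(h))

  refl <- reflection_set(h, spec$cell, spec$symmetry)
  n <- nrow(h)
  s2 <- refl$s2

  env_calc <- 30 * exp(-spec$b_model * s2 / 4)
  env_mask <- 30 * exp(-spec$b_mask * s2 / 4)
  f_calc <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * env_calc
  f_mask <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * env_mask

  kmask <- if (is.null(spec$k_mask_curve)) {
    spec$k_sol * exp(-spec$b_sol * s2 / 4)
  } else {
    spec$k_mask_curve(s2)
  }
  kaniso <- k_aniso_exponential(spec$u_aniso, h)
  ktot <- spec$k_overall * kaniso

  noise_factor <- 1 + stats::rnorm(n, sd = spec$noise)
  if (spec$outlier_fraction > 0) {
    n_out <- round(spec$outlier_fraction * n)
    if (n_out > 0) {
      out_idx <- sample.int(n, n_out)
      noise_factor[out_idx] <- noise_factor[out_idx] *
        stats::rlnorm(n_out, sdlog = 1)
    }
  }

  if (!twinned) {
    f_obs <- pmax(ktot * Mod(f_calc + kmask * f_mask) * noise_factor, 0)
  } else {
    inputs0 <- scaling_inputs(refl, rep(1, n), f_calc, f_mask,
                              twin_operators = spec$twin_operators)
    mates <- twin_mate_table(refl, inputs0$twin_operators)
    if (any(is.na(mates)))
      stop("internal error: twin closure left unresolved mates")
    itot <- numeric(n)
    for (j in seq_along(spec$twin_fractions)) {
      idx <- mates[, j]
      itot <- itot + spec$twin_fractions[j] *
        (ktot * Mod(f_calc[idx] + kmask * f_mask[idx]))^2
    }
    f_obs <- pmax(sqrt(itot) * noise_factor, 0)
  }

  inputs <- scaling_inputs(refl, f_obs, f_calc, f_mask,
                           twin_operators = spec$twin_operators)
  truth <- list(k_mask = kmask, k_aniso = kaniso, k_overall = spec$k_overall,
                k_sol = spec$k_sol, b_sol = spec$b_sol,
                u_aniso = spec$u_aniso, noise_factor = noise_factor,
                twin_fractions = spec$twin_fractions, seed = spec$seed)
  list(inputs = inputs, truth = truth)
}

#' Low-resolution anticorrelation stress case
#'
#' Builds inputs in which the mask structure factors are exactly
#' anticorrelated with the model ones, `F_mask = -p F_calc`, the
#' low-resolution regime in which Babinet-principle scaling applies.
#' Under this relation the model amplitude depends on `k_total` and
#' `k_mask` only through `k_total (1 - p k_mask)`, so distinct scale
#' pairs satisfying that invariant are exactly degenerate; the case
#' exercises solver robustness under the degeneracy.
#'
#' @param spec A [simulation_spec()]; its `d_range` should be
#'   low-resolution only (default is used with d > 8).
#' @param p Anticorrelation scale factor in [0, 1).
#' @return A list with `inputs` ([scaling_inputs()]), `truth`, and `p`.
#' @export
babinet_stress_case <- function(spec = simulation_spec(d_range = c(8, 40),
                                                       n = 600),
                                p = 0.9) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  hall <- lattice_indices(spec$cell, spec$d_range)
  if (nrow(hall) < spec$n)
    stop("unsatisfiable spec: too few low-resolution lattice points")
  h <- hall[sort(sample.int(nrow(hall), spec$n)), , drop = FALSE]
  refl <- reflection_set(unname(as.matrix(h)), spec$cell, spec$symmetry)
  n <- nrow(refl$indices)
  env_calc <- 30 * exp(-spec$b_model * refl$s2 / 4)
  f_calc <- complex(real = stats::rnorm(n), imaginary = stats::rnorm(n)) * env_calc
  f_mask <- -p * f_calc
  kmask <- spec$k_sol * exp(-spec$b_sol * refl$s2 / 4)
  noise_factor <- 1 + stats::rnorm(n, sd = spec$noise)
  f_obs <- pmax(spec$k_overall * Mod(f_calc + kmask * f_mask) * noise_factor, 0)
  list(inputs = scaling_inputs(refl, f_obs, f_calc, f_mask),
       truth = list(k_mask = kmask, k_overall = spec$k_overall,
                    noise_factor = noise_factor),
       p = p)
}
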
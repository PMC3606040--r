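#' Parse a twin law given as an "h,k,l"-style triplet
#'
#' Converts e.g. `"-h,-k,l"` or `"k,h,-l"` into the 3x3 integer matrix
#' T acting on Miller-index column vectors: h' = T h.
#'
#' @param law Character scalar with three comma-separated components in
#'   h, k, l (integer coefficients, e.g. `"h+k, -k, -l"`).
#' @return 3x3 integer matrix.
#' @examples
#' parse_twin_law("k,h,-l")
#' @export
parse_twin_law <- function(law) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(law)), ",")[[1]]
  if (length(parts) != 3L)
    stop(sprintf("twin law '%s' must have three comma-separated components", law))
  M <- matrix(0L, 3, 3)
  for (i in 1:3) {
    expr <- parts[i]
    m <- gregexpr("([+-]?[0-9]*)\\*?([hkl])", expr)[[1]]
    if (m[1] == -1 || sum(attr(m, "match.length")) != nchar(expr))
      stop(sprintf("cannot parse twin-law component '%s'", parts[i]))
    starts <- m
    lens <- attr(m, "match.length")
    for (j in seq_along(starts)) {
      tok <- substr(expr, starts[j], starts[j] + lens[j] - 1L)
      axis <- substr(tok, nchar(tok), nchar(tok))
      coef <- sub("\\*?[hkl]$", "", tok)
      val <- if (coef %in% c("", "+")) 1L
             else if (coef == "-") -1L
             else as.integer(coef)
      M[i, match(axis, c("h", "k", "l"))] <-
        M[i, match(axis, c("h", "k", "l"))] + val
    }
  }
  M
}

# accept NULL, strings, or matrices; ensure identity first
normalize_twin_operators <- function(ops) {
  if (is.null(ops)) return(NULL)
  if (!is.list(ops)) ops <- list(ops)
  mats <- lapply(ops, function(o) {
    m <- if (is.character(o)) parse_twin_law(o) else round(as.matrix(o))
    if (!all(dim(m) == c(3, 3))) stop("twin operators must be 3x3 matrices")
    storage.mode(m) <- "double"
    m
  })
  is_id <- vapply(mats, function(m) all(m == diag(3)), logical(1))
  mats <- c(list(diag(3)), mats[!is_id])
  if (length(mats) == 1L) NULL else mats
}

#' Total twinned model intensity
#'
#' Weighted sum of per-domain model intensities,
#' `I_model(s) = sum_j alpha_j I_j(s)`.
#'
#' @param fractions Numeric vector of twin fractions (length N).
#' @param intensities Matrix (n x N) of per-domain model intensities.
#' @return Numeric vector of length n.
#' @export
twin_total_intensity <- function(fractions, intensities) {
  I <- as.matrix(intensities)
  stopifnot(ncol(I) == length(fractions))
  drop(I %*% fractions)
}

#' Estimate twin fractions by the constrained linear system
#'
#' Minimizes `sum((I_obs - sum_j alpha_j I_j)^2)` subject to
#' `sum(alpha_j) = 1` via a Lagrange multiplier, giving an
#' (N+1) x (N+1) linear system.  The multiplier term is pre-scaled by
#' the mean of `sum_j I_j^2` over reflections so that lambda is
#' numerically comparable to the fractions.
#'
#' @param i_obs Observed intensities (F_obs^2).
#' @param intensities Matrix (n x N) of per-domain model intensities
#'   (domain 1 = identity operator).
#' @return List with `fractions` (summing to 1), `lambda`, and
#'   `regularized` (TRUE when a singular system required ridging).
#' @export
estimate_twin_fractions <- function(i_obs, intensities) {
  I <- as.matrix(intensities)
  N <- ncol(I)
  if (N == 1L)
    return(list(fractions = 1, lambda = 0, regularized = FALSE))
  G <- crossprod(I)
  g <- drop(crossprod(I, i_obs))
  cc <- mean(rowSums(I^2))
  if (cc <= 0) cc <- 1
  M <- rbind(cbind(G, rep(cc / 2, N)), c(rep(1, N), 0))
  rhs <- c(g, 1)
  regularized <- FALSE
  sol <- tryCatch(solve(M, rhs), error = function(e) NULL)
  if (is.null(sol) || any(!is.finite(sol))) {
    regularized <- TRUE
    warning("singular twin-fraction system; solving with ridge regularization")
    ridge <- diag(c(rep(1e-8 * mean(diag(G)), N), 0))
    sol <- solve(M + ridge, rhs)
  }
  list(fractions = sol[1:N], lambda = sol[N + 1L], regularized = regularized)
}

# map each reflection through each twin operator to a row index of the
# stored set, using the point group (and Friedel symmetry) to land on the
# stored representative; NA when the mate is absent
twin_mate_table <- function(refl, operators) {
  h <- refl$indices
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  # register every point-group + Friedel image of each stored reflection
  lookup <- new.env(hash = TRUE, parent = emptyenv())
  rots <- c(refl$rotations, lapply(refl$rotations, function(R) -R))
  for (R in rots) {
    ks <- key(round(h %*% t(R)))
    for (i in seq_along(ks))
      if (!exists(ks[i], envir = lookup)) assign(ks[i], i, envir = lookup)
  }
  vapply(operators, function(Tj) {
    ks <- key(round(h %*% t(Tj)))
    vapply(seq_along(ks), function(i) {
      if (exists(ks[i], envir = lookup)) get(ks[i], envir = lookup) else NA_integer_
    }, integer(1))
  }, integer(nrow(h)))
}

#' Per-bin scales under twinning
#'
#' Given fixed twin fractions, minimizes
#' `sum((K I_obs - sum_j alpha_j (u_j + 2 k v_j + k^2 w_j))^2)` for one
#' bin.  The fraction-weighted moments have the same algebraic structure
#' as the untwinned case, so the same cubic solve applies; with a single
#' domain this reduces exactly to [solve_bin_scales()].
#'
#' @param u,v,w Matrices (n x N): per-domain moments of the bin's
#'   reflections (see [bin_moments()]), columns ordered as the domains.
#' @param i_obs Observed intensities of the bin.
#' @param fractions Twin fractions summing to 1.
#' @return As [solve_bin_scales()].
#' @export
solve_twin_bin_scales <- function(u, v, w, i_obs, fractions) {
  u <- as.matrix(u); v <- as.matrix(v); w <- as.matrix(w)
  stopifnot(ncol(u) == length(fractions))
  mom <- structure(
    list(u = drop(u %*% fractions), v = drop(v %*% fractions),
         w = drop(w %*% fractions), i_obs = as.numeric(i_obs)),
    class = "bin_moments")
  solve_bin_scales(mom)
}

#' Iterated twin-fraction and scale determination
#'
#' Alternates twin-fraction estimation with bin-wise scale
#' determination (isotropic + solvent; no anisotropic stage) until the
#' twinned R factor changes by less than `tol` or `max_iter` is
#' reached.  Fractions falling outside [0, 1] cause the corresponding
#' operators to be dropped for the current iteration and the reduced
#' system re-solved; the full set is tried again at the next iteration.
#'
#' @param inputs A [scaling_inputs()] with `twin_operators` set (or
#'   `operators` supplied here).
#' @param operators Optional override for the twin operators.
#' @param min_count,max_bins Binning parameters (see [log_d_bins()]).
#' @param max_iter Iteration cap (default 10).
#' @param tol Convergence threshold on the twinned R factor change
#'   (default 1e-4 absolute).
#' @return List with `fractions`, `lambda`, `r_factor`, `iterations`,
#'   `trace` (R per iteration), `k_mask_bins`, `k_iso_bins`, `k_mask`,
#'   `k_iso` (per reflection), `untwinned_fallback`.
#' @export
iterate_twin_scaling <- function(inputs, operators = NULL, min_count = 300,
                                 max_bins = 30, max_iter = 10, tol = 1e-4) {
  stopifnot(inherits(inputs, "scaling_inputs"))
  ops <- normalize_twin_operators(
    if (is.null(operators)) inputs$twin_operators else operators)
  res <- run_scaling(inputs, aniso_method = "none", twin_operators = ops,
                     min_count = min_count, max_bins = max_bins,
                     max_cycles = max_iter, tol = tol, grid_refine = FALSE)
  list(fractions = res$twin$fractions, lambda = res$twin$lambda,
       r_factor = res$r_all, iterations = res$cycles, trace = res$trace,
       k_mask_bins = res$bins$k_mask_smoothed, k_iso_bins = res$bins$k_iso,
       k_mask = res$k_mask, k_iso = res$k_isotropic * res$k_overall,
       untwinned_fallback = isTRUE(res$twin$untwinned_fallback))
}
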
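#' Reflection set
#'
#' Bundle of unique Miller indices with their unit cell, point-group
#' rotations and derived resolution quantities.  This is the core data
#' model every scaling operation works on.
#'
#' @param indices Integer matrix (n x 3) of Miller indices (h, k, l);
#'   one row per unique reflection.
#' @param cell A [unit_cell()].
#' @param symmetry Crystal-system name or Hermann-Mauguin symbol (see
#'   [point_group_rotations()]), or a list of 3x3 rotation matrices
#'   acting on Miller-index columns.
#'
#' @return Object of class `reflection_set` with fields `indices`,
#'   `cell`, `rotations`, `gstar`, `s2` (Angstrom^-2) and `d`
#'   (Angstrom).
#' @examples
#' rs <- reflection_set(rbind(c(1, 0, 0), c(1, 2, 3)),
#'                      unit_cell(20, 30, 40), "orthorhombic")
#' rs$d
#' @export
reflection_set <- function(indices, cell, symmetry = "triclinic") {
  h <- as_index_matrix(indices)
  if (anyDuplicated(paste(h[, 1], h[, 2], h[, 3])))
    stop("reflection indices must be unique (merge equivalents upstream)")
  rot <- if (is.list(symmetry)) symmetry else point_group_rotations(symmetry)
  gstar <- reciprocal_metric_tensor(cell)
  s2 <- s_squared(h, gstar)
  structure(
    list(indices = h, cell = cell, rotations = rot, gstar = gstar,
         s2 = s2, d = 1 / sqrt(s2)),
    class = "reflection_set")
}

#' @export
print.reflection_set <- function(x, ...) {
  cat(sprintf("reflection_set: %d reflections, d = %.3g-%.3g A, %d point-group rotations\n",
              nrow(x$indices), max(x$d), min(x$d), length(x$rotations)))
  invisible(x)
}

#' Scaling inputs
#'
#' Aligns observed amplitudes and the two complex model contributions on
#' one [reflection_set()].
#'
#' @param refl A [reflection_set()].
#' @param f_obs Numeric vector of observed amplitudes (>= 0; negative or
#'   zero entries are kept but excluded from scaling sums downstream).
#' @param f_calc,f_mask Complex vectors: structure factors of the atomic
#'   model and of the bulk-solvent mask.
#' @param twin_operators Optional list of 3x3 integer matrices (or
#'   "h,k,l"-style strings, see [parse_twin_law()]) acting on Miller
#'   indices; the identity is prepended if absent.
#'
#' @return Object of class `scaling_inputs`.
#' @export
scaling_inputs <- function(refl, f_obs, f_calc, f_mask,
                           twin_operators = NULL) {
  stopifnot(inherits(refl, "reflection_set"))
  n <- nrow(refl$indices)
  f_obs <- as.numeric(f_obs)
  f_calc <- as.complex(f_calc)
  f_mask <- as.complex(f_mask)
  if (length(f_obs) != n || length(f_calc) != n || length(f_mask) != n)
    stop("f_obs, f_calc, f_mask must each match the reflection count")
  if (any(!is.finite(f_obs)) || any(!is.finite(Re(f_calc))) ||
      any(!is.finite(Im(f_calc))) || any(!is.finite(Re(f_mask))) ||
      any(!is.finite(Im(f_mask))))
    stop("non-finite values in scaling inputs")
  ops <- normalize_twin_operators(twin_operators)
  structure(
    list(refl = refl, f_obs = f_obs, f_calc = f_calc, f_mask = f_mask,
         twin_operators = ops),
    class = "scaling_inputs")
}

#' @export
print.scaling_inputs <- function(x, ...) {
  print(x$refl)
  cat(sprintf("  <F_obs> = %.4g, <|F_calc|> = %.4g, <|F_mask|> = %.4g",
              mean(x$f_obs), mean(Mod(x$f_calc)), mean(Mod(x$f_mask))))
  if (!is.null(x$twin_operators))
    cat(sprintf(", %d twin operators", length(x$twin_operators)))
  cat("\n")
  invisible(x)
}
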
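#' Unit cell
#'
#' Construct a crystallographic unit cell from the six cell parameters.
#'
#' @param a,b,c Cell edge lengths in Angstrom; must be positive.
#' @param alpha,beta,gamma Cell angles in degrees; must lie in (0, 180).
#'
#' @return An object of class `unit_cell` with fields `a`, `b`, `c`,
#'   `alpha`, `beta`, `gamma` and the cell `volume` (Angstrom^3).
#' @examples
#' uc <- unit_cell(77.3, 77.3, 37.1, 90, 90, 90)
#' uc$volume
#' @export
unit_cell <- function(a, b, c, alpha = 90, beta = 90, gamma = 90) {
  len <- c(a, b, c)
  ang <- c(alpha, beta, gamma)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("invalid cell: edge lengths must be positive and finite")
  if (any(!is.finite(ang)) || any(ang <= 0) || any(ang >= 180))
    stop("invalid cell: angles must lie in (0, 180) degrees")
  ca <- cos(ang * pi / 180)
  # volume via the metric determinant; near-degenerate cells are rejected
  det_arg <- 1 - sum(ca^2) + 2 * prod(ca)
  if (det_arg <= 1e-12)
    stop("invalid cell: degenerate (volume ~ 0)")
  vol <- prod(len) * sqrt(det_arg)
  structure(
    list(a = a, b = b, c = c, alpha = alpha, beta = beta, gamma = gamma,
         volume = vol),
    class = "unit_cell")
}

#' @export
print.unit_cell <- function(x, ...) {
  cat(sprintf("unit cell  %.4g %.4g %.4g  %.4g %.4g %.4g  (V = %.6g A^3)\n",
              x$a, x$b, x$c, x$alpha, x$beta, x$gamma, x$volume))
  invisible(x)
}

#' Direct-space metric tensor of a unit cell
#'
#' @param cell A [unit_cell()].
#' @return Symmetric positive-definite 3x3 matrix G with
#'   `G[i, j] = a_i . a_j` in Angstrom^2.
#' @export
direct_metric_tensor <- function(cell) {
  stopifnot(inherits(cell, "unit_cell"))
  len <- c(cell$a, cell$b, cell$c)
  ca <- cos(c(cell$alpha, cell$beta, cell$gamma) * pi / 180)
  G <- diag(len^2)
  G[1, 2] <- G[2, 1] <- len[1] * len[2] * ca[3]
  G[1, 3] <- G[3, 1] <- len[1] * len[3] * ca[2]
  G[2, 3] <- G[3, 2] <- len[2] * len[3] * ca[1]
  G
}

#' Reciprocal-space metric tensor
#'
#' Returns the tensor G* such that `s^2 = h' G* h` for a Miller-index
#' column vector h, where s = 1/d is the length of the reciprocal-space
#' vector of the reflection.
#'
#' @param cell A [unit_cell()].
#' @return Symmetric positive-definite 3x3 matrix in Angstrom^-2.
#' @examples
#' reciprocal_metric_tensor(unit_cell(2, 4, 5, 90, 90, 90))
#' @export
reciprocal_metric_tensor <- function(cell) {
  G <- direct_metric_tensor(cell)
  gstar <- solve(G)
  (gstar + t(gstar)) / 2
}

#' Squared reciprocal-space vector lengths
#'
#' @param indices Integer matrix (n x 3) of Miller indices, one row per
#'   reflection.
#' @param gstar Reciprocal metric tensor from [reciprocal_metric_tensor()].
#' @return Numeric vector of s^2 values (Angstrom^-2); zero only for the
#'   (0,0,0) index.
#' @export
s_squared <- function(indices, gstar) {
  h <- as_index_matrix(indices)
  rowSums((h %*% gstar) * h)
}

#' Resolution (d-spacing) of reflections
#'
#' @inheritParams s_squared
#' @return d = 1/s in Angstrom; `Inf` for (0,0,0).
#' @export
d_spacing <- function(indices, gstar) {
  1 / sqrt(s_squared(indices, gstar))
}

# coerce index input (matrix, data.frame, or length-3 vector) to n x 3 matrix
as_index_matrix <- function(indices) {
  if (is.null(dim(indices))) {
    if (length(indices) != 3L) stop("indices must be triples (h, k, l)")
    indices <- matrix(indices, ncol = 3L)
  }
  h <- as.matrix(indices)
  if (ncol(h) != 3L) stop("indices must have three columns (h, k, l)")
  storage.mode(h) <- "double"
  unname(h)
}
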
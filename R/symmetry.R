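#' Point-group rotations acting on Miller indices
#'
#' Resolves a crystal-system name, point-group symbol or space-group
#' Hermann-Mauguin symbol to the list of rotation matrices of the
#' corresponding crystal-system point group, expressed in the basis that
#' acts on Miller-index column vectors.  Only the rotation content
#' matters for symmetrizing second-rank tensors, so the holohedral
#' (Laue-complete) rotation group of the crystal system is returned;
#' inversion is omitted because a symmetric tensor is inversion-invariant.
#'
#' @param symbol One of the crystal-system names `"triclinic"`,
#'   `"monoclinic"`, `"orthorhombic"`, `"tetragonal"`, `"trigonal"`,
#'   `"hexagonal"`, `"cubic"`, or a Hermann-Mauguin space-group symbol
#'   such as `"P 21 21 21"`, `"P41212"`, `"R 3"`, `"I a -3 d"` from which
#'   the crystal system is inferred.
#' @return List of 3x3 integer matrices forming a closed group containing
#'   the identity.  Matrices act on Miller-index columns: h' = R h.
#' @examples
#' length(point_group_rotations("cubic"))
#' length(point_group_rotations("P 21 21 21"))
#' @export
point_group_rotations <- function(symbol) {
  system <- crystal_system_of(symbol)
  gen <- holohedral_generators(system)
  # generators are direct-space rotation parts; Miller-index columns
  # transform by the transpose
  close_group(lapply(gen, t))
}

#' Crystal system of a space-group or point-group symbol
#'
#' @inheritParams point_group_rotations
#' @return Crystal-system name as a character scalar.
#' @export
crystal_system_of <- function(symbol) {
  s <- tolower(trimws(symbol))
  systems <- c("triclinic", "monoclinic", "orthorhombic", "tetragonal",
               "trigonal", "hexagonal", "cubic")
  if (s %in% systems) return(s)
  # Hermann-Mauguin: lattice letter then symmetry fields
  compact <- gsub("[[:space:]]+", "", s)
  if (!grepl("^[pabcifr]", compact))
    stop(sprintf("cannot parse symmetry symbol '%s'", symbol))
  body <- sub("^[pabcifr]", "", compact)
  lattice <- substr(compact, 1, 1)
  fields <- hm_fields(body)
  if (length(fields) == 0L)
    stop(sprintf("cannot parse symmetry symbol '%s'", symbol))
  prim <- fields[1]
  has3sec <- length(fields) >= 2L && grepl("^-?3", fields[2])
  if (has3sec) return("cubic")
  if (grepl("^-?6", prim)) return("hexagonal")
  if (grepl("^-?4", prim)) return("tetragonal")
  if (grepl("^-?3", prim)) return("trigonal")
  if (lattice == "r") return("trigonal")
  if (grepl("^-?1$", prim) && length(fields) == 1L) return("triclinic")
  if (length(fields) >= 3L) return("orthorhombic")
  "monoclinic"
}

# split an HM symbol body into rotation/mirror fields, e.g.
# "212121" -> c("21","21","21"); "m-3m" -> c("m","-3","m"); "42_12" forms
hm_fields <- function(body) {
  out <- character(0)
  i <- 1L
  n <- nchar(body)
  while (i <= n) {
    ch <- substr(body, i, i)
    if (ch == "/") { i <- i + 1L; next }
    if (ch == "-") {
      out <- c(out, substr(body, i, i + 1L)); i <- i + 2L; next
    }
    if (ch %in% c("m", "a", "b", "c", "d", "n", "e")) {
      out <- c(out, ch); i <- i + 1L; next
    }
    # digit, possibly followed by a screw subscript digit
    nxt <- if (i < n) substr(body, i + 1L, i + 1L) else ""
    if (ch %in% c("2", "3", "4", "6") && nxt %in% c("1", "2", "3", "4", "5")) {
      out <- c(out, paste0(ch, nxt)); i <- i + 2L
    } else {
      out <- c(out, ch); i <- i + 1L
    }
  }
  out
}

# direct-space rotation generators of the holohedral point group,
# in the conventional setting (monoclinic b-unique, trigonal hexagonal axes)
holohedral_generators <- function(system) {
  id <- diag(3)
  r2z <- diag(c(-1, -1, 1))
  r2y <- diag(c(-1, 1, -1))
  r2x <- diag(c(1, -1, -1))
  r4z <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)       # column-built
  r3z_hex <- matrix(c(0, 1, 0, -1, -1, 0, 0, 0, 1), 3, 3)
  r6z_hex <- matrix(c(1, 1, 0, -1, 0, 0, 0, 0, 1), 3, 3)
  r3_diag <- matrix(c(0, 1, 0, 0, 0, 1, 1, 0, 0), 3, 3)    # x,y,z -> z,x,y
  r2_110 <- matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3)
  switch(system,
    triclinic    = list(id),
    monoclinic   = list(r2y),
    orthorhombic = list(r2z, r2x),
    tetragonal   = list(r4z, r2x),
    trigonal     = list(r3z_hex, r2_110),
    hexagonal    = list(r6z_hex, r2_110),
    cubic        = list(r4z, r3_diag, r2x),
    stop(sprintf("unknown crystal system '%s'", system)))
}

# close a set of integer rotation matrices under multiplication
close_group <- function(gen) {
  key <- function(m) paste(as.integer(round(m)), collapse = ",")
  elems <- list(diag(3))
  names(elems) <- key(diag(3))
  queue <- gen
  while (length(queue) > 0L) {
    m <- round(queue[[1]])
    queue <- queue[-1]
    k <- key(m)
    if (!is.null(elems[[k]])) next
    elems[[k]] <- m
    for (e in elems) {
      queue <- c(queue, list(m %*% e), list(e %*% m))
    }
    if (length(elems) > 96L) stop("rotation set does not close to a group")
  }
  unname(elems)
}

# --- symmetry constraints for symmetric second-rank tensors ----------------

# map a symmetric 6-vector (U11,U22,U33,U12,U13,U23) to the 3x3 matrix
sym6_to_mat <- function(u) {
  matrix(c(u[1], u[4], u[5],
           u[4], u[2], u[6],
           u[5], u[6], u[3]), 3, 3)
}

mat_to_sym6 <- function(m) {
  c(m[1, 1], m[2, 2], m[3, 3], m[1, 2], m[1, 3], m[2, 3])
}

#' Derive the symmetry constraint matrix for anisotropic scale tensors
#'
#' Solves the linear system `R' U R = U` over all rotations `R` of the
#' point group, acting in the Miller-index basis, and returns a basis of
#' the invariant subspace of symmetric tensors as a constraint matrix
#' `C`.  The redundant six coefficients are recovered from the
#' independent ones via `U = t(C) %*% U_ind` (see
#' [expand_independent()]).  Rows are reduced to row-echelon form with
#' the first nonzero element of each row equal to 1, so e.g. the
#' tetragonal system yields rows (1,1,0,0,0,0) and (0,0,1,0,0,0).
#'
#' @param rotations List of 3x3 rotation matrices acting on Miller-index
#'   columns, e.g. from [point_group_rotations()].
#' @return Matrix with 6 columns; the number of rows is the number of
#'   independent tensor coefficients (6, 4, 3, 2, 2, 2 or 1 for the seven
#'   crystal systems).
#' @examples
#' derive_constraint_matrix(point_group_rotations("tetragonal"))
#' @export
derive_constraint_matrix <- function(rotations) {
  stopifnot(is.list(rotations), length(rotations) >= 1L)
  basis6 <- diag(6)
  blocks <- lapply(rotations, function(R) {
    A <- vapply(seq_len(6), function(j) {
      mat_to_sym6(t(R) %*% sym6_to_mat(basis6[, j]) %*% R)
    }, numeric(6))
    A - diag(6)
  })
  stacked <- do.call(rbind, blocks)   # >= 6 rows: one 6x6 block per rotation
  sv <- svd(stacked, nu = 0, nv = 6)
  tol <- 1e-9 * max(sv$d, 1)
  nsp <- sv$v[, sv$d < tol, drop = FALSE]
  if (ncol(nsp) == 0L) stop("no invariant tensor directions found")
  C <- rref_rows(t(nsp))
  dimnames(C) <- list(NULL, c("U11", "U22", "U33", "U12", "U13", "U23"))
  C
}

# reduced row echelon form with unit leading entries and tidied zeros
rref_rows <- function(M, tol = 1e-9) {
  M <- as.matrix(M)
  r <- 1L
  for (j in seq_len(ncol(M))) {
    if (r > nrow(M)) break
    p <- which.max(abs(M[r:nrow(M), j])) + r - 1L
    if (abs(M[p, j]) < tol) next
    if (p != r) M[c(p, r), ] <- M[c(r, p), ]
    M[r, ] <- M[r, ] / M[r, j]
    for (i in seq_len(nrow(M))[-r]) M[i, ] <- M[i, ] - M[i, j] * M[r, ]
    r <- r + 1L
  }
  M[abs(M) < tol] <- 0
  # drop exact-zero rows (rank deficiency cannot occur for a group, but be safe)
  M[rowSums(abs(M)) > 0, , drop = FALSE]
}

#' Expand independent tensor coefficients to the full symmetric 6-vector
#'
#' @param u_ind Numeric vector of independent coefficients, one per row
#'   of `C`.
#' @param C Constraint matrix from [derive_constraint_matrix()].
#' @return Length-6 vector (U11, U22, U33, U12, U13, U23) satisfying all
#'   point-group constraints.
#' @examples
#' C <- derive_constraint_matrix(point_group_rotations("tetragonal"))
#' expand_independent(c(0.01, 0.02), C)
#' @export
expand_independent <- function(u_ind, C) {
  if (length(u_ind) != nrow(C))
    stop(sprintf("dimension mismatch: %d independent coefficients for a %d-row constraint matrix",
                 length(u_ind), nrow(C)))
  drop(t(C) %*% u_ind)
}

#' Convert a scale tensor from the Miller-index basis to Cartesian B values
#'
#' The anisotropic scale tensor U is expressed in the Miller-index basis
#' (the form exp(-2 pi^2 h' U h)).  For reporting, the equivalent
#' Cartesian tensor is `U_cart = O U O'` with O the orthogonalization
#' matrix of the cell, and B = 8 pi^2 U_cart.
#'
#' @param u Symmetric 6-vector (U11, U22, U33, U12, U13, U23) in the
#'   Miller-index basis (Angstrom^2 after scaling by the cell).
#' @param cell A [unit_cell()].
#' @return Length-6 vector of Cartesian B values
#'   (B11, B22, B33, B12, B13, B23).
#' @export
u_star_to_b_cartesian <- function(u, cell) {
  O <- orthogonalization_matrix(cell)
  8 * pi^2 * mat_to_sym6(O %*% sym6_to_mat(u) %*% t(O))
}

# columns are the cell basis vectors in a Cartesian frame (PDB convention)
orthogonalization_matrix <- function(cell) {
  ca <- cos(c(cell$alpha, cell$beta, cell$gamma) * pi / 180)
  sg <- sin(cell$gamma * pi / 180)
  cstar <- (ca[1] - ca[2] * ca[3]) / sg
  v <- sqrt(1 - ca[2]^2 - cstar^2)
  matrix(c(cell$a, 0, 0,
           cell$b * ca[3], cell$b * sg, 0,
           cell$c * ca[2], cell$c * cstar, cell$c * v), 3, 3)
}
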
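# shared fixture builders; all randomness is seeded by the caller

random_cell <- function() {
  repeat {
    len <- runif(3, 5, 60)
    ang <- runif(3, 75, 105)
    uc <- tryCatch(unit_cell(len[1], len[2], len[3], ang[1], ang[2], ang[3]),
                   error = function(e) NULL)
    if (!is.null(uc)) return(uc)
  }
}

# one random resolution bin worth of structure factors
random_bin <- function(n = 50, k_mask = 0.4, noise = 0.1) {
  fc <- complex(real = rnorm(n), imaginary = rnorm(n)) * 5
  fm <- complex(real = rnorm(n), imaginary = rnorm(n)) * 3
  fo <- Mod(fc + k_mask * fm) * pmax(1 + rnorm(n, sd = noise), 0.05)
  list(fc = fc, fm = fm, fo = fo,
       mom = bin_moments(fc, fm, fo))
}

# independent evaluation of the bin least-squares target on a (K, k) grid:
# direct residual algebra per trial k, quadratic in K (no normal equations)
grid_min_ls <- function(mom, k_grid, K_grid) {
  A <- sum(mom$i_obs^2)
  best <- Inf
  for (k in k_grid) {
    m <- mom$u + 2 * k * mom$v + k^2 * mom$w
    c1 <- sum(mom$i_obs * m)
    c0 <- sum(m^2)
    vals <- K_grid^2 * A - 2 * K_grid * c1 + c0
    best <- min(best, vals)
  }
  best
}

# group-averaging projector onto point-group-invariant symmetric tensors:
# an oracle for the constraint machinery that never touches the null space
group_average_tensor <- function(u6, rotations) {
  m <- matrix(c(u6[1], u6[4], u6[5],
                u6[4], u6[2], u6[6],
                u6[5], u6[6], u6[3]), 3, 3)
  acc <- matrix(0, 3, 3)
  for (R in rotations) acc <- acc + t(R) %*% m %*% R
  acc <- acc / length(rotations)
  c(acc[1, 1], acc[2, 2], acc[3, 3], acc[1, 2], acc[1, 3], acc[2, 3])
}

quad_form <- function(u6, h) {
  V <- cbind(h[, 1]^2, h[, 2]^2, h[, 3]^2,
             2 * h[, 1] * h[, 2], 2 * h[, 1] * h[, 3], 2 * h[, 2] * h[, 3])
  drop(V %*% u6)
}

crystal_systems <- c("triclinic", "monoclinic", "orthorhombic", "tetragonal",
                     "trigonal", "hexagonal", "cubic")

# a cell whose metric actually has the symmetry of the given system
cell_for_system <- function(system) {
  switch(system,
         triclinic    = unit_cell(10, 12, 15, 80, 95, 100),
         monoclinic   = unit_cell(10, 12, 15, 90, 101, 90),
         orthorhombic = unit_cell(10, 12, 15, 90, 90, 90),
         tetragonal   = unit_cell(10, 10, 15, 90, 90, 90),
         trigonal     = unit_cell(10, 10, 15, 90, 90, 120),
         hexagonal    = unit_cell(10, 10, 15, 90, 90, 120),
         cubic        = unit_cell(10, 10, 10, 90, 90, 90))
}

random_index_set <- function(n = 200, hmax = 8) {
  h <- unique(cbind(sample(-hmax:hmax, n, TRUE), sample(-hmax:hmax, n, TRUE),
                    sample(0:hmax, n, TRUE)))
  h[rowSums(abs(h)) > 0, , drop = FALSE]
}
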
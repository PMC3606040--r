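# builds aligned per-domain intensity fixtures on a P4 tetragonal lattice
twin_fixture <- function(n = 3000, fractions = c(0.7, 0.3), noise = 0,
                         k_sol = 0, seed = 30) {
  spec <- simulation_spec(cell = unit_cell(60, 60, 90), symmetry = "P4",
                          n = n, d_range = c(2.5, 25), k_sol = k_sol,
                          b_sol = 50, noise = noise, seed = seed,
                          twin_operators = list("k,h,-l"),
                          twin_fractions = fractions)
  sim <- simulate_reflections(spec)
  ins <- sim$inputs
  mates <- bulksolv:::twin_mate_table(ins$refl, ins$twin_operators)
  imod <- vapply(seq_len(ncol(mates)), function(j) {
    (sim$truth$k_aniso * Mod(ins$f_calc[mates[, j]] +
                               sim$truth$k_mask * ins$f_mask[mates[, j]]))^2
  }, numeric(length(ins$f_obs)))
  list(sim = sim, inputs = ins, mates = mates, imod = imod)
}

test_that("twin laws parse to integer matrices", {
  expect_equal(parse_twin_law("h,k,l"), diag(3), ignore_attr = TRUE)
  expect_equal(parse_twin_law("-h,-k,l"),
               matrix(c(-1, 0, 0, 0, -1, 0, 0, 0, 1), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(parse_twin_law("k, h, -l"),
               matrix(c(0, 1, 0, 1, 0, 0, 0, 0, -1), 3, 3, byrow = TRUE),
               ignore_attr = TRUE)
  expect_equal(parse_twin_law("h+k,-k,-l")[1, ], c(1, 1, 0))
  expect_error(parse_twin_law("h,k"), "three")
  expect_error(parse_twin_law("h,k,q"), "cannot parse")
})

test_that("total twinned intensity is the fraction-weighted mean", {
  I <- cbind(c(10, 4), c(20, 6))
  expect_equal(twin_total_intensity(c(0.7, 0.3), I), c(13, 4.6))
  expect_equal(twin_total_intensity(1, I[, 1, drop = FALSE]), I[, 1])
  expect_equal(twin_total_intensity(c(0.5, 0.5), cbind(I[, 1], I[, 1])), I[, 1])
})

test_that("fraction estimation recovers exact fractions and keeps the constraint", {
  fx <- twin_fixture(n = 3000, fractions = c(0.7, 0.3), noise = 0)
  iobs <- fx$inputs$f_obs^2
  est <- estimate_twin_fractions(iobs, fx$imod)
  expect_equal(est$fractions, c(0.7, 0.3), tolerance = 1e-8)
  expect_lt(abs(sum(est$fractions) - 1), 1e-12)
  # single domain: constraint alone fixes the answer
  est1 <- estimate_twin_fractions(iobs, fx$imod[, 1, drop = FALSE])
  expect_identical(est1$fractions, 1)
})

test_that("constraint holds to 1e-12 across random noisy estimations", {
  set.seed(31)
  fx <- twin_fixture(n = 2000, fractions = c(0.6, 0.4), noise = 0.05, seed = 31)
  for (rep in 1:10) {
    sub <- sample(nrow(fx$imod), 500)
    est <- estimate_twin_fractions(fx$inputs$f_obs[sub]^2,
                                   fx$imod[sub, , drop = FALSE])
    expect_lt(abs(sum(est$fractions) - 1), 1e-12)
  }
})

test_that("noisy fraction estimate matches an exhaustive 1-D scan oracle", {
  set.seed(32)
  n <- 30
  I1 <- runif(n, 1, 10); I2 <- runif(n, 1, 10)
  iobs <- 0.65 * I1 + 0.35 * I2 + rnorm(n, sd = 0.5)
  est <- estimate_twin_fractions(iobs, cbind(I1, I2))
  # eliminate the constraint by substitution and scan alpha1
  a_grid <- seq(-0.5, 1.5, by = 1e-4)
  res <- vapply(a_grid, function(a) {
    sum((iobs - a * I1 - (1 - a) * I2)^2)
  }, numeric(1))
  expect_lt(abs(est$fractions[1] - a_grid[which.min(res)]), 1e-4 + 1e-8)
})

test_that("exchange of the domain operators permutes the fractions", {
  fx <- twin_fixture(n = 2000, fractions = c(0.7, 0.3), noise = 0.02, seed = 33)
  iobs <- fx$inputs$f_obs^2
  a <- estimate_twin_fractions(iobs, fx$imod)$fractions
  b <- estimate_twin_fractions(iobs, fx$imod[, 2:1])$fractions
  expect_equal(a, rev(b), tolerance = 1e-10)
})

test_that("twinned bin solve reduces bit-identically to the untwinned path", {
  set.seed(34)
  bin <- random_bin(50, k_mask = 0.3, noise = 0.1)
  ref <- solve_bin_scales(bin$mom)
  tw <- solve_twin_bin_scales(matrix(bin$mom$u), matrix(bin$mom$v),
                              matrix(bin$mom$w), bin$mom$i_obs, 1)
  expect_identical(tw$K, ref$K)
  expect_identical(tw$k_mask, ref$k_mask)
  expect_identical(tw$ls, ref$ls)
})

test_that("twinned bin solve recovers a noiseless twinned construction", {
  set.seed(35)
  n <- 60
  f1c <- complex(real = rnorm(n), imaginary = rnorm(n)) * 5
  f1m <- complex(real = rnorm(n), imaginary = rnorm(n)) * 3
  f2c <- complex(real = rnorm(n), imaginary = rnorm(n)) * 5
  f2m <- complex(real = rnorm(n), imaginary = rnorm(n)) * 3
  al <- c(0.6, 0.4)
  iobs <- al[1] * Mod(f1c + 0.3 * f1m)^2 + al[2] * Mod(f2c + 0.3 * f2m)^2
  sol <- solve_twin_bin_scales(cbind(Mod(f1c)^2, Mod(f2c)^2),
                               cbind(Re(f1c * Conj(f1m)), Re(f2c * Conj(f2m))),
                               cbind(Mod(f1m)^2, Mod(f2m)^2), iobs, al)
  expect_equal(sol$k_mask, 0.3, tolerance = 1e-8)
  expect_equal(sol$K, 1, tolerance = 1e-8)
})

test_that("twinned bin solve beats the brute-force grid on noisy bins", {
  set.seed(36)
  for (rep in 1:5) {
    n <- 50
    u <- cbind(runif(n, 0, 25), runif(n, 0, 25))
    w <- cbind(runif(n, 0, 9), runif(n, 0, 9))
    v <- sqrt(u * w) * matrix(runif(2 * n, -1, 1), n, 2)
    al <- c(0.55, 0.45)
    iobs <- drop((u + 2 * 0.4 * v + 0.16 * w) %*% al) *
      (1 + rnorm(n, sd = 0.15))
    sol <- solve_twin_bin_scales(u, v, w, iobs, al)
    mom_bar <- structure(list(u = drop(u %*% al), v = drop(v %*% al),
                              w = drop(w %*% al), i_obs = iobs),
                         class = "bin_moments")
    gmin <- grid_min_ls(mom_bar,
                        seq(0, max(1, 2 * sol$k_mask), length.out = 200),
                        seq(0.2, 3, length.out = 200) * sol$K)
    expect_lte(sol$ls, gmin + 1e-9 * abs(gmin))
  }
})

test_that("a spurious operator on untwinned data converges to zero fraction", {
  spec <- simulation_spec(cell = unit_cell(60, 60, 90), symmetry = "P4",
                          n = 4000, d_range = c(2.5, 25), k_sol = 0.3,
                          b_sol = 50, noise = 0, seed = 37,
                          twin_operators = list("k,h,-l"),
                          twin_fractions = c(1, 0))
  sim <- simulate_reflections(spec)
  res <- iterate_twin_scaling(sim$inputs, min_count = 200)
  expect_lt(abs(res$fractions[1] - 1), 1e-3)
  expect_lt(abs(res$fractions[2]), 1e-3)
  expect_equal(sum(res$fractions), 1, tolerance = 1e-12)
})

test_that("joint fraction and scale recovery on noiseless twinned data", {
  spec <- simulation_spec(cell = unit_cell(60, 60, 90), symmetry = "P4",
                          n = 5000, d_range = c(2.5, 25), k_sol = 0.35,
                          b_sol = 50, noise = 0, seed = 38,
                          twin_operators = list("k,h,-l"),
                          twin_fractions = c(0.55, 0.45))
  sim <- simulate_reflections(spec)
  res <- iterate_twin_scaling(sim$inputs, min_count = 300)
  expect_equal(res$fractions, c(0.55, 0.45), tolerance = 1e-2)
  expect_lt(res$r_factor, 0.01)
  expect_true(all(res$fractions >= 0 & res$fractions <= 1))
})

test_that("an iteration cap of one performs exactly one estimate-then-scale round", {
  spec <- simulation_spec(cell = unit_cell(60, 60, 90), symmetry = "P4",
                          n = 2500, d_range = c(2.5, 25), k_sol = 0.3,
                          b_sol = 50, noise = 0.02, seed = 39,
                          twin_operators = list("k,h,-l"),
                          twin_fractions = c(0.7, 0.3))
  sim <- simulate_reflections(spec)
  one <- iterate_twin_scaling(sim$inputs, max_iter = 1, min_count = 200)
  expect_identical(one$iterations, 1L)
  ref <- run_scaling(sim$inputs, aniso_method = "none", max_cycles = 1,
                     min_count = 200, grid_refine = FALSE)
  expect_identical(one$fractions, ref$twin$fractions)
  expect_identical(one$r_factor, ref$r_all)
})
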
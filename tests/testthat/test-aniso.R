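test_that("exponential scale factor evaluates the quadratic form", {
  h <- rbind(c(0, 0, 0), c(1, 1, 1), c(2, -1, 3))
  expect_equal(k_aniso_exponential(rep(0, 6), h), rep(1, 3))
  expect_equal(k_aniso_exponential(runif(6), h[1, , drop = FALSE]), 1)
  # cubic a = 1, U = 0.01 I, index (1,1,1): exp(-2 pi^2 * 0.03)
  expect_equal(k_aniso_exponential(c(0.01, 0.01, 0.01, 0, 0, 0), c(1, 1, 1)),
               exp(-2 * pi^2 * 0.03))
})

test_that("polynomial scale factor is 1 at the origin and linear in coefficients", {
  h <- rbind(c(0, 0, 0), c(1, 2, 3), c(-2, 0, 1))
  s2 <- c(0, 0.1, 0.05)
  expect_equal(k_aniso_polynomial(rep(0, 6), rep(0, 6), h, s2), rep(1, 3))
  v0 <- runif(6, -1e-3, 1e-3); v1 <- runif(6, -1e-3, 1e-3)
  expect_equal(k_aniso_polynomial(v0, v1, h, s2)[1], 1)
  # linearity
  a <- k_aniso_polynomial(v0, v1, h, s2) - 1
  b <- k_aniso_polynomial(2 * v0, 2 * v1, h, s2) - 1
  expect_equal(b, 2 * a)
})

test_that("polynomial form matches the exponential Taylor expansion for isotropic U", {
  uc <- unit_cell(20, 25, 30)
  gs <- reciprocal_metric_tensor(uc)
  h <- random_index_set(150, 6)
  set.seed(10)
  g6 <- c(gs[1, 1], gs[2, 2], gs[3, 3], gs[1, 2], gs[1, 3], gs[2, 3])
  s2 <- s_squared(h, gs)
  prev_err <- Inf
  for (cc in c(0.4, 0.2, 0.1, 0.05)) {
    u <- cc * g6
    v0 <- -2 * pi^2 * cc * g6
    v1 <- 2 * pi^4 * cc^2 * g6
    ke <- k_aniso_exponential(u, h)
    kp <- k_aniso_polynomial(v0, v1, h, s2)
    x <- 2 * pi^2 * cc * s2
    # remainder of the two-term Taylor expansion is O(x^3)
    expect_lt(max(abs(kp - ke)), max(x^3))
    err <- max(abs(kp - ke))
    expect_lt(err, prev_err)
    prev_err <- err
  }
})

test_that("analytic exponential fit recovers known tensors in every crystal system", {
  set.seed(11)
  for (sys in crystal_systems) {
    C <- derive_constraint_matrix(point_group_rotations(sys))
    u0 <- expand_independent(runif(nrow(C), -2e-3, 2e-3), C)
    h <- random_index_set(300, 7)
    m <- 10 * exp(-0.02 * rowSums(h^2))
    fo <- m * k_aniso_exponential(u0, h)
    fit <- fit_exponential_aniso(fo, m, h, C)
    expect_lt(max(abs(fit$u - u0)), 1e-8 * max(1, max(abs(u0))), label = sys)
    expect_identical(fit$n_excluded, 0L)
  }
})

test_that("exact data gives a zero tensor and excluded reflections are counted", {
  set.seed(12)
  h <- random_index_set(100, 5)
  m <- runif(nrow(h), 1, 10)
  fit <- fit_exponential_aniso(m, m, h)
  expect_lt(max(abs(fit$u)), 1e-12)
  fo <- m
  fo[1:3] <- 0
  expect_identical(fit_exponential_aniso(fo, m, h)$n_excluded, 3L)
})

test_that("analytic exponential fit agrees with direct numerical minimization of the log residual", {
  set.seed(13)
  h <- random_index_set(60, 5)[1:50, ]
  m <- runif(50, 5, 15)
  fo <- m * exp(rnorm(50, sd = 0.2))
  fit <- fit_exponential_aniso(fo, m, h, diag(6))
  obj <- function(u) sum((log(fo) - log(m * k_aniso_exponential(u, h)))^2)
  ref <- optim(rep(0, 6), obj, method = "BFGS",
               control = list(maxit = 2000, reltol = 1e-14))
  expect_lt(max(abs(fit$u - ref$par)), 1e-6)
  expect_lte(obj(fit$u), ref$value + 1e-10)
})

test_that("analytic exponential fit is invariant under point-group re-indexing", {
  set.seed(14)
  rot <- point_group_rotations("tetragonal")
  C <- derive_constraint_matrix(rot)
  h <- random_index_set(200, 6)
  m <- 10 * exp(-0.02 * rowSums(h^2))
  fo <- m * exp(rnorm(nrow(h), sd = 0.1))
  fit1 <- fit_exponential_aniso(fo, m, h, C)
  R <- rot[[which(!vapply(rot, function(x) all(x == diag(3)), logical(1)))[1]]]
  fit2 <- fit_exponential_aniso(fo, m, h %*% t(R), C)
  expect_equal(fit1$u, fit2$u, tolerance = 1e-10)
})

test_that("rank-deficient exponential systems raise a rank error", {
  # all indices along one axis cannot determine the full tensor
  h <- cbind(1:12, 0, 0)
  m <- rep(2, 12)
  expect_error(fit_exponential_aniso(m * exp(rnorm(12)), m, h, diag(6)),
               "rank-deficient")
})

test_that("polynomial fit is exact on data generated from known (V0, V1)", {
  set.seed(15)
  h <- random_index_set(200, 6)
  gs <- reciprocal_metric_tensor(unit_cell(25, 30, 35))
  s2 <- s_squared(h, gs)
  m <- 10 * exp(-3 * s2)
  v0 <- runif(6, -1e-2, 1e-2)
  v1 <- runif(6, -1e-2, 1e-2)
  fo <- m * k_aniso_polynomial(v0, v1, h, s2)
  fit <- fit_polynomial_aniso(fo, m, h, s2)
  expect_equal(fit$v0, v0, tolerance = 1e-8)
  expect_equal(fit$v1, v1, tolerance = 1e-8)
  # exact data -> zero coefficients
  fit0 <- fit_polynomial_aniso(m, m, h, s2)
  expect_lt(max(abs(c(fit0$v0, fit0$v1))), 1e-10)
})

test_that("polynomial fit matches an explicitly summed normal-equation oracle", {
  set.seed(16)
  h <- random_index_set(40, 4)[1:30, ]
  gs <- reciprocal_metric_tensor(unit_cell(15, 18, 21))
  s2 <- s_squared(h, gs)
  m <- runif(30, 2, 8)
  fo <- m * (1 + rnorm(30, sd = 0.1))
  # oracle: assemble the 12x12 normal equations by explicit loops
  basis_row <- function(i) {
    V <- c(h[i, 1]^2, h[i, 2]^2, h[i, 3]^2,
           2 * h[i, 1] * h[i, 2], 2 * h[i, 1] * h[i, 3], 2 * h[i, 2] * h[i, 3])
    m[i] * c(V, s2[i] * V)
  }
  N <- matrix(0, 12, 12); b <- numeric(12)
  for (i in 1:30) {
    xi <- basis_row(i)
    N <- N + outer(xi, xi)
    b <- b + xi * (fo[i] - m[i])
  }
  ref <- solve(N, b)
  fit <- fit_polynomial_aniso(fo, m, h, s2)
  expect_equal(c(fit$v0, fit$v1), ref, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("minimized exponential fit never increases the amplitude residual", {
  set.seed(17)
  C <- derive_constraint_matrix(point_group_rotations("orthorhombic"))
  h <- random_index_set(300, 7)
  u0 <- expand_independent(c(1e-3, -2e-3, 3e-3), C)
  m <- 10 * exp(-0.02 * rowSums(h^2))
  amp_res <- function(u, fo) sum((fo - k_aniso_exponential(u, h) * m)^2)

  # noiseless: both routes find the same (zero-residual) tensor
  fo <- m * k_aniso_exponential(u0, h)
  fa <- fit_exponential_aniso(fo, m, h, C)
  fm <- fit_exponential_aniso_minimized(fo, m, h, C)
  expect_equal(fm$u, fa$u, tolerance = 1e-6, ignore_attr = TRUE)

  # heteroscedastic noise: the amplitude-residual optimum is at least as good
  fo2 <- fo * (1 + rnorm(nrow(h), sd = 0.05 + 0.3 * (rowSums(h^2) < 20)))
  fa2 <- fit_exponential_aniso(fo2, m, h, C)
  fm2 <- fit_exponential_aniso_minimized(fo2, m, h, C)
  expect_lte(fm2$residual, amp_res(fa2$u, fo2) + 1e-10)
  expect_equal(fm2$residual, amp_res(fm2$u, fo2))

  # a stationary start is returned unchanged (up to optimizer no-ops)
  fm3 <- fit_exponential_aniso_minimized(fo, m, h, C, start = fm$u)
  expect_lte(fm3$residual, fm$residual + 1e-10)
})

test_that("log-residual and amplitude-residual minima differ on noisy data", {
  set.seed(18)
  C <- diag(6)
  h <- random_index_set(400, 7)
  m <- 10 * exp(-0.015 * rowSums(h^2))
  fo <- m * exp(rnorm(nrow(h), sd = 0.3))   # multiplicative, skewed in amplitude
  fa <- fit_exponential_aniso(fo, m, h, C)
  fm <- fit_exponential_aniso_minimized(fo, m, h, C)
  res <- function(u) sum((fo - k_aniso_exponential(u, h) * m)^2)
  expect_lt(res(fm$u), res(fa$u))   # strict: the two targets disagree
})
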
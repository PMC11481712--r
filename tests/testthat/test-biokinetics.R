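ref_deposit <- apportion_deposit(
  polydisperse_deposition(aerosol_spec(5, 2.5), ref_worker))

test_that("the K_factor scales exactly the eight correlated routes", {
  s1 <- build_full_system(ref_deposit, rate_modifiers(kpt = 1))
  s2 <- build_full_system(ref_deposit, rate_modifiers(kpt = 2))
  tr <- load_reference_rates("hrtm_transport")
  scaled <- tr[tr$kpt_scaled, ]
  for (i in seq_len(nrow(scaled))) {
    src <- scaled$source[i]; dst <- scaled$destination[i]
    expect_equal(s2$A[dst, src], 2 * s1$A[dst, src])
  }
  # the three AI-region rates are untouched by kpt
  expect_equal(s2$A["INT", "ALV"], s1$A["INT", "ALV"])
  expect_equal(s2$A["bbprime", "ALV"], s1$A["bbprime", "ALV"])
  expect_equal(s2$A["LNTH", "INT"], s1$A["LNTH", "INT"])
  # off-diagonal entries that changed are exactly the eight routes
  delta <- s2$A - s1$A
  diag(delta) <- 0
  changed <- which(abs(delta) > 0, arr.ind = TRUE)
  expect_equal(nrow(changed), 8L)
})

test_that("reference modifiers reproduce the reference matrix entrywise", {
  a <- build_full_system(ref_deposit)$A
  b <- build_full_system(ref_deposit, rate_modifiers(
    kpt = 1, l_alv_int = 0.001, l_alv_bb = 0.002, l_int_lnth = 0.00003))$A
  expect_identical(a, b)
})

test_that("a toy three-compartment table assembles the hand-built matrix", {
  k12 <- 0.1; k2b <- 0.3; kbe <- 0.05
  dep <- structure(c(ET1 = 1), class = "compartment_deposit")
  sys <- build_full_system(dep, tables = toy_tables(k12, k2b, kbe))
  lam <- log(2) / 8.0252
  A <- sys$A
  expect_equal(A["ET2prime", "ET1"], k12)
  expect_equal(A["ET1", "ET1"], -k12 - lam)
  expect_equal(A["Blood", "ET2prime"], k2b)
  expect_equal(A["ET2prime", "ET2prime"], -k2b - lam)
  expect_equal(A["Excreta", "Blood"], kbe)
  expect_equal(A["Blood", "Blood"], -kbe - lam)
  expect_equal(A["Excreta", "Excreta"], -lam)
  # everything else in the touched rows/columns is zero
  A["ET2prime", "ET1"] <- A["Blood", "ET2prime"] <- A["Excreta", "Blood"] <- 0
  diag(A) <- diag(A) + lam
  diag(A)[match(c("ET1", "ET2prime", "Blood"), sys$compartments)] <-
    diag(A)[match(c("ET1", "ET2prime", "Blood"), sys$compartments)] +
    c(k12, k2b, kbe)
  expect_lt(max(abs(A)), 1e-14)
})

test_that("non-default AI modifiers require their routes in the table", {
  dep <- structure(c(ET1 = 1), class = "compartment_deposit")
  expect_error(
    build_full_system(dep, rate_modifiers(l_alv_bb = 0.01),
                      tables = toy_tables()),
    "ALV -> bbprime")
})

test_that("single-compartment retention follows the closed form", {
  sys <- single_compartment_system(k = 0.1)
  ret <- solve_retention(sys, times = c(5, 10, 20))
  expect_equal(ret$fractions[1, ], exp(-0.1 * c(5, 10, 20)),
               tolerance = 1e-12)
})

test_that("a closed system without decay conserves total activity", {
  full <- build_full_system(ref_deposit)
  closed <- full
  diag(closed$A) <- diag(closed$A) + full$lambda # remove decay
  closed$lambda <- 0
  ret <- solve_retention(closed, times = c(0.01, 1, 10, 100, 1000, 18262.5))
  sums <- colSums(ret$fractions)
  expect_equal(sums, rep(sum(full$initial), 6), tolerance = 1e-9)
})

test_that("uniform decay factors out as exp(lambda t)", {
  full <- build_full_system(ref_deposit)
  closed <- full
  diag(closed$A) <- diag(closed$A) + full$lambda
  closed$lambda <- 0
  times <- c(0.1, 1, 10, 50)
  with_decay <- solve_retention(full, times = times)$fractions
  without <- solve_retention(closed, times = times)$fractions
  scaled <- sweep(with_decay, 2, exp(full$lambda * times), `*`)
  expect_equal(scaled, without, tolerance = 1e-9)
})

test_that("the algebraic solution matches a stiff numerical integrator on
           the full inhalation system", {
  skip_if_not_installed("deSolve")
  sys <- build_full_system(ref_deposit)
  times <- exp(seq(log(1e-3), log(1000), length.out = 20))
  alg <- solve_retention(sys, times = times)$fractions
  rhs <- function(t, y, parms) list(parms %*% y)
  num <- deSolve::radau(y = sys$initial, times = c(0, times), func = rhs,
                        parms = sys$A, rtol = 1e-12, atol = 1e-25)
  num <- t(num[-1, -1, drop = FALSE])
  mask <- num > 1e-15
  expect_lt(max(abs(alg[mask] - num[mask]) / num[mask]), 1e-8)
})

test_that("algebraic and numerical solutions agree on random small systems", {
  skip_if_not_installed("deSolve")
  set.seed(314)
  rhs <- function(t, y, parms) list(parms %*% y)
  for (case in 1:100) {
    sys <- random_system(n = sample(3:6, 1), lambda = runif(1, 0, 0.2))
    times <- sort(exp(runif(5, log(0.01), log(20))))
    alg <- solve_retention(sys, times = times)$fractions
    num <- deSolve::lsoda(y = sys$initial, times = c(0, times), func = rhs,
                          parms = sys$A, rtol = 1e-13, atol = 1e-20)
    num <- t(num[-1, -1, drop = FALSE])
    mask <- num > 1e-12
    expect_lt(max(abs(alg[mask] - num[mask]) / num[mask]), 1e-8)
  }
})

test_that("commitment integrals reduce to closed forms", {
  sys <- single_compartment_system(k = 0.1)
  u <- integrate_retention(sys, tau = 50, aggregate = FALSE)
  expect_equal(as.numeric(u), (1 - exp(-5)) / 0.1, tolerance = 1e-12)
  # tau -> infinity limit with decay: 1 / (k + lambda)
  sysl <- single_compartment_system(k = 0.1, lambda = 0.05)
  u_inf <- integrate_retention(sysl, tau = 1e6, aggregate = FALSE)
  expect_equal(as.numeric(u_inf), 1 / 0.15, tolerance = 1e-10)
})

test_that("eigen-space integration matches quadrature of the solved curves", {
  sys <- build_full_system(ref_deposit)
  tau <- 1000
  U <- integrate_retention(sys, tau = tau, aggregate = FALSE)
  tt <- c(0, exp(seq(log(1e-7), log(tau), length.out = 6000)))
  X <- solve_retention(sys, times = tt[-1])$fractions
  X <- cbind(sys$initial, X)
  dt <- diff(tt)
  quad <- as.numeric((X[, -ncol(X)] + X[, -1]) %*% dt / 2)
  mask <- quad > 1e-10
  expect_lt(max(abs(unclass(U)[mask] - quad[mask]) / quad[mask]), 1e-4)
})

test_that("integrated activity never decreases with the commitment period", {
  sys <- build_full_system(ref_deposit)
  taus <- c(1, 10, 100, 1000, 18262.5)
  us <- vapply(taus, function(tau)
    unclass(integrate_retention(sys, tau = tau)), numeric(12))
  expect_true(all(diff(t(us)) >= -1e-15))
})

test_that("invalid inputs are rejected", {
  sys <- single_compartment_system(0.1)
  expect_error(solve_retention(sys, times = c(2, 1)), "increasing")
  bad <- sys; bad$A[1, 1] <- NaN
  expect_error(solve_retention(bad, times = 1), "non-finite")
  expect_error(integrate_retention(sys, tau = -1), "positive")
  expect_error(rate_modifiers(kpt = 0), "positive")
})
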
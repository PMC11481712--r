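pattern_sit <- breathing_pattern("sitting")

test_that("filtration chain handles degenerate stages and validates input", {
  expect_equal(filtration_chain(rep(0, 5), rep(1, 5)), rep(0, 5))
  expect_equal(filtration_chain(0.5, 1), 0.5)
  expect_error(filtration_chain(c(0.5, 1.2), c(1, 1)), "eta")
  expect_error(filtration_chain(c(0.5, 0.5), c(1, 0)), "phi")
})

test_that("escape-fraction form equals the classical recursion and a
           sequential-filter simulation", {
  set.seed(42)
  for (rep in 1:50) {
    eta <- runif(9, 0.01, 0.99)
    phi <- sort(runif(9, 0.3, 1), decreasing = TRUE)
    de <- filtration_chain(eta, phi)
    expect_equal(de, de_recursion_oracle(eta, phi), tolerance = 1e-12)
    expect_equal(de, de_simulation_oracle(eta, phi), tolerance = 1e-12)
    expect_lte(sum(de), 1)
  }
  # zero-efficiency stages break the classical recursion but not the
  # simulation oracle
  eta <- c(0.4, 0, 0.3, 0, 0.2)
  phi <- c(1, 1, 0.9, 0.8, 0.7)
  expect_equal(filtration_chain(eta, phi), de_simulation_oracle(eta, phi))
})

test_that("aerodynamic efficiency obeys its limits and monotonicity", {
  for (r in c("ET1", "ET2", "BB", "bb", "AI")) {
    expect_equal(aerodynamic_efficiency(r, 5, pattern_sit, multiplier = 0), 0)
    expect_lt(aerodynamic_efficiency(r, 1e-4, pattern_sit), 1e-6)
  }
  grid <- seq(1, 20, length.out = 200)
  for (r in c("ET1", "ET2")) {
    eff <- aerodynamic_efficiency(r, grid, pattern_sit)
    expect_true(all(diff(eff) >= 0))
  }
  expect_error(aerodynamic_efficiency("XX", 5, pattern_sit), "unknown region")
  expect_error(aerodynamic_efficiency("ET1", -1, pattern_sit), "positive")
})

test_that("thermodynamic efficiency weakens with size and stays in [0,1]", {
  grid <- exp(seq(log(0.01), log(1), length.out = 150))
  for (r in c("ET1", "ET2", "BB", "bb", "AI")) {
    expect_equal(thermodynamic_efficiency(r, 0.1, pattern_sit,
                                          multiplier = 0), 0)
    eff <- thermodynamic_efficiency(r, grid, pattern_sit)
    expect_true(all(diff(eff) <= 1e-15))
  }
  set.seed(1)
  d <- exp(runif(2e5, log(1e-3), log(50)))
  eff <- thermodynamic_efficiency("AI", d, pattern_sit,
                                  multiplier = exp(rnorm(1)))
  expect_true(all(eff >= 0 & eff <= 1))
})

test_that("monodisperse deposition is deterministic and conserves activity", {
  a <- monodisperse_deposition(5, ref_worker)
  b <- monodisperse_deposition(5, ref_worker)
  expect_identical(a[1:7], b[1:7])
  set.seed(99)
  for (rep in 1:25) {
    mult <- deposition_multipliers(
      cae = setNames(exp(rnorm(5, 0, 0.5)), c("ET1", "ET2", "BB", "bb", "AI")),
      cth = setNames(exp(rnorm(5, 0, 0.3)), c("ET1", "ET2", "BB", "bb", "AI"))
    )
    fn <- runif(1, 0.4, 1)
    d <- exp(runif(1, log(0.05), log(30)))
    dep <- monodisperse_deposition(d, worker_scenario(fn = fn), mult)
    total <- sum(unlist(dep[c("ET1", "ET2", "BB", "bb", "AI", "exhaled",
                              "not_inhaled")]))
    expect_equal(total, 1, tolerance = 1e-9)
    expect_true(all(unlist(dep[1:7]) >= 0))
  }
})

test_that("switching off the thermodynamic component leaves the pure
           aerodynamic chain", {
  mult <- deposition_multipliers(cth = setNames(rep(0, 5),
                                                c("ET1", "ET2", "BB", "bb",
                                                  "AI")))
  dep <- monodisperse_deposition(5, ref_worker, mult)
  # rebuild by hand from the aerodynamic efficiencies only
  filters <- c("ET1", "ET2", "BB", "bb", "AI", "bb", "BB", "ET2", "ET1")
  hand <- setNames(numeric(5), c("ET1", "ET2", "BB", "bb", "AI"))
  w <- hrtmdose:::hd_read_csv("worker_scenario.csv")$air_fraction
  inh <- hrtmdose:::inhalable_fraction(5)
  for (k in seq_along(ref_worker$patterns)) {
    pat <- ref_worker$patterns[[k]]
    mech <- hrtmdose:::pattern_mechanics(pat)
    eta <- vapply(filters, function(r)
      aerodynamic_efficiency(r, 5, pat), numeric(1))
    de <- filtration_chain(eta, mech$phi[filters])
    for (r in names(hand)) {
      hand[r] <- hand[r] + w[k] * sum(de[filters == r])
    }
  }
  hand <- hand * inh
  expect_equal(unlist(dep[names(hand)]), hand, tolerance = 1e-12)
})

test_that("alveolar deposit falls off for coarse aerosols", {
  ai <- vapply(c(5, 8, 12, 16, 20), function(d)
    monodisperse_deposition(d, ref_worker)$AI, numeric(1))
  # strictly falling until the upstream filters capture everything
  expect_true(all(diff(ai) <= 0))
  expect_gt(ai[1], 10 * ai[2])
})

test_that("reference deposition is locked for the 5 um worker aerosol", {
  dep <- polydisperse_deposition(aerosol_spec(amad = 5, gsd = 2.5),
                                 ref_worker)
  golden <- c(ET1 = 0.317895811420243, ET2 = 0.369694066350264,
              BB = 0.0174502680696085, bb = 0.0109924627137968,
              AI = 0.0526355857361567, exhaled = 0.134001570255271,
              not_inhaled = 0.0973302354546597)
  expect_equal(unlist(dep[names(golden)]), golden, tolerance = 1e-10)
})

test_that("polydisperse integration collapses to monodisperse at gsd 1 and
           matches a Monte Carlo size average", {
  mono <- monodisperse_deposition(5, ref_worker)
  poly <- polydisperse_deposition(aerosol_spec(amad = 5, gsd = 1), ref_worker)
  expect_equal(unlist(poly[1:7]), unlist(mono[1:7]), tolerance = 1e-12)

  aero <- aerosol_spec(amad = 5, gsd = 2.5)
  quad <- polydisperse_deposition(aero, ref_worker)
  set.seed(2024)
  d <- rlnorm(1e5, log(5), log(2.5))
  mc <- colMeans(hrtmdose:::regional_deposition_matrix(
    d, ref_worker, deposition_multipliers()))
  for (r in c("ET1", "ET2", "BB", "bb", "AI")) {
    expect_lt(abs(quad[[r]] - mc[[r]]), 0.002)
  }
})

test_that("quadrature is stable under node doubling", {
  a <- polydisperse_deposition(aerosol_spec(5, 2.5), ref_worker, nodes = 61)
  b <- polydisperse_deposition(aerosol_spec(5, 2.5), ref_worker, nodes = 121)
  expect_equal(unlist(a[1:7]), unlist(b[1:7]), tolerance = 1e-6)
})

test_that("alveolar deposit responds monotonically to its aerodynamic
           multiplier", {
  spec <- dist_spec("lognormal", gm = 1, gsd = 1.3)
  mults <- quantile_dist(spec, seq(0.05, 0.95, by = 0.1))
  ai <- vapply(mults, function(m) {
    monodisperse_deposition(5, ref_worker,
                            deposition_multipliers(cae = c(AI = m)))$AI
  }, numeric(1))
  expect_true(all(diff(ai) > 0))
})

test_that("deposit apportionment sequesters f_d and conserves the total", {
  dep <- monodisperse_deposition(5, ref_worker)
  dep$ET2 <- 0.1 # forced value for the worked example
  comp <- apportion_deposit(dep, c(ETseq = 0.002, BBseq = 0.002,
                                   bbseq = 0.002))
  expect_equal(unname(comp["ETseq"]), 0.0002)
  expect_equal(unname(comp["ET2prime"]), 0.0998)

  comp0 <- apportion_deposit(dep, c(ETseq = 0, BBseq = 0, bbseq = 0))
  expect_equal(unname(comp0[c("ETseq", "BBseq", "bbseq")]), rep(0, 3))

  set.seed(5)
  for (rep in 1:10) {
    fd <- setNames(runif(3, 0, 0.5), c("ETseq", "BBseq", "bbseq"))
    d <- monodisperse_deposition(exp(runif(1, log(0.1), log(20))), ref_worker)
    comp <- apportion_deposit(d, fd)
    expect_equal(sum(comp), sum(unlist(d[c("ET1", "ET2", "BB", "bb", "AI")])),
                 tolerance = 1e-12)
    expect_equal(unname(comp["INT"]), 0)
  }
  expect_error(apportion_deposit(dep, c(ETseq = 1)), "f_d")
})
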
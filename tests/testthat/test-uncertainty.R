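params <- reference_parameter_table()
specs <- attr(params, "specs")

test_that("the uncertain-parameter set transcribes all eighteen entries", {
  expect_equal(nrow(params), 18L)
  fn <- specs$Fn
  expect_equal(fn$family, "triangular")
  expect_equal(c(fn$min, fn$mode, fn$max), c(0.4, 1, 1))
  expect_equal(specs$Cae_ET1[c("gm", "gsd")], list(gm = 1, gsd = 1.82))
  expect_equal(specs$Cae_AI$gsd, 1.3)
  expect_equal(specs$Cth_ET1$gsd, 1.18)
  expect_equal(specs$fd_ETseq[c("gm", "gsd")], list(gm = 0.002, gsd = 1.73))
  expect_equal(specs$L_ALV_INT[c("gm", "gsd")], list(gm = 0.001, gsd = 4.5))
  expect_equal(specs$L_ALV_bb[c("gm", "gsd")], list(gm = 0.002, gsd = 3.2))
  expect_equal(specs$L_INT_LNTH[c("gm", "gsd")],
               list(gm = 0.00003, gsd = 3))
  expect_equal(specs$K_factor[c("gm", "gsd")], list(gm = 1, gsd = 1.73))
  # bindings cover every stochastic slot
  expect_setequal(
    params$binding,
    c("fn", "kpt", paste0("cae.", c("ET1", "ET2", "BB", "bb", "AI")),
      paste0("cth.", c("ET1", "ET2", "BB", "bb", "AI")),
      paste0("fd.", c("ETseq", "BBseq", "bbseq")),
      "rate.alv_int", "rate.alv_bb", "rate.int_lnth"))
})

test_that("inverse CDFs hit medians, support endpoints and the true CDF", {
  ln <- dist_spec("lognormal", gm = 1, gsd = 1.82)
  expect_equal(quantile_dist(ln, 0.5), 1)
  tri <- dist_spec("triangular", min = 0.4, mode = 1, max = 1)
  expect_equal(quantile_dist(tri, 0), 0.4)
  expect_equal(quantile_dist(tri, 1), 1)
  # right-triangular CDF form F(x) = (x-min)^2 / ((max-min)(mode-min))
  x <- quantile_dist(tri, 0.49)
  expect_equal((x - 0.4) ^ 2 / (0.6 * 0.6), 0.49, tolerance = 1e-12)
  expect_error(dist_spec("lognormal", gm = -1, gsd = 2), "gm")
  expect_error(dist_spec("triangular", min = 1, mode = 0.5, max = 2), "min")
})

test_that("quantiles invert the CDF to bisection accuracy", {
  bisect <- function(cdf, u, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (cdf(mid) < u) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }
  ln <- dist_spec("lognormal", gm = 1, gsd = 1.73)
  for (u in c(0.025, 0.31, 0.5, 0.83, 0.975)) {
    expect_equal(quantile_dist(ln, u),
                 bisect(function(x) cdf_dist(ln, x), u, 1e-6, 1e6),
                 tolerance = 1e-10)
  }
  tri <- dist_spec("triangular", min = 0.4, mode = 0.7, max = 1.1)
  for (u in c(0.05, 0.4, 0.77, 0.99)) {
    expect_equal(quantile_dist(tri, u),
                 bisect(function(x) cdf_dist(tri, x), u, 0.4, 1.1),
                 tolerance = 1e-10)
  }
})

test_that("latin hypercube designs are stratified in every column", {
  d2 <- lhs_design(params, n = 2, seed = 1)
  for (j in colnames(d2)) {
    u <- cdf_dist(specs[[j]], d2[, j])
    expect_true(min(u) < 0.5 && max(u) >= 0.5)
  }
  d4 <- lhs_design(params, n = 4, seed = 2)
  for (j in colnames(d4)) {
    u <- cdf_dist(specs[[j]], d4[, j])
    expect_setequal(ceiling(u * 4), 1:4)
  }
  for (n in c(1, 3, 7, 25, 100)) {
    d <- lhs_design(params, n = n, seed = n)
    for (j in colnames(d)) {
      u <- cdf_dist(specs[[j]], d[, j])
      expect_setequal(ceiling(u * n), seq_len(n))
    }
  }
  expect_error(lhs_design(params, n = 0), "n must be")
})

test_that("designs are bit-reproducible by seed and statistically sane", {
  a <- lhs_design(params, n = 200, seed = 99)
  b <- lhs_design(params, n = 200, seed = 99)
  expect_identical(unclass(a), unclass(b))
  big <- lhs_design(params, n = 1e4, seed = 11)
  expect_equal(median(big[, "K_factor"]), 1, tolerance = 0.02)
  # stratified lognormal sampling recovers the log-scale spread
  expect_equal(sd(log(big[, "K_factor"])), log(1.73), tolerance = 0.01)
})

test_that("the precision-driven sample size follows the normal formula", {
  expect_equal(required_sample_size(sd = 1, precision = 1), 4L)
  expect_equal(required_sample_size(sd = 0, precision = 0.1), 1L)
  expect_error(required_sample_size(1, 0), "positive")
  n <- required_sample_size(sd = 1, precision = 0.2)
  expect_equal(n, ceiling((qnorm(0.975) / 0.2) ^ 2))
  # the returned n actually delivers the requested CI half-width
  set.seed(77)
  hw <- replicate(500, {
    x <- rnorm(n)
    qnorm(0.975) * sd(x) / sqrt(n)
  })
  expect_equal(mean(hw), 0.2, tolerance = 0.02)
})

test_that("a point-mass design propagates to the deterministic value", {
  sp <- fixture_s_pair()
  det <- deterministic_cedc(s_pair = sp)$E
  neutral <- c(Fn = 1, Cae_ET1 = 1, Cae_ET2 = 1, Cae_BB = 1, Cae_bb = 1,
               Cae_AI = 1, Cth_ET1 = 1, Cth_ET2 = 1, Cth_BB = 1, Cth_bb = 1,
               Cth_AI = 1, fd_ETseq = 0.002, fd_BBseq = 0.002,
               fd_bbseq = 0.002, L_ALV_INT = 0.001, L_ALV_bb = 0.002,
               L_INT_LNTH = 0.00003, K_factor = 1)
  design <- matrix(rep(neutral, each = 3), nrow = 3,
                   dimnames = list(NULL, names(neutral)))
  attr(design, "params") <- params
  cedc <- propagate(design, s_pair = sp)
  expect_equal(as.numeric(cedc), rep(det, 3), tolerance = 1e-12)
  expect_equal(summarize_cedc(cedc)$sd, 0)
  expect_error(best_fit_distribution(rep(1, 60)), "degenerate")
})

test_that("a small propagation is positive and bit-reproducible", {
  sp <- fixture_s_pair()
  d <- lhs_design(params, n = 16, seed = 5)
  a <- propagate(d, s_pair = sp)
  b <- propagate(d, s_pair = sp)
  expect_identical(as.numeric(a), as.numeric(b))
  expect_length(as.numeric(a), 16)
  expect_true(all(as.numeric(a) > 0))
})

test_that("summary statistics match an order-statistic oracle", {
  const <- summarize_cedc(rep(3.5, 10))
  expect_equal(const$mean, 3.5)
  expect_equal(const$sd, 0)
  expect_equal(const$q2.5, 3.5)
  expect_equal(const$q97.5, 3.5)

  x <- sample(1:100)
  s <- summarize_cedc(x)
  oracle <- function(p) {
    xs <- sort(x)
    h <- (length(xs) - 1) * p + 1
    lo <- floor(h)
    xs[lo] + (h - lo) * (xs[min(lo + 1, length(xs))] - xs[lo])
  }
  expect_equal(s$q2.5, oracle(0.025))
  expect_equal(s$q25, oracle(0.25))
  expect_equal(s$q50, oracle(0.5))
  expect_equal(s$q75, oracle(0.75))
  expect_equal(s$q97.5, oracle(0.975))
  expect_equal(s$sd, sd(x))
  expect_error(summarize_cedc(numeric(0)), "empty")
})

test_that("the K-S statistic equals the explicit sup-distance", {
  set.seed(12)
  for (rep in 1:20) {
    x <- rnorm(200, mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    cdf <- function(q) pnorm(q, 0.3, 1.2)
    D <- unname(suppressWarnings(ks.test(x, cdf)$statistic))
    expect_equal(D, ks_distance_oracle(x, cdf), tolerance = 1e-12)
  }
  # quantile-matched sample attains the minimal distance 1/(2n)
  n <- 40
  x <- qnorm((seq_len(n) - 0.5) / n)
  D <- unname(suppressWarnings(ks.test(x, pnorm)$statistic))
  expect_equal(D, 1 / (2 * n), tolerance = 1e-12)
})

test_that("distribution fitting recovers a known generator", {
  set.seed(2025)
  x <- rnorm(5000)
  fits <- suppressWarnings(best_fit_distribution(
    x, candidates = c("normal", "lognormal", "gamma", "loggamma", "uniform")))
  expect_equal(fits$family[1], "normal")
  expect_true(fits$accepted[1])
  expect_true(all(fits$D >= 0 & fits$D <= 1))
  expect_true(all(fits$p >= 0 & fits$p <= 1))
  expect_error(best_fit_distribution(rnorm(10)), "at least 50")
})

test_that("lognormal data land in the log-family group", {
  set.seed(31)
  x <- rlnorm(3000, meanlog = -18, sdlog = 0.1)
  fits <- suppressWarnings(best_fit_distribution(
    x, candidates = c("normal", "lognormal", "loggamma", "uniform")))
  expect_true(fits$family[1] %in% c("lognormal", "loggamma"))
})

test_that("uncertainty factors are scale-free interval widths", {
  expect_equal(uncertainty_factor(2, 2, 2)$uf, 1)
  u <- uncertainty_factor(1.1e-8, 8.5e-9, 1.2e-8)
  expect_equal(u$uf, max(1.1 / 0.85, 1.2 / 1.1), tolerance = 1e-12)
  set.seed(4)
  for (rep in 1:10) {
    c0 <- runif(1, 0.5, 2); ql <- c0 * runif(1, 0.3, 1)
    qu <- c0 * runif(1, 1, 3); alpha <- exp(rnorm(1))
    expect_equal(uncertainty_factor(alpha * c0, alpha * ql, alpha * qu)$uf,
                 uncertainty_factor(c0, ql, qu)$uf, tolerance = 1e-12)
  }
  expect_error(uncertainty_factor(-1, 1, 1), "positive")
})
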
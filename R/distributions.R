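# Distribution specifications for the uncertain parameters (lognormal and
# triangular), their inverse CDFs for stratified sampling, and the family
# catalogue used when characterising the dose-coefficient distribution.

#' Distribution specification
#'
#' @param family `"lognormal"` or `"triangular"`.
#' @param ... for lognormal: `gm` (geometric mean / median > 0) and `gsd`
#'   (> 1); for triangular: `min`, `mode`, `max` with
#'   min <= mode <= max and min < max.
#' @return a `dist_spec` list.
#' @export
dist_spec <- function(family, ...) {
  args <- list(...)
  if (family == "lognormal") {
    gm <- args$gm; gsd <- args$gsd
    if (is.null(gm) || is.null(gsd) || gm <= 0 || gsd <= 1) {
      stop("lognormal spec needs gm > 0 and gsd > 1")
    }
    out <- list(family = "lognormal", gm = gm, gsd = gsd)
  } else if (family == "triangular") {
    mn <- args$min; md <- args$mode; mx <- args$max
    if (is.null(mn) || is.null(md) || is.null(mx) ||
        mn > md || md > mx || mn >= mx) {
      stop("triangular spec needs min <= mode <= max and min < max")
    }
    out <- list(family = "triangular", min = mn, mode = md, max = mx)
  } else {
    stop("unknown distribution family '", family, "'")
  }
  class(out) <- "dist_spec"
  out
}

#' Inverse CDF of a distribution specification
#'
#' For the triangular family the piecewise quadratic inverse is used; when
#' the mode coincides with the maximum the CDF is
#' F(x) = (x - min)^2 / ((max - min)(mode - min)) on the whole support.
#'
#' @param spec a [dist_spec()].
#' @param u probabilities in \[0, 1\] (vectorised).
#' @return quantile values.
#' @export
quantile_dist <- function(spec, u) {
  if (!inherits(spec, "dist_spec")) stop("spec must be a dist_spec")
  if (any(u < 0 | u > 1)) stop("u must lie in [0, 1]")
  if (spec$family == "lognormal") {
    return(qlnorm(u, meanlog = log(spec$gm), sdlog = log(spec$gsd)))
  }
  a <- spec$min; m <- spec$mode; b <- spec$max
  fc <- (m - a) / (b - a)
  lower <- a + sqrt(u * (b - a) * (m - a))
  upper <- b - sqrt((1 - u) * (b - a) * (b - m))
  ifelse(u <= fc, lower, upper)
}

#' CDF of a distribution specification
#' @inheritParams quantile_dist
#' @param x quantiles (vectorised).
#' @return probabilities.
#' @export
cdf_dist <- function(spec, x) {
  if (spec$family == "lognormal") {
    return(plnorm(x, meanlog = log(spec$gm), sdlog = log(spec$gsd)))
  }
  a <- spec$min; m <- spec$mode; b <- spec$max
  p <- numeric(length(x))
  p[x >= b] <- 1
  mid1 <- x > a & x < b & (x <= m | m == b)
  p[mid1] <- (x[mid1] - a) ^ 2 / ((b - a) * (m - a))
  mid2 <- x > a & x < b & x > m & m < b
  p[mid2] <- 1 - (b - x[mid2]) ^ 2 / ((b - a) * (b - m))
  p
}

# ---- family catalogue for sample characterisation --------------------------
#
# Each entry fits its parameters by maximum likelihood (closed form where it
# exists) and exposes the fitted CDF for the one-sample K-S test. The
# log-gamma family is parameterised as X = exp(c + G), G ~ gamma(shape,
# rate): log X follows a shifted gamma, a right-skewed family on the log
# scale.

fit_family <- function(family, x) {
  n <- length(x)
  switch(family,
    normal = {
      pars <- list(mean = mean(x), sd = sd(x) * sqrt((n - 1) / n))
      list(params = pars, cdf = function(q) pnorm(q, pars$mean, pars$sd))
    },
    uniform = {
      pars <- list(min = min(x), max = max(x))
      list(params = pars, cdf = function(q) punif(q, pars$min, pars$max))
    },
    lognormal = {
      if (any(x <= 0)) stop("lognormal needs positive data")
      lx <- log(x)
      pars <- list(meanlog = mean(lx), sdlog = sd(lx) * sqrt((n - 1) / n))
      list(params = pars, cdf = function(q) plnorm(q, pars$meanlog, pars$sdlog))
    },
    gamma = {
      if (any(x <= 0)) stop("gamma needs positive data")
      sc <- mean(x) # fit on scaled data, transform the rate back
      ft <- fitdistrplus::fitdist(x / sc, "gamma")
      pars <- list(shape = unname(coef(ft)["shape"]),
                   rate = unname(coef(ft)["rate"]) / sc)
      list(params = pars, cdf = function(q) pgamma(q, pars$shape, pars$rate))
    },
    weibull = {
      if (any(x <= 0)) stop("weibull needs positive data")
      sc <- mean(x)
      ft <- fitdistrplus::fitdist(x / sc, "weibull")
      pars <- list(shape = unname(coef(ft)["shape"]),
                   scale = unname(coef(ft)["scale"]) * sc)
      list(params = pars, cdf = function(q) pweibull(q, pars$shape, pars$scale))
    },
    beta = {
      if (any(x <= 0 | x >= 1)) stop("beta needs data strictly inside (0, 1)")
      ft <- fitdistrplus::fitdist(x, "beta")
      pars <- as.list(coef(ft))
      list(params = pars, cdf = function(q) pbeta(q, pars$shape1, pars$shape2))
    },
    loggamma = {
      if (any(x <= 0)) stop("log-gamma needs positive data")
      lx <- log(x)
      nll <- function(th) {
        shape <- exp(th[1]); rate <- exp(th[2])
        c0 <- min(lx) - exp(th[3])
        -sum(dgamma(lx - c0, shape = shape, rate = rate, log = TRUE))
      }
      init <- c(log(2), log(2 / max(sd(lx), 1e-12)), log(sd(lx) + 1e-12))
      opt <- optim(init, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000))
      pars <- list(shape = exp(opt$par[1]), rate = exp(opt$par[2]),
                   c = min(lx) - exp(opt$par[3]))
      list(params = pars,
           cdf = function(q) {
             p <- numeric(length(q))
             pos <- q > 0
             p[pos] <- pgamma(log(q[pos]) - pars$c, shape = pars$shape,
                              rate = pars$rate)
             p
           })
    },
    triangular = {
      rng <- diff(range(x))
      nll <- function(th) {
        a <- min(x) - exp(th[1]); b <- max(x) + exp(th[2])
        m <- a + (b - a) / (1 + exp(-th[3]))
        d <- ifelse(x <= m, 2 * (x - a) / ((b - a) * (m - a)),
                    2 * (b - x) / ((b - a) * (b - m)))
        if (any(d <= 0) || !all(is.finite(d))) return(1e10)
        -sum(log(d))
      }
      init <- c(log(rng / 10), log(rng / 10), 0)
      opt <- optim(init, nll, method = "Nelder-Mead",
                   control = list(maxit = 2000))
      a <- min(x) - exp(opt$par[1]); b <- max(x) + exp(opt$par[2])
      m <- a + (b - a) / (1 + exp(-opt$par[3]))
      spec <- dist_spec("triangular", min = a, mode = m, max = b)
      list(params = list(min = a, mode = m, max = b),
           cdf = function(q) cdf_dist(spec, q))
    },
    stop("unknown candidate family '", family, "'")
  )
}

hd_candidate_families <- c("normal", "lognormal", "gamma", "loggamma",
                           "beta", "weibull", "triangular", "uniform")
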
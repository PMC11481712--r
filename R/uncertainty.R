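# Latin-hypercube uncertainty propagation over the eighteen uncertain
# respiratory-tract parameters, summary statistics of the resulting dose
# coefficient sample, distribution characterisation by one-sample
# Kolmogorov-Smirnov fitting, and uncertainty factors.

#' The eighteen uncertain-parameter distributions
#'
#' Bundled transcription of the stochastic parameter set: the nasal
#' fraction of inhaled air (triangular), ten lognormal multipliers on the
#' regional aerodynamic/thermodynamic deposition efficiencies, three
#' lognormal sequestered-deposit fractions, the three alveolar-interstitial
#' clearance rates, and the particle-transport scale factor K_factor.
#'
#' @return an `uncertain_parameter_set`: data frame with columns `name`,
#'   `family`, `binding` and a `specs` attribute holding one [dist_spec()]
#'   per row.
#' @export
reference_parameter_table <- function() {
  tab <- hd_read_csv("uncertain_parameters.csv")
  if (nrow(tab) != 18L) stop("expected exactly 18 uncertain parameters")
  specs <- lapply(seq_len(nrow(tab)), function(i) {
    if (tab$family[i] == "lognormal") {
      dist_spec("lognormal", gm = tab$p1[i], gsd = tab$p2[i])
    } else {
      dist_spec("triangular", min = tab$p1[i], mode = tab$p2[i],
                max = tab$p3[i])
    }
  })
  names(specs) <- tab$name
  out <- tab[, c("name", "family", "binding", "provenance")]
  attr(out, "specs") <- specs
  class(out) <- c("uncertain_parameter_set", "data.frame")
  out
}

#' Latin hypercube design over an uncertain-parameter set
#'
#' The unit hypercube is sampled with one point in each of the n
#' equal-probability strata per column (strata order permuted independently
#' per column, position within a stratum uniform), then mapped through each
#' parameter's inverse CDF. Reproducible by seed.
#'
#' @param params an `uncertain_parameter_set`
#'   (default [reference_parameter_table()]).
#' @param n number of samples (>= 1).
#' @param seed integer seed.
#' @return a `design_matrix`: n x p numeric matrix with parameter-name
#'   columns and attributes `seed` and `params`.
#' @export
lhs_design <- function(params = reference_parameter_table(), n, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  specs <- attr(params, "specs")
  p <- length(specs)
  u <- with_seed(seed, lhs::randomLHS(as.integer(n), p))
  x <- vapply(seq_len(p), function(j) quantile_dist(specs[[j]], u[, j]),
              numeric(n))
  x <- matrix(x, nrow = n, dimnames = list(NULL, names(specs)))
  structure(x, seed = as.integer(seed), params = params,
            class = c("design_matrix", class(x)))
}

#' Sample size for a target precision of the mean
#'
#' n = ceiling((z_(1+conf)/2 * sd / E)^2), at least 1: the classical
#' normal-approximation sample size so that the half-width of the
#' confidence interval for the mean is at most E.
#'
#' @param sd anticipated standard deviation of the response.
#' @param precision desired half-width E, in the response units (> 0).
#' @param confidence confidence level in (0, 1); default 0.95.
#' @return integer sample size.
#' @export
required_sample_size <- function(sd, precision, confidence = 0.95) {
  if (precision <= 0) stop("precision must be positive")
  if (sd < 0) stop("sd must be non-negative")
  if (confidence <= 0 || confidence >= 1) stop("confidence must be in (0, 1)")
  z <- qnorm((1 + confidence) / 2)
  max(1L, as.integer(ceiling((z * sd / precision) ^ 2)))
}

# translate one design row into the deterministic chain's bindings
bind_row <- function(row, params) {
  bindings <- params$binding
  cae <- cth <- c(ET1 = 1, ET2 = 1, BB = 1, bb = 1, AI = 1)
  f_d <- c(ETseq = 0.002, BBseq = 0.002, bbseq = 0.002)
  mods <- list(kpt = 1, l_alv_int = 0.001, l_alv_bb = 0.002,
               l_int_lnth = 0.00003)
  fn <- NULL
  for (i in seq_along(bindings)) {
    b <- bindings[i]
    v <- row[[params$name[i]]]
    if (b == "fn") {
      fn <- v
    } else if (b == "kpt") {
      mods$kpt <- v
    } else if (startsWith(b, "cae.")) {
      cae[sub("^cae\\.", "", b)] <- v
    } else if (startsWith(b, "cth.")) {
      cth[sub("^cth\\.", "", b)] <- v
    } else if (startsWith(b, "fd.")) {
      f_d[sub("^fd\\.", "", b)] <- v
    } else if (b == "rate.alv_int") {
      mods$l_alv_int <- v
    } else if (b == "rate.alv_bb") {
      mods$l_alv_bb <- v
    } else if (b == "rate.int_lnth") {
      mods$l_int_lnth <- v
    } else {
      stop("unresolved binding '", b, "'")
    }
  }
  list(multipliers = deposition_multipliers(cae = cae, cth = cth),
       f_d = f_d,
       modifiers = do.call(rate_modifiers, mods),
       fn = fn)
}

#' Propagate a design through the deterministic dose chain
#'
#' Each design row binds its eighteen values onto the model (efficiency
#' multipliers to the deposition model, sequestered fractions to the
#' deposit apportionment, the nasal fraction to the breathing scenario, the
#' three alveolar-interstitial rates and the K_factor scale to the
#' transport matrix) and evaluates the committed effective dose
#' coefficient. Systemic and dissolution rates stay at their reference
#' values.
#'
#' @param design a [lhs_design()] matrix.
#' @param aerosol an [aerosol_spec()].
#' @param s_pair an `s_table_pair`.
#' @param nuclide nuclide id.
#' @param tau commitment period, days.
#' @param tables rate tables (bundled by default).
#' @param weights tissue weighting factors.
#' @param progress print a dot every 100 rows.
#' @return a `cedc_sample`: numeric vector of committed effective dose
#'   coefficients (Sv/Bq), with the design kept as an attribute.
#' @export
propagate <- function(design, aerosol = aerosol_spec(amad = 5), s_pair,
                      nuclide = "I-131", tau = 18262.5,
                      tables = default_rate_tables(),
                      weights = tissue_weights(), progress = FALSE) {
  validate_s_table_pair(s_pair)
  params <- attr(design, "params")
  if (is.null(params)) stop("design carries no parameter set")
  n <- nrow(design)
  out <- numeric(n)
  for (i in seq_len(n)) {
    row <- as.list(design[i, ])
    bound <- tryCatch(bind_row(row, params), error = function(e) {
      stop("row ", i, ": ", conditionMessage(e), call. = FALSE)
    })
    out[i] <- tryCatch({
      res <- deterministic_cedc(
        aerosol = aerosol,
        scenario = worker_scenario(fn = bound$fn),
        s_pair = s_pair, nuclide = nuclide, tau = tau, weights = weights,
        multipliers = bound$multipliers, f_d = bound$f_d,
        modifiers = bound$modifiers, tables = tables
      )
      res$E
    }, error = function(e) {
      stop("propagation failed at row ", i, " (",
           paste(sprintf("%s=%.4g", params$name, unlist(row)),
                 collapse = ", "), "): ", conditionMessage(e),
           call. = FALSE)
    })
    if (progress && i %% 100 == 0) cat(".")
  }
  if (progress) cat("\n")
  structure(out, design = design, class = "cedc_sample")
}

#' Summary statistics of a dose-coefficient sample
#'
#' Mean, sample standard deviation (n - 1 denominator), minimum, maximum
#' and the 2.5th/25th/50th/75th/97.5th percentiles by linear interpolation
#' between order statistics.
#'
#' @param sample numeric vector (a `cedc_sample` or any non-empty vector).
#' @return a `cedc_summary` list.
#' @export
summarize_cedc <- function(sample) {
  x <- as.numeric(sample)
  if (length(x) == 0L) stop("empty sample")
  qs <- quantile(x, c(0.025, 0.25, 0.5, 0.75, 0.975), names = FALSE,
                 type = 7)
  structure(list(
    n = length(x), mean = mean(x), sd = if (length(x) > 1) sd(x) else 0,
    min = min(x), max = max(x),
    q2.5 = qs[1], q25 = qs[2], q50 = qs[3], q75 = qs[4], q97.5 = qs[5]
  ), class = "cedc_summary")
}

#' @export
print.cedc_summary <- function(x, ...) {
  cat("<dose-coefficient sample summary> n =", x$n, "\n")
  v <- unlist(x[-1])
  print(signif(v, 4))
  invisible(x)
}

#' Rank candidate distributions by Kolmogorov-Smirnov distance
#'
#' Fits each candidate family to the sample by maximum likelihood, runs a
#' one-sample two-sided K-S test of the sample against the fitted CDF, and
#' ranks the families by ascending sup-distance D. The best fit is
#' additionally required to have p > `alpha`; otherwise it is flagged.
#' Families that cannot be fitted (e.g. positive-support families on
#' negative data) are skipped with a warning.
#'
#' @param sample numeric vector with at least 50 observations.
#' @param candidates character vector of family names; default the bundled
#'   catalogue (normal, lognormal, gamma, log-gamma, beta, weibull,
#'   triangular, uniform).
#' @param alpha significance level for the flag (default 0.05).
#' @return a `dist_fit_ranking`: data frame `family`, `D`, `p`,
#'   `accepted`, ordered by D, with fitted parameters in attribute
#'   `params`.
#' @export
best_fit_distribution <- function(sample, candidates = hd_candidate_families,
                                  alpha = 0.05) {
  x <- as.numeric(sample)
  if (length(x) < 50L) stop("need at least 50 observations to characterise")
  if (length(candidates) == 0L) stop("candidate list must be non-empty")
  if (sd(x) == 0) stop("sample is degenerate (zero spread); nothing to fit")
  fits <- list()
  for (fam in candidates) {
    ft <- tryCatch(fit_family(fam, x), error = function(e) {
      warning("family '", fam, "' skipped: ", conditionMessage(e),
              call. = FALSE)
      NULL
    })
    if (is.null(ft)) next
    ks <- suppressWarnings(ks.test(x, ft$cdf))
    fits[[fam]] <- list(params = ft$params, D = unname(ks$statistic),
                        p = ks$p.value)
  }
  if (!length(fits)) stop("no candidate family could be fitted")
  tab <- data.frame(
    family = names(fits),
    D = vapply(fits, `[[`, numeric(1), "D"),
    p = vapply(fits, `[[`, numeric(1), "p"),
    row.names = NULL
  )
  tab <- tab[order(tab$D), ]
  tab$accepted <- tab$p > alpha
  attr(tab, "params") <- lapply(fits[tab$family], `[[`, "params")
  attr(tab, "alpha") <- alpha
  class(tab) <- c("dist_fit_ranking", "data.frame")
  tab
}

#' @export
print.dist_fit_ranking <- function(x, ...) {
  cat("<distribution fit ranking> (one-sample two-sided K-S)\n")
  print.data.frame(transform(x, D = signif(D, 3), p = signif(p, 3)))
  if (!x$accepted[1]) {
    cat("note: best family fails the p >", attr(x, "alpha"),
        "acceptance flag\n")
  }
  invisible(x)
}

#' Uncertainty factor around a central estimate
#'
#' UF = max(C / Q_L, Q_U / C) for a central estimate C and the 2.5th /
#' 97.5th percentile bounds: the multiplicative width of the ~95% interval
#' relative to the central value.
#'
#' @param central central estimate C (> 0).
#' @param q_l lower (2.5th percentile) bound (> 0).
#' @param q_u upper (97.5th percentile) bound (> 0).
#' @return a `uf_result` list with both ratios and `uf`.
#' @export
uncertainty_factor <- function(central, q_l, q_u) {
  for (v in c(central = central, q_l = q_l, q_u = q_u)) {
    if (!is.finite(v) || v <= 0) stop("all inputs must be positive")
  }
  structure(list(central = central, q_l = q_l, q_u = q_u,
                 ratio_lower = central / q_l, ratio_upper = q_u / central,
                 uf = max(central / q_l, q_u / central)),
            class = "uf_result")
}

#' @export
print.uf_result <- function(x, ...) {
  cat("<uncertainty factor>\n")
  cat(sprintf("  C = %.3g, Q_L = %.3g, Q_U = %.3g\n", x$central, x$q_l, x$q_u))
  cat(sprintf("  C/Q_L = %.2f, Q_U/C = %.2f, UF = %.2f\n",
              x$ratio_lower, x$ratio_upper, x$uf))
  invisible(x)
}
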
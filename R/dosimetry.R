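# Committed dose coefficients: time-integrated activity per source region
# combined with sex-specific S coefficients (Sv per nuclear transformation)
# into committed equivalent doses h(T), then tissue-weighted and
# sex-averaged into the committed effective dose coefficient E.

# Bq d -> nuclear transformations; the single place the unit conversion
# happens
SECONDS_PER_DAY <- 86400

#' Committed equivalent dose coefficients for one sex
#'
#' h(T) = sum over source regions S of U(S) x S(T <- S), with U converted
#' from Bq d to nuclear transformations.
#'
#' @param U an `integrated_activity` (Bq d per Bq intake) or named vector.
#' @param s one sex's S table: data frame with `source`, `target`,
#'   `S_Sv_per_transformation` covering every source in `U`.
#' @return named vector of committed equivalent dose per tissue (Sv/Bq).
#' @export
committed_equivalent_dose <- function(U, s) {
  u <- unclass(U)
  sm <- s_matrix(s)
  missing_sources <- setdiff(names(u), rownames(sm))
  if (length(missing_sources)) {
    stop("S table misses source region(s): ",
         paste(missing_sources, collapse = ", "))
  }
  transformations <- u * SECONDS_PER_DAY
  drop(transformations %*% sm[names(u), , drop = FALSE])
}

#' Sex-averaged committed effective dose coefficient
#'
#' E = sum over tissues of w_T (h_M(T) + h_F(T)) / 2.
#'
#' @param h_M,h_F named committed equivalent dose vectors (Sv/Bq) over the
#'   same tissue set.
#' @param w named tissue weighting factors; must sum to one and match the
#'   tissue set of `h_M`/`h_F`.
#' @return the committed effective dose coefficient (Sv/Bq).
#' @export
committed_effective <- function(h_M, h_F, w = tissue_weights()) {
  if (!setequal(names(h_M), names(h_F))) stop("tissue sets of h_M and h_F differ")
  if (!setequal(names(w), names(h_M))) {
    stop("tissue set of the weights differs from the dose vectors")
  }
  tiss <- names(w)
  sum(w * (h_M[tiss] + h_F[tiss]) / 2)
}

#' Deterministic committed effective dose coefficient
#'
#' The full deterministic chain per unit intake: polydisperse regional
#' deposition, apportionment onto transport compartments, assembly of the
#' coupled biokinetic system at reference rates (all multipliers one),
#' commitment integration and sex-averaged dosimetry.
#'
#' @param aerosol an [aerosol_spec()].
#' @param scenario a [worker_scenario()]; the reference worker by default.
#' @param s_pair an `s_table_pair` (real coefficients read with
#'   [read_s_table()], or the bundled synthetic stand-in).
#' @param nuclide nuclide id.
#' @param tau commitment period in days (50 y default).
#' @param weights tissue weighting factors.
#' @param multipliers,f_d,modifiers stochastic bindings; reference values
#'   by default, which makes the result deterministic.
#' @param tables rate tables (bundled models by default).
#' @return a `dose_coefficient_result`: list with `h_M`, `h_F`, `E`,
#'   `tau_days`, and the regional deposition used.
#' @export
deterministic_cedc <- function(aerosol = aerosol_spec(amad = 5),
                               scenario = worker_scenario(),
                               s_pair,
                               nuclide = "I-131",
                               tau = 18262.5,
                               weights = tissue_weights(),
                               multipliers = deposition_multipliers(),
                               f_d = c(ETseq = 0.002, BBseq = 0.002,
                                       bbseq = 0.002),
                               modifiers = rate_modifiers(),
                               tables = default_rate_tables()) {
  validate_s_table_pair(s_pair)
  regional <- polydisperse_deposition(aerosol, scenario, multipliers)
  deposit <- apportion_deposit(regional, f_d)
  system <- build_full_system(deposit, modifiers, tables, nuclide)
  U <- integrate_retention(system, tau = tau)
  h_M <- committed_equivalent_dose(U, s_pair$M)
  h_F <- committed_equivalent_dose(U, s_pair$F)
  E <- committed_effective(h_M, h_F, weights)
  structure(list(h_M = h_M, h_F = h_F, E = E, tau_days = tau,
                 deposition = regional, integrated_activity = U),
            class = "dose_coefficient_result")
}

#' @export
print.dose_coefficient_result <- function(x, ...) {
  cat("<committed dose coefficients> tau =", attr(x$integrated_activity,
                                                  "tau_days"), "d\n")
  cat("  E =", format(x$E, digits = 4), "Sv/Bq\n")
  top <- sort(x$h_M, decreasing = TRUE)
  cat("  largest male tissue coefficients:\n")
  print(signif(head(top, 3), 3))
  invisible(x)
}
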
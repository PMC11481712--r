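# Bundled reference constants: transfer-rate tables, deposition constants,
# tissue weighting factors, nuclide data. All tables ship as CSV under
# inst/extdata with a provenance string per entry; they are data, not code.

# compartment vocabulary shared by every rate table
hd_compartments <- c(
  "ET1", "ETseq", "ET2prime", "BBprime", "BBseq", "bbprime", "bbseq",
  "ALV", "INT", "LNET", "LNTH",
  "Oesophagus", "Gut",
  "Blood", "Thyroid", "RestOfBody", "UBcontents",
  "Environment", "Excreta"
)

# the eight particle-transport routes scaled together by the Kpt factor
hd_kpt_routes <- data.frame(
  source = c("ET1", "ET1", "ETseq", "ET2prime", "BBseq", "BBprime",
             "bbseq", "bbprime"),
  destination = c("ET2prime", "Environment", "LNET", "Oesophagus", "LNTH",
                  "ET2prime", "LNTH", "BBprime"),
  stringsAsFactors = FALSE
)

#' Load a bundled first-order transfer-rate table
#'
#' Rate tables are the model definition: each row is one first-order route
#' `source -> destination` with its transfer coefficient in d^-1 and a
#' provenance citation. Four tables are bundled: the respiratory-tract
#' particle-transport model (`hrtm_transport`), fast (Type F) dissolution to
#' blood (`typeF_dissolution`), the lumped alimentary link
#' (`alimentary_link`), and the iodine systemic model (`iodine_systemic`).
#'
#' @param model_name one of `"hrtm_transport"`, `"typeF_dissolution"`,
#'   `"alimentary_link"`, `"iodine_systemic"`.
#' @return a `ref_rate_table`: data frame with columns `source`,
#'   `destination`, `rate_per_day`, `kpt_scaled`, `provenance`.
#' @examples
#' tr <- load_reference_rates("hrtm_transport")
#' subset(tr, source == "ALV")
#' @export
load_reference_rates <- function(model_name) {
  tables <- c("hrtm_transport", "typeF_dissolution", "alimentary_link",
              "iodine_systemic")
  if (length(model_name) != 1L || !model_name %in% tables) {
    stop("unknown model_name '", paste(model_name, collapse = ","),
         "'; available tables: ", paste(tables, collapse = ", "))
  }
  tab <- hd_read_csv(paste0(model_name, ".csv"))
  validate_rate_table(tab, model_name)
  class(tab) <- c("ref_rate_table", "data.frame")
  attr(tab, "model_name") <- model_name
  tab
}

validate_rate_table <- function(tab, name = "rate table") {
  need <- c("source", "destination", "rate_per_day", "kpt_scaled", "provenance")
  if (!all(need %in% names(tab))) {
    stop(name, ": missing columns ", paste(setdiff(need, names(tab)),
                                           collapse = ", "))
  }
  ids <- unique(c(tab$source, tab$destination))
  bad <- setdiff(ids, hd_compartments)
  if (length(bad)) {
    stop(name, ": unknown compartment id(s): ", paste(bad, collapse = ", "))
  }
  if (any(!is.finite(tab$rate_per_day)) || any(tab$rate_per_day < 0)) {
    stop(name, ": all rates must be finite and >= 0")
  }
  if (any(!nzchar(tab$provenance))) {
    stop(name, ": every entry must carry a provenance citation")
  }
  scaled <- tab[tab$kpt_scaled, c("source", "destination")]
  if (nrow(scaled)) {
    key <- function(d) paste(d$source, d$destination, sep = "->")
    if (!setequal(key(scaled), key(hd_kpt_routes)) ||
        nrow(scaled) != nrow(hd_kpt_routes)) {
      stop(name, ": the Kpt-scaled subset must be exactly the eight ",
           "particle-transport routes")
    }
  }
  invisible(tab)
}

#' @export
print.ref_rate_table <- function(x, ...) {
  cat("<reference rate table: ", attr(x, "model_name"), "> ",
      nrow(x), " routes\n", sep = "")
  print.data.frame(x[, c("source", "destination", "rate_per_day",
                         "kpt_scaled")], ...)
  invisible(x)
}

#' Query the provenance of a bundled constant
#'
#' Every bundled constant is reachable through a provenance query returning
#' its source citation.
#'
#' @param table a data frame with a `provenance` column, as returned by the
#'   loaders in this package.
#' @param ... name/value filters on the remaining columns, e.g.
#'   `source = "ALV", destination = "INT"`.
#' @return character vector of citations for the matching rows.
#' @export
provenance <- function(table, ...) {
  if (!"provenance" %in% names(table)) stop("table carries no provenance")
  filters <- list(...)
  keep <- rep(TRUE, nrow(table))
  for (nm in names(filters)) {
    if (!nm %in% names(table)) stop("no column '", nm, "' to filter on")
    keep <- keep & table[[nm]] %in% filters[[nm]]
  }
  table$provenance[keep]
}

#' Tissue weighting factors
#'
#' Bundled effective-dose tissue weighting factors w_T; they are
#' non-negative and sum to one.
#'
#' @return named numeric vector of w_T by tissue.
#' @export
tissue_weights <- function() {
  tab <- hd_read_csv("tissue_weights.csv")
  w <- setNames(tab$w_t, tab$tissue)
  if (any(w < 0) || abs(sum(w) - 1) > 1e-9) {
    stop("tissue weights must be non-negative and sum to 1")
  }
  w
}

#' Nuclide physical data
#'
#' @param nuclide nuclide id, e.g. `"I-131"`.
#' @return list with `half_life_days` and the decay constant
#'   `lambda_per_day` = ln(2) / half-life.
#' @export
nuclide_data <- function(nuclide = "I-131") {
  tab <- hd_read_csv("nuclides.csv")
  row <- tab[tab$nuclide == nuclide, ]
  if (nrow(row) != 1L) {
    stop("unknown nuclide '", nuclide, "'; available: ",
         paste(tab$nuclide, collapse = ", "))
  }
  list(nuclide = nuclide, half_life_days = row$half_life_days,
       lambda_per_day = log(2) / row$half_life_days,
       provenance = row$provenance)
}

# mapping from biokinetic compartments to dosimetric source regions
source_region_map <- function() {
  hd_read_csv("source_region_map.csv")
}

#' Compare computed total deposition against a reference table
#'
#' For each aerosol size the percent relative difference
#' RD% = (calc - ref) / ref * 100 and the absolute difference in percentage
#' points of deposition AD = (calc - ref) * 100 are reported, the two
#' headline metrics of a deposition benchmark.
#'
#' @param calculated data frame with columns `amad_um` and `total` (fraction
#'   of inhaled activity, 0-1).
#' @param reference data frame with the same columns on the same AMAD grid;
#'   reference totals must be positive.
#' @return data frame with columns `amad_um`, `rd_percent`, `ad_pp`.
#' @examples
#' calc <- data.frame(amad_um = 5, total = 0.495)
#' ref  <- data.frame(amad_um = 5, total = 0.500)
#' benchmark_deposition(calc, ref)  # RD -1%, AD -0.5 pp
#' @export
benchmark_deposition <- function(calculated, reference) {
  for (nm in c("amad_um", "total")) {
    if (!nm %in% names(calculated) || !nm %in% names(reference)) {
      stop("both inputs need columns 'amad_um' and 'total'")
    }
  }
  calculated <- calculated[order(calculated$amad_um), ]
  reference <- reference[order(reference$amad_um), ]
  if (nrow(calculated) != nrow(reference) ||
      any(calculated$amad_um != reference$amad_um)) {
    stop("mismatched AMAD grids between calculated and reference tables")
  }
  if (any(reference$total <= 0)) stop("reference totals must be positive")
  data.frame(
    amad_um = calculated$amad_um,
    rd_percent = (calculated$total - reference$total) / reference$total * 100,
    ad_pp = (calculated$total - reference$total) * 100
  )
}
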
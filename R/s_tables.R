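# S-coefficient tables: radiation-weighted mean dose to a target tissue per
# nuclear transformation in a source region, per sex. Real tables are
# external reference data supplied as CSV; a synthetic generator is bundled
# so the full dose chain is testable without them.

#' Generate a synthetic S-coefficient table pair
#'
#' Produces a complete source x target x sex grid of strictly positive
#' S values (Sv per nuclear transformation) as a pure function of the seed.
#' The values are lognormal draws around `magnitude` with a mild self-dose
#' enhancement when a source region name matches a target tissue name; they
#' stand in for real dosimetric S-coefficient tables, which are external,
#' and carry no anatomical meaning.
#'
#' @param seed integer; identical seeds give bit-identical tables.
#' @param sources character vector of source region names.
#' @param targets character vector of target tissue names.
#' @param magnitude positive scale of the generated values (Sv per
#'   transformation); default 1e-15 is a plausible order for photon/beta
#'   self-irradiation of organ-scale masses.
#' @return an `s_table_pair`: list with data frames `M` and `F`, columns
#'   `source`, `target`, `S_Sv_per_transformation`, plus the seed.
#' @export
generate_synthetic_s_table <- function(seed, sources, targets,
                                       magnitude = 1e-15) {
  if (length(sources) == 0L || length(targets) == 0L) {
    stop("sources and targets must be non-empty")
  }
  stopifnot_scalar_number(magnitude, "magnitude", positive = TRUE)
  grid <- expand.grid(source = sources, target = targets,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  draw <- function(sex_shift) {
    n <- nrow(grid)
    vals <- with_seed(seed + sex_shift, {
      v <- magnitude * exp(rnorm(n, mean = 0, sd = 1))
      v * ifelse(grid$source == grid$target, 25, 1)
    })
    data.frame(grid, S_Sv_per_transformation = vals,
               stringsAsFactors = FALSE)
  }
  out <- list(M = draw(0L), F = draw(1L), seed = as.integer(seed),
              synthetic = TRUE)
  class(out) <- "s_table_pair"
  out
}

#' Read an S-coefficient table pair from CSV
#'
#' Expected columns: `source`, `target`, `sex` (M/F),
#' `S_Sv_per_transformation`. The grid must be complete for both sexes.
#'
#' @param path CSV file path.
#' @return an `s_table_pair` (see [generate_synthetic_s_table()]).
#' @export
read_s_table <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("source", "target", "sex", "S_Sv_per_transformation")
  if (!all(need %in% names(tab))) {
    stop("S-table must have columns ", paste(need, collapse = ", "))
  }
  out <- list(
    M = tab[tab$sex == "M", c("source", "target", "S_Sv_per_transformation")],
    F = tab[tab$sex == "F", c("source", "target", "S_Sv_per_transformation")],
    seed = NA_integer_, synthetic = FALSE
  )
  class(out) <- "s_table_pair"
  validate_s_table_pair(out)
  out
}

validate_s_table_pair <- function(pair) {
  sources <- unique(pair$M$source)
  targets <- unique(pair$M$target)
  for (sex in c("M", "F")) {
    tab <- pair[[sex]]
    if (any(tab$S_Sv_per_transformation < 0)) {
      stop("S values must be non-negative (sex ", sex, ")")
    }
    got <- paste(tab$source, tab$target)
    want <- as.vector(outer(sources, targets, paste))
    if (!setequal(got, want) || anyDuplicated(got)) {
      stop("incomplete or duplicated source x target grid (sex ", sex, ")")
    }
  }
  invisible(pair)
}

#' @export
print.s_table_pair <- function(x, ...) {
  cat("<S-coefficient table pair>",
      if (isTRUE(x$synthetic)) " (synthetic)" else "", "\n",
      "  sources: ", length(unique(x$M$source)),
      ", targets: ", length(unique(x$M$target)), "\n", sep = "")
  invisible(x)
}

# S map lookup as a sources x targets matrix for fast summation
s_matrix <- function(tab) {
  sources <- sort(unique(tab$source))
  targets <- sort(unique(tab$target))
  m <- matrix(NA_real_, length(sources), length(targets),
              dimnames = list(sources, targets))
  m[cbind(match(tab$source, sources), match(tab$target, targets))] <-
    tab$S_Sv_per_transformation
  if (anyNA(m)) stop("S-table grid incomplete")
  m
}
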
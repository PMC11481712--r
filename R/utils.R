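#' Evaluate an expression under a temporary RNG state
#'
#' Runs `expr` with the global random-number generator seeded to `seed` and
#' restores the previous RNG state afterwards, so seeded helpers are pure
#' functions of their seed and never perturb the caller's stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive per-stage child seeds from one run seed
#'
#' One global seed is expanded into reproducible child seeds by a fixed
#' affine scheme, so pipeline stages can be re-run in isolation with the
#' stream they saw inside the full run. Values stay below 2^31.
#'
#' @param seed integer run seed.
#' @param stage stage name, e.g. "lhs", "propagate", "sensitivity".
#' @return integer seed for the stage.
#' @export
stage_seed <- function(seed, stage) {
  offsets <- c(
    lhs = 101L, propagate = 211L, s_table = 307L,
    sensitivity = 401L, fit = 503L, export = 601L
  )
  if (!stage %in% names(offsets)) {
    stop("unknown stage '", stage, "'; known stages: ",
         paste(names(offsets), collapse = ", "))
  }
  (as.integer(seed) %% 1000000L) * 1000L + offsets[[stage]]
}

# path to a bundled table, failing loudly if the install is broken
hd_extdata <- function(file) {
  path <- system.file("extdata", file, package = "hrtmdose")
  if (identical(path, "")) stop("bundled data file not found: ", file)
  path
}

# memoised reader for the bundled CSVs (they are immutable per install)
hd_csv_cache <- new.env(parent = emptyenv())
hd_read_csv <- function(file) {
  if (is.null(hd_csv_cache[[file]])) {
    hd_csv_cache[[file]] <- read.csv(hd_extdata(file),
                                     stringsAsFactors = FALSE)
  }
  hd_csv_cache[[file]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop("'", name, "' must be a single finite number")
  }
  if (positive && x <= 0) stop("'", name, "' must be positive")
  invisible(x)
}
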
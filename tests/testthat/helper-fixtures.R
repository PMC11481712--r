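# Shared fixtures: all built in code at test time.

# the reference worker scenario, built once per test run
ref_worker <- worker_scenario()

ref_sources <- unique(hrtmdose:::source_region_map()$source_region)
ref_targets <- names(tissue_weights())

# small synthetic S-coefficient pair over the full source/target grids
fixture_s_pair <- function(seed = 7, magnitude = 1e-15) {
  generate_synthetic_s_table(seed, ref_sources, ref_targets, magnitude)
}

# a rate-table data frame in the bundled CSV layout
make_rate_table <- function(source, destination, rate,
                            kpt_scaled = FALSE) {
  data.frame(source = source, destination = destination,
             rate_per_day = rate,
             kpt_scaled = rep_len(kpt_scaled, length(source)),
             provenance = "test fixture", stringsAsFactors = FALSE)
}

empty_rate_table <- function() {
  data.frame(source = character(0), destination = character(0),
             rate_per_day = numeric(0), kpt_scaled = logical(0),
             provenance = character(0), stringsAsFactors = FALSE)
}

# three-compartment toy: ET1 -> ET2prime -> Blood -> Excreta
toy_tables <- function(k12 = 0.1, k2b = 0.3, kbe = 0.05) {
  list(
    transport = make_rate_table("ET1", "ET2prime", k12),
    dissolution = make_rate_table("ET2prime", "Blood", k2b),
    alimentary = empty_rate_table(),
    systemic = make_rate_table("Blood", "Excreta", kbe)
  )
}

# a single-compartment system with total outflow k and no decay sink split
single_compartment_system <- function(k, lambda = 0) {
  structure(list(compartments = "X",
                 A = matrix(-(k + lambda), 1, 1,
                            dimnames = list("X", "X")),
                 lambda = lambda, nuclide = "toy",
                 initial = c(X = 1)),
            class = "compartment_system")
}

# random closed first-order system: n compartments, non-negative
# off-diagonal rates, diagonals = -(column outflow) - lambda
random_system <- function(n, lambda = 0, density = 0.5) {
  A <- matrix(0, n, n)
  for (j in seq_len(n)) {
    for (i in seq_len(n)) {
      if (i != j && runif(1) < density) A[i, j] <- runif(1, 0, 2)
    }
  }
  diag(A) <- -colSums(A) - lambda
  comps <- paste0("C", seq_len(n))
  dimnames(A) <- list(comps, comps)
  x0 <- runif(n)
  x0 <- x0 / sum(x0)
  structure(list(compartments = comps, A = A, lambda = lambda,
                 nuclide = "toy", initial = setNames(x0, comps)),
            class = "compartment_system")
}

# literal deposition-efficiency recursion (divides by the previous stage
# efficiency; valid only for eta > 0): the independent oracle for the
# escape-fraction implementation
de_recursion_oracle <- function(eta, phi) {
  n <- length(eta)
  de <- numeric(n)
  de[1] <- phi[1] * eta[1]
  if (n > 1) {
    for (j in 2:n) {
      de[j] <- de[j - 1] * eta[j] * (phi[j] / phi[j - 1]) *
        (1 / eta[j - 1] - 1)
    }
  }
  de
}

# stage-by-stage sequential filter simulation tracking the surviving
# airborne concentration (handles eta = 0)
de_simulation_oracle <- function(eta, phi) {
  conc <- 1
  de <- numeric(length(eta))
  for (j in seq_along(eta)) {
    de[j] <- phi[j] * conc * eta[j]
    conc <- conc * (1 - eta[j])
  }
  de
}

# explicit one-sample two-sided K-S sup-distance over the sorted sample
ks_distance_oracle <- function(x, cdf) {
  x <- sort(x)
  n <- length(x)
  Fx <- cdf(x)
  max(abs(seq_len(n) / n - Fx), abs((seq_len(n) - 1) / n - Fx))
}

# conditional expectation of a single regression tree under the
# cover-weighted reference measure, following x on features in S
tree_expvalue_oracle <- function(tr, cover, x, S) {
  rec <- function(j) {
    if (tr$left[j + 1] < 0) return(tr$value[j + 1])
    d <- tr$feature[j + 1] + 1
    if (d %in% S) {
      if (x[d] <= tr$threshold[j + 1]) rec(tr$left[j + 1]) else
        rec(tr$right[j + 1])
    } else {
      l <- tr$left[j + 1]; r <- tr$right[j + 1]
      (cover[l + 1] * rec(l) + cover[r + 1] * rec(r)) / cover[j + 1]
    }
  }
  rec(0)
}

# brute-force Shapley values by coalition enumeration over all subsets
shapley_bruteforce <- function(tr, cover, x, M) {
  phi <- numeric(M)
  subsets <- lapply(0:(2 ^ M - 1), function(mask) {
    which(bitwAnd(mask, 2 ^ (seq_len(M) - 1)) > 0)
  })
  ev <- vapply(subsets, function(S) tree_expvalue_oracle(tr, cover, x, S),
               numeric(1))
  names(ev) <- vapply(subsets, function(S) paste(S, collapse = ","),
                      character(1))
  lookup <- function(S) ev[[match(paste(sort(S), collapse = ","),
                                  names(ev))]]
  for (i in seq_len(M)) {
    for (k in seq_along(subsets)) {
      S <- subsets[[k]]
      if (i %in% S) next
      w <- factorial(length(S)) * factorial(M - length(S) - 1) /
        factorial(M)
      phi[i] <- phi[i] + w * (lookup(c(S, i)) - lookup(S))
    }
  }
  phi
}
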
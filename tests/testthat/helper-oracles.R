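# Independent oracles for the gap test, kept deliberately free of the
# package's masking/median machinery.

# Non-overlap gap via pure min/max arithmetic: positive iff the two groups
# are disjoint intervals, in which case it equals the distance between them.
gap_oracle <- function(b1, b2) {
  max(min(b2) - max(b1), min(b1) - max(b2))
}

# Brute-force mask enumeration: is there ANY masking of at most m1 samples
# from group 1 and m2 from group 2 (never a whole group) whose remaining
# values are separated by at least d?
exhaustive_detect <- function(b1, b2, d, m1, m2) {
  subsets_up_to <- function(n, m) {
    out <- list(integer(0))
    for (k in seq_len(min(m, n - 1))) {
      out <- c(out, utils::combn(n, k, simplify = FALSE))
    }
    out
  }
  for (s1 in subsets_up_to(length(b1), m1)) {
    k1 <- if (length(s1)) b1[-s1] else b1
    for (s2 in subsets_up_to(length(b2), m2)) {
      k2 <- if (length(s2)) b2[-s2] else b2
      if (gap_oracle(k1, k2) >= d) return(TRUE)
    }
  }
  FALSE
}

# Small dataset builders -----------------------------------------------------

toy_design <- function(n1, n2, m = c(0, 0), range_constraints = NULL,
                       groups = c("A", "B")) {
  group_design(
    data.frame(
      sample_id = c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2))),
      group = rep(groups, c(n1, n2))
    ),
    mask_limits = m, range_constraints = range_constraints
  )
}

toy_dataset <- function(beta_rows, n1, n2, detp = NULL) {
  samples <- c(sprintf("a%d", seq_len(n1)), sprintf("b%d", seq_len(n2)))
  beta <- do.call(rbind, beta_rows)
  rownames(beta) <- names(beta_rows)
  colnames(beta) <- samples
  if (!is.null(detp)) {
    detp <- do.call(rbind, detp)
    dimnames(detp) <- dimnames(beta)
  }
  beta_dataset(beta, detp)
}

# Shared expensive fixtures, built once per test run ------------------------

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .fixture_cache)) {
    assign(key, force(expr), envir = .fixture_cache)
  }
  get(key, envir = .fixture_cache)
}

# Contamination-recovery scenario: high-precision planted sites, one fully
# contaminated sample per group.
contaminated_sim <- function(n_sites = 10000, seed = 101) {
  simulate_methylation(sim_config(
    n_sites = n_sites, contam_per_group = c(1, 1), contam_shift = 1,
    effect = 0.5, concentration = 200, missing_rate = 0,
    detection_fail_rate = 0, seed = seed
  ))
}

# Clean moderate-effect scenario used for monotonicity and oracle checks.
plain_sim <- function(n_sites = 10000, seed = 202) {
  simulate_methylation(sim_config(
    n_sites = n_sites, effect = 0.4, missing_rate = 0,
    detection_fail_rate = 0, seed = seed
  ))
}
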
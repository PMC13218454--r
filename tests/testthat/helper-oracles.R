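# Shared fixtures and independent oracles used across test files.

base_params <- function() default_parameters()

# Exhaustive path-enumeration oracle for small Markov chains: occupancy
# after k cycles as the sum over every explicit state sequence. Kept
# deliberately independent of run_cohort's matrix-product implementation.
enumerate_occupancy <- function(matrix, init, cycles) {
  n_states <- nrow(matrix)
  occ <- base::matrix(0, cycles + 1L, n_states,
                      dimnames = list(0:cycles, rownames(matrix)))
  occ[1, ] <- init
  for (k in seq_len(cycles)) {
    paths <- expand.grid(rep(list(seq_len(n_states)), k + 1L))
    for (r in seq_len(nrow(paths))) {
      seq_states <- as.integer(paths[r, ])
      prob <- init[seq_states[1]]
      for (step in seq_len(k)) {
        prob <- prob * matrix[seq_states[step], seq_states[step + 1L]]
      }
      occ[k + 1L, seq_states[k + 1L]] <- occ[k + 1L, seq_states[k + 1L]] + prob
    }
  }
  occ
}

# Truncated-normal mean on [lower, upper] in closed form.
truncnorm_mean <- function(mean, sd, lower, upper) {
  a <- (lower - mean) / sd
  b <- (upper - mean) / sd
  mean + sd * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

# Parameter set with every transition switched off: nobody moves, nobody
# dies. Useful for closed-form QALY checks.
frozen_params <- function() {
  p <- base_params()
  for (nm in names(p$transitions)) p$transitions[[nm]] <- 0
  p
}
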
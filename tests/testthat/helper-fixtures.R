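# Shared fixtures for the test suite.

# The headline parameter set of the equilibrium phase diagrams.
fig_params <- function(beta = 0.95, s = 0.3) {
  coop_params(N = 20, beta = beta, s = s, B = 1.435, C_G = 0.1, C_C = 0.2)
}

# A random point on the 6-genotype simplex (optionally with some genotypes
# forced to zero).
random_state <- function(zero = integer(0)) {
  x <- stats::rexp(6)
  x[zero] <- 0
  coop_state(x / sum(x))
}

# A random valid parameter set with small N (keeps enumeration cheap).
random_params <- function(max_N = 8) {
  repeat {
    C_G <- runif(1, 0, 0.5)
    C_C <- runif(1, 0, 0.5)
    if (1 - C_G - C_C > 0.05) break
  }
  coop_params(N = sample.int(max_N, 1), beta = runif(1), s = runif(1),
              B = runif(1, 0, 2), C_G = C_G, C_C = C_C,
              mu = sample(c(0, runif(1, 0, 0.2)), 1))
}

p_total_of <- function(state) plasmid_marginals(state)[["p_total"]]

traj_p_total <- function(traj) {
  rowSums(traj[, c("noncoop:coopP", "noncoop:defP",
                   "coop:coopP", "coop:defP")])
}
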
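# shared fixtures: the excitation parameterization used by the synthetic
# generators throughout the suite (chosen to produce seizure ensembles
# with varied recruitment extent and onsets spread over the 90 s window,
# with the star components inside the hyperprior's central band)
q_star <- function() excitation_params(-6, -2.5, 3, 5)

# a small cascade with hand-computable onsets: two nodes, w21 = 1,
# rates f(c1, 0) = 0.5, f(c2, 0) = 0.05, f(c2, 1) = 0.5
cascade_fixture <- function() {
  q <- excitation_params(0, log(0.5), 2, 0)
  list(q = q,
       c = c(log(0.5) - 1, log(0.05) - 1),
       W = connectome(matrix(c(0, 0, 1, 0), 2, 2, byrow = TRUE)))
}

# draw q from the hyperprior truncated to moderate values, giving
# well-behaved random instances for oracle comparisons
random_q <- function() {
  repeat {
    v <- c(stats::rnorm(2, 0, 30), abs(stats::rnorm(2, 0, 30)))
    if (all(abs(v) <= 3)) return(excitation_params(v[1], v[2], v[3], v[4]))
  }
}

# uniform excitatory coupling: q_ab >= q_aa with equal input slopes at
# both excitability anchors, so the rate is nondecreasing in the seizing
# input for every c -- the regime in which cascade monotonicity holds
excitatory_q <- function() {
  qaa <- stats::runif(1, -3, 1)
  qab <- qaa + stats::runif(1, 0, 3)
  s <- stats::runif(1, 0, 2)
  excitation_params(qaa, qab, s, s)
}
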
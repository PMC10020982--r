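# Shared fixtures built in code.

# fast demo clone: equilibrium (N*, A*, I*, E*) = (70, 28/3, 14/3, 30)
demo_clone <- function(...) {
  args <- list(b = 0.1, u = 0.2, r = 1, d_A = 0.5, d_I = 1)
  args[names(list(...))] <- list(...)
  do.call(clone_params, args)
}

demo_system <- function(..., K = 100) system_params(K, demo_clone(...))

# random persistent clone whose monoclonal equilibrium exists for K = 100:
# rates drawn log-uniformly, redrawn until r > d_A and E* < 0.9 K
random_viable_clone <- function(K = 100) {
  repeat {
    b <- exp(stats::runif(1, log(0.02), log(1)))
    u <- exp(stats::runif(1, log(0.05), log(1)))
    r <- exp(stats::runif(1, log(0.1), log(2)))
    d_A <- exp(stats::runif(1, log(0.05), log(2)))
    d_I <- exp(stats::runif(1, log(0.1), log(2)))
    cl <- clone_params(b, u, r, d_A, d_I)
    if (cl$r > cl$d_A * 1.05 &&
        empty_niche_equilibrium(cl) < 0.9 * K) return(cl)
  }
}

eq_state_of <- function(params) {
  eq <- monoclonal_equilibrium(params)
  make_state(params, eq$N_star, eq$A_star, eq$I_star)
}
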
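# Shared helpers. All fixtures are generated in code; nothing is read from
# disk.

# relative difference with an absolute floor so exact zeros compare cleanly
rel_diff <- function(a, b, floor = 1e-9) {
  max(abs(a - b) / (pmax(abs(a), abs(b)) + floor))
}

species_names <- c("W", "Wp", "WK", "WpP", "K", "P")

state_vec <- function(state) unclass(state)[species_names]

# parameter set from regime-style ratios: W_T = 1, k2 = 1, Km1 = kap1,
# Km2 = kap2, k1 fixed by the maximal-rate ratio v = k1*K_T/(k2*P_T)
quick_params <- function(eps_K, eps_P, v, kap1 = 1, kap2 = 1,
                         d1 = 1, d2 = 1, W_T = 1) {
  K_T <- eps_K * W_T
  P_T <- eps_P * W_T
  k1 <- v * P_T / K_T
  make_cycle_parameters(a1 = (d1 + k1) / (kap1 * W_T), d1 = d1, k1 = k1,
                        a2 = (d2 + 1) / (kap2 * W_T), d2 = d2, k2 = 1,
                        W_T = W_T, K_T = K_T, P_T = P_T)
}

# brute-force phosphoform distribution: enumerate all 2^n site patterns
enum_distribution <- function(p, n, total) {
  patterns <- expand.grid(rep(list(0:1), n))
  w <- apply(patterns, 1L, function(s) prod(ifelse(s == 1, p, 1 - p)))
  out <- tapply(w * total, rowSums(patterns), sum)
  as.numeric(out[as.character(0:n)])
}

# wide sampling across all regimes used by the oracle-equivalence and
# root-uniqueness suites (spec ranges)
wide_regime <- function(seed) {
  regime_spec("comparable", seed = seed,
              eps_K = c(1e-4, 10), eps_P = c(1e-4, 10),
              kappa = c(1e-3, 1e3), v_ratio = c(1e-3, 1e3))
}

solve_quietly <- function(params) {
  withCallingHandlers(solve_steady_state(params),
                      message = function(m) invokeRestart("muffleMessage"))
}
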
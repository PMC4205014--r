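# Seeded fixture generation: random parameter sets in the regimes the model
# contrasts, and synthetic "measured" steady states for the Km-recovery
# round trip. Everything is reproducible from an integer seed and nothing is
# read from disk.

# run code under a local RNG stream without disturbing the caller's state
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

runif_log <- function(n, lo, hi) exp(stats::runif(n, log(lo), log(hi)))

default_regime_ranges <- list(
  substrate_excess = list(eps_K = c(1e-4, 1e-3), eps_P = c(1e-4, 1e-3)),
  comparable       = list(eps_K = c(0.3, 3),     eps_P = c(0.3, 3)),
  phosphatase_excess = list(eps_K = c(1e-3, 1),  eps_P = c(1, 10))
)

#' Specify a sampling regime for random parameter sets
#'
#' Regimes mirror the concentration contrasts the model distinguishes:
#' `substrate_excess` (both enzyme totals at most `1e-3` of the substrate —
#' the Goldbeter-Koshland regime), `comparable` (enzyme:substrate ratios in
#' `[0.3, 3]`, where sequestration matters) and `phosphatase_excess`.
#' All quantities are sampled log-uniformly within their ranges.
#'
#' @param name one of `"substrate_excess"`, `"comparable"`,
#'   `"phosphatase_excess"`.
#' @param seed integer seed for reproducibility.
#' @param eps_K,eps_P ranges (length-2) for the enzyme:substrate ratios;
#'   defaults depend on `name`.
#' @param kappa range for both normalized Michaelis constants
#'   (default `c(1e-3, 1e3)`).
#' @param v_ratio range for the maximal-rate ratio `k1*K_T/(k2*P_T)`
#'   (default `c(1e-3, 1e3)`).
#' @param d_rate range for the dissociation rates `d1`, `d2`
#'   (default `c(0.1, 10)`).
#' @return List of class `regime_spec`.
#' @export
regime_spec <- function(name = c("substrate_excess", "comparable",
                                 "phosphatase_excess"),
                        seed = 1L,
                        eps_K = NULL, eps_P = NULL,
                        kappa = c(1e-3, 1e3),
                        v_ratio = c(1e-3, 1e3),
                        d_rate = c(0.1, 10)) {
  name <- match.arg(name)
  defaults <- default_regime_ranges[[name]]
  if (is.null(eps_K)) eps_K <- defaults$eps_K
  if (is.null(eps_P)) eps_P <- defaults$eps_P
  ranges <- list(eps_K = eps_K, eps_P = eps_P, kappa = kappa,
                 v_ratio = v_ratio, d_rate = d_rate)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || any(r <= 0) || r[2] < r[1]) {
      pc_stop("pc_invalid_regime",
              sprintf("range %s must be positive, finite, ordered", nm))
    }
  }
  structure(c(list(name = name, seed = as.integer(seed)), ranges),
            class = "regime_spec")
}

#' Sample seeded random cycle parameter sets within a regime
#'
#' Concentrations are in units of the substrate total (`W_T = 1`) and time in
#' units of `1/k2` (`k2 = 1`); `k1` is derived from the sampled maximal-rate
#' ratio, the association rates from the sampled normalized Michaelis
#' constants. The draw is deterministic under the regime's seed.
#'
#' @param regime a [regime_spec()].
#' @param count number of parameter sets (positive integer).
#' @return List of [make_cycle_parameters()] objects.
#' @export
sample_parameters <- function(regime, count) {
  stopifnot(inherits(regime, "regime_spec"))
  count <- as.integer(count)
  if (count < 1L) pc_invalid_parameter("count must be >= 1")
  with_local_seed(regime$seed, {
    lapply(seq_len(count), function(i) {
      eps_K <- runif_log(1L, regime$eps_K[1], regime$eps_K[2])
      eps_P <- runif_log(1L, regime$eps_P[1], regime$eps_P[2])
      kap1 <- runif_log(1L, regime$kappa[1], regime$kappa[2])
      kap2 <- runif_log(1L, regime$kappa[1], regime$kappa[2])
      v <- runif_log(1L, regime$v_ratio[1], regime$v_ratio[2])
      d1 <- runif_log(1L, regime$d_rate[1], regime$d_rate[2])
      d2 <- runif_log(1L, regime$d_rate[1], regime$d_rate[2])
      W_T <- 1
      K_T <- eps_K * W_T
      P_T <- eps_P * W_T
      k2 <- 1
      k1 <- v * k2 * P_T / K_T
      make_cycle_parameters(
        a1 = (d1 + k1) / (kap1 * W_T), d1 = d1, k1 = k1,
        a2 = (d2 + k2) / (kap2 * W_T), d2 = d2, k2 = k2,
        W_T = W_T, K_T = K_T, P_T = P_T)
    })
  })
}

#' Generate a synthetic measured steady state
#'
#' Solves the closed-form steady state for `params` and multiplies each
#' measured species (`W`, `Wp`, `WK`, `WpP`) by independent lognormal noise
#' with unit mean and relative standard deviation `rel_noise`. Lognormal
#' noise keeps concentrations positive; `rel_noise = 0` returns the exact
#' steady state.
#'
#' @param params a [make_cycle_parameters()] object.
#' @param rel_noise relative standard deviation (>= 0).
#' @param seed integer seed.
#' @return A [measured_state()] (totals are the true totals of `params`).
#' @export
make_measured_state <- function(params, rel_noise = 0, seed = 1L) {
  if (!is.finite(rel_noise) || rel_noise < 0) {
    pc_invalid_parameter("rel_noise must be >= 0")
  }
  sol <- solve_steady_state(params)
  s <- unclass(sol$state)
  noise <- if (rel_noise > 0) {
    sdlog <- sqrt(log(1 + rel_noise^2))
    with_local_seed(seed, stats::rlnorm(4L, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  } else rep(1, 4L)
  noisy <- s[c("W", "Wp", "WK", "WpP")] * noise
  # noise can push a complex above its enzyme total; cap to keep the
  # measurement physically consistent
  noisy[["WK"]] <- min(noisy[["WK"]], params$K_T)
  noisy[["WpP"]] <- min(noisy[["WpP"]], params$P_T)
  measured_state(W = noisy[["W"]], Wp = noisy[["Wp"]],
                 WK = noisy[["WK"]], WpP = noisy[["WpP"]],
                 K_T = params$K_T, P_T = params$P_T, W_T = params$W_T,
                 rel_noise = rel_noise)
}
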
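#' Construct a cycle state
#'
#' The six species of the cycle: free substrate `W`, free phospho-substrate
#' `Wp`, kinase-substrate complex `WK`, phosphatase-phospho-substrate complex
#' `WpP`, free kinase `K`, free phosphatase `P`.
#'
#' @param W,Wp,WK,WpP,K,P nonnegative concentrations.
#' @return A named numeric vector of class `cycle_state`.
#' @export
make_cycle_state <- function(W, Wp, WK, WpP, K, P) {
  x <- c(W = W, Wp = Wp, WK = WK, WpP = WpP, K = K, P = P)
  stopifnot_finite(x, "cycle state")
  if (any(x < 0)) {
    pc_invalid_state(sprintf("negative concentration(s): %s",
                             paste(names(x)[x < 0], collapse = ", ")))
  }
  structure(x, class = "cycle_state")
}

#' Default initial condition: resting cell
#'
#' All substrate unphosphorylated and free, all enzyme free, no complexes.
#'
#' @param params a [make_cycle_parameters()] object.
#' @return A `cycle_state`.
#' @export
default_initial_state <- function(params) {
  make_cycle_state(W = params$W_T, Wp = 0, WK = 0, WpP = 0,
                   K = params$K_T, P = params$P_T)
}

#' Mass-action right-hand side of the cycle ODEs
#'
#' Time derivatives of all six species under
#' `W + K <-> WK -> Wp + K` and `Wp + P <-> WpP -> W + P`.
#' The three conservation sums (`dW+dWp+dWK+dWpP`, `dK+dWK`, `dP+dWpP`) are
#' zero by construction of the returned vector, not merely numerically.
#'
#' @param state a [make_cycle_state()] vector (or any named nonnegative
#'   vector with the six species).
#' @param params a [make_cycle_parameters()] object.
#' @return Named numeric vector of derivatives (conc/time).
#' @export
reaction_rhs <- function(state, params) {
  s <- unclass(state)
  if (any(s < 0)) pc_invalid_state("negative concentration in state")
  bind1 <- params$a1 * s[["W"]] * s[["K"]]   # W + K -> WK
  diss1 <- params$d1 * s[["WK"]]             # WK -> W + K
  cat1  <- params$k1 * s[["WK"]]             # WK -> Wp + K
  bind2 <- params$a2 * s[["Wp"]] * s[["P"]]  # Wp + P -> WpP
  diss2 <- params$d2 * s[["WpP"]]            # WpP -> Wp + P
  cat2  <- params$k2 * s[["WpP"]]            # WpP -> W + P
  dWK  <- bind1 - diss1 - cat1
  dWpP <- bind2 - diss2 - cat2
  c(W   = -bind1 + diss1 + cat2,
    Wp  = cat1 - bind2 + diss2,
    WK  = dWK,
    WpP = dWpP,
    K   = -dWK,
    P   = -dWpP)
}

#' Residuals of the three conservation laws
#'
#' @param state a cycle state.
#' @param params a [make_cycle_parameters()] object supplying the totals.
#' @return Named vector `(substrate, kinase, phosphatase)`:
#'   `W+Wp+WK+WpP - W_T`, `K+WK - K_T`, `P+WpP - P_T`.
#' @export
conservation_residuals <- function(state, params) {
  s <- unclass(state)
  c(substrate   = s[["W"]] + s[["Wp"]] + s[["WK"]] + s[["WpP"]] - params$W_T,
    kinase      = s[["K"]] + s[["WK"]] - params$K_T,
    phosphatase = s[["P"]] + s[["WpP"]] - params$P_T)
}
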
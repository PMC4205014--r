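# Classical Goldbeter-Koshland (zero-order ultrasensitivity) baseline.
# The approximation drops the Michaelis complexes from the substrate
# conservation law, which is justified only when both enzyme totals are far
# below the substrate total.

#' Inputs to the Goldbeter-Koshland function
#'
#' @param v1 maximal kinase rate `k1*K_T` (conc/time).
#' @param v2 maximal phosphatase rate `k2*P_T` (conc/time).
#' @param kappa1,kappa2 Michaelis constants normalized by the substrate total.
#' @return List of class `gk_inputs`.
#' @export
gk_inputs <- function(v1, v2, kappa1, kappa2) {
  x <- c(v1 = v1, v2 = v2, kappa1 = kappa1, kappa2 = kappa2)
  stopifnot_finite(x, "GK inputs")
  if (any(x < 0)) pc_invalid_parameter("GK inputs must be >= 0")
  structure(as.list(x), class = "gk_inputs")
}

#' @rdname gk_inputs
#' @param params a [make_cycle_parameters()] object to convert.
#' @export
gk_inputs_from_params <- function(params) {
  gk_inputs(v1 = params$k1 * params$K_T, v2 = params$k2 * params$P_T,
            kappa1 = params$Km1 / params$W_T, kappa2 = params$Km2 / params$W_T)
}

#' Goldbeter-Koshland phosphorylated fraction
#'
#' Steady-state modified fraction `phi` of the complex-free balance
#' `v1*(1-phi)/(kappa1 + 1 - phi) = v2*phi/(kappa2 + phi)`, i.e. the root in
#' `[0, 1]` of `(v1-v2)*phi^2 + B*phi - v1*kappa2` with
#' `B = v2 - v1 + kappa1*v2 + kappa2*v1`, evaluated with the
#' cancellation-free quadratic branch.
#'
#' @param inputs a [gk_inputs()] object.
#' @return The fraction in `[0, 1]`.
#' @export
gk_fraction <- function(inputs) {
  v1 <- inputs$v1; v2 <- inputs$v2
  j1 <- inputs$kappa1; j2 <- inputs$kappa2
  if (v1 == 0 && v2 == 0) {
    pc_stop("pc_indeterminate_switch", "v1 = v2 = 0: no flux either way")
  }
  if (v1 == 0) return(0)
  if (v2 == 0) return(1)
  a <- v1 - v2
  B <- v2 - v1 + j1 * v2 + j2 * v1
  cc <- -v1 * j2
  if (a == 0) {
    if (B == 0) {
      pc_stop("pc_indeterminate_switch",
              "v1 = v2 with kappa1 = kappa2 = 0: zero-order singular point")
    }
    return(min(1, max(0, -cc / B)))   # phi = kappa2/(kappa1 + kappa2)
  }
  disc <- B * B - 4 * a * cc
  if (disc < 0) disc <- 0
  q <- -(B + sign(B) * sqrt(disc)) / 2
  roots <- c(if (a != 0) q / a else NULL, if (q != 0) cc / q else 0)
  adm <- roots[roots >= -1e-12 & roots <= 1 + 1e-12]
  if (length(adm) == 0L) {
    pc_stop("pc_indeterminate_switch", "no GK root in [0, 1]")
  }
  min(1, max(0, adm[[1L]]))
}

#' Validity diagnostic for the Goldbeter-Koshland approximation
#'
#' The approximation requires both enzyme totals to be small relative to the
#' substrate total. Flags `valid` iff `max(K_T, P_T)/W_T <= threshold`.
#'
#' @param params a [make_cycle_parameters()] object.
#' @param threshold dimensionless enzyme:substrate ratio above which the
#'   complex-free assumption is deemed broken (default `0.01`, the regime in
#'   which agreement within 1% holds).
#' @return List of class `gk_validity`: `valid`, `eps_K`, `eps_P`,
#'   `threshold`.
#' @export
gk_validity_check <- function(params, threshold = 0.01) {
  eps_K <- params$K_T / params$W_T
  eps_P <- params$P_T / params$W_T
  structure(
    list(valid = max(eps_K, eps_P) <= threshold,
         eps_K = eps_K, eps_P = eps_P, threshold = threshold),
    class = "gk_validity")
}

#' @export
print.gk_validity <- function(x, ...) {
  cat(sprintf("<gk_validity> %s (eps_K = %g, eps_P = %g, threshold = %g)\n",
              if (x$valid) "valid" else "INVALID", x$eps_K, x$eps_P, x$threshold))
  invisible(x)
}
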
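# Distributive multisite phosphorylation with n independent, identical
# sites. Site-level kinetics are the single-site cycle applied to the site
# pool: a protein at concentration W_T with n sites carries a site
# concentration n*W_T, while the enzyme totals are unchanged. Site
# occupancies are then independent Bernoulli(p) draws, so the phosphoform
# classes are binomial.

#' Per-site phosphorylation probability of an n-site protein
#'
#' Solves the single-site closed form with the substrate total replaced by
#' the site total `n*W_T` (enzyme totals unchanged) and returns the
#' probability `p` that any given site is phosphorylated at steady state.
#'
#' @param params a [make_cycle_parameters()] object; `W_T` is the protein
#'   concentration.
#' @param n number of phosphorylation sites (positive integer).
#' @return `p` in `[0, 1]`, with the full site-level
#'   `steady_state_solution` attached as attribute `"solution"`.
#' @export
site_probability <- function(params, n) {
  n <- check_n_sites(n)
  site_params <- make_cycle_parameters(
    a1 = params$a1, d1 = params$d1, k1 = params$k1,
    a2 = params$a2, d2 = params$d2, k2 = params$k2,
    W_T = n * params$W_T, K_T = params$K_T, P_T = params$P_T)
  sol <- solve_steady_state(site_params)
  structure(sol$p, solution = sol)
}

check_n_sites <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1 || n != round(n)) {
    pc_invalid_parameter("n must be a single positive integer")
  }
  as.integer(n)
}

# Multiplicative recurrence: exact in double precision for n <= 60.
binomial_coefficients <- function(n) {
  out <- numeric(n + 1L)
  out[1L] <- 1
  for (m in seq_len(n)) out[m + 1L] <- out[m] * (n - m + 1) / m
  out
}

#' Binomial distribution of phosphoform classes
#'
#' With independent identical sites, the concentration of protein carrying
#' exactly `m` of `n` phosphorylated sites is
#' `total * choose(n, m) * p^m * (1-p)^(n-m)`.
#'
#' @param p per-site phosphorylation probability in `[0, 1]`.
#' @param n number of sites (positive integer).
#' @param total total protein concentration (>= 0).
#' @return Object of class `multisite_distribution`: list with `n`, `p`,
#'   `total` and `species`, a vector of `n + 1` concentrations named
#'   `m0 ... mn`.
#' @export
species_distribution <- function(p, n, total) {
  n <- check_n_sites(n)
  if (length(p) != 1L || !is.finite(p) || p < 0 || p > 1) {
    pc_stop("pc_invalid_probability", sprintf("p = %s is not in [0, 1]",
                                              format(p)))
  }
  if (!is.finite(total) || total < 0) {
    pc_invalid_parameter("total must be finite and >= 0")
  }
  m <- 0:n
  species <- total * binomial_coefficients(n) * p^m * (1 - p)^(n - m)
  names(species) <- paste0("m", m)
  structure(list(n = n, p = p, total = total, species = species),
            class = "multisite_distribution")
}

#' @export
print.multisite_distribution <- function(x, ...) {
  cat(sprintf("<multisite_distribution> n = %d, p = %.6g, total = %g\n",
              x$n, x$p, x$total))
  print(signif(x$species, 6))
  invisible(x)
}

#' @export
as.data.frame.multisite_distribution <- function(x, ...) {
  data.frame(n = x$n, p = x$p, m = 0:x$n,
             species_concentration = unname(x$species))
}

#' Write phosphoform distributions as CSV
#'
#' Columns `n,p,m,species_concentration`.
#'
#' @param dists a `multisite_distribution` or list of them.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_distribution_csv <- function(dists, path) {
  if (inherits(dists, "multisite_distribution")) dists <- list(dists)
  utils::write.csv(do.call(rbind, lapply(dists, as.data.frame)),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Effective Hill coefficient of a monotone dose-response
#'
#' Model-free steepness measure `n_H = log(81) / log(EC90/EC10)`, where EC10
#' and EC90 are the doses at which the response reaches 10% and 90% of its
#' maximum, obtained by monotone linear interpolation of response against
#' log-dose.
#'
#' @param dose strictly increasing positive stimulus values.
#' @param response response values, monotone non-decreasing in `dose`,
#'   spanning both 10% and 90% of their own maximum within the grid.
#' @return The Hill coefficient estimate (scalar).
#' @export
effective_hill <- function(dose, response) {
  if (length(dose) != length(response) || length(dose) < 3L) {
    pc_invalid_parameter("dose and response must be equal-length vectors (>= 3)")
  }
  if (any(dose <= 0) || any(diff(dose) <= 0)) {
    pc_invalid_parameter("dose must be strictly increasing and positive")
  }
  rmax <- max(response)
  if (rmax <= 0) pc_stop("pc_coverage_error", "response is identically zero")
  if (any(diff(response) < -1e-9 * rmax)) {
    pc_stop("pc_monotonicity_error", "response is not monotone non-decreasing")
  }
  # monotone cubic (Hyman-filtered) interpolant of response on log-dose;
  # falls back to piecewise-linear if the spline cannot be built
  ld <- log(dose)
  resp_mono <- cummax(response)  # absorb sub-tolerance numeric wiggle
  fit <- tryCatch(stats::splinefun(ld, resp_mono, method = "hyman"),
                  error = function(e) stats::approxfun(ld, resp_mono))
  ec <- function(frac) {
    target <- frac * rmax
    if (response[1L] > target || max(response) < target) {
      pc_stop("pc_coverage_error",
              sprintf("grid does not span %g%% of the response maximum",
                      100 * frac))
    }
    i <- which(resp_mono >= target)[1L]
    if (i == 1L) return(dose[1L])
    root <- stats::uniroot(function(z) fit(z) - target,
                           c(ld[i - 1L], ld[i]), tol = 1e-12)$root
    exp(root)
  }
  ec10 <- ec(0.1)
  ec90 <- ec(0.9)
  if (ec90 <= ec10) {
    pc_stop("pc_coverage_error", "EC90 <= EC10: response too steep for grid")
  }
  log(81) / log(ec90 / ec10)
}
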
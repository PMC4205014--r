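# Named sweep experiments: STAT3 (single site, JAK kinase, SHP-1
# phosphatase) and IRF-5 (six independent sites, TBK-1 kinase, alkaline
# phosphatase). The paper's figures print no rate constants, so the bundled
# configurations are regime-representative: order-unity rates with
# documented enzyme:substrate ratios, never "paper-exact".

#' Configure a sweep scenario
#'
#' @param name identifier for reports and manifests.
#' @param n_sites number of phosphorylation sites (1 for STAT3, 6 for IRF-5).
#' @param base_params a [make_cycle_parameters()] object; the unswept
#'   quantities are taken from here.
#' @param sweep_axis `"kinase_total_ratio"` sweeps the kinase total
#'   (`K_T = axis * P_T`, phosphatase fixed); `"rate_ratio"` sweeps the
#'   maximal-rate ratio `v = k1*K_T/(k2*P_T)` through the catalytic kinase
#'   activity `k1` (with `a1` rescaled so the base `Km1` is preserved).
#' @param grid strictly increasing positive axis values.
#' @param compare_gk also evaluate the Goldbeter-Koshland baseline per point.
#' @return List of class `scenario_config`.
#' @export
scenario_config <- function(name, n_sites, base_params,
                            sweep_axis = c("kinase_total_ratio", "rate_ratio"),
                            grid, compare_gk = TRUE) {
  sweep_axis <- match.arg(sweep_axis)
  n_sites <- check_n_sites(n_sites)
  stopifnot(inherits(base_params, "cycle_parameters"))
  if (length(grid) == 0L) {
    pc_stop("pc_invalid_config", "sweep grid must have at least one point")
  }
  if (any(!is.finite(grid)) || any(grid <= 0) || any(diff(grid) <= 0)) {
    pc_stop("pc_invalid_config", "grid must be strictly increasing and > 0")
  }
  structure(list(name = name, n_sites = n_sites, base_params = base_params,
                 sweep_axis = sweep_axis, grid = as.numeric(grid),
                 compare_gk = isTRUE(compare_gk)),
            class = "scenario_config")
}

# parameter set at one sweep point
params_at <- function(config, r) {
  b <- config$base_params
  if (config$sweep_axis == "kinase_total_ratio") {
    make_cycle_parameters(a1 = b$a1, d1 = b$d1, k1 = b$k1,
                          a2 = b$a2, d2 = b$d2, k2 = b$k2,
                          W_T = b$W_T, K_T = r * b$P_T, P_T = b$P_T)
  } else {
    if (b$K_T <= 0 || b$P_T <= 0) {
      pc_stop("pc_invalid_config",
              "rate_ratio sweep needs positive K_T and P_T in base_params")
    }
    k1 <- r * b$k2 * b$P_T / b$K_T
    make_cycle_parameters(a1 = (b$d1 + k1) / b$Km1, d1 = b$d1, k1 = k1,
                          a2 = b$a2, d2 = b$d2, k2 = b$k2,
                          W_T = b$W_T, K_T = b$K_T, P_T = b$P_T)
  }
}

#' Run a sweep scenario
#'
#' For each grid point the swept quantity is rescaled, the site-level closed
#' form is solved (substrate total `n_sites * W_T`, see
#' [site_probability()]), the phosphoform distribution is built over the
#' protein total `W_T`, and optionally the Goldbeter-Koshland fraction of
#' the same site-level system is evaluated. Solver failures at individual
#' points are recorded in the `error` column, not raised.
#'
#' @param config a [scenario_config()].
#' @return Object of class `sweep_result`: the `config` plus a data frame
#'   `table` with columns `axis`, `p`, `amp_free`, `gk` (if enabled),
#'   `species_0 ... species_n` (summing to `W_T`), `eps_K`, `eps_P`,
#'   `kappa1`, `kappa2`, `error`.
#' @export
run_sweep <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  n <- config$n_sites
  rows <- lapply(config$grid, function(r) {
    out <- data.frame(axis = r, p = NA_real_, amp_free = NA_real_,
                      gk = NA_real_, eps_K = NA_real_, eps_P = NA_real_,
                      kappa1 = NA_real_, kappa2 = NA_real_,
                      error = NA_character_)
    sp <- matrix(NA_real_, 1L, n + 1L,
                 dimnames = list(NULL, paste0("species_", 0:n)))
    tryCatch({
      pr <- params_at(config, r)
      p <- site_probability(pr, n)
      sol <- attr(p, "solution")
      dist <- species_distribution(as.numeric(p), n, pr$W_T)
      site_pr <- sol$params   # site-level parameter set (W_T scaled by n)
      nd <- nondimensionalize(site_pr)
      out$p <- as.numeric(p)
      out$amp_free <- sol$amp_free
      out$eps_K <- nd$eps_K
      out$eps_P <- nd$eps_P
      out$kappa1 <- nd$kappa1
      out$kappa2 <- nd$kappa2
      sp[1L, ] <- dist$species
      if (config$compare_gk) {
        out$gk <- gk_fraction(gk_inputs_from_params(site_pr))
      }
    }, pc_error = function(e) out$error <<- conditionMessage(e))
    cbind(out, as.data.frame(sp))
  })
  tab <- do.call(rbind, rows)
  if (!config$compare_gk) tab$gk <- NULL
  structure(list(config = config, table = tab), class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> scenario '%s': %d points over %s\n",
              x$config$name, nrow(x$table), x$config$sweep_axis))
  print(utils::head(x$table, 5L))
  if (nrow(x$table) > 5L) cat("  ...\n")
  invisible(x)
}

#' Summarize agreement with the Goldbeter-Koshland baseline and steepness
#'
#' @param result a [run_sweep()] result obtained with `compare_gk = TRUE`.
#' @return List of class `regime_report`: `max_abs_diff` (over the grid, of
#'   `|p - gk|`), `agreement` (`max_abs_diff < 0.01`), `divergence`
#'   (`max_abs_diff > 0.05`), `hill_p` and `hill_full` (effective Hill
#'   coefficients of `p` and of the fully phosphorylated class along the
#'   axis; `NA` with a reason when the grid does not span 10-90% of the
#'   response).
#' @export
regime_report <- function(result) {
  stopifnot(inherits(result, "sweep_result"))
  tab <- result$table
  if (is.null(tab$gk)) {
    pc_stop("pc_invalid_config", "regime_report requires compare_gk = TRUE")
  }
  ok <- is.na(tab$error)
  max_abs_diff <- max(abs(tab$p[ok] - tab$gk[ok]))
  try_hill <- function(response) {
    tryCatch(effective_hill(tab$axis[ok], response[ok]),
             pc_error = function(e) structure(NA_real_,
                                              reason = conditionMessage(e)))
  }
  full_col <- paste0("species_", result$config$n_sites)
  structure(
    list(scenario = result$config$name,
         max_abs_diff = max_abs_diff,
         agreement = max_abs_diff < 0.01,
         divergence = max_abs_diff > 0.05,
         hill_p = try_hill(tab$p),
         hill_full = try_hill(tab[[full_col]]),
         n_failed = sum(!ok)),
    class = "regime_report")
}

#' @export
print.regime_report <- function(x, ...) {
  cat(sprintf("<regime_report> scenario '%s'\n", x$scenario))
  cat(sprintf("  max |p - GK| = %.4g  ->  %s\n", x$max_abs_diff,
              if (x$agreement) "agreement" else if (x$divergence)
                "divergence" else "intermediate"))
  cat(sprintf("  effective Hill: p = %.4g, fully phosphorylated = %.4g\n",
              x$hill_p, x$hill_full))
  if (x$n_failed > 0) cat(sprintf("  %d grid point(s) failed\n", x$n_failed))
  invisible(x)
}

default_grid <- function() 10^seq(-2, 2, length.out = 50L)

# order-unity base rates giving Km = 1 on both sides
base_rates <- function(W_T = 1, K_T, P_T) {
  make_cycle_parameters(a1 = 2, d1 = 1, k1 = 1, a2 = 2, d2 = 1, k2 = 1,
                        W_T = W_T, K_T = K_T, P_T = P_T)
}

#' Bundled scenario configurations
#'
#' Regime-representative configurations (the underlying publications print
#' no rate constants):
#' \describe{
#'   \item{`stat3`, `stat3_substrate_excess`}{single site, both enzyme
#'     totals `1e-4` of the substrate; kinase-total sweep. The
#'     Goldbeter-Koshland regime.}
#'   \item{`stat3_comparable`}{single site, phosphatase total equal to the
#'     substrate total (`eps_P = 1`), kinase dilute; maximal-rate-ratio
#'     sweep. The divergence/amplitude-modulation regime.}
#'   \item{`irf5`, `irf5_substrate_excess`}{six sites, dilute enzymes,
#'     kinase-total sweep.}
#'   \item{`irf5_comparable`}{six sites, kinase total equal to the protein
#'     total (`eps_K = 1`), rate-ratio sweep.}
#'   \item{`irf5_dilute`}{six sites, dilute enzymes, rate-ratio sweep: the
#'     matched control for `irf5_comparable`.}
#' }
#'
#' @param name scenario name; omit to get the list of names.
#' @return A [scenario_config()] (or character vector of names).
#' @export
scenario_preset <- function(name = NULL) {
  presets <- list(
    stat3 = function() scenario_config(
      "stat3", 1L, base_rates(K_T = 1e-4, P_T = 1e-4),
      "kinase_total_ratio", default_grid()),
    stat3_comparable = function() scenario_config(
      "stat3_comparable", 1L, base_rates(K_T = 1e-4, P_T = 1),
      "rate_ratio", default_grid()),
    irf5 = function() scenario_config(
      "irf5", 6L, base_rates(K_T = 1e-3, P_T = 1e-3),
      "kinase_total_ratio", default_grid()),
    irf5_comparable = function() scenario_config(
      "irf5_comparable", 6L, base_rates(K_T = 1, P_T = 1e-3),
      "rate_ratio", default_grid()),
    irf5_dilute = function() scenario_config(
      "irf5_dilute", 6L, base_rates(K_T = 1e-3, P_T = 1e-3),
      "rate_ratio", default_grid())
  )
  presets$stat3_substrate_excess <- presets$stat3
  presets$irf5_substrate_excess <- presets$irf5
  if (is.null(name)) return(names(presets))
  if (!name %in% names(presets)) {
    pc_stop("pc_unknown_scenario",
            sprintf("unknown scenario '%s'; available: %s", name,
                    paste(names(presets), collapse = ", ")))
  }
  presets[[name]]()
}

#' Write a sweep result as CSV
#'
#' Columns `axis,p,gk,species_0..species_n` (plus diagnostics).
#'
#' @param result a [run_sweep()] result.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(result, path) {
  stopifnot(inherits(result, "sweep_result"))
  utils::write.csv(result$table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
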
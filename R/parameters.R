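#' Construct a phosphorylation-cycle parameter set
#'
#' A single covalent modification cycle couples six mass-action rate constants
#' with three conserved totals:
#' \deqn{W + K \rightleftharpoons WK \rightarrow W_p + K}{W + K <-> WK -> Wp + K}
#' \deqn{W_p + P \rightleftharpoons W_pP \rightarrow W + P}{Wp + P <-> WpP -> W + P}
#' where `W` is the substrate protein (e.g. STAT3, IRF-5), `K` the kinase
#' (JAK, TBK-1) and `P` the phosphatase (SHP-1, alkaline phosphatase).
#' Units are arbitrary but consistent: concentrations in one nominal
#' concentration unit, rates in its reciprocal-time combinations.
#'
#' The Michaelis constants are derived on construction:
#' `Km1 = (d1 + k1)/a1`, `Km2 = (d2 + k2)/a2`.
#'
#' @param a1,a2 association rates of kinase/substrate and
#'   phosphatase/phospho-substrate (1/(conc*time)).
#' @param d1,d2 dissociation rates of the two Michaelis complexes (1/time).
#' @param k1,k2 catalytic phosphorylation and dephosphorylation rates (1/time).
#' @param W_T,K_T,P_T total substrate, kinase and phosphatase concentrations.
#' @return An object of class `cycle_parameters`: a named list with the nine
#'   inputs plus derived `Km1`, `Km2`.
#' @examples
#' p <- make_cycle_parameters(a1 = 1, d1 = 1, k1 = 1,
#'                            a2 = 1, d2 = 1, k2 = 1,
#'                            W_T = 1, K_T = 0.01, P_T = 0.01)
#' p$Km1  # (d1 + k1)/a1 = 2
#' @export
make_cycle_parameters <- function(a1, d1, k1, a2, d2, k2, W_T, K_T, P_T) {
  vals <- c(a1 = a1, d1 = d1, k1 = k1, a2 = a2, d2 = d2, k2 = k2,
            W_T = W_T, K_T = K_T, P_T = P_T)
  stopifnot_finite(vals, "cycle parameters")
  if (any(vals < 0)) {
    pc_invalid_parameter(sprintf(
      "negative parameter(s): %s",
      paste(names(vals)[vals < 0], collapse = ", ")))
  }
  if (W_T <= 0) pc_invalid_parameter("W_T must be > 0")
  if (K_T > 0 && a1 <= 0) {
    pc_invalid_parameter("a1 must be > 0 when K_T > 0 (kinase cannot bind)")
  }
  if (P_T > 0 && a2 <= 0) {
    pc_invalid_parameter("a2 must be > 0 when P_T > 0 (phosphatase cannot bind)")
  }
  Km1 <- if (a1 > 0) (d1 + k1) / a1 else Inf
  Km2 <- if (a2 > 0) (d2 + k2) / a2 else Inf
  structure(
    list(a1 = a1, d1 = d1, k1 = k1, a2 = a2, d2 = d2, k2 = k2,
         W_T = W_T, K_T = K_T, P_T = P_T, Km1 = Km1, Km2 = Km2),
    class = "cycle_parameters")
}

#' @export
print.cycle_parameters <- function(x, ...) {
  cat("<cycle_parameters>\n")
  cat(sprintf("  kinase step:      a1 = %g, d1 = %g, k1 = %g  (Km1 = %g)\n",
              x$a1, x$d1, x$k1, x$Km1))
  cat(sprintf("  phosphatase step: a2 = %g, d2 = %g, k2 = %g  (Km2 = %g)\n",
              x$a2, x$d2, x$k2, x$Km2))
  cat(sprintf("  totals: W_T = %g, K_T = %g, P_T = %g\n", x$W_T, x$K_T, x$P_T))
  invisible(x)
}

#' @export
as.data.frame.cycle_parameters <- function(x, ...) {
  as.data.frame(unclass(x)[c("a1", "d1", "k1", "a2", "d2", "k2",
                             "W_T", "K_T", "P_T", "Km1", "Km2")])
}

param_keys <- c("a1", "d1", "k1", "a2", "d2", "k2", "W_T", "K_T", "P_T")

#' Read cycle parameters from a flat key-value config file
#'
#' The accepted format is one `key: value` (or `key = value`) pair per line
#' with keys `a1,d1,k1,a2,d2,k2,W_T,K_T,P_T`; blank lines and `#` comments are
#' ignored. A JSON object with the same keys is accepted as an alternative
#' dialect (detected by a leading `{`).
#'
#' @param path file path.
#' @return A [make_cycle_parameters()] object.
#' @export
read_cycle_config <- function(path) {
  if (!file.exists(path)) {
    pc_stop("pc_invalid_config", sprintf("config file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  txt <- trimws(paste(lines, collapse = "\n"))
  if (!nzchar(txt)) pc_stop("pc_invalid_config", "empty config file")
  if (startsWith(txt, "{")) {
    vals <- tryCatch(jsonlite::fromJSON(txt),
                     error = function(e) pc_stop("pc_invalid_config",
                       paste("malformed JSON config:", conditionMessage(e))))
    vals <- lapply(vals, function(v) suppressWarnings(as.numeric(v)))
  } else {
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    m <- regmatches(lines, regexec("^([A-Za-z_][A-Za-z0-9_]*)\\s*[:=]\\s*(\\S+)$", lines))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad)) {
      pc_stop("pc_invalid_config",
              sprintf("malformed config line(s): %s",
                      paste(lines[bad], collapse = "; ")))
    }
    vals <- stats::setNames(
      lapply(m, function(x) suppressWarnings(as.numeric(x[3]))),
      vapply(m, `[`, "", 2))
  }
  missing <- setdiff(param_keys, names(vals))
  if (length(missing)) {
    pc_stop("pc_invalid_config",
            sprintf("config missing key(s): %s", paste(missing, collapse = ", ")))
  }
  if (anyNA(unlist(vals[param_keys]))) {
    pc_stop("pc_invalid_config", "non-numeric value in config")
  }
  do.call(make_cycle_parameters, lapply(vals[param_keys], as.numeric))
}

#' Write cycle parameters as a flat key-value config file
#'
#' @param params a [make_cycle_parameters()] object.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_cycle_config <- function(params, path) {
  stopifnot(inherits(params, "cycle_parameters"))
  writeLines(sprintf("%s: %.17g", param_keys,
                     unlist(unclass(params)[param_keys])), path)
  invisible(path)
}
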
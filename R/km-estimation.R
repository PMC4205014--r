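# Recovery of the Michaelis constants from measured steady-state
# concentrations: inverting the quasi-steady-state complex relations gives
#   Km1 = W  * (K_T - WK)  / WK  = W  * K / WK
#   Km2 = Wp * (P_T - WpP) / WpP = Wp * P / WpP .

#' Construct a measured steady state
#'
#' @param W,Wp,WK,WpP measured species concentrations (>= 0).
#' @param K_T,P_T,W_T known totals.
#' @param rel_noise optional annotation: relative standard deviation of the
#'   measurement noise (`NA` if unknown).
#' @return List of class `measured_state`.
#' @export
measured_state <- function(W, Wp, WK, WpP, K_T, P_T, W_T, rel_noise = NA_real_) {
  vals <- c(W = W, Wp = Wp, WK = WK, WpP = WpP, K_T = K_T, P_T = P_T, W_T = W_T)
  stopifnot_finite(vals, "measured state")
  if (any(vals < 0)) pc_invalid_state("measured concentrations must be >= 0")
  if (WK > K_T) {
    pc_stop("pc_inconsistent_measurement",
            sprintf("WK = %g exceeds the kinase total K_T = %g", WK, K_T))
  }
  if (WpP > P_T) {
    pc_stop("pc_inconsistent_measurement",
            sprintf("WpP = %g exceeds the phosphatase total P_T = %g", WpP, P_T))
  }
  structure(c(as.list(vals), list(rel_noise = rel_noise)),
            class = "measured_state")
}

#' Estimate the Michaelis constants from one measured steady state
#'
#' @param m a [measured_state()].
#' @param partial if `TRUE`, a constant whose complex measurement is zero is
#'   returned as `NA` instead of raising; the other is still estimated.
#' @return Named vector `c(Km1 =, Km2 =)`.
#' @examples
#' # half-saturated kinase: WK = K_T/2  =>  Km1 = W
#' m <- measured_state(W = 2, Wp = 1, WK = 0.5, WpP = 0.25,
#'                     K_T = 1, P_T = 1, W_T = 3.75)
#' estimate_michaelis_constants(m)["Km1"]  # = 2
#' @export
estimate_michaelis_constants <- function(m, partial = FALSE) {
  stopifnot(inherits(m, "measured_state"))
  km_one <- function(free, complex, total, label) {
    if (complex <= 0) {
      if (partial) return(NA_real_)
      pc_stop("pc_nonidentifiable",
              sprintf("%s is not identifiable: measured complex is zero", label))
    }
    free * (total - complex) / complex
  }
  c(Km1 = km_one(m$W, m$WK, m$K_T, "Km1"),
    Km2 = km_one(m$Wp, m$WpP, m$P_T, "Km2"))
}

#' Estimate Michaelis constants from replicate measurements
#'
#' Per-replicate inversions summarized by the median, which is robust to the
#' right-skew of the ratio estimator under multiplicative noise.
#'
#' @param measurements list of [measured_state()] objects.
#' @param partial passed to [estimate_michaelis_constants()].
#' @return List with `per_replicate` (matrix, one row per replicate) and
#'   `median` (named vector).
#' @export
estimate_michaelis_constants_replicates <- function(measurements, partial = TRUE) {
  est <- t(vapply(measurements, estimate_michaelis_constants,
                  c(Km1 = 0, Km2 = 0), partial = partial))
  list(per_replicate = est,
       median = apply(est, 2L, stats::median, na.rm = TRUE))
}

measurement_cols <- c("W", "Wp", "WK", "WpP", "K_T", "P_T", "W_T")

#' Read replicate measurements from CSV
#'
#' Expects columns `W,Wp,WK,WpP,K_T,P_T,W_T`, one row per replicate.
#'
#' @param path CSV file path.
#' @return List of [measured_state()] objects.
#' @export
read_measurements_csv <- function(path) {
  df <- tryCatch(utils::read.csv(path),
                 error = function(e) pc_stop("pc_schema_error",
                   paste("cannot read measurements CSV:", conditionMessage(e))))
  missing <- setdiff(measurement_cols, names(df))
  if (length(missing)) {
    pc_stop("pc_schema_error",
            sprintf("measurements CSV missing column(s): %s",
                    paste(missing, collapse = ", ")))
  }
  if (nrow(df) == 0L) pc_stop("pc_schema_error", "measurements CSV has no rows")
  lapply(seq_len(nrow(df)), function(i) {
    do.call(measured_state, as.list(df[i, measurement_cols]))
  })
}

#' Write replicate measurements as CSV
#'
#' @param measurements list of [measured_state()] objects.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_measurements_csv <- function(measurements, path) {
  if (inherits(measurements, "measured_state")) measurements <- list(measurements)
  df <- do.call(rbind, lapply(measurements, function(m) {
    as.data.frame(unclass(m)[measurement_cols])
  }))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
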
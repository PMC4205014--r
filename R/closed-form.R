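# Closed-form steady state of the modification cycle with retained complexes.
#
# At steady state the complexes obey the quasi-steady-state relations
#   WK  = K_T * W  / (Km1 + W),    WpP = P_T * Wp / (Km2 + Wp)
# and the two catalytic fluxes balance, k1*WK = k2*WpP. Writing
# w = W/W_T, wp = Wp/W_T, kappa_i = Km_i/W_T, eps_K = K_T/W_T,
# eps_P = P_T/W_T and v = k1*K_T/(k2*P_T), flux balance gives
#   wp(w) = kappa2 * v * w / (kappa1 + (1 - v) * w)
# and substrate conservation becomes the monotone balance
#   G(w) = w + wp(w) + (eps_K + v*eps_P) * w/(kappa1 + w) - 1 = 0 .
# Clearing denominators yields a cubic in w whose unique admissible real
# root is evaluated in closed form (depressed cubic; Cardano branch for one
# real root, trigonometric branch otherwise). G'(w) >= 1 on the admissible
# domain, so the root is always well conditioned.

#' Quasi-steady-state complex concentrations
#'
#' Michaelis-type expressions for the two complexes given the free substrate
#' pools: `WK = K_T*W/(Km1+W)`, `WpP = P_T*Wp/(Km2+Wp)`.
#'
#' @param freeW,freeWp free unphosphorylated / phosphorylated substrate.
#' @param params a [make_cycle_parameters()] object.
#' @return Named vector `c(WK =, WpP =)`.
#' @export
complex_concentrations <- function(freeW, freeWp, params) {
  if (freeW < 0 || freeWp < 0) pc_invalid_state("free concentrations must be >= 0")
  WK <- if (params$K_T > 0) params$K_T * freeW / (params$Km1 + freeW) else 0
  WpP <- if (params$P_T > 0) params$P_T * freeWp / (params$Km2 + freeWp) else 0
  c(WK = WK, WpP = WpP)
}

#' Nondimensionalize a cycle parameter set
#'
#' Scales concentrations by the substrate total `W_T`:
#' `kappa1 = Km1/W_T`, `kappa2 = Km2/W_T`, `eps_K = K_T/W_T`,
#' `eps_P = P_T/W_T`, and the maximal-rate ratio
#' `v_ratio = k1*K_T/(k2*P_T)`. The mapping is inverted by choosing a
#' concentration unit `W_T` and a time unit (e.g. `1/k2`), from which
#' `Km_i = kappa_i*W_T`, `K_T = eps_K*W_T`, `P_T = eps_P*W_T` and
#' `k1 = v_ratio*k2*P_T/K_T`.
#'
#' When `k2*P_T = 0` the ratio is reported as `Inf` with `v_infinite = TRUE`
#' rather than raising an error.
#'
#' @param params a [make_cycle_parameters()] object.
#' @return List of class `nd_parameters` with fields `kappa1`, `kappa2`,
#'   `eps_K`, `eps_P`, `v_ratio`, `v_infinite`.
#' @export
nondimensionalize <- function(params) {
  if (params$W_T <= 0) pc_invalid_parameter("W_T must be > 0")
  denom <- params$k2 * params$P_T
  num <- params$k1 * params$K_T
  v_infinite <- denom == 0 && num > 0
  v_ratio <- if (denom == 0) {
    if (num > 0) Inf else NaN
  } else num / denom
  structure(
    list(kappa1 = params$Km1 / params$W_T,
         kappa2 = params$Km2 / params$W_T,
         eps_K = params$K_T / params$W_T,
         eps_P = params$P_T / params$W_T,
         v_ratio = v_ratio,
         v_infinite = v_infinite),
    class = "nd_parameters")
}

#' Monotone steady-state balance function
#'
#' Returns the function `G(w)` (and its derivative) whose unique zero on the
#' admissible domain is the normalized free-substrate steady state. `G` is
#' continuous and strictly increasing there (`G'(w) >= 1`), which is the
#' one-real-root property of the cycle.
#'
#' @param nd an [nondimensionalize()] object with finite positive `v_ratio`.
#' @return List with elements `G`, `dG` (functions of `w`) and `domain_max`.
#' @export
steady_state_fn <- function(nd) {
  v <- nd$v_ratio
  if (!is.finite(v) || v < 0) pc_invalid_parameter("v_ratio must be finite and >= 0")
  k1 <- nd$kappa1; k2 <- nd$kappa2
  seq_coef <- nd$eps_K + v * nd$eps_P
  A <- 1 - v
  G <- function(w) {
    w + k2 * v * w / (k1 + A * w) + seq_coef * w / (k1 + w) - 1
  }
  dG <- function(w) {
    1 + k2 * v * k1 / (k1 + A * w)^2 + seq_coef * k1 / (k1 + w)^2
  }
  list(G = G, dG = dG, domain_max = admissible_domain_max(nd))
}

# Upper end of the admissible root interval: w <= 1 from conservation and,
# when v > 1, w < kappa1/(v-1) where the flux-balance pole sits.
admissible_domain_max <- function(nd) {
  v <- nd$v_ratio
  dm <- 1
  if (is.finite(v) && v > 1) dm <- min(dm, nd$kappa1 / (v - 1))
  dm
}

#' Coefficients of the steady-state cubic
#'
#' Clearing denominators in the balance `G(w) = 0` (see [steady_state_fn()])
#' gives `F(w) = c3*w^3 + c2*w^2 + c1*w + c0` with
#' \deqn{c_3 = 1 - v}
#' \deqn{c_2 = \kappa_1(2 - v) + \kappa_2 v + (\epsilon_K + v\epsilon_P)(1-v) - (1-v)}
#' \deqn{c_1 = \kappa_1(\kappa_1 + \kappa_2 v + \epsilon_K + v\epsilon_P + v - 2)}
#' \deqn{c_0 = -\kappa_1^2 .}
#' On the admissible domain `F` and `G` share their unique root; `F` itself
#' need not be monotone (the monotonicity statement belongs to `G`).
#'
#' Balanced maximal rates (`v = 1`) make `c3 = 0`: the equation degenerates
#' to a quadratic and a `pc_degenerate_cubic` condition is raised, directing
#' callers to [solve_steady_state_numeric()] (or to the quadratic branch that
#' [solve_steady_state()] applies itself).
#'
#' @param nd an [nondimensionalize()] object.
#' @return List of class `cubic_coefficients`: `c3, c2, c1, c0, domain_max`.
#' @export
cubic_coefficients <- function(nd) {
  v <- nd$v_ratio
  if (!is.finite(v) || v < 0) {
    pc_invalid_parameter("cubic requires finite nonnegative v_ratio")
  }
  k1 <- nd$kappa1; k2 <- nd$kappa2
  if (!is.finite(k1) || k1 <= 0) {
    pc_invalid_parameter("cubic requires finite positive kappa1")
  }
  A <- 1 - v
  seq_coef <- nd$eps_K + v * nd$eps_P
  co <- structure(
    list(c3 = A,
         c2 = k1 * (2 - v) + k2 * v + seq_coef * A - A,
         c1 = k1 * (k1 + k2 * v + seq_coef + v - 2),
         c0 = -k1 * k1,
         domain_max = admissible_domain_max(nd)),
    class = "cubic_coefficients")
  scale <- max(abs(co$c2), abs(co$c1), abs(co$c0))
  if (abs(co$c3) <= 1e-12 * scale) {
    pc_stop("pc_degenerate_cubic",
            "leading coefficient vanishes (balanced maximal rates, v ~ 1); use the numeric solver",
            coefficients = co)
  }
  co
}

# x^2 + b*x - c = 0 with c >= 0: the nonnegative root, cancellation-free.
stable_quad_pos <- function(b, c) {
  if (c < 0) pc_invalid_parameter("stable_quad_pos needs c >= 0")
  disc <- sqrt(b * b + 4 * c)
  if (b >= 0) {
    if (b + disc == 0) 0 else 2 * c / (b + disc)
  } else {
    (disc - b) / 2
  }
}

#' Unique admissible real root of the steady-state cubic
#'
#' Evaluates the closed-form root of `c3*w^3 + c2*w^2 + c1*w + c0 = 0` lying
#' in `[0, domain_max]`. The depressed-cubic discriminant selects the branch:
#' Cardano's radical form for the single-real-root case, the trigonometric
#' form when three real roots exist (only one of which can be admissible).
#' The returned root is polished by Newton steps on the polynomial.
#'
#' @param coeffs a [cubic_coefficients()] object (or plain list with fields
#'   `c3, c2, c1, c0, domain_max`).
#' @return The root (scalar), clamped into `[0, domain_max]` only within
#'   `1e-12` numerical slack; outside that a `pc_root_domain` internal
#'   consistency error is raised. Near-degenerate discriminants raise
#'   `pc_degenerate_cubic`.
#' @export
real_root <- function(coeffs) {
  c3 <- coeffs$c3; c2 <- coeffs$c2; c1 <- coeffs$c1; c0 <- coeffs$c0
  dm <- coeffs$domain_max
  if (!is.finite(c3) || c3 == 0) {
    pc_stop("pc_degenerate_cubic", "zero leading coefficient")
  }
  b <- c2 / c3; cc <- c1 / c3; d <- c0 / c3
  p <- cc - b * b / 3
  q <- 2 * b^3 / 27 - b * cc / 3 + d
  shift <- -b / 3
  disc <- (q / 2)^2 + (p / 3)^3
  disc_scale <- max((q / 2)^2, abs(p / 3)^3, .Machine$double.xmin)
  if (disc <= 0 && abs(disc) <= 1e-12 * disc_scale) {
    pc_stop("pc_degenerate_cubic",
            "discriminant within numerical slack of zero; use the numeric solver")
  }
  roots <- numeric()
  if (disc > 0) {
    # one real root: Cardano, largest-magnitude radical first to avoid
    # subtractive cancellation
    s1 <- -q / 2 + sqrt(disc)
    s2 <- -q / 2 - sqrt(disc)
    s <- if (abs(s1) >= abs(s2)) s1 else s2
    u <- sign(s) * abs(s)^(1 / 3)
    t0 <- if (u == 0) 0 else u - p / (3 * u)
    roots <- shift + t0
  }
  if (p < 0) {
    # three-real-root (trigonometric) branch; also evaluated when the
    # computed discriminant is positive but cancellation-prone, since its
    # sign is then unreliable -- spurious candidates are removed below by
    # the polish + domain filter
    m <- 2 * sqrt(-p / 3)
    arg <- 3 * q / (p * m)
    arg <- min(1, max(-1, arg))
    theta <- acos(arg) / 3
    roots <- c(roots, shift + m * cos(theta - 2 * pi * (0:2) / 3))
  }
  if (length(roots) == 0L) {
    pc_stop("pc_degenerate_cubic", "no real-root branch applies; use the numeric solver")
  }
  # extra candidate seed for a root far below the coefficient scale
  # (F(0) = c0 < 0 and |r| small make r ~ -c0/c1): the branch formulas can
  # lose such a root entirely to cancellation in the depressed-cubic shift
  if (c1 != 0) roots <- c(roots, -c0 / c1)
  # The branch formulas can lose absolute precision when the coefficient
  # scales are extreme (the depressed-cubic shift dwarfs the admissible
  # domain), so every real candidate is Newton-polished on the polynomial
  # BEFORE the domain filter is applied.
  polish <- function(r) {
    for (i in 1:40) {
      Fv <- ((c3 * r + c2) * r + c1) * r + c0
      dF <- (3 * c3 * r + 2 * c2) * r + c1
      if (dF == 0) break
      step <- Fv / dF
      r <- r - step
      if (abs(step) < 1e-16 * max(1, abs(r))) break
    }
    r
  }
  roots <- sort(vapply(roots, polish, 0))
  # merge candidates that converged to the same root (relative tolerance:
  # duplicates from the two branches agree to near machine precision)
  keep <- c(TRUE, diff(roots) > 1e-8 * pmax(abs(roots[-1L]), abs(dm)))
  roots <- roots[keep]
  slack <- 1e-12 * max(1, dm)
  adm <- roots[roots >= -slack & roots <= dm + slack]
  if (length(adm) > 1L) {
    pc_stop("pc_degenerate_cubic",
            "multiple admissible real roots (numerical degeneracy); use the numeric solver")
  }
  if (length(adm) == 0L) {
    # a root hovering just beyond the domain boundary signals a
    # near-double root at the flux-balance pole: defer to the numeric
    # solver rather than fail
    near <- any(roots >= -1e-6 * max(1, dm) & roots <= dm * (1 + 1e-6) + slack)
    if (near) {
      pc_stop("pc_degenerate_cubic",
              "root within numerical slack of the domain boundary; use the numeric solver")
    }
    pc_stop("pc_root_domain",
            sprintf("no real root in [0, %g] (roots: %s)", dm,
                    paste(signif(roots, 6), collapse = ", ")))
  }
  min(max(adm[[1L]], 0), dm)
}

# Build the full solution object from the normalized free-substrate root.
reconstruct_solution <- function(w, params, nd, method, residual = NA_real_) {
  v <- nd$v_ratio
  W <- w * params$W_T
  wp <- if (v == 0) 0 else nd$kappa2 * v * w / (nd$kappa1 + (1 - v) * w)
  wp <- max(wp, 0)
  Wp <- wp * params$W_T
  cx <- complex_concentrations(W, Wp, params)
  state <- make_cycle_state(W = W, Wp = Wp, WK = cx[["WK"]], WpP = cx[["WpP"]],
                            K = params$K_T - cx[["WK"]],
                            P = params$P_T - cx[["WpP"]])
  new_steady_state_solution(state, params, method, root = w, residual = residual)
}

new_steady_state_solution <- function(state, params, method, root = NA_real_,
                                      residual = NA_real_) {
  s <- unclass(state)
  p <- (s[["Wp"]] + s[["WpP"]]) / params$W_T
  p <- min(max(p, 0), 1)
  flux_gap <- {
    f1 <- params$k1 * s[["WK"]]; f2 <- params$k2 * s[["WpP"]]
    if (max(f1, f2) > 0) abs(f1 - f2) / max(f1, f2) else 0
  }
  structure(
    list(state = state,
         p = p,
         amp_free = s[["Wp"]] / params$W_T,
         root = root,
         residual = residual,
         flux_gap = flux_gap,
         method = method,
         params = params),
    class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf("<steady_state_solution> method = %s\n", x$method))
  cat(sprintf("  p (site phosphorylation probability) = %.6g\n", x$p))
  cat(sprintf("  free phospho-substrate fraction      = %.6g\n", x$amp_free))
  s <- unclass(x$state)
  cat(sprintf("  W = %.6g, Wp = %.6g, WK = %.6g, WpP = %.6g, K = %.6g, P = %.6g\n",
              s[["W"]], s[["Wp"]], s[["WK"]], s[["WpP"]], s[["K"]], s[["P"]]))
  cat(sprintf("  root = %.6g, residual = %.3g, flux gap = %.3g\n",
              x$root, x$residual, x$flux_gap))
  invisible(x)
}

#' @export
as.data.frame.steady_state_solution <- function(x, ...) {
  s <- unclass(x$state)
  data.frame(method = x$method, p = x$p, W = s[["W"]], Wp = s[["Wp"]],
             WK = s[["WK"]], WpP = s[["WpP"]], K = s[["K"]], P = s[["P"]],
             residual = x$residual)
}

# Degenerate-flux special cases, shared by both solvers.
# Returns NULL when the generic cubic applies.
special_case_solution <- function(params, method) {
  no_kin <- params$K_T * params$k1 == 0
  no_pho <- params$P_T * params$k2 == 0
  if (!no_kin && !no_pho) return(NULL)
  if (no_kin) {
    # no phosphorylation flux: all substrate unphosphorylated; kinase (if
    # any, with k1 = 0) still binds: W + K_T*W/(Km1+W) = W_T
    W <- if (params$K_T > 0 && is.finite(params$Km1)) {
      stable_quad_pos(params$Km1 + params$K_T - params$W_T,
                      params$Km1 * params$W_T)
    } else params$W_T
    cx <- complex_concentrations(W, 0, params)
    state <- make_cycle_state(W = W, Wp = 0, WK = cx[["WK"]], WpP = 0,
                              K = params$K_T - cx[["WK"]], P = params$P_T)
    return(new_steady_state_solution(state, params, method, root = W / params$W_T,
                                     residual = 0))
  }
  # kinase flux present, no dephosphorylation flux: all substrate ends
  # phosphorylated (p = 1); a k2 = 0 phosphatase still binds:
  # Wp + P_T*Wp/(Km2+Wp) = W_T
  Wp <- if (params$P_T > 0 && is.finite(params$Km2)) {
    stable_quad_pos(params$Km2 + params$P_T - params$W_T,
                    params$Km2 * params$W_T)
  } else params$W_T
  cx <- complex_concentrations(0, Wp, params)
  state <- make_cycle_state(W = 0, Wp = Wp, WK = 0, WpP = cx[["WpP"]],
                            K = params$K_T, P = params$P_T - cx[["WpP"]])
  new_steady_state_solution(state, params, method, root = 0, residual = 0)
}

#' Closed-form steady state of the cycle
#'
#' Solves the steady-state cubic analytically (see [cubic_coefficients()] and
#' [real_root()]) and reconstructs all six species from the root: `Wp` via
#' flux balance, complexes via the quasi-steady-state relations. The
#' phosphorylation probability is `p = (Wp + WpP)/W_T`: a site bound to the
#' phosphatase still carries its phosphate. The free phospho-substrate
#' fraction `Wp/W_T` — the observable signal amplitude — is reported
#' alongside as `amp_free`.
#'
#' Degenerate cases are handled explicitly: absent kinase flux
#' (`k1*K_T = 0`) gives `p = 0`, absent dephosphorylation flux
#' (`k2*P_T = 0`) gives `p = 1`, and a degenerate cubic (balanced maximal
#' rates, `v = 1`) falls back to [solve_steady_state_numeric()] with a
#' notice.
#'
#' @param params a [make_cycle_parameters()] object.
#' @return A `steady_state_solution`: fields `state` (a `cycle_state`), `p`,
#'   `amp_free`, `root` (normalized free substrate `W/W_T`), `residual`
#'   (scaled cubic value at the root), `flux_gap`
#'   (relative `|k1*WK - k2*WpP|`), `method`.
#' @export
solve_steady_state <- function(params) {
  stopifnot(inherits(params, "cycle_parameters"))
  sp <- special_case_solution(params, "closed_form")
  if (!is.null(sp)) return(sp)
  nd <- nondimensionalize(params)
  sol <- tryCatch({
    co <- cubic_coefficients(nd)
    w <- real_root(co)
    Fv <- ((co$c3 * w + co$c2) * w + co$c1) * w + co$c0
    res <- Fv / max(abs(co$c3), abs(co$c2), abs(co$c1), abs(co$c0))
    reconstruct_solution(w, params, nd, "closed_form", residual = res)
  }, pc_degenerate_cubic = function(e) {
    message("closed form degenerate (", conditionMessage(e),
            "); falling back to the numeric solver")
    solve_steady_state_numeric(params)
  })
  sol
}

#' Numeric steady state by bracketed root finding (independent oracle)
#'
#' Finds the zero of the monotone balance `G(w)` (see [steady_state_fn()])
#' with Brent's method on the bracket `[0, domain_max]`, tightened by Newton
#' steps on `G`, then reconstructs the species exactly as the closed form
#' does. Used to cross-validate [solve_steady_state()].
#'
#' @param params a [make_cycle_parameters()] object.
#' @return A `steady_state_solution` with `method = "numeric"`.
#' @export
solve_steady_state_numeric <- function(params) {
  stopifnot(inherits(params, "cycle_parameters"))
  sp <- special_case_solution(params, "numeric")
  if (!is.null(sp)) return(sp)
  nd <- nondimensionalize(params)
  fn <- steady_state_fn(nd)
  hi <- fn$domain_max
  # back off the flux-balance pole (v > 1) until G is finite and positive
  if (fn$G(hi) <= 0 || !is.finite(fn$G(hi))) {
    hi0 <- hi
    for (i in 1:60) {
      hi <- hi0 * (1 - 2^-(53 - i))
      g <- fn$G(hi)
      if (is.finite(g) && g > 0) break
    }
  }
  if (!is.finite(fn$G(hi)) || fn$G(hi) <= 0 || fn$G(0) >= 0) {
    pc_stop("pc_bracket_error",
            sprintf("no sign change on [0, %g]: G(0) = %g, G(hi) = %g",
                    hi, fn$G(0), fn$G(hi)))
  }
  w <- stats::uniroot(fn$G, c(0, hi), tol = 1e-13)$root
  for (i in 1:6) {  # Newton tightening; G' >= 1 so this is safe
    g <- fn$G(w)
    step <- g / fn$dG(w)
    wn <- w - step
    if (wn < 0) wn <- w / 2
    if (wn > fn$domain_max) wn <- (w + fn$domain_max) / 2
    w <- wn
    if (abs(step) < 1e-17) break
  }
  reconstruct_solution(min(max(w, 0), fn$domain_max), params, nd, "numeric",
                       residual = fn$G(w))
}

#' Write steady-state solutions as CSV
#'
#' Columns `method,p,W,Wp,WK,WpP,K,P,residual`, one row per solution.
#'
#' @param solutions a `steady_state_solution` or list of them.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_solutions_csv <- function(solutions, path) {
  if (inherits(solutions, "steady_state_solution")) solutions <- list(solutions)
  df <- do.call(rbind, lapply(solutions, as.data.frame))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
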
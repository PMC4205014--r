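# Implicit time integration to steady state.
#
# The six-species system has three conservation laws, so integration is done
# in the reduced coordinates x = (Wp, WK, WpP) with
#   W = W_T - Wp - WK - WpP,  K = K_T - WK,  P = P_T - WpP,
# which makes conservation exact to machine precision along the whole
# trajectory. Zero-order (near-saturated) regimes are stiff, so the stepper
# is adaptive backward Euler (L-stable) with an analytic Jacobian and
# pseudo-transient step growth; once the derivative max-norm is small the
# fixed point is polished by damped Newton on the mass-action RHS itself.
# Nothing here touches the closed-form cubic: this is its independent oracle.

rhs_reduced <- function(x, pr) {
  Wp <- x[1L]; WK <- x[2L]; WpP <- x[3L]
  W <- pr$W_T - Wp - WK - WpP
  K <- pr$K_T - WK
  P <- pr$P_T - WpP
  c(pr$k1 * WK - pr$a2 * Wp * P + pr$d2 * WpP,
    pr$a1 * W * K - (pr$d1 + pr$k1) * WK,
    pr$a2 * Wp * P - (pr$d2 + pr$k2) * WpP)
}

jac_reduced <- function(x, pr) {
  Wp <- x[1L]; WK <- x[2L]; WpP <- x[3L]
  W <- pr$W_T - Wp - WK - WpP
  K <- pr$K_T - WK
  P <- pr$P_T - WpP
  matrix(c(
    -pr$a2 * P,        pr$k1,                            pr$a2 * Wp + pr$d2,
    -pr$a1 * K,       -pr$a1 * (W + K) - pr$d1 - pr$k1, -pr$a1 * K,
     pr$a2 * P,        0,                               -pr$a2 * Wp - pr$d2 - pr$k2
  ), nrow = 3L, byrow = TRUE)
}

solve3 <- function(A, b) {
  # direct 3x3 solve; falls back to base solve on (near-)singularity
  out <- tryCatch(solve(A, b), error = function(e) NULL)
  if (is.null(out)) rep(NA_real_, 3L) else out
}

reduced_to_state <- function(x, pr) {
  clamp0 <- function(v) if (v < 0) 0 else v
  Wp <- clamp0(x[1L]); WK <- clamp0(x[2L]); WpP <- clamp0(x[3L])
  make_cycle_state(W = clamp0(pr$W_T - Wp - WK - WpP), Wp = Wp,
                   WK = WK, WpP = WpP,
                   K = clamp0(pr$K_T - WK), P = clamp0(pr$P_T - WpP))
}

# Newton on rhs_reduced(x) = 0, started inside the attractor's basin (the
# integrator has already brought the derivative below its tolerance). Full
# steps, damped only to preserve nonnegativity: a residual-norm line search
# would reject the correct step along a slow eigen-direction, because
# roundoff re-excites the fast components of f. Convergence is judged by
# step size (affine-invariant), with a divergence guard on growing steps.
newton_polish <- function(x, pr, max_iter = 30L) {
  scale <- max(pr$W_T, pr$K_T, pr$P_T)
  prev_step <- Inf
  grow <- 0L
  best <- x
  for (i in seq_len(max_iter)) {
    f <- rhs_reduced(x, pr)
    dx <- solve3(jac_reduced(x, pr), -f)
    if (anyNA(dx)) break
    lambda <- 1
    while (min(x + lambda * dx) < -1e-9 * scale && lambda > 1e-8) {
      lambda <- lambda / 2
    }
    x <- x + lambda * dx
    step <- max(abs(lambda * dx))
    if (step < prev_step) {
      best <- x
      grow <- 0L
    } else {
      grow <- grow + 1L
      if (grow >= 3L) return(pmax(best, 0))
    }
    prev_step <- step
    if (step < 1e-15 * scale) break
  }
  pmax(x, 0)
}

#' Integrate the cycle ODEs to steady state
#'
#' Brute-force steady-state computation: the mass-action equations are
#' integrated with an adaptive implicit (backward Euler) method until the
#' max-norm of the time derivative falls below `rel_tol * W_T`, then the
#' fixed point is tightened by Newton iteration on the right-hand side.
#' Serves as the independent oracle for [solve_steady_state()].
#'
#' @param params a [make_cycle_parameters()] object.
#' @param initial optional initial `cycle_state`; must satisfy the
#'   conservation totals of `params` (checked to `1e-8` relative). Default:
#'   [default_initial_state()].
#' @param rel_tol steady-state detection threshold on
#'   `max|dx/dt| / W_T` (default `1e-9`).
#' @param t_max time horizon in model time units (default `1e6`); a
#'   convergence error carrying the last state is raised if it is reached
#'   before the derivative criterion is met.
#' @param keep_trajectory if `TRUE`, attach the accepted integration steps as
#'   attribute `"trajectory"` (data frame `time,W,Wp,WK,WpP,K,P`).
#' @return The terminal `cycle_state`, with attributes `time` (model time
#'   reached) and `n_steps`.
#' @export
integrate_to_steady_state <- function(params, initial = NULL, rel_tol = 1e-9,
                                      t_max = 1e6, keep_trajectory = FALSE) {
  pr <- params
  if (is.null(initial)) initial <- default_initial_state(pr)
  res <- conservation_residuals(initial, pr)
  tot <- c(pr$W_T, max(pr$K_T, pr$W_T * 1e-30), max(pr$P_T, pr$W_T * 1e-30))
  if (any(abs(res) > 1e-8 * tot + 1e-14 * pr$W_T)) {
    pc_invalid_state("initial state violates the conservation totals of params")
  }
  s <- unclass(initial)
  x <- c(s[["Wp"]], s[["WK"]], s[["WpP"]])
  dtol <- rel_tol * pr$W_T
  scale <- pr$W_T
  # initial step from the fastest rate in the problem
  rate_scale <- max(pr$a1 * pr$W_T, pr$a2 * pr$W_T, pr$d1, pr$d2,
                    pr$k1, pr$k2, 1e-12)
  h <- min(0.01 / rate_scale, t_max / 10)
  t <- 0
  n_steps <- 0L
  traj <- if (keep_trajectory) list(c(0, reduced_to_state(x, pr))) else NULL
  repeat {
    f <- rhs_reduced(x, pr)
    if (max(abs(f)) <= dtol) break
    if (t >= t_max) {
      pc_stop("pc_convergence_error",
              sprintf("no steady state within t_max = %g (max|dx/dt| = %g)",
                      t_max, max(abs(f))),
              last_state = reduced_to_state(x, pr), time = t)
    }
    h <- min(h, t_max - t)
    # backward Euler step solved by Newton
    ok <- FALSE
    repeat {
      xn <- x
      conv <- FALSE
      for (it in 1:12) {
        g <- xn - x - h * rhs_reduced(xn, pr)
        if (max(abs(g)) <= 1e-12 * scale + 1e-10 * max(abs(xn))) {
          conv <- TRUE
          break
        }
        A <- diag(3L) - h * jac_reduced(xn, pr)
        dx <- solve3(A, -g)
        if (anyNA(dx)) break
        xn <- xn + dx
        if (max(abs(dx)) <= 1e-13 * scale) {
          conv <- TRUE
          break
        }
      }
      if (conv && min(xn) >= -1e-12 * scale &&
          (pr$W_T - sum(xn)) >= -1e-12 * scale &&
          xn[2L] <= pr$K_T + 1e-12 * scale &&
          xn[3L] <= pr$P_T + 1e-12 * scale) {
        ok <- TRUE
        break
      }
      h <- h / 4
      if (h < 1e-300) {
        pc_stop("pc_convergence_error", "step size underflow",
                last_state = reduced_to_state(x, pr), time = t)
      }
    }
    x <- pmax(xn, 0)
    t <- t + h
    n_steps <- n_steps + 1L
    if (keep_trajectory) traj[[length(traj) + 1L]] <- c(t, reduced_to_state(x, pr))
    h <- h * 2  # pseudo-transient growth toward the attractor
    if (n_steps > 100000L) {
      pc_stop("pc_convergence_error", "step budget exhausted",
              last_state = reduced_to_state(x, pr), time = t)
    }
  }
  x <- newton_polish(x, pr)
  out <- reduced_to_state(x, pr)
  attr(out, "time") <- t
  attr(out, "n_steps") <- n_steps
  if (keep_trajectory) {
    m <- do.call(rbind, traj)
    colnames(m) <- c("time", "W", "Wp", "WK", "WpP", "K", "P")
    attr(out, "trajectory") <- as.data.frame(m)
  }
  out
}

#' Write a time course as CSV
#'
#' @param trajectory data frame with columns `time,W,Wp,WK,WpP,K,P`, e.g. the
#'   `"trajectory"` attribute of [integrate_to_steady_state()].
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_time_course <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
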
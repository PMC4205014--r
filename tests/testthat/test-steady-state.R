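test_that("complex_concentrations implements the Michaelis relations", {
  p <- make_cycle_parameters(1, 1, 1, 1, 1, 1, W_T = 10, K_T = 2, P_T = 3)
  # Km1 = Km2 = 2
  expect_identical(unname(complex_concentrations(0, 0, p)), c(0, 0))
  expect_equal(complex_concentrations(p$Km1, 0, p)[["WK"]], p$K_T / 2)
  p2 <- make_cycle_parameters(2, 1, 1, 1, 1, 1, W_T = 10, K_T = 2, P_T = 3)
  expect_equal(complex_concentrations(3, 0, p2)[["WK"]], 1.5)  # Km1 = 1
  expect_error(complex_concentrations(-1, 0, p), class = "pc_invalid_state")
})

test_that("nondimensionalize produces the documented ratios", {
  p <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 2, K_T = 0.002, P_T = 0.5)
  nd <- nondimensionalize(p)
  expect_equal(nd$kappa1, p$Km1 / p$W_T)
  expect_equal(nd$kappa1, 0.5)
  expect_equal(nd$eps_K, 1e-3)
  expect_equal(nd$v_ratio, (p$k1 * p$K_T) / (p$k2 * p$P_T))
  # balanced maximal rates
  pb <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0.3, P_T = 0.3)
  expect_equal(nondimensionalize(pb)$v_ratio, 1)
  # k2*P_T = 0 is flagged, not an error
  pinf <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0.3, P_T = 0)
  ndinf <- nondimensionalize(pinf)
  expect_true(ndinf$v_infinite)
  expect_identical(ndinf$v_ratio, Inf)
})

test_that("the cubic vanishes at the numeric root and the balance function is increasing", {
  sets <- sample_parameters(wide_regime(31), 100)
  for (pr in sets) {
    nd <- nondimensionalize(pr)
    w <- solve_steady_state_numeric(pr)$root
    co <- tryCatch(cubic_coefficients(nd),
                   pc_degenerate_cubic = function(e) NULL)
    if (!is.null(co)) {
      scale <- max(abs(co$c3), abs(co$c2), abs(co$c1), abs(co$c0))
      Fw <- ((co$c3 * w + co$c2) * w + co$c1) * w + co$c0
      expect_lt(abs(Fw) / scale, 1e-8)
      # bracket endpoints have opposite (or zero) signs
      F0 <- co$c0
      Fd <- ((co$c3 * co$domain_max + co$c2) * co$domain_max + co$c1) *
        co$domain_max + co$c0
      expect_lte(sign(F0) * sign(Fd), 0)
    }
    # derivative of the monotone balance positive across the domain
    fn <- steady_state_fn(nd)
    ws <- seq(1e-6, fn$domain_max * (1 - 1e-9), length.out = 50)
    expect_true(all(fn$dG(ws) > 0))
  }
})

test_that("real_root solves a constructed factorization exactly", {
  # (w - c) * (w^2 + 1): unique real root at c
  for (cval in c(0.1, 0.4, 0.9)) {
    co <- list(c3 = 1, c2 = -cval, c1 = 1, c0 = -cval, domain_max = 1)
    expect_equal(real_root(co), cval, tolerance = 1e-12)
  }
  expect_error(real_root(list(c3 = 0, c2 = 1, c1 = 1, c0 = -0.5,
                              domain_max = 1)),
               class = "pc_degenerate_cubic")
  # root outside the admissible domain is an internal-consistency error
  expect_error(real_root(list(c3 = 1, c2 = -2, c1 = 1, c0 = -2,
                              domain_max = 1)),
               class = "pc_root_domain")
})

test_that("closed-form root matches bracketed root finding to 1e-10 (1000 sets)", {
  sets <- sample_parameters(wide_regime(32), 1000)
  worst <- 0
  for (pr in sets) {
    a <- solve_quietly(pr)
    b <- solve_steady_state_numeric(pr)
    worst <- max(worst, abs(a$root - b$root))
  }
  expect_lt(worst, 1e-10)
})

test_that("closed form agrees with the ODE oracle per species (seeded sets)", {
  sets <- sample_parameters(wide_regime(33), 200)
  for (pr in sets) {
    a <- solve_quietly(pr)
    o <- integrate_to_steady_state(pr, t_max = 1e12)
    expect_lt(rel_diff(state_vec(a$state), state_vec(o), 1e-9 * pr$W_T), 1e-6)
  }
})

test_that("symmetric parameters give the half-phosphorylated fixed point", {
  p <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0.4, P_T = 0.4)
  for (sol in list(solve_quietly(p), solve_steady_state_numeric(p))) {
    expect_equal(sol$p, 0.5, tolerance = 1e-12)
    s <- state_vec(sol$state)
    expect_equal(s[["W"]], s[["Wp"]])
    expect_equal(s[["WK"]], s[["WpP"]])
  }
})

test_that("degenerate-flux limits short-circuit correctly", {
  pK0 <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0, P_T = 0.5)
  for (sol in list(solve_steady_state(pK0), solve_steady_state_numeric(pK0))) {
    expect_identical(sol$p, 0)
    expect_identical(sol$state[["Wp"]], 0)
  }
  pP0 <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0.5, P_T = 0)
  expect_identical(solve_steady_state(pP0)$p, 1)
  expect_equal(solve_steady_state(pP0)$state[["Wp"]], 1)
  # k2 = 0 with P_T > 0: still fully phosphorylated, but phosphatase-bound
  pk20 <- make_cycle_parameters(2, 1, 1, 2, 1, 0, W_T = 1, K_T = 0.5, P_T = 0.5)
  sol <- solve_steady_state(pk20)
  expect_identical(sol$p, 1)
  expect_gt(sol$state[["WpP"]], 0)
  o <- integrate_to_steady_state(pk20, t_max = 1e12)
  expect_lt(rel_diff(state_vec(sol$state), state_vec(o)), 1e-6)
})

test_that("flux balance and conservation hold at the closed-form steady state", {
  sets <- sample_parameters(wide_regime(34), 200)
  for (pr in sets) {
    sol <- solve_quietly(pr)
    s <- state_vec(sol$state)
    f1 <- pr$k1 * s[["WK"]]
    f2 <- pr$k2 * s[["WpP"]]
    expect_lt(abs(f1 - f2) / max(f1, f2), 1e-8)
    expect_lt(max(abs(conservation_residuals(sol$state, pr))), 1e-8 * pr$W_T)
    expect_gte(sol$p, 0)
    expect_lte(sol$p, 1)
  }
})

test_that("p responds monotonically to the enzyme totals", {
  base <- quick_params(0.1, 0.1, 1, kap1 = 0.5, kap2 = 2)
  KTs <- 10^seq(-3, 1, length.out = 25)
  pK <- vapply(KTs, function(KT) {
    pr <- make_cycle_parameters(base$a1, base$d1, base$k1, base$a2, base$d2,
                                base$k2, base$W_T, KT, base$P_T)
    solve_quietly(pr)$p
  }, 0)
  expect_true(all(diff(pK) >= -1e-12))
  PTs <- 10^seq(-3, 1, length.out = 25)
  pP <- vapply(PTs, function(PT) {
    pr <- make_cycle_parameters(base$a1, base$d1, base$k1, base$a2, base$d2,
                                base$k2, base$W_T, base$K_T, PT)
    solve_quietly(pr)$p
  }, 0)
  expect_true(all(diff(pP) <= 1e-12))
})

test_that("solutions can be written as CSV with the documented schema", {
  p <- quick_params(0.5, 0.5, 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_solutions_csv(list(solve_steady_state(p),
                           solve_steady_state_numeric(p)), path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("method", "p", "W", "Wp", "WK", "WpP",
                                  "K", "P", "residual"))
  expect_identical(back$method, c("closed_form", "numeric"))
})
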
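test_that("make_cycle_parameters derives Michaelis constants and rejects bad input", {
  p <- make_cycle_parameters(1, 1, 1, 1, 1, 1, W_T = 1, K_T = 0.1, P_T = 0.1)
  expect_identical(p$Km1, 2)
  p2 <- make_cycle_parameters(2, 0.5, 1.5, 4, 1, 1, W_T = 2, K_T = 0.1, P_T = 0.1)
  expect_identical(p2$Km1, 1)
  expect_identical(p2$Km2, 0.5)

  expect_error(make_cycle_parameters(1, 1, 1, 1, 1, 1, W_T = 0, K_T = 1, P_T = 1),
               class = "pc_invalid_parameter")
  expect_error(make_cycle_parameters(-1, 1, 1, 1, 1, 1, W_T = 1, K_T = 1, P_T = 1),
               class = "pc_invalid_parameter")
  expect_error(make_cycle_parameters(0, 1, 1, 1, 1, 1, W_T = 1, K_T = 1, P_T = 1),
               class = "pc_invalid_parameter")  # a1 = 0 with K_T > 0
  expect_error(make_cycle_parameters(1, 1, 1, 1, 1, NA, W_T = 1, K_T = 1, P_T = 1),
               class = "pc_invalid_parameter")
  # a1 = 0 is fine when there is no kinase
  expect_silent(make_cycle_parameters(0, 0, 0, 1, 1, 1, W_T = 1, K_T = 0, P_T = 1))
})

test_that("reaction_rhs reproduces hand-evaluated mass-action terms", {
  p <- make_cycle_parameters(1, 2, 3, 4, 5, 6, W_T = 10, K_T = 8, P_T = 10)
  # all-zero state -> all-zero derivative
  z <- make_cycle_state(0, 0, 0, 0, 0, 0)
  expect_identical(unname(reaction_rhs(z, p)), rep(0, 6))
  # single binding event: dWK = a1*W*K
  s1 <- make_cycle_state(W = 1, Wp = 0, WK = 0, WpP = 0, K = 1, P = 1)
  d1 <- reaction_rhs(s1, p)
  expect_identical(d1[["WK"]], 1)
  expect_identical(d1[["W"]], -1)
  expect_identical(d1[["K"]], -1)
  expect_identical(unname(d1[c("Wp", "WpP", "P")]), c(0, 0, 0))
  # full state, frozen hand evaluation of every term
  s2 <- make_cycle_state(W = 1, Wp = 2, WK = 3, WpP = 4, K = 5, P = 6)
  d2 <- reaction_rhs(s2, p)
  expect_equal(unname(d2[species_names]), c(25, -19, -10, 4, 10, -4))
  # cross-check against an independent stoichiometry-matrix evaluation
  N <- matrix(c(
    # bind1 diss1 cat1 bind2 diss2 cat2
    -1, 1, 0, 0, 0, 1,   # W
    0, 0, 1, -1, 1, 0,   # Wp
    1, -1, -1, 0, 0, 0,  # WK
    0, 0, 0, 1, -1, -1,  # WpP
    -1, 1, 1, 0, 0, 0,   # K
    0, 0, 0, -1, 1, 1    # P
  ), nrow = 6, byrow = TRUE, dimnames = list(species_names, NULL))
  flux <- c(p$a1 * s2[["W"]] * s2[["K"]], p$d1 * s2[["WK"]], p$k1 * s2[["WK"]],
            p$a2 * s2[["Wp"]] * s2[["P"]], p$d2 * s2[["WpP"]], p$k2 * s2[["WpP"]])
  expect_equal(unname(d2[species_names]), as.numeric(N %*% flux))
  expect_error(reaction_rhs(c(W = -1, Wp = 0, WK = 0, WpP = 0, K = 1, P = 1), p),
               class = "pc_invalid_state")
})

test_that("derivatives satisfy structural conservation for random states", {
  set.seed(11)
  p <- make_cycle_parameters(1.3, 0.7, 2.1, 0.9, 1.8, 0.4,
                             W_T = 5, K_T = 2, P_T = 3)
  for (i in 1:50) {
    s <- stats::runif(6, 0, 3)
    names(s) <- species_names
    d <- reaction_rhs(s, p)
    expect_equal(sum(d[c("W", "Wp", "WK", "WpP")]), 0)
    expect_equal(d[["K"]], -d[["WK"]])
    expect_equal(d[["P"]], -d[["WpP"]])
  }
})

test_that("conservation_residuals measures deviation from the totals", {
  p <- make_cycle_parameters(1, 1, 1, 1, 1, 1, W_T = 2, K_T = 0.5, P_T = 0.25)
  r0 <- conservation_residuals(default_initial_state(p), p)
  expect_identical(unname(r0), c(0, 0, 0))
  s <- make_cycle_state(W = 2 + 0.125, Wp = 0, WK = 0, WpP = 0,
                        K = 0.5, P = 0.25)
  expect_equal(unname(conservation_residuals(s, p)), c(0.125, 0, 0))
})

test_that("integrator handles the no-kinase and no-phosphatase limits", {
  p0 <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0, P_T = 0.5)
  s0 <- integrate_to_steady_state(p0)
  expect_identical(s0[["Wp"]], 0)
  expect_identical(s0[["WpP"]], 0)
  expect_equal(s0[["W"]], 1)

  p1 <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0.5, P_T = 0)
  s1 <- integrate_to_steady_state(p1)
  expect_equal(s1[["Wp"]], 1, tolerance = 1e-9)
  expect_lt(s1[["W"]], 1e-9)
  expect_lt(s1[["WK"]], 1e-9)
})

test_that("integration conserves totals and positivity along the trajectory", {
  sets <- sample_parameters(wide_regime(21), 10)
  for (pr in sets) {
    st <- integrate_to_steady_state(pr, keep_trajectory = TRUE, t_max = 1e12)
    tr <- attr(st, "trajectory")
    expect_lt(max(abs(tr$W + tr$Wp + tr$WK + tr$WpP - pr$W_T)), 1e-9 * pr$W_T)
    expect_lt(max(abs(tr$K + tr$WK - pr$K_T)), 1e-9 * max(pr$K_T, pr$W_T))
    expect_lt(max(abs(tr$P + tr$WpP - pr$P_T)), 1e-9 * max(pr$P_T, pr$W_T))
    expect_gte(min(as.matrix(tr[, -1L])), -1e-12 * pr$W_T)
  }
})

test_that("the steady state is a unique attractor across initial conditions", {
  # >= 100 seeded sets x 3 distinct valid initial states
  sets <- sample_parameters(wide_regime(22), 100)
  for (pr in sets) {
    wk <- min(pr$K_T, pr$W_T) / 2
    wpp <- min(pr$P_T, (pr$W_T - wk)) / 2
    inits <- list(
      default_initial_state(pr),
      make_cycle_state(0, pr$W_T, 0, 0, pr$K_T, pr$P_T),
      make_cycle_state(pr$W_T - wk - wpp, 0, wk, wpp,
                       pr$K_T - wk, pr$P_T - wpp))
    term <- lapply(inits, function(s0) {
      state_vec(integrate_to_steady_state(pr, s0, t_max = 1e12))
    })
    expect_lt(rel_diff(term[[1]], term[[2]], 1e-9 * pr$W_T), 1e-5)
    expect_lt(rel_diff(term[[1]], term[[3]], 1e-9 * pr$W_T), 1e-5)
  }
})

test_that("integrator rejects inconsistent initial states and reports non-convergence", {
  p <- make_cycle_parameters(2, 1, 1, 2, 1, 1, W_T = 1, K_T = 0.5, P_T = 0.5)
  bad <- make_cycle_state(2, 0, 0, 0, 0.5, 0.5)  # substrate total violated
  expect_error(integrate_to_steady_state(p, bad), class = "pc_invalid_state")
  # very slow kinetics cannot converge within a tiny horizon
  slow <- make_cycle_parameters(1e-6, 1e-7, 1e-7, 1e-6, 1e-7, 1e-7,
                                W_T = 1, K_T = 0.5, P_T = 0.5)
  err <- tryCatch(integrate_to_steady_state(slow, t_max = 1),
                  pc_convergence_error = function(e) e)
  expect_s3_class(err, "pc_convergence_error")
  expect_s3_class(err$last_state, "cycle_state")
})

test_that("config round trip preserves parameters; time courses are written as CSV", {
  p <- make_cycle_parameters(1.25, 0.5, 2, 0.75, 1.5, 3,
                             W_T = 2, K_T = 0.25, P_T = 0.5)
  path <- withr::local_tempfile(fileext = ".cfg")
  write_cycle_config(p, path)
  expect_equal(unclass(read_cycle_config(path)), unclass(p))
  # JSON dialect
  jpath <- withr::local_tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(unclass(p)[c("a1","d1","k1","a2","d2","k2",
                                           "W_T","K_T","P_T")],
                              auto_unbox = TRUE), jpath)
  expect_equal(unclass(read_cycle_config(jpath)), unclass(p))
  expect_error(read_cycle_config(withr::local_tempfile(fileext = ".cfg")),
               class = "pc_invalid_config")

  st <- integrate_to_steady_state(p, keep_trajectory = TRUE)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_time_course(attr(st, "trajectory"), csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("time", "W", "Wp", "WK", "WpP", "K", "P"))
  expect_equal(nrow(back), nrow(attr(st, "trajectory")))
})
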
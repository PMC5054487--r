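test_that("a dead system (no enzymes, no pools, no demand) has zero residuals", {
  m <- default_consortium()
  m$enzymes[] <- 0
  st <- compartment_state(m, matrix(0, 2, 2), c(X = 0, P = 0))
  expect_equal(unname(balance_residuals(m, st)), rep(0, 6))
})

test_that("residuals equal the hand-assembled combination of the rate laws", {
  for (seed in 1:5) {
    m <- default_consortium(inv_K_I = 10, permeabilities = c(2, 0.3))
    set.seed(seed)
    m$enzymes[] <- runif(6, 0, 3)
    st <- random_state(m, seed + 100)
    res <- balance_residuals(m, st)
    for (i in 1:2) {
      X <- st$intra[i, 1]; P <- st$intra[i, 2]
      VS <- synthesis_rate(m$kinetics[[1]], m$enzymes[i, 1],
                           m$substrate_conc, X, inhibitor = P)
      VX <- synthesis_rate(m$kinetics[[2]], m$enzymes[i, 2], X, P)
      VP <- consumption_rate(m$kinetics[[3]], m$enzymes[i, 3], P)
      UX <- transport_rate(m$permeabilities[["X"]], X, st$extra[["X"]])
      UP <- transport_rate(m$permeabilities[["P"]], P, st$extra[["P"]])
      expect_equal(unname(res[paste0("cell", i, ".X")]), VS - VX - UX)
      expect_equal(unname(res[paste0("cell", i, ".P")]), VX - VP - UP)
    }
    n <- m$fractions; N <- m$total_cells
    U1 <- transport_rate(m$permeabilities, st$intra[1, ], st$extra)
    U2 <- transport_rate(m$permeabilities, st$intra[2, ], st$extra)
    expect_equal(unname(res["medium.X"]),
                 unname(N * (n[1] * U1[1] + n[2] * U2[1])))
    expect_equal(unname(res["medium.P"]),
                 unname(N * (n[1] * U1[2] + n[2] * U2[2] - m$host_demand)))
  }
})

test_that("a root-found single-cell steady state duplicated in both cells balances", {
  m <- default_consortium(inv_K_I = 0.5)
  m$enzymes[] <- 1
  ss <- single_cell_steady(c(1, 1, 1), S = 10, inv_K_I = 0.5)
  expect_false(is.null(ss))
  # identical cells, medium in equilibrium with them: no exchange anywhere
  st <- compartment_state(m, rbind(c(ss$X, ss$P), c(ss$X, ss$P)),
                          c(X = ss$X, P = ss$P))
  expect_lt(max(abs(balance_residuals(m, st))), 1e-9)
})

test_that("host demand enters the extracellular product balance only", {
  m <- default_consortium(host_demand = 0.4)
  st <- random_state(m, 1)
  res0 <- balance_residuals(m, st)
  m2 <- m; m2$host_demand <- 0
  res1 <- balance_residuals(m2, st)
  expect_equal(unname(res0["medium.P"] - res1["medium.P"]),
               -m$total_cells * 0.4)
  keep <- setdiff(names(res0), "medium.P")
  expect_equal(res0[keep], res1[keep])
})

test_that("dynamics hold a steady state fixed and relax pure diffusion", {
  fit <- optimize_allocation(default_consortium(inv_K_I = 10,
                                                permeabilities = c(10, 0.1)),
                             options = fast_opts())
  tr <- simulate(fit, horizon = 40)
  final <- attr(tr, "final_state")
  expect_equal(final$intra, fit$state$intra, tolerance = 1e-5)
  expect_equal(final$extra, fit$state$extra, tolerance = 1e-5)

  # no enzymes: an intracellular X pool equilibrates with the medium
  m <- default_consortium(permeabilities = c(1, 1))
  m$enzymes[] <- 0
  st <- compartment_state(m, rbind(c(4, 0), c(0, 0)), c(X = 0, P = 0))
  tr <- simulate_dynamics(m, st, horizon = 400)
  fin <- attr(tr, "final_state")
  xs <- c(fin$intra[, 1], fin$extra[["X"]])
  expect_lt(max(xs) - min(xs), 1e-4)
})

test_that("with no permeability the medium has no pools and cells are isolated", {
  m <- default_consortium(permeabilities = c(0, 0))
  st <- compartment_state(m, rbind(c(1, 1), c(2, 2)))
  expect_length(st$extra, 0)
  res <- balance_residuals(m, st)
  expect_false(any(grepl("^medium", names(res))))
})

test_that("steady-state solutions are independent of the total population size", {
  for (N in c(1, 1e6)) {
    m <- default_consortium(inv_K_I = 10, permeabilities = c(10, 0.1),
                            total_cells = N)
    fit <- optimize_allocation(m, options = fast_opts())
    if (N == 1) ref <- fit
    expect_equal(fit$state$intra, ref$state$intra, tolerance = 1e-10)
    expect_equal(fit$cost, ref$cost, tolerance = 1e-10)
    expect_lt(fit$steady_state$residual_norm, 1e-8)
  }
})
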
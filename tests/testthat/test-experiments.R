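test_that("regime classification separates neutralist, cheater and complementation", {
  # neutralist: symmetric, no exchange
  neu <- optimize_allocation(default_consortium(inv_K_I = 0.1),
                             options = fast_opts())
  expect_identical(classify_regime(neu), "neutralist")
  # cheater: X flows to cell 2 but P cannot cross the membrane at all
  che <- optimize_allocation(default_consortium(inv_K_I = 10,
                                                permeabilities = c(10, 0)),
                             options = fast_opts())
  expect_identical(classify_regime(che), "cheater")
  expect_equal(unname(che$asymmetries["E_S"]), 1)
  expect_gt(che$fluxes$U[1, "X"], 0)
  expect_equal(unname(che$fluxes$U[1, "P"]), 0)
  # complementation: X one way, P shuttled back
  com <- optimize_allocation(default_consortium(inv_K_I = 10,
                                                permeabilities = c(10, 0.5)),
                             options = fast_opts())
  expect_identical(classify_regime(com), "complementation")
  expect_lt(com$fluxes$U[1, "P"], 0)
  # classification refuses unconverged solutions
  bad <- optimize_allocation(default_consortium(host_demand = 1,
                                                permeabilities = c(1, 0)),
                             options = fast_opts())
  expect_error(classify_regime(bad), "unconverged")
})

test_that("regime labels are invariant under cell relabelling", {
  fit <- optimize_allocation(default_consortium(inv_K_I = 10,
                                                permeabilities = c(10, 0.5)),
                             options = fast_opts())
  flipped <- fit
  flipped$asymmetries <- -fit$asymmetries
  flipped$fluxes$U <- fit$fluxes$U[2:1, , drop = FALSE]
  flipped$enzymes <- fit$enzymes[2:1, ]
  expect_identical(classify_regime(flipped), classify_regime(fit))
})

test_that("a small strong-inhibition phase diagram shows the expected regime structure", {
  D <- exp(seq(log(0.05), log(25), length.out = 4))
  pd <- phase_diagram(D_X_values = D, D_P_values = D, inv_K_I_values = 10,
                      options = fast_opts(seed = 8))
  expect_s3_class(pd, "phase_diagram")
  expect_equal(nrow(pd), 16L)
  expect_true(all(pd$feasible))
  # asymmetry appears only where D_X is large relative to D_P
  asym <- pd$A_S > 0.5
  expect_true(any(asym))
  expect_true(all(pd$D_X[asym] / pd$D_P[asym] >
                    min(pd$D_X[!asym] / pd$D_P[!asym])))
  # within the asymmetric region: A_S = 1 exactly, A_X < 0, A_P > 0
  expect_true(all(abs(pd$A_S[asym] - 1) < 1e-9))
  expect_true(all(pd$A_X[asym] < 0))
  expect_true(all(pd$A_P[asym] > 0))
  # costs vary smoothly along D_P within the same regime
  for (dx in D) {
    row <- pd[pd$D_X == dx, ]
    same <- diff(as.integer(factor(row$regime))) == 0
    jumps <- abs(diff(row$cost)) / row$cost[-1]
    expect_true(all(jumps[same] < 0.10))
  }
})

test_that("demand asymmetry pushes the split orientation the other way round", {
  sw <- allocation_sweep(default_consortium(inv_K_I = 10,
                                            permeabilities = c(10, 2)),
                         param = "rho_J", values = c(0, 0.6),
                         options = fast_opts(n_starts = 8))
  base <- sw[sw$value == 0, ]
  ref <- optimize_allocation(default_consortium(inv_K_I = 10,
                                                permeabilities = c(10, 2)),
                             options = fast_opts(n_starts = 8))
  expect_equal(base$cost, ref$cost, tolerance = 1e-6)
  # with J_P,1 > J_P,2 the producing role falls to cell 2: complete splitting
  # with E_S,1 = E_X,2 = 0
  hi <- attr(sw, "fits")[[2]]
  expect_equal(unname(hi$enzymes[1, "E_S"]), 0)
  expect_equal(unname(hi$enzymes[2, "E_X"]), 0)
})

test_that("optimal cost increases with the host demand", {
  sw <- allocation_sweep(default_consortium(inv_K_I = 10,
                                            permeabilities = c(5, 2)),
                         param = "host_demand", values = c(0, 0.5, 1),
                         options = fast_opts(n_starts = 8))
  expect_true(all(diff(sw$cost) > 0))
})

test_that("unequal populations keep the sweep feasible and enhance asymmetry", {
  sw <- allocation_sweep(default_consortium(inv_K_I = 10,
                                            permeabilities = c(5, 2)),
                         param = "n1", values = c(0.5, 0.25),
                         options = fast_opts(n_starts = 8))
  expect_true(all(sw$feasible))
  expect_gte(abs(sw$A_X[sw$value == 0.25]), abs(sw$A_X[sw$value == 0.5]))
})

test_that("sensitivity covariances vanish when A_S never moves", {
  # deep inside the symmetric region every perturbed optimum stays symmetric
  m <- default_consortium(inv_K_I = 0.1, permeabilities = c(0.2, 0.2))
  sens <- sensitivity_analysis(m, rel_magnitude = 0.1, n_samples = 12,
                               seed = 3)
  expect_equal(sens$n_converged, 12L)
  expect_true(all(abs(sens$estimates$covariance) < 1e-10))
})

test_that("sensitivity analysis is reproducible given the seed", {
  b <- find_regime_boundary(options = fast_opts(n_starts = 4))
  s1 <- sensitivity_analysis(b$model, n_samples = 10, seed = 21)
  s2 <- sensitivity_analysis(b$model, n_samples = 10, seed = 21)
  expect_identical(s1$estimates, s2$estimates)
  expect_identical(s1$samples, s2$samples)
})

test_that("split_point reads clean and near-clean partitions and rejects others", {
  # hand-built: cell 1 runs steps 1-2, cell 2 the rest (consumption ignored)
  E <- rbind(c(1, 1, 0, 0, 0, 0, 1e-4), c(0, 0, 1, 1, 1, 1, 1))
  expect_identical(split_point(E), 2L)
  expect_identical(split_point(rbind(c(1, 1, 1), c(1, 1, 1))), NA_integer_)
  # mixed expression on both sides of every cut is no split
  E2 <- rbind(c(1, 0, 1, 0, 1, 0, 1), c(0, 1, 0, 1, 0, 1, 1))
  expect_identical(split_point(E2), NA_integer_)
})

test_that("the extended chain splits at the permeable intermediate", {
  ex <- extended_split_experiment(3, options = solver_options(n_starts = 10,
                                                              seed = 13))
  expect_true(ex$fit$converged)
  expect_identical(ex$split, 3L)
  expect_equal(unname(ex$fit$asymmetries["E_S"]), 1)
  # cell 2 runs nothing upstream of the permeable metabolite
  expect_equal(unname(ex$fit$enzymes[2, 1:3]), c(0, 0, 0))
  # residual co-expression downstream in cell 1 is percent-level, so a strict
  # partition threshold reports no clean split: the clean pattern is the
  # limit, not the exact optimum
  expect_identical(split_point(ex$fit, tol = 1e-6), NA_integer_)
})

test_that("with every intermediate impermeable the extended chain stays symmetric", {
  m <- extended_consortium(1, D_permeable = 15, D_impermeable = 1e-3)
  m$permeabilities[1] <- 1e-3          # now only P permeates
  fit <- optimize_allocation(m, options = solver_options(n_starts = 8,
                                                         seed = 9))
  expect_true(fit$converged)
  expect_equal(max(abs(fit$asymmetries)), 0, tolerance = 1e-8)
  expect_identical(split_point(fit), NA_integer_)
})

test_that("the general machinery at m = 1 agrees with the base model", {
  for (seed in 1:3) {
    set.seed(seed)
    D <- exp(runif(2, log(0.2), log(10)))
    ki <- exp(runif(1, log(0.5), log(20)))
    mm <- default_consortium(inv_K_I = ki, permeabilities = D)
    f1 <- optimize_allocation(mm, options = fast_opts(seed = 30 + seed))
    f2 <- optimize_allocation(mm, options = fast_opts(seed = 60 + seed,
                                                      n_starts = 10))
    expect_equal(f1$cost, f2$cost, tolerance = 1e-4)
    expect_equal(unname(abs(f1$asymmetries["E_S"])),
                 unname(abs(f2$asymmetries["E_S"])), tolerance = 1e-4)
  }
})
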
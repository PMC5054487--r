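## Return a copy of a model with selected parameters replaced.  Used by the
## sweep drivers; validation matches the constructor's.
.model_with <- function(model, inv_K_I = NULL, inhibition_mode = NULL,
                        D_X = NULL, D_P = NULL, demands = NULL,
                        host_demand = NULL, fractions = NULL) {
  m <- model$chain_length
  if (!is.null(inv_K_I)) {
    model$kinetics[[1]]$inv_K_I <- inv_K_I
    if (inv_K_I > 0 && model$kinetics[[1]]$inhibition_mode == "none")
      model$kinetics[[1]]$inhibition_mode <- "uncompetitive"
    if (inv_K_I == 0) model$kinetics[[1]]$inhibition_mode <- "none"
  }
  if (!is.null(inhibition_mode) && model$kinetics[[1]]$inv_K_I > 0)
    model$kinetics[[1]]$inhibition_mode <- inhibition_mode
  if (!is.null(D_X)) {
    stopifnot(m == 1L)
    model$permeabilities[1L] <- D_X
  }
  if (!is.null(D_P)) model$permeabilities[m + 1L] <- D_P
  if (!is.null(demands)) model$demands <- demands
  if (!is.null(host_demand)) model$host_demand <- host_demand
  if (!is.null(fractions)) model$fractions <- fractions
  model
}

## One tidy summary row for a fit (two-reaction model).
.fit_row <- function(fit) {
  if (!fit$feasible)
    return(data.frame(cost = NA_real_, A_S = NA_real_, A_X = NA_real_,
                      A_P = NA_real_, U_X1 = NA_real_, U_P1 = NA_real_,
                      E_S2_frac = NA_real_, E_X1_frac = NA_real_,
                      regime = "infeasible", boundary = FALSE,
                      feasible = FALSE, converged = FALSE))
  E <- fit$enzymes
  tot <- sum(E)
  m <- fit$model$chain_length
  data.frame(cost = fit$cost,
             A_S = unname(fit$asymmetries[1L]),
             A_X = unname(fit$asymmetries[2L]),
             A_P = unname(fit$asymmetries[m + 2L]),
             U_X1 = unname(fit$fluxes$U[1L, 1L]),
             U_P1 = unname(fit$fluxes$U[1L, m + 1L]),
             E_S2_frac = E[2L, 1L] / tot,
             E_X1_frac = E[1L, 2L] / tot,
             regime = classify_regime(fit),
             boundary = fit$boundary,
             feasible = TRUE, converged = fit$converged)
}

#' Map optimal allocation regimes over the permeability plane
#'
#' For each inhibition strength, optimizes the consortium over a grid of
#' intermediate/product permeabilities `(D_X, D_P)`, warm-starting along each
#' `D_P` row (continuation) with a fresh multistart fallback, and records the
#' cost, enzyme asymmetries, exchange fluxes and regime label at every point.
#'
#' @param model A two-reaction [consortium_model()] template.
#' @param D_X_values,D_P_values Nonnegative permeability grids.
#' @param inv_K_I_values Inhibition strengths `1/K_I` (one slice each).
#' @param options A [solver_options()].
#' @param regime_tol Tolerance passed to [classify_regime()].
#' @return A data.frame of class `"phase_diagram"`, one row per grid point,
#'   with columns `inv_K_I, D_X, D_P, cost, A_S, A_X, A_P, U_X1, U_P1,
#'   E_S2_frac, E_X1_frac, regime, boundary, feasible, converged`.
#' @export
phase_diagram <- function(model = default_consortium(),
                          D_X_values, D_P_values,
                          inv_K_I_values = c(0.1, 1, 10, 30),
                          options = solver_options(), regime_tol = 1e-3) {
  stopifnot(model$chain_length == 1L,
            length(D_X_values) >= 1, length(D_P_values) >= 1,
            all(D_X_values >= 0), all(D_P_values >= 0))
  rows <- list()
  for (ki in inv_K_I_values) {
    for (dx in D_X_values) {
      models <- lapply(D_P_values, function(dp)
        .model_with(model, inv_K_I = ki, D_X = dx, D_P = dp))
      fits <- continuation_sweep(models, options = options)
      for (j in seq_along(fits)) {
        row <- .fit_row(fits[[j]])
        rows[[length(rows) + 1L]] <-
          cbind(data.frame(inv_K_I = ki, D_X = dx, D_P = D_P_values[j]), row)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("phase_diagram", "data.frame")
  attr(out, "seed") <- options$seed
  out
}

#' Heat map of an asymmetry surface over the permeability plane
#'
#' @param x A [phase_diagram()] result.
#' @param what Column to plot (default the first-enzyme asymmetry `A_S`).
#' @param inv_K_I Which inhibition slice to show (default the first).
#' @param ... Passed to [graphics::image()].
#' @export
plot.phase_diagram <- function(x, what = "A_S", inv_K_I = NULL, ...) {
  if (is.null(inv_K_I)) inv_K_I <- x$inv_K_I[1L]
  sl <- x[x$inv_K_I == inv_K_I, ]
  dx <- sort(unique(sl$D_X)); dp <- sort(unique(sl$D_P))
  z <- matrix(NA_real_, length(dx), length(dp))
  z[cbind(match(sl$D_X, dx), match(sl$D_P, dp))] <- sl[[what]]
  graphics::image(log10(dx), log10(dp), z,
                  xlab = "log10 D_X", ylab = "log10 D_P",
                  main = sprintf("%s at 1/K_I = %g", what, inv_K_I), ...)
  invisible(x)
}

#' Classify the cooperative regime of a fitted allocation
#'
#' Labels a converged optimum as `"neutralist"` (identical allocation, no
#' exchange), `"cheater"` (one cell lacks the first enzyme and consumes leaked
#' intermediate without returning product), `"complementation"` (intermediate
#' flows one way and product is shuttled back), or `"boundary"` when the
#' pattern is mixed.  Labels are invariant under relabelling of the cells (the
#' fit is canonicalized to `A_S >= 0` before classification).
#'
#' @param fit A feasible, converged [optimize_allocation()] fit.
#' @param tol Tolerance on asymmetries and on exchange fluxes (the latter
#'   relative to the total demand).
#' @return A character label.
#' @export
classify_regime <- function(fit, tol = 1e-3) {
  stopifnot(inherits(fit, "allocation_fit"))
  if (!fit$feasible || !fit$converged)
    stop("cannot classify an unconverged solution", call. = FALSE)
  m <- fit$model$chain_length
  A <- fit$asymmetries
  U <- fit$fluxes$U
  if (A[1L] < 0) {        # canonical orientation: cell 1 carries E_S
    A <- -A
    U <- U[2:1, , drop = FALSE]
  }
  scale <- max(sum(fit$model$demands) + fit$model$host_demand, 1e-12)
  ftol <- tol * scale
  UX1 <- max(U[1L, seq_len(m)])       # largest intermediate export of cell 1
  UP1 <- U[1L, m + 1L]
  if (max(abs(A)) <= tol && max(abs(U)) <= ftol) return("neutralist")
  if (A[1L] >= 1 - tol && UX1 > ftol) {
    if (UP1 < -ftol) return("complementation")
    if (abs(UP1) <= ftol) return("cheater")
  }
  "boundary"
}

#' Sweep demand asymmetry, host demand, or population fraction
#'
#' Re-optimizes the consortium along one swept scalar: the demand-flux
#' asymmetry `rho_J = (J_P,1 - J_P,2) / (J_P,1 + J_P,2)` at fixed total
#' demand, the host demand `J_P,0`, or the population fraction `n1`.  Solves
#' are warm-started along the sweep.
#'
#' @param model A two-reaction [consortium_model()] template.
#' @param param One of `"rho_J"`, `"host_demand"`, `"n1"`.
#' @param values Sweep values (`rho_J` in `[0, 1)`, `host_demand >= 0`,
#'   `n1` in `(0, 1)`).
#' @param options A [solver_options()].
#' @return A data.frame of class `"allocation_sweep"`, one row per value,
#'   with the same summary columns as [phase_diagram()] plus the enzyme
#'   concentrations.
#' @export
allocation_sweep <- function(model = default_consortium(),
                             param = c("rho_J", "host_demand", "n1"),
                             values, options = solver_options()) {
  param <- match.arg(param)
  stopifnot(model$chain_length == 1L, length(values) >= 1)
  Jtot <- sum(model$demands)
  models <- lapply(values, function(v) {
    switch(param,
           rho_J = {
             stopifnot(v >= 0, v < 1)
             .model_with(model, demands = Jtot / 2 * c(1 + v, 1 - v))
           },
           host_demand = .model_with(model, host_demand = v),
           n1 = {
             stopifnot(v > 0, v < 1)
             .model_with(model, fractions = c(v, 1 - v))
           })
  })
  fits <- continuation_sweep(models, options = options)
  rows <- lapply(seq_along(fits), function(j) {
    row <- .fit_row(fits[[j]])
    E <- fits[[j]]$enzymes
    ed <- if (is.null(E)) {
      data.frame(E_S1 = NA_real_, E_X1 = NA_real_, E_P1 = NA_real_,
                 E_S2 = NA_real_, E_X2 = NA_real_, E_P2 = NA_real_)
    } else {
      data.frame(E_S1 = E[1, 1], E_X1 = E[1, 2], E_P1 = E[1, 3],
                 E_S2 = E[2, 1], E_X2 = E[2, 2], E_P2 = E[2, 3])
    }
    cbind(data.frame(param = param, value = values[j]), row, ed)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("allocation_sweep", "data.frame")
  attr(out, "fits") <- fits
  out
}

#' Locate the symmetric/asymmetric regime boundary along D_X
#'
#' Bisects `D_X` (at fixed `D_P` and inhibition strength) for the point where
#' the constrained symmetric and split strategies cost the same — the
#' transition line of the permeability phase diagram.
#'
#' @param model A two-reaction [consortium_model()] template.
#' @param inv_K_I Inhibition strength of the slice.
#' @param D_P Product permeability held fixed.
#' @param interval Search interval for `D_X`.
#' @param options A [solver_options()].
#' @param tol Relative bisection tolerance on `D_X`.
#' @return A list with the boundary `D_X`, the model at the boundary, and the
#'   two branch costs there.
#' @export
find_regime_boundary <- function(model = default_consortium(),
                                 inv_K_I = 10, D_P = 5,
                                 interval = c(0.05, 30),
                                 options = solver_options(n_starts = 8),
                                 tol = 1e-3) {
  gap <- function(dx) {
    mm <- .model_with(model, inv_K_I = inv_K_I, D_X = dx, D_P = D_P)
    cs <- optimize_allocation(mm, constraint = "symmetric",
                              options = options)$cost
    ca <- optimize_allocation(mm, constraint = "split", options = options)$cost
    if (!is.finite(ca)) ca <- Inf
    cs - ca                      # negative: symmetric cheaper
  }
  lo <- interval[1]; hi <- interval[2]
  if (gap(lo) >= 0 || gap(hi) <= 0)
    stop("no symmetric/asymmetric crossing inside the interval", call. = FALSE)
  while (hi / lo > 1 + tol) {
    mid <- sqrt(lo * hi)
    if (gap(mid) < 0) lo <- mid else hi <- mid
  }
  dx <- sqrt(lo * hi)
  mm <- .model_with(model, inv_K_I = inv_K_I, D_X = dx, D_P = D_P)
  list(D_X = dx, D_P = D_P, inv_K_I = inv_K_I, model = mm)
}

#' Seeded sensitivity analysis of the asymmetric optimum
#'
#' Randomly perturbs every positive kinetic parameter of a base model
#' (multiplicatively, log-uniform with half-width `rel_magnitude`), re-fits
#' the optimal allocation for each sample, and summarizes how the optimal
#' first-enzyme asymmetry `A_S` co-varies with each parameter: the sample
#' covariance `cov(A_S, k_i)` and, as a scale-free companion, the Pearson
#' correlation.  The base point should sit near the symmetric/asymmetric
#' boundary (see [find_regime_boundary()]) so that perturbations can tip the
#' optimum either way.
#'
#' @param model Base-point [consortium_model()].
#' @param rel_magnitude Half-width of the log-uniform perturbation.
#' @param n_samples Number of parameter samples (>= 2).
#' @param seed Integer seed controlling the whole analysis.
#' @param options A [solver_options()] for the per-sample fits (branch search
#'   with a few starts keeps 200 samples affordable).
#' @return A list of class `"sensitivity_result"`: data.frame `estimates`
#'   (`parameter`, `covariance`, `correlation`), `A_S` per sample, the sample
#'   matrix, counts and the seed.
#' @export
sensitivity_analysis <- function(model, rel_magnitude = 0.3, n_samples = 200,
                                 seed = 1,
                                 options = solver_options(n_starts = 4,
                                                          search = "branches")) {
  stopifnot(n_samples >= 2)
  base <- .parameter_vector(model)
  samples <- matrix(NA_real_, n_samples, length(base),
                    dimnames = list(NULL, names(base)))
  A_S <- rep(NA_real_, n_samples)
  seeds <- .with_seed(seed, sample.int(2^31 - 2, n_samples + 1))
  for (s in seq_len(n_samples)) {
    draw <- sample_perturbed_parameters(model, rel_magnitude = rel_magnitude,
                                        seed = seeds[s])
    samples[s, ] <- draw$values
    opt <- options
    opt$seed <- seeds[n_samples + 1L]
    fit <- optimize_allocation(draw$model, options = opt)
    if (fit$feasible && fit$converged) A_S[s] <- abs(fit$asymmetries[1L])
  }
  ok <- is.finite(A_S)
  est <- data.frame(
    parameter = names(base),
    covariance = apply(samples[ok, , drop = FALSE], 2,
                       function(k) stats::cov(A_S[ok], k)),
    correlation = apply(samples[ok, , drop = FALSE], 2, function(k) {
      if (stats::sd(k) == 0 || stats::sd(A_S[ok]) == 0) 0
      else stats::cor(A_S[ok], k)
    }),
    row.names = NULL)
  structure(list(estimates = est, A_S = A_S, samples = samples,
                 n_samples = n_samples, n_converged = sum(ok),
                 rel_magnitude = rel_magnitude, seed = seed,
                 base = base),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat(sprintf("Sensitivity of A_S: %d / %d converged samples, delta = %g\n",
              x$n_converged, x$n_samples, x$rel_magnitude))
  est <- x$estimates[order(-abs(x$estimates$covariance)), ]
  print(est, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Optimal splitting of an extended chain with one permeable intermediate
#'
#' Builds the extended-chain configuration (see [extended_consortium()]) in
#' which only the product and one chosen intermediate can permeate, fits the
#' optimal allocation, and locates the pathway splitting point.  With a clean
#' optimum the chain splits exactly at the permeable intermediate: the first
#' cell runs the chain up to it, the second cell takes over from there.
#'
#' @param permeable_index Index of the permeable intermediate (1..m).
#' @param chain_length Number of intermediates (default 5).
#' @param options A [solver_options()].
#' @param ... Further overrides passed to [extended_consortium()].
#' @return A list with the fit and `split` (the [split_point()] index, or NA).
#' @export
extended_split_experiment <- function(permeable_index, chain_length = 5,
                                      options = solver_options(), ...) {
  model <- extended_consortium(permeable_index, chain_length = chain_length,
                               ...)
  fit <- optimize_allocation(model, options = options)
  list(fit = fit, split = split_point(fit),
       permeable_index = permeable_index)
}

#' Pathway splitting point of a fitted allocation
#'
#' Returns `k` when cell 1 expresses the synthesis enzymes of steps `1..k`
#' (above `tol` times its total enzyme) and cell 2 those of steps `k+1..m+1`,
#' i.e. the chain is split after the reaction producing the k-th
#' intermediate.  The consumption enzyme (present in both cells) is ignored.
#' Returns `NA` when no such partition exists (e.g. a symmetric allocation).
#'
#' The default threshold (5 percent of the cell's total enzyme) reads the
#' partition at the gene presence/absence level: optimal allocations of
#' extended chains retain percent-level residual co-expression of the
#' partner's enzymes whose removal perturbs the optimal cost by well under
#' one percent, and such marginal enzymes are treated as dispensable.  Use a
#' small `tol` (e.g. `1e-6`) to demand numerically exact splits instead.
#'
#' @param fit A converged [optimize_allocation()] fit, or a `2 x (m+2)`
#'   enzyme matrix.
#' @param tol Relative expression threshold.
#' @return Integer split index in `1..m`, or `NA`.
#' @export
split_point <- function(fit, tol = 0.05) {
  E <- if (inherits(fit, "allocation_fit")) {
    if (!fit$feasible || !fit$converged)
      stop("cannot locate a split point of an unconverged solution",
           call. = FALSE)
    fit$enzymes
  } else as.matrix(fit)
  nsyn <- ncol(E) - 1L
  m <- nsyn - 1L
  on1 <- E[1L, seq_len(nsyn)] > tol * sum(E[1L, ])
  on2 <- E[2L, seq_len(nsyn)] > tol * sum(E[2L, ])
  for (k in seq_len(m)) {
    head <- seq_len(k)
    if (all(on1[head]) && !any(on1[-head]) &&
        !any(on2[head]) && all(on2[-head])) return(k)
  }
  NA_integer_
}
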
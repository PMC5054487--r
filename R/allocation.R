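#' Normalized enzyme asymmetry between the two cells
#'
#' `A = (e1 - e2) / (e1 + e2)`: 0 for identical allocation, +1 / -1 when cell
#' 2 / cell 1 completely lacks the enzyme.  The indeterminate case
#' `e1 = e2 = 0` is defined as 0 (attribute `"both_absent"` marks it).
#'
#' @param e1,e2 Nonnegative enzyme concentrations (vectorized).
#' @return Numeric vector in `[-1, 1]` with logical attribute `"both_absent"`.
#' @export
enzyme_asymmetry <- function(e1, e2) {
  if (any(e1 < 0) || any(e2 < 0))
    stop("enzyme concentrations must be nonnegative", call. = FALSE)
  tot <- e1 + e2
  out <- ifelse(tot == 0, 0, (e1 - e2) / ifelse(tot == 0, 1, tot))
  attr(out, "both_absent") <- tot == 0
  out
}

#' Population-weighted total enzyme cost
#'
#' `C = sum_i n_i * sum_alpha [E_alpha,i]`, the objective minimized by
#' [optimize_allocation()].
#'
#' @param enzymes `2 x k` matrix of enzyme concentrations (rows = cells).
#' @param fractions Length-2 population fractions summing to one.
#' @return The scalar cost (concentration units).
#' @export
total_cost <- function(enzymes, fractions = c(0.5, 0.5)) {
  enzymes <- as.matrix(enzymes)
  if (nrow(enzymes) != 2L || any(enzymes < 0))
    stop("'enzymes' must be a nonnegative 2-row matrix", call. = FALSE)
  if (length(fractions) != 2L || abs(sum(fractions) - 1) > 1e-12)
    stop("'fractions' must sum to 1", call. = FALSE)
  fractions[1] * sum(enzymes[1, ]) + fractions[2] * sum(enzymes[2, ])
}

#' Solver options for the enzyme-allocation optimizer
#'
#' @param n_starts Number of random multistarts (>= 1).
#' @param seed Integer seed; every random initialization is drawn from it, so
#'   results are reproducible.
#' @param constraint_tolerance Feasibility tolerance on constraint violations
#'   (flux units).
#' @param optimality_tolerance Relative convergence tolerance of the local
#'   searches.
#' @param symmetry_restriction `"A_S_nonnegative"` (default) resolves the
#'   mirror degeneracy of a symmetric consortium by reporting the solution
#'   with `[E_S,1] >= [E_S,2]`; `"none"` leaves the orientation free.  The
#'   restriction is only meaningful (and only applied) when the two cells have
#'   equal fractions and demands.
#' @param init_range Range (concentration units) from which random starting
#'   concentrations are drawn log-uniformly.
#' @param maxit Iteration cap of each local Nelder-Mead search.
#' @param search `"full"` runs the free multistart search in the whole
#'   concentration space in addition to the structured branches;
#'   `"branches"` restricts the search to the symmetric and active-set
#'   branches (much faster, exploits the known structure of the optima; used
#'   by the sensitivity analysis).
#' @param warm_start Optional previous [optimize_allocation()] fit whose
#'   concentrations and active set seed the search.
#' @return A list of class `"solver_options"`.
#' @export
solver_options <- function(n_starts = 24, seed = 1,
                           constraint_tolerance = 1e-7,
                           optimality_tolerance = 1e-10,
                           symmetry_restriction = c("A_S_nonnegative", "none"),
                           init_range = c(1e-3, 1e2),
                           maxit = 400, search = c("full", "branches"),
                           warm_start = NULL) {
  stopifnot(n_starts >= 1, constraint_tolerance > 0, optimality_tolerance > 0)
  structure(list(n_starts = as.integer(n_starts), seed = as.integer(seed),
                 constraint_tolerance = constraint_tolerance,
                 optimality_tolerance = optimality_tolerance,
                 symmetry_restriction = match.arg(symmetry_restriction),
                 init_range = init_range, maxit = as.integer(maxit),
                 search = match.arg(search), warm_start = warm_start),
            class = "solver_options")
}

## Run code with a temporary RNG seed, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

## ---- fast evaluation context ------------------------------------------
##
## Steady state is solved in closed form: reaction rates are linear in their
## enzyme concentration and exchange fluxes are linear in concentrations, so
## given the intracellular concentrations (the only decision variables, on a
## log scale) the extracellular pools follow from exchange closure, the
## required fluxes from propagating the (tight) demands up the chain, and the
## enzymes as flux / per-enzyme rate.  Nonnegativity of the enzymes becomes a
## set of affine constraints on the concentrations, handled by hinge penalties
## in the smooth search and exactly by active-set elimination in the polish.

.alloc_context <- function(model) {
  m <- model$chain_length
  syn <- model$kinetics[seq_len(m + 1L)]
  list(m = m, S = model$substrate_conc, n = model$fractions,
       J = model$demands, J0 = model$host_demand,
       D = unname(model$permeabilities),
       kcat = vapply(syn, `[[`, numeric(1), "k_cat"),
       KMf = vapply(syn, `[[`, numeric(1), "K_M_fwd"),
       KMr = vapply(syn, `[[`, numeric(1), "K_M_rev"),
       Keq = vapply(syn, `[[`, numeric(1), "K_eq"),
       invKI = model$kinetics[[1L]]$inv_K_I,
       mode = model$kinetics[[1L]]$inhibition_mode,
       kcatP = model$kinetics[[m + 2L]]$k_cat,
       KMP = model$kinetics[[m + 2L]]$K_M_fwd,
       model = model)
}

## Extracellular pools and exchange fluxes for intracellular matrix cc
## (2 x (m+1)).  Returns list(e, U, pen) where pen accumulates negative
## extracellular pools.
.exchange_eval <- function(ctx, cc) {
  mp1 <- ctx$m + 1L
  e <- numeric(mp1)
  U <- matrix(0, 2L, mp1)
  pen <- 0
  for (k in seq_len(mp1)) {
    if (ctx$D[k] > 0) {
      ek <- ctx$n[1] * cc[1L, k] + ctx$n[2] * cc[2L, k]
      if (k == mp1 && ctx$J0 > 0) ek <- ek - ctx$J0 / ctx$D[k]
      if (ek < 0) { pen <- pen - ek; ek <- 0 }
      e[k] <- ek
      U[1L, k] <- ctx$D[k] * (cc[1L, k] - ek)
      U[2L, k] <- ctx$D[k] * (cc[2L, k] - ek)
    } else e[k] <- NA_real_
  }
  list(e = e, U = U, pen = pen)
}

## Per-enzyme synthesis rates f[i, j] for all steps; inhibitor is the cell's
## own product pool acting on step 1.
.per_enzyme_rates <- function(ctx, cc) {
  mp1 <- ctx$m + 1L
  f <- matrix(0, 2L, mp1)
  P <- cc[, mp1]
  for (i in 1:2) {
    sub <- c(ctx$S, cc[i, seq_len(ctx$m)])
    prod <- cc[i, seq_len(mp1)]
    drive <- (sub - prod / ctx$Keq) / ctx$KMf
    sat <- 1 + sub / ctx$KMf + prod / ctx$KMr
    fi <- ctx$kcat * drive / sat
    if (ctx$invKI > 0) {
      if (ctx$mode == "uncompetitive")
        fi[1L] <- fi[1L] / (1 + P[i] * ctx$invKI)
      else
        fi[1L] <- ctx$kcat[1L] * drive[1L] /
          (sat[1L] + P[i] * ctx$invKI)
    }
    f[i, ] <- fi
  }
  f
}

## Full evaluation at concentrations cc with a logical active-set matrix
## (2 x (m+1); TRUE = enzyme forced to zero).  Returns cost, penalty, and all
## reconstruction pieces.
.alloc_eval <- function(ctx, cc, active = NULL, W = 1e5, f_min = 1e-8,
                        Vcons = NULL) {
  mp1 <- ctx$m + 1L
  if (is.null(active)) active <- matrix(FALSE, 2L, mp1)
  if (is.null(Vcons)) Vcons <- ctx$J
  ex <- .exchange_eval(ctx, cc)
  pen <- ex$pen
  V <- matrix(0, 2L, mp1)
  V[, mp1] <- Vcons + ex$U[, mp1]
  if (ctx$m >= 1L) for (j in ctx$m:1L) V[, j] <- V[, j + 1L] + ex$U[, j]
  f <- .per_enzyme_rates(ctx, cc)
  E <- matrix(0, 2L, mp1)
  for (i in 1:2) for (j in seq_len(mp1)) {
    v <- V[i, j]
    if (active[i, j]) { pen <- pen + abs(v); next }
    if (v < 0) { pen <- pen - v; next }
    fij <- f[i, j]
    if (fij <= f_min) {
      pen <- pen + (f_min - fij) + 1
      E[i, j] <- v / f_min
    } else E[i, j] <- v / fij
  }
  g <- ctx$kcatP * cc[, mp1] / (cc[, mp1] + ctx$KMP)
  Econs <- ifelse(Vcons > 0, Vcons / pmax(g, f_min), 0)
  cost <- ctx$n[1] * (sum(E[1L, ]) + Econs[1L]) +
    ctx$n[2] * (sum(E[2L, ]) + Econs[2L])
  list(cost = cost, pen = pen, obj = cost + W * pen,
       E = cbind(E, Econs), V = V, Vcons = Vcons, U = ex$U, e = ex$e, f = f)
}

## Objective over z = log concentrations (length 2*(m+1), cell-major per
## species: c11, c21, c12, c22, ...).
.obj_interior <- function(ctx, W = 1e5) {
  mp1 <- ctx$m + 1L
  function(z) {
    z <- pmin(pmax(z, -30), 30)
    cc <- matrix(exp(z), 2L, mp1)
    .alloc_eval(ctx, cc, W = W)$obj
  }
}

## Affine map of required synthesis fluxes: vec(V) = A %*% vec(cc) + b
## (column-major over the 2 x (m+1) layout).  Exact because exchange and
## demand propagation are affine in the concentrations.
.flux_affine <- function(ctx) {
  mp1 <- ctx$m + 1L
  nv <- 2L * mp1
  Vof <- function(cvec) {
    cc <- matrix(cvec, 2L, mp1)
    e <- numeric(mp1); U <- matrix(0, 2L, mp1)
    for (k in seq_len(mp1)) {
      if (ctx$D[k] > 0) {
        ek <- ctx$n[1] * cc[1L, k] + ctx$n[2] * cc[2L, k]
        if (k == mp1 && ctx$J0 > 0) ek <- ek - ctx$J0 / ctx$D[k]
        U[, k] <- ctx$D[k] * (cc[, k] - ek)
      }
    }
    V <- matrix(0, 2L, mp1)
    V[, mp1] <- ctx$J + U[, mp1]
    if (ctx$m >= 1L) for (j in ctx$m:1L) V[, j] <- V[, j + 1L] + U[, j]
    as.numeric(V)
  }
  b <- Vof(numeric(nv))
  A <- matrix(0, nv, nv)
  for (k in seq_len(nv)) {
    unit <- numeric(nv); unit[k] <- 1
    A[, k] <- Vof(unit) - b
  }
  list(A = A, b = b)
}

## Solve one active-set branch: enzymes in `zero` (matrix of (cell, step)
## rows) are forced to exactly zero, i.e. their required fluxes vanish, which
## is an affine constraint on the concentrations; the remaining degrees of
## freedom are searched by Nelder-Mead.  Returns NULL when the constraint set
## is inconsistent (e.g. a split requested across an impermeable metabolite).
.solve_active <- function(ctx, zero, starts, maxit, reltol, W = 1e5) {
  mp1 <- ctx$m + 1L
  nv <- 2L * mp1
  act <- matrix(FALSE, 2L, mp1)
  act[zero] <- TRUE
  idx <- which(as.logical(act))
  af <- .flux_affine(ctx)
  Az <- af$A[idx, , drop = FALSE]
  bz <- af$b[idx]
  sv <- svd(Az, nu = nrow(Az), nv = nv)
  r <- sum(sv$d > max(sv$d[1], 1) * 1e-12)
  ## particular least-squares solution; inconsistent systems are infeasible
  dinv <- c(1 / sv$d[seq_len(r)], rep(0, length(sv$d) - r))
  cp <- sv$v[, seq_along(sv$d), drop = FALSE] %*%
    (dinv * crossprod(sv$u, -bz))
  if (max(abs(Az %*% cp + bz)) > 1e-8 * (1 + max(abs(bz)))) return(NULL)
  Nb <- sv$v[, setdiff(seq_len(nv), seq_len(r)), drop = FALSE]
  if (ncol(Nb) == 0L) return(NULL)
  cp <- as.numeric(cp)
  obj <- function(y) {
    cvec <- cp + as.numeric(Nb %*% y)
    penc <- sum(pmax(1e-9 - cvec, 0))
    cc <- matrix(pmax(cvec, 1e-12), 2L, mp1)
    ev <- .alloc_eval(ctx, cc, active = act, W = W)
    ev$obj + W * penc
  }
  it <- maxit * max(1L, ncol(Nb) - 1L)
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    y0 <- crossprod(Nb, starts[s, ] - cp)
    fit <- stats::optim(as.numeric(y0), obj, method = "Nelder-Mead",
                        control = list(maxit = it, reltol = reltol))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = it, reltol = reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  cvec <- cp + as.numeric(Nb %*% best$par)
  list(cc = matrix(pmax(cvec, 1e-12), 2L, mp1), active = act,
       objective = best$value)
}

## Fully symmetric branch: both cells share enzymes and concentrations, all
## intermediate exchange vanishes and each cell exports exactly the host
## demand.  Searched over the m+1 shared log concentrations.
.solve_symmetric <- function(ctx, starts, maxit, reltol, W = 1e5) {
  mp1 <- ctx$m + 1L
  if (ctx$J0 > 0 && ctx$D[mp1] <= 0) return(NULL)
  Vp <- max(ctx$J)
  obj <- function(z) {
    z <- pmin(pmax(z, -30), 30)
    cvec <- exp(z)
    pen <- 0
    if (ctx$J0 > 0) {
      eP <- cvec[mp1] - ctx$J0 / ctx$D[mp1]
      if (eP < 0) pen <- pen - eP
    }
    V <- rep(Vp + ctx$J0, mp1)
    sub <- c(ctx$S, cvec[seq_len(ctx$m)])
    drive <- (sub - cvec / ctx$Keq) / ctx$KMf
    sat <- 1 + sub / ctx$KMf + cvec / ctx$KMr
    f <- ctx$kcat * drive / sat
    if (ctx$invKI > 0) {
      if (ctx$mode == "uncompetitive")
        f[1L] <- f[1L] / (1 + cvec[mp1] * ctx$invKI)
      else f[1L] <- ctx$kcat[1L] * drive[1L] / (sat[1L] + cvec[mp1] * ctx$invKI)
    }
    cost <- 0
    for (j in seq_len(mp1)) {
      if (f[j] <= 1e-8) { pen <- pen + (1e-8 - f[j]) + 1 }
      else cost <- cost + V[j] / f[j]
    }
    g <- ctx$kcatP * cvec[mp1] / (cvec[mp1] + ctx$KMP)
    cost <- cost + if (Vp > 0) Vp / max(g, 1e-8) else 0
    cost + W * pen
  }
  it <- maxit * max(1L, ceiling(mp1 / 2))
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    z0 <- log(starts[s, seq_len(mp1)])
    fit <- stats::optim(z0, obj, method = "Nelder-Mead",
                        control = list(maxit = it, reltol = reltol))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = it, reltol = reltol))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  cvec <- exp(pmin(pmax(best$par, -30), 30))
  list(cc = rbind(cvec, cvec), active = matrix(FALSE, 2L, mp1),
       objective = best$value, symmetric = TRUE)
}

## Candidate active sets: the partial split (one cell drops the first enzyme)
## and every clean split point of the chain; mirrored copies when the
## orientation is free.
.candidate_sets <- function(m, mirrored) {
  sets <- list()
  for (k in seq_len(m)) {
    ## partial split: cell 2 drops the leading enzymes, cell 1 keeps all
    sets <- c(sets, list(cbind(2L, 1L:k)))
    ## clean split after step k: cell 1 additionally drops the tail
    z1 <- cbind(1L, (k + 1L):(m + 1L))
    sets <- c(sets, list(rbind(z1, cbind(2L, 1L:k))))
  }
  if (mirrored)
    sets <- c(sets, lapply(sets, function(z) cbind(3L - z[, 1L], z[, 2L])))
  sets
}

#' Minimize the total enzyme cost of the consortium
#'
#' Fits the cost-optimal enzyme allocation of a [consortium_model()]: the
#' population-weighted total enzyme concentration is minimized subject to
#' steady state of every metabolite pool, the minimum product-consumption
#' demand of each cell, the host demand drawn from the medium, and
#' nonnegativity of all concentrations.  Steady state is eliminated exactly
#' (rates are linear in enzymes and transport is linear in concentrations), so
#' the search runs over the intracellular metabolite concentrations; demands
#' are met with equality at any optimum (excess production is never
#' cost-optimal) and this is verified on the returned solution.
#'
#' The search combines `options$n_starts` seeded random Nelder-Mead starts in
#' the full concentration space with structured branches: the fully symmetric
#' allocation and the active-set branches in which one cell drops the first
#' enzyme or the chain is split cleanly at some step (these reproduce the
#' exact zero-enzyme optima characteristic of metabolic complementation).  The
#' best feasible solution is then polished: enzymes below `1e-6` of the total
#' are forced to exact zeros and the reduced problem is re-solved.  Ties
#' between the symmetric and an asymmetric branch (within relative `1e-6`)
#' are resolved in favour of the symmetric solution and flagged as a regime
#' boundary.
#'
#' @param model A [consortium_model()].
#' @param constraint `"none"` for the unconstrained optimum, `"symmetric"` to
#'   force identical allocation in both cells, `"split"` to force cell 2 to
#'   lack the first enzyme (`[E_S,2] = 0`).
#' @param options A [solver_options()] object.
#' @return An object of class `"allocation_fit"`; see
#'   [summary.allocation_fit()].  Key fields: `enzymes` (optimal `2 x (m+2)`
#'   matrix), `cost`, `asymmetries`, `state`, `steady_state`, `fluxes`,
#'   `converged`, `feasible`, `boundary`, `branch`, `starts` (per-start
#'   diagnostics), `seed`.
#' @examples
#' \donttest{
#' fit <- optimize_allocation(default_consortium(inv_K_I = 10,
#'                                               permeabilities = c(10, 0.1)))
#' summary(fit)
#' }
#' @export
optimize_allocation <- function(model, constraint = c("none", "symmetric",
                                                      "split"),
                                options = solver_options()) {
  stopifnot(inherits(model, "consortium_model"),
            inherits(options, "solver_options"))
  constraint <- match.arg(constraint)
  ctx <- .alloc_context(model)
  mp1 <- ctx$m + 1L
  if (ctx$J0 > 0 && ctx$D[mp1] <= 0)
    return(.infeasible_fit(model, options, constraint,
                           "host demand J_P,0 > 0 requires D_P > 0"))
  mirror_sym <- isTRUE(all.equal(ctx$n[1], ctx$n[2])) &&
    isTRUE(all.equal(ctx$J[1], ctx$J[2]))
  restrict <- options$symmetry_restriction == "A_S_nonnegative" && mirror_sym
  .with_seed(options$seed,
             .search_allocation(model, ctx, constraint, options, restrict))
}

.search_allocation <- function(model, ctx, constraint, options, restrict) {
  mp1 <- ctx$m + 1L
  reltol <- options$optimality_tolerance
  maxit <- options$maxit
  {
    ns <- options$n_starts
    lo <- log(options$init_range[1]); hi <- log(options$init_range[2])
    starts <- matrix(exp(stats::runif(ns * 2L * mp1, lo, hi)), ns)
    ws <- options$warm_start
    if (!is.null(ws) && inherits(ws, "allocation_fit") && ws$feasible)
      starts <- rbind(as.numeric(ws$state$intra), starts)
    branch_fits <- list()
    start_log <- list()
    ## symmetric branch
    if (constraint %in% c("none", "symmetric")) {
      nss <- min(nrow(starts), max(6L, ceiling(ns / 4)))
      bs <- .solve_symmetric(ctx, starts[seq_len(nss), , drop = FALSE],
                             maxit, reltol)
      if (!is.null(bs)) branch_fits$symmetric <- bs
    }
    ## interior multistart
    if (constraint == "none" && options$search == "full") {
      objf <- .obj_interior(ctx)
      it <- maxit * max(1L, ceiling(2L * mp1 / 2))
      best <- NULL
      vals <- numeric(0)
      for (s in seq_len(nrow(starts))) {
        z0 <- log(starts[s, ])
        fit <- stats::optim(z0, objf, method = "Nelder-Mead",
                            control = list(maxit = it, reltol = reltol))
        fit <- stats::optim(fit$par, objf, method = "Nelder-Mead",
                            control = list(maxit = it, reltol = reltol))
        vals <- c(vals, fit$value)
        if (is.null(best) || fit$value < best$value) best <- fit
      }
      start_log$interior <- vals
      branch_fits$interior <- list(
        cc = matrix(exp(pmin(pmax(best$par, -30), 30)), 2L, mp1),
        active = matrix(FALSE, 2L, mp1), objective = best$value)
    }
    ## active-set branches; the symmetric and interior solutions seed them
    ## (continuation across branches)
    if (constraint != "symmetric") {
      sets <- .candidate_sets(ctx$m, mirrored = !restrict)
      if (constraint == "split")
        sets <- Filter(function(z) any(z[, 1L] == 2L & z[, 2L] == 1L), sets)
      nsa <- max(4L, ceiling(ns / 6))
      seeds <- NULL
      if (!is.null(branch_fits$symmetric))
        seeds <- rbind(seeds, as.numeric(branch_fits$symmetric$cc))
      if (!is.null(branch_fits$interior))
        seeds <- rbind(seeds, as.numeric(branch_fits$interior$cc))
      for (ii in seq_along(sets)) {
        ba <- .solve_active(ctx, sets[[ii]],
                            rbind(seeds,
                                  starts[seq_len(min(nrow(starts), nsa)), ,
                                         drop = FALSE]),
                            maxit, reltol)
        if (!is.null(ba)) branch_fits[[paste0("active", ii)]] <- ba
      }
    }
    if (!length(branch_fits))
      return(.infeasible_fit(model, options, constraint,
                             "no feasible branch found"))
    ## exact re-evaluation and branch selection; the symmetric branch serves
    ## the larger of the two demands in both cells
    Vsym <- rep(max(ctx$J), 2L)
    evals <- lapply(branch_fits, function(b)
      .alloc_eval(ctx, b$cc, active = b$active,
                  Vcons = if (isTRUE(b$symmetric)) Vsym else NULL))
    feas <- vapply(evals, function(e) e$pen < options$constraint_tolerance,
                   logical(1))
    if (!any(feas))
      return(.infeasible_fit(model, options, constraint,
                             "no feasible branch found"))
    costs <- vapply(evals, `[[`, numeric(1), "cost")
    costs[!feas] <- Inf
    pick <- names(which.min(costs))
    sel <- branch_fits[[pick]]
    sel_eval <- evals[[pick]]
    ## refinement pass: re-solve the winning branch from its own solution
    ## with a doubled iteration budget
    ref <- if (isTRUE(sel$symmetric)) {
      .solve_symmetric(ctx, rbind(as.numeric(sel$cc)), 2L * maxit, reltol)
    } else if (any(sel$active)) {
      .solve_active(ctx, which(sel$active, arr.ind = TRUE),
                    rbind(as.numeric(sel$cc)), 2L * maxit, reltol)
    } else {
      objf <- .obj_interior(ctx)
      ft <- stats::optim(log(as.numeric(sel$cc)), objf,
                         method = "Nelder-Mead",
                         control = list(maxit = 2L * maxit * mp1,
                                        reltol = reltol))
      list(cc = matrix(exp(pmin(pmax(ft$par, -30), 30)), 2L, mp1),
           active = sel$active, objective = ft$value)
    }
    if (!is.null(ref)) {
      ev <- .alloc_eval(ctx, ref$cc, active = ref$active,
                        Vcons = if (isTRUE(sel$symmetric)) Vsym else NULL)
      if (ev$pen < options$constraint_tolerance && ev$cost < sel_eval$cost) {
        ref$symmetric <- sel$symmetric
        sel <- ref
        sel_eval <- ev
      }
    }
    ## polish: promote near-zero enzymes to exact zeros and re-solve
    tau <- 1e-6 * sum(sel_eval$E)
    small <- sel_eval$E[, seq_len(mp1), drop = FALSE] < tau & !sel$active
    if (any(small) && constraint != "symmetric") {
      zero <- which(small | sel$active, arr.ind = TRUE)
      ba <- .solve_active(ctx, zero,
                          rbind(as.numeric(sel$cc),
                                starts[seq_len(min(nrow(starts), 4L)), ,
                                       drop = FALSE]),
                          maxit, reltol)
      if (!is.null(ba)) {
        ev <- .alloc_eval(ctx, ba$cc, active = ba$active)
        if (ev$pen < options$constraint_tolerance &&
            ev$cost <= sel_eval$cost * (1 + 1e-6) + 1e-12) {
          sel <- ba; sel_eval <- ev; pick <- "polished"
        }
      }
    }
    ## boundary tie-break in favour of the symmetric solution
    boundary <- FALSE
    if (constraint == "none" && !is.null(branch_fits$symmetric) &&
        feas[["symmetric"]] && pick != "symmetric") {
      csym <- evals[["symmetric"]]$cost
      if (csym <= sel_eval$cost * (1 + 1e-6) + 1e-12) {
        if (csym > sel_eval$cost) boundary <- TRUE
        sel <- branch_fits$symmetric; sel_eval <- evals[["symmetric"]]
        pick <- "symmetric"
      }
    }
    .build_fit(model, ctx, sel, sel_eval, pick, boundary, restrict,
               options, constraint, start_log)
  }
}

.infeasible_fit <- function(model, options, constraint, reason) {
  structure(list(model = model, enzymes = NULL, cost = NA_real_,
                 asymmetries = NULL, state = NULL, steady_state = NULL,
                 fluxes = NULL, converged = FALSE, feasible = FALSE,
                 boundary = FALSE, branch = "infeasible", reason = reason,
                 constraint = constraint, seed = options$seed,
                 n_starts_used = 0L, starts = NULL),
            class = "allocation_fit")
}

.build_fit <- function(model, ctx, sel, sel_eval, branch, boundary, restrict,
                       options, constraint, start_log) {
  mp1 <- ctx$m + 1L
  cc <- sel$cc
  E <- sel_eval$E
  ## mirror orientation: report A_S >= 0 for a symmetric consortium
  if (restrict && E[1L, 1L] < E[2L, 1L]) {
    E <- E[2:1, , drop = FALSE]
    cc <- cc[2:1, , drop = FALSE]
    sel_eval <- .alloc_eval(ctx, cc, active = sel$active[2:1, , drop = FALSE])
    E <- sel_eval$E
  }
  model$enzymes <- matrix(E, 2L, mp1 + 1L,
                          dimnames = list(c("cell1", "cell2"), model$steps))
  exch <- model$species[model$permeabilities > 0]
  state <- compartment_state(model, cc,
                             stats::setNames(sel_eval$e[model$permeabilities > 0],
                                             exch))
  ss <- steady_state_solution(model, state)
  asym <- enzyme_asymmetry(E[1L, ], E[2L, ])
  names(asym) <- model$steps
  cost <- total_cost(model$enzymes, model$fractions)
  tightness <- abs(sel_eval$Vcons - ctx$J)
  structure(list(
    model = model, enzymes = model$enzymes, cost = cost,
    asymmetries = asym, state = state, steady_state = ss,
    fluxes = ss$fluxes,
    converged = sel_eval$pen < options$constraint_tolerance && ss$accepted,
    feasible = sel_eval$pen < options$constraint_tolerance,
    active_demands = tightness <= options$constraint_tolerance,
    boundary = boundary, branch = branch, constraint = constraint,
    seed = options$seed, n_starts_used = options$n_starts,
    starts = start_log, options = options),
    class = "allocation_fit")
}

#' Maximize the demand that fits within an enzyme budget
#'
#' Dual formulation of [optimize_allocation()]: finds the largest uniform
#' scaling factor `lambda` of all demand fluxes such that the cost-minimal
#' allocation sustaining `lambda * (J_P,1, J_P,2, J_P,0)` fits within
#' `enzyme_budget`.  Computed by root finding on the monotone map
#' `lambda -> C(lambda)`; with `enzyme_budget = C*` (the optimal cost of the
#' unscaled problem) the achieved `lambda` is 1.
#'
#' @param model A [consortium_model()] with at least one positive demand.
#' @param enzyme_budget Total enzyme concentration available (>= 0).
#' @param options A [solver_options()].
#' @param lambda_tol Convergence tolerance on `lambda`.
#' @return The [optimize_allocation()] fit at the achieved scaling, with extra
#'   fields `lambda` and `budget`.
#' @export
maximize_flux_under_budget <- function(model, enzyme_budget,
                                       options = solver_options(),
                                       lambda_tol = 1e-4) {
  stopifnot(enzyme_budget >= 0)
  if (enzyme_budget == 0) {
    fit <- .infeasible_fit(model, options, "none", "zero budget")
    fit$lambda <- 0; fit$budget <- 0
    return(fit)
  }
  if (sum(model$demands) + model$host_demand <= 0)
    stop("model has no demand to scale", call. = FALSE)
  scale_model <- function(lam) {
    model$demands <- lam * model$demands
    model$host_demand <- lam * model$host_demand
    model
  }
  cost_at <- function(lam) {
    f <- optimize_allocation(scale_model(lam), options = options)
    if (!f$feasible) Inf else f$cost
  }
  c1 <- cost_at(1)
  lam <- enzyme_budget / c1          # exact if cost is linear in the demands
  lo <- lam / 4; hi <- lam * 4
  while (is.finite(cost_at(hi)) && cost_at(hi) < enzyme_budget) hi <- hi * 2
  while (cost_at(lo) > enzyme_budget) lo <- lo / 2
  root <- stats::uniroot(function(l) cost_at(l) - enzyme_budget,
                         lower = lo, upper = hi, tol = lambda_tol)
  lam <- root$root
  fit <- optimize_allocation(scale_model(lam), options = options)
  fit$lambda <- lam
  fit$budget <- enzyme_budget
  fit
}

#' Solve a smooth parameter path with warm starts
#'
#' Solves a sequence of models (e.g. along a permeability ramp), warm-starting
#' each solve from the previous optimum; when the cost jumps by more than
#' `jump_tol` (relative) between consecutive points, the point is re-solved
#' from a fresh multistart and the cheaper solution kept.  Per-point failures
#' are recorded, not fatal.
#'
#' @param models A list of [consortium_model()] objects along the path.
#' @param options A [solver_options()].
#' @param jump_tol Relative cost jump that triggers the fresh-multistart
#'   fallback.
#' @return A list of [optimize_allocation()] fits, one per path point.
#' @export
continuation_sweep <- function(models, options = solver_options(),
                               jump_tol = 0.2) {
  stopifnot(length(models) >= 1)
  fits <- vector("list", length(models))
  prev <- NULL
  for (i in seq_along(models)) {
    opt <- options
    opt$warm_start <- prev
    fit <- tryCatch(optimize_allocation(models[[i]], options = opt),
                    error = function(e) .infeasible_fit(models[[i]], options,
                                                        "none",
                                                        conditionMessage(e)))
    if (!is.null(prev) && fit$feasible && prev$feasible &&
        abs(fit$cost - prev$cost) > jump_tol * max(prev$cost, 1e-12)) {
      opt$warm_start <- NULL
      fresh <- optimize_allocation(models[[i]], options = opt)
      if (fresh$feasible && fresh$cost < fit$cost) fit <- fresh
    }
    fits[[i]] <- fit
    if (fit$feasible) prev <- fit
  }
  fits
}
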
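#' Compartment concentrations of the consortium
#'
#' Bundles the intracellular concentrations of both cells and the extracellular
#' concentrations of the exchangeable species.  Species with zero permeability
#' have no extracellular pool and are omitted from `extra` (their exchange flux
#' is identically zero).
#'
#' @param model A [consortium_model()].
#' @param intra `2 x (m+1)` matrix of intracellular concentrations
#'   (rows = cells, columns = `X1..Xm, P`), all finite and >= 0.
#' @param extra Named vector of extracellular concentrations for the
#'   exchangeable species (those with `D > 0`); missing species default to 0.
#' @return An object of class `"compartment_state"`.
#' @export
compartment_state <- function(model, intra, extra = NULL) {
  stopifnot(inherits(model, "consortium_model"))
  m <- model$chain_length
  intra <- as.matrix(intra)
  if (!all(dim(intra) == c(2L, m + 1L)))
    stop("'intra' must be a 2 x ", m + 1, " matrix", call. = FALSE)
  if (any(!is.finite(intra)) || any(intra < 0))
    stop("concentrations must be finite and nonnegative", call. = FALSE)
  dimnames(intra) <- list(c("cell1", "cell2"), model$species)
  exch <- names(model$permeabilities)[model$permeabilities > 0]
  full <- stats::setNames(numeric(length(exch)), exch)
  if (!is.null(extra)) {
    if (is.null(names(extra)) && length(extra) == length(exch))
      names(extra) <- exch
    bad <- setdiff(names(extra), exch)
    if (length(bad))
      stop("extracellular pool given for non-exchangeable species: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(extra)) || any(extra < 0))
      stop("concentrations must be finite and nonnegative", call. = FALSE)
    full[names(extra)] <- extra
  }
  structure(list(intra = intra, extra = full), class = "compartment_state")
}

#' @export
print.compartment_state <- function(x, ...) {
  cat("Compartment state\n  intracellular:\n")
  print(round(x$intra, 6))
  cat("  extracellular:\n")
  print(round(x$extra, 6))
  invisible(x)
}

## Evaluate all reaction and transport fluxes for given concentrations.
## Returns V (2 x (m+1) synthesis fluxes), Vcons (2), U (2 x (m+1)).
.flux_eval <- function(model, intra, extra_full) {
  m <- model$chain_length
  S <- model$substrate_conc
  V <- matrix(0, 2, m + 1L)
  U <- matrix(0, 2, m + 1L)
  D <- model$permeabilities
  P <- intra[, m + 1L]
  for (i in 1:2) {
    V[i, 1L] <- model$enzymes[i, 1L] *
      .per_enzyme_synthesis(model$kinetics[[1L]], S, intra[i, 1L], P[i])
    if (m >= 1L) for (j in 2:(m + 1L)) {
      V[i, j] <- model$enzymes[i, j] *
        .per_enzyme_synthesis(model$kinetics[[j]], intra[i, j - 1L],
                              intra[i, j])
    }
  }
  Vcons <- model$enzymes[, m + 2L] *
    .per_enzyme_consumption(model$kinetics[[m + 2L]], P)
  for (k in seq_len(m + 1L)) {
    if (D[k] > 0) U[, k] <- D[k] * (intra[, k] - extra_full[k])
  }
  list(V = V, Vcons = Vcons, U = U)
}

## Expand a state's sparse extracellular vector to length m+1 (zeros for
## non-exchangeable species, which never enter any flux).
.extra_full <- function(model, state) {
  out <- stats::setNames(numeric(model$chain_length + 1L), model$species)
  out[names(state$extra)] <- state$extra
  out
}

#' Time derivatives of every metabolite pool
#'
#' Evaluates the mass-balance right-hand sides of the model: for each cell the
#' balances of the intermediates (`synthesis in - conversion out - exchange`)
#' and of the product (`synthesis - consumption - exchange`), and for the
#' medium the population-weighted exchange of each exchangeable species, the
#' extracellular product balance additionally carrying the host-demand sink
#' `-N * J_P,0`.  The clamped substrate has no balance equation.  A steady
#' state is a root of this map.
#'
#' @param model A [consortium_model()] (its `enzymes` matrix is used).
#' @param state A [compartment_state()].
#' @return Named vector of time derivatives (intracellular pools of both
#'   cells, then extracellular pools).
#' @export
balance_residuals <- function(model, state) {
  stopifnot(inherits(model, "consortium_model"),
            inherits(state, "compartment_state"))
  m <- model$chain_length
  ext <- .extra_full(model, state)
  fl <- .flux_eval(model, state$intra, ext)
  n <- model$fractions
  N <- model$total_cells
  res_in <- matrix(0, 2, m + 1L)
  for (k in seq_len(m)) res_in[, k] <- fl$V[, k] - fl$V[, k + 1L] - fl$U[, k]
  res_in[, m + 1L] <- fl$V[, m + 1L] - fl$Vcons - fl$U[, m + 1L]
  exch <- names(state$extra)
  res_ex <- stats::setNames(numeric(length(exch)), exch)
  for (k in exch) {
    kk <- match(k, model$species)
    res_ex[k] <- N * (n[1] * fl$U[1, kk] + n[2] * fl$U[2, kk])
  }
  if ("P" %in% exch) res_ex["P"] <- res_ex["P"] - N * model$host_demand
  out <- c(stats::setNames(res_in[1, ], paste0("cell1.", model$species)),
           stats::setNames(res_in[2, ], paste0("cell2.", model$species)),
           if (length(exch))
             stats::setNames(res_ex, paste0("medium.", exch)))
  out
}

#' Steady-state summary with fluxes and residual norm
#'
#' Packages a candidate steady state together with all reaction and transport
#' fluxes evaluated at it and the max-norm of the balance residuals.
#'
#' @param model A [consortium_model()].
#' @param state A [compartment_state()].
#' @param tol Acceptance tolerance on the residual max-norm.
#' @return An object of class `"steady_state_solution"` with elements `state`,
#'   `fluxes` (list `V`, `Vcons`, `U`), `residuals`, `residual_norm`,
#'   `accepted`.
#' @export
steady_state_solution <- function(model, state, tol = 1e-8) {
  res <- balance_residuals(model, state)
  fl <- .flux_eval(model, state$intra, .extra_full(model, state))
  dimnames(fl$V) <- list(c("cell1", "cell2"), model$steps[seq_len(model$chain_length + 1L)])
  dimnames(fl$U) <- list(c("cell1", "cell2"), model$species)
  structure(list(state = state, fluxes = fl, residuals = res,
                 residual_norm = max(abs(res)), tol = tol,
                 accepted = max(abs(res)) <= tol),
            class = "steady_state_solution")
}

#' @export
print.steady_state_solution <- function(x, ...) {
  cat(sprintf("Steady-state solution (residual max-norm %.3g, %s)\n",
              x$residual_norm,
              if (x$accepted) "accepted" else "NOT steady"))
  print(x$state)
  cat("  synthesis fluxes:\n"); print(round(x$fluxes$V, 6))
  cat("  consumption fluxes:", round(x$fluxes$Vcons, 6), "\n")
  cat("  exchange fluxes (positive = excretion):\n")
  print(round(x$fluxes$U, 6))
  invisible(x)
}

#' Integrate the consortium dynamics forward in time
#'
#' Integrates the balance equations with `deSolve::ode` (lsoda).  Rates are
#' evaluated at concentrations clamped to zero from below, which keeps the
#' trajectories nonnegative up to integrator noise; returned concentrations are
#' clamped likewise.
#'
#' @param model A [consortium_model()] (its `enzymes` matrix is used).
#' @param initial A [compartment_state()].
#' @param horizon Final time (> 0).
#' @param n_steps Number of output points.
#' @param ... Passed on to [deSolve::ode()].
#' @return A data.frame of class `"consortium_trajectory"`: `time` plus one
#'   column per pool, with the final [compartment_state()] in attribute
#'   `"final_state"`.
#' @export
simulate_dynamics <- function(model, initial, horizon, n_steps = 200, ...) {
  stopifnot(inherits(model, "consortium_model"),
            inherits(initial, "compartment_state"))
  if (!is.numeric(horizon) || horizon <= 0)
    stop("'horizon' must be positive", call. = FALSE)
  m <- model$chain_length
  exch <- names(initial$extra)
  y0 <- c(initial$intra[1, ], initial$intra[2, ], initial$extra)
  names(y0) <- c(paste0("cell1.", model$species),
                 paste0("cell2.", model$species),
                 paste0("medium.", exch))
  n_in <- 2L * (m + 1L)
  deriv <- function(t, y, parms) {
    y <- pmax(y, 0)
    intra <- rbind(y[seq_len(m + 1L)], y[m + 1L + seq_len(m + 1L)])
    extra <- stats::setNames(y[n_in + seq_along(exch)], exch)
    st <- structure(list(intra = intra, extra = extra),
                    class = "compartment_state")
    list(unname(balance_residuals(model, st)))
  }
  times <- seq(0, horizon, length.out = max(2L, n_steps))
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL, ...)
  if (attr(sol, "istate")[1] < 0)
    stop("dynamics integration failed; istate = ", attr(sol, "istate")[1],
         " at t = ", max(sol[, "time"]), call. = FALSE)
  out <- as.data.frame(unclass(sol))
  out[, -1] <- pmax(as.matrix(out[, -1, drop = FALSE]), 0)
  yT <- as.numeric(out[nrow(out), -1])
  final <- compartment_state(
    model,
    rbind(yT[seq_len(m + 1L)], yT[m + 1L + seq_len(m + 1L)]),
    stats::setNames(yT[n_in + seq_along(exch)], exch))
  attr(out, "final_state") <- final
  class(out) <- c("consortium_trajectory", "data.frame")
  out
}
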
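#' @export
print.allocation_fit <- function(x, ...) {
  if (!x$feasible) {
    cat("Enzyme allocation: INFEASIBLE (", x$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("Optimal enzyme allocation (constraint: %s)\n", x$constraint))
  cat(sprintf("  cost C = %.6g   branch: %s%s\n", x$cost, x$branch,
              if (x$boundary) " [regime boundary]" else ""))
  cat("  asymmetries:",
      paste(sprintf("A_%s = %.4g", sub("^E_", "", names(x$asymmetries)),
                    x$asymmetries), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize an enzyme-allocation fit
#'
#' @param object An [optimize_allocation()] fit.
#' @param ... Unused.
#' @return The fit, invisibly, after printing enzyme concentrations, fluxes,
#'   asymmetries and solver diagnostics.
#' @export
summary.allocation_fit <- function(object, ...) {
  print(object)
  if (!object$feasible) return(invisible(object))
  cat("\nEnzyme concentrations:\n")
  print(round(object$enzymes, 6))
  cat("\nMetabolite concentrations:\n")
  print(round(object$state$intra, 6))
  cat("  medium:", paste(sprintf("%s = %.6g", names(object$state$extra),
                                 object$state$extra), collapse = ", "), "\n")
  cat("\nExchange fluxes (positive = excretion):\n")
  print(round(object$fluxes$U, 6))
  cat("\nConsumption fluxes:", round(object$fluxes$Vcons, 6),
      " (demands:", object$model$demands, ")\n")
  cat(sprintf("\nConverged: %s   steady-state residual: %.3g   seed: %d   starts: %d\n",
              object$converged, object$steady_state$residual_norm,
              object$seed, object$n_starts_used))
  invisible(object)
}

#' @export
coef.allocation_fit <- function(object, ...) object$enzymes

#' @export
residuals.allocation_fit <- function(object, ...) {
  if (!object$feasible) stop("infeasible fit has no residuals", call. = FALSE)
  object$steady_state$residuals
}

#' Integrate the dynamics from the fitted steady state
#'
#' Validation helper: simulates the consortium forward from the optimal steady
#' state (optionally perturbed), using the fitted enzyme concentrations.  A
#' correct steady state stays put.
#'
#' @param object An [optimize_allocation()] fit.
#' @param nsim Number of trajectories.
#' @param seed Optional seed for the perturbations.
#' @param horizon Integration time.
#' @param perturb Relative multiplicative perturbation applied to the initial
#'   concentrations (0 = start exactly at the optimum).
#' @param ... Passed to [simulate_dynamics()].
#' @return A trajectory (or list of trajectories when `nsim > 1`).
#' @export
simulate.allocation_fit <- function(object, nsim = 1, seed = NULL,
                                    horizon = 50, perturb = 0, ...) {
  if (!object$feasible) stop("cannot simulate an infeasible fit", call. = FALSE)
  run1 <- function() {
    st <- object$state
    if (perturb > 0) {
      st$intra <- st$intra * exp(stats::runif(length(st$intra),
                                              -perturb, perturb))
      st$extra <- st$extra * exp(stats::runif(length(st$extra),
                                              -perturb, perturb))
    }
    simulate_dynamics(object$model, st, horizon = horizon, ...)
  }
  out <- if (is.null(seed)) replicate(nsim, run1(), simplify = FALSE)
  else .with_seed(seed, replicate(nsim, run1(), simplify = FALSE))
  if (nsim == 1L) out[[1L]] else out
}

#' Plot the fitted enzyme allocation
#'
#' Grouped barplot of the optimal enzyme concentrations of the two cells; the
#' visual signature of metabolic complementation is a complementary on/off
#' pattern along the chain.
#'
#' @param x An [optimize_allocation()] fit.
#' @param ... Passed to [graphics::barplot()].
#' @export
plot.allocation_fit <- function(x, ...) {
  if (!x$feasible) stop("cannot plot an infeasible fit", call. = FALSE)
  graphics::barplot(x$enzymes, beside = TRUE,
                    legend.text = rownames(x$enzymes),
                    ylab = "enzyme concentration",
                    main = sprintf("Optimal allocation (C = %.4g)", x$cost),
                    ...)
  invisible(x)
}
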
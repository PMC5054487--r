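#' Kinetic constants of one enzymatic step
#'
#' Bundles the constants of a single reaction of the pathway.  Synthesis steps
#' follow reversible Michaelis-Menten kinetics; the first step of the chain may
#' additionally be inhibited by the pathway end product, either uncompetitively
#' (the inhibitor scales the whole rate) or competitively (the inhibitor adds to
#' the saturation denominator).  The final consumption step is irreversible
#' Michaelis-Menten, for which only `k_cat` and `K_M_fwd` are used.
#'
#' All quantities are in dimensionless model units (the canonical
#' parameterization sets every constant to one).
#'
#' @param k_cat Turnover number (1/time). Must be positive.
#' @param K_M_fwd Forward Michaelis constant (concentration). Positive.
#' @param K_M_rev Backward Michaelis constant (concentration). Positive.
#' @param K_eq Equilibrium constant (dimensionless). Positive.
#' @param inv_K_I Inverse inhibition constant (1/concentration); 0 means no
#'   inhibition.  Stored as 0 whenever `inhibition_mode = "none"`.
#' @param inhibition_mode One of `"none"`, `"uncompetitive"`, `"competitive"`.
#' @param reversible Logical; `FALSE` selects the irreversible consumption law.
#' @return An object of class `"reaction_kinetics"`.
#' @seealso [synthesis_rate()], [consumption_rate()]
#' @export
reaction_kinetics <- function(k_cat = 1, K_M_fwd = 1, K_M_rev = 1, K_eq = 1,
                              inv_K_I = 0,
                              inhibition_mode = c("none", "uncompetitive",
                                                  "competitive"),
                              reversible = TRUE) {
  inhibition_mode <- match.arg(inhibition_mode)
  for (nm in c("k_cat", "K_M_fwd", "K_M_rev", "K_eq")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("'", nm, "' must be a single positive finite number", call. = FALSE)
  }
  if (!is.numeric(inv_K_I) || length(inv_K_I) != 1L || !is.finite(inv_K_I) ||
      inv_K_I < 0)
    stop("'inv_K_I' must be a single nonnegative finite number", call. = FALSE)
  if (inhibition_mode == "none") inv_K_I <- 0
  if (inv_K_I == 0) inhibition_mode <- "none"
  structure(
    list(k_cat = k_cat, K_M_fwd = K_M_fwd, K_M_rev = K_M_rev, K_eq = K_eq,
         inv_K_I = inv_K_I, inhibition_mode = inhibition_mode,
         reversible = isTRUE(reversible)),
    class = "reaction_kinetics")
}

#' @export
print.reaction_kinetics <- function(x, ...) {
  cat(if (x$reversible) "Reversible Michaelis-Menten step"
      else "Irreversible Michaelis-Menten consumption step", "\n")
  cat(sprintf("  k_cat = %g, K_M+ = %g", x$k_cat, x$K_M_fwd))
  if (x$reversible)
    cat(sprintf(", K_M- = %g, K_eq = %g", x$K_M_rev, x$K_eq))
  cat("\n")
  if (x$inhibition_mode != "none")
    cat(sprintf("  %s product inhibition, 1/K_I = %g\n",
                x$inhibition_mode, x$inv_K_I))
  invisible(x)
}

.check_conc <- function(x, what) {
  if (!is.numeric(x) || any(!is.finite(x)) || any(x < 0))
    stop("'", what, "' must be nonnegative and finite", call. = FALSE)
  x
}

## Rate per unit enzyme of a reversible synthesis step; vectorized over
## concentrations.  `inhibitor` is the end-product concentration acting on the
## (possibly inhibited) step.
.per_enzyme_synthesis <- function(kin, substrate, product, inhibitor = 0) {
  drive <- (substrate - product / kin$K_eq) / kin$K_M_fwd
  sat <- 1 + substrate / kin$K_M_fwd + product / kin$K_M_rev
  switch(kin$inhibition_mode,
         none = kin$k_cat * drive / sat,
         uncompetitive = kin$k_cat * drive / sat / (1 + inhibitor * kin$inv_K_I),
         competitive = kin$k_cat * drive / (sat + inhibitor * kin$inv_K_I))
}

.per_enzyme_consumption <- function(kin, product) {
  kin$k_cat * product / (product + kin$K_M_fwd)
}

#' Rate of a reversible, possibly product-inhibited synthesis step
#'
#' Reversible Michaelis-Menten rate law with optional end-product inhibition of
#' the step.  In uncompetitive mode the factor `1/(1 + [P]/K_I)` scales the
#' whole rate; in competitive mode `[P]/K_I` is added to the saturation
#' denominator; with `inv_K_I = 0` the plain reversible law is recovered.  The
#' sign of the rate equals the sign of the thermodynamic driving force
#' `substrate - product_of_step/K_eq`.
#'
#' @param kin A [reaction_kinetics()] object (must be reversible).
#' @param enzyme Enzyme concentration (>= 0).
#' @param substrate Concentration of the step's substrate.
#' @param product_of_step Concentration of the step's direct product.
#' @param inhibitor Concentration of the pathway end product acting as
#'   inhibitor (ignored when `inhibition_mode = "none"`).
#' @return The reaction flux (model units).
#' @examples
#' kin <- reaction_kinetics()
#' synthesis_rate(kin, enzyme = 1, substrate = 10, product_of_step = 0) # 10/11
#' @export
synthesis_rate <- function(kin, enzyme, substrate, product_of_step,
                           inhibitor = 0) {
  stopifnot(inherits(kin, "reaction_kinetics"))
  if (!kin$reversible)
    stop("synthesis_rate() requires a reversible step; see consumption_rate()",
         call. = FALSE)
  .check_conc(enzyme, "enzyme"); .check_conc(substrate, "substrate")
  .check_conc(product_of_step, "product_of_step")
  .check_conc(inhibitor, "inhibitor")
  enzyme * .per_enzyme_synthesis(kin, substrate, product_of_step, inhibitor)
}

#' Diffusive exchange flux across the cell membrane
#'
#' First-order, non-saturating exchange `D * ([in] - [out])`; positive fluxes
#' correspond to excretion, negative ones to uptake.
#'
#' @param D Permeability constant (1/time, >= 0).
#' @param conc_in Intracellular concentration.
#' @param conc_out Extracellular concentration.
#' @return The transport flux.
#' @export
transport_rate <- function(D, conc_in, conc_out) {
  if (!is.numeric(D) || any(!is.finite(D)) || any(D < 0))
    stop("'D' must be nonnegative and finite", call. = FALSE)
  .check_conc(conc_in, "conc_in"); .check_conc(conc_out, "conc_out")
  D * (conc_in - conc_out)
}

#' Irreversible consumption rate of the end product
#'
#' Irreversible Michaelis-Menten law `k_cat * E * [P] / ([P] + K_M)` modelling
#' incorporation of the end product into biomass; always nonnegative and
#' saturating at `k_cat * E`.
#'
#' @param kin A [reaction_kinetics()] object; `K_M_fwd` is the Michaelis
#'   constant of the consumption reaction.
#' @param enzyme Enzyme concentration (>= 0).
#' @param product End-product concentration (>= 0).
#' @return The consumption flux (>= 0).
#' @export
consumption_rate <- function(kin, enzyme, product) {
  stopifnot(inherits(kin, "reaction_kinetics"))
  .check_conc(enzyme, "enzyme"); .check_conc(product, "product")
  enzyme * .per_enzyme_consumption(kin, product)
}
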
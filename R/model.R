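#' Two-population consortium sharing one linear biosynthetic pathway
#'
#' Constructs the kinetic model of two cell populations (fractions `n1`, `n2`)
#' that both encode the same linear chain `S -> X1 -> ... -> Xm -> P`, exchange
#' the intermediates and the product with the common medium by passive
#' diffusion, and must each sustain a minimum consumption flux of the end
#' product `P`; the host may impose an additional extracellular demand.  The
#' substrate concentration `[S]` is clamped (its balance equation is not part
#' of the model).
#'
#' The reaction chain has `m + 2` steps: step 1 (`E_S`) converts `S` to `X1`
#' and is the only step that may carry end-product inhibition; steps
#' `2 .. m+1` (`E_X1 .. E_Xm`, or `E_X` when `m = 1`) are the remaining
#' reversible conversions, the last of which produces `P`; step `m + 2`
#' (`E_P`) is the irreversible consumption of `P`.  Enzyme concentrations are
#' stored as a `2 x (m+2)` matrix (rows = cells) and are the quantities
#' optimized by [optimize_allocation()].
#'
#' @param substrate_conc Clamped substrate concentration `[S]` (> 0).
#' @param chain_length Number of intermediate metabolites `m` (>= 1).
#' @param kinetics List of `m + 2` [reaction_kinetics()] objects (the last one
#'   irreversible).  Defaults to all constants equal to one.
#' @param permeabilities Numeric vector of length `m + 1`: permeability `D` of
#'   `X1 .. Xm` and `P` (>= 0; a zero makes the species non-exchangeable and
#'   removes its extracellular pool from the state).
#' @param demands Length-2 vector of minimum product consumption fluxes
#'   `J_P,1`, `J_P,2` (>= 0).
#' @param host_demand Host demand flux `J_P,0` (>= 0), drawn from the
#'   extracellular product pool (normalized per total cell).
#' @param fractions Length-2 vector of population fractions summing to one.
#' @param total_cells Total population size `N` (> 0).  Steady-state solutions
#'   do not depend on it (it cancels from the balance equations); it only
#'   scales the extracellular dynamics in [simulate_dynamics()].
#' @param enzymes Optional `2 x (m+2)` matrix of enzyme concentrations
#'   (defaults to all ones); used by [balance_residuals()] and
#'   [simulate_dynamics()] and replaced by the optimum in an
#'   [optimize_allocation()] fit.
#' @param inv_K_I Convenience override: inverse inhibition constant placed on
#'   step 1 when `kinetics` is not supplied.
#' @param inhibition_mode Inhibition mechanism of step 1 when `kinetics` is not
#'   supplied: `"uncompetitive"` (default when `inv_K_I > 0`) or
#'   `"competitive"`.
#' @return An object of class `"consortium_model"`.
#' @seealso [default_consortium()], [optimize_allocation()]
#' @export
consortium_model <- function(substrate_conc = 10, chain_length = 1,
                             kinetics = NULL, permeabilities = NULL,
                             demands = c(1, 1), host_demand = 0,
                             fractions = c(0.5, 0.5), total_cells = 1,
                             enzymes = NULL, inv_K_I = 0,
                             inhibition_mode = c("uncompetitive",
                                                 "competitive")) {
  inhibition_mode <- match.arg(inhibition_mode)
  m <- chain_length
  if (!is.numeric(m) || length(m) != 1L || m < 1 || m != round(m))
    stop("'chain_length' must be a positive integer", call. = FALSE)
  m <- as.integer(m)
  if (!is.numeric(substrate_conc) || length(substrate_conc) != 1L ||
      substrate_conc <= 0)
    stop("'substrate_conc' must be a single positive number", call. = FALSE)
  if (is.null(kinetics)) {
    kinetics <- c(
      list(reaction_kinetics(inv_K_I = inv_K_I,
                             inhibition_mode =
                               if (inv_K_I > 0) inhibition_mode else "none")),
      replicate(m, reaction_kinetics(), simplify = FALSE),
      list(reaction_kinetics(reversible = FALSE)))
  }
  if (length(kinetics) != m + 2L ||
      !all(vapply(kinetics, inherits, logical(1), "reaction_kinetics")))
    stop("'kinetics' must be a list of ", m + 2,
         " reaction_kinetics objects", call. = FALSE)
  if (!kinetics[[1]]$reversible || kinetics[[m + 2L]]$reversible ||
      !all(vapply(kinetics[seq_len(m + 1L)], `[[`, logical(1), "reversible")))
    stop("steps 1..m+1 must be reversible, the last step irreversible",
         call. = FALSE)
  if (any(vapply(kinetics[-1], `[[`, numeric(1), "inv_K_I") > 0))
    stop("only the first reaction may carry product inhibition", call. = FALSE)
  if (is.null(permeabilities)) permeabilities <- rep(1, m + 1L)
  if (length(permeabilities) != m + 1L || any(!is.finite(permeabilities)) ||
      any(permeabilities < 0))
    stop("'permeabilities' must be ", m + 1,
         " nonnegative values (X1..Xm, P)", call. = FALSE)
  species <- .species_names(m)
  permeabilities <- stats::setNames(as.numeric(permeabilities), species)
  if (length(demands) != 2L || any(demands < 0))
    stop("'demands' must be two nonnegative fluxes", call. = FALSE)
  if (length(fractions) != 2L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-12)
    stop("'fractions' must be two nonnegative values summing to 1",
         call. = FALSE)
  if (!is.numeric(host_demand) || length(host_demand) != 1L || host_demand < 0)
    stop("'host_demand' must be a single nonnegative flux", call. = FALSE)
  if (!is.numeric(total_cells) || length(total_cells) != 1L || total_cells <= 0)
    stop("'total_cells' must be positive", call. = FALSE)
  steps <- .step_names(m)
  if (is.null(enzymes)) enzymes <- matrix(1, 2, m + 2L)
  enzymes <- as.matrix(enzymes)
  if (!all(dim(enzymes) == c(2L, m + 2L)) || any(enzymes < 0))
    stop("'enzymes' must be a nonnegative 2 x ", m + 2, " matrix",
         call. = FALSE)
  dimnames(enzymes) <- list(c("cell1", "cell2"), steps)
  structure(
    list(substrate_conc = substrate_conc, chain_length = m,
         kinetics = kinetics, permeabilities = permeabilities,
         demands = as.numeric(demands), host_demand = host_demand,
         fractions = as.numeric(fractions), total_cells = total_cells,
         enzymes = enzymes, species = species, steps = steps),
    class = "consortium_model")
}

.species_names <- function(m) {
  if (m == 1L) c("X", "P") else c(paste0("X", seq_len(m)), "P")
}

.step_names <- function(m) {
  if (m == 1L) c("E_S", "E_X", "E_P")
  else c("E_S", paste0("E_X", seq_len(m)), "E_P")
}

#' @export
print.consortium_model <- function(x, ...) {
  m <- x$chain_length
  cat(sprintf("Two-cell consortium model: S -> %s -> P (%d intermediate%s)\n",
              paste(x$species[seq_len(m)], collapse = " -> "),
              m, if (m > 1) "s" else ""))
  cat(sprintf("  [S] = %g, fractions n = (%g, %g), N = %g\n",
              x$substrate_conc, x$fractions[1], x$fractions[2], x$total_cells))
  cat(sprintf("  demands J_P = (%g, %g), host demand J_P,0 = %g\n",
              x$demands[1], x$demands[2], x$host_demand))
  cat("  permeabilities:",
      paste(sprintf("D_%s = %g", names(x$permeabilities), x$permeabilities),
            collapse = ", "), "\n")
  k1 <- x$kinetics[[1]]
  if (k1$inv_K_I > 0)
    cat(sprintf("  %s product inhibition of E_S with 1/K_I = %g\n",
                k1$inhibition_mode, k1$inv_K_I))
  else cat("  no product inhibition\n")
  invisible(x)
}

#' Canonical model parameterization
#'
#' Returns the canonical two-reaction consortium: all kinetic constants equal
#' to one, `[S] = 10`, equal population fractions `n1 = n2 = 1/2`, equal cell
#' demands `J_P,1 = J_P,2 = 1`, no host demand, and unit permeabilities.
#' Overrides are applied last; an unknown override name is an error.
#'
#' @param ... Named overrides among `substrate_conc`, `chain_length`,
#'   `kinetics`, `permeabilities`, `demands`, `host_demand`, `fractions`,
#'   `total_cells`, `enzymes`, `inv_K_I`, `inhibition_mode`, and `K_eq` (a
#'   scalar applied to every reversible step).
#' @return A [consortium_model()].
#' @examples
#' m <- default_consortium(inv_K_I = 10, permeabilities = c(10, 0.1))
#' @export
default_consortium <- function(...) {
  overrides <- list(...)
  allowed <- c(names(formals(consortium_model)), "K_eq")
  allowed <- setdiff(allowed, "...")
  unknown <- setdiff(names(overrides), allowed)
  if (length(unknown) || (length(overrides) && is.null(names(overrides))))
    stop("unknown override key(s): ",
         paste(if (length(unknown)) unknown else "<unnamed>", collapse = ", "),
         call. = FALSE)
  K_eq <- overrides$K_eq
  overrides$K_eq <- NULL
  args <- list(substrate_conc = 10, chain_length = 1,
               demands = c(1, 1), host_demand = 0, fractions = c(0.5, 0.5))
  args[names(overrides)] <- overrides
  if (is.null(args$permeabilities) && is.null(overrides$permeabilities))
    args$permeabilities <- rep(1, args$chain_length + 1)
  model <- do.call(consortium_model, args)
  if (!is.null(K_eq)) {
    for (j in seq_len(model$chain_length + 1L)) model$kinetics[[j]]$K_eq <- K_eq
  }
  model
}

#' Extended-chain configuration with a single permeable intermediate
#'
#' Builds the five-intermediate chain used to study where a long pathway
#' splits: `K_eq = 4/3` on every reversible step, `[S] = 20`, uncompetitive
#' inhibition with `1/K_I = 10`, permeability 15 for the product and for one
#' chosen intermediate, and 1e-3 for all other intermediates.
#'
#' @param permeable_index Index (1..m) of the single permeable intermediate.
#' @param chain_length Number of intermediates (default 5).
#' @param D_permeable Permeability of the product and the chosen intermediate.
#' @param D_impermeable Permeability of all other intermediates.
#' @param ... Further overrides passed to [default_consortium()].
#' @return A [consortium_model()].
#' @export
extended_consortium <- function(permeable_index, chain_length = 5,
                                D_permeable = 15, D_impermeable = 1e-3, ...) {
  m <- chain_length
  if (permeable_index < 1 || permeable_index > m)
    stop("'permeable_index' must lie in 1..", m, call. = FALSE)
  D <- c(rep(D_impermeable, m), D_permeable)
  D[permeable_index] <- D_permeable
  default_consortium(chain_length = m, substrate_conc = 20, inv_K_I = 10,
                     K_eq = 4 / 3, permeabilities = D, ...)
}

## ---- YAML serialization -------------------------------------------------

#' Write / read a consortium model as YAML
#'
#' Round-trips every field of the model (including kinetic constants per step
#' and the enzyme matrix) through a human-editable YAML file.
#'
#' @param model A [consortium_model()].
#' @param path File path.
#' @return `write_consortium_yaml()` returns `path` invisibly;
#'   `read_consortium_yaml()` returns the reconstructed model.
#' @export
write_consortium_yaml <- function(model, path) {
  stopifnot(inherits(model, "consortium_model"))
  kin <- lapply(model$kinetics, function(k) {
    list(k_cat = k$k_cat, K_M_fwd = k$K_M_fwd, K_M_rev = k$K_M_rev,
         K_eq = k$K_eq, inv_K_I = k$inv_K_I,
         inhibition_mode = k$inhibition_mode, reversible = k$reversible)
  })
  obj <- list(substrate_conc = model$substrate_conc,
              chain_length = model$chain_length,
              kinetics = kin,
              permeabilities = as.numeric(model$permeabilities),
              demands = model$demands,
              host_demand = model$host_demand,
              fractions = model$fractions,
              total_cells = model$total_cells,
              enzymes = list(cell1 = as.numeric(model$enzymes[1, ]),
                             cell2 = as.numeric(model$enzymes[2, ])))
  yaml::write_yaml(obj, path, precision = 15)
  invisible(path)
}

#' @rdname write_consortium_yaml
#' @export
read_consortium_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  needed <- c("substrate_conc", "chain_length", "kinetics", "permeabilities",
              "demands", "host_demand", "fractions", "total_cells", "enzymes")
  missing <- setdiff(needed, names(obj))
  if (length(missing))
    stop("model YAML is missing field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  kin <- lapply(obj$kinetics, function(k)
    reaction_kinetics(k_cat = k$k_cat, K_M_fwd = k$K_M_fwd,
                      K_M_rev = k$K_M_rev, K_eq = k$K_eq,
                      inv_K_I = k$inv_K_I,
                      inhibition_mode = k$inhibition_mode,
                      reversible = k$reversible))
  consortium_model(substrate_conc = obj$substrate_conc,
                   chain_length = obj$chain_length,
                   kinetics = kin,
                   permeabilities = unlist(obj$permeabilities),
                   demands = unlist(obj$demands),
                   host_demand = obj$host_demand,
                   fractions = unlist(obj$fractions),
                   total_cells = obj$total_cells,
                   enzymes = rbind(unlist(obj$enzymes$cell1),
                                   unlist(obj$enzymes$cell2)))
}
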
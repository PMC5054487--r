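## Flatten the positive kinetic/permeability parameters of a model into a
## named vector (the quantities randomized by the sensitivity analysis).
## Demands and population fractions are not kinetic parameters and are left
## untouched; zero entries (no inhibition, impermeable species) cannot be
## perturbed multiplicatively and are excluded.
.parameter_vector <- function(model) {
  m <- model$chain_length
  out <- c(substrate_conc = model$substrate_conc)
  for (j in seq_len(m + 1L)) {
    k <- model$kinetics[[j]]
    nm <- model$steps[j]
    out[paste0(c("k_cat.", "K_M_fwd.", "K_M_rev.", "K_eq."), nm)] <-
      c(k$k_cat, k$K_M_fwd, k$K_M_rev, k$K_eq)
  }
  kP <- model$kinetics[[m + 2L]]
  out[c("k_cat.E_P", "K_M.E_P")] <- c(kP$k_cat, kP$K_M_fwd)
  if (model$kinetics[[1L]]$inv_K_I > 0)
    out["inv_K_I"] <- model$kinetics[[1L]]$inv_K_I
  D <- model$permeabilities
  keep <- D > 0
  if (any(keep))
    out[paste0("D_", names(D)[keep])] <- unname(D[keep])
  out
}

.apply_parameters <- function(model, values) {
  m <- model$chain_length
  model$substrate_conc <- unname(values["substrate_conc"])
  for (j in seq_len(m + 1L)) {
    nm <- model$steps[j]
    model$kinetics[[j]]$k_cat <- unname(values[paste0("k_cat.", nm)])
    model$kinetics[[j]]$K_M_fwd <- unname(values[paste0("K_M_fwd.", nm)])
    model$kinetics[[j]]$K_M_rev <- unname(values[paste0("K_M_rev.", nm)])
    model$kinetics[[j]]$K_eq <- unname(values[paste0("K_eq.", nm)])
  }
  model$kinetics[[m + 2L]]$k_cat <- unname(values["k_cat.E_P"])
  model$kinetics[[m + 2L]]$K_M_fwd <- unname(values["K_M.E_P"])
  if ("inv_K_I" %in% names(values))
    model$kinetics[[1L]]$inv_K_I <- unname(values["inv_K_I"])
  D <- model$permeabilities
  for (k in names(D)) {
    nm <- paste0("D_", k)
    if (nm %in% names(values)) model$permeabilities[k] <- unname(values[nm])
  }
  model
}

#' Randomly perturbed copy of a model's kinetic parameters
#'
#' Multiplies every positive kinetic parameter (kinetic constants, inhibition
#' strength, substrate level, nonzero permeabilities) by `exp(u)` with `u`
#' drawn independently and uniformly from `[-rel_magnitude, rel_magnitude]`.
#' Positivity is preserved by construction and the expected log-perturbation
#' is zero.  Deterministic given the seed.
#'
#' @param model Base [consortium_model()].
#' @param rel_magnitude Half-width of the log-uniform perturbation (> 0).
#' @param seed Integer seed.
#' @return A list of class `"parameter_sample"`: `model` (perturbed),
#'   `values` (named perturbed parameter vector), `base` (unperturbed
#'   vector), `factors` (`values / base`), `rel_magnitude`, `seed`.
#' @export
sample_perturbed_parameters <- function(model, rel_magnitude = 0.3,
                                        seed = 1) {
  stopifnot(inherits(model, "consortium_model"), rel_magnitude > 0)
  base <- .parameter_vector(model)
  u <- .with_seed(seed, stats::runif(length(base), -rel_magnitude,
                                     rel_magnitude))
  values <- base * exp(u)
  structure(list(model = .apply_parameters(model, values), values = values,
                 base = base, factors = exp(u),
                 rel_magnitude = rel_magnitude, seed = seed),
            class = "parameter_sample")
}

#' Tryptophan-pathway metabolite fixture
#'
#' The seven metabolites of tryptophan biosynthesis (chorismate through
#' L-tryptophan) with pinned SMILES in their physiological protonation
#' states, pathway positions 1-7, and indole flagged as substrate-channeled
#' (it is transferred internally within tryptophan synthase and never
#' diffuses freely).
#'
#' @return A data.frame with columns `name`, `smiles`, `position`,
#'   `channeled`; pass to [compute_pathway_descriptors()].
#' @export
trp_pathway_fixture <- function() {
  read_pathway_tsv(system.file("extdata", "trp_pathway.tsv",
                               package = "metsplit", mustWork = TRUE))
}

#' Generate a synthetic pathway with a known most-permeable intermediate
#'
#' Draws descriptor tables (no structures involved) in which exactly the
#' requested interior positions carry high-permeability descriptors (low
#' TPSA) while every other metabolite is firmly low-permeability, so the
#' ground-truth splitting point is known by construction:
#' the requested position, or — when several are requested — the requested
#' position with the lowest TPSA (the predictor's tie-break).
#'
#' @param seed Integer seed.
#' @param length Number of metabolites including the two endpoints (>= 4).
#' @param permeable_positions Interior positions (2..length-1) to make
#'   highly permeable.
#' @return A descriptor data.frame as from [compute_descriptors()] (with
#'   `smiles = NA`), with attributes `"truth"` (ground-truth position) and
#'   `"permeable_positions"`.
#' @export
synthetic_pathway <- function(seed, length = 6, permeable_positions) {
  if (length < 4)
    stop("'length' must be at least 4 (two endpoints + two intermediates)",
         call. = FALSE)
  interior <- 2:(length - 1)
  if (!all(permeable_positions %in% interior))
    stop("'permeable_positions' must be interior positions (2..length-1)",
         call. = FALSE)
  .with_seed(seed, {
    n <- length
    tpsa <- stats::runif(n, 165, 245)        # firmly low-permeability
    logp <- stats::runif(n, -3, 1.5)
    mw <- stats::runif(n, 200, 480)
    tpsa[permeable_positions] <- stats::runif(base::length(permeable_positions),
                                              10, 55)
    mw[permeable_positions] <- stats::runif(base::length(permeable_positions),
                                            80, 250)
    df <- data.frame(name = paste0("M", seq_len(n)), smiles = NA_character_,
                     position = seq_len(n), channeled = FALSE,
                     mw = mw, hbd = 0L, hba = 0L, logp_primary = logp,
                     logp_secondary = NA_real_, tpsa = tpsa)
    truth <- as.integer(permeable_positions[which.min(tpsa[permeable_positions])])
    attr(df, "truth") <- truth
    attr(df, "permeable_positions") <- permeable_positions
    df
  })
}
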
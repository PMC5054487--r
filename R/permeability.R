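#' Physicochemical permeability descriptors from SMILES
#'
#' Computes, with OpenBabel (via \pkg{ChemmineOB}), the descriptors used as
#' passive-membrane-permeability estimators for pathway metabolites: molecular
#' weight, hydrogen-bond donor and acceptor counts, an atom-contribution
#' octanol-water logP, and the topological polar surface area (TPSA, Ertl's
#' fragment-contribution method).  The structure is taken exactly as given —
#' no automatic (de)protonation — so charged species must be encoded
#' explicitly in the SMILES.
#'
#' @param name Compound name(s), used in error messages and outputs.
#' @param smiles SMILES string(s).
#' @param position Optional pathway position(s) (1-based along the chain).
#' @param channeled Logical flag(s): substrate-channeled intermediates are
#'   excluded from splitting-point prediction.
#' @return A data.frame with one row per compound and columns `name`,
#'   `smiles`, `position`, `channeled`, `mw`, `hbd`, `hba`, `logp_primary`,
#'   `logp_secondary` (NA unless a second estimator is supplied), `tpsa`.
#' @examples
#' \donttest{
#' compute_descriptors("indole", "c1ccc2c(c1)cc[nH]2")  # TPSA 15.79
#' }
#' @export
compute_descriptors <- function(name, smiles, position = seq_along(smiles),
                                channeled = FALSE) {
  stopifnot(length(name) == length(smiles))
  channeled <- rep_len(as.logical(channeled), length(smiles))
  rows <- lapply(seq_along(smiles), function(i) {
    p <- tryCatch(
      suppressWarnings(
        ChemmineOB::prop_OB(ChemmineOB::forEachMol("SMILES", smiles[i],
                                                   identity))),
      error = function(e) NULL)
    if (is.null(p) || !is.data.frame(p) || nrow(p) != 1L ||
        !is.finite(p$MW) || p$MW <= 0)
      stop("cannot parse SMILES for record '", name[i], "': ", smiles[i],
           call. = FALSE)
    data.frame(name = name[i], smiles = smiles[i], position = position[i],
               channeled = channeled[i], mw = p$MW, hbd = p$HBD,
               hba = p$HBA2, logp_primary = p$logP,
               logp_secondary = NA_real_, tpsa = p$TPSA)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compute descriptors for a whole pathway table
#'
#' @param pathway A data.frame with columns `name`, `smiles`, `position`,
#'   `channeled` (e.g. from [trp_pathway_fixture()] or [read_pathway_tsv()]).
#' @return The descriptor table of [compute_descriptors()], ordered by
#'   position.
#' @export
compute_pathway_descriptors <- function(pathway) {
  need <- c("name", "smiles", "position", "channeled")
  if (!all(need %in% names(pathway)))
    stop("pathway table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- compute_descriptors(pathway$name, pathway$smiles, pathway$position,
                             pathway$channeled)
  out[order(out$position), , drop = FALSE]
}

#' Load a permeability classification ruleset
#'
#' The permeability classes `H` (high), `MH`, `ML`, `L` (low) are assigned by
#' two declared, editable rules shipped as YAML: a single-parameter TPSA
#' ladder (`one_param`) and a three-parameter decision list on TPSA, logP and
#' molecular weight (`three_param`).  The shipped defaults are calibrated so
#' that the tryptophan-pathway reference table is reproduced; they are a
#' classification convention, not a mechanistic permeability model.  All
#' comparisons are strict (`<`): a descriptor landing exactly on a threshold
#' falls into the less-permeable class and is flagged.
#'
#' @param path YAML file; defaults to the ruleset shipped with the package.
#' @return An object of class `"permeability_ruleset"`.
#' @export
permeability_ruleset <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "permeability_rules.yaml",
                        package = "metsplit", mustWork = TRUE)
  rs <- yaml::read_yaml(path)
  if (!all(c("classes", "one_param", "three_param") %in% names(rs)))
    stop("ruleset must define 'classes', 'one_param' and 'three_param'",
         call. = FALSE)
  thr <- unlist(rs$one_param$tpsa)
  if (length(thr) != length(rs$classes) - 1L || is.unsorted(thr, strictly = TRUE))
    stop("one_param TPSA thresholds must be strictly increasing and one",
         " fewer than the classes", call. = FALSE)
  structure(rs, class = "permeability_ruleset")
}

#' @export
print.permeability_ruleset <- function(x, ...) {
  cat("Permeability ruleset; classes:", paste(x$classes, collapse = " > "),
      "\n  1PR TPSA thresholds:", paste(unlist(x$one_param$tpsa),
                                        collapse = ", "), "\n")
  cat("  3PR decision list:\n")
  for (r in x$three_param$rules) {
    cond <- r[setdiff(names(r), "class")]
    cat("   ", r$class, if (length(cond))
      paste0("if ", paste(names(cond), "<", unlist(cond), collapse = " and "))
      else "otherwise", "\n")
  }
  invisible(x)
}

## Rank of a class label: larger = more permeable.
.class_rank <- function(labels, ruleset) {
  match(labels, rev(ruleset$classes))
}

.classify_1pr <- function(tpsa, ruleset) {
  thr <- unlist(ruleset$one_param$tpsa)
  cls <- character(length(tpsa))
  tie <- logical(length(tpsa))
  for (i in seq_along(tpsa)) {
    k <- sum(!(tpsa[i] < thr)) + 1L       # first threshold not strictly above
    cls[i] <- ruleset$classes[k]
    tie[i] <- any(tpsa[i] == thr)
  }
  list(class = cls, tie = tie)
}

.classify_3pr <- function(tpsa, logp, mw, ruleset) {
  n <- length(tpsa)
  cls <- character(n); tie <- logical(n)
  for (i in seq_len(n)) {
    val <- c(tpsa = tpsa[i], logp = logp[i], mw = mw[i])
    for (r in ruleset$three_param$rules) {
      lims <- unlist(r[setdiff(names(r), "class")])
      if (length(lims) == 0L) {       # unconditional fallback rule
        cls[i] <- r$class
        break
      }
      names(lims) <- sub("_max$", "", names(lims))
      if (any(val[names(lims)] == lims)) tie[i] <- TRUE
      if (all(val[names(lims)] < lims)) {
        cls[i] <- r$class
        break
      }
    }
    if (cls[i] == "") cls[i] <- ruleset$classes[length(ruleset$classes)]
  }
  list(class = cls, tie = tie)
}

#' Assign permeability classes to metabolite records
#'
#' Applies the single-parameter (TPSA) and three-parameter (TPSA, logP, MW)
#' rules of a [permeability_ruleset()] to a descriptor table.
#'
#' @param records Descriptor table from [compute_descriptors()] (or any
#'   data.frame with `tpsa`, `logp_primary`, `mw`).
#' @param ruleset A [permeability_ruleset()].
#' @return `records` with added columns `perm_class_1`, `perm_class_3` and
#'   logical `threshold_tie` (descriptor exactly on a class threshold; such
#'   records sit in the less-permeable class by convention).
#' @export
classify_permeability <- function(records, ruleset = permeability_ruleset()) {
  need <- c("tpsa", "logp_primary", "mw")
  if (!all(need %in% names(records)))
    stop("records are missing descriptor column(s): ",
         paste(setdiff(need, names(records)), collapse = ", "),
         "; run compute_descriptors() first", call. = FALSE)
  if (any(!is.finite(records$tpsa)) || any(!is.finite(records$mw)))
    stop("descriptors contain missing values; refusing to classify",
         call. = FALSE)
  r1 <- .classify_1pr(records$tpsa, ruleset)
  r3 <- .classify_3pr(records$tpsa, records$logp_primary, records$mw, ruleset)
  records$perm_class_1 <- r1$class
  records$perm_class_3 <- r3$class
  records$threshold_tie <- r1$tie | r3$tie
  records
}

#' Predict the splitting point of a pathway from permeability
#'
#' The model predicts that when metabolic complementation is optimal, a
#' pathway splits at its most membrane-permeable intermediate.  This predictor
#' ranks the interior intermediates (pathway endpoints excluded) that are not
#' substrate-channeled by their permeability class and returns the best one;
#' ties are broken by lower TPSA, then lower molecular weight.
#'
#' @param pathway Classified descriptor table (see [classify_permeability()])
#'   with `position` and `channeled` columns, ordered or orderable by
#'   position; at least 2 intermediates between the endpoints.
#' @param ruleset A [permeability_ruleset()] (for the class ranking).
#' @param rule Which class column drives the ranking: the three-parameter
#'   (default) or one-parameter rule.
#' @param ignore_channeling Rank channeled intermediates too.
#' @return A list of class `"breaking_point"`: `position`, `name`, `class`,
#'   and the ranked candidate table; `position` is `NA` when every
#'   intermediate is channeled.
#' @export
predict_breaking_point <- function(pathway,
                                   ruleset = permeability_ruleset(),
                                   rule = c("three_param", "one_param"),
                                   ignore_channeling = FALSE) {
  rule <- match.arg(rule)
  col <- if (rule == "three_param") "perm_class_3" else "perm_class_1"
  if (!col %in% names(pathway))
    pathway <- classify_permeability(pathway, ruleset)
  pathway <- pathway[order(pathway$position), , drop = FALSE]
  n <- nrow(pathway)
  if (n < 4L)
    stop("need at least 2 interior intermediates between the endpoints",
         call. = FALSE)
  cand <- pathway[-c(1L, n), , drop = FALSE]
  if (!ignore_channeling) cand <- cand[!cand$channeled, , drop = FALSE]
  if (nrow(cand) == 0L)
    return(structure(list(position = NA_integer_, name = NA_character_,
                          class = NA_character_, candidates = cand,
                          reason = "all intermediates are channeled"),
                     class = "breaking_point"))
  cand$rank <- .class_rank(cand[[col]], ruleset)
  ord <- order(-cand$rank, cand$tpsa, cand$mw)
  cand <- cand[ord, , drop = FALSE]
  structure(list(position = cand$position[1L], name = cand$name[1L],
                 class = cand[[col]][1L], candidates = cand),
            class = "breaking_point")
}

#' @export
print.breaking_point <- function(x, ...) {
  if (is.na(x$position)) {
    cat("No splitting-point prediction:", x$reason, "\n")
  } else {
    cat(sprintf("Predicted pathway splitting point: %s (position %d, class %s)\n",
                x$name, x$position, x$class))
  }
  invisible(x)
}

#' Read a pathway metabolite table from TSV
#'
#' @param path TSV file with columns `name`, `smiles`, `position`,
#'   `channeled`.
#' @return A data.frame ordered by position.
#' @export
read_pathway_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          comment.char = "#")
  need <- c("name", "smiles", "position", "channeled")
  if (!all(need %in% names(df)))
    stop("pathway TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  df$channeled <- as.logical(df$channeled)
  df[order(df$position), , drop = FALSE]
}
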
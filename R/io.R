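## 32-bit FNV-1a hash of a character string; used to stamp outputs with a
## stable configuration fingerprint without adding a dependency.
.fnv1a <- function(text) {
  bytes <- utf8ToInt(enc2utf8(paste(text, collapse = "\n")))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    ## xor on the low 24 bits (h may exceed the integer range)
    low <- h %% 16777216
    h <- (h - low) + bitwXor(as.integer(low), as.integer(b %% 16777216))
    ## 32-bit modular multiply by the FNV prime, split to keep exactness
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  sprintf("%08x", h)
}

.known_config_keys <- list(
  model = c("substrate_conc", "chain_length", "inv_K_I", "inhibition_mode",
            "K_eq", "permeabilities", "demands", "host_demand", "fractions",
            "total_cells"),
  solver = c("n_starts", "constraint_tolerance", "optimality_tolerance",
             "symmetry_restriction", "maxit", "search"),
  experiment = c("D_X_values", "D_P_values", "inv_K_I_values", "param",
                 "values", "n_samples", "rel_magnitude", "permeable_index",
                 "chain_length"),
  permeability = c("pathway_tsv", "ruleset_yaml", "rule"))

#' Load and validate a run configuration
#'
#' A run configuration is a YAML file with optional sections `model`,
#' `solver`, `experiment`, `permeability`, plus `seed` and `out_dir`.
#' Missing entries default to the canonical model ([default_consortium()])
#' and default [solver_options()]; unknown keys (anywhere) are rejected with
#' the offending key named.
#'
#' @param path YAML file path.
#' @return A list of class `"run_config"` with elements `model`
#'   (a [consortium_model()]), `solver` (a [solver_options()]), `experiment`,
#'   `permeability`, `seed`, `out_dir`, and `text` (the raw YAML, hashed into
#'   every output).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  text <- readLines(path, warn = FALSE)
  cfg <- yaml::yaml.load(paste(text, collapse = "\n"))
  if (is.null(cfg)) cfg <- list()
  top_known <- c(names(.known_config_keys), "seed", "out_dir")
  bad <- setdiff(names(cfg), top_known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  for (sec in names(.known_config_keys)) {
    bad <- setdiff(names(cfg[[sec]]), .known_config_keys[[sec]])
    if (length(bad))
      stop("unknown key(s) in '", sec, "' section: ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  seed <- if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  marg <- cfg$model
  if (!is.null(marg$permeabilities))
    marg$permeabilities <- unlist(marg$permeabilities)
  if (!is.null(marg$demands)) marg$demands <- unlist(marg$demands)
  if (!is.null(marg$fractions)) marg$fractions <- unlist(marg$fractions)
  model <- do.call(default_consortium, marg %||% list())
  sarg <- cfg$solver %||% list()
  sarg$seed <- seed
  solver <- do.call(solver_options, sarg)
  structure(list(model = model, solver = solver,
                 experiment = cfg$experiment %||% list(),
                 permeability = cfg$permeability %||% list(),
                 seed = seed, out_dir = cfg$out_dir %||% ".",
                 text = text),
            class = "run_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Save a run configuration back to YAML
#'
#' @param config A `"run_config"` object (its raw text is preserved, so a
#'   save/load round trip is exact).
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "run_config"))
  writeLines(config$text, path)
  invisible(path)
}

## Tabular representation of the result objects write_results() understands.
.result_table <- function(result) {
  if (inherits(result, c("phase_diagram", "allocation_sweep")))
    return(as.data.frame(result))
  if (inherits(result, "sensitivity_result")) return(result$estimates)
  if (inherits(result, "breaking_point")) return(result$candidates)
  if (inherits(result, "allocation_fit")) {
    if (!result$feasible)
      return(data.frame(cost = NA_real_, feasible = FALSE,
                        reason = result$reason))
    E <- result$enzymes
    cells <- rep(rownames(E), each = ncol(E))
    return(data.frame(
      quantity = c("cost", paste0(cells, ".", colnames(E)),
                   paste0("A_", sub("^E_", "", names(result$asymmetries)))),
      value = c(result$cost, as.numeric(t(E)),
                as.numeric(result$asymmetries))))
  }
  if (is.data.frame(result)) {
    ## descriptor tables are written with the reference column layout
    if (all(c("name", "mw", "logp_primary", "tpsa", "perm_class_1",
              "perm_class_3") %in% names(result))) {
      out <- result[, c("name", "mw", "logp_primary", "tpsa",
                        "perm_class_1", "perm_class_3")]
      names(out) <- c("name", "MW", "logP", "TPSA", "1PR", "3PR")
      return(out)
    }
    return(result)
  }
  stop("no tabular form known for objects of class ",
       paste(class(result), collapse = "/"), call. = FALSE)
}

#' Write a result table plus provenance metadata
#'
#' Writes `name.csv` (the tabular content, RFC-4180, no row names) and
#' `name.json` (metadata: package version, seed, configuration hash, result
#' class).  Outputs are a pure function of (result, config, seed): re-running
#' with identical inputs reproduces byte-identical files.
#'
#' @param result A result object: [phase_diagram()], [allocation_sweep()],
#'   [sensitivity_analysis()], [predict_breaking_point()],
#'   [optimize_allocation()] fit, or a classified descriptor table.
#' @param out_dir Output directory (created if needed).
#' @param name Basename of the two files.
#' @param config Optional `"run_config"` whose text is hashed into the
#'   metadata.
#' @param seed Seed recorded in the metadata (defaults to the config's, or
#'   the result's when it carries one).
#' @return Named character vector of the paths written, invisibly.
#' @export
write_results <- function(result, out_dir, name = "result", config = NULL,
                          seed = NULL) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  tab <- .result_table(result)
  csv <- file.path(out_dir, paste0(name, ".csv"))
  json <- file.path(out_dir, paste0(name, ".json"))
  utils::write.csv(tab, csv, row.names = FALSE)
  if (is.null(seed))
    seed <- attr(result, "seed") %||% result$seed %||% config$seed %||% NA
  meta <- list(package = "metsplit",
               version = as.character(utils::packageVersion("metsplit")),
               result_class = class(result)[1L],
               seed = seed,
               config_hash = if (is.null(config)) NA
                             else .fnv1a(config$text),
               rows = nrow(tab))
  jsonlite::write_json(meta, json, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(csv = csv, json = json))
}
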
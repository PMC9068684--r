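# Model configuration files: JSON with fields
#   N            integer >= 3
#   symmetry     "dihedral" | "reflection" | "rotation" | "trivial" |
#                {"generators": ["(1 2)", ...]}
#   reversible   logical (default true)
#   rearrangements  [{"perm": "(1 2)", "weight": 0.5 or "2/3"}, ...]

#' Resolve a symmetry specification to a subgroup
#'
#' @param symmetry string keyword or `list(generators = ...)`.
#' @param N degree.
#' @return a `symm_subgroup`.
#' @export
resolve_symmetry <- function(symmetry, N) {
  if (is.list(symmetry)) {
    gens <- lapply(symmetry$generators, parse_perm, N = N)
    return(subgroup_closure(N, gens))
  }
  switch(as.character(symmetry),
    dihedral  = dihedral_group(N),
    reflection = subgroup_closure(N, list(rev(seq_len(N)))),
    rotation  = subgroup_closure(N, list(c(seq_len(N)[-1], 1L))),
    trivial   = subgroup_closure(N, list()),
    stop("unknown symmetry keyword: ", symmetry))
}

#' Read and validate a model configuration file
#'
#' @param path JSON file.
#' @return validated config list (not yet expanded into a model).
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("model config not found: ", path)
  cfg <- jsonlite::read_json(path, simplifyVector = FALSE)
  validate_model_config(cfg)
  cfg
}

#' @keywords internal
validate_model_config <- function(cfg) {
  need <- function(ok, field, msg)
    if (!ok) stop(sprintf("model config field '%s': %s", field, msg))
  need(!is.null(cfg$N) && is.numeric(cfg$N) && cfg$N == round(cfg$N) && cfg$N >= 3,
       "N", "must be an integer >= 3")
  need(!is.null(cfg$symmetry) &&
         (is.character(cfg$symmetry) || is.list(cfg$symmetry)),
       "symmetry", "must be a keyword or {generators: [...]}")
  if (is.character(cfg$symmetry))
    need(cfg$symmetry %in% c("dihedral", "reflection", "rotation", "trivial"),
         "symmetry", "unknown keyword")
  need(is.null(cfg$reversible) || is.logical(cfg$reversible),
       "reversible", "must be logical")
  need(!is.null(cfg$rearrangements) && length(cfg$rearrangements) > 0,
       "rearrangements", "must be a non-empty list")
  for (r in cfg$rearrangements) {
    need(!is.null(r$perm), "rearrangements.perm", "missing")
    need(!is.null(r$weight) && (is.numeric(r$weight) || is.character(r$weight)),
         "rearrangements.weight", "must be numeric or a fraction string")
  }
  invisible(cfg)
}

#' Write a model configuration file
#'
#' @param cfg config list (see `read_model_config`) or a `model_spec`
#'   (serialized back to its base types).
#' @param path output JSON path.
#' @return invisibly, `path`.
#' @export
write_model_config <- function(cfg, path) {
  if (inherits(cfg, "model_spec")) {
    cfg <- list(
      N = cfg$N,
      symmetry = list(generators = vapply(cfg$Z$generators, format_perm,
                                          character(1))),
      reversible = cfg$reversible,
      rearrangements = lapply(cfg$base, function(t)
        list(perm = format_perm(t$perm),
             weight = sprintf("%d/%d", t$weight[1], t$weight[2]))))
  }
  validate_model_config(cfg)
  jsonlite::write_json(cfg, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Parse a model configuration into a built model
#'
#' Reads, validates, expands (orbits, weights) and logs the expanded model.
#'
#' @param path JSON config file.
#' @param quiet suppress the expansion log.
#' @return a `model_spec`.
#' @export
parse_model_config <- function(path, quiet = FALSE) {
  cfg <- read_model_config(path)
  Z <- resolve_symmetry(cfg$symmetry, cfg$N)
  base <- lapply(cfg$rearrangements, function(r)
    list(perm = r$perm, weight = r$weight))
  rev <- if (is.null(cfg$reversible)) TRUE else isTRUE(cfg$reversible)
  ms <- build_model(cfg$N, Z, base, enforce_reversibility = rev)
  if (!quiet) {
    message(sprintf("model: N = %d, |Z| = %d, %d type(s) -> %d instance(s)",
                    ms$N, ms$Z$size, length(ms$base), length(ms$expanded)))
    for (t in ms$base)
      message(sprintf("  type %s: orbit %d, per-instance weight %g/%g",
                      format_perm(t$perm), length(t$orbit),
                      t$instance_weight[1], t$instance_weight[2]))
  }
  ms
}
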
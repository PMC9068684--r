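# Rearrangement models (M, w): a user supplies base rearrangement TYPES with
# per-type weights; the model is closed under conjugation by the symmetry
# subgroup (condition M1) and, when requested, under inversion (condition M2).
# Each type's weight is split uniformly over the distinct permutations of its
# orbit and the whole distribution is renormalized to sum to one, so that a
# type keeps its total relative rate regardless of orbit size.

#' @keywords internal
conjugation_orbit <- function(a, Z, include_inverse = FALSE) {
  seen <- new.env(parent = emptyenv())
  out <- list()
  seeds <- list(a)
  if (include_inverse) seeds <- c(seeds, list(perm_inverse(a)))
  for (s in seeds) {
    for (d in Z$elements) {
      x <- compose(d, compose(s, perm_inverse(d)))
      k <- perm_key(x)
      if (!exists(k, seen, inherits = FALSE)) {
        assign(k, TRUE, seen)
        out[[length(out) + 1L]] <- x
      }
    }
  }
  out
}

#' Build a rearrangement model
#'
#' Expands base rearrangement types into their symmetry-closed permutation set
#' with exact rational weights. Two base types whose clouds have the same
#' action (`z a z` equal, i.e. same double coset) are an error: such
#' complementary rearrangements must be deduplicated deliberately by the user.
#'
#' @param N number of regions.
#' @param Z symmetry `symm_subgroup` (e.g. `dihedral_group(N)`).
#' @param base list of `list(perm = ..., weight = ...)`; `perm` may be a
#'   permutation vector or a cycle/one-line string, `weight` a positive number
#'   or fraction string such as `"2/3"`.
#' @param enforce_reversibility close each orbit under inversion (M2).
#' @return object of class `model_spec` with fields `N`, `Z`, `base`
#'   (types with orbit and cloud weight), `expanded` (distinct permutations
#'   with exact rational weights summing to 1), `reversible`, `generates`,
#'   `trivial`.
#' @export
build_model <- function(N, Z, base, enforce_reversibility = TRUE) {
  if (Z$degree != N) stop("symmetry subgroup degree mismatch")
  if (length(base) == 0L) stop("empty rearrangement list")
  types <- lapply(base, function(b) {
    a <- if (is.character(b$perm)) parse_perm(b$perm, N) else as_perm(b$perm)
    if (length(a) != N) stop("base rearrangement degree mismatch")
    w <- as_rational(b$weight)
    if (w[1] <= 0) stop("zero/negative weight in model")
    list(perm = a, weight = w)
  })
  # base elements lying in Z act as the identity cloud: allowed but flagged
  in_Z <- vapply(types, function(t) subgroup_contains(Z, t$perm), logical(1))
  if (any(in_Z))
    warning("base rearrangement(s) lie in the symmetry subgroup: identity ",
            "cloud action, inflates self-loop probability")
  # duplicate cloud actions among base types (complementary rearrangements)
  dkeys <- vapply(types, function(t)
    perm_key(double_coset_canonical(t$perm, Z)), character(1))
  if (anyDuplicated(dkeys)) {
    dup <- which(duplicated(dkeys))[1]
    stop(sprintf(paste0(
      "duplicate cloud action: base rearrangements %s and %s have the same ",
      "action z*a*z (complementary rearrangements under the symmetry); ",
      "include only one"),
      format_perm(types[[which(dkeys == dkeys[dup])[1]]]$perm),
      format_perm(types[[dup]]$perm)))
  }
  # expand orbits; per-instance weight = type weight / orbit size
  acc <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  total <- c(0, 1)
  for (i in seq_along(types)) {
    orb <- conjugation_orbit(types[[i]]$perm, Z, enforce_reversibility)
    types[[i]]$orbit <- orb
    w_inst <- rat_mul(types[[i]]$weight, c(1, length(orb)))
    types[[i]]$instance_weight <- w_inst
    total <- rat_add(total, types[[i]]$weight)
    for (x in orb) {
      k <- perm_key(x)
      cur <- if (exists(k, acc, inherits = FALSE)) get(k, acc) else c(0, 1)
      assign(k, rat_add(cur, w_inst), acc)
      assign(k, x, store)
    }
  }
  inv_total <- c(total[2], total[1])
  keys <- ls(acc)
  expanded <- lapply(keys, function(k) {
    w <- rat_mul(get(k, acc), inv_total)
    list(perm = get(k, store), num = w[1], den = w[2])
  })
  for (i in seq_along(types)) {
    types[[i]]$cloud_weight <- rat_mul(types[[i]]$weight, inv_total)
    types[[i]]$instance_weight <- rat_mul(types[[i]]$instance_weight, inv_total)
  }
  # exhaustive M1 (and M2) verification on the expanded set
  ekeys <- vapply(expanded, function(t) perm_key(t$perm), character(1))
  wt_of <- stats::setNames(lapply(expanded, function(t) c(t$num, t$den)), ekeys)
  for (t in expanded) {
    for (d in Z$elements) {
      ck <- perm_key(compose(d, compose(t$perm, perm_inverse(d))))
      if (is.null(wt_of[[ck]]) || !identical(wt_of[[ck]], c(t$num, t$den)))
        stop("internal error: M1 closure violated")
    }
    if (enforce_reversibility) {
      ik <- perm_key(perm_inverse(t$perm))
      if (is.null(wt_of[[ik]]) || !identical(wt_of[[ik]], c(t$num, t$den)))
        stop("internal error: M2 closure violated")
    }
  }
  trivial <- all(in_Z)
  gen <- if (N <= 8) {
    generates_full_group(c(lapply(expanded, `[[`, "perm"), Z$elements), N)
  } else NA
  if (isFALSE(gen))
    warning("model plus symmetry subgroup does not generate S_N: genomes in ",
            "other cosets are unrelated under the model (likelihood 0)")
  structure(list(N = N, Z = Z, base = types, expanded = expanded,
                 reversible = enforce_reversibility, generates = gen,
                 trivial = trivial),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("<rearrangement model: N = %d, |Z| = %d, %d type(s), %d instance(s)%s>\n",
              x$N, x$Z$size, length(x$base), length(x$expanded),
              if (x$reversible) ", reversible" else ""))
  for (t in x$base)
    cat(sprintf("  type %s: weight %g/%g, orbit size %d\n",
                format_perm(t$perm), t$cloud_weight[1], t$cloud_weight[2],
                length(t$orbit)))
  invisible(x)
}

#' Model element s (and cloud form s-tilde)
#'
#' `s = sum_{a in M} w(a) a` in the group algebra, and
#' `s_tilde = sum_types w_type * z a_type`, the genome-algebra model element
#' with one cloud per rearrangement type. The two differ as algebra elements
#' but have the same action: `z s z = s_tilde z` exactly.
#'
#' @param ms a `model_spec`.
#' @return list with `algelem` fields `s` and `s_tilde`.
#' @export
model_element <- function(ms) {
  s <- alg_elem(ms$N, lapply(ms$expanded, `[[`, "perm"),
                num = vapply(ms$expanded, `[[`, numeric(1), "num"),
                den = vapply(ms$expanded, `[[`, numeric(1), "den"))
  z <- symmetry_element(ms$Z)
  st <- NULL
  for (t in ms$base) {
    term <- alg_scale(alg_mul(z, alg_elem(ms$N, list(t$perm))),
                      t$cloud_weight[1], t$cloud_weight[2])
    st <- if (is.null(st)) term else alg_add(st, term)
  }
  list(s = s, s_tilde = st)
}

#' Reduced model matrices rho_p^A(z s)
#'
#' For every partition with `k_p > 0`, the `k_p x k_p` symmetric matrix
#' `t(Q) rho_p(s) Q` representing the model element on the module `W_p`. Its
#' eigenvalues are exactly the eigenvalues of the full `rho_p(s)` that carry
#' non-zero weight in the likelihood, all within [-1, 1].
#'
#' @param ms a reversible `model_spec` (M2 is required for symmetry).
#' @param rps list from `reduced_irreps(ms$N, ms$Z)`.
#' @param tol symmetry assertion tolerance.
#' @return list parallel to `rps`; `NULL` entries where `k_p = 0`.
#' @export
reduced_model_matrices <- function(ms, rps, tol = 1e-10) {
  if (!isTRUE(ms$reversible))
    stop("model is not reversible (M2): reduced model matrices need not be ",
         "symmetric; rebuild with enforce_reversibility = TRUE")
  me <- model_element(ms)
  lapply(rps, function(rp) {
    if (rp$k == 0L) return(NULL)
    M <- reduced_rep_matrix(rp, me$s)
    if (max(abs(M - t(M))) > tol)
      stop("reduced model matrix not symmetric despite M2")
    (M + t(M)) / 2
  })
}
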
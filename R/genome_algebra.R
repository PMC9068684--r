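# The genome algebra A = z R[S_N]: projections rho_p(z), the reduced
# irreducible representations rho_p^A on W_p = z V_p, the regular character
# of A, and the dimension of the class algebra A_0 = z R[S_N] z.

#' @keywords internal
subgroup_cache_key <- function(Z) {
  paste0("N", Z$degree, "|", paste(Z$keys, collapse = ";"))
}

#' Projection rho_p(z) of the symmetry element
#'
#' The average of the YOR matrices over the symmetry subgroup: a real
#' symmetric idempotent whose only eigenvalues are 0 and 1.
#'
#' @param p a partition of N.
#' @param Z a `symm_subgroup` of degree N.
#' @return a symmetric `D_p x D_p` projection matrix.
#' @export
symmetry_projection <- function(p, Z) {
  if (sum(p) != Z$degree) stop("degree mismatch")
  key <- paste0(partition_key(p), "#", subgroup_cache_key(Z))
  hit <- .ga_cache$proj[[key]]
  if (!is.null(hit)) return(hit)
  d <- hook_dimension(p)
  M <- matrix(0, d, d)
  for (z in Z$elements) M <- M + irrep_matrix(p, z)
  M <- M / Z$size
  M <- (M + t(M)) / 2
  .ga_cache$proj[[key]] <- M
  M
}

#' Reduced irreducible representation data for one partition
#'
#' Extracts an orthonormal basis Q of the eigenvalue-1 eigenspace of
#' `rho_p(z)`; the genome-algebra representation of any element `tau` in A is
#' then `t(Q) %*% rho_p(tau) %*% Q` on the `k_p`-dimensional module
#' `W_p = z V_p`. `k_p` may be zero.
#'
#' @param p a partition of N.
#' @param Z a `symm_subgroup`.
#' @param tol tolerance on eigenvalue deviation from \{0, 1\}; violation is a
#'   hard error (it signals a broken representation, not data noise).
#' @return object of class `reduced_irrep`: list with `partition`, `D`, `k`,
#'   `Q` (`D x k`, orthonormal columns).
#' @export
reduced_irrep <- function(p, Z, tol = 1e-9) {
  P <- symmetry_projection(p, Z)
  es <- eigen(P, symmetric = TRUE)
  ev <- es$values
  if (any(pmin(abs(ev), abs(ev - 1)) > tol))
    stop("symmetry projection has eigenvalues off {0,1}: broken representation")
  sel <- ev > 0.5
  k <- sum(sel)
  k_trace <- round(sum(diag(P)))
  if (k != k_trace)
    stop("eigenvalue count and projection trace disagree for k_p")
  Q <- es$vectors[, sel, drop = FALSE]
  if (k > 0) Q <- qr.Q(qr(Q))   # re-orthonormalize
  structure(list(partition = as.integer(p), D = hook_dimension(p),
                 k = as.integer(k), Q = Q),
            class = "reduced_irrep")
}

#' @export
print.reduced_irrep <- function(x, ...) {
  cat(sprintf("<reduced irrep, partition (%s): D_p = %d, k_p = %d>\n",
              paste(x$partition, collapse = ","), x$D, x$k))
  invisible(x)
}

#' Reduced representation data for all partitions of N
#'
#' @param N degree.
#' @param Z a `symm_subgroup` of degree N.
#' @return list of `reduced_irrep`, in the fixed `partitions(N)` order.
#' @export
reduced_irreps <- function(N, Z) {
  lapply(partitions(N), reduced_irrep, Z = Z)
}

#' Genome-algebra representation matrix of an algebra element
#'
#' `t(Q) rho_p(tau) Q`, the `k_p x k_p` matrix of the action of `tau` on the
#' module `W_p`. Permutations are accepted and interpreted as the cloud
#' `z sigma` (the projection onto W_p makes the leading `z` implicit).
#'
#' @param rp a `reduced_irrep`.
#' @param tau an `algelem`, or a permutation (treated as `z tau`).
#' @return `k_p x k_p` matrix (0 x 0 when `k_p = 0`).
#' @export
reduced_rep_matrix <- function(rp, tau) {
  if (rp$k == 0L) return(matrix(0, 0, 0))
  if (!inherits(tau, "algelem"))
    tau <- alg_elem(length(as_perm(tau)), list(as_perm(tau)))
  crossprod(rp$Q, algebra_rep(rp$partition, tau) %*% rp$Q)
}

#' Number of genome clouds K = N!/|Z|
#' @param N degree.
#' @param Z a `symm_subgroup`.
#' @return integer `N!/|Z|`.
#' @export
cloud_count <- function(N, Z) {
  K <- factorial(N) / Z$size
  stopifnot(abs(K - round(K)) < 1e-9)
  as.integer(round(K))
}

#' Regular character of the genome algebra at a cloud
#'
#' The exact case split: `K` when `sigma` lies in the symmetry subgroup
#' (then `z sigma = z`), else 0. With `check = TRUE` the value is recomputed
#' as `sum_p D_p tr(rho_p^A(z sigma))` (the character decomposition) and the
#' two routes are asserted equal.
#'
#' @param sigma permutation.
#' @param Z a `symm_subgroup`.
#' @param check cross-check against the irreducible-character route.
#' @param rps optional precomputed `reduced_irreps(N, Z)` (used when checking).
#' @return numeric: `K * [sigma in Z]`.
#' @export
regular_character_A <- function(sigma, Z, check = TRUE, rps = NULL) {
  sigma <- as_perm(sigma)
  N <- Z$degree
  val <- if (subgroup_contains(Z, sigma)) cloud_count(N, Z) else 0
  if (check) {
    if (is.null(rps)) rps <- reduced_irreps(N, Z)
    alt <- sum(vapply(rps, function(rp) {
      if (rp$k == 0L) return(0)
      rp$D * sum(diag(reduced_rep_matrix(rp, sigma)))
    }, numeric(1)))
    if (abs(alt - val) > 1e-8)
      stop(sprintf("regular character mismatch: case split %g vs spectral %g",
                   val, alt))
  }
  val
}

#' Dimension of the class algebra A_0 = z R[S_N] z
#'
#' The number of double cosets `Z g Z`, computed by Burnside's lemma over the
#' `Z x Z` action `g -> z1 g z2^{-1}`. The fixed-point count
#' `|{g : g^{-1} z1 g = z2}|` is the S_N-centralizer size of `z1` when the two
#' have equal cycle type and 0 otherwise, so the count is exact integer
#' arithmetic.
#'
#' @param N degree (resource guard N <= 8).
#' @param Z a `symm_subgroup`.
#' @return integer: the number of distinct rearrangement actions; also equals
#'   `sum_p k_p^2`.
#' @export
class_algebra_dimension <- function(N, Z) {
  if (N > 8) stop("class_algebra_dimension: resource guard, N <= 8")
  types <- vapply(Z$elements, function(z) paste(cycle_type(z), collapse = ","),
                  character(1))
  cents <- vapply(Z$elements, centralizer_size, numeric(1))
  total <- 0
  tab <- split(cents, types)
  for (grp in tab) total <- total + length(grp)^2 * grp[[1]]
  L <- total / Z$size^2
  stopifnot(abs(L - round(L)) < 1e-9)
  as.integer(round(L))
}

#' Dimension table of the genome algebra
#'
#' One row per partition of N with the irreducible dimension `D_p` and the
#' reduced-module dimension `k_p`; the identities `sum D_p^2 = N!`,
#' `sum D_p k_p = N!/|Z|` and `sum k_p^2 = dim(A_0)` summarize the table.
#'
#' @param N degree.
#' @param Z a `symm_subgroup`.
#' @return data.frame with columns `partition`, `D`, `k`.
#' @export
dims_table <- function(N, Z) {
  rps <- reduced_irreps(N, Z)
  data.frame(
    partition = vapply(rps, function(r) paste(r$partition, collapse = ","),
                       character(1)),
    D = vapply(rps, function(r) r$D, integer(1)),
    k = vapply(rps, function(r) r$k, integer(1)),
    stringsAsFactors = FALSE)
}
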
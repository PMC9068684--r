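# Brute-force Markov oracle. The regular representation of the model element
# on the cloud basis is a K x K column-stochastic transition matrix built by
# direct coset counting; its matrix powers give path probabilities and a
# truncated Poisson sum gives likelihoods, independently of all
# representation-theoretic machinery.

#' Cloud basis of the genome algebra
#'
#' Canonical representatives of all `K = N!/|Z|` genome clouds, the reference
#' cloud `[e]` first and the rest in lexicographic order, plus an index lookup
#' for every permutation of S_N.
#'
#' @param N degree (resource guard N <= 8).
#' @param Z a `symm_subgroup`.
#' @return list with `reps` (list of K canonical permutations), `keys`,
#'   and `index` (environment mapping any permutation key to its cloud index).
#' @export
cloud_basis <- function(N, Z) {
  if (N > 8) stop("cloud_basis: resource guard, N <= 8")
  perms <- all_permutations(N)
  canon <- new.env(parent = emptyenv())
  reps <- list()
  keys <- character(0)
  for (p in perms) {
    cp <- coset_canonical(p, Z)
    ck <- perm_key(cp)
    if (!exists(ck, canon, inherits = FALSE)) {
      assign(ck, NA_integer_, canon)
      reps[[length(reps) + 1L]] <- cp
      keys <- c(keys, ck)
    }
  }
  K <- cloud_count(N, Z)
  stopifnot(length(reps) == K)
  ident_key <- perm_key(coset_canonical(perm_identity(N), Z))
  ord <- c(which(keys == ident_key), setdiff(order(keys), which(keys == ident_key)))
  reps <- reps[ord]
  keys <- keys[ord]
  index <- new.env(parent = emptyenv())
  for (i in seq_len(K)) assign(keys[i], i, index)
  for (p in perms) {
    k <- perm_key(p)
    if (!exists(k, index, inherits = FALSE))
      assign(k, get(perm_key(coset_canonical(p, Z)), index), index)
  }
  list(N = N, Z = Z, reps = reps, keys = keys, index = index)
}

#' Cloud-level Markov transition matrix
#'
#' The regular representation of `z s` on the cloud basis, assembled as the
#' weighted sum over model permutations `a` of the matrices of the clouds
#' `z a`, each built by direct coset counting:
#' entry (i, j) of `rho_reg^A(z a)` is `(1/|Z|) |{d in Z : a d sigma_j in [sigma_i]}|`.
#'
#' @param ms a `model_spec` (N <= 8).
#' @param cb optional precomputed `cloud_basis`.
#' @return object of class `cloud_markov`: list with `basis` and the K x K
#'   column-stochastic `matrix` (symmetric iff the model satisfies M2).
#' @export
cloud_markov_matrix <- function(ms, cb = NULL) {
  K <- cloud_count(ms$N, ms$Z)
  if (ms$N > 8) stop(sprintf("cloud_markov_matrix: resource guard (K = %d)", K))
  if (is.null(cb)) cb <- cloud_basis(ms$N, ms$Z)
  M <- matrix(0, K, K)
  zsize <- ms$Z$size
  for (t in ms$expanded) {
    a <- t$perm
    w <- t$num / t$den
    Pa <- matrix(0, K, K)
    for (j in seq_len(K)) {
      sj <- cb$reps[[j]]
      for (d in ms$Z$elements) {
        tau <- compose(a, compose(d, sj))
        i <- get(perm_key(tau), cb$index)
        Pa[i, j] <- Pa[i, j] + 1 / zsize
      }
    }
    M <- M + w * Pa
  }
  structure(list(basis = cb, matrix = M), class = "cloud_markov")
}

#' @export
print.cloud_markov <- function(x, ...) {
  cat(sprintf("<cloud Markov matrix: %d genome clouds>\n", nrow(x$matrix)))
  invisible(x)
}

#' Oracle path probability by matrix power readout
#'
#' The (cloud(sigma), reference) entry of the k-th power of the cloud Markov
#' matrix.
#'
#' @param cm a `cloud_markov`.
#' @param sigma target genome.
#' @param k nonnegative integer(s).
#' @return numeric vector of path probabilities.
#' @export
oracle_path_probability <- function(cm, sigma, k) {
  i <- get(perm_key(coset_canonical(as_perm(sigma), cm$basis$Z)),
           cm$basis$index)
  kmax <- max(k)
  K <- nrow(cm$matrix)
  col <- c(1, rep(0, K - 1))   # reference cloud is index 1
  out <- numeric(length(k))
  out[k == 0] <- as.numeric(i == 1L)
  for (step in seq_len(kmax)) {
    col <- cm$matrix %*% col
    out[k == step] <- col[i]
  }
  out
}

#' Oracle likelihood by truncated Poisson series
#'
#' `sum_k alpha_k e^{-T} T^k / k!`, truncated where the Poisson(T) tail falls
#' below 1e-12 (path probabilities are bounded by 1, so the truncation error
#' is below the tail mass).
#'
#' @param cm a `cloud_markov`.
#' @param sigma target genome.
#' @param T nonnegative time(s).
#' @return numeric vector of likelihoods.
#' @export
oracle_likelihood <- function(cm, sigma, T) {
  if (any(T < 0)) stop("T must be nonnegative")
  kmax <- max(10, stats::qpois(1e-12, max(T), lower.tail = FALSE) + 10)
  alphas <- oracle_path_probability(cm, sigma, 0:kmax)
  vapply(T, function(tt)
    sum(alphas * stats::dpois(0:kmax, tt)), numeric(1))
}

#' Full-group Markov transition matrix on all N! permutations
#'
#' Entry (i, j) is `w(sigma_i sigma_j^{-1})` when that quotient lies in the
#' expanded model and 0 otherwise; each column holds exactly |M| non-zero
#' entries. Doubly stochastic iff the model is reversible.
#'
#' @param ms a `model_spec` with N <= 5 (cost guard).
#' @return list with `perms` (lexicographic, identity first) and the
#'   `N! x N!` column-stochastic `matrix`.
#' @export
full_group_markov_matrix <- function(ms) {
  if (ms$N > 5) stop("full_group_markov_matrix: resource guard, N <= 5")
  perms <- all_permutations(ms$N)
  n <- length(perms)
  keys <- vapply(perms, perm_key, character(1))
  idx <- stats::setNames(seq_len(n), keys)
  M <- matrix(0, n, n)
  for (t in ms$expanded) {
    w <- t$num / t$den
    for (j in seq_len(n)) {
      i <- idx[[perm_key(compose(t$perm, perms[[j]]))]]
      M[i, j] <- M[i, j] + w
    }
  }
  list(perms = perms, matrix = M)
}

#' Exhaustive permutation path probabilities (tiny-n oracle)
#'
#' `beta_k(sigma)`: total weight of all k-length model sequences composing to
#' `sigma`, by direct enumeration of all |M|^k sequences. Only for oracle
#' duty at desk scale.
#'
#' @param ms a `model_spec`.
#' @param sigma target permutation.
#' @param k path length with `|M|^k <= 2e5`.
#' @return numeric probability.
#' @export
enumerate_beta <- function(ms, sigma, k) {
  m <- length(ms$expanded)
  if (m^k > 2e5) stop("enumerate_beta: too many sequences")
  sigma <- as_perm(sigma)
  target <- perm_key(sigma)
  total <- 0
  rec <- function(cur, depth, wt) {
    if (depth == k) {
      if (perm_key(cur) == target) total <<- total + wt
      return(invisible())
    }
    for (t in ms$expanded)
      rec(compose(t$perm, cur), depth + 1L, wt * t$num / t$den)
  }
  rec(perm_identity(ms$N), 0L, 1)
  total
}
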
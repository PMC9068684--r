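# Symmetry subgroups of S_N: explicit element lists, built by closure.
# Sizes in play are tiny (|D_N| = 2N, |S_N| <= 8! under resource guards),
# so a hash-set BFS closure is the right tool.

new_symm_subgroup <- function(degree, generators, elements) {
  keys <- vapply(elements, perm_key, character(1))
  ord <- order(keys)
  elements <- elements[ord]
  keys <- keys[ord]
  structure(
    list(degree = degree, generators = generators,
         elements = elements, keys = keys, size = length(elements)),
    class = "symm_subgroup")
}

#' @export
print.symm_subgroup <- function(x, ...) {
  cat(sprintf("<symmetry subgroup of S_%d, order %d, %d generator(s)>\n",
              x$degree, x$size, length(x$generators)))
  invisible(x)
}

#' Closure of a generating set
#'
#' Builds the subgroup of S_N generated by `generators` as an explicit element
#' list (breadth-first closure). The empty generating set yields the trivial
#' subgroup \{e\}.
#'
#' @param N degree.
#' @param generators list of permutations of degree N.
#' @return a `symm_subgroup` object with fields `degree`, `generators`,
#'   `elements` (sorted lexicographically), `keys`, `size`.
#' @export
subgroup_closure <- function(N, generators = list()) {
  gens <- lapply(generators, function(g) {
    g <- as_perm(g)
    if (length(g) != N) stop("generator degree mismatch")
    g
  })
  seen <- new.env(parent = emptyenv())
  id <- perm_identity(N)
  assign(perm_key(id), TRUE, envir = seen)
  elements <- list(id)
  frontier <- list(id)
  while (length(frontier) > 0L) {
    nxt <- list()
    for (x in frontier) {
      for (g in gens) {
        y <- compose(g, x)
        k <- perm_key(y)
        if (!exists(k, envir = seen, inherits = FALSE)) {
          assign(k, TRUE, envir = seen)
          elements[[length(elements) + 1L]] <- y
          nxt[[length(nxt) + 1L]] <- y
        }
      }
    }
    frontier <- nxt
  }
  new_symm_subgroup(N, gens, elements)
}

#' Dihedral symmetry group of a circular genome
#'
#' The 2N rotations and reflections of N positions on a circle, generated by
#' the rotation `(1 2 ... N)` and the reflection `i -> N+1-i`.
#'
#' @param N number of regions, at least 3.
#' @return a `symm_subgroup` of order 2N.
#' @export
dihedral_group <- function(N) {
  if (N < 3) stop("dihedral_group requires N >= 3")
  r <- c(seq_len(N)[-1], 1L)          # rotation: i -> i+1 (mod N)
  f <- rev(seq_len(N))                # reflection: i -> N+1-i
  Z <- subgroup_closure(N, list(r, f))
  stopifnot(Z$size == 2L * N)
  Z
}

#' Membership test in a symmetry subgroup
#' @param sigma permutation.
#' @param Z a `symm_subgroup`.
#' @return logical.
#' @export
subgroup_contains <- function(Z, sigma) {
  perm_key(as_perm(sigma)) %in% Z$keys
}

#' Canonical representative of a right coset (genome cloud)
#'
#' All permutations `z * sigma`, z in Z, represent the same physical genome;
#' this returns the lexicographically smallest one-line form among them, a
#' deterministic label for the cloud.
#'
#' @param sigma permutation.
#' @param Z a `symm_subgroup` of matching degree.
#' @return permutation; constant on the coset `Z sigma`.
#' @export
coset_canonical <- function(sigma, Z) {
  sigma <- as_perm(sigma)
  if (length(sigma) != Z$degree) stop("degree mismatch")
  best <- NULL
  for (z in Z$elements) {
    cand <- z[sigma]
    if (is.null(best) || lex_less(cand, best)) best <- cand
  }
  best
}

#' @keywords internal
lex_less <- function(a, b) {
  d <- a - b
  i <- which(d != 0L)
  length(i) > 0L && d[i[1]] < 0L
}

#' Canonical representative of a double coset
#'
#' Label for the class `Z sigma Z` (genomes with identical rearrangement
#' action / likelihood function): the lex-min of `coset_canonical(sigma z)`
#' over z in Z.
#'
#' @inheritParams coset_canonical
#' @return permutation; constant on the double coset.
#' @export
double_coset_canonical <- function(sigma, Z) {
  sigma <- as_perm(sigma)
  best <- NULL
  for (z in Z$elements) {
    cand <- coset_canonical(compose(sigma, z), Z)
    if (is.null(best) || lex_less(cand, best)) best <- cand
  }
  best
}

#' Test whether two permutations lie in the same double coset
#'
#' True iff `tau = z1 sigma z2` for some z1, z2 in Z, i.e. the two genomes
#' have the same action as rearrangement clouds (and identical likelihoods).
#'
#' @param sigma,tau permutations of the degree of `Z`.
#' @param Z a `symm_subgroup`.
#' @return logical.
#' @export
double_coset_equal <- function(sigma, tau, Z) {
  identical(double_coset_canonical(sigma, Z), double_coset_canonical(tau, Z))
}

#' Does a rearrangement set generate the full symmetric group?
#'
#' Computes the closure of `M` and compares its order to N!. Guarded to
#' N <= 8 (the closure is stored explicitly).
#'
#' @param M list of permutations of degree N.
#' @param N degree.
#' @return logical.
#' @export
generates_full_group <- function(M, N) {
  if (N > 8) stop("generates_full_group: resource guard, N <= 8 required")
  H <- subgroup_closure(N, M)
  H$size == factorial(N)
}

#' Enumerate all permutations of degree N
#'
#' @param N degree, guarded to N <= 8.
#' @return list of `N!` permutations in lexicographic order.
#' @export
all_permutations <- function(N) {
  if (N > 8) stop("all_permutations: resource guard, N <= 8 required")
  if (N == 1L) return(list(1L))
  sub <- all_permutations(N - 1L)
  out <- vector("list", factorial(N))
  idx <- 1L
  for (first in seq_len(N)) {
    rest <- setdiff(seq_len(N), first)
    for (q in sub) {
      out[[idx]] <- c(first, rest[q])
      idx <- idx + 1L
    }
  }
  out
}

#' Brute-force double-coset classes
#'
#' Partitions S_N into classes `Z sigma Z` by direct enumeration; used as the
#' independent oracle for the Burnside dimension count of the class algebra.
#'
#' @param N degree (N <= 6 recommended).
#' @param Z a `symm_subgroup`.
#' @return named integer vector: class canonical key -> class size.
#' @export
double_coset_classes <- function(N, Z) {
  if (N > 6) stop("double_coset_classes: resource guard, N <= 6")
  sizes <- new.env(parent = emptyenv())
  for (p in all_permutations(N)) {
    k <- perm_key(double_coset_canonical(p, Z))
    assign(k, (if (exists(k, sizes, inherits = FALSE)) get(k, sizes) else 0L) + 1L,
           envir = sizes)
  }
  keys <- ls(sizes)
  stats::setNames(vapply(keys, function(k) get(k, sizes), integer(1)), keys)
}
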
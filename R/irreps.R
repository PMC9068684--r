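# Irreducible representations of S_N in Young's orthogonal form (YOR).
# Matrices for the Coxeter generators (i, i+1) are built from axial distances
# over the standard Young tableaux of a shape; a general permutation is
# decomposed into adjacent transpositions by bubble sort. Everything is
# deterministic and cached, since the model assembly reuses the same handful
# of permutations per partition.

#' All partitions of N in reverse lexicographic order
#'
#' This fixed order indexes every per-partition array in the package
#' (dimensions, reduced-module sizes, spectral data).
#'
#' @param N positive integer.
#' @return list of integer vectors, weakly decreasing, summing to N;
#'   starts at `(N)` and ends at `(1,...,1)`.
#' @export
partitions <- function(N) {
  if (N < 1) stop("N must be >= 1")
  rec <- function(n, cap) {
    if (n == 0L) return(list(integer(0)))
    out <- list()
    for (m in seq.int(min(n, cap), 1L)) {
      for (tail in rec(n - m, m)) out[[length(out) + 1L]] <- c(m, tail)
    }
    out
  }
  rec(as.integer(N), as.integer(N))
}

#' @keywords internal
partition_key <- function(p) paste(p, collapse = ",")

#' Irreducible dimension by the hook-length formula
#'
#' @param p a partition (weakly decreasing positive integers).
#' @return integer: `n! / prod(hook lengths)`, the number of standard Young
#'   tableaux of shape `p`.
#' @export
hook_dimension <- function(p) {
  p <- as.integer(p)
  if (is.unsorted(rev(p)) || any(p < 1L)) stop("not a partition")
  n <- sum(p)
  conj <- vapply(seq_len(p[1]), function(j) sum(p >= j), integer(1))
  hooks <- numeric(0)
  for (r in seq_along(p)) for (cc in seq_len(p[r]))
    hooks <- c(hooks, (p[r] - cc) + (conj[cc] - r) + 1L)
  d <- factorial(n) / prod(hooks)
  stopifnot(abs(d - round(d)) < 1e-9)
  as.integer(round(d))
}

#' Standard Young tableaux of a shape
#'
#' Each tableau is encoded as the vector `rowof` with `rowof[v]` the row in
#' which value `v` sits (rows are filled left to right, so this determines the
#' tableau). The enumeration order is deterministic: values are placed in the
#' lowest feasible row first.
#'
#' @param p a partition of N.
#' @return list of integer vectors of length N.
#' @export
standard_tableaux <- function(p) {
  p <- as.integer(p)
  n <- sum(p)
  nr <- length(p)
  out <- list()
  rowof <- integer(n)
  fill <- integer(nr)
  place <- function(v) {
    if (v > n) { out[[length(out) + 1L]] <<- rowof; return(invisible()) }
    for (r in seq_len(nr)) {
      if (fill[r] < p[r] && (r == 1L || fill[r] < fill[r - 1L])) {
        fill[r] <<- fill[r] + 1L
        rowof[v] <<- r
        place(v + 1L)
        fill[r] <<- fill[r] - 1L
      }
    }
  }
  place(1L)
  out
}

# cache environments (populated lazily, bounded by explicit flushes)
.ga_cache <- new.env(parent = emptyenv())
.ga_cache$gen <- new.env(parent = emptyenv())
.ga_cache$mat <- new.env(parent = emptyenv())
.ga_cache$proj <- new.env(parent = emptyenv())
.ga_cache$mat_count <- 0L

#' Flush internal matrix caches
#' @return invisible NULL.
#' @export
clear_irrep_cache <- function() {
  .ga_cache$gen <- new.env(parent = emptyenv())
  .ga_cache$mat <- new.env(parent = emptyenv())
  .ga_cache$proj <- new.env(parent = emptyenv())
  .ga_cache$mat_count <- 0L
  invisible(NULL)
}

#' Young-orthogonal generator matrices for a partition
#'
#' @param p a partition of N.
#' @return list of N-1 orthogonal, symmetric involutions, the images of the
#'   adjacent transpositions (i, i+1) for i = 1..N-1.
#' @export
yor_generators <- function(p) {
  key <- partition_key(p)
  if (!is.null(.ga_cache$gen[[key]])) return(.ga_cache$gen[[key]])
  n <- sum(p)
  tabs <- standard_tableaux(p)
  d <- length(tabs)
  stopifnot(d == hook_dimension(p))
  tab_index <- new.env(parent = emptyenv())
  for (t in seq_len(d)) assign(paste(tabs[[t]], collapse = ","), t, tab_index)
  # content (= column - row) of each value in each tableau
  contents <- lapply(tabs, function(rowof) {
    fill <- integer(length(p))
    cont <- numeric(n)
    for (v in seq_len(n)) {
      r <- rowof[v]
      fill[r] <- fill[r] + 1L
      cont[v] <- fill[r] - r
    }
    cont
  })
  gens <- vector("list", max(n - 1L, 0L))
  for (i in seq_len(n - 1L)) {
    M <- matrix(0, d, d)
    for (t in seq_len(d)) {
      ax <- contents[[t]][i + 1L] - contents[[t]][i]   # axial distance
      M[t, t] <- 1 / ax
      if (abs(ax) >= 2) {
        swapped <- tabs[[t]]
        swapped[c(i, i + 1L)] <- swapped[c(i + 1L, i)]
        t2 <- get(paste(swapped, collapse = ","), tab_index)
        M[t, t2] <- sqrt(1 - 1 / ax^2)
      }
    }
    gens[[i]] <- M
  }
  .ga_cache$gen[[key]] <- gens
  gens
}

#' @keywords internal
adjacent_word <- function(sigma) {
  # bubble-sort decomposition: returns indices w_1..w_k such that
  # sigma o s_{w_1} o ... o s_{w_k} = e, hence sigma = s_{w_k} o ... o s_{w_1}
  x <- as_perm(sigma)
  word <- integer(0)
  repeat {
    j <- which(x[-length(x)] > x[-1])
    if (length(j) == 0L) break
    j <- j[1]
    x[c(j, j + 1L)] <- x[c(j + 1L, j)]
    word <- c(word, j)
  }
  word
}

#' Irreducible representation matrix of a permutation
#'
#' Young's orthogonal form: real, orthogonal, and a homomorphism under the
#' package composition convention. Results are cached per
#' (partition, permutation).
#'
#' @param p a partition of N.
#' @param sigma a permutation of degree N.
#' @return a `D_p x D_p` orthogonal matrix.
#' @export
irrep_matrix <- function(p, sigma) {
  sigma <- as_perm(sigma)
  if (length(sigma) != sum(p)) stop("degree mismatch: |sigma| != sum(p)")
  key <- paste0(partition_key(p), "|", perm_key(sigma))
  hit <- .ga_cache$mat[[key]]
  if (!is.null(hit)) return(hit)
  gens <- yor_generators(p)
  d <- hook_dimension(p)
  M <- diag(1, d)
  for (w in adjacent_word(sigma)) M <- gens[[w]] %*% M
  if (.ga_cache$mat_count > 50000L) clear_irrep_cache()
  .ga_cache$mat[[key]] <- M
  .ga_cache$mat_count <- .ga_cache$mat_count + 1L
  M
}

#' Representation matrix of an algebra element
#'
#' Linear extension of the irreducible representation to the group algebra:
#' the coefficient-weighted sum of the matrices of the support permutations.
#'
#' @param p a partition of N.
#' @param tau an `algelem` of degree N.
#' @return a `D_p x D_p` numeric matrix.
#' @export
algebra_rep <- function(p, tau) {
  if (!inherits(tau, "algelem")) stop("tau must be an algelem")
  if (sum(p) != tau$degree) stop("degree mismatch")
  d <- hook_dimension(p)
  M <- matrix(0, d, d)
  for (i in seq_along(tau$perms))
    M <- M + (tau$num[i] / tau$den[i]) * irrep_matrix(p, tau$perms[[i]])
  M
}

#' Irreducible character of a permutation
#' @param p partition.
#' @param sigma permutation.
#' @return trace of the YOR matrix.
#' @export
sn_character <- function(p, sigma) sum(diag(irrep_matrix(p, sigma)))
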
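# Sparse elements of the group algebra R[S_N] with exact rational
# coefficients. Coefficients are stored as reduced numerator/denominator
# pairs in doubles; all counting identities of the framework (idempotency of
# the symmetry element, commutation with the model element, the regular
# character case split) involve only small fractions, so exact arithmetic is
# both feasible and the honest way to test them. Numerators/denominators are
# guarded against leaving the exactly-representable integer range.

.rat_gcd <- function(a, b) {
  a <- abs(a); b <- abs(b)
  while (b > 0) { t <- a %% b; a <- b; b <- t }
  a
}

.rat_check <- function(x) {
  if (any(abs(x) >= 2^53)) stop("rational overflow: coefficient outside exact integer range")
  x
}

#' @keywords internal
rat_reduce <- function(num, den) {
  if (den == 0) stop("zero denominator")
  if (num == 0) return(c(0, 1))
  g <- .rat_gcd(num, den)
  s <- if (den < 0) -1 else 1
  c(.rat_check(s * num / g), .rat_check(s * den / g))
}

#' @keywords internal
rat_add <- function(a, b) rat_reduce(a[1] * b[2] + b[1] * a[2], a[2] * b[2])

#' @keywords internal
rat_mul <- function(a, b) rat_reduce(a[1] * b[1], a[2] * b[2])

#' Parse a rational number
#'
#' Accepts a fraction string (`"2/3"`), an integer-like string, or a numeric.
#' Numerics are converted by continued fractions with denominator bound 1e6;
#' exact model weights should be passed as strings or integer ratios.
#'
#' @param x numeric or character scalar.
#' @return length-2 vector `c(numerator, denominator)`, reduced.
#' @export
as_rational <- function(x) {
  if (is.character(x)) {
    x <- trimws(x)
    if (grepl("/", x)) {
      parts <- as.numeric(strsplit(x, "/")[[1]])
      if (length(parts) != 2 || anyNA(parts)) stop("bad fraction: ", x)
      return(rat_reduce(parts[1], parts[2]))
    }
    x <- as.numeric(x)
  }
  if (!is.finite(x)) stop("weight must be finite")
  if (x == round(x)) return(rat_reduce(round(x), 1))
  # continued-fraction approximation, exact for any double that is a ratio
  # of small integers (model weights in practice)
  num0 <- 0; den0 <- 1; num1 <- 1; den1 <- 0
  y <- x
  for (i in 1:40) {
    a <- floor(y)
    num2 <- a * num1 + num0; den2 <- a * den1 + den0
    num0 <- num1; den0 <- den1; num1 <- num2; den1 <- den2
    if (den1 > 1e6 || abs(num1 / den1 - x) < 1e-14) break
    frac <- y - a
    if (frac < 1e-15) break
    y <- 1 / frac
  }
  rat_reduce(num1, den1)
}

# --- algebra elements -------------------------------------------------------

new_algelem <- function(degree, perms, num, den) {
  keep <- num != 0
  perms <- perms[keep]; num <- num[keep]; den <- den[keep]
  keys <- vapply(perms, perm_key, character(1))
  ord <- order(keys)
  structure(list(degree = degree, perms = perms[ord], keys = keys[ord],
                 num = num[ord], den = den[ord]),
            class = "algelem")
}

#' Construct a group-algebra element
#'
#' A sparse formal linear combination of permutations with exact rational
#' coefficients.
#'
#' @param degree degree N.
#' @param perms list of permutations of degree N.
#' @param num,den numerators and denominators (recycled) of the coefficients.
#' @return an object of class `algelem`.
#' @export
alg_elem <- function(degree, perms, num = 1, den = 1) {
  perms <- lapply(perms, function(p) {
    p <- as_perm(p)
    if (length(p) != degree) stop("term degree mismatch")
    p
  })
  n <- length(perms)
  num <- rep_len(num, n); den <- rep_len(den, n)
  acc <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  for (i in seq_len(n)) {
    k <- perm_key(perms[[i]])
    r <- rat_reduce(num[i], den[i])
    if (exists(k, acc, inherits = FALSE)) r <- rat_add(get(k, acc), r)
    assign(k, r, acc); assign(k, perms[[i]], store)
  }
  keys <- ls(acc)
  rs <- lapply(keys, function(k) get(k, acc))
  new_algelem(degree,
              lapply(keys, function(k) get(k, store)),
              vapply(rs, `[`, numeric(1), 1),
              vapply(rs, `[`, numeric(1), 2))
}

#' @export
print.algelem <- function(x, ...) {
  n <- length(x$perms)
  cat(sprintf("<group-algebra element, S_%d, %d term(s)>\n", x$degree, n))
  show <- seq_len(min(n, 8L))
  for (i in show)
    cat(sprintf("  %s/%s * %s\n", format(x$num[i]), format(x$den[i]),
                format_perm(x$perms[[i]])))
  if (n > 8L) cat("  ...\n")
  invisible(x)
}

#' Sum of two algebra elements
#' @param x,y `algelem` objects of equal degree.
#' @return `algelem`.
#' @export
alg_add <- function(x, y) {
  stopifnot(x$degree == y$degree)
  alg_elem(x$degree, c(x$perms, y$perms), c(x$num, y$num), c(x$den, y$den))
}

#' Scale an algebra element by an exact rational
#' @param x `algelem`.
#' @param num,den rational scalar numerator/denominator.
#' @return `algelem`.
#' @export
alg_scale <- function(x, num, den = 1) {
  if (num == 0) return(new_algelem(x$degree, list(), numeric(0), numeric(0)))
  n <- length(x$perms)
  nn <- numeric(n); dd <- numeric(n)
  for (i in seq_len(n)) {
    r <- rat_mul(c(x$num[i], x$den[i]), rat_reduce(num, den))
    nn[i] <- r[1]; dd[i] <- r[2]
  }
  new_algelem(x$degree, x$perms, nn, dd)
}

#' Bilinear product of two algebra elements
#'
#' Induced by group multiplication under the package's composition convention.
#'
#' @param x,y `algelem` objects of equal degree.
#' @return `algelem`; coefficient sums multiply (probability is conserved).
#' @export
alg_mul <- function(x, y) {
  stopifnot(x$degree == y$degree)
  acc <- new.env(parent = emptyenv())
  store <- new.env(parent = emptyenv())
  for (i in seq_along(x$perms)) {
    ci <- c(x$num[i], x$den[i])
    for (j in seq_along(y$perms)) {
      p <- compose(x$perms[[i]], y$perms[[j]])
      k <- perm_key(p)
      r <- rat_mul(ci, c(y$num[j], y$den[j]))
      if (exists(k, acc, inherits = FALSE)) r <- rat_add(get(k, acc), r)
      assign(k, r, acc); assign(k, p, store)
    }
  }
  keys <- ls(acc)
  rs <- lapply(keys, function(k) get(k, acc))
  new_algelem(x$degree,
              lapply(keys, function(k) get(k, store)),
              vapply(rs, `[`, numeric(1), 1),
              vapply(rs, `[`, numeric(1), 2))
}

#' Integer power of an algebra element
#' @param x `algelem`.
#' @param k nonnegative integer.
#' @return `algelem`; `k = 0` gives the identity element.
#' @export
alg_pow <- function(x, k) {
  out <- alg_elem(x$degree, list(perm_identity(x$degree)))
  for (i in seq_len(k)) out <- alg_mul(out, x)
  out
}

#' Exact coefficient sum of an algebra element
#' @param x `algelem`.
#' @return rational `c(num, den)`.
#' @export
alg_coeff_sum <- function(x) {
  r <- c(0, 1)
  for (i in seq_along(x$num)) r <- rat_add(r, c(x$num[i], x$den[i]))
  r
}

#' Exact coefficient of a permutation in an algebra element
#' @param x `algelem`.
#' @param p permutation.
#' @return rational `c(num, den)` (0/1 if absent).
#' @export
alg_coeff <- function(x, p) {
  i <- match(perm_key(as_perm(p)), x$keys)
  if (is.na(i)) c(0, 1) else c(x$num[i], x$den[i])
}

#' Exact equality of algebra elements
#' @param x,y `algelem` objects.
#' @return logical; TRUE iff all coefficients agree exactly.
#' @export
alg_equal <- function(x, y) {
  x$degree == y$degree && identical(x$keys, y$keys) &&
    identical(x$num, y$num) && identical(x$den, y$den)
}

#' Numeric coefficients of an algebra element
#' @param x `algelem`.
#' @return data.frame with columns `key`, `num`, `den`, `coeff`.
#' @export
alg_terms <- function(x) {
  data.frame(key = x$keys, num = x$num, den = x$den,
             coeff = x$num / x$den, stringsAsFactors = FALSE)
}

#' The symmetry element z of a subgroup
#'
#' The normalized sum `(1/|Z|) sum_{z in Z} z`: an exact idempotent that
#' projects the group algebra onto the genome algebra `z R[S_N]`, where it
#' acts as a left identity. A permutation cloud is `z * sigma`.
#'
#' @param Z a `symm_subgroup`.
#' @return `algelem` with coefficient 1/|Z| on every element of Z.
#' @export
symmetry_element <- function(Z) {
  alg_elem(Z$degree, Z$elements, num = 1, den = Z$size)
}

#' A permutation cloud as an algebra element
#' @param sigma permutation.
#' @param Z a `symm_subgroup`.
#' @return `algelem` equal to `z * sigma`.
#' @export
cloud_element <- function(sigma, Z) {
  sigma <- as_perm(sigma)
  alg_elem(Z$degree, lapply(Z$elements, function(z) compose(z, sigma)),
           num = 1, den = Z$size)
}
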
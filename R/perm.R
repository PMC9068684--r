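# Permutations are plain integer vectors in one-line notation: p[i] = j means
# region i sits in position j. Regions/positions are 1-based. Rearrangements
# act on genomes by LEFT multiplication: genome sigma becomes compose(a, sigma).

#' Identity permutation
#'
#' @param N number of regions (degree).
#' @return integer vector `1:N`.
#' @export
perm_identity <- function(N) seq_len(N)

#' Validate and coerce a permutation
#'
#' @param x integer-like vector; must be a bijection of `1..length(x)`.
#' @return integer vector in one-line notation.
#' @export
as_perm <- function(x) {
  p <- as.integer(x)
  N <- length(p)
  if (N < 1L || anyNA(p) || length(unique(p)) != N || min(p) != 1L || max(p) != N)
    stop("not a permutation of 1..", N)
  p
}

#' Compose two permutations
#'
#' Convention: `compose(p, q)(i) = p(q(i))`, so a rearrangement `a` applied to
#' a genome `sigma` is `compose(a, sigma)`.
#'
#' @param p,q permutations of equal degree.
#' @return the composite permutation.
#' @export
compose <- function(p, q) {
  if (length(p) != length(q)) stop("degree mismatch in compose()")
  p[q]
}

#' Invert a permutation
#' @param p permutation.
#' @return the inverse permutation.
#' @export
perm_inverse <- function(p) {
  r <- integer(length(p))
  r[p] <- seq_along(p)
  r
}

#' @keywords internal
perm_key <- function(p) paste(p, collapse = " ")

#' Cycle decomposition of a permutation
#' @param p permutation.
#' @return list of integer vectors, one per nontrivial cycle, each starting at
#'   its smallest element; empty list for the identity.
#' @export
perm_cycles <- function(p) {
  N <- length(p)
  seen <- logical(N)
  out <- list()
  for (i in seq_len(N)) {
    if (seen[i] || p[i] == i) { seen[i] <- TRUE; next }
    cyc <- i
    j <- p[i]
    seen[i] <- TRUE
    while (j != i) {
      cyc <- c(cyc, j)
      seen[j] <- TRUE
      j <- p[j]
    }
    out[[length(out) + 1L]] <- cyc
  }
  out
}

#' Format a permutation as text
#'
#' @param p permutation.
#' @param style `"cycle"` (default) or `"oneline"`.
#' @return character scalar; the identity prints as `"e"` in cycle style.
#' @export
format_perm <- function(p, style = c("cycle", "oneline")) {
  style <- match.arg(style)
  if (style == "oneline") return(paste(p, collapse = " "))
  cyc <- perm_cycles(p)
  if (length(cyc) == 0L) return("e")
  paste(vapply(cyc, function(v) paste0("(", paste(v, collapse = " "), ")"),
               character(1)), collapse = "")
}

#' Parse a permutation from text
#'
#' Accepts one-line notation (`"2 1 3 4"`) and cycle notation
#' (`"(1 2)(3 4)"`, commas allowed); `"e"` or `"()"` denote the identity.
#'
#' @param text character scalar.
#' @param N degree; required for cycle notation unless it can be inferred
#'   (it is taken as the largest symbol mentioned when omitted).
#' @return integer permutation.
#' @export
parse_perm <- function(text, N = NULL) {
  text <- trimws(text)
  if (text %in% c("e", "()", "(1)")) {
    if (is.null(N)) stop("degree N required to parse the identity")
    return(perm_identity(N))
  }
  if (grepl("\\(", text)) {
    chunks <- regmatches(text, gregexpr("\\(([^()]*)\\)", text))[[1]]
    cyc <- lapply(chunks, function(ch) {
      v <- as.integer(strsplit(gsub("[(),]", " ", ch), "\\s+")[[1]])
      v[!is.na(v)]
    })
    top <- max(unlist(cyc))
    if (is.null(N)) N <- top
    if (top > N) stop("cycle entry exceeds degree N")
    p <- perm_identity(N)
    # rightmost cycle acts first, matching function composition
    for (v in rev(cyc)) {
      if (anyDuplicated(v)) stop("repeated symbol within a cycle")
      q <- perm_identity(N)
      q[v] <- c(v[-1], v[1])
      p <- compose(p, q)
    }
    return(as_perm(p))
  }
  v <- as.integer(strsplit(gsub(",", " ", text), "\\s+")[[1]])
  v <- v[!is.na(v)]
  if (!is.null(N) && length(v) != N) stop("one-line form has wrong degree")
  as_perm(v)
}

#' Cycle type of a permutation
#' @param p permutation.
#' @return integer vector of cycle lengths (including fixed points), sorted
#'   decreasingly; this is a partition of the degree.
#' @export
cycle_type <- function(p) {
  lens <- vapply(perm_cycles(p), length, integer(1))
  nfix <- length(p) - sum(lens)
  sort(c(lens, rep(1L, nfix)), decreasing = TRUE)
}

#' Centralizer size of a permutation in the symmetric group
#' @param p permutation.
#' @return `prod(j^m_j * m_j!)` over cycle lengths j with multiplicity m_j.
#' @export
centralizer_size <- function(p) {
  ct <- cycle_type(p)
  tab <- table(ct)
  prod(as.numeric(names(tab))^as.numeric(tab) * factorial(as.numeric(tab)))
}
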
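# Deterministic fixture models and sample genomes for tests and demos.

#' Fixture rearrangement models
#'
#' Two stock circular-genome models with dihedral symmetry:
#' \describe{
#'   \item{`adjacent-swaps`}{inversions of two adjacent regions, the N
#'     position swaps `(i, i+1)` (indices mod N), uniform weights.}
#'   \item{`small-inversions`}{inversions of two or three consecutive regions,
#'     realized as the transposition types `(1 2)` (weight 2/3) and `(1 3)`
#'     (weight 1/3) with their dihedral orbits — the shorter inversion twice
#'     as likely. At N = 5 the two types are complementary rearrangements
#'     with identical cloud action; the fixture then builds the deduplicated
#'     one-type model with the merged weight and logs the merge.}
#' }
#' Sample genomes are drawn uniformly over clouds (uniform random permutation,
#' then canonicalized), fully determined by `seed`.
#'
#' @param kind `"adjacent-swaps"` or `"small-inversions"`.
#' @param N number of regions (>= 4 for small-inversions).
#' @param seed integer seed for the sample genomes.
#' @param n_genomes how many sample genomes to draw.
#' @return list with `model` (a `model_spec`), `genomes` (list of canonical
#'   permutations), and `note` (character, e.g. the dedup message).
#' @export
fixture_model <- function(kind = c("adjacent-swaps", "small-inversions"),
                          N, seed = 1L, n_genomes = 5L) {
  kind <- match.arg(kind)
  Z <- dihedral_group(N)
  note <- character(0)
  if (kind == "adjacent-swaps") {
    model <- build_model(N, Z, list(list(perm = "(1 2)", weight = 1)))
  } else {
    if (N < 4) stop("small-inversions requires N >= 4")
    base <- list(list(perm = "(1 2)", weight = "2/3"),
                 list(perm = "(1 3)", weight = "1/3"))
    model <- tryCatch(build_model(N, Z, base), error = function(e) {
      if (!grepl("duplicate cloud action", conditionMessage(e))) stop(e)
      note <<- paste("duplicate cloud action at N =", N,
                     "- merged (1 3) into (1 2) with combined weight 1")
      message(note)
      build_model(N, Z, list(list(perm = "(1 2)", weight = 1)))
    })
  }
  set.seed(as.integer(seed))
  genomes <- lapply(seq_len(n_genomes), function(i)
    coset_canonical(sample(N), Z))
  list(model = model, genomes = genomes, note = note)
}
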
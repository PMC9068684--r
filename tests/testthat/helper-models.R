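# Shared fixtures; everything is generated in code with fixed seeds.

adjacent_swap_model <- local({
  cache <- list()
  function(N) {
    key <- as.character(N)
    if (is.null(cache[[key]]))
      cache[[key]] <<- fixture_model("adjacent-swaps", N, seed = 1)$model
    cache[[key]]
  }
})

small_inversion_model <- local({
  cache <- list()
  function(N) {
    key <- as.character(N)
    if (is.null(cache[[key]]))
      cache[[key]] <<- suppressMessages(
        fixture_model("small-inversions", N, seed = 1))$model
    cache[[key]]
  }
})

# trivial symmetry with a single oriented 3-cycle: M1 holds vacuously, M2
# fails, and the cloud chain IS the permutation-level chain, so its matrix is
# genuinely asymmetric. (With rotation-only symmetry the inverse 3-cycle lands
# in the same double coset and the cloud chain is reversible anyway.)
nonreversible_model <- function(N = 4) {
  Z <- subgroup_closure(N, list())
  suppressWarnings(
    build_model(N, Z, list(list(perm = "(1 2 3)", weight = 1)),
                enforce_reversibility = FALSE))
}

expect_rational_equal <- function(x, num, den = 1) {
  expect_identical(x, genomealg:::rat_reduce(num, den))
}
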
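# Model construction: symmetry closure, reversibility, weights, hazards.

test_that("adjacent-swap orbit expands to the N position swaps, weight 1/N", {
  ms <- adjacent_swap_model(6)
  expect_equal(length(ms$expanded), 6)
  keys <- sort(vapply(ms$expanded, function(t) format_perm(t$perm), character(1)))
  expect_identical(keys, sort(c("(1 2)", "(2 3)", "(3 4)", "(4 5)", "(5 6)",
                                "(1 6)")))
  for (t in ms$expanded) expect_rational_equal(c(t$num, t$den), 1, 6)
  expect_true(ms$generates)
  expect_false(ms$trivial)
})

test_that("two-type small-inversion model reproduces the published weights", {
  ms <- small_inversion_model(6)
  expect_equal(length(ms$base), 2)
  expect_equal(length(ms$expanded), 12)   # two orbits of N = 6 each
  # per-instance weights 2/(3N) and 1/(3N); per-type cloud weights 2/3, 1/3
  expect_rational_equal(ms$base[[1]]$instance_weight, 2, 18)
  expect_rational_equal(ms$base[[2]]$instance_weight, 1, 18)
  expect_rational_equal(ms$base[[1]]$cloud_weight, 2, 3)
  expect_rational_equal(ms$base[[2]]$cloud_weight, 1, 3)
})

test_that("duplicate cloud action raises; fixture deduplicates with a log", {
  Z5 <- dihedral_group(5)
  expect_error(
    build_model(5, Z5, list(list(perm = "(1 2)", weight = "2/3"),
                            list(perm = "(1 3)", weight = "1/3"))),
    "duplicate cloud action")
  expect_message(fx <- fixture_model("small-inversions", 5, seed = 2),
                 "merged")
  expect_equal(length(fx$model$base), 1)
  expect_rational_equal(fx$model$base[[1]]$cloud_weight, 1, 1)
  # the hazard itself: z(1 2)z = z(1 3)z exactly at N = 5
  z <- symmetry_element(Z5)
  lhs <- alg_mul(alg_mul(z, alg_elem(5, list(parse_perm("(1 2)", 5)))), z)
  rhs <- alg_mul(alg_mul(z, alg_elem(5, list(parse_perm("(1 3)", 5)))), z)
  expect_true(alg_equal(lhs, rhs))
  # ... but not at N = 6
  Z6 <- dihedral_group(6)
  z6 <- symmetry_element(Z6)
  lhs6 <- alg_mul(alg_mul(z6, alg_elem(6, list(parse_perm("(1 2)", 6)))), z6)
  rhs6 <- alg_mul(alg_mul(z6, alg_elem(6, list(parse_perm("(1 3)", 6)))), z6)
  expect_false(alg_equal(lhs6, rhs6))
})

test_that("degenerate and invalid bases are handled explicitly", {
  Z <- dihedral_group(5)
  # two warnings: identity action, and the lazy model does not generate S_N
  expect_warning(
    expect_warning(ms <- build_model(5, Z, list(list(perm = "e", weight = 1))),
                   "symmetry subgroup"),
    "does not generate")
  expect_true(ms$trivial)
  expect_equal(vapply(ms$expanded, function(t) format_perm(t$perm),
                      character(1)), "e")
  expect_error(build_model(5, Z, list(list(perm = "(1 2)", weight = 0))),
               "weight")
  expect_error(build_model(5, Z, list()), "empty")
  # non-generating model warns
  Zr <- subgroup_closure(4, list())
  expect_warning(build_model(4, Zr, list(list(perm = "(1 2)(3 4)", weight = 1))),
                 "does not generate")
})

test_that("model element: coefficient sum 1, commutes with z, cloud form acts equally", {
  for (N in 5:6) {
    ms <- small_inversion_model(N)
    z <- symmetry_element(ms$Z)
    me <- model_element(ms)
    expect_rational_equal(alg_coeff_sum(me$s), 1, 1)
    expect_true(alg_equal(alg_mul(z, me$s), alg_mul(me$s, z)))   # M1, exact
    # s_tilde differs from z*s as an element but acts identically:
    expect_true(alg_equal(alg_mul(alg_mul(z, me$s), z),
                          alg_mul(me$s_tilde, z)))
    # M2 exactly: the inverse of every instance carries the same weight
    for (t in ms$expanded)
      expect_identical(alg_coeff(me$s, perm_inverse(t$perm)), c(t$num, t$den))
  }
})

test_that("reduced model matrices are symmetric with spectrum inside [-1,1]", {
  ms <- adjacent_swap_model(6)
  rps <- reduced_irreps(6, ms$Z)
  mats <- reduced_model_matrices(ms, rps)
  me <- model_element(ms)
  top <- -Inf
  for (i in seq_along(rps)) {
    if (rps[[i]]$k == 0) { expect_null(mats[[i]]); next }
    M <- mats[[i]]
    expect_lt(max(abs(M - t(M))), 1e-10)
    ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
    expect_true(all(ev >= -1 - 1e-9 & ev <= 1 + 1e-9))
    top <- max(top, ev)
    # eigenvalues are a subset of the full rho_p(s) spectrum
    full <- eigen(algebra_rep(rps[[i]]$partition, me$s), symmetric = TRUE,
                  only.values = TRUE)$values
    for (l in ev) expect_lt(min(abs(full - l)), 1e-9)
  }
  expect_equal(top, 1, tolerance = 1e-12)   # attained in the trivial partition
  expect_equal(mats[[1]], matrix(1, 1, 1), tolerance = 1e-12)
  # a non-reversible model is rejected with advice
  msn <- nonreversible_model(4)
  expect_error(reduced_model_matrices(msn, reduced_irreps(4, msn$Z)),
               "reversib")
})
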
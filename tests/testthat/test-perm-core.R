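# Permutations, subgroups, cosets and the sparse group algebra.

test_that("composition, inverse and parsing behave as a group action", {
  N <- 6
  e <- perm_identity(N)
  r <- c(2:N, 1L)
  s12 <- parse_perm("(1 2)", N)
  expect_identical(compose(e, r), r)
  expect_identical(compose(r, perm_inverse(r)), e)
  # conjugating the adjacent swap by the rotation shifts it one position
  expect_identical(compose(r, compose(s12, perm_inverse(r))),
                   parse_perm("(2 3)", N))
  set.seed(7)
  for (i in 1:25) {
    a <- sample(N); b <- sample(N); cc <- sample(N)
    expect_identical(compose(compose(a, b), cc), compose(a, compose(b, cc)))
    expect_identical(compose(perm_inverse(a), a), e)
  }
  # text round trips, both notations
  for (i in 1:10) {
    p <- sample(N)
    expect_identical(parse_perm(format_perm(p, "cycle"), N), p)
    expect_identical(parse_perm(format_perm(p, "oneline")), p)
  }
  expect_identical(parse_perm("2 1 3 4 5 6"), c(2L, 1L, 3:6))
  expect_error(compose(1:3, 1:4), "degree mismatch")
  expect_error(as_perm(c(1, 1, 3)), "not a permutation")
})

test_that("dihedral and general subgroup closures have the right structure", {
  expect_equal(dihedral_group(6)$size, 12)
  expect_equal(dihedral_group(3)$size, 6)   # D_3 is all of S_3
  expect_error(dihedral_group(2), "N >= 3")
  N <- 6
  r <- c(2:N, 1L)
  x <- r
  for (i in 1:(N - 1)) x <- compose(r, x)
  expect_identical(x, perm_identity(N))     # r^N = e
  expect_equal(subgroup_closure(N)$size, 1)
  expect_equal(subgroup_closure(N, list(rev(1:N)))$size, 2)
  expect_equal(subgroup_closure(N, list(r, rev(1:N)))$size, 2 * N)
  # closure is closed under product and inverse, contains identity
  Z <- dihedral_group(5)
  expect_true(subgroup_contains(Z, perm_identity(5)))
  for (a in Z$elements) {
    expect_true(subgroup_contains(Z, perm_inverse(a)))
    expect_true(subgroup_contains(Z, compose(a, Z$elements[[3]])))
  }
})

test_that("coset canonicalization partitions S_N into |Z|-sized classes", {
  for (N in 4:5) {
    Z <- dihedral_group(N)
    keys <- vapply(all_permutations(N),
                   function(p) perm_key(coset_canonical(p, Z)), character(1))
    expect_equal(length(unique(keys)), factorial(N) / (2 * N))
    expect_true(all(table(keys) == Z$size))
  }
  # idempotent, constant on the coset, [d] = [e] for d in Z
  Z <- dihedral_group(6)
  set.seed(11)
  for (i in 1:10) {
    p <- sample(6)
    cp <- coset_canonical(p, Z)
    expect_identical(coset_canonical(cp, Z), cp)
    d <- Z$elements[[sample(Z$size, 1)]]
    expect_identical(coset_canonical(compose(d, p), Z), cp)
  }
  eZ <- coset_canonical(perm_identity(6), Z)
  for (d in Z$elements) expect_identical(coset_canonical(d, Z), eZ)
  expect_equal(length(unique(vapply(all_permutations(6),
    function(p) perm_key(coset_canonical(p, Z)), character(1)))), 60)
})

test_that("double cosets: equivalence, N=5 complementarity, unequal sizes", {
  Z6 <- dihedral_group(6)
  s12 <- parse_perm("(1 2)", 6)
  s23 <- parse_perm("(2 3)", 6)
  expect_true(double_coset_equal(s12, s23, Z6))
  expect_false(identical(coset_canonical(s12, Z6), coset_canonical(s23, Z6)))
  set.seed(3)
  p <- sample(6)
  expect_true(double_coset_equal(p, p, Z6))
  Z5 <- dihedral_group(5)
  expect_true(double_coset_equal(parse_perm("(1 2)", 5),
                                 parse_perm("(1 3)", 5), Z5))
  sizes <- double_coset_classes(5, Z5)
  expect_equal(sum(sizes), 120)
  expect_gt(length(unique(as.integer(sizes))), 1)   # classes need not be equal
})

test_that("generates_full_group distinguishes generating sets", {
  N <- 5
  adj <- lapply(1:(N - 1), function(i) parse_perm(sprintf("(%d %d)", i, i + 1), N))
  expect_true(generates_full_group(adj, N))
  expect_true(generates_full_group(list(parse_perm("(1 2)", N), c(2:N, 1L)), N))
  expect_false(generates_full_group(list(parse_perm("(1 2 3)", 3)), 3))
})

test_that("group-algebra elements support exact rational arithmetic", {
  N <- 5
  x <- alg_elem(N, list(perm_identity(N), parse_perm("(1 2)", N)),
                num = c(1, 1), den = c(3, 3))
  expect_rational_equal(alg_coeff_sum(x), 2, 3)
  y <- alg_scale(x, 3, 2)
  expect_rational_equal(alg_coeff_sum(y), 1, 1)
  # product of coefficient-sum-1 elements has coefficient sum 1 (exactly)
  Z <- dihedral_group(N)
  z <- symmetry_element(Z)
  expect_rational_equal(alg_coeff_sum(alg_mul(z, y)), 1, 1)
  # bilinearity spot check
  a <- alg_elem(N, list(parse_perm("(1 2 3)", N)))
  lhs <- alg_mul(alg_add(x, a), z)
  rhs <- alg_add(alg_mul(x, z), alg_mul(a, z))
  expect_true(alg_equal(lhs, rhs))
  # cloud element is z * sigma
  set.seed(5)
  p <- sample(N)
  expect_true(alg_equal(cloud_element(p, Z),
                        alg_mul(z, alg_elem(N, list(p)))))
  expect_rational_equal(as_rational("2/3"), 2, 3)
  expect_rational_equal(as_rational(0.25), 1, 4)
})
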
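# Spectral path probabilities, likelihood curves and MLE behaviour.

test_that("spectral decomposition: projections resolve the identity", {
  ms <- adjacent_swap_model(6)
  sd <- spectral_decompose(ms)
  nterms <- 0
  for (part in sd$parts) {
    k <- nrow(part$E[[1]])
    total <- Reduce(`+`, part$E)
    expect_lt(max(abs(total - diag(k))), 1e-10)
    for (i in seq_along(part$E)) {
      Ei <- part$E[[i]]
      expect_lt(max(abs(Ei %*% Ei - Ei)), 1e-10)
      for (j in seq_along(part$E)) if (j != i)
        expect_lt(max(abs(Ei %*% part$E[[j]])), 1e-10)
    }
    nterms <- nterms + length(part$lambda)
    expect_true(all(abs(part$lambda) <= 1 + 1e-9))
  }
  # at most sum k_p = 8 distinct eigenvalue terms at N = 6
  expect_lte(nterms, 8)
  expect_equal(sd$parts[[1]]$lambda, 1, tolerance = 1e-12)
})

test_that("alpha_0 is the cloud indicator and alpha_k conserves probability", {
  ms <- adjacent_swap_model(5)
  sd <- spectral_decompose(ms)
  Z <- ms$Z
  expect_equal(path_probability(ms, sd, perm_identity(5), 0), 1,
               tolerance = 1e-10)
  for (d in Z$elements[c(2, 5)])
    expect_equal(path_probability(ms, sd, d, 0), 1, tolerance = 1e-10)
  expect_lt(abs(path_probability(ms, sd, parse_perm("(1 2)", 5), 0)), 1e-10)
  # conservation: sum over all K clouds of alpha_k = 1 for k = 0..8
  cb <- cloud_basis(5, Z)
  A <- vapply(cb$reps, function(g) path_probability(ms, sd, g, 0:8),
              numeric(9))
  expect_equal(unname(rowSums(A)), rep(1, 9), tolerance = 1e-10)
  expect_true(all(A >= -1e-12 & A <= 1 + 1e-12))
})

test_that("spectral route equals Markov oracle and Poisson power series", {
  set.seed(31)
  for (builder in list(adjacent_swap_model, small_inversion_model)) {
    ms <- builder(5)
    sd <- spectral_decompose(ms)
    cm <- cloud_markov_matrix(ms)
    for (i in 1:6) {
      g <- sample(5)
      expect_equal(path_probability(ms, sd, g, 0:8),
                   oracle_path_probability(cm, g, 0:8), tolerance = 1e-10)
      Tt <- runif(1, 0, 12)
      # closed form vs truncated Poisson series over oracle alphas
      expect_equal(likelihood(ms, sd, g, Tt), oracle_likelihood(cm, g, Tt),
                   tolerance = 1e-8)
    }
    # power-series identity with spectral alphas directly
    g <- sample(5)
    Tt <- 3.7
    alphas <- path_probability(ms, sd, g, 0:80)
    expect_equal(sum(alphas * dpois(0:80, Tt)),
                 likelihood(ms, sd, g, Tt), tolerance = 1e-8)
  }
})

test_that("full group-algebra route agrees and knocked-out traces vanish", {
  ms <- adjacent_swap_model(5)
  sd <- spectral_decompose(ms)
  set.seed(37)
  for (i in 1:5) {
    g <- sample(5)
    Tt <- runif(1, 0, 10)
    expect_equal(likelihood_full_group(ms, g, Tt),
                 likelihood(ms, sd, g, Tt), tolerance = 1e-8)
  }
  g <- sample(5)
  L <- likelihood_full_group(ms, g, 1, detail = TRUE)
  tab <- attr(L, "traces")
  expect_gt(sum(!tab$in_reduced), 0)          # some eigenvalues are projected out
  expect_lt(max(abs(tab$c[!tab$in_reduced])), 1e-10)
})

test_that("beta-level oracle: regular matrix entries equal exhaustive path sums", {
  ms <- adjacent_swap_model(4)
  fm <- full_group_markov_matrix(ms)
  n <- length(fm$perms)
  expect_equal(unname(colSums(fm$matrix)), rep(1, n), tolerance = 1e-12)
  expect_equal(unname(rowSums(fm$matrix)), rep(1, n), tolerance = 1e-12)
  expect_true(all(colSums(fm$matrix > 0) == length(ms$expanded)))
  set.seed(41)
  Pk <- diag(n)
  for (k in 1:4) {
    Pk <- fm$matrix %*% Pk
    for (i in sample(n, 3)) {
      # beta_k(sigma) = P^k entry (sigma, e), e is the first basis element
      expect_equal(Pk[i, 1], enumerate_beta(ms, fm$perms[[i]], k),
                   tolerance = 1e-12)
    }
  }
  # and the algebraic route: coefficient of sigma in s^k
  me <- model_element(ms)
  s3 <- alg_pow(me$s, 3)
  for (i in sample(n, 4)) {
    cf <- alg_coeff(s3, fm$perms[[i]])
    expect_equal(cf[1] / cf[2], enumerate_beta(ms, fm$perms[[i]], 3),
                 tolerance = 1e-12)
  }
})

test_that("class invariance: alpha and L constant on [sigma]_D and [sigma]_DR", {
  ms <- adjacent_swap_model(5)
  sd <- spectral_decompose(ms)
  Z <- ms$Z
  set.seed(43)
  sigma <- sample(5)
  base_a <- path_probability(ms, sd, sigma, 0:6)
  base_L <- likelihood(ms, sd, sigma, c(0.8, 3))
  for (i in 1:8) {
    d1 <- Z$elements[[sample(Z$size, 1)]]
    d2 <- Z$elements[[sample(Z$size, 1)]]
    memb <- compose(d1, compose(sigma, d2))
    if (i %% 2 == 0) memb <- compose(d1, compose(perm_inverse(sigma), d2))
    expect_equal(path_probability(ms, sd, memb, 0:6), base_a,
                 tolerance = 1e-9)
    expect_equal(likelihood(ms, sd, memb, c(0.8, 3)), base_L,
                 tolerance = 1e-9)
  }
  # directionless distance: L(T|sigma) = L(T|sigma^{-1})
  expect_equal(likelihood(ms, sd, perm_inverse(sigma), c(0.8, 3)), base_L,
               tolerance = 1e-10)
})

test_that("MLE: identity target, class-constant results, and the NONE flag", {
  ms <- adjacent_swap_model(5)
  sd <- spectral_decompose(ms)
  r0 <- mle(ms, sd, perm_identity(5))
  expect_equal(r0$mle_time, 0)
  expect_equal(r0$max_likelihood, 1, tolerance = 1e-10)
  expect_false(r0$no_finite_mle)
  set.seed(47)
  sigma <- sample(5)
  Z <- ms$Z
  r1 <- mle(ms, sd, sigma)
  d1 <- Z$elements[[4]]; d2 <- Z$elements[[7]]
  r2 <- mle(ms, sd, compose(d1, compose(sigma, d2)))
  r3 <- mle(ms, sd, compose(d1, compose(perm_inverse(sigma), d2)))
  expect_equal(r1$mle_time, r2$mle_time, tolerance = 1e-5)
  expect_equal(r1$max_likelihood, r2$max_likelihood, tolerance = 1e-9)
  expect_equal(r1$mle_time, r3$mle_time, tolerance = 1e-5)
  expect_equal(r1$asymptote, 1 / cloud_count(5, Z), tolerance = 1e-10)
  # asymptote equals the large-T oracle value
  cm <- cloud_markov_matrix(ms)
  expect_equal(oracle_likelihood(cm, sigma, 500), r1$asymptote,
               tolerance = 1e-6)
})
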
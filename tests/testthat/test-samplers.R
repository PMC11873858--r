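test_that("identical seeds give bit-identical retained draws", {
  sp <- space4
  persons <- generate_person_bank(60, seed = 301)
  items <- generate_item_bank(6, 0.2, seed = 302)
  sim <- generate_responses(persons, items, sp, seed = 303)
  cfg <- chain_config("rmm", n_iterations = 120, burnin = 40, thin = 2,
                      seed = 7)
  f1 <- fit_likert(sim$scores, sp, config = cfg)
  f2 <- fit_likert(sim$scores, sp, config = cfg)
  expect_identical(f1$draws, f2$draws)
  expect_identical(f1$zbar, f2$zbar)
  # a different seed moves at least the trait draws
  cfg2 <- chain_config("rmm", n_iterations = 120, burnin = 40, thin = 2,
                       seed = 8)
  f3 <- fit_likert(sim$scores, sp, config = cfg2)
  expect_false(identical(f1$draws$theta2, f3$draws$theta2))
})

test_that("every retained draw satisfies the parameter invariants", {
  sp <- space4
  persons <- generate_person_bank(80, seed = 311)
  items <- generate_item_bank(5, 0.2, seed = 312)
  sim <- generate_responses(persons, items, sp, seed = 313)
  for (model in c("rmm", "grm", "irtree")) {
    cfg <- chain_config(model, n_iterations = 150, burnin = 50, thin = 1,
                        seed = 17)
    fit <- fit_likert(sim$scores, sp, config = cfg)
    expect_true(all(fit$draws$alpha2 >= 0))
    if (model != "grm") expect_true(all(fit$draws$alpha1 >= 0))
    dd <- fit$draws$delta
    # sampled thresholds live in [-5, 5]; the reported draws carry the
    # likelihood-invariant identification shift delta - alpha2 * mu2, so
    # they can exceed the box by at most |alpha2 * mu2| (tiny at realistic
    # N; generous slack here because N = 80 keeps mu2 noisy)
    expect_true(all(dd >= -6.5 & dd <= 6.5))
    # ordered thresholds in every draw
    if (dim(dd)[3] > 1L)
      expect_true(all(apply(dd, c(1, 2), function(v) all(diff(v) >= 0))))
    # identification holds exactly in every retained draw
    expect_equal(fit$draws$mu, matrix(0, nrow(fit$draws$mu), 2))
    expect_true(all(abs(fit$draws$Sigma[, 1, 1] - 1) < 1e-12))
    expect_true(all(abs(fit$draws$Sigma[, 2, 2] - 1) < 1e-12))
  }
})

test_that("latent indicator sampling matches its Bernoulli posterior", {
  sp <- space4
  it <- fixture_items(1L)
  theta <- matrix(c(0.4, -0.2), 1)
  X <- matrix(sp$m, 1, 1)
  pim <- posterior_informative_given_middle(drop(theta), it, sp)
  set.seed(71)
  draws <- replicate(1e5, sample_latent_indicators(X, theta, it, sp)[1, 1])
  se <- sqrt(pim * (1 - pim) / 1e5)
  expect_lt(abs(mean(draws) - pim), 3 * se)
  # beta -> -inf: the non-response path is unreachable, Z = 1 almost surely
  it_inf <- item_params(it$alpha1, -60, it$alpha2, it$delta)
  set.seed(72)
  z <- replicate(1e4, sample_latent_indicators(X, theta, it_inf, sp)[1, 1])
  expect_gt(mean(z), 0.999)
  # non-middle scores are informative by observation
  X2 <- matrix(c(0L, 4L), 1)
  expect_equal(sample_latent_indicators(X2, theta, fixture_items(2L), sp),
               matrix(1L, 1, 2))
})

test_that("an empty dataset returns prior draws", {
  sp <- space4
  cfg <- chain_config("rmm", n_iterations = 4300, burnin = 300, thin = 1,
                      seed = 5)
  X0 <- matrix(integer(0), 0, 4)
  fit <- fit_likert(X0, sp, config = cfg)
  D <- nrow(fit$draws$beta)
  expect_equal(D, 4000L)
  # beta prior: normal(-2, variance 4)
  expect_equal(mean(fit$draws$beta), -2, tolerance = 0.1)
  expect_equal(sd(fit$draws$beta), 2, tolerance = 0.1)
  # alpha1 prior: normal(0.5, variance 4) truncated at zero; its mean is
  # mu + sigma * phi(a) / (1 - Phi(a)) at a = (0 - mu)/sigma
  a <- (0 - 0.5) / 2
  m_trunc <- 0.5 + 2 * dnorm(a) / (1 - pnorm(a))
  expect_equal(mean(fit$draws$alpha1), m_trunc, tolerance = 0.1)
  # thresholds flat on the ordered region of [-5, 5]
  dd <- fit$draws$delta
  expect_true(all(dd >= -5 & dd <= 5))
  expect_true(all(apply(dd, c(1, 2), function(v) all(diff(v) >= 0))))
  # with no data there is no latent scale to standardize: Sigma draws come
  # straight from the inverse-Wishart prior, symmetric and positive definite
  expect_true(all(apply(fit$draws$Sigma, 1, function(S)
    isSymmetric(S) && all(eigen(S, only.values = TRUE)$values > 0))))
})

test_that("alpha2 recovers the generating slopes at study scale", {
  sp <- space4
  persons <- generate_person_bank(1000, seed = 321)
  items <- generate_item_bank(25, 0.2, seed = 322)
  sim <- generate_responses(persons, items, sp, seed = 323)
  cfg <- chain_config("rmm", n_iterations = 1500, burnin = 300, thin = 2,
                      seed = 31)
  fit <- fit_likert(sim$scores, sp, config = cfg)
  est <- colMeans(fit$draws$alpha2)
  expect_gte(mean(abs(est - items$alpha2) <= 0.15), 0.9)
})

test_that("GRM trait estimates agree with a quadrature EAP oracle", {
  sp <- space4
  persons <- generate_person_bank(400, seed = 331)
  items <- generate_item_bank(20, 0, seed = 332)
  sim <- generate_responses(persons, items, sp, seed = 333)
  cfg <- chain_config("grm", n_iterations = 800, burnin = 200, thin = 2,
                      seed = 41)
  fit <- fit_likert(sim$scores, sp, config = cfg)
  est <- colMeans(fit$draws$theta2)
  # independent EAP under the generating item parameters on a dense grid
  grid <- seq(-5, 5, length.out = 201)
  lg <- sapply(grid, function(t2) {
    ll <- numeric(nrow(sim$scores))
    for (i in seq_len(20)) {
      pr <- grm_category_probs(t2, items$alpha2[i], items$delta[i, ])
      ll <- ll + log(pmax(pr[sim$scores[, i] + 1L], 1e-300))
    }
    ll
  })
  w <- exp(lg - apply(lg, 1, max)) * rep(dnorm(grid), each = 400)
  eap <- drop(w %*% grid) / rowSums(w)
  expect_gt(cor(est, eap), 0.99)
  # the fit standardizes theta2 to population mean zero while the oracle
  # uses the generating prior, so the levels may differ by a small shift
  expect_equal(mean(est - eap), 0, tolerance = 0.15)
})

test_that("irtree warns when an item carries only middle responses", {
  sp <- space4
  persons <- generate_person_bank(40, seed = 341)
  items <- generate_item_bank(3, 0.2, seed = 342)
  sim <- generate_responses(persons, items, sp, seed = 343)
  X <- sim$scores
  X[, 2] <- sp$m
  cfg <- chain_config("irtree", n_iterations = 60, burnin = 20, thin = 1,
                      seed = 51)
  expect_warning(fit_likert(X, sp, config = cfg), "middle")
})

test_that("scores outside the space or non-integers are rejected", {
  sp <- space4
  cfg <- chain_config("rmm", n_iterations = 20, burnin = 5, thin = 1,
                      seed = 61)
  X <- matrix(c(0L, 5L, 1L, 2L), 2, 2)
  expect_error(fit_likert(X, sp, config = cfg), "0..4")
  Xf <- matrix(c(0.5, 1, 2, 3), 2, 2)
  expect_error(fit_likert(Xf, sp, config = cfg), "integer")
})
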
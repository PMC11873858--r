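test_that("category space enforces an even maximum score and locates the middle", {
  sp <- likert_space(4)
  expect_equal(sp$m, 2L)
  expect_equal(sp$n_categories, 5L)
  expect_error(likert_space(3), "even")
  expect_error(likert_space(0), "even|>= 2")
})

test_that("graded-response cumulative probabilities match the probit form", {
  # flat thresholds at the trait location give one half everywhere
  expect_equal(grm_cumulative(0, 0.5, c(0, 0, 0, 0)), rep(0.5, 4))
  # zero slope removes the trait dependence entirely
  d <- c(-1, 0, 1, 2)
  expect_equal(grm_cumulative(5, 0, d), pnorm(-d))
  expect_equal(grm_cumulative(-5, 0, d), pnorm(-d))
  # direct normal-CDF evaluation at the linear predictor
  d2 <- c(-1.5, -0.5, 0.5, 1.5)
  expect_equal(grm_cumulative(1, 0.61, d2), pnorm(0.61 - d2))
  # nonincreasing in the category index, all interior
  cum <- grm_cumulative(0.3, 0.8, d2)
  expect_true(all(diff(cum) <= 0))
  expect_true(all(cum > 0 & cum < 1))
  expect_error(grm_cumulative(0, 0.5, c(1, 0, -1, 2)), "nondecreasing")
  expect_error(grm_cumulative(0, -0.1, d2), "nonnegative")
})

test_that("category probabilities are adjacent differences and sum to one", {
  d <- c(-1.5, -0.5, 0.5, 1.5)
  p <- grm_category_probs(1, 0.61, d)
  cum <- pnorm(0.61 - d)
  expect_equal(p, c(1 - cum[1], -diff(cum), cum[4]), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  # symmetric thresholds at theta2 = 0 give a symmetric distribution
  ps <- grm_category_probs(0, 0.7, c(-2, -0.5, 0.5, 2))
  expect_equal(ps, rev(ps), tolerance = 1e-12)
  # property: normalization over many random draws
  set.seed(41)
  for (r in 1:200) {
    it <- random_item_draw(1L)
    expect_equal(sum(grm_category_probs(rnorm(1), it$alpha2, it$delta[1, ])),
                 1, tolerance = 1e-10)
  }
})

test_that("first-node informative probability follows the normal ogive", {
  # zero slope: only the intercept matters
  expect_equal(informative_prob(c(-3, 0, 3), 0, -0.7), rep(pnorm(0.7), 3))
  expect_equal(informative_prob(0, 0.61, -1.6), pnorm(1.6))
  # monotone: nonincreasing in theta1 and in beta
  th <- seq(-3, 3, length.out = 21)
  expect_true(all(diff(informative_prob(th, 0.61, -1)) < 0))
  bs <- seq(-3, 3, length.out = 21)
  expect_true(all(diff(informative_prob(0.2, 0.61, bs)) < 0))
  # limit: an infinitely negative intercept guarantees an informative response
  expect_equal(informative_prob(0, 0.61, -50), 1, tolerance = 1e-12)
  expect_error(informative_prob(0, -1, 0), "nonnegative")
})

test_that("tree response probabilities normalize and collapse correctly", {
  sp <- likert_space(4)
  set.seed(42)
  for (r in 1:200) {
    it <- random_item_draw(1L)
    th <- rnorm(2)
    pr <- response_category_probs(th, it, sp)
    expect_true(all(pr >= 0))
    expect_equal(sum(pr), 1, tolerance = 1e-10)
    # mixture decomposition: middle = non-response mass + informative neutral
    p1 <- informative_prob(th[1], it$alpha1, it$beta)
    g <- grm_category_probs(th[2], it$alpha2, it$delta[1, ])
    expect_equal(pr[sp$m + 1], (1 - p1) + p1 * g[sp$m + 1], tolerance = 1e-12)
    expect_equal(pr[-(sp$m + 1)], (p1 * g)[-(sp$m + 1)], tolerance = 1e-12)
  }
  # degenerate mixture: the non-response path shut off leaves the pure GRM
  it <- fixture_items(1L)
  it_off <- item_params(it$alpha1, -1000, it$alpha2, it$delta)
  pr <- response_category_probs(c(0.5, -0.3), it_off, sp)
  expect_equal(pr, grm_category_probs(-0.3, it$alpha2, it$delta[1, ]),
               tolerance = 1e-12)
  expect_error(response_prob(7, c(0, 0), it, sp), "0..4")
})

test_that("tree probabilities agree with simulated traversal frequencies", {
  sp <- likert_space(4)
  it <- item_params(0.61, -1.6, 0.6, matrix(c(-1.5, -0.5, 0.5, 1.5), 1))
  th <- c(0.5, -0.3)
  set.seed(7)
  n <- 1e6
  oracle <- simulate_tree_frequencies(th, it, sp, n)
  pr <- response_category_probs(th, it, sp)
  se <- sqrt(pr * (1 - pr) / n)
  expect_true(all(abs(pr - oracle$freq) < 3 * se))
  # conditional informativeness among observed middle responses
  pim <- posterior_informative_given_middle(th, it, sp)
  zmid <- oracle$z[oracle$x == sp$m]
  se_z <- sqrt(pim * (1 - pim) / length(zmid))
  expect_lt(abs(mean(zmid) - pim), 3 * se_z)
})

test_that("informativeness posterior matches the closed slope-zero form", {
  sp <- likert_space(4)
  # alpha2 = 0: the middle-category probability is a known constant c
  d <- c(-1, -0.2, 0.4, 1.3)
  it <- item_params(0.61, -0.8, 0, matrix(d, 1))
  cc <- pnorm(-d[2]) - pnorm(-d[3])
  th <- c(0.7, 2.2)
  p <- informative_prob(th[1], 0.61, -0.8)
  expect_equal(posterior_informative_given_middle(th, it, sp),
               p * cc / (1 - p + p * cc), tolerance = 1e-12)
  # non-response path impossible: the middle response must be informative
  it1 <- item_params(0.61, -1000, 0.6, matrix(d, 1))
  expect_equal(posterior_informative_given_middle(c(0, 0), it1, sp), 1,
               tolerance = 1e-9)
})

test_that("log-likelihood multiplies cell probabilities of the tree", {
  sp <- likert_space(4)
  set.seed(99)
  it <- random_item_draw(3L)
  theta <- cbind(rnorm(5), rnorm(5))
  X <- matrix(sample(0:4, 15, replace = TRUE), 5, 3)
  ll <- log_likelihood(X, theta, it, sp, model = "rmm")
  manual <- 0
  for (p in 1:5) for (i in 1:3)
    manual <- manual + log(response_prob(X[p, i], theta[p, ], it, sp, item = i))
  expect_equal(ll, manual, tolerance = 1e-10)
  # one person, one item, non-middle score: the two-factor product
  x1 <- matrix(3L, 1, 1)
  ll1 <- log_likelihood(x1, matrix(c(0.2, -0.4), 1), it[1], sp)
  p1 <- informative_prob(0.2, it$alpha1, it$beta[1])
  g <- grm_category_probs(-0.4, it$alpha2[1], it$delta[1, ])
  expect_equal(ll1, log(p1 * g[4]), tolerance = 1e-12)
  expect_error(log_likelihood(X, theta[1:3, ], it, sp), "persons")
})

test_that("likelihood is invariant under identification rescaling", {
  sp <- likert_space(4)
  set.seed(3)
  it <- random_item_draw(4L)
  theta <- cbind(rnorm(8, 0.5, 1.4), rnorm(8, -0.3, 0.8))
  X <- matrix(sample(0:4, 32, replace = TRUE), 8, 4)
  draw <- list(theta = theta, mu = c(0.5, -0.3),
               Sigma = matrix(c(1.96, 0.4, 0.4, 0.64), 2),
               alpha1 = it$alpha1, beta = it$beta, alpha2 = it$alpha2,
               delta = it$delta)
  rs <- rescale_identification(draw)
  it2 <- item_params(rs$alpha1, rs$beta, rs$alpha2, rs$delta)
  expect_equal(log_likelihood(X, theta, it, sp),
               log_likelihood(X, rs$theta, it2, sp), tolerance = 1e-10)
  expect_equal(rs$mu, c(0, 0))
  expect_equal(diag(rs$Sigma), c(1, 1))
  expect_equal(rs$Sigma[1, 2], stats::cov2cor(draw$Sigma)[1, 2])
  # an already standardized draw passes through unchanged
  std <- list(theta = theta, mu = c(0, 0), Sigma = diag(2),
              alpha1 = it$alpha1, beta = it$beta, alpha2 = it$alpha2,
              delta = it$delta)
  expect_equal(rescale_identification(std), std)
})

test_that("mixture model nests the GRM and the IRTree baseline in the limits", {
  sp <- likert_space(4)
  set.seed(12)
  theta <- cbind(rnorm(6), rnorm(6))
  X <- matrix(sample(0:4, 30, replace = TRUE), 6, 5)
  base <- random_item_draw(5L)
  # beta -> -inf: every response informative, likelihood -> GRM likelihood
  it_grm <- item_params(base$alpha1, rep(-60, 5), base$alpha2, base$delta)
  expect_equal(log_likelihood(X, theta, it_grm, sp, "rmm"),
               log_likelihood(X, theta, it_grm, sp, "grm"), tolerance = 1e-8)
  # beta -> +inf: node 1 absorbs everything; middle category takes all mass
  it_nr <- item_params(base$alpha1, rep(60, 5), base$alpha2, base$delta)
  pm <- response_category_probs(theta[1, ], it_nr, sp)
  expect_equal(pm[sp$m + 1], 1, tolerance = 1e-12)
})

test_that("Gauss-Hermite marginal matches dense numerical integration", {
  sp <- likert_space(4)
  set.seed(21)
  it <- random_item_draw(5L)
  x <- matrix(sample(0:4, 5, replace = TRUE), 1)
  th2 <- 0.4
  mu <- c(0.1, -0.2)
  Sigma <- matrix(c(1, -0.3, -0.3, 1.2), 2)
  got <- marginal_loglik_theta1(x, th2, it, mu, Sigma, sp, n_nodes = 10)
  # trapezoid oracle on a dense grid of the conditional normal
  mc <- mu[1] + Sigma[1, 2] / Sigma[2, 2] * (th2 - mu[2])
  vc <- Sigma[1, 1] - Sigma[1, 2]^2 / Sigma[2, 2]
  grid <- seq(mc - 8 * sqrt(vc), mc + 8 * sqrt(vc), length.out = 4000)
  f <- vapply(grid, function(t1) {
    exp(sum(cell_loglik_test(x, t1, th2, it, sp))) *
      dnorm(grid[1] * 0 + t1, mc, sqrt(vc))
  }, numeric(1))
  oracle <- log(sum((f[-1] + f[-length(f)]) / 2 * diff(grid)))
  expect_equal(as.numeric(got), oracle, tolerance = 1e-4)
  # quadrature converged: more nodes barely move the value
  got40 <- marginal_loglik_theta1(x, th2, it, mu, Sigma, sp, n_nodes = 40)
  expect_lt(abs(got - got40), 1e-3)
  # integrand free of theta1: marginal equals the conditional likelihood
  it0 <- item_params(0, it$beta, it$alpha2, it$delta)
  S0 <- diag(2)
  got0 <- marginal_loglik_theta1(x, th2, it0, c(0, 0), S0, sp)
  cond <- sum(cell_loglik_test(x, 123, th2, it0, sp))
  expect_equal(as.numeric(got0), cond, tolerance = 1e-10)
  expect_error(marginal_loglik_theta1(x, th2, it, mu,
                                      matrix(c(1, 2, 2, 1), 2), sp),
               "positive definite")
})
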
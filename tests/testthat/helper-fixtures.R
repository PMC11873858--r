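# Shared fixtures, built in code at test time.

space4 <- likert_space(4)

# a small deterministic item set used across model-core tests
fixture_items <- function(K = 3L) {
  item_params(alpha1 = 0.61,
              beta = seq(-1.6, -1.2, length.out = K),
              alpha2 = seq(0.5, 0.7, length.out = K),
              delta = matrix(rep(c(-1.5, -0.5, 0.5, 1.5), each = K), K))
}

# random but seeded parameter draws within the prior's support
random_item_draw <- function(K, h = 4L) {
  item_params(alpha1 = runif(1L, 0.2, 1.2),
              beta = rnorm(K, -1.5, 0.5),
              alpha2 = runif(K, 0.3, 1),
              delta = t(apply(matrix(runif(K * h, -3, 3), K), 1L, sort)))
}

# thin wrapper over the internal per-cell log-probability matrix, used by
# integration oracles that need the likelihood at fixed theta1
cell_loglik_test <- function(x, t1, t2, items, space, model = "rmm") {
  n <- nrow(x)
  rmixtree:::cell_loglik(x, rep(t1, n), rep(t2, n), items, space, model)
}

# Monte-Carlo traversal of the decision tree at fixed person/item values;
# independent oracle for the closed-form probabilities
simulate_tree_frequencies <- function(theta, items, space, n, item = 1L) {
  p1 <- pnorm(-items$alpha1 * theta[1L] - items$beta[item])
  z <- runif(n) < p1
  eta2 <- items$alpha2[item] * theta[2L]
  y2 <- rnorm(n, eta2)
  x <- rowSums(outer(y2, items$delta[item, ], `>`))
  x[!z] <- space$m
  list(freq = tabulate(x + 1L, nbins = space$h + 1L) / n,
       z = z, x = x)
}
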
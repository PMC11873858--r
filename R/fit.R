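#' Fit a Likert response model by Gibbs sampling
#'
#' Draws from the joint posterior of one of three models for an N x K
#' matrix of Likert scores with a middle category:
#' \describe{
#'   \item{`"rmm"`}{the response-mixture tree: a normal-ogive non-response
#'     node followed by a probit graded response model over all `h + 1`
#'     categories; for every observed middle response the latent path
#'     indicator `Z` is sampled along with the parameters.}
#'   \item{`"grm"`}{the plain probit graded response model (no first node;
#'     every response is informative).}
#'   \item{`"irtree"`}{the pure IRTree baseline: every middle response is a
#'     non-response, and the second node spans the `h` non-middle
#'     categories with `h - 1` thresholds (scores remapped monotonically).}
#' }
#' Estimation uses Albert-Chib probit data augmentation: truncated-normal
#' propensities `Y1` (first node, positive iff informative) and `Y2`
#' (second node, confined to the observed category's threshold band) make
#' every conditional standard.  After each full sweep the draw is
#' standardized with [rescale_identification()] so the latent traits have
#' mean 0 and variance 1 in every retained draw.
#'
#' @param data Integer N x K matrix of scores `0..h` (persons in rows).
#' @param space A [likert_space()].
#' @param config A [chain_config()]; `config$model` selects the model.
#' @param prior A [prior_spec()].
#' @param verbose Print progress every 500 iterations.
#'
#' @return An object of class `likert_fit` with components
#'   `draws` (retained draws: `alpha1`, `beta`, `alpha2`, `delta`
#'   (draws x K x n_thresholds), `mu`, `Sigma`, `theta1`, `theta2`),
#'   `zbar` (posterior mean of the informativeness indicator per cell,
#'   `"rmm"` only), `model`, `space`, `config`, `prior` and `dim`.
#' @examples
#' sp <- likert_space(4)
#' persons <- generate_person_bank(80, seed = 1)
#' items <- generate_item_bank(5, nr_rate = 0.2, seed = 2)
#' sim <- generate_responses(persons, items, sp, seed = 3)
#' fit <- fit_likert(sim$scores, sp,
#'                   chain_config("rmm", n_iterations = 120, burnin = 40,
#'                                seed = 7))
#' fit
#' @export
fit_likert <- function(data, space, config = chain_config(),
                       prior = prior_spec(), verbose = FALSE) {
  space <- as_likert_space(space)
  stopifnot(inherits(config, "chain_config"), inherits(prior, "prior_spec"))
  if (is.data.frame(data)) data <- as.matrix(data)
  data <- validate_scores(data, space)
  if (!is.null(config$seed)) set.seed(config$seed)
  model <- config$model
  N <- nrow(data); K <- ncol(data)
  if (K < 1L) stop("`data` must contain at least one item")
  if (N == 0L)
    return(prior_sample_fit(K, space, config, prior))
  h <- space$h; m <- space$m
  n_thr <- if (model == "irtree") h - 1L else h

  if (model == "irtree") {
    all_mid <- colSums(data != m) == 0L
    if (any(all_mid))
      warning(sprintf("item(s) %s have only middle-category responses; their second-node parameters are prior-dominated",
                      paste(which(all_mid), collapse = ", ")))
  }

  # --- initialization: moment-based starts to shorten the burn-in ---------
  # second trait: standardized person mean score plus a little jitter
  rowm <- rowMeans(data)
  th2_0 <- (rowm - mean(rowm)) / max(stats::sd(rowm), 1e-8)
  theta <- cbind(rnorm(N, 0, 0.3), th2_0 + rnorm(N, 0, 0.3))
  alpha1 <- prior$alpha1_mean
  beta <- rep(prior$beta_mean, K)
  alpha2 <- rep(prior$alpha2_mean, K)
  delta <- threshold_starts(data, space, n_thr, model)
  mu <- c(0, 0); Sigma <- diag(2)
  Z <- matrix(1L, N, K)
  if (model == "irtree") Z <- matrix(as.integer(data != m), N, K)
  if (model %in% c("rmm", "irtree")) {
    # start the non-response path at its method-of-moments estimate: the
    # middle category's excess share over its neighbours' average, per item
    mid_share <- colMeans(data == m)
    neigh <- (colMeans(data == m - 1L) + colMeans(data == m + 1L)) / 2
    nr0 <- pmin(pmax(mid_share - neigh, 0.01), 0.8)
    beta <- qnorm(nr0) * sqrt(1 + alpha1^2)
    # first trait: each person's own excess middle share on the probit scale;
    # non-response probability is Phi(alpha1 * theta1 + beta)
    row_mid <- rowMeans(data == m)
    row_neigh <- (rowMeans(data == m - 1L) + rowMeans(data == m + 1L)) / 2
    nr_p <- pmin(pmax(row_mid - row_neigh, 0.005), 0.9)
    th1_0 <- (qnorm(nr_p) - mean(beta)) / max(alpha1, 0.1)
    th1_0 <- pmin(pmax(th1_0, -3), 3)
    th1_0 <- (th1_0 - mean(th1_0)) / max(stats::sd(th1_0), 1e-8)
    theta[, 1L] <- th1_0 + rnorm(N, 0, 0.3)
  }
  mid_mask <- data == m
  if (model == "rmm") {
    # Z start consistent with the trait/intercept starts: cell-level
    # posterior odds of the non-response path against an informative middle,
    # with the item's neighbour share standing in for the informative
    # middle-category probability
    mid_cells <- which(mid_mask, arr.ind = TRUE)
    if (nrow(mid_cells) > 0L) {
      p_nr <- pnorm(alpha1 * theta[mid_cells[, 1L], 1L] +
                      beta[mid_cells[, 2L]])
      gm <- pmax(neigh, 0.02)[mid_cells[, 2L]]
      frac_nr <- p_nr / (p_nr + (1 - p_nr) * gm)
      Z[mid_cells] <- as.integer(runif(nrow(mid_cells)) >= frac_nr)
    }
  }
  Y1 <- matrix(0, N, K); Y2 <- matrix(0, N, K)
  mn <- matrix(Inf, K, n_thr + 1L); mx <- matrix(-Inf, K, n_thr + 1L)
  keep <- seq.int(config$burnin + 1L, config$n_iterations)
  keep <- keep[(keep - config$burnin - 1L) %% config$thin == 0L]
  D <- length(keep)
  draws <- list(
    alpha1 = numeric(D), beta = matrix(NA_real_, D, K),
    alpha2 = matrix(NA_real_, D, K), delta = array(NA_real_, c(D, K, n_thr)),
    mu = matrix(0, D, 2L), Sigma = array(NA_real_, c(D, 2L, 2L)),
    theta1 = if (model == "grm") NULL else matrix(NA_real_, D, N),
    theta2 = matrix(NA_real_, D, N))
  zbar <- if (model == "rmm" && config$store_z == "mean") matrix(0, N, K) else NULL
  d <- 0L

  for (it in seq_len(config$n_iterations)) {
    if (model == "rmm") {
      sweep_rmm(data, m, Z, Y1, Y2, theta[, 1L], theta[, 2L],
                alpha1, beta, alpha2, delta, mn, mx)
    } else if (model == "grm") {
      sweep_grm(data, Y2, theta[, 2L], alpha2, delta, mn, mx)
    } else {
      sweep_irtree(data, m, Y1, Y2, theta[, 1L], theta[, 2L],
                   alpha1, beta, alpha2, delta, mn, mx)
    }

    th2 <- theta[, 2L]
    if (model != "grm") {
      th1 <- theta[, 1L]
      # alpha1 | beta: pooled regression of Y1 + beta on -theta1
      rs1 <- rowSums(Y1)
      prec <- 1 / prior$alpha1_var + K * sum(th1^2)
      bnat <- prior$alpha1_mean / prior$alpha1_var -
        (sum(th1 * rs1) + sum(beta) * sum(th1))
      alpha1 <- rtnorm(1L, bnat / prec, sqrt(1 / prec), lo = 0)
      # beta | alpha1
      tgt <- colSums(Y1) + alpha1 * sum(th1)
      prec <- 1 / prior$beta_var + N
      beta <- rnorm(K, (prior$beta_mean / prior$beta_var - tgt) / prec,
                    sqrt(1 / prec))
    }
    # alpha2: per-item regression of Y2 on theta2 over informative cells
    if (model == "grm") {
      sw <- rep(sum(th2^2), K)
      sy <- drop(crossprod(Y2, th2))
    } else {
      sw <- drop(crossprod(Z, th2^2))
      sy <- drop(crossprod(Z * Y2, th2))
    }
    prec <- 1 / prior$alpha2_var + sw
    alpha2 <- rtnorm(K, (prior$alpha2_mean / prior$alpha2_var + sy) / prec,
                     sqrt(1 / prec), lo = 0)
    # thresholds: uniform on the interval free of augmented propensities
    for (k in seq_len(n_thr)) {
      lo <- pmax(mx[, k], if (k > 1L) delta[, k - 1L] else prior$threshold_lo,
                 prior$threshold_lo)
      hi <- pmin(mn[, k + 1L],
                 if (k < n_thr) delta[, k + 1L] else prior$threshold_hi,
                 prior$threshold_hi)
      hi <- pmax(hi, lo)            # degenerate guard; interval is a point
      delta[, k] <- lo + runif(K) * (hi - lo)
    }

    # person parameters: joint bivariate-normal conditional
    if (model == "grm") {
      prec <- 1 / Sigma[2L, 2L] + sum(alpha2^2)
      bnat <- mu[2L] / Sigma[2L, 2L] + drop(Y2 %*% alpha2)
      theta[, 2L] <- rnorm(N, bnat / prec, sqrt(1 / prec))
      theta[, 1L] <- 0
    } else {
      Om <- solve(Sigma)
      A <- drop(Z %*% alpha2^2)
      c1 <- -alpha1 * (rowSums(Y1) + sum(beta))
      c2 <- drop((Z * Y2) %*% alpha2)
      p11 <- Om[1L, 1L] + alpha1^2 * K
      p22 <- Om[2L, 2L] + A
      p12 <- Om[1L, 2L]
      b1 <- drop(Om %*% mu)[1L] + c1
      b2 <- drop(Om %*% mu)[2L] + c2
      dt <- p11 * p22 - p12^2
      m1 <- (p22 * b1 - p12 * b2) / dt
      m2 <- (p11 * b2 - p12 * b1) / dt
      C11 <- p22 / dt; C22 <- p11 / dt; C12 <- -p12 / dt
      l11 <- sqrt(C11); l21 <- C12 / l11
      l22 <- sqrt(pmax(C22 - l21^2, 1e-12))
      z1 <- rnorm(N); z2 <- rnorm(N)
      theta[, 1L] <- m1 + l11 * z1
      theta[, 2L] <- m2 + l21 * z1 + l22 * z2
    }

    # hyperparameters and identification rescaling
    if (model == "grm") {
      mu2 <- rnorm(1L, mean(theta[, 2L]), sqrt(Sigma[2L, 2L] / N))
      ssq <- sum((theta[, 2L] - mu2)^2)
      sig2 <- 1 / rgamma(1L, shape = (prior$sigma_df + N) / 2,
                         rate = (prior$sigma_scale[1L, 1L] + ssq) / 2)
      s <- sqrt(sig2)
      theta[, 2L] <- (theta[, 2L] - mu2) / s
      delta <- delta - alpha2 * mu2   # with the pre-rescale slope
      alpha2 <- alpha2 * s
      mu <- c(0, 0); Sigma <- diag(2)
    } else {
      mu <- colMeans(theta) +
        drop(t(chol(Sigma)) %*% rnorm(2L)) / sqrt(N)
      S <- crossprod(sweep(theta, 2L, mu))
      W <- rWishart(1L, prior$sigma_df + N,
                    solve(prior$sigma_scale + S))[, , 1L]
      Sigma <- solve(W)
      Sigma <- (Sigma + t(Sigma)) / 2
      dr <- rescale_identification(list(theta = theta, mu = mu, Sigma = Sigma,
                                        alpha1 = alpha1, beta = beta,
                                        alpha2 = alpha2, delta = delta))
      theta <- dr$theta; mu <- dr$mu; Sigma <- dr$Sigma
      alpha1 <- dr$alpha1; beta <- dr$beta
      alpha2 <- dr$alpha2; delta <- dr$delta
    }

    # alternating the collapsed moves with plain augmented sweeps halves
    # their cost while still spanning the whole burn-in window; no retained
    # draw is ever produced by the approximate collapsed kernel
    if (model == "rmm" && it <= config$burnin && it %% 2L == 1L) {
      bb <- burnin_boost_node1(data, mid_mask, theta, alpha1, beta,
                               alpha2, delta, Sigma, space, prior)
      alpha1 <- bb$alpha1
      beta <- bb$beta
      theta[, 1L] <- bb$theta1
      theta[, 2L] <- bb$theta2
      delta <- bb$delta
    }

    if (it > config$burnin && (it - config$burnin - 1L) %% config$thin == 0L) {
      d <- d + 1L
      draws$alpha1[d] <- alpha1
      draws$beta[d, ] <- beta
      draws$alpha2[d, ] <- alpha2
      draws$delta[d, , ] <- delta
      draws$mu[d, ] <- mu
      draws$Sigma[d, , ] <- Sigma
      if (model != "grm") draws$theta1[d, ] <- theta[, 1L]
      draws$theta2[d, ] <- theta[, 2L]
      if (!is.null(zbar)) zbar <- zbar + (Z - zbar) / d
    }
    if (verbose && it %% 500L == 0L)
      message(sprintf("  iteration %d / %d", it, config$n_iterations))
  }

  structure(list(model = model, space = space, draws = draws, zbar = zbar,
                 config = config, prior = prior,
                 dim = c(N = N, K = K, retained = D)),
            class = "likert_fit")
}

# delta' handling for the GRM branch above is done inline; keep the algebra
# here for reference: with theta2' = (theta2 - mu)/s the linear predictor
# alpha2*theta2 - delta = (alpha2*s)*theta2' - (delta - alpha2*mu).

# quantile-based threshold starts, per item.  Under the mixture model the
# observed middle-category count is deflated by the item's estimated
# non-response share first; otherwise the starting middle band is too wide,
# which lets the second node explain non-responses informatively and locks
# the chain into an under-filtering configuration that the prescribed
# burn-in cannot undo.  The probit quantiles are then placed on the scale
# of the latent propensity (variance 1 + alpha2^2 at the starting slope).
threshold_starts <- function(data, space, n_thr, model, alpha2_start = 0.5) {
  K <- ncol(data); h <- space$h; m <- space$m
  delta <- matrix(NA_real_, K, n_thr)
  sc <- sqrt(1 + alpha2_start^2)
  for (i in seq_len(K)) {
    x <- data[, i]
    if (model == "irtree") {
      x <- x[x != m]
      x <- ifelse(x > m, x - 1L, x)
      cats <- n_thr + 1L
    } else cats <- h + 1L
    if (length(x) == 0L) {
      delta[i, ] <- seq(-1.5, 1.5, length.out = n_thr)
      next
    }
    cnt <- tabulate(x + 1L, nbins = cats)
    if (model == "rmm") {
      nr_i <- max(mean(x == m) - (mean(x == m - 1L) + mean(x == m + 1L)) / 2,
                  0)
      cnt[m + 1L] <- max(cnt[m + 1L] - round(nr_i * length(x)), 1L)
    }
    cum <- cumsum(cnt) / sum(cnt)
    q <- sc * qnorm(pmin(pmax(cum[seq_len(n_thr)], 0.01), 0.99))
    delta[i, ] <- cummax(q + seq(0, 1e-3, length.out = n_thr))
  }
  delta
}

# Burn-in booster for the mixture model: re-draws the whole first node --
# person traits theta1 (griddy, Gumbel-max), item intercepts beta (griddy
# Gibbs), and the slope alpha1 (random-walk Metropolis) -- from posteriors
# conditional on theta2 and the second-node parameters only, with the path
# indicators and augmented propensities integrated out analytically.  The
# data-augmentation kernel mixes this block slowly when the path labels
# start far from their stationary share, because mislabeled cells, the
# trait ordering, and the intercept level reinforce one another; the
# collapsed moves let each component jump directly to the value the
# observed middle-category pattern supports.  Applied during burn-in only,
# so every retained draw is still produced by the exact augmented Gibbs
# kernel.
burnin_boost_node1 <- function(data, mid_mask, theta, alpha1, beta,
                               alpha2, delta, Sigma, space, prior) {
  m <- space$m
  N <- nrow(data); K <- ncol(data)
  eta2 <- outer(theta[, 2L], alpha2)
  gm <- pnorm(sweep(eta2, 2L, delta[, m])) -
    pnorm(sweep(eta2, 2L, delta[, m + 1L]))

  # theta1, person by person on a shared grid; the conditional prior given
  # theta2 comes from the current correlation
  tgrid <- seq(-3.5, 3.5, length.out = 41L)
  P1g <- pnorm(outer(-alpha1 * tgrid, beta, `-`))       # grid x item
  LL <- log(pmax(P1g, 1e-300)) %*% (!t(mid_mask))       # grid x person
  for (i in seq_len(K)) {
    idx <- which(mid_mask[, i])
    if (length(idx))
      LL[, idx] <- LL[, idx] +
        log1p(-outer(P1g[, i], 1 - gm[idx, i]))
  }
  rho <- Sigma[1L, 2L] / sqrt(Sigma[1L, 1L] * Sigma[2L, 2L])
  cm <- rho * theta[, 2L]
  cs <- sqrt(max(1 - rho^2, 1e-8))
  LL <- LL + dnorm(outer(tgrid, cm, `-`) / cs, log = TRUE)
  gum <- -log(-log(matrix(runif(length(LL)), nrow(LL))))
  theta[, 1L] <- tgrid[max.col(t(LL + gum))]
  th1 <- theta[, 1L]

  # theta2, person by person on the same grid, with the middle-category
  # mixture marginalized over the path indicator: without this the trait
  # update sees only the currently informative-labeled cells, so an
  # over- or under-filtered label set reproduces itself through the trait
  h <- space$h
  CUM <- lapply(seq_len(h), function(k)
    pnorm(outer(tgrid, alpha2) - rep(delta[, k], each = length(tgrid))))
  LL2 <- matrix(0, length(tgrid), N)
  for (cc in seq(0L, h)) {
    if (cc == m) next
    gcat <- (if (cc == 0L) 1 else CUM[[cc]]) -
      (if (cc == h) 0 else CUM[[cc + 1L]])
    LL2 <- LL2 + log(pmax(gcat, 1e-300)) %*% t(data == cc)
  }
  gmid <- CUM[[m]] - CUM[[m + 1L]]
  for (i in seq_len(K)) {
    idx <- which(mid_mask[, i])
    if (length(idx) == 0L) next
    p1i <- pnorm(-alpha1 * th1[idx] - beta[i])
    LL2[, idx] <- LL2[, idx] + log1p(-outer(1 - gmid[, i], p1i))
  }
  LL2 <- LL2 + dnorm(outer(tgrid, rho * th1, `-`) / cs, log = TRUE)
  gum <- -log(-log(matrix(runif(length(LL2)), nrow(LL2))))
  theta[, 2L] <- tgrid[max.col(t(LL2 + gum))]
  eta2 <- outer(theta[, 2L], alpha2)
  gm <- pnorm(sweep(eta2, 2L, delta[, m])) -
    pnorm(sweep(eta2, 2L, delta[, m + 1L]))

  # each beta_i is conditionally independent given alpha1 and the traits
  bgrid <- seq(min(beta) - 0.75, max(beta) + 0.75, length.out = 41L)
  P1 <- pnorm(outer(-alpha1 * th1, bgrid, `-`))
  nonmid_ll <- crossprod(log(pmax(P1, 1e-300)), !mid_mask)  # grid x item
  lprior <- dnorm(bgrid, prior$beta_mean, sqrt(prior$beta_var), log = TRUE)
  for (i in seq_len(K)) {
    idx <- which(mid_mask[, i])
    ll <- nonmid_ll[, i] + lprior
    if (length(idx))
      ll <- ll +
        colSums(log1p(-P1[idx, , drop = FALSE] * (1 - gm[idx, i])))
    beta[i] <- bgrid[sample.int(length(bgrid), 1L, prob = exp(ll - max(ll)))]
  }

  # random-walk Metropolis on alpha1 under the same collapsed likelihood
  ll_a <- function(a) {
    P <- pnorm(outer(-a * th1, beta, `-`))
    sum(log(pmax(P[!mid_mask], 1e-300))) +
      sum(log1p(-P[mid_mask] * (1 - gm[mid_mask]))) +
      dnorm(a, prior$alpha1_mean, sqrt(prior$alpha1_var), log = TRUE)
  }
  cur <- ll_a(alpha1)
  for (s in 1:3) {
    prop <- alpha1 + rnorm(1L, 0, 0.08)
    if (prop >= 0) {
      cand <- ll_a(prop)
      if (log(runif(1L)) < cand - cur) {
        alpha1 <- prop
        cur <- cand
      }
    }
  }

  # random-walk Metropolis on each threshold with the path indicators
  # integrated out.  The data-augmentation update confines each threshold
  # to the gap between order statistics of the propensities, which shrinks
  # like 1/N; without this move the starting thresholds persist through
  # the whole prescribed chain and pin the middle band, and with it the
  # split of middle responses between the two paths.
  P1c <- pnorm(outer(-alpha1 * th1, beta, `-`))
  for (i in seq_len(K)) {
    eta <- eta2[, i]
    for (k in seq_len(h)) {
      lo <- if (k > 1L) delta[i, k - 1L] else -5
      hi <- if (k < h) delta[i, k + 1L] else 5
      prop <- delta[i, k] + rnorm(1L, 0, 0.08)
      if (prop <= lo || prop >= hi) next
      dll <- 0
      for (cc in c(k - 1L, k)) {         # categories whose mass moves
        idx <- which(data[, i] == cc)
        if (length(idx) == 0L) next
        dn <- if (cc > 0L) delta[i, cc] else -Inf       # lower threshold
        up <- if (cc < h) delta[i, cc + 1L] else Inf    # upper threshold
        g_old <- pnorm(eta[idx] - dn) - pnorm(eta[idx] - up)
        g_new <- pnorm(eta[idx] - (if (cc == k) prop else dn)) -
          pnorm(eta[idx] - (if (cc == k - 1L) prop else up))
        if (cc == m) {                   # mixture form for the middle
          p1 <- P1c[idx, i]
          dll <- dll + sum(log(pmax((1 - p1) + p1 * g_new, 1e-300))) -
            sum(log(pmax((1 - p1) + p1 * g_old, 1e-300)))
        } else {
          dll <- dll + sum(log(pmax(g_new, 1e-300))) -
            sum(log(pmax(g_old, 1e-300)))
        }
      }
      if (log(runif(1L)) < dll) delta[i, k] <- prop
    }
  }

  list(alpha1 = alpha1, beta = beta, theta1 = theta[, 1L],
       theta2 = theta[, 2L], delta = delta)
}

# prior-predictive draws for an empty dataset (N = 0): the Gibbs conditionals
# all collapse to the prior.  mu has an improper flat prior and is kept at 0.
prior_sample_fit <- function(K, space, config, prior) {
  model <- config$model
  n_thr <- if (model == "irtree") space$h - 1L else space$h
  keep <- seq.int(config$burnin + 1L, config$n_iterations)
  keep <- keep[(keep - config$burnin - 1L) %% config$thin == 0L]
  D <- length(keep)
  draws <- list(
    alpha1 = rtnorm(D, prior$alpha1_mean, sqrt(prior$alpha1_var), lo = 0),
    beta = matrix(rnorm(D * K, prior$beta_mean, sqrt(prior$beta_var)), D, K),
    alpha2 = matrix(rtnorm(D * K, prior$alpha2_mean, sqrt(prior$alpha2_var),
                           lo = 0), D, K),
    delta = array(NA_real_, c(D, K, n_thr)),
    mu = matrix(0, D, 2L),
    Sigma = array(NA_real_, c(D, 2L, 2L)),
    theta1 = NULL, theta2 = matrix(NA_real_, D, 0L))
  for (d in seq_len(D)) {
    for (i in seq_len(K))
      draws$delta[d, i, ] <- sort(runif(n_thr, prior$threshold_lo,
                                        prior$threshold_hi))
    W <- rWishart(1L, prior$sigma_df, solve(prior$sigma_scale))[, , 1L]
    draws$Sigma[d, , ] <- solve(W)
  }
  structure(list(model = model, space = space, draws = draws, zbar = NULL,
                 config = config, prior = prior,
                 dim = c(N = 0L, K = K, retained = D)),
            class = "likert_fit")
}

#' @export
print.likert_fit <- function(x, ...) {
  cat(sprintf("Gibbs fit of the %s model\n", toupper(x$model)))
  cat(sprintf("  data: %d persons x %d items (scores 0..%d)\n",
              x$dim["N"], x$dim["K"], x$space$h))
  cat(sprintf("  chain: %d iterations, %d burnin, thin %d -> %d retained draws\n",
              x$config$n_iterations, x$config$burnin, x$config$thin,
              x$dim["retained"]))
  if (x$model != "grm" && x$dim["N"] > 0) {
    cat(sprintf("  posterior mean alpha1 = %.3f, mean beta = %.3f\n",
                mean(x$draws$alpha1), mean(x$draws$beta)))
    Sb <- apply(x$draws$Sigma, c(2L, 3L), mean)
    cat(sprintf("  posterior mean cor(theta1, theta2) = %.3f\n", Sb[1L, 2L]))
  }
  invisible(x)
}

#' Posterior point estimates from a fitted model
#'
#' @param object A `likert_fit`.
#' @param pars One of `"theta2"`, `"theta1"`, `"alpha1"`, `"beta"`,
#'   `"alpha2"`, `"delta"`, `"mu"`, `"Sigma"`.
#' @param ... Unused.
#' @return Posterior means with the parameter block's natural shape.
#' @export
coef.likert_fit <- function(object, pars = "theta2", ...) {
  dr <- object$draws[[pars]]
  if (is.null(dr)) stop(sprintf("no draws for '%s' under model '%s'",
                                pars, object$model))
  if (is.matrix(dr)) colMeans(dr)
  else if (is.array(dr)) apply(dr, seq_along(dim(dr))[-1L], mean)
  else mean(dr)
}

#' Posterior item parameters as an `item_params` object
#'
#' Posterior means of the item block of a fitted model, reassembled into a
#' [item_params()] object (used by [dic()] for the plug-in deviance).
#'
#' @param fit A `likert_fit`.
#' @return A [item_params()] object.
#' @export
posterior_items <- function(fit) {
  item_params(alpha1 = if (fit$model == "grm") 0 else mean(fit$draws$alpha1),
              beta = if (fit$model == "grm") rep(0, fit$dim["K"])
                     else colMeans(fit$draws$beta),
              alpha2 = colMeans(fit$draws$alpha2),
              delta = apply(fit$draws$delta, c(2L, 3L), mean))
}

#' Posterior summary table of a fitted model
#'
#' Mean, SD and central 95% interval of every retained scalar parameter,
#' with flattened names (`beta[3]`, `delta[2,1]`, ...).
#'
#' @param fit A `likert_fit`.
#' @param include_theta Include the (large) person-parameter blocks.
#' @return A data frame with columns `parameter`, `mean`, `sd`, `q2.5`,
#'   `q97.5`.
#' @export
posterior_summary <- function(fit, include_theta = FALSE) {
  blocks <- c("alpha1", "beta", "alpha2", "delta", "mu", "Sigma")
  if (include_theta) blocks <- c(blocks, "theta1", "theta2")
  rows <- list()
  for (b in blocks) {
    dr <- fit$draws[[b]]
    if (is.null(dr) || length(dr) == 0L) next
    M <- if (is.matrix(dr)) dr
         else if (is.array(dr)) matrix(dr, nrow = dim(dr)[1L])
         else matrix(dr, ncol = 1L)
    nm <- if (is.array(dr) && length(dim(dr)) == 3L)
      as.vector(outer(seq_len(dim(dr)[2L]), seq_len(dim(dr)[3L]),
                      function(i, j) sprintf("%s[%d,%d]", b, i, j)))
    else if (is.matrix(dr) && ncol(dr) > 1L)
      sprintf("%s[%d]", b, seq_len(ncol(dr)))
    else b
    qs <- apply(M, 2L, stats::quantile, probs = c(0.025, 0.975), names = FALSE)
    rows[[b]] <- data.frame(parameter = nm, mean = colMeans(M),
                            sd = apply(M, 2L, sd),
                            q2.5 = qs[1L, ], q97.5 = qs[2L, ])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
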
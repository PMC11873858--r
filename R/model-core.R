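#' @useDynLib rmixtree, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats pnorm qnorm rnorm runif rWishart uniroot var cor sd
NULL

# smallest probability allowed before taking logs; probit tails underflow
.PROB_FLOOR <- 1e-300

#' Cumulative category probabilities of the probit graded response model
#'
#' Computes `P(X >= k | Z = 1)` for `k = 1..h` in the second node of the
#' tree: `pnorm(alpha2 * theta2 - delta_k)`.
#'
#' @param theta2 Substantive latent trait value(s).
#' @param alpha2 Item slope (nonnegative scalar).
#' @param delta Nondecreasing threshold vector of length `h`.
#' @return A vector of length `h` (or a `length(theta2)` x `h` matrix when
#'   `theta2` has several elements), nonincreasing along `k`.
#' @examples
#' grm_cumulative(0, 0.5, c(0, 0, 0, 0))       # all 0.5
#' grm_cumulative(1, 0.61, c(-1.5, -0.5, 0.5, 1.5))
#' @export
grm_cumulative <- function(theta2, alpha2, delta) {
  check_slope(alpha2, "alpha2")
  check_thresholds(delta)
  out <- pnorm(outer(alpha2 * theta2, delta, `-`))
  if (length(theta2) == 1L) drop(out) else out
}

#' Category probabilities of the probit graded response model
#'
#' Adjacent differences of [grm_cumulative()] giving `P(X = x | Z = 1)` for
#' `x = 0..h`; the result is a probability vector.
#'
#' @inheritParams grm_cumulative
#' @return Probability vector of length `h + 1` (or a matrix with one row
#'   per element of `theta2`).
#' @export
grm_category_probs <- function(theta2, alpha2, delta) {
  cum <- grm_cumulative(theta2, alpha2, delta)
  if (is.matrix(cum)) {
    n <- nrow(cum)
    cbind(1 - cum[, 1L], cum[, -ncol(cum), drop = FALSE] -
            cum[, -1L, drop = FALSE], cum[, ncol(cum)], deparse.level = 0)
  } else {
    c(1 - cum[1L], -diff(cum), cum[length(cum)])
  }
}

#' Probability of an informative response at the first tree node
#'
#' Normal-ogive non-response node: `P(Z = 1) = pnorm(-alpha1 * theta1 -
#' beta)`.  Higher non-response tendency `theta1`, or higher `beta`, lowers
#' the probability that the response is informative.
#'
#' @param theta1 Non-response tendency value(s).
#' @param alpha1 Common first-node slope (nonnegative scalar).
#' @param beta Item parameter; the item intercept is `-beta`.
#' @return Probability (vectorized over `theta1` and/or `beta`).
#' @examples
#' informative_prob(0, 0.61, -1.6)   # pnorm(1.6)
#' @export
informative_prob <- function(theta1, alpha1, beta) {
  check_slope(alpha1, "alpha1")
  pnorm(-alpha1 * theta1 - beta)
}

#' Category probabilities of the full response-mixture tree
#'
#' Probability of each observed score `0..h` for one item under the
#' response-mixture model: a non-middle score requires an informative
#' response followed by that graded-response category, while the middle
#' score `m` pools the non-response path and the informative neutral path.
#'
#' @param theta Length-2 vector `c(theta1, theta2)`.
#' @param items A [item_params()] object.
#' @param space A [likert_space()].
#' @param item Which item of `items` to use (default 1).
#' @return Probability vector over scores `0..h` (sums to 1).
#' @export
response_category_probs <- function(theta, items, space, item = 1L) {
  space <- as_likert_space(space)
  stopifnot(inherits(items, "likert_items"), length(theta) == 2L)
  if (ncol(items$delta) != space$h)
    stop("`items` must carry h thresholds per item for the response-mixture tree")
  p1 <- informative_prob(theta[1L], items$alpha1, items$beta[item])
  g <- grm_category_probs(theta[2L], items$alpha2[item],
                          items$delta[item, ])
  pr <- p1 * g
  pr[space$m + 1L] <- pr[space$m + 1L] + (1 - p1)
  pr
}

#' Probability of a single score under the response-mixture tree
#'
#' @param score Integer score(s) in `0..h`.
#' @inheritParams response_category_probs
#' @return Probability of each requested score.
#' @seealso [response_category_probs()] for the whole category distribution.
#' @export
response_prob <- function(score, theta, items, space, item = 1L) {
  space <- as_likert_space(space)
  if (any(score != round(score)) || any(score < 0) || any(score > space$h))
    stop(sprintf("`score` must be an integer in 0..%d", space$h))
  pr <- response_category_probs(theta, items, space, item)
  pr[score + 1L]
}

#' Posterior probability that an observed middle response is informative
#'
#' Given that person `p` answered the middle category, the probability that
#' the response came through the informative (second-node) path rather than
#' the non-response path:
#' `P(Z=1 | X=m) = P(Z=1) P(X=m | Z=1) / P(X=m)`.
#'
#' @inheritParams response_category_probs
#' @return A probability in `[0, 1]`.
#' @export
posterior_informative_given_middle <- function(theta, items, space, item = 1L) {
  space <- as_likert_space(space)
  p1 <- informative_prob(theta[1L], items$alpha1, items$beta[item])
  gm <- grm_category_probs(theta[2L], items$alpha2[item],
                           items$delta[item, ])[space$m + 1L]
  num <- p1 * gm
  den <- (1 - p1) + num
  if (den < .PROB_FLOOR) {
    warning("middle-category probability underflow; flooring denominator")
    den <- .PROB_FLOOR
  }
  num / den
}

# ---- vectorized cell log-probabilities -------------------------------------

# N x (h+1) matrix of second-node category probabilities for one item
grm_probs_item <- function(theta2, alpha2_i, delta_i) {
  cum <- pnorm(outer(alpha2_i * theta2, delta_i, `-`))
  h <- length(delta_i)
  cbind(1 - cum[, 1L], cum[, -h, drop = FALSE] - cum[, -1L, drop = FALSE],
        cum[, h], deparse.level = 0)
}

# N x K matrix of log P(x_pi | theta_p) under the requested model
cell_loglik <- function(X, theta1, theta2, items, space, model = "rmm") {
  N <- nrow(X); K <- ncol(X)
  out <- matrix(NA_real_, N, K)
  m <- space$m
  for (i in seq_len(K)) {
    x <- X[, i]
    if (model == "grm") {
      g <- grm_probs_item(theta2, items$alpha2[i], items$delta[i, ])
      pr <- g[cbind(seq_len(N), x + 1L)]
    } else if (model == "rmm") {
      p1 <- pnorm(-items$alpha1 * theta1 - items$beta[i])
      g <- grm_probs_item(theta2, items$alpha2[i], items$delta[i, ])
      pr <- p1 * g[cbind(seq_len(N), x + 1L)]
      mid <- x == m
      pr[mid] <- pr[mid] + (1 - p1[if (length(p1) > 1L) mid else 1L])
    } else { # irtree: middle = non-response; node 2 over remapped categories
      p1 <- pnorm(-items$alpha1 * theta1 - items$beta[i])
      xr <- ifelse(X[, i] > m, X[, i] - 1L, X[, i])
      g <- grm_probs_item(theta2, items$alpha2[i], items$delta[i, ])
      pr <- p1 * g[cbind(seq_len(N), xr + 1L)]
      pr[x == m] <- (1 - p1)[if (length(p1) > 1L) x == m else 1L]
    }
    out[, i] <- log(pmax(pr, .PROB_FLOOR))
  }
  out
}

#' Log-likelihood of a score matrix
#'
#' Sum over persons and items of the log response probabilities under the
#' response-mixture model, the graded response model, or the IRTree
#' baseline (in which every middle response is a non-response and the
#' second node spans only the non-middle categories).
#'
#' @param data Integer N x K score matrix.
#' @param theta N x 2 matrix of person parameters (column 1 = non-response
#'   tendency, column 2 = substantive trait).  For `model = "grm"` an
#'   N-vector of `theta2` values is also accepted.
#' @param items A [item_params()] object (with `h` thresholds per item for
#'   `"rmm"`/`"grm"`, `h - 1` for `"irtree"`).
#' @param space A [likert_space()].
#' @param model One of `"rmm"`, `"grm"`, `"irtree"`.
#' @return A single log-likelihood value (finite for finite parameters).
#' @export
log_likelihood <- function(data, theta, items, space,
                           model = c("rmm", "grm", "irtree")) {
  model <- match.arg(model)
  space <- as_likert_space(space)
  data <- validate_scores(data, space)
  if (is.vector(theta)) theta <- cbind(theta1 = 0, theta2 = theta)
  if (nrow(theta) != nrow(data))
    stop("`theta` and `data` disagree on the number of persons")
  if (items$K != ncol(data))
    stop("`items` and `data` disagree on the number of items")
  expected_h <- if (model == "irtree") space$h - 1L else space$h
  if (ncol(items$delta) != expected_h)
    stop(sprintf("model '%s' needs %d thresholds per item", model, expected_h))
  sum(cell_loglik(data, theta[, 1L], theta[, 2L], items, space, model))
}

# ---- Gauss-Hermite marginalization of theta1 --------------------------------

.gh_cache <- new.env(parent = emptyenv())

gh_nodes <- function(n) {
  key <- as.character(n)
  if (is.null(.gh_cache[[key]]))
    .gh_cache[[key]] <- pracma::gaussHermite(n)
  .gh_cache[[key]]
}

#' Per-person log-likelihood with the non-response trait integrated out
#'
#' For each person the conditional likelihood of their responses given
#' `theta2` is integrated over the non-response tendency `theta1` under its
#' conditional normal distribution implied by `(mu, Sigma)`, using
#' Gauss-Hermite quadrature.  Used by [dic()] for the tree-based models.
#'
#' @param data Integer N x K score matrix (a single person's responses may
#'   be given as a 1 x K matrix or a vector).
#' @param theta2 Vector of substantive trait values, one per person.
#' @param items A [item_params()] object.
#' @param mu Length-2 latent population mean.
#' @param Sigma 2 x 2 latent population covariance (positive definite).
#' @param space A [likert_space()].
#' @param n_nodes Number of quadrature nodes (default 10).
#' @param model `"rmm"` or `"irtree"`.
#' @return Vector of per-person marginal log-likelihood values.
#' @export
marginal_loglik_theta1 <- function(data, theta2, items, mu, Sigma, space,
                                   n_nodes = 10L, model = c("rmm", "irtree")) {
  model <- match.arg(model)
  space <- as_likert_space(space)
  if (is.vector(data)) data <- matrix(as.integer(data), nrow = 1L)
  data <- validate_scores(data, space)
  if (n_nodes < 2L) stop("`n_nodes` must be at least 2")
  ev <- eigen(Sigma, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) stop("`Sigma` must be positive definite")
  N <- nrow(data)
  # conditional normal theta1 | theta2
  mc <- mu[1L] + Sigma[1L, 2L] / Sigma[2L, 2L] * (theta2 - mu[2L])
  vc <- Sigma[1L, 1L] - Sigma[1L, 2L]^2 / Sigma[2L, 2L]
  gh <- gh_nodes(n_nodes)
  scale <- sqrt(2 * max(vc, 0))
  logw <- log(gh$w) - 0.5 * log(pi)
  K <- ncol(data)
  m <- space$m
  is_mid <- data == m
  # second-node pieces are free of theta1: compute them once
  lg_nonmid <- matrix(0, N, K)   # log g_x for informative (non-middle) cells
  g_mid <- matrix(0, N, K)       # g_m for middle cells (rmm mixture only)
  for (i in seq_len(K)) {
    if (model == "rmm") {
      g <- grm_probs_item(theta2, items$alpha2[i], items$delta[i, ])
      pr <- g[cbind(seq_len(N), data[, i] + 1L)]
      g_mid[, i] <- ifelse(is_mid[, i], pr, 0)
    } else { # irtree second node over remapped non-middle categories
      xr <- ifelse(data[, i] > m, data[, i] - 1L, data[, i])
      g <- grm_probs_item(theta2, items$alpha2[i], items$delta[i, ])
      pr <- g[cbind(seq_len(N), xr + 1L)]
    }
    lg_nonmid[, i] <- ifelse(is_mid[, i], 0, log(pmax(pr, .PROB_FLOOR)))
  }
  base_ll <- rowSums(lg_nonmid)
  ll_nodes <- matrix(NA_real_, N, n_nodes)
  for (j in seq_len(n_nodes)) {
    t1 <- mc + scale * gh$x[j]
    p1 <- pnorm(outer(-items$alpha1 * t1, items$beta, `-`))
    if (model == "rmm") {
      cell <- ifelse(is_mid, (1 - p1) + p1 * g_mid, p1)
    } else {
      cell <- ifelse(is_mid, 1 - p1, p1)
    }
    ll_nodes[, j] <- base_ll + rowSums(log(pmax(cell, .PROB_FLOOR)))
  }
  ll_nodes <- sweep(ll_nodes, 2L, logw, `+`)
  mx <- apply(ll_nodes, 1L, max)
  mx + log(rowSums(exp(ll_nodes - mx)))
}

# ---- small validators -------------------------------------------------------

check_slope <- function(a, name) {
  if (length(a) != 1L || !is.finite(a) || a < 0)
    stop(sprintf("`%s` must be a single nonnegative number", name))
  invisible(a)
}

check_thresholds <- function(delta) {
  if (is.unsorted(delta, strictly = FALSE))
    stop("thresholds must be nondecreasing")
  invisible(delta)
}
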
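#' Identification rescaling of one posterior draw
#'
#' The latent population mean and covariance are sampled freely during the
#' Gibbs run; for identification each draw is mapped to the standardized
#' scale: latent traits are centered at `mu` and divided by the latent
#' standard deviations, `mu` becomes `(0, 0)`, `Sigma` becomes the
#' correlation matrix, and compensating affine transforms are applied to
#' the item parameters so the likelihood is unchanged:
#' `alpha1' = alpha1 * s1`, `beta' = beta + alpha1 * mu1`,
#' `alpha2' = alpha2 * s2`, `delta'[i, ] = delta[i, ] - alpha2[i] * mu2`.
#'
#' @param draw A list with elements `theta` (N x 2), `mu` (length 2),
#'   `Sigma` (2 x 2), `alpha1`, `beta`, `alpha2`, `delta`.
#' @return The rescaled draw (same structure).
#' @examples
#' dr <- list(theta = cbind(rnorm(5, 1, 2), rnorm(5)), mu = c(1, 0),
#'            Sigma = matrix(c(4, 0.6, 0.6, 1), 2), alpha1 = 0.6,
#'            beta = c(-1.5, -2), alpha2 = c(0.5, 0.7),
#'            delta = rbind(c(-1, 0, 1, 2), c(-2, -1, 0, 1)))
#' rs <- rescale_identification(dr)
#' rs$mu; diag(rs$Sigma)
#' @export
rescale_identification <- function(draw) {
  s <- sqrt(diag(draw$Sigma))
  if (any(!is.finite(s)) || any(s <= 0))
    stop("latent variances must be positive for identification rescaling")
  mu <- draw$mu
  out <- draw
  out$theta <- sweep(sweep(draw$theta, 2L, mu), 2L, s, `/`)
  out$alpha1 <- draw$alpha1 * s[1L]
  out$beta <- draw$beta + draw$alpha1 * mu[1L]
  out$alpha2 <- draw$alpha2 * s[2L]
  out$delta <- draw$delta - draw$alpha2 * mu[2L]
  out$Sigma <- draw$Sigma / tcrossprod(s)
  out$mu <- c(0, 0)
  out
}

#' Redraw the latent informativeness indicators at fixed parameters
#'
#' For each observed middle-category response the path indicator `Z` is
#' drawn from its conditional posterior
#' [posterior_informative_given_middle()]; all other cells are informative
#' by observation (`Z = 1`).
#'
#' @param data Integer N x K score matrix.
#' @param theta N x 2 matrix of person parameters.
#' @param items A [item_params()] object.
#' @param space A [likert_space()].
#' @return An integer N x K matrix of 0/1 indicators.
#' @export
sample_latent_indicators <- function(data, theta, items, space) {
  space <- as_likert_space(space)
  data <- validate_scores(data, space)
  N <- nrow(data); K <- ncol(data)
  Z <- matrix(1L, N, K)
  m <- space$m
  for (i in seq_len(K)) {
    mid <- which(data[, i] == m)
    if (length(mid) == 0L) next
    p1 <- informative_prob(theta[mid, 1L], items$alpha1, items$beta[i])
    cum <- pnorm(outer(items$alpha2[i] * theta[mid, 2L], items$delta[i, ], `-`))
    gm <- cum[, m] - cum[, m + 1L]
    num <- p1 * gm
    post <- num / pmax((1 - p1) + num, .PROB_FLOOR)
    Z[mid, i] <- as.integer(runif(length(mid)) < post)
  }
  Z
}
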
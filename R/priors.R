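#' Prior specification for the Gibbs samplers
#'
#' Low-informative semi-conjugate priors: normal priors (variance
#' `slope_var`) truncated to nonnegative values for the slopes, a normal
#' prior for the first-node item parameters `beta`, a flat prior on the
#' ordered threshold region within `[threshold_lo, threshold_hi]`, an
#' improper flat prior for the latent mean, and an inverse-Wishart prior
#' for the latent covariance.
#'
#' @param alpha1_mean,alpha1_var Prior mean/variance of the common
#'   first-node slope before truncation at 0 (defaults 0.5, 4).
#' @param beta_mean,beta_var Prior mean/variance of each `beta[i]`
#'   (defaults -2, 4).
#' @param alpha2_mean,alpha2_var Prior mean/variance of each second-node
#'   slope before truncation at 0 (defaults 0.5, 4).
#' @param threshold_lo,threshold_hi Bounds of the flat ordered-threshold
#'   prior (defaults -5, 5).
#' @param sigma_df,sigma_scale Inverse-Wishart degrees of freedom and scale
#'   matrix for the 2 x 2 latent covariance (defaults 4 and the identity).
#' @return An object of class `prior_spec`.
#' @export
prior_spec <- function(alpha1_mean = 0.5, alpha1_var = 4,
                       beta_mean = -2, beta_var = 4,
                       alpha2_mean = 0.5, alpha2_var = 4,
                       threshold_lo = -5, threshold_hi = 5,
                       sigma_df = 4, sigma_scale = diag(2)) {
  if (threshold_lo >= threshold_hi) stop("threshold bounds out of order")
  if (sigma_df <= nrow(sigma_scale) + 1)
    stop("`sigma_df` must exceed dimension + 1 for a proper prior")
  structure(list(alpha1_mean = alpha1_mean, alpha1_var = alpha1_var,
                 beta_mean = beta_mean, beta_var = beta_var,
                 alpha2_mean = alpha2_mean, alpha2_var = alpha2_var,
                 threshold_lo = threshold_lo, threshold_hi = threshold_hi,
                 sigma_df = sigma_df, sigma_scale = sigma_scale),
            class = "prior_spec")
}

#' @export
print.prior_spec <- function(x, ...) {
  cat("Prior specification:\n")
  cat(sprintf("  alpha1 ~ N(%.2f, %.2f) truncated >= 0 (shared)\n",
              x$alpha1_mean, x$alpha1_var))
  cat(sprintf("  beta_i ~ N(%.2f, %.2f)\n", x$beta_mean, x$beta_var))
  cat(sprintf("  alpha2_i ~ N(%.2f, %.2f) truncated >= 0\n",
              x$alpha2_mean, x$alpha2_var))
  cat(sprintf("  thresholds flat on the ordered region in [%.1f, %.1f]\n",
              x$threshold_lo, x$threshold_hi))
  cat(sprintf("  mu flat (improper); Sigma ~ inv-Wishart(df %g, scale I)\n",
              x$sigma_df))
  invisible(x)
}

#' Chain configuration for the Gibbs samplers
#'
#' @param model One of `"rmm"` (response-mixture tree), `"grm"` (graded
#'   response model; no first node) or `"irtree"` (every middle response is
#'   a non-response).
#' @param n_iterations Total number of Gibbs iterations (default 2500).
#' @param burnin Iterations discarded before retention (default 500).
#' @param thin Keep every `thin`-th post-burnin iteration (default 2).
#' @param seed RNG seed for the run (integer) or `NULL` to use the current
#'   RNG state.
#' @param store_z `"mean"` (default) keeps the running posterior mean of the
#'   informativeness indicators; `"none"` skips them.
#' @return An object of class `chain_config`.
#' @export
chain_config <- function(model = c("rmm", "grm", "irtree"),
                         n_iterations = 2500L, burnin = 500L, thin = 2L,
                         seed = NULL, store_z = c("mean", "none")) {
  model <- match.arg(model)
  store_z <- match.arg(store_z)
  if (burnin >= n_iterations) stop("`burnin` must be smaller than `n_iterations`")
  if (thin < 1L) stop("`thin` must be at least 1")
  structure(list(model = model, n_iterations = as.integer(n_iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = seed, store_z = store_z),
            class = "chain_config")
}
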
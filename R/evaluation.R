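#' Deviance information criterion of a fitted model
#'
#' `DIC = 2 * mean posterior deviance - deviance at the posterior means`
#' (the Spiegelhalter pD variant).  For the tree-based models (`"rmm"`,
#' `"irtree"`) the deviance is `-2` times the log-likelihood with the
#' non-response trait integrated out by Gauss-Hermite quadrature
#' ([marginal_loglik_theta1()], 10 nodes by default), conditioning on
#' `theta2`, the item parameters and the latent moments; the plain
#' conditional likelihood is used for the `"grm"` (which has no `theta1`).
#'
#' @param fit A `likert_fit` with at least one retained draw.
#' @param data The integer score matrix the model was fitted to.
#' @param n_nodes Gauss-Hermite node count for the theta1 integral.
#' @return The DIC value, with attributes `pD`, `mean_deviance` and
#'   `deviance_at_means`.
#' @export
dic <- function(fit, data, n_nodes = 10L) {
  stopifnot(inherits(fit, "likert_fit"))
  if (fit$dim["retained"] < 1L) stop("empty chain: no retained draws")
  space <- fit$space
  data <- validate_scores(data, space)
  D <- fit$dim["retained"]
  devs <- numeric(D)
  for (d in seq_len(D)) {
    devs[d] <- deviance_draw(fit, data, d, n_nodes)
  }
  dbar <- mean(devs)
  dhat <- deviance_at_means(fit, data, n_nodes)
  out <- 2 * dbar - dhat
  attributes(out) <- list(pD = dbar - dhat, mean_deviance = dbar,
                          deviance_at_means = dhat)
  out
}

deviance_draw <- function(fit, data, d, n_nodes) {
  dr <- fit$draws
  items <- item_params(
    alpha1 = if (fit$model == "grm") 0 else dr$alpha1[d],
    beta = if (fit$model == "grm") rep(0, fit$dim["K"]) else dr$beta[d, ],
    alpha2 = dr$alpha2[d, ],
    delta = matrix(dr$delta[d, , ], nrow = fit$dim["K"]))
  theta2 <- dr$theta2[d, ]
  if (fit$model == "grm") {
    -2 * sum(cell_loglik(data, NULL, theta2, items, fit$space, "grm"))
  } else {
    Sg <- matrix(dr$Sigma[d, , ], 2L)
    -2 * sum(marginal_loglik_theta1(data, theta2, items, dr$mu[d, ], Sg,
                                    fit$space, n_nodes, fit$model))
  }
}

deviance_at_means <- function(fit, data, n_nodes) {
  items <- posterior_items(fit)
  theta2 <- colMeans(fit$draws$theta2)
  if (fit$model == "grm") {
    -2 * sum(cell_loglik(data, NULL, theta2, items, fit$space, "grm"))
  } else {
    Sg <- apply(fit$draws$Sigma, c(2L, 3L), mean)
    Sg <- (Sg + t(Sg)) / 2
    mu <- colMeans(fit$draws$mu)
    -2 * sum(marginal_loglik_theta1(data, theta2, items, mu, Sg,
                                    fit$space, n_nodes, fit$model))
  }
}

#' Recovery metrics of point estimates against known truth
#'
#' Across-replication summaries for one parameter block: for each unit
#' (person or item parameter) the bias is the mean over replications of
#' `estimate - truth`; `avg_abs_bias` averages the absolute biases over
#' units, `variance` averages the across-replication variance of the
#' estimates (denominator R, so the decomposition
#' `mse = mean squared bias + variance` holds exactly unit by unit), and
#' `mse` averages the mean squared errors.
#'
#' @param truth Numeric vector of generating values (length P).
#' @param estimates P x R matrix of point estimates, one column per
#'   replication.
#' @return An object of class `recovery_metrics`: a list with
#'   `avg_abs_bias`, `variance`, `mse`, the number of replications, and the
#'   per-unit `bias` vector.
#' @examples
#' truth <- c(0, 1, -1)
#' est <- truth + 0.2      # constant shift in a single replication
#' recovery_metrics(truth, cbind(est, est))
#' @export
recovery_metrics <- function(truth, estimates) {
  estimates <- as.matrix(estimates)
  if (nrow(estimates) != length(truth))
    stop("`estimates` must have one row per element of `truth`")
  if (ncol(estimates) < 1L) stop("at least one replication is required")
  R <- ncol(estimates)
  err <- estimates - truth
  bias <- rowMeans(err)
  vr <- rowMeans((estimates - rowMeans(estimates))^2)
  mse <- rowMeans(err^2)
  structure(list(avg_abs_bias = mean(abs(bias)), variance = mean(vr),
                 mse = mean(mse), n_replications = R, bias = bias),
            class = "recovery_metrics")
}

#' @export
print.recovery_metrics <- function(x, ...) {
  cat(sprintf("Recovery over %d replication(s): avg |bias| = %.4f, variance = %.4f, MSE = %.4f\n",
              x$n_replications, x$avg_abs_bias, x$variance, x$mse))
  invisible(x)
}

#' Posterior summary of the non-informative response share
#'
#' Uses the posterior mean of the informativeness indicator stored by the
#' response-mixture sampler: for every observed middle-category response
#' the posterior probability that it was a non-response, `P(Z = 0 | X)`,
#' and 0 for every other cell.  Averages are reported per person, per item,
#' over the whole matrix, and restricted to middle-category cells.
#'
#' @param fit A `likert_fit` with `model = "rmm"` (fitted with
#'   `store_z = "mean"`).
#' @param data The score matrix the model was fitted to.
#' @return An object of class `nr_summary`: a list with `overall`,
#'   `among_middle`, `per_person`, `per_item` and `middle_share` (the raw
#'   fraction of middle responses).
#' @export
nr_summary <- function(fit, data) {
  stopifnot(inherits(fit, "likert_fit"))
  if (fit$model != "rmm" || is.null(fit$zbar))
    stop("non-informativeness summaries need an RMM fit with stored indicators")
  data <- validate_scores(data, fit$space)
  pnc <- (1 - fit$zbar) * (data == fit$space$m)
  mid <- data == fit$space$m
  structure(list(overall = mean(pnc),
                 among_middle = if (any(mid)) mean(pnc[mid]) else 0,
                 per_person = rowMeans(pnc),
                 per_item = colMeans(pnc),
                 middle_share = mean(mid)),
            class = "nr_summary")
}

#' @export
print.nr_summary <- function(x, ...) {
  cat(sprintf("Estimated non-informative responses: %.2f%% of all responses\n",
              100 * x$overall))
  cat(sprintf("  %.2f%% of middle-category responses (middle share %.2f%%)\n",
              100 * x$among_middle, 100 * x$middle_share))
  invisible(x)
}
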
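#' Item parameters of the response-mixture tree
#'
#' Bundles the item parameters of the two tree nodes.  The first node is a
#' normal-ogive non-response model with one common slope `alpha1` and an item
#' intercept `-beta[i]`; the second node is a probit graded response model
#' with per-item slopes `alpha2` and ordered thresholds `delta`.
#'
#' For the response-mixture model and the plain graded response model the
#' threshold matrix has `h` columns (the second node spans all `h + 1`
#' categories, including the middle one).  For the IRTree baseline, whose
#' second node spans only the `h` non-middle categories, it has `h - 1`
#' columns.
#'
#' @param alpha1 Common first-node slope (single nonnegative number).
#' @param beta Numeric vector of length K; item `i`'s first-node intercept
#'   is `-beta[i]`, so larger `beta` means a lower non-response probability.
#' @param alpha2 Numeric vector of length K of nonnegative second-node slopes.
#' @param delta Numeric K x h (or K x (h-1)) matrix of thresholds, each row
#'   nondecreasing.  Ties are allowed (they give a zero-probability
#'   category); the prior truncates thresholds to `[-5, 5]`.
#'
#' @return An object of class `likert_items` (a list with the four
#'   components and `K`, the number of items).
#' @examples
#' it <- item_params(alpha1 = 0.61, beta = c(-1.6, -1.4),
#'                   alpha2 = c(0.5, 0.7),
#'                   delta = rbind(c(-1.5, -0.5, 0.5, 1.5),
#'                                 c(-2, -1, 1, 2)))
#' it
#' @export
item_params <- function(alpha1, beta, alpha2, delta) {
  if (length(alpha1) != 1L || !is.finite(alpha1) || alpha1 < 0)
    stop("`alpha1` must be a single nonnegative number")
  beta <- as.numeric(beta)
  alpha2 <- as.numeric(alpha2)
  if (is.vector(delta)) delta <- matrix(delta, nrow = 1L)
  delta <- as.matrix(delta)
  K <- length(beta)
  if (length(alpha2) != K || nrow(delta) != K)
    stop("`beta`, `alpha2` and rows of `delta` must agree in length")
  if (any(!is.finite(alpha2)) || any(alpha2 < 0))
    stop("all `alpha2` must be nonnegative")
  if (any(!is.finite(delta)))
    stop("thresholds must be finite")
  unordered <- apply(delta, 1L, is.unsorted, strictly = FALSE)
  if (any(unordered))
    stop(sprintf("thresholds of item %d are not nondecreasing",
                 which(unordered)[1L]))
  structure(list(alpha1 = as.numeric(alpha1), beta = beta, alpha2 = alpha2,
                 delta = delta, K = K),
            class = "likert_items")
}

#' @export
print.likert_items <- function(x, ...) {
  cat(sprintf("Item parameters for %d item(s), %d threshold(s) per item\n",
              x$K, ncol(x$delta)))
  cat(sprintf("  node 1: common slope alpha1 = %.3f, beta in [%.3f, %.3f]\n",
              x$alpha1, min(x$beta), max(x$beta)))
  cat(sprintf("  node 2: alpha2 in [%.3f, %.3f], thresholds in [%.3f, %.3f]\n",
              min(x$alpha2), max(x$alpha2), min(x$delta), max(x$delta)))
  invisible(x)
}

#' @export
`[.likert_items` <- function(x, i) {
  item_params(x$alpha1, x$beta[i], x$alpha2[i], x$delta[i, , drop = FALSE])
}

#' @export
length.likert_items <- function(x) x$K

#' @export
as.data.frame.likert_items <- function(x, ...) {
  d <- as.data.frame(x$delta)
  names(d) <- paste0("delta", seq_len(ncol(d)))
  cbind(data.frame(item = seq_len(x$K), alpha1 = x$alpha1,
                   beta = x$beta, alpha2 = x$alpha2), d)
}
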
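#' Generate a bank of person parameters
#'
#' Non-response tendency `theta1` and substantive trait `theta2` are drawn
#' independently from the standard normal distribution.  The same bank is
#' reused across replications and conditions of a simulation study; a
#' doubled sample size reuses the bank twice.
#'
#' @param n Number of persons.
#' @param seed Optional RNG seed.
#' @return An `n` x 2 matrix with columns `theta1`, `theta2`.
#' @export
generate_person_bank <- function(n, seed = NULL) {
  if (n < 1L) stop("`n` must be at least 1")
  if (!is.null(seed)) set.seed(seed)
  matrix(rnorm(2L * n), n, 2L, dimnames = list(NULL, c("theta1", "theta2")))
}

#' Generate a bank of item parameters
#'
#' Builds the item bank used by the recovery study, for 5-category items:
#' a location `gamma_i` equidistant on `[-1, 1]` over the 25-item bank;
#' four thresholds drawn uniformly from `[-2,-1]`, `[-1,0]`, `[0,1]`,
#' `[1,2]`, redrawn until every adjacent gap exceeds 0.5, then shifted by
#' `gamma_i`; second-node slopes `alpha2 ~ U(0.44, 0.78)`; a common
#' first-node slope `alpha1 = 0.61`; and first-node parameters `beta`
#' drawn with SD 0.2 around the mean calibrated (via
#' [calibrate_beta_mean()]) so the marginal non-response rate equals
#' `nr_rate`.  With `nr_rate = 0` every `beta` is set to `-1000`, which
#' shuts the non-response path off entirely.
#'
#' @param k Number of items: 25 (the bank) or 50 (the bank used twice).
#' @param nr_rate Target overall share of non-informative responses
#'   (0, or in (0, 1)).
#' @param seed Optional RNG seed.
#' @param alpha1 Common first-node slope (default 0.61).
#' @param beta_sd Spread of the `beta` draws (default 0.2).
#' @return A [item_params()] object with attribute `gamma` (locations) and
#'   `beta_mean` (the calibrated mean).
#' @export
generate_item_bank <- function(k = 25L, nr_rate = 0.2, seed = NULL,
                               alpha1 = 0.61, beta_sd = 0.2) {
  if (!is.null(seed)) set.seed(seed)
  if (!is.finite(nr_rate) || nr_rate < 0 || nr_rate >= 1)
    stop("`nr_rate` must be 0 or in (0, 1)")
  bank_k <- if (k > 25L) 25L else as.integer(k)
  gamma <- if (bank_k == 1L) 0 else seq(-1, 1, length.out = bank_k)
  lo <- c(-2, -1, 0, 1); hi <- c(-1, 0, 1, 2)
  delta <- matrix(NA_real_, bank_k, 4L)
  for (i in seq_len(bank_k)) {
    repeat {
      d <- lo + runif(4L) * (hi - lo)
      if (all(diff(d) > 0.5)) break
    }
    delta[i, ] <- d + gamma[i]
  }
  alpha2 <- runif(bank_k, 0.44, 0.78)
  if (nr_rate == 0) {
    beta <- rep(-1000, bank_k)
    beta_mean <- -1000
  } else {
    beta_mean <- calibrate_beta_mean(nr_rate, alpha1 = alpha1,
                                     beta_sd = beta_sd)
    beta <- rnorm(bank_k, beta_mean, beta_sd)
  }
  idx <- rep_len(seq_len(bank_k), k)  # k = 50 reuses the bank twice
  out <- item_params(alpha1, beta[idx], alpha2[idx],
                     delta[idx, , drop = FALSE])
  attr(out, "gamma") <- gamma[idx]
  attr(out, "beta_mean") <- beta_mean
  out
}

#' Calibrate the first-node intercept mean to a target non-response rate
#'
#' Under the tree, a response is non-informative with probability
#' `1 - pnorm(-alpha1 * theta1 - beta)`.  Marginalizing over
#' `theta1 ~ N(0, 1)` and `beta ~ N(beta_mean, beta_sd^2)` gives the
#' overall rate `pnorm(beta_mean / sqrt(1 + alpha1^2 + beta_sd^2))`.
#' The function root-solves this marginal for the `beta` mean that attains
#' `target` exactly.
#'
#' @param target Desired overall fraction of non-informative responses,
#'   in (0, 1).
#' @param alpha1 Common first-node slope.
#' @param beta_sd Spread of the item `beta` values.
#' @return The calibrated `beta` mean, with attributes `target` and
#'   `achieved` (the marginal rate at the returned mean).
#' @examples
#' calibrate_beta_mean(0.5, alpha1 = 0, beta_sd = 0)  # 0 by symmetry
#' calibrate_beta_mean(0.2)                           # about -1.0
#' @export
calibrate_beta_mean <- function(target, alpha1 = 0.61, beta_sd = 0.2) {
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop("`target` must be in (0, 1)")
  check_slope(alpha1, "alpha1")
  s <- sqrt(1 + alpha1^2 + beta_sd^2)
  f <- function(b) pnorm(b / s) - target
  root <- uniroot(f, lower = -40, upper = 40, tol = 1e-10)$root
  structure(root, target = target, achieved = pnorm(root / s))
}

#' Simulate responses from the response-mixture tree
#'
#' Traverses the decision tree cell by cell: the path indicator is drawn
#' with probability [informative_prob()]; a non-informative response emits
#' the middle category, an informative one a category from the second-node
#' graded response model.
#'
#' @param persons N x 2 matrix of `(theta1, theta2)`.
#' @param items A [item_params()] object with `h` thresholds per item.
#' @param space A [likert_space()].
#' @param seed Optional RNG seed.
#' @return A list with `scores` (integer N x K matrix) and `Z` (the true
#'   informativeness indicators).
#' @export
generate_responses <- function(persons, items, space, seed = NULL) {
  space <- as_likert_space(space)
  if (!is.null(seed)) set.seed(seed)
  if (ncol(items$delta) != space$h)
    stop("`items` must carry h thresholds per item")
  N <- nrow(persons); K <- items$K
  p1 <- pnorm(outer(-items$alpha1 * persons[, 1L], items$beta, `-`))
  Z <- matrix(as.integer(runif(N * K) < p1), N, K)
  eta2 <- outer(persons[, 2L], items$alpha2)
  y2 <- eta2 + matrix(rnorm(N * K), N, K)
  # informative category = number of thresholds below the latent propensity
  X <- matrix(0L, N, K)
  for (k in seq_len(space$h))
    X <- X + (y2 > matrix(items$delta[, k], N, K, byrow = TRUE))
  X[Z == 0L] <- space$m
  storage.mode(X) <- "integer"
  list(scores = X, Z = Z)
}

#' Design of a parameter-recovery simulation study
#'
#' @param N Persons per replication (a value above the person-bank size
#'   reuses the bank; 2000 uses the 1000-person bank twice).
#' @param K Items (25 uses the item bank once, 50 twice).
#' @param nr_rate Overall non-informative response rate (0.2, 0.1 or 0).
#' @param n_replications Number of generated data sets (the full study
#'   used 100; desk-scale runs use 10).
#' @param chain List with `n_iterations`, `burnin`, `thin` for the fits.
#' @param models Models fitted to every replication.
#' @param seed Study master seed; replication and chain seeds are derived
#'   from it deterministically.
#' @param person_bank_n Size of the person bank (default 1000).
#' @return An object of class `simulation_design`.
#' @export
simulation_design <- function(N = 1000L, K = 25L, nr_rate = 0.2,
                              n_replications = 10L,
                              chain = list(n_iterations = 1500L,
                                           burnin = 300L, thin = 2L),
                              models = c("rmm", "grm"), seed = 1L,
                              person_bank_n = 1000L) {
  models <- match.arg(models, c("rmm", "grm", "irtree"), several.ok = TRUE)
  structure(list(N = as.integer(N), K = as.integer(K), nr_rate = nr_rate,
                 n_replications = as.integer(n_replications), chain = chain,
                 models = models, seed = as.integer(seed),
                 person_bank_n = as.integer(person_bank_n)),
            class = "simulation_design")
}

# deterministic per-replication / per-model seed stream, kept below 2^31
derive_seed <- function(seed, rep, model_idx = 0L) {
  (as.numeric(seed) * 97 + rep * 7919 + model_idx * 131071) %% 2147483629
}

#' Run a parameter-recovery simulation study
#'
#' Generates `n_replications` data sets from the response-mixture tree
#' under the design's condition, fits each requested model to every data
#' set, and aggregates posterior-mean point estimates into
#' [recovery_metrics()] for the parameter blocks shared by the models
#' (`theta2`, `alpha2`, `delta`).
#'
#' @param design A [simulation_design()].
#' @param verbose Print per-replication progress.
#' @return An object of class `simulation_result`: a list with `design`,
#'   `truth` (person bank, item bank), `metrics` (per model, per block),
#'   `estimates` (per model: `theta2` N x R, `alpha2` K x R, `delta`
#'   K x h x R matrices of posterior means) and `failures`.
#' @export
run_simulation_study <- function(design, verbose = FALSE) {
  stopifnot(inherits(design, "simulation_design"))
  space <- likert_space(4L)
  persons_bank <- generate_person_bank(design$person_bank_n,
                                       seed = derive_seed(design$seed, 0L, 1L))
  persons <- persons_bank[rep_len(seq_len(design$person_bank_n), design$N), ,
                          drop = FALSE]
  items <- generate_item_bank(design$K, design$nr_rate,
                              seed = derive_seed(design$seed, 0L, 2L))
  R <- design$n_replications
  h <- space$h
  est <- lapply(design$models, function(m)
    list(theta2 = matrix(NA_real_, design$N, R),
         alpha2 = matrix(NA_real_, design$K, R),
         delta = array(NA_real_, c(design$K, h, R))))
  names(est) <- design$models
  failures <- list()
  for (r in seq_len(R)) {
    sim <- generate_responses(persons, items, space,
                              seed = derive_seed(design$seed, r, 0L))
    for (mi in seq_along(design$models)) {
      model <- design$models[mi]
      res <- tryCatch({
        cfg <- chain_config(model,
                            n_iterations = design$chain$n_iterations,
                            burnin = design$chain$burnin,
                            thin = design$chain$thin,
                            seed = derive_seed(design$seed, r, mi))
        fit <- fit_likert(sim$scores, space, cfg)
        est[[model]]$theta2[, r] <- coef(fit, "theta2")
        est[[model]]$alpha2[, r] <- coef(fit, "alpha2")
        est[[model]]$delta[, , r] <- coef(fit, "delta")
        NULL
      }, error = function(e) conditionMessage(e))
      if (!is.null(res)) {
        failures[[length(failures) + 1L]] <-
          list(replication = r, model = model, message = res)
        warning(sprintf("replication %d, model %s failed: %s", r, model, res))
      }
    }
    if (verbose) message(sprintf("replication %d / %d done", r, R))
  }
  metrics <- lapply(design$models, function(model) {
    ok <- !apply(est[[model]]$theta2, 2L, anyNA)
    list(theta2 = recovery_metrics(persons[, 2L],
                                   est[[model]]$theta2[, ok, drop = FALSE]),
         alpha2 = recovery_metrics(items$alpha2,
                                   est[[model]]$alpha2[, ok, drop = FALSE]),
         delta = recovery_metrics(as.vector(items$delta),
                                  apply(est[[model]]$delta[, , ok, drop = FALSE],
                                        3L, as.vector)))
  })
  names(metrics) <- design$models
  structure(list(design = design, space = space,
                 truth = list(persons = persons, items = items),
                 metrics = metrics, estimates = est, failures = failures),
            class = "simulation_result")
}

#' @export
print.simulation_result <- function(x, ...) {
  d <- x$design
  cat(sprintf("Recovery study: N = %d, K = %d, NR-rate = %.0f%%, %d replication(s)\n",
              d$N, d$K, 100 * d$nr_rate, d$n_replications))
  print(as.data.frame(x), digits = 4)
  invisible(x)
}

#' Tabulate a simulation result
#'
#' One row per model x parameter block with the three recovery metrics —
#' the shape used for condition-level result tables.
#'
#' @param x A `simulation_result`.
#' @param ... Unused.
#' @return A data frame.
#' @export
as.data.frame.simulation_result <- function(x, ...) {
  rows <- list()
  for (model in names(x$metrics))
    for (block in names(x$metrics[[model]])) {
      mm <- x$metrics[[model]][[block]]
      rows[[paste(model, block)]] <-
        data.frame(N = x$design$N, K = x$design$K,
                   nr_rate = x$design$nr_rate, model = model, block = block,
                   avg_abs_bias = mm$avg_abs_bias, variance = mm$variance,
                   mse = mm$mse)
    }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
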
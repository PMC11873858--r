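#' Read a response matrix from a delimited text file
#'
#' One row per respondent, one column per item, integer scores `0..h`,
#' comma-delimited, with an optional header row.  Validation reports the
#' offending cell for out-of-range or non-integer values; ragged rows are
#' rejected by the reader.
#'
#' @param path Path to the CSV file.
#' @param space A [likert_space()].
#' @param header Does the file carry a header row?  `NA` (default)
#'   auto-detects by checking whether the first row parses as numbers.
#' @return A validated integer matrix with attributes `n_persons`,
#'   `n_items`, `category_freq` (per-item category frequencies) and
#'   `middle_share`.
#' @export
read_response_matrix <- function(path, space, header = NA) {
  space <- as_likert_space(space)
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  if (is.na(header)) {
    first <- strsplit(readLines(path, n = 1L), ",")[[1L]]
    header <- anyNA(suppressWarnings(as.numeric(first)))
  }
  df <- utils::read.csv(path, header = header)
  mat <- as.matrix(df)
  if (!is.numeric(mat)) {
    bad <- which(is.na(suppressWarnings(matrix(as.numeric(mat), nrow(mat)))),
                 arr.ind = TRUE)[1L, ]
    stop(sprintf("non-numeric score at row %d, column %d", bad[1L], bad[2L]))
  }
  mat <- validate_scores(mat, space)
  dimnames(mat) <- NULL
  attr(mat, "n_persons") <- nrow(mat)
  attr(mat, "n_items") <- ncol(mat)
  attr(mat, "category_freq") <-
    apply(mat, 2L, function(x) tabulate(x + 1L, nbins = space$n_categories))
  attr(mat, "middle_share") <- mean(mat == space$m)
  mat
}

#' Write a response matrix as CSV
#'
#' @param data Integer score matrix.
#' @param path Output path.
#' @param header Write a header row of item names (default TRUE).
#' @return `path`, invisibly.
#' @export
write_response_matrix <- function(data, path, header = TRUE) {
  df <- as.data.frame(data)
  names(df) <- paste0("item", seq_len(ncol(df)))
  utils::write.csv(df, path, row.names = FALSE)
  if (!header) {
    # rewrite without the header line
    writeLines(readLines(path)[-1L], path)
  }
  invisible(path)
}

#' Export retained draws as a flat CSV
#'
#' One row per retained draw; columns are flattened parameter names
#' (`alpha1`, `beta.3`, `delta.2.1`, ...).  Person parameters are omitted
#' unless requested (they dominate the file size).
#'
#' @param fit A `likert_fit`.
#' @param path Output CSV path.
#' @param include_theta Also write the person-parameter draws.
#' @return `path`, invisibly.
#' @export
export_draws <- function(fit, path, include_theta = FALSE) {
  dr <- fit$draws
  D <- fit$dim["retained"]
  flat <- function(x, name) {
    if (is.null(x)) return(NULL)
    if (!is.array(x) && !is.matrix(x)) {
      out <- matrix(x, ncol = 1L); colnames(out) <- name
    } else if (is.matrix(x)) {
      out <- x
      colnames(out) <- if (ncol(x) == 1L) name
                       else paste(name, seq_len(ncol(x)), sep = ".")
    } else {
      out <- matrix(x, nrow = dim(x)[1L])
      colnames(out) <- as.vector(outer(seq_len(dim(x)[2L]), seq_len(dim(x)[3L]),
                                       function(i, j) paste(name, i, j, sep = ".")))
    }
    out
  }
  blocks <- list(flat(dr$alpha1, "alpha1"), flat(dr$beta, "beta"),
                 flat(dr$alpha2, "alpha2"), flat(dr$delta, "delta"),
                 flat(dr$mu, "mu"), flat(dr$Sigma, "Sigma"))
  if (include_theta)
    blocks <- c(blocks, list(flat(dr$theta1, "theta1"),
                             flat(dr$theta2, "theta2")))
  tab <- do.call(cbind, Filter(Negate(is.null), blocks))
  utils::write.csv(cbind(draw = seq_len(D), tab), path, row.names = FALSE)
  invisible(path)
}

#' Write a reproducibility manifest for a run
#'
#' Records everything needed to reproduce a run byte for byte: seed, model,
#' chain configuration, package version, input checksum and timestamps.
#'
#' @param path Output JSON path.
#' @param config The [chain_config()] used.
#' @param input_path Path of the input data file (checksummed if present).
#' @param extra Optional named list merged into the manifest.
#' @return The manifest list, invisibly.
#' @export
write_run_manifest <- function(path, config, input_path = NULL, extra = list()) {
  manifest <- c(list(
    model = config$model,
    n_iterations = config$n_iterations,
    burnin = config$burnin,
    thin = config$thin,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("rmixtree")),
    r_version = R.version.string,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    input = if (!is.null(input_path))
      list(path = input_path,
           md5 = unname(tools::md5sum(input_path))) else NULL
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Tidy trace data of a fitted chain
#'
#' @param fit A `likert_fit`.
#' @param pars Character vector of parameter names as in
#'   [posterior_summary()] (e.g. `"alpha1"`, `"beta[3]"`, `"delta[2,1]"`);
#'   `"theta1[p]"`/`"theta2[p]"` address person parameters.
#' @return A data frame with columns `draw`, `parameter`, `value`.
#' @export
trace_data <- function(fit, pars = "alpha1") {
  out <- lapply(pars, function(p) {
    base <- sub("\\[.*", "", p)
    idx <- regmatches(p, regexpr("\\[.*\\]", p))
    dr <- fit$draws[[base]]
    if (is.null(dr)) stop(sprintf("unknown parameter '%s'", p))
    v <- if (length(idx) == 0L) {
      if (is.matrix(dr) || is.array(dr)) stop(sprintf("'%s' needs an index", p))
      dr
    } else {
      ij <- as.integer(strsplit(gsub("\\[|\\]", "", idx), ",")[[1L]])
      if (length(ij) == 1L) dr[, ij[1L]] else dr[, ij[1L], ij[2L]]
    }
    data.frame(draw = seq_along(v), parameter = p, value = v)
  })
  do.call(rbind, out)
}

#' Trace plots of selected parameters
#'
#' Quick base-graphics trace panels for visual convergence checks.
#'
#' @inheritParams trace_data
#' @return The tidy trace data, invisibly.
#' @export
plot_traces <- function(fit, pars = "alpha1") {
  td <- trace_data(fit, pars)
  op <- graphics::par(mfrow = c(length(pars), 1L), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  for (p in pars) {
    v <- td$value[td$parameter == p]
    graphics::plot(v, type = "l", xlab = "", ylab = p, main = "")
  }
  invisible(td)
}

#' Split-chain R-hat and effective sample size of one parameter trace
#'
#' Potential scale reduction computed on the two halves of a single chain,
#' and an autocorrelation-based effective sample size; intended as a rough
#' numeric complement to visual trace inspection.
#'
#' @param x Numeric vector of retained draws.
#' @return A named vector with `rhat` and `ess`.
#' @export
chain_diagnostics <- function(x) {
  n <- length(x) %/% 2L
  halves <- cbind(x[seq_len(n)], x[seq.int(length(x) - n + 1L, length(x))])
  W <- mean(apply(halves, 2L, var))
  B <- n * var(colMeans(halves))
  rhat <- if (W > 0) sqrt(((n - 1) / n * W + B / n) / W) else 1
  ac <- stats::acf(x, plot = FALSE, lag.max = min(100L, length(x) - 1L))$acf[-1L]
  pos <- which(ac < 0.05)
  cutoff <- if (length(pos)) pos[1L] - 1L else length(ac)
  ess <- length(x) / (1 + 2 * sum(ac[seq_len(cutoff)]))
  c(rhat = rhat, ess = ess)
}
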
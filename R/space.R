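#' Category space of a Likert item with a middle category
#'
#' Defines the response categories `0, ..., h` of a Likert item whose middle
#' category `m = h/2` can be reached either as a neutral (informative)
#' response or as a covert non-response.  `h` must be even so that a unique
#' middle category exists.
#'
#' @param h Maximum item score (integer, even, at least 2).  A 5-category
#'   Likert item has `h = 4`.
#'
#' @return An object of class `likert_space`: a list with elements `h`,
#'   `m` (middle category, `h/2`) and `n_categories` (`h + 1`).
#' @examples
#' sp <- likert_space(4)
#' sp$m            # middle category of a 5-point scale
#' @export
likert_space <- function(h) {
  if (length(h) != 1L || !is.finite(h) || h != round(h))
    stop("`h` must be a single integer")
  h <- as.integer(h)
  if (h < 2L || h %% 2L != 0L)
    stop("`h` must be an even integer >= 2 so that a middle category exists")
  structure(list(h = h, m = h %/% 2L, n_categories = h + 1L),
            class = "likert_space")
}

#' @export
print.likert_space <- function(x, ...) {
  cat(sprintf("Likert category space: scores 0..%d (%d categories), middle category m = %d\n",
              x$h, x$n_categories, x$m))
  invisible(x)
}

as_likert_space <- function(space) {
  if (inherits(space, "likert_space")) return(space)
  likert_space(space)
}

#' Validate a matrix of Likert item scores
#'
#' Checks that `data` is a rectangular integer matrix with all values in
#' `0..h`.  Missing values are rejected: the model has no missing-data
#' mechanism beyond the latent non-response path.
#'
#' @param data Matrix (or data frame) of item scores, persons in rows,
#'   items in columns.
#' @param space A [likert_space()].
#' @return The validated integer matrix (invisibly usable downstream).
#' @export
validate_scores <- function(data, space) {
  space <- as_likert_space(space)
  if (is.data.frame(data)) data <- as.matrix(data)
  if (!is.matrix(data)) stop("`data` must be a matrix of item scores")
  if (anyNA(data)) {
    bad <- which(is.na(data), arr.ind = TRUE)[1L, ]
    stop(sprintf("missing score at row %d, column %d: missing responses are not supported",
                 bad[1L], bad[2L]))
  }
  if (!is.numeric(data) || any(data != round(data)))
    stop("item scores must be integers")
  out_of_range <- data < 0 | data > space$h
  if (any(out_of_range)) {
    bad <- which(out_of_range, arr.ind = TRUE)[1L, ]
    stop(sprintf("score %g at row %d, column %d outside 0..%d",
                 data[bad[1L], bad[2L]], bad[1L], bad[2L], space$h))
  }
  storage.mode(data) <- "integer"
  data
}
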
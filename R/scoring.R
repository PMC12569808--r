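#' Criteria matrix of raw measurements
#'
#' Runs-by-criteria matrix of raw measurements \eqn{x_{ij}} (percent units in
#' typical formulation work), with an optimization direction per criterion.
#'
#' @param values Numeric matrix or data.frame, runs in rows, criteria in
#'   columns; all finite; at least 2 runs.
#' @param directions Character vector, `"benefit"` or `"cost"` per column
#'   (recycled if length 1). Defaults to all-benefit.
#' @return A `criteria_matrix` object.
#' @export
criteria_matrix <- function(values, directions = "benefit") {
  V <- as.matrix(values)
  storage.mode(V) <- "double"
  if (nrow(V) < 2L) stop("need at least 2 runs", call. = FALSE)
  if (!all(is.finite(V))) stop("criteria values must be finite", call. = FALSE)
  if (is.null(colnames(V))) colnames(V) <- paste0("C", seq_len(ncol(V)))
  if (is.null(rownames(V))) rownames(V) <- as.character(seq_len(nrow(V)))
  directions <- rep_len(match.arg(directions, c("benefit", "cost"),
                                  several.ok = TRUE), ncol(V))
  structure(V, directions = directions, class = c("criteria_matrix", "matrix"))
}

as_criteria_matrix <- function(X, directions = NULL) {
  if (inherits(X, "criteria_matrix")) {
    if (!is.null(directions))
      attr(X, "directions") <- rep_len(directions, ncol(X))
    return(X)
  }
  criteria_matrix(X, directions %||% "benefit")
}

#' Min-max standardization of a criteria matrix
#'
#' Rescales each criterion column to \[0, 1\]:
#' \eqn{C_{ij} = (x_{ij} - \min_i x_{ij}) / (\max_i x_{ij} - \min_i x_{ij})}
#' for benefit criteria, and \eqn{(\max - x) / (\max - \min)} for cost
#' criteria. A zero-range column is set to all zeros with a warning (paired
#' with the entropy convention that such a column carries weight 0).
#'
#' @param X A [criteria_matrix()] (or coercible matrix/data.frame).
#' @return A `normalized_matrix` with the same shape and labels; every
#'   non-degenerate column attains 0 and 1.
#' @examples
#' X <- criteria_matrix(cbind(a = c(1, 3, 2), b = c(10, 0, 5)))
#' minmax_normalize(X)
#' @export
minmax_normalize <- function(X) {
  X <- as_criteria_matrix(X)
  dirs <- attr(X, "directions")
  V <- unclass(X)
  out <- V
  for (j in seq_len(ncol(V))) {
    rng <- range(V[, j])
    span <- rng[2] - rng[1]
    if (span == 0) {
      warning("column '", colnames(V)[j],
              "' has zero range; normalized to 0", call. = FALSE)
      out[, j] <- 0
    } else if (dirs[j] == "benefit") {
      out[, j] <- (V[, j] - rng[1]) / span
    } else {
      out[, j] <- (rng[2] - V[, j]) / span
    }
  }
  structure(out, directions = dirs,
            class = c("normalized_matrix", "matrix"))
}

#' Weighted comprehensive score per run
#'
#' Scores each run as the weighted sum of its standardized criterion values,
#' \eqn{\mathrm{score}_i = \mathrm{scale} \cdot \sum_j C_{ij} W_j}. With the
#' default scale of 100 the score lies on a 0-100 scale (the weighted-sum
#' formula itself yields 0-1; published comprehensive scores conventionally
#' use the x100 form).
#'
#' @param C A `normalized_matrix` from [minmax_normalize()] (a raw
#'   [criteria_matrix()] is normalized first).
#' @param W A [weight_vector()] whose labels match `C`'s columns.
#' @param scale Positive scale factor, default 100.
#' @return A `score_vector`: named numeric of per-run scores in
#'   \[0, scale\].
#' @examples
#' C <- minmax_normalize(criteria_matrix(cbind(a = c(1, 0), b = c(0, 1))))
#' comprehensive_score(C, weight_vector(c(0.6, 0.4), c("a", "b"), "combined"))
#' @export
comprehensive_score <- function(C, W, scale = 100) {
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  if (!inherits(C, "normalized_matrix")) C <- minmax_normalize(C)
  W <- as_weights(W, "combined")
  if (!identical(colnames(C), names(W)))
    stop("weight labels must match criteria columns (same names, same order)",
         call. = FALSE)
  s <- as.numeric(unclass(C) %*% unclass(W)) * scale
  structure(stats::setNames(s, rownames(C)), scale = scale,
            class = "score_vector")
}

#' @export
print.score_vector <- function(x, digits = 2, ...) {
  cat("Comprehensive scores (0-", format(attr(x, "scale") %||% 100),
      " scale):\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}
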
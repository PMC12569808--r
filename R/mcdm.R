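#' Criterion specification
#'
#' Describes one quality criterion entering the weighting stage: its name, its
#' importance tier (1 = most important; tiers must be consecutive integers
#' starting at 1 across the full set), and its optimization direction.
#'
#' @param name Character scalar, unique criterion label.
#' @param tier Positive integer importance rank.
#' @param direction `"benefit"` (larger is better) or `"cost"`.
#' @return A `criterion_spec` object (named list).
#' @examples
#' criterion_spec("paeoniflorin", tier = 1, direction = "benefit")
#' @export
criterion_spec <- function(name, tier, direction = c("benefit", "cost")) {
  direction <- match.arg(direction)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (length(tier) != 1L || !is.finite(tier) || tier < 1 || tier != round(tier))
    stop("`tier` must be a single positive integer", call. = FALSE)
  structure(list(name = name, tier = as.integer(tier), direction = direction),
            class = "criterion_spec")
}

validate_criteria <- function(criteria) {
  stopifnot(is.list(criteria), length(criteria) >= 1L)
  criteria <- lapply(criteria, function(cr) {
    if (inherits(cr, "criterion_spec")) cr
    else criterion_spec(cr$name, cr$tier, cr$direction %||% "benefit")
  })
  nms <- vapply(criteria, `[[`, character(1), "name")
  if (anyDuplicated(nms)) stop("criterion names must be unique", call. = FALSE)
  tiers <- vapply(criteria, `[[`, integer(1), "tier")
  ut <- sort(unique(tiers))
  if (!identical(ut, seq_len(max(ut))))
    stop("tiers must be consecutive integers starting at 1", call. = FALSE)
  criteria
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a reciprocal pairwise judgment matrix from importance tiers
#'
#' Constructs the AHP judgment matrix from a tier assignment and a map from
#' tier gap to importance ratio. Criteria in the same tier compare as 1; when
#' criterion e sits in a more important (lower-numbered) tier than f, entry
#' (e, f) is the map's ratio for that gap and (f, e) its reciprocal.
#'
#' The default map encodes the conventional 1-3-5 verbal scale: equal
#' importance within a tier, "slightly more important" (3) one tier apart,
#' "significantly more important" (5) two tiers apart.
#'
#' @param criteria List of [criterion_spec()] objects (or plain lists with
#'   `name` and `tier`).
#' @param tier_ratio_map Named numeric vector mapping tier gap (as character
#'   `"0"`, `"1"`, ...) to a ratio >= 1.
#' @return A `judgment_matrix`: a positive reciprocal matrix with unit
#'   diagonal, dimnames set to the criterion names.
#' @examples
#' crit <- list(
#'   criterion_spec("paeoniflorin", 1), criterion_spec("albiflorin", 1),
#'   criterion_spec("liquiritin", 2), criterion_spec("glycyrrhizic acid", 2),
#'   criterion_spec("ganoderic acid A", 3), criterion_spec("dry extract ratio", 3))
#' build_judgment_matrix(crit)
#' @export
build_judgment_matrix <- function(criteria,
                                  tier_ratio_map = c("0" = 1, "1" = 3, "2" = 5)) {
  criteria <- validate_criteria(criteria)
  if (length(criteria) < 2L) stop("need at least 2 criteria", call. = FALSE)
  if (any(!is.finite(tier_ratio_map) | tier_ratio_map <= 0))
    stop("tier ratios must be positive and finite", call. = FALSE)
  if (any(tier_ratio_map < 1))
    stop("tier ratios must be >= 1 (reciprocals are implied)", call. = FALSE)
  tiers <- vapply(criteria, `[[`, integer(1), "tier")
  nms <- vapply(criteria, `[[`, character(1), "name")
  gaps <- unique(abs(outer(tiers, tiers, "-")))
  missing_gaps <- setdiff(as.character(gaps), names(tier_ratio_map))
  if (length(missing_gaps))
    stop("tier_ratio_map lacks ratios for tier gap(s): ",
         paste(missing_gaps, collapse = ", "), call. = FALSE)
  n <- length(criteria)
  J <- matrix(1, n, n, dimnames = list(nms, nms))
  for (e in seq_len(n)) for (f in seq_len(n)) {
    gap <- tiers[f] - tiers[e]  # positive: e more important than f
    r <- tier_ratio_map[[as.character(abs(gap))]]
    J[e, f] <- if (gap > 0) r else if (gap < 0) 1 / r else 1
  }
  new_judgment_matrix(J)
}

new_judgment_matrix <- function(J) {
  stopifnot(is.matrix(J), nrow(J) == ncol(J), all(J > 0))
  if (any(abs(diag(J) - 1) > 1e-12))
    stop("judgment matrix diagonal must be 1", call. = FALSE)
  if (max(abs(J * t(J) - 1)) > 1e-12)
    stop("judgment matrix must be reciprocal (a_ef * a_fe = 1)", call. = FALSE)
  structure(J, class = c("judgment_matrix", "matrix"))
}

#' @export
print.judgment_matrix <- function(x, digits = 4, ...) {
  cat("Reciprocal judgment matrix (", nrow(x), " criteria)\n", sep = "")
  print(round(unclass(x), digits), ...)
  invisible(x)
}

# Saaty random-consistency indices, n = 1..10
saaty_ri <- c(0, 0, 0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45, 1.49)

#' Weight vector constructor
#'
#' A labelled vector of nonnegative criterion weights summing to one, tagged
#' with its role in the combined-weighting scheme.
#'
#' @param values Numeric weights, nonnegative, summing to 1 within 1e-9.
#' @param labels Criterion names, same length as `values`.
#' @param role `"subjective"`, `"objective"`, or `"combined"`.
#' @return A `weight_vector` object.
#' @export
weight_vector <- function(values, labels,
                          role = c("subjective", "objective", "combined")) {
  role <- match.arg(role)
  stopifnot(length(values) == length(labels), all(is.finite(values)))
  if (any(values < -1e-12)) stop("weights must be nonnegative", call. = FALSE)
  if (abs(sum(values) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(values)), ")", call. = FALSE)
  values <- pmax(values, 0)
  structure(stats::setNames(as.numeric(values), labels),
            role = role, class = "weight_vector")
}

#' @export
print.weight_vector <- function(x, ...) {
  cat(attr(x, "role"), "weight vector (percent):\n")
  print(stats::setNames(round(100 * as.numeric(x), 2), names(x)))
  invisible(x)
}

#' AHP priority weights from a judgment matrix
#'
#' Extracts criterion weights from a reciprocal judgment matrix, by the
#' principal right eigenvector (power iteration) or the row geometric mean.
#' Returns the weights together with the standard AHP consistency
#' diagnostics: the principal eigenvalue `lambda_max` (computed as the mean of
#' the components of `J w / w`), the consistency index
#' `CI = (lambda_max - n) / (n - 1)`, and the consistency ratio `CR = CI / RI(n)`
#' with Saaty's random indices (CR < 0.1 is the conventional acceptance bar).
#'
#' @param J A `judgment_matrix` (or plain reciprocal matrix).
#' @param method `"eigenvector"` (default) or `"geometric_mean"`.
#' @param ri_table Numeric vector of random indices indexed by matrix order;
#'   defaults to Saaty's values for n = 1..10.
#' @param tol,max_iter Power-iteration convergence tolerance and cap.
#' @return An `ahp_result` list: `weights` (a [weight_vector()], role
#'   subjective), `lambda_max`, `consistency_index`, `consistency_ratio`,
#'   `method`.
#' @examples
#' crit <- list(criterion_spec("x", 1), criterion_spec("y", 2),
#'              criterion_spec("z", 3))
#' ahp_weights(build_judgment_matrix(crit))
#' @export
ahp_weights <- function(J, method = c("eigenvector", "geometric_mean"),
                        ri_table = saaty_ri, tol = 1e-12, max_iter = 10000L) {
  method <- match.arg(method)
  if (!inherits(J, "judgment_matrix")) J <- new_judgment_matrix(as.matrix(J))
  n <- nrow(J)
  if (n < 2L || n > length(ri_table))
    stop("matrix order ", n, " outside the random-index table (2..",
         length(ri_table), ")", call. = FALSE)
  Jm <- unclass(J)
  if (method == "eigenvector") {
    w <- rep(1 / n, n)
    converged <- FALSE
    for (i in seq_len(max_iter)) {
      w_new <- as.numeric(Jm %*% w)
      w_new <- w_new / sum(w_new)
      if (max(abs(w_new - w)) < tol) { w <- w_new; converged <- TRUE; break }
      w <- w_new
    }
    if (!converged)
      stop("power iteration did not converge in ", max_iter, " iterations",
           call. = FALSE)
  } else {
    w <- apply(Jm, 1L, function(r) exp(mean(log(r))))
    w <- w / sum(w)
  }
  lambda_max <- mean(as.numeric(Jm %*% w) / w)
  ci <- (lambda_max - n) / (n - 1)
  ri <- ri_table[n]
  cr <- if (ri > 0) ci / ri else 0
  structure(list(
    weights = weight_vector(w, rownames(Jm) %||% paste0("C", seq_len(n)),
                            role = "subjective"),
    lambda_max = lambda_max, consistency_index = ci, consistency_ratio = cr,
    method = method), class = "ahp_result")
}

#' @export
print.ahp_result <- function(x, ...) {
  cat("AHP result (", x$method, ")\n", sep = "")
  print(x$weights)
  cat(sprintf("lambda_max = %.6f, CI = %.6f, CR = %.6f%s\n",
              x$lambda_max, x$consistency_index, x$consistency_ratio,
              if (x$consistency_ratio < 0.1) "  (consistent)" else
                "  (CR >= 0.1: revise judgments)"))
  invisible(x)
}

#' Entropy (information) weights from a criteria matrix
#'
#' Objective weighting: criteria whose measurements are more dispersed across
#' runs carry more information and receive larger weights. The pipeline is
#' min-max standardization per column (cost columns inverted), column
#' proportions \eqn{p_{ij} = C_{ij} / \sum_i C_{ij}}, Shannon entropy
#' \eqn{e_j = -\frac{1}{\ln m}\sum_i p_{ij}\ln p_{ij}} (with
#' \eqn{0 \ln 0 := 0}), divergence \eqn{d_j = 1 - e_j}, and weights
#' \eqn{w_j = d_j / \sum_j d_j}.
#'
#' A zero-dispersion column carries no information: it gets divergence 0
#' (hence weight 0) with a warning.
#'
#' @param X A [criteria_matrix()] or plain numeric matrix / data.frame
#'   (runs in rows, criteria in columns).
#' @param directions Optional character vector `"benefit"`/`"cost"` per
#'   column; defaults to the matrix's own directions or all-benefit.
#' @return A [weight_vector()] with role `"objective"`.
#' @export
entropy_weights <- function(X, directions = NULL) {
  X <- as_criteria_matrix(X, directions)
  V <- unclass(minmax_normalize(X))
  m <- nrow(V)
  dj <- vapply(seq_len(ncol(V)), function(j) {
    cs <- sum(V[, j])
    if (cs <= 0) return(0)  # degenerate column already warned on normalize
    p <- V[, j] / cs
    plogp <- ifelse(p > 0, p * log(p), 0)
    e <- -sum(plogp) / log(m)
    1 - e
  }, numeric(1))
  if (all(dj == 0))
    stop("all criteria have zero dispersion; entropy weights undefined",
         call. = FALSE)
  weight_vector(dj / sum(dj), colnames(V), role = "objective")
}

#' Combine subjective and objective weights
#'
#' Multiplicative combination: \eqn{W_j = W_{jS} W_{jO} / \sum_k W_{kS} W_{kO}}.
#' Inputs must share labels in the same order.
#'
#' @param subjective,objective [weight_vector()] objects (or named numerics
#'   summing to 1) over the same criteria.
#' @return A [weight_vector()] with role `"combined"`.
#' @examples
#' s <- weight_vector(c(0.6, 0.4), c("a", "b"), "subjective")
#' o <- weight_vector(c(0.5, 0.5), c("a", "b"), "objective")
#' combine_weights(s, o)
#' @export
combine_weights <- function(subjective, objective) {
  s <- as_weights(subjective, "subjective")
  o <- as_weights(objective, "objective")
  if (!identical(names(s), names(o)))
    stop("subjective and objective weights must share labels and order",
         call. = FALSE)
  prod <- unclass(s) * unclass(o)
  if (sum(prod) <= 0)
    stop("all subjective x objective products are zero; cannot combine",
         call. = FALSE)
  weight_vector(prod / sum(prod), names(s), role = "combined")
}

as_weights <- function(w, role) {
  if (inherits(w, "weight_vector")) return(w)
  if (is.null(names(w))) names(w) <- paste0("C", seq_along(w))
  weight_vector(w / sum(w), names(w), role = role)
}
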
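#' Box-Behnken design for three factors
#'
#' Generates the canonical 3-factor Box-Behnken design: the 12 edge midpoints
#' of the coded cube (each factor pair at all four (+/-1, +/-1) combinations
#' with the third factor at 0) plus replicated center points.
#'
#' @param factors A named list of 3 factor specs, each a numeric
#'   `c(low, center, high)` (strictly increasing) or a list with `low`,
#'   `center`, `high`.
#' @param center_count Number of center-point replicates (>= 1), default 5.
#' @return A `bbd_design` with `factors` (data.frame name/low/center/high
#'   plus derived `half_range`), `coded` (m x 3 matrix in {-1, 0, 1}),
#'   `center_count`.
#' @examples
#' generate_bbd(list(diluent = c(6, 10, 14), ethanol = c(80, 85, 90),
#'                   binder = c(10, 12, 14)), center_count = 5)
#' @export
generate_bbd <- function(factors, center_count = 5L) {
  if (length(factors) != 3L)
    stop("only 3-factor Box-Behnken designs are supported", call. = FALSE)
  if (center_count < 1L) stop("center_count must be >= 1", call. = FALSE)
  fs <- factor_frame(factors)
  pairs <- utils::combn(3L, 2L)
  pts <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(p) {
    out <- matrix(0, 4L, 3L)
    out[, pairs[1L, p]] <- c(-1, -1, 1, 1)
    out[, pairs[2L, p]] <- c(-1, 1, -1, 1)
    out
  }))
  coded <- rbind(pts, matrix(0, center_count, 3L))
  colnames(coded) <- fs$name
  rownames(coded) <- as.character(seq_len(nrow(coded)))
  structure(list(factors = fs, coded = coded,
                 center_count = as.integer(center_count)),
            class = "bbd_design")
}

factor_frame <- function(factors) {
  nms <- names(factors) %||% paste0("x", seq_along(factors))
  rows <- lapply(seq_along(factors), function(i) {
    f <- factors[[i]]
    v <- if (is.list(f)) c(f$low, f$center, f$high) else as.numeric(f)
    if (length(v) != 3L || any(!is.finite(v)) || !all(diff(v) > 0))
      stop("factor '", nms[i],
           "' must give strictly increasing (low, center, high)",
           call. = FALSE)
    data.frame(name = nms[i], low = v[1], center = v[2], high = v[3])
  })
  fs <- do.call(rbind, rows)
  # half-ranges must be symmetric for the +/-1 coding to hit low and high
  if (any(abs((fs$high - fs$center) - (fs$center - fs$low)) > 1e-9))
    stop("levels must be symmetric about the center for +/-1 coding",
         call. = FALSE)
  fs$half_range <- (fs$high - fs$low) / 2
  fs
}

#' @export
print.bbd_design <- function(x, ...) {
  cat("Box-Behnken design: ", nrow(x$coded), " runs (12 edge midpoints + ",
      x$center_count, " center points)\n", sep = "")
  print(x$factors, row.names = FALSE)
  invisible(x)
}

#' Convert between natural and coded factor units
#'
#' Coding convention: `coded = (natural - center) / half_range`, so low maps
#' to -1, center to 0, high to +1. The round trip is exact.
#'
#' @param design A `bbd_design`.
#' @param natural,coded Matrix or data.frame of settings (columns in the
#'   design's factor order).
#' @return Matrix of converted settings.
#' @export
code_units <- function(design, natural) {
  fs <- design$factors
  N <- as.matrix(natural)
  sweep(sweep(N, 2L, fs$center, "-"), 2L, fs$half_range, "/")
}

#' @rdname code_units
#' @export
decode_units <- function(design, coded) {
  fs <- design$factors
  Cd <- as.matrix(coded)
  sweep(sweep(Cd, 2L, fs$half_range, "*"), 2L, fs$center, "+")
}

quad_model_matrix <- function(coded) {
  a <- coded[, 1L]; b <- coded[, 2L]; cc <- coded[, 3L]
  X <- cbind(1, a, b, cc, a * b, a * cc, b * cc, a^2, b^2, cc^2)
  nm <- colnames(coded) %||% c("a", "b", "c")
  colnames(X) <- c("(Intercept)", nm, paste0(nm[1], ":", nm[2]),
                   paste0(nm[1], ":", nm[3]), paste0(nm[2], ":", nm[3]),
                   paste0(nm, "^2"))
  X
}

#' Fit the full quadratic response surface
#'
#' Ordinary least squares of the response on the 10-term second-order model
#' in coded units: intercept, 3 linear, 3 two-way interaction, and 3 pure
#' quadratic terms.
#'
#' @param design A `bbd_design`.
#' @param y Numeric response, one value per run, in the design's run order.
#' @return A `quadratic_model` with `coefficients` (named, coded scale),
#'   `r2`, `r2_adj`, `sigma2` (residual mean square), the sums of squares
#'   `total_ss`, `model_ss`, `residual_ss`, `pure_error_ss`, `lack_of_fit_ss`,
#'   standard errors, and the design.
#' @examples
#' des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(-1, 0, 1)))
#' y <- 5 - 2 * des$coded[, "b"] + des$coded[, "a"]^2
#' fit_quadratic(des, y)
#' @export
fit_quadratic <- function(design, y) {
  stopifnot(inherits(design, "bbd_design"))
  y <- as.numeric(y)
  m <- nrow(design$coded)
  if (length(y) != m)
    stop("response length ", length(y), " does not match ", m, " runs",
         call. = FALSE)
  X <- quad_model_matrix(design$coded)
  if (m <= ncol(X))
    stop("need more runs (", m, ") than model terms (", ncol(X), ")",
         call. = FALSE)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("model matrix is rank-deficient; design does not support the full ",
         "quadratic", call. = FALSE)
  beta <- qr.coef(qrX, y)
  res <- y - as.numeric(X %*% beta)
  rss <- sum(res^2)
  tss <- sum((y - mean(y))^2)
  df_res <- m - ncol(X)
  sigma2 <- rss / df_res
  XtXi <- chol2inv(qr.R(qrX))
  se <- sqrt(sigma2 * diag(XtXi))
  names(se) <- colnames(X)
  is_center <- rowSums(design$coded != 0) == 0L
  pe <- if (sum(is_center) >= 2L)
    sum((y[is_center] - mean(y[is_center]))^2) else NA_real_
  structure(list(
    coefficients = beta, se = se, residuals = res,
    fitted = y - res, y = y,
    r2 = 1 - rss / tss, r2_adj = 1 - (rss / df_res) / (tss / (m - 1)),
    sigma2 = sigma2, df_residual = df_res,
    total_ss = tss, model_ss = tss - rss, residual_ss = rss,
    pure_error_ss = pe,
    lack_of_fit_ss = if (is.na(pe)) NA_real_ else rss - pe,
    xtx_inv = XtXi, design = design), class = "quadratic_model")
}

#' @export
print.quadratic_model <- function(x, digits = 4, ...) {
  cat("Quadratic response surface (coded units)\n")
  print(round(x$coefficients, digits))
  cat(sprintf("R2 = %.4f, adj R2 = %.4f, residual SS = %.4f on %d df\n",
              x$r2, x$r2_adj, x$residual_ss, x$df_residual))
  invisible(x)
}

#' @export
predict.quadratic_model <- function(object, coded, ...) {
  Cd <- matrix(as.numeric(as.matrix(coded)), ncol = 3L)
  as.numeric(quad_model_matrix(Cd) %*% object$coefficients)
}

#' Response-surface ANOVA with lack of fit
#'
#' Partitions variation for the fitted quadratic: the 9-df model row, one row
#' per term (partial sum of squares, \eqn{\beta_j^2 / [(X'X)^{-1}]_{jj}};
#' for the mutually orthogonal linear and interaction columns of a
#' Box-Behnken design this equals the sequential SS), the residual, and its
#' split into lack of fit and pure error from the center-point replicates.
#' The lack-of-fit F is MS(lack of fit) / MS(pure error); an insignificant
#' lack of fit supports the adequacy of the quadratic.
#'
#' @param model A `quadratic_model` from [fit_quadratic()].
#' @return An `anova_table` data.frame (source, ss, df, ms, F, p) with rows
#'   Model, each term, Residual, Lack of fit, Pure error, Total. With fewer
#'   than 2 center replicates the lack-of-fit rows are `NA` and a warning is
#'   issued.
#' @export
rsm_anova <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  beta <- model$coefficients[-1L]
  dXtXi <- diag(model$xtx_inv)[-1L]
  term_ss <- beta^2 / dXtXi
  p <- length(beta)
  df_res <- model$df_residual
  ms_res <- model$residual_ss / df_res
  model_F <- (model$model_ss / p) / ms_res
  term_F <- (term_ss / 1) / ms_res
  have_pe <- !is.na(model$pure_error_ss)
  if (!have_pe)
    warning("fewer than 2 center replicates: lack-of-fit test unavailable",
            call. = FALSE)
  df_pe <- if (have_pe) model$design$center_count - 1L else NA_integer_
  df_lof <- if (have_pe) df_res - df_pe else NA_integer_
  lof_F <- lof_p <- NA_real_
  if (have_pe && df_lof > 0L && model$pure_error_ss > 0) {
    lof_F <- (model$lack_of_fit_ss / df_lof) / (model$pure_error_ss / df_pe)
    lof_p <- stats::pf(lof_F, df_lof, df_pe, lower.tail = FALSE)
  }
  src <- c("Model", names(beta), "Residual", "Lack of fit", "Pure error",
           "Total")
  out <- data.frame(
    source = src,
    ss = c(model$model_ss, term_ss, model$residual_ss,
           model$lack_of_fit_ss, model$pure_error_ss, model$total_ss),
    df = c(p, rep(1L, p), df_res, df_lof, df_pe, length(model$y) - 1L),
    ms = c(model$model_ss / p, term_ss, ms_res,
           if (have_pe && df_lof > 0L) model$lack_of_fit_ss / df_lof else NA,
           if (have_pe) model$pure_error_ss / df_pe else NA, NA),
    F = c(model_F, term_F, NA, lof_F, NA, NA),
    p = c(stats::pf(model_F, p, df_res, lower.tail = FALSE),
          stats::pf(term_F, 1, df_res, lower.tail = FALSE),
          NA, lof_p, NA, NA),
    row.names = NULL)
  structure(out, class = c("anova_table", "data.frame"))
}

#' Optimum of the fitted surface over the coded cube
#'
#' Maximizes (or minimizes) the fitted quadratic over the coded cube
#' \[-1, 1\]^3 exactly, by enumerating the face lattice of the box: for every
#' pattern of coordinates fixed at -1/+1 with the rest free, the stationary
#' point of the reduced quadratic is a candidate when it is feasible; the
#' cube's vertices complete the candidate set. The best candidate is the
#' global constrained optimum, decoded to natural units via the design's
#' centers and half-ranges.
#'
#' @param model A `quadratic_model`.
#' @param sense `"maximize"` (default) or `"minimize"`.
#' @return An `optimum_point` with `coded`, `natural`, `predicted`,
#'   `at_boundary` (logical per factor), and `natural_rounded` (diluent-style
#'   whole-unit reporting: each coordinate rounded to its factor's display
#'   granularity of 1 unit).
#' @examples
#' des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1), c = c(-1, 0, 1)))
#' m <- fit_quadratic(des, 10 - des$coded[, 1]^2 - des$coded[, 2]^2 -
#'                      des$coded[, 3]^2 + rep(0, 17))
#' optimize_surface(m)
#' @export
optimize_surface <- function(model, sense = c("maximize", "minimize")) {
  sense <- match.arg(sense)
  stopifnot(inherits(model, "quadratic_model"))
  b <- model$coefficients
  g <- b[2:4]
  H <- matrix(c(2 * b[8],     b[5],     b[6],
                b[5],     2 * b[9],     b[7],
                b[6],         b[7], 2 * b[10]), 3L, 3L)
  sgn <- if (sense == "maximize") 1 else -1
  cand <- list()
  # enumerate fixed/free patterns: 0 = free, -1/+1 = fixed at that bound
  for (pa in c(0L, -1L, 1L)) for (pb in c(0L, -1L, 1L)) for (pc in c(0L, -1L, 1L)) {
    pat <- c(pa, pb, pc)
    free <- pat == 0L
    x <- as.numeric(pat)
    if (any(free)) {
      # stationary point of the quadratic restricted to the free coordinates
      Hf <- H[free, free, drop = FALSE]
      gf <- g[free] + H[free, !free, drop = FALSE] %*% x[!free]
      sol <- tryCatch(solve(Hf, -gf), error = function(e) NULL)
      if (is.null(sol) || any(abs(sol) > 1)) next
      x[free] <- sol
    }
    cand[[length(cand) + 1L]] <- x
  }
  vals <- vapply(cand, function(x)
    sum(b * c(1, x, x[1] * x[2], x[1] * x[3], x[2] * x[3], x^2)), numeric(1))
  best <- cand[[which.max(sgn * vals)]]
  fs <- model$design$factors
  natural <- as.numeric(decode_units(model$design, matrix(best, 1L)))
  names(best) <- names(natural) <- fs$name
  structure(list(
    coded = best, natural = natural,
    natural_rounded = stats::setNames(round(natural), fs$name),
    predicted = max(sgn * vals) * sgn,
    at_boundary = stats::setNames(abs(abs(best) - 1) < 1e-9, fs$name),
    sense = sense), class = "optimum_point")
}

#' @export
print.optimum_point <- function(x, digits = 3, ...) {
  cat("Constrained ", x$sense, "r of the quadratic surface\n", sep = "")
  cat("  coded:   ", paste(names(x$coded), round(x$coded, digits),
                           sep = "=", collapse = ", "), "\n")
  cat("  natural: ", paste(names(x$natural), round(x$natural, digits),
                           sep = "=", collapse = ", "), "\n")
  cat("  rounded: ", paste(names(x$natural_rounded), x$natural_rounded,
                           sep = "=", collapse = ", "), "\n")
  cat(sprintf("  predicted response: %.*f\n", digits, x$predicted))
  bd <- names(x$at_boundary)[x$at_boundary]
  if (length(bd))
    cat("  at cube boundary: ", paste(bd, collapse = ", "), "\n", sep = "")
  invisible(x)
}
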
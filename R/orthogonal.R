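#' Balanced orthogonal design
#'
#' Represents a balanced orthogonal array (e.g. L9(3^3)): each level of each
#' factor occurs equally often. Constructed from a data.frame or matrix of
#' natural-unit factor settings, one column per factor, one row per run.
#'
#' @param assignment Data.frame/matrix of factor settings (natural units or
#'   level labels); columns are factors.
#' @return An `orthogonal_design` with components `factors` (named list of
#'   level vectors, in first-appearance order sorted by level value where
#'   numeric) and `assignment` (integer matrix of level indices).
#' @examples
#' l9 <- expand.grid(A = 1:3, B = 1:3)[c(1, 4, 7, 2, 5, 8, 3, 6, 9), ]
#' orthogonal_design(data.frame(A = rep(1:3, each = 3), B = rep(1:3, 3)))
#' @export
orthogonal_design <- function(assignment) {
  A <- as.data.frame(assignment)
  if (!ncol(A)) stop("design needs at least one factor", call. = FALSE)
  if (is.null(names(A)) || any(!nzchar(names(A))))
    names(A) <- paste0("F", seq_len(ncol(A)))
  factors <- lapply(A, function(col) {
    lv <- unique(col)
    if (is.numeric(lv)) sort(lv) else lv
  })
  idx <- mapply(function(col, lv) match(col, lv), A, factors)
  idx <- matrix(as.integer(idx), nrow = nrow(A),
                dimnames = list(rownames(A), names(A)))
  des <- structure(list(factors = factors, assignment = idx),
                   class = "orthogonal_design")
  check_balance(des)
  des
}

check_balance <- function(design) {
  idx <- design$assignment
  for (j in seq_len(ncol(idx))) {
    tab <- tabulate(idx[, j], nbins = length(design$factors[[j]]))
    if (length(unique(tab)) != 1L)
      stop("design is unbalanced: factor '", colnames(idx)[j],
           "' levels occur ", paste(tab, collapse = "/"), " times",
           call. = FALSE)
  }
  invisible(design)
}

#' @export
print.orthogonal_design <- function(x, ...) {
  m <- nrow(x$assignment)
  cat("Balanced orthogonal design: ", m, " runs, ",
      ncol(x$assignment), " factors\n", sep = "")
  for (nm in names(x$factors))
    cat("  ", nm, ": levels ", paste(x$factors[[nm]], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}

#' Range analysis of an orthogonal experiment
#'
#' For each factor, computes the per-level response sums K, the per-level
#' means k, and the range R = max(k) - min(k). Larger R marks a more
#' influential factor; the per-factor level with the highest mean k is the
#' recommended setting.
#'
#' @param design An [orthogonal_design()].
#' @param y Numeric response, one value per run (e.g. comprehensive scores).
#' @return A `range_table` list: `K`, `k` (level-by-factor matrices), `R`
#'   (named vector), `ranking` (factor names by descending R, ties broken by
#'   design order), `optimal_levels` (named vector of best natural-unit
#'   levels).
#' @examples
#' des <- orthogonal_design(data.frame(A = rep(1:3, each = 3), B = rep(1:3, 3)))
#' range_analysis(des, rnorm(9))
#' @export
range_analysis <- function(design, y) {
  stopifnot(inherits(design, "orthogonal_design"))
  check_balance(design)
  y <- as.numeric(y)
  idx <- design$assignment
  if (length(y) != nrow(idx))
    stop("response length ", length(y), " does not match ", nrow(idx),
         " runs", call. = FALSE)
  nlev <- max(vapply(design$factors, length, integer(1)))
  K <- k <- matrix(NA_real_, nlev, ncol(idx),
                   dimnames = list(paste0("level", seq_len(nlev)),
                                   colnames(idx)))
  R <- stats::setNames(numeric(ncol(idx)), colnames(idx))
  opt <- stats::setNames(vector("list", ncol(idx)), colnames(idx))
  for (j in seq_len(ncol(idx))) {
    lev <- design$factors[[j]]
    Ks <- vapply(seq_along(lev), function(l) sum(y[idx[, j] == l]), numeric(1))
    reps <- sum(idx[, j] == 1L)
    K[seq_along(lev), j] <- Ks
    k[seq_along(lev), j] <- Ks / reps
    R[j] <- max(Ks / reps) - min(Ks / reps)
    opt[[j]] <- lev[which.max(Ks / reps)]
  }
  ord <- order(-R, seq_along(R))  # ties: keep design factor order
  structure(list(K = K, k = k, R = R,
                 ranking = colnames(idx)[ord],
                 optimal_levels = opt),
            class = "range_table")
}

#' @export
print.range_table <- function(x, digits = 3, ...) {
  cat("Range analysis\n")
  tab <- rbind(x$K, x$k, R = x$R)
  rownames(tab) <- c(paste0("K", seq_len(nrow(x$K))),
                     paste0("k", seq_len(nrow(x$k))), "R")
  print(round(tab, digits))
  cat("Factor importance: ", paste(x$ranking, collapse = " > "), "\n", sep = "")
  cat("Optimal levels: ",
      paste(names(x$optimal_levels),
            vapply(x$optimal_levels, function(v) paste(format(v)), ""),
            sep = "=", collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' ANOVA of a balanced orthogonal experiment
#'
#' Partitions the total sum of squares over the design's factors, with the
#' unassigned remainder as the error term (equivalent to the empty column of
#' the array):
#' \eqn{SS_{factor} = \sum_{levels} K^2 / r - (\sum y)^2 / m}, where r is the
#' number of runs per level, and \eqn{SS_{error} = SS_{total} - \sum SS_{factor}}.
#' F ratios test each factor mean square against the error mean square; P
#' values come from the upper tail of the F distribution.
#'
#' @inheritParams range_analysis
#' @return An `anova_table` data.frame with columns `source`, `ss`, `df`,
#'   `ms`, `F`, `p` (rows: one per factor, Error, Total). With zero error df
#'   the F and p columns are `NA` (flagged in printing).
#' @export
orthogonal_anova <- function(design, y) {
  stopifnot(inherits(design, "orthogonal_design"))
  check_balance(design)
  y <- as.numeric(y)
  idx <- design$assignment
  m <- nrow(idx)
  if (length(y) != m)
    stop("response length ", length(y), " does not match ", m, " runs",
         call. = FALSE)
  cf <- sum(y)^2 / m
  ss_tot <- sum(y^2) - cf
  ss_f <- df_f <- stats::setNames(numeric(ncol(idx)), colnames(idx))
  for (j in seq_len(ncol(idx))) {
    reps <- sum(idx[, j] == 1L)
    Ks <- tapply(y, idx[, j], sum)
    ss <- sum(Ks^2) / reps - cf
    if (ss < -1e-9)
      stop("negative factor sum of squares (", format(ss),
           "): numerical failure", call. = FALSE)
    ss_f[j] <- max(ss, 0)
    df_f[j] <- length(design$factors[[j]]) - 1L
  }
  ss_err <- ss_tot - sum(ss_f)
  if (ss_err < -1e-9 * max(ss_tot, 1))
    stop("negative error sum of squares: factors overfit the design",
         call. = FALSE)
  ss_err <- max(ss_err, 0)
  df_err <- (m - 1L) - sum(df_f)
  ms_f <- ss_f / df_f
  if (df_err >= 1L) {
    ms_err <- ss_err / df_err
    Fv <- ms_f / ms_err
    pv <- stats::pf(Fv, df_f, df_err, lower.tail = FALSE)
  } else {
    ms_err <- NA_real_
    Fv <- rep(NA_real_, length(ms_f))
    pv <- rep(NA_real_, length(ms_f))
  }
  out <- data.frame(
    source = c(colnames(idx), "Error", "Total"),
    ss = c(ss_f, ss_err, ss_tot),
    df = c(df_f, df_err, m - 1L),
    ms = c(ms_f, ms_err, NA),
    F = c(Fv, NA, NA),
    p = c(pv, NA, NA),
    row.names = NULL, check.names = FALSE)
  structure(out, class = c("anova_table", "data.frame"))
}

format_p <- function(p, floor = 1e-3, digits = 3) {
  ifelse(is.na(p), "",
         ifelse(p < floor, paste0("<", format(floor, scientific = FALSE)),
                formatC(p, digits = digits, format = "f")))
}

#' @export
print.anova_table <- function(x, digits = 3, ...) {
  y <- as.data.frame(x)
  y$p <- format_p(y$p)
  num <- vapply(y, is.numeric, logical(1))
  y[num] <- lapply(y[num], function(col) round(col, digits))
  print(y, row.names = FALSE, na.print = "")
  invisible(x)
}
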
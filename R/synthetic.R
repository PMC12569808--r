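# Run code under a private RNG stream without disturbing the caller's state.
local_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

#' Generate a perturbed reciprocal judgment matrix
#'
#' Builds a judgment matrix from a known weight vector,
#' \eqn{\alpha_{ef} = (w_e / w_f) e^{\varepsilon_{ef}}} with independent
#' Gaussian log-perturbations on the upper triangle, reciprocals enforced
#' below and unit diagonal. With `perturbation_sd = 0` the matrix is fully
#' consistent and [ahp_weights()] recovers `true_weights` exactly.
#'
#' @param true_weights Positive weights summing to 1.
#' @param perturbation_sd Standard deviation of the log-scale noise (>= 0).
#' @param seed Integer seed; identical inputs give identical output.
#' @return A `judgment_matrix`.
#' @export
gen_judgment_matrix <- function(true_weights, perturbation_sd = 0, seed = 1L) {
  w <- as.numeric(true_weights)
  if (any(!is.finite(w)) || any(w <= 0) || abs(sum(w) - 1) > 1e-9)
    stop("true_weights must be positive and sum to 1", call. = FALSE)
  if (perturbation_sd < 0) stop("perturbation_sd must be >= 0", call. = FALSE)
  n <- length(w)
  J <- outer(w, w, "/")
  if (perturbation_sd > 0) {
    eps <- local_seed(seed, matrix(stats::rnorm(n * n, 0, perturbation_sd), n))
    for (e in seq_len(n - 1L)) for (f in (e + 1L):n) {
      J[e, f] <- J[e, f] * exp(eps[e, f])
      J[f, e] <- 1 / J[e, f]
    }
  }
  diag(J) <- 1
  nms <- names(true_weights) %||% paste0("C", seq_len(n))
  dimnames(J) <- list(nms, nms)
  new_judgment_matrix(J)
}

#' Generate an orthogonal-experiment response from additive factor effects
#'
#' Simulates a per-run response as grand mean + per-factor level effects +
#' Gaussian noise, on a balanced orthogonal design. With zero noise the
#' response is exactly additive, so the design's ANOVA error SS is 0 and
#' range analysis recovers the true effect ordering.
#'
#' @param design An [orthogonal_design()].
#' @param level_effects Named list, one numeric vector of per-level effects
#'   per design factor (matching that factor's level count).
#' @param grand_mean Baseline response level.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric response vector, one value per run.
#' @export
gen_orthogonal_response <- function(design, level_effects, grand_mean = 50,
                                    noise_sd = 0, seed = 1L) {
  stopifnot(inherits(design, "orthogonal_design"))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  idx <- design$assignment
  if (!identical(sort(names(level_effects)), sort(colnames(idx))))
    stop("level_effects must name exactly the design factors", call. = FALSE)
  y <- rep(grand_mean, nrow(idx))
  for (nm in colnames(idx)) {
    eff <- level_effects[[nm]]
    if (length(eff) != length(design$factors[[nm]]))
      stop("effects for factor '", nm, "' must have ",
           length(design$factors[[nm]]), " levels", call. = FALSE)
    y <- y + eff[idx[, nm]]
  }
  if (noise_sd > 0)
    y <- y + local_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  y
}

#' Generate a Box-Behnken response from a known quadratic surface
#'
#' Evaluates a 10-coefficient quadratic (intercept, 3 linear, 3 interaction,
#' 3 quadratic, coded scale, in [fit_quadratic()]'s term order) at each coded
#' run and adds Gaussian noise. With zero noise [fit_quadratic()] returns the
#' true coefficients to numerical precision.
#'
#' @param design A `bbd_design`.
#' @param true_coefficients Numeric vector of 10 coded-scale coefficients.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Integer seed.
#' @return Numeric response vector, one value per run.
#' @export
gen_bbd_response <- function(design, true_coefficients, noise_sd = 0,
                             seed = 1L) {
  stopifnot(inherits(design, "bbd_design"))
  if (length(true_coefficients) != 10L)
    stop("need exactly 10 coefficients (intercept, 3 linear, 3 interaction, ",
         "3 quadratic)", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  y <- as.numeric(quad_model_matrix(design$coded) %*%
                    as.numeric(true_coefficients))
  if (noise_sd > 0)
    y <- y + local_seed(seed, stats::rnorm(length(y), 0, noise_sd))
  y
}
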
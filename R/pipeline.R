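#' Run the full weighting / scoring / DOE / RSM / validation pipeline
#'
#' Executes the two-stage optimization workflow end to end:
#' criterion weighting (AHP subjective x entropy objective, combined
#' multiplicatively), min-max standardization and comprehensive scoring of
#' the orthogonal extraction experiment, range analysis and ANOVA of the
#' scores, the Box-Behnken quadratic fit with lack-of-fit ANOVA and
#' constrained optimization, and replicate-set RSD validation. One CSV is
#' written per analysis table plus a JSON summary of both optima. All CSVs
#' carry full machine precision; rounding is left to the display layer.
#'
#' @param config A named list (or path to a YAML file holding one) with
#'   entries:
#'   \describe{
#'     \item{criteria}{path to the criteria spec (YAML/JSON).}
#'     \item{orthogonal_data}{path to the per-run criterion measurement CSV.}
#'     \item{orthogonal_design}{path to the design CSV (factor columns in
#'       natural units; may carry a `score` column).}
#'     \item{scores}{optional path to an externally supplied per-run score
#'       CSV; when given it overrides the internally computed scores for the
#'       range/ANOVA stage (published score tables are often not exactly
#'       re-derivable from the raw measurements, so reproducing a published
#'       analysis requires feeding the published scores).}
#'     \item{objective_weights}{optional path to a weight-coefficient CSV
#'       whose `objective` column replaces the entropy weights.}
#'     \item{bbd_factors, bbd_data}{paths to the Box-Behnken factor spec and
#'       run CSV.}
#'     \item{validation}{optional path to a replicate-set CSV.}
#'     \item{out_dir}{output directory (created if needed).}
#'     \item{options}{optional list: `ahp_method`, `score_scale`,
#'       `optimize_sense`.}
#'   }
#' @return Invisibly, a list with all stage results (`weights`, `scores`,
#'   `range`, `anova`, `model`, `rsm_anova`, `optimum`, `validation`,
#'   `summary`) and `files` (paths written).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  required <- c("criteria", "orthogonal_data", "orthogonal_design",
                "bbd_factors", "bbd_data", "out_dir")
  missing_keys <- setdiff(required, names(config))
  if (length(missing_keys))
    stop("pipeline config lacks: ", paste(missing_keys, collapse = ", "),
         call. = FALSE)
  opts <- config$options %||% list()
  ahp_method <- opts$ahp_method %||% "eigenvector"
  score_scale <- opts$score_scale %||% 100
  sense <- opts$optimize_sense %||% "maximize"
  out_dir <- config$out_dir
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  written <- character()
  emit <- function(obj, file) {
    path <- file.path(out_dir, file)
    if (is.data.frame(obj)) utils::write.csv(obj, path, row.names = FALSE)
    else jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                              pretty = TRUE)
    written <<- c(written, path)
    path
  }
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      unlink(written)  # no partial output bundle
      stop("pipeline stage [", name, "]: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  # -- stage 1: weights ------------------------------------------------
  res <- list()
  stage("weights", {
    spec <- read_criteria_spec(config$criteria)
    X <- read_criteria_data(config$orthogonal_data, spec$criteria)
    J <- build_judgment_matrix(spec$criteria, spec$tier_ratio_map)
    ahp <- ahp_weights(J, method = ahp_method)
    obj <- if (!is.null(config$objective_weights))
      read_weight_table(config$objective_weights)$objective
    else suppressWarnings(entropy_weights(X))
    comb <- combine_weights(ahp$weights, obj)
    res$weights <- data.frame(
      criterion = names(comb),
      subjective = 100 * as.numeric(ahp$weights),
      objective = 100 * as.numeric(obj),
      combined = 100 * as.numeric(comb))
    res$ahp <- ahp
    res$criteria_matrix <- X
    res$combined <- comb
    emit(res$weights, "weights.csv")
  })

  # -- stage 2: comprehensive scores ----------------------------------
  stage("scores", {
    scores <- if (!is.null(config$scores)) read_scores(config$scores)
    else comprehensive_score(minmax_normalize(res$criteria_matrix),
                             res$combined, scale = score_scale)
    res$scores <- scores
    emit(data.frame(run = names(scores) %||% seq_along(scores),
                    score = as.numeric(scores)), "scores.csv")
  })

  # -- stage 3: range analysis + ANOVA --------------------------------
  stage("orthogonal", {
    od <- read_orthogonal_design(config$orthogonal_design)
    rt <- range_analysis(od$design, res$scores)
    at <- orthogonal_anova(od$design, res$scores)
    res$range <- rt
    res$anova <- at
    ktab <- data.frame(statistic = c(paste0("K", seq_len(nrow(rt$K))),
                                     paste0("k", seq_len(nrow(rt$k))), "R"),
                       rbind(rt$K, rt$k, t(rt$R)), check.names = FALSE,
                       row.names = NULL)
    emit(ktab, "range_analysis.csv")
    emit(as.data.frame(at), "orthogonal_anova.csv")
  })

  # -- stage 4: response surface --------------------------------------
  stage("rsm", {
    factors <- read_bbd_factors(config$bbd_factors)
    bb <- read_bbd_data(config$bbd_data, factors)
    model <- fit_quadratic(bb$design, bb$y)
    at <- rsm_anova(model)
    opt <- optimize_surface(model, sense = sense)
    res$model <- model
    res$rsm_anova <- at
    res$optimum <- opt
    emit(as.data.frame(at), "rsm_anova.csv")
    emit(list(coefficients = as.list(model$coefficients),
              r2 = model$r2, r2_adj = model$r2_adj,
              residual_ss = model$residual_ss,
              pure_error_ss = model$pure_error_ss,
              lack_of_fit_ss = model$lack_of_fit_ss), "rsm_model.json")
  })

  # -- stage 5: validation --------------------------------------------
  if (!is.null(config$validation)) stage("validation", {
    sets <- read_replicate_sets(config$validation)
    rep <- validate_batches(sets)
    res$validation <- rep
    emit(as.data.frame(rep), "validation_report.csv")
  })

  # -- summary ---------------------------------------------------------
  stage("summary", {
    res$summary <- list(
      extraction_optimum = lapply(res$range$optimal_levels, identity),
      extraction_factor_ranking = res$range$ranking,
      granulation_optimum = list(
        natural = as.list(res$optimum$natural),
        rounded = as.list(res$optimum$natural_rounded),
        predicted_response = res$optimum$predicted),
      validation_all_pass = if (!is.null(res$validation))
        all(res$validation$pass) else NA)
    emit(res$summary, "summary.json")
  })
  res$files <- written
  invisible(res)
}
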
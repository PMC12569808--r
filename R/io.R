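#' Read a criteria specification file
#'
#' Reads a YAML or JSON criteria specification: a `criteria` list of
#' `{name, tier, direction}` entries and an optional `tier_ratio_map` of
#' tier-gap to importance ratio.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return List with `criteria` (list of [criterion_spec()]) and
#'   `tier_ratio_map` (named numeric).
#' @export
read_criteria_spec <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(spec$criteria)) stop("spec has no `criteria` entry", call. = FALSE)
  criteria <- validate_criteria(spec$criteria)
  trm <- if (!is.null(spec$tier_ratio_map))
    unlist(spec$tier_ratio_map) else c("0" = 1, "1" = 3, "2" = 5)
  list(criteria = criteria, tier_ratio_map = trm)
}

#' Read a criteria measurement table
#'
#' Reads a CSV of per-run criterion measurements (header row of criterion
#' names, one row per run; an optional first column named `run` supplies row
#' labels) and aligns its columns to a criteria specification's order and
#' directions.
#'
#' @param path CSV path.
#' @param criteria Optional list of [criterion_spec()]; when given, columns
#'   are reordered to match and directions attached.
#' @return A [criteria_matrix()].
#' @export
read_criteria_data <- function(path, criteria = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (tolower(names(df)[1]) %in% c("run", "no", "no.")) {
    rn <- df[[1]]
    df <- df[-1]
    rownames(df) <- rn
  }
  if (is.null(criteria)) return(criteria_matrix(df))
  criteria <- validate_criteria(criteria)
  nms <- vapply(criteria, `[[`, character(1), "name")
  missing_cols <- setdiff(nms, names(df))
  if (length(missing_cols))
    stop("data lacks criterion column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  criteria_matrix(df[nms],
                  vapply(criteria, `[[`, character(1), "direction"))
}

#' Read an orthogonal design (and optional response) table
#'
#' CSV layout: optional `run` column, one column per factor in natural
#' units, and optionally a final response column named `score` or
#' `response`.
#'
#' @param path CSV path.
#' @return List with `design` (an [orthogonal_design()]) and `y` (numeric
#'   response or `NULL`).
#' @export
read_orthogonal_design <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (tolower(names(df)[1]) %in% c("run", "no", "no.")) {
    rownames(df) <- df[[1]]
    df <- df[-1]
  }
  resp <- which(tolower(names(df)) %in% c("score", "response", "y"))
  y <- NULL
  if (length(resp)) {
    y <- as.numeric(df[[resp[1]]])
    df <- df[-resp]
  }
  list(design = orthogonal_design(df), y = y)
}

#' Read Box-Behnken factor specs and run data
#'
#' `read_bbd_factors()` reads a YAML/JSON list of 3 factors with
#' `low`/`center`/`high` in natural units. `read_bbd_data()` reads a CSV of
#' natural-unit factor settings plus a response column, codes the settings,
#' and returns a design whose run order follows the file.
#'
#' @param path File path.
#' @return `read_bbd_factors()`: named list of `c(low, center, high)`.
#'   `read_bbd_data()`: list with `design` (a `bbd_design` in the file's run
#'   order) and `y` (response).
#' @export
read_bbd_factors <- function(path) {
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = FALSE)
  fl <- spec$factors %||% spec
  stats::setNames(
    lapply(fl, function(f) c(f$low, f$center, f$high)),
    vapply(fl, function(f) f$name, character(1)))
}

#' @rdname read_bbd_factors
#' @param factors Factor list as returned by `read_bbd_factors()`.
#' @export
read_bbd_data <- function(path, factors) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (tolower(names(df)[1]) %in% c("run", "no", "no.")) df <- df[-1]
  fnames <- names(factors)
  missing_cols <- setdiff(fnames, names(df))
  if (length(missing_cols))
    stop("data lacks factor column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  resp <- setdiff(names(df), fnames)
  if (length(resp) != 1L)
    stop("expected exactly one response column, found: ",
         paste(resp, collapse = ", "), call. = FALSE)
  template <- generate_bbd(factors, center_count = 5L)
  coded <- code_units(template, as.matrix(df[fnames]))
  if (max(abs(coded - round(coded))) > 1e-9)
    stop("factor settings do not code to -1/0/+1 under the stated levels",
         call. = FALSE)
  coded <- round(coded)
  colnames(coded) <- fnames
  rownames(coded) <- as.character(seq_len(nrow(coded)))
  n_center <- sum(rowSums(coded != 0) == 0L)
  des <- structure(list(factors = template$factors, coded = coded,
                        center_count = as.integer(n_center)),
                   class = "bbd_design")
  list(design = des, y = as.numeric(df[[resp]]))
}

#' Read replicate sets for method validation
#'
#' CSV layout: `label`, `context`, then replicate value columns (`v1`,
#' `v2`, ...; trailing empty cells allowed).
#'
#' @param path CSV path.
#' @return Named list of replicate sets suitable for [validate_batches()].
#' @export
read_replicate_sets <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stopifnot(all(c("label", "context") %in% names(df)))
  vcols <- setdiff(names(df), c("label", "context"))
  out <- lapply(seq_len(nrow(df)), function(i) {
    vals <- suppressWarnings(as.numeric(unlist(df[i, vcols])))
    list(values = vals[is.finite(vals)], context = df$context[i])
  })
  stats::setNames(out, df$label)
}

#' Read a per-run score table
#'
#' @param path CSV with columns `run` and `score`.
#' @return Named numeric vector of scores.
#' @export
read_scores <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  stats::setNames(as.numeric(df$score), df$run)
}

#' Read a published weight-coefficient table
#'
#' CSV with columns `criterion`, `subjective`, `objective` (and optionally
#' `combined`), in percent.
#'
#' @param path CSV path.
#' @return List of [weight_vector()]s (`subjective`, `objective`, and
#'   `combined` when present), each normalized from the percent columns.
#' @export
read_weight_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  grab <- function(col, role) {
    if (!col %in% names(df)) return(NULL)
    v <- as.numeric(df[[col]])
    weight_vector(v / sum(v), df$criterion, role)
  }
  out <- list(subjective = grab("subjective", "subjective"),
              objective = grab("objective", "objective"),
              combined = grab("combined", "combined"))
  out[!vapply(out, is.null, logical(1))]
}
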
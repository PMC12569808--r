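fixture <- function(f) {
  path <- system.file("extdata", f, package = "procopt")
  if (!nzchar(path)) path <- file.path("../../inst/extdata", f)
  path
}

# six extraction quality criteria, two per importance tier
extraction_criteria <- function() {
  list(
    criterion_spec("Albiflorin", 1), criterion_spec("Paeoniflorin", 1),
    criterion_spec("Liquiritin", 2), criterion_spec("Glycyrrhizic acid", 2),
    criterion_spec("Ganoderic acid A", 3), criterion_spec("Dry extract ratio", 3))
}

# balanced L9(3^3) design matching the extraction experiment's layout
l9_design <- function() {
  orthogonal_design(data.frame(
    A = rep(1:3, each = 3),
    B = rep(1:3, 3),
    C = c(1, 3, 2, 3, 2, 1, 2, 1, 3)))
}

published_scores <- c(71.59, 26.21, 54.18, 25.15, 25.62, 38.90,
                      74.45, 63.52, 46.76)

published_bbd <- function() {
  factors <- read_bbd_factors(fixture("granulation_bbd_factors.yaml"))
  read_bbd_data(fixture("granulation_bbd_runs.csv"), factors)
}
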
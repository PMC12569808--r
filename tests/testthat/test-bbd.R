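test_that("the generated 3-factor design is the canonical point set", {
  des <- generate_bbd(list(a = c(6, 10, 14), b = c(80, 85, 90),
                           c = c(10, 12, 14)), center_count = 5)
  expect_equal(nrow(des$coded), 17L)
  expect_equal(sum(rowSums(des$coded != 0) == 0), 5L)
  # columns sum to zero and are pairwise orthogonal
  expect_equal(unname(colSums(des$coded)), c(0, 0, 0))
  expect_equal(unname(crossprod(des$coded)), diag(c(8, 8, 8)))
  # coded run set equals the published run set, order-independent
  pub <- published_bbd()
  key <- function(M) unname(sort(apply(M, 1, paste, collapse = ",")))
  expect_equal(key(des$coded), key(pub$design$coded))

  expect_equal(nrow(generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                                      c = c(-1, 0, 1)), 1)$coded), 13L)
  expect_error(generate_bbd(list(a = c(0, 1, 2), b = c(0, 1, 2))), "3-factor")
  expect_error(generate_bbd(list(a = c(0, 1, 3), b = c(-1, 0, 1),
                                 c = c(-1, 0, 1))), "symmetric")
})

test_that("natural/coded round trip is exact", {
  des <- generate_bbd(list(a = c(6, 10, 14), b = c(80, 85, 90),
                           c = c(10, 12, 14)))
  nat <- decode_units(des, des$coded)
  expect_equal(code_units(des, nat), des$coded, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(decode_units(des, matrix(c(0.185, -1, -0.075), 1))),
               matrix(c(10.74, 80, 11.85), 1), tolerance = 1e-12)
})

test_that("the quadratic fit reproduces the published molding-rate equation", {
  bb <- published_bbd()
  m <- fit_quadratic(bb$design, bb$y)
  b <- unname(m$coefficients)
  expect_equal(b[1], 84.03, tolerance = 0.01)
  expect_equal(b[2:4], c(-0.94, -10.26, 1.83), tolerance = 0.01)
  expect_equal(b[5], -1.33, tolerance = 0.01)
  expect_lt(abs(b[6] - 0.098), 0.005)
  expect_equal(b[7], 2.13, tolerance = 0.01)
  expect_equal(b[8:10], c(-1.03, -0.17, -1.85), tolerance = 0.01)
  expect_equal(m$r2, 0.9886, tolerance = 0.0005)
  expect_equal(m$r2_adj, 0.9739, tolerance = 0.0005)
})

test_that("the fit matches R's own least-squares oracle", {
  bb <- published_bbd()
  m <- fit_quadratic(bb$design, bb$y)
  cd <- as.data.frame(bb$design$coded)
  names(cd) <- c("a", "b", "cc")
  cd$y <- bb$y
  oracle <- stats::lm(y ~ a + b + cc + I(a * b) + I(a * cc) + I(b * cc) +
                        I(a^2) + I(b^2) + I(cc^2), cd)
  expect_equal(unname(m$coefficients), unname(stats::coef(oracle)),
               tolerance = 1e-9)
  expect_equal(m$residual_ss, sum(stats::resid(oracle)^2), tolerance = 1e-9)
  expect_equal(m$r2, summary(oracle)$r.squared, tolerance = 1e-12)
})

test_that("linear coefficients equal their closed-form contrasts", {
  bb <- published_bbd()
  m <- fit_quadratic(bb$design, bb$y)
  cb <- bb$design$coded[, 2]
  expect_equal(unname(m$coefficients[3]),
               (sum(bb$y[cb == 1]) - sum(bb$y[cb == -1])) / 8,
               tolerance = 1e-9)
  expect_equal((288.68 - 370.73) / 8, -10.25625)  # the published contrast
  # property: holds for every linear and interaction term on random data
  des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                           c = c(-1, 0, 1)))
  set.seed(17)
  for (i in 1:5) {
    y <- stats::rnorm(17, 80, 5)
    mm <- fit_quadratic(des, y)
    for (j in 1:3) {
      cj <- des$coded[, j]
      expect_equal(unname(mm$coefficients[1 + j]),
                   (sum(y[cj == 1]) - sum(y[cj == -1])) / 8,
                   tolerance = 1e-9)
    }
    # interaction contrast: quarter of the 4-point cross difference
    ab <- des$coded[, 1] * des$coded[, 2]
    expect_equal(unname(mm$coefficients[5]),
                 (sum(y[ab == 1]) - sum(y[ab == -1])) / 4, tolerance = 1e-9)
  }
})

test_that("a noiseless quadratic is interpolated exactly", {
  des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                           c = c(-1, 0, 1)))
  truth <- c(80, 1, -4, 2, 0.5, -0.25, 1.5, -2, 0.75, -1)
  y <- gen_bbd_response(des, truth, noise_sd = 0)
  m <- fit_quadratic(des, y)
  expect_equal(unname(m$coefficients), truth, tolerance = 1e-9)
  expect_equal(m$residual_ss, 0, tolerance = 1e-9)
  at <- rsm_anova(m)
  expect_equal(at$ss[at$source %in% c("Residual", "Lack of fit",
                                      "Pure error")],
               c(0, 0, 0), tolerance = 1e-9)
})

test_that("the RSM ANOVA reproduces the published molding-rate table", {
  bb <- published_bbd()
  at <- rsm_anova(fit_quadratic(bb$design, bb$y))
  ss <- stats::setNames(at$ss, at$source)
  Fv <- stats::setNames(at$F, at$source)
  expect_equal(unname(Fv["Model"]), 67.36, tolerance = 0.1)
  expect_equal(unname(ss["ethanol"]), 841.53, tolerance = 0.05)
  expect_equal(unname(ss["Pure error"]), 5.45, tolerance = 0.01)
  expect_equal(at$df[at$source == "Lack of fit"], 3L)
  expect_equal(unname(ss["Lack of fit"]), 5.18, tolerance = 0.01)
  expect_equal(unname(round(Fv["Lack of fit"], 2)), 1.27)
  # published per-term partial SS
  expect_equal(unname(ss[c("diluent", "binder")]), c(7.03, 26.75),
               tolerance = 0.01)
  expect_equal(unname(ss[c("diluent^2", "ethanol^2", "binder^2")]),
               c(4.50, 0.116, 14.35), tolerance = 0.01)
})

test_that("ANOVA partitions close: model + residual = total, lof + pure = residual", {
  des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                           c = c(-1, 0, 1)))
  set.seed(29)
  for (i in 1:5) {
    y <- gen_bbd_response(des, stats::rnorm(10), noise_sd = 1, seed = i)
    m <- fit_quadratic(des, y)
    at <- rsm_anova(m)
    ss <- stats::setNames(at$ss, at$source)
    expect_equal(unname(ss["Model"] + ss["Residual"]), unname(ss["Total"]),
                 tolerance = 1e-6 * max(ss["Total"], 1))
    expect_equal(unname(ss["Lack of fit"] + ss["Pure error"]),
                 unname(ss["Residual"]), tolerance = 1e-9)
    # partial SS of the orthogonal columns reduces to the contrast form
    beta <- m$coefficients
    expect_equal(unname(ss[c("a", "b", "c")]), unname(8 * beta[2:4]^2),
                 tolerance = 1e-9)
    expect_equal(unname(ss[c("a:b", "a:c", "b:c")]),
                 unname(4 * beta[5:7]^2), tolerance = 1e-9)
  }
})

test_that("lack of fit is flagged unavailable without center replicates", {
  des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                           c = c(-1, 0, 1)), center_count = 1)
  y <- gen_bbd_response(des, c(80, 1, -4, 2, 0.5, -0.25, 1.5, -2, 0.75, -1),
                        noise_sd = 0.5, seed = 2)
  m <- fit_quadratic(des, y)
  expect_true(is.na(m$pure_error_ss))
  expect_warning(at <- rsm_anova(m), "center replicates")
  expect_true(is.na(at$ss[at$source == "Pure error"]))
})

test_that("the constrained optimum matches the published granulation settings", {
  bb <- published_bbd()
  opt <- optimize_surface(fit_quadratic(bb$design, bb$y), "maximize")
  expect_equal(unname(opt$natural_rounded),
               c(11, 80, 12))  # diluent parts, ethanol %, binder %
  expect_true(opt$at_boundary["ethanol"])
  expect_equal(unname(opt$natural["ethanol"]), 80)
  expect_equal(unname(opt$natural["diluent"]), 10.7, tolerance = 0.1)
  expect_equal(unname(opt$natural["binder"]), 11.8, tolerance = 0.1)
})

test_that("a concave bowl peaks at the coded origin", {
  des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                           c = c(-1, 0, 1)))
  y <- gen_bbd_response(des, c(10, 0, 0, 0, 0, 0, 0, -1, -1, -1), 0)
  opt <- optimize_surface(fit_quadratic(des, y))
  expect_equal(unname(opt$coded), c(0, 0, 0), tolerance = 1e-9)
  expect_equal(opt$predicted, 10, tolerance = 1e-9)
})

test_that("the optimizer matches an exhaustive grid search on random surfaces", {
  des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                           c = c(-1, 0, 1)))
  step <- 0.02
  grid <- as.matrix(expand.grid(a = seq(-1, 1, step), b = seq(-1, 1, step),
                                c = seq(-1, 1, step)))
  set.seed(101)
  for (i in 1:5) {
    truth <- stats::rnorm(10, 0, 2)
    y <- gen_bbd_response(des, truth, noise_sd = 0)
    m <- fit_quadratic(des, y)
    b <- unname(m$coefficients)
    vals <- b[1] + grid %*% b[2:4] + b[5] * grid[, 1] * grid[, 2] +
      b[6] * grid[, 1] * grid[, 3] + b[7] * grid[, 2] * grid[, 3] +
      grid^2 %*% b[8:10]
    for (sense in c("maximize", "minimize")) {
      opt <- optimize_surface(m, sense)
      sgn <- if (sense == "maximize") 1 else -1
      best_grid <- max(sgn * vals) * sgn
      expect_true(all(abs(opt$coded) <= 1 + 1e-12))
      # never worse than the grid, and never better than a grid step allows
      expect_gte(sgn * opt$predicted, sgn * best_grid - 1e-9)
      expect_lte(sgn * (opt$predicted - best_grid), sum(abs(b)) * step^2)
      idx <- which.max(sgn * as.numeric(vals))
      expect_lte(max(abs(opt$coded - grid[idx, ])), step + 1e-9)
    }
  }
})

test_that("dominant negative linear terms drive the maximizer to the lower face", {
  des <- generate_bbd(list(a = c(-1, 0, 1), b = c(-1, 0, 1),
                           c = c(-1, 0, 1)))
  # |linear b| exceeds the interacting magnitudes: b saturates at -1
  y <- gen_bbd_response(des, c(84, -1, -10, 2, -1.3, 0.1, 2.1, -1, -0.2, -1.8), 0)
  opt <- optimize_surface(fit_quadratic(des, y))
  expect_equal(unname(opt$coded[2]), -1)
})
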
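bm_data <- function(seed, n = 48, beta = 2, lambda_noise = 1) {
  withr::with_seed(seed, {
    tr <- ape::rphylo(n, 1, 0)
    V <- ape::vcv(tr)
    x <- MASS::mvrnorm(1, rep(0, n), V)
    y <- beta * x + MASS::mvrnorm(1, rep(0, n), lambda_noise * V)
    list(tree = tr, data = tibble::tibble(species = tr$tip.label,
                                          x = x, y = y))
  })
}

test_that("lambda = 0 reproduces ordinary least squares", {
  d <- bm_data(1)
  f0 <- pgls_fit(d$data, "y", "x", d$tree, lambda = 0)
  ols <- stats::lm(y ~ x, d$data)
  expect_equal(f0$coefficients$estimate, unname(stats::coef(ols)),
               tolerance = 1e-8)
  expect_equal(f0$r_squared, summary(ols)$r.squared, tolerance = 1e-8)
})

test_that("a star phylogeny gives OLS for any lambda", {
  withr::with_seed(2, {
    tr <- ape::stree(20, type = "star")
    tr$edge.length <- rep(1, nrow(tr$edge))
    d <- tibble::tibble(species = tr$tip.label, x = stats::rnorm(20),
                        y = stats::rnorm(20))
    f <- suppressWarnings(pgls_fit(d, "y", "x", tr, lambda = 1))
    ols <- stats::lm(y ~ x, d)
    expect_equal(f$coefficients$estimate, unname(stats::coef(ols)),
                 tolerance = 1e-8)
  })
})

test_that("estimates agree with an independent GLS implementation", {
  skip_if_not_installed("nlme")
  d <- bm_data(42, n = 48)
  f <- pgls_fit(d$data, "y", "x", d$tree, lambda = "REML")
  g <- nlme::gls(y ~ x, data = as.data.frame(d$data),
                 correlation = ape::corPagel(0.8, d$tree, form = ~species),
                 method = "REML")
  expect_equal(f$coefficients$estimate, unname(stats::coef(g)),
               tolerance = 1e-3)
  expect_equal(f$lambda, unname(stats::coef(g$modelStruct$corStruct)),
               tolerance = 0.01)
})

test_that("a constant response has zero slope and zero R-squared", {
  d <- bm_data(3)
  d$data$y <- 5
  f <- pgls_fit(d$data, "y", "x", d$tree, lambda = 0.5)
  expect_equal(f$coefficients$estimate[2], 0, tolerance = 1e-10)
  expect_equal(f$r_squared, 0, tolerance = 1e-10)
})

test_that("the profiled likelihood at the optimum beats a lambda grid", {
  # fixed-lambda fits report the full (ML) likelihood, so the comparable
  # optimised fit is the ML one
  d <- bm_data(4)
  f <- pgls_fit(d$data, "y", "x", d$tree, lambda = "ML")
  grid <- seq(1e-6, 1, length.out = 21)
  lls <- vapply(grid, function(l) {
    pgls_fit(d$data, "y", "x", d$tree, lambda = l)$logLik
  }, numeric(1))
  expect_gte(f$logLik + 1e-6, max(lls))
})

test_that("permuting species rows leaves the fit unchanged", {
  d <- bm_data(5)
  f1 <- pgls_fit(d$data, "y", "x", d$tree)
  perm <- d$data[sample(nrow(d$data)), ]
  f2 <- pgls_fit(perm, "y", "x", d$tree)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-10)
  expect_equal(f1$lambda, f2$lambda, tolerance = 1e-8)
})

test_that("categorical predictors use lexicographic treatment coding", {
  d <- bm_data(6)
  d$data$diet <- rep(c("omnivore", "carnivore", "herbivore"), length.out = 48)
  f <- pgls_fit(d$data, "y", "diet", d$tree, lambda = 0.5)
  expect_equal(f$coefficients$term,
               c("(Intercept)", "dietherbivore", "dietomnivore"))
  expect_equal(f$df[1], 2)
})

test_that("input validation rejects undersized or degenerate problems", {
  d <- bm_data(7)
  expect_error(pgls_fit(d$data[1:2, ], "y", "x", d$tree), ">= 3 species")
  d$data$z <- d$data$x
  expect_error(pgls_fit(d$data, "y", c("x", "z"), d$tree), "singular")
})

test_that("family count correlations report R2 = 1 for identical counts", {
  withr::with_seed(8, {
    tr <- ape::rphylo(24, 1, 0)
    counts <- tibble::tibble(species = tr$tip.label,
                             OR = stats::rpois(24, 50))
    counts$TAAR <- counts$OR
    res <- family_count_correlations(counts, tr,
                                     families = c("OR", "TAAR"))
    expect_equal(res$r_squared, 1, tolerance = 1e-6)
    # fewer than 3 shared species: skipped with a warning
    expect_warning(
      out <- family_count_correlations(counts[1:2, ], tr,
                                       families = c("OR", "TAAR")),
      "skipped")
    expect_equal(nrow(out), 0L)
  })
})

test_that("trophic levels map onto the three diet classes", {
  expect_equal(diet_from_trophic_level(c(2.19, 2.2, 2.79, 2.8)),
               c("herbivore", "omnivore", "omnivore", "carnivore"))
  expect_equal(diet_from_trophic_level(2.196), "omnivore")
  expect_equal(diet_from_trophic_level(2.193), "herbivore")
  expect_equal(diet_from_trophic_level(1.0), "herbivore")
  expect_equal(diet_from_trophic_level(4.5), "carnivore")
  expect_error(diet_from_trophic_level(0), "> 0")
})

test_that("pgls fits expose broom-style methods and a plot", {
  d <- bm_data(9)
  f <- pgls_fit(d$data, "y", "x", d$tree)
  expect_s3_class(tidy(f), "tbl_df")
  expect_equal(nrow(tidy(f)), 2L)
  expect_equal(glance(f)$n, 48)
  expect_s3_class(autoplot(f), "ggplot")
})
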
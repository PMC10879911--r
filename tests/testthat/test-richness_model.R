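test_that("spearman_correlation handles monotone maps, ties and errors", {
  x <- 1:10
  expect_equal(spearman_correlation(x, x^2)$rho, 1)
  expect_equal(spearman_correlation(x, -x)$rho, -1)
  # frozen values from an independent rank-and-Pearson computation
  xt <- c(1, 2, 2, 3, 4, 4, 4, 5, 6, 7)
  yt <- c(2.1, 1.9, 3.0, 3.0, 2.5, 4.1, 3.9, 5.0, 4.8, 6.2)
  ct <- spearman_correlation(xt, yt)
  expect_equal(ct$rho, 0.8796966720, tolerance = 1e-9)
  expect_equal(ct$p_value, 0.0007906288, tolerance = 1e-8)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:3, 3:1), "at least 4")
})

test_that("fit_quasipoisson matches closed forms and the IRLS oracle", {
  # intercept-only: coefficient is log(mean richness)
  tab <- data.frame(richness = c(3L, 5L, 7L, 9L))
  f0 <- fit_quasipoisson(tab, character(0))
  expect_equal(unname(f0$coefficients), log(6), tolerance = 1e-10)

  # fixed fixture vs hand-rolled IRLS (frozen from the oracle run)
  tab <- data.frame(richness = c(3L, 2L, 4L, 6L, 5L, 8L, 4L, 7L, 9L, 12L,
                                 10L, 15L),
                    x1 = seq(0, 1, length.out = 12),
                    x2 = c(rep(0, 6), rep(1, 6)))
  fit <- fit_quasipoisson(tab, c("x1", "x2"))
  expect_equal(unname(fit$coefficients),
               c(0.941108053362, 2.348583256166, -0.570198654795),
               tolerance = 1e-8)
  expect_equal(fit$dispersion, 0.256274960783, tolerance = 1e-8)
  X <- cbind(1, tab$x1, tab$x2)
  expect_equal(unname(fit$coefficients), oracle_irls(X, tab$richness),
               tolerance = 1e-8)
  # quasipoisson SEs are Poisson SEs scaled by sqrt(phi)
  pois <- glm(richness ~ x1 + x2, poisson, tab)
  expect_equal(unname(fit$std_errors),
               unname(sqrt(diag(vcov(pois))) * sqrt(fit$dispersion)),
               tolerance = 1e-6)
  # score equations essentially solved
  mu <- exp(drop(X %*% fit$coefficients))
  expect_lt(max(abs(t(X) %*% (tab$richness - mu))), 1e-8)
})

test_that("dispersion is near 1 for equidispersed Poisson data", {
  set.seed(2024)
  n <- 500
  x <- runif(n)
  tab <- data.frame(richness = rpois(n, exp(1 + 0.5 * x)), x = x)
  fit <- fit_quasipoisson(tab, "x")
  expect_gt(fit$dispersion, 0.8)
  expect_lt(fit$dispersion, 1.2)
})

test_that("degenerate designs are rejected", {
  tab <- data.frame(richness = c(2L, 4L, 6L, 3L, 5L), x = 1:5, y = 2 * (1:5))
  expect_error(fit_quasipoisson(tab, c("x", "y")), "singular")
  expect_error(fit_quasipoisson(tab[1:2, ], "x"), "n > p")
  expect_error(fit_quasipoisson(tab, "nope"), "not in table")
})

test_that("anova_f compares nested fits by scaled deviance", {
  set.seed(5)
  tab <- data.frame(richness = rpois(30, 6), x = runif(30), z = runif(30))
  full <- fit_quasipoisson(tab, c("x", "z"))
  red <- fit_quasipoisson(tab, "x")
  out <- anova_f(red, full)
  expect_s3_class(out, "deviance_test")
  expect_equal(out$term_tested, "z")
  expect_equal(out$df_num, 1L)
  expect_equal(out$df_den, full$df_residual)
  expect_equal(out$f_value,
               ((red$deviance - full$deviance) / 1) / full$dispersion)
  # identical models: F = 0, p = 1
  same <- anova_f(full, full)
  expect_equal(same$f_value, 0)
  expect_equal(same$p_value, 1)
  # non-nested rejected
  other <- fit_quasipoisson(tab, "z")
  expect_error(anova_f(other, fit_quasipoisson(tab, "x")), "nested")
})

test_that("anova_f detects a true elevation effect at study scale", {
  # n = 28 sites, log-linear decline of -0.001/m: removal should be
  # rejected (p < .05) in at least 90% of 200 replicates
  bands <- default_site_layout()$band
  hits <- 0
  set.seed(42)
  for (r in 1:200) {
    y <- rpois(28, exp(2.7 - 0.001 * bands))
    tab <- data.frame(richness = y, elev = bands)
    full <- fit_quasipoisson(tab, "elev")
    red <- fit_quasipoisson(tab, character(0))
    if (anova_f(red, full)$p_value < 0.05) hits <- hits + 1
  }
  expect_gte(hits, 180)
})

test_that("backwards stepwise keeps signal and sheds noise", {
  set.seed(99)
  # strong single significant term: identity (no removal)
  n <- 60
  x <- runif(n)
  tab <- data.frame(richness = rpois(n, exp(1 + 1.5 * x)), x = x)
  sw <- backwards_stepwise(tab, "x")
  expect_null(sw$trace)
  expect_equal(sw$fit$terms, "x")

  # selection consistency: elevation signal + 3 pure-noise covariates
  keep_elev <- 0
  keep_noise <- c(n1 = 0, n2 = 0, n3 = 0)
  for (r in 1:100) {
    n <- 200
    elev <- runif(n, 1100, 2500)
    tab <- data.frame(richness = rpois(n, exp(2.5 - 0.001 * elev)),
                      elev = elev, n1 = runif(n), n2 = runif(n),
                      n3 = runif(n))
    sw <- backwards_stepwise(tab, c("elev", "n1", "n2", "n3"),
                             criterion = "strict_alpha")
    if ("elev" %in% sw$fit$terms) keep_elev <- keep_elev + 1
    for (nm in names(keep_noise)) {
      if (nm %in% sw$fit$terms) keep_noise[nm] <- keep_noise[nm] + 1
    }
  }
  expect_gte(keep_elev, 95)
  for (nm in names(keep_noise)) expect_lte(keep_noise[[nm]], 10)
})

test_that("all-noise models collapse towards the intercept", {
  set.seed(3)
  sizes <- integer(40)
  for (r in 1:40) {
    n <- 100
    tab <- data.frame(richness = rpois(n, 5), n1 = runif(n), n2 = runif(n))
    sw <- suppressWarnings(
      backwards_stepwise(tab, c("n1", "n2"), criterion = "strict_alpha")
    )
    sizes[r] <- length(sw$fit$terms)
  }
  counts <- table(factor(sizes, levels = 0:2))
  expect_equal(names(which.max(counts)), "0")
})

test_that("stepwise trace is reproducible", {
  com <- generate_community(seed = 8)
  eff <- effort_from_records(com$occurrences, com$visits)
  rt <- richness_per_site(com$occurrences, com$sites, eff)
  terms <- c("elevation_band_lower", "se_value", "veg_cover", "slope")
  a <- backwards_stepwise(rt, terms)
  b <- backwards_stepwise(rt, terms)
  expect_identical(a$trace, b$trace)
  expect_identical(a$fit$coefficients, b$fit$coefficients)
})

test_that("term_f_table matches an independent deviance-drop oracle", {
  set.seed(14)
  n <- 40
  tab <- data.frame(x1 = runif(n), x2 = runif(n))
  tab$richness <- rpois(n, exp(1 + 0.8 * tab$x1 - 0.5 * tab$x2))
  fit <- fit_quasipoisson(tab, c("x1", "x2"))
  tab_f <- term_f_table(fit, type = "sequential")
  # oracle: deviances of the nested sequence via hand-rolled IRLS
  X_full <- cbind(1, tab$x1, tab$x2)
  y <- tab$richness
  devs <- c(
    oracle_poisson_deviance(X_full[, 1, drop = FALSE], y,
                            oracle_irls(X_full[, 1, drop = FALSE], y)),
    oracle_poisson_deviance(X_full[, 1:2], y, oracle_irls(X_full[, 1:2], y)),
    oracle_poisson_deviance(X_full, y, oracle_irls(X_full, y))
  )
  phi <- oracle_pearson_phi(X_full, y, oracle_irls(X_full, y))
  expect_equal(tab_f$f_value, -diff(devs) / phi, tolerance = 1e-7)
  # single-covariate model: sequential test equals anova_f vs intercept
  f1 <- fit_quasipoisson(tab, "x1")
  seq1 <- term_f_table(f1, type = "sequential")
  cmp <- anova_f(fit_quasipoisson(tab, character(0)), f1)
  expect_equal(seq1$f_value, cmp$f_value)
  expect_equal(seq1$p_value, cmp$p_value)
})
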
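test_that("species-level filter and singleton removal", {
  mixed <- occ_tbl(occ("S1", "spA"), occ("S1", "G", rank = "higher"),
                   occ("S1", "spB"))
  expect_equal(nrow(filter_species_level(mixed)), 2)
  expect_equal(filter_species_level(mixed)$taxon_id, c("spA", "spB"))
  pure <- occ_tbl(occ("S1", "spA"), occ("S1", "spB"))
  expect_equal(filter_species_level(pure), pure)

  # singleton = one individual across the whole study, not one record/site
  r <- occ_tbl(occ("S1", "spA", count = 1), occ("S2", "spA", count = 1),
               occ("S1", "spB", count = 1),
               occ("S1", "spC", count = 2))
  out <- remove_singletons(r)
  expect_setequal(unique(out$taxon_id), c("spA", "spC"))
  expect_equal(attr(out, "singletons"), "spB")
  expect_equal(remove_singletons(pure)$taxon_id, character(0))
  none <- occ_tbl(occ("S1", "spA", count = 3), occ("S1", "spB", count = 2))
  expect_equal(remove_singletons(none)$taxon_id, none$taxon_id)
})

test_that("species_elevational_range implements the band-bound formulas", {
  sites <- sites_tbl(seq(1100, 2500, 100),
                     ids = paste0("S", seq(1100, 2500, 100)))
  at <- function(band, sp) occ(paste0("S", band), sp)
  # single band -> 100 m range, midpoint at band centre
  r <- species_elevational_range(at(1400, "spA"), sites)
  expect_equal(r$range_m, 100)
  expect_equal(r$midpoint_m, 1450)
  # full span 1100..2500 -> 1500 m
  r <- species_elevational_range(occ_tbl(at(1100, "spB"), at(2500, "spB")),
                                 sites)
  expect_equal(r$range_m, 1500)
  # bands {1600, 2000} -> 500 m, midpoint 1850
  r <- species_elevational_range(occ_tbl(at(1600, "spC"), at(2000, "spC")),
                                 sites)
  expect_equal(r$range_m, 500)
  expect_equal(r$midpoint_m, 1850)
  expect_equal(attr(r, "window"), c(1100, 2600))
})

test_that("ranges satisfy the algebraic identities and the brute oracle", {
  set.seed(77)
  sites <- sites_tbl(seq(1100, 2500, 100),
                     ids = paste0("S", seq(1100, 2500, 100)))
  for (i in 1:60) {
    recs <- do.call(rbind, lapply(1:10, function(j) {
      occ(paste0("S", sample(seq(1100, 2500, 100), 1)),
          paste0("sp", sample(4, 1)))
    }))
    got <- species_elevational_range(recs, sites)
    ora <- oracle_ranges(recs, sites)
    expect_equal(got$range_m, ora$range_m)
    expect_equal(got$midpoint_m, ora$midpoint_m)
    # identities: range positive multiple of 100; midpoint centred
    expect_true(all(got$range_m >= 100))
    expect_true(all(got$range_m %% 100 == 0))
    expect_equal(got$midpoint_m - got$min_band, got$range_m / 2)
    expect_true(all(got$min_band <= got$midpoint_m - 50 &
                      got$midpoint_m + 50 <= got$max_band + 100))
    # removing records never increases a range
    sub <- recs[-sample(nrow(recs), 1), , drop = FALSE]
    before <- setNames(got$range_m, got$species_id)
    after <- species_elevational_range(sub, sites)
    expect_true(all(after$range_m <= before[after$species_id]))
  }
})

test_that("fit_polynomials: nested RSS, closed-form AIC, raw-scale coefficients", {
  set.seed(31)
  x <- runif(50, 1100, 2600)
  y <- 2 * x + 1 + rnorm(50)
  fits <- fit_polynomials(x, y, max_order = 4)
  rss <- vapply(fits, `[[`, 0, "rss")
  expect_true(all(diff(rss) <= 1e-6))              # nested monotonicity
  aic <- vapply(fits, `[[`, 0, "aic")
  expect_equal(which.min(aic), 1L)                 # order 1 wins on a line
  # AIC and adjusted R2 agree with the independent closed-form oracle
  for (k in 1:4) {
    o <- oracle_poly_stats(x, y, k)
    expect_equal(fits[[k]]$rss, o$rss, tolerance = 1e-8)
    expect_equal(fits[[k]]$aic, o$aic, tolerance = 1e-8)
    expect_equal(fits[[k]]$adj_r2, o$adj_r2, tolerance = 1e-8)
  }
  # AIC convention matches stats::AIC for a Gaussian linear model
  expect_equal(fits[[1]]$aic, AIC(lm(y ~ x)), tolerance = 1e-8)
  # raw-scale coefficients reproduce the fitted values
  b <- fits[[2]]$coefficients
  expect_equal(unname(b[1] + b[2] * x + b[3] * x^2),
               unname(fits[[2]]$fitted), tolerance = 1e-6)
  expect_equal(unname(fits[[1]]$coefficients), unname(coef(lm(y ~ x))),
               tolerance = 1e-6)
  expect_error(fit_polynomials(x[1:4], y[1:4], 4), "n > max_order")
  expect_error(fit_polynomials(rep(1500, 50), y), "zero variance")
})

test_that("select_model minimises AIC and runs nested F-tests", {
  set.seed(8)
  x <- runif(40, 1100, 2600)
  y <- 900 - 0.0013 * (x - 1850)^2 + rnorm(40, 0, 30)  # clean hump
  fits <- fit_polynomials(x, y)
  sel <- select_model(fits)
  expect_equal(sel$best$order, 2)
  expect_equal(which.max(sel$adj_r2), 2L)
  expect_equal(nrow(sel$comparisons), 3)
  # F formula check against direct arithmetic
  with(sel$comparisons[1, ], {
    lo <- fits[[1]]; hi <- fits[[2]]
    expect_equal(f_value, ((lo$rss - hi$rss) / 1) / (hi$rss / hi$residual_df))
  })
  expect_lt(sel$comparisons$p_value[1], 0.001)   # quadratic >> linear
  expect_gt(sel$comparisons$p_value[3], 0.05)    # quartic adds nothing
})

test_that("linear-truth communities recover the generating slope", {
  # range = 0.4 * midpoint + noise: order 1 selected in most replicates and
  # the slope estimate is within 2 SE of truth in ~95% of them
  set.seed(606)
  reps <- 200
  order1 <- 0; covered <- 0
  for (r in 1:reps) {
    pts <- simulate_species_ranges(
      30, list(type = "rapoport_linear", coef = c(intercept = 0, slope = 0.4),
               noise_sd = 300))
    fits <- fit_polynomials(pts$midpoint_m, pts$range_m)
    if (select_model(fits)$best$order == 1) order1 <- order1 + 1
    lmfit <- summary(lm(range_m ~ midpoint_m, pts))
    est <- lmfit$coefficients["midpoint_m", ]
    if (abs(est["Estimate"] - 0.4) <= 2 * est["Std. Error"]) {
      covered <- covered + 1
    }
  }
  expect_gt(order1, reps / 2)
  expect_gte(covered / reps, 0.85)
})

test_that("stevens_estimate averages ranges over covering species", {
  sites <- sites_tbl(seq(1100, 2500, 100),
                     ids = paste0("S", seq(1100, 2500, 100)))
  at <- function(band, sp) occ(paste0("S", band), sp)
  # two species, ranges 100 and 500, overlapping at 1600 -> mean 300
  recs <- occ_tbl(at(1600, "spA"),
                  at(1600, "spB"), at(2000, "spB"))
  rng <- species_elevational_range(recs, sites)
  st <- stevens_estimate(rng)
  expect_equal(st$mean_range_m[st$band == 1600], 300)
  expect_equal(st$mean_range_m[st$band == 2000], 500)
  expect_false(1100 %in% st$band)
  # identical ranges -> constant across bands
  same <- occ_tbl(at(1200, "spX"), at(1500, "spX"),
                  at(1200, "spY"), at(1500, "spY"))
  st <- stevens_estimate(species_elevational_range(same, sites))
  expect_true(all(st$mean_range_m == 400))
  # Rapoport-positive community: band vs mean range correlates positively
  set.seed(12)
  cfg <- scenario_config(range_model = list(
    type = "rapoport_linear", coef = c(intercept = -200, slope = 0.5),
    noise_sd = 100))
  com <- generate_community(cfg, seed = 21)
  sp <- remove_singletons(filter_species_level(com$occurrences))
  st <- stevens_estimate(species_elevational_range(sp, com$sites))
  expect_gt(spearman_correlation(st$band, st$mean_range_m)$rho, 0)
})

test_that("pagel_estimate regresses range on the upper range extreme", {
  sites <- sites_tbl(seq(1100, 2500, 100),
                     ids = paste0("S", seq(1100, 2500, 100)))
  at <- function(band, sp) occ(paste0("S", band), sp)
  # degenerate: all species share the same maximum elevation
  recs <- occ_tbl(at(1500, "spA"), at(1500, "spB"), at(1500, "spC"))
  expect_error(pagel_estimate(species_elevational_range(recs, sites)),
               "variance")
  # five-species toy table vs closed-form OLS
  rng <- data.frame(species_id = paste0("s", 1:5),
                    min_band = c(1100, 1200, 1300, 1200, 1500),
                    max_band = c(1400, 1800, 2000, 2400, 2500))
  rng$range_m <- rng$max_band + 100 - rng$min_band
  attr(rng, "band_width") <- 100
  pe <- pagel_estimate(rng)
  xx <- rng$max_band + 100; yy <- rng$range_m
  expect_equal(pe$slope, sum((xx - mean(xx)) * (yy - mean(yy))) /
                 sum((xx - mean(xx))^2), tolerance = 1e-10)
  expect_equal(pe$intercept, mean(yy) - pe$slope * mean(xx),
               tolerance = 1e-10)
  # slope recovery when range is proportional to max elevation
  set.seed(9)
  maxb <- sample(seq(1500, 2500, 100), 40, replace = TRUE)
  truth <- 0.5
  rng2 <- data.frame(species_id = paste0("t", 1:40),
                     min_band = maxb - round(pmax(
                       100, truth * (maxb + 100) + rnorm(40, 0, 80)) / 100) *
                       100 + 100,
                     max_band = maxb)
  rng2$range_m <- rng2$max_band + 100 - rng2$min_band
  attr(rng2, "band_width") <- 100
  pe2 <- pagel_estimate(rng2)
  expect_gt(pe2$slope, 0.3)
  expect_lt(pe2$p_value, 0.01)
})
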
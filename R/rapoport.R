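#' Keep only records identified to species level
#'
#' Range-size analysis treats species as data points, so records left at a
#' higher taxonomic rank (whose members may have distinct ecological
#' requirements) are excluded first.
#'
#' @param records occurrence records.
#' @return the subset of `records` with `rank == "species"`.
#' @export
filter_species_level <- function(records) {
  records[records$rank == "species", , drop = FALSE]
}

#' Remove singleton species
#'
#' A singleton is a species represented by a single individual in the whole
#' study (total `count` across all records equals 1); a one-specimen range
#' carries no information about range size, so these species are dropped.
#'
#' @param records species-rank occurrence records.
#' @return `records` without singleton species; the dropped species ids are
#'   attached as `attr(, "singletons")`.
#' @export
remove_singletons <- function(records) {
  if (!NROW(records)) {
    attr(records, "singletons") <- character(0)
    return(records)
  }
  totals <- tapply(records$count, records$taxon_id, sum)
  singles <- names(totals)[totals == 1]
  out <- records[!(records$taxon_id %in% singles), , drop = FALSE]
  attr(out, "singletons") <- singles
  out
}

#' Band-based elevational range and midpoint per species (modified Rohde)
#'
#' For each species the elevational range is the upper bound of the highest
#' occupied band minus the lower bound of the lowest occupied band,
#' \eqn{R = (\mathrm{max\_band} + w) - \mathrm{min\_band}}, and the midpoint
#' is halfway between those extremes,
#' \eqn{M = (\mathrm{min\_band} + \mathrm{max\_band} + w)/2}, with band
#' width \eqn{w} (100 m).  A species seen in a single band therefore gets
#' the minimum range of 100 m as a natural consequence of the formula.
#' Using the midpoint (rather than the mean elevation of captures) avoids
#' bias from uneven observation numbers along the range.
#'
#' @param records occurrence records, typically after
#'   [filter_species_level()] and [remove_singletons()].
#' @param sites site table mapping `site_id` to `elevation_band_lower`.
#' @param band_width band width in metres (default 100).
#' @return a `data.frame` of class `species_ranges` with one row per species:
#'   `species_id`, `suborder`, `n_records` (individuals), `min_band`,
#'   `max_band`, `range_m`, `midpoint_m`.  The surveyed elevational window
#'   `[lowest band lower bound, highest band upper bound]` is attached as
#'   `attr(, "window")` so boundary-touching species can be flagged.
#' @export
species_elevational_range <- function(records, sites, band_width = 100) {
  orphans <- setdiff(unique(records$site_id), sites$site_id)
  if (length(orphans)) {
    stop("occurrence record(s) reference unknown site_id: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  band_of <- setNames(sites$elevation_band_lower, sites$site_id)
  bands <- band_of[records$site_id]
  sp <- factor(records$taxon_id)
  min_band <- tapply(bands, sp, min)
  max_band <- tapply(bands, sp, max)
  n_rec <- tapply(records$count, sp, sum)
  subord <- if ("suborder" %in% names(records)) {
    tapply(records$suborder, sp, function(s) s[1])
  } else {
    rep(NA_character_, nlevels(sp))
  }
  out <- data.frame(
    species_id = levels(sp),
    suborder = as.character(subord),
    n_records = as.numeric(n_rec),
    min_band = as.numeric(min_band),
    max_band = as.numeric(max_band),
    stringsAsFactors = FALSE
  )
  out$range_m <- (out$max_band + band_width) - out$min_band
  out$midpoint_m <- (out$min_band + out$max_band + band_width) / 2
  rownames(out) <- NULL
  attr(out, "window") <- c(min(sites$elevation_band_lower),
                           max(sites$elevation_band_lower) + band_width)
  attr(out, "band_width") <- band_width
  class(out) <- c("species_ranges", "data.frame")
  out
}

#' Polynomial regressions of range size on range midpoint
#'
#' Ordinary least squares fits of elevational range on range midpoint for
#' polynomial orders 1..`max_order`.  The predictor is centred and scaled
#' internally for numerical conditioning; coefficients are reported on the
#' original metre scale.  AIC uses the full Gaussian log-likelihood with the
#' error variance counted as a parameter,
#' \eqn{AIC = n\ln(RSS/n) + n\ln(2\pi) + n + 2(k+2)} for order \eqn{k},
#' matching mainstream statistical software.
#'
#' @param midpoint,range_m numeric vectors: one point per species.
#' @param max_order highest polynomial order to fit (default 4).
#' @return a list of class `poly_fit_list`; element `k` has class `poly_fit`
#'   with fields `order`, `coefficients` (original scale, intercept first),
#'   `rss`, `aic`, `adj_r2`, `r2`, `n`, `residual_df`, `fitted`.
#' @export
fit_polynomials <- function(midpoint, range_m, max_order = 4) {
  stopifnot(length(midpoint) == length(range_m))
  keep <- is.finite(midpoint) & is.finite(range_m)
  x <- midpoint[keep]; y <- range_m[keep]
  n <- length(x)
  if (n <= max_order + 1) {
    stop("need more points than parameters: n > max_order + 1", call. = FALSE)
  }
  mx <- mean(x); sx <- stats::sd(x)
  if (sx == 0) stop("midpoint has zero variance", call. = FALSE)
  z <- (x - mx) / sx
  tss <- sum((y - mean(y))^2)
  fits <- lapply(seq_len(max_order), function(k) {
    design <- outer(z, 0:k, `^`)
    fit <- lm.fit(design, y)
    if (fit$rank < k + 1) {
      stop("rank-deficient design for polynomial order ", k, call. = FALSE)
    }
    rss <- sum(fit$residuals^2)
    r2 <- 1 - rss / tss
    adj <- 1 - (1 - r2) * (n - 1) / (n - k - 1)
    aic <- n * log(rss / n) + n * log(2 * pi) + n + 2 * (k + 2)
    structure(list(
      order = k,
      coefficients = poly_rescale(fit$coefficients, mx, sx),
      rss = rss, aic = aic, r2 = r2, adj_r2 = adj,
      n = n, residual_df = n - (k + 1),
      fitted = fit$fitted.values,
      center = mx, scale = sx
    ), class = "poly_fit")
  })
  structure(fits, class = "poly_fit_list")
}

# Coefficients of sum_j b_j ((x - m)/s)^j as a polynomial in x.
poly_rescale <- function(beta, m, s) {
  base <- c(-m / s, 1 / s)          # (x - m)/s as a degree-1 polynomial in x
  acc <- c(beta[1])                  # degree-0 term
  pw <- 1
  for (j in seq_along(beta)[-1]) {
    pw <- polymul(pw, base)
    acc <- padd(acc, beta[j] * pw)
  }
  names(acc) <- paste0("b", seq_along(acc) - 1)
  acc
}

polymul <- function(a, b) {
  out <- numeric(length(a) + length(b) - 1)
  for (i in seq_along(a)) {
    idx <- i + seq_along(b) - 1
    out[idx] <- out[idx] + a[i] * b
  }
  out
}

padd <- function(a, b) {
  n <- max(length(a), length(b))
  length(a) <- n; length(b) <- n
  a[is.na(a)] <- 0; b[is.na(b)] <- 0
  a + b
}

#' @export
print.poly_fit <- function(x, ...) {
  cat(sprintf("order-%d polynomial: AIC = %.1f, adj R2 = %.3f, RSS = %.1f (n = %d)\n",
              x$order, x$aic, x$adj_r2, x$rss, x$n))
  print(signif(x$coefficients, 4))
  invisible(x)
}

#' Select the best polynomial order
#'
#' The best model minimises AIC; the adjusted-R-squared ranking is reported
#' as corroboration and a disagreement is flagged (AIC wins ties and
#' conflicts).  Consecutive orders are also compared by nested F-tests
#' \eqn{F = ((RSS_{k-1} - RSS_k)/\Delta p) / (RSS_k / df_k)}.
#'
#' @param fits a `poly_fit_list` from [fit_polynomials()].
#' @return a list with `best` (the winning `poly_fit`), `comparisons` (a
#'   data.frame of consecutive-order F-tests), `aic`, `adj_r2`, and
#'   `conflict` (logical: did the two criteria disagree).
#' @export
select_model <- function(fits) {
  stopifnot(length(fits) >= 1)
  aic <- vapply(fits, `[[`, 0, "aic")
  adj <- vapply(fits, `[[`, 0, "adj_r2")
  best_aic <- which.min(aic)
  best_adj <- which.max(adj)
  conflict <- best_aic != best_adj
  if (conflict) {
    message("AIC prefers order ", fits[[best_aic]]$order,
            " but adjusted R2 prefers order ", fits[[best_adj]]$order,
            "; keeping the AIC choice")
  }
  comparisons <- NULL
  if (length(fits) > 1) {
    rows <- lapply(seq_len(length(fits) - 1), function(i) {
      lo <- fits[[i]]; hi <- fits[[i + 1]]
      dp <- lo$residual_df - hi$residual_df
      f <- ((lo$rss - hi$rss) / dp) / (hi$rss / hi$residual_df)
      f <- max(f, 0)
      data.frame(order_low = lo$order, order_high = hi$order,
                 f_value = f, df_num = dp, df_den = hi$residual_df,
                 p_value = pf(f, dp, hi$residual_df, lower.tail = FALSE))
    })
    comparisons <- do.call(rbind, rows)
  }
  list(best = fits[[best_aic]], comparisons = comparisons,
       aic = aic, adj_r2 = adj, conflict = conflict)
}

#' Stevens' band-mean range estimator (comparator)
#'
#' For every elevational band, the mean range size of all species whose
#' range covers that band.  Data points are bands, not species, so they are
#' not independent — provided for comparison with the midpoint method, not
#' as the primary test.
#'
#' @param ranges a `species_ranges` table.
#' @param bands band lower bounds to evaluate; defaults to every band from
#'   the lowest to the highest occupied.
#' @return a `data.frame` with `band`, `mean_range_m`, `n_species` (bands
#'   covered by no species are absent).
#' @export
stevens_estimate <- function(ranges, bands = NULL) {
  w <- attr(ranges, "band_width") %||% 100
  if (is.null(bands)) {
    bands <- seq(min(ranges$min_band), max(ranges$max_band), by = w)
  }
  rows <- lapply(bands, function(b) {
    hit <- ranges$min_band <= b & b <= ranges$max_band
    if (!any(hit)) return(NULL)
    data.frame(band = b, mean_range_m = mean(ranges$range_m[hit]),
               n_species = sum(hit))
  })
  do.call(rbind, rows)
}

#' Pagel's range-extreme regression (comparator)
#'
#' Regresses range size on the upper extreme of each species' range
#' (the upper bound of its highest occupied band).
#'
#' @param ranges a `species_ranges` table with at least 3 species.
#' @return a list with `slope`, `intercept`, `p_value` (slope t-test),
#'   `r_squared` and `n`.
#' @export
pagel_estimate <- function(ranges) {
  w <- attr(ranges, "band_width") %||% 100
  n <- nrow(ranges)
  if (n < 3) stop("need at least 3 species", call. = FALSE)
  x <- ranges$max_band + w
  y <- ranges$range_m
  if (stats::var(x) == 0) {
    stop("all species share the same maximum elevation: no predictor variance",
         call. = FALSE)
  }
  slope <- stats::cov(x, y) / stats::var(x)
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  rss <- sum(res^2)
  se_slope <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  tstat <- slope / se_slope
  list(slope = slope, intercept = intercept,
       p_value = 2 * pt(-abs(tstat), n - 2),
       r_squared = 1 - rss / sum((y - mean(y))^2), n = n)
}
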
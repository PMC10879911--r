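# Independent oracles.  Each is written on a deliberately different code
# path from the implementation in R/: explicit loops, normal equations and
# hand-rolled IRLS, so agreement is evidence rather than tautology.

# Poisson log-link IRLS via normal equations (vs stats::glm in the package).
oracle_irls <- function(X, y, iter = 80) {
  beta <- c(log(mean(y) + 0.1), rep(0, ncol(X) - 1))
  for (i in seq_len(iter)) {
    eta <- drop(X %*% beta)
    mu <- exp(eta)
    z <- eta + (y - mu) / mu
    beta <- drop(solve(t(X) %*% (mu * X), t(X) %*% (mu * z)))
  }
  unname(beta)
}

oracle_poisson_deviance <- function(X, y, beta) {
  mu <- exp(drop(X %*% beta))
  2 * sum(ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
}

oracle_pearson_phi <- function(X, y, beta) {
  mu <- exp(drop(X %*% beta))
  sum((y - mu)^2 / mu) / (length(y) - ncol(X))
}

# OLS by normal equations on a standardised polynomial basis (RSS, R2 and
# AIC are invariant to the basis, so this stays comparable while keeping the
# normal equations well conditioned).
oracle_poly_stats <- function(x, y, k) {
  X <- outer((x - mean(x)) / sd(x), 0:k, `^`)
  beta <- drop(solve(t(X) %*% X, t(X) %*% y))
  rss <- sum((y - drop(X %*% beta))^2)
  n <- length(y)
  r2 <- 1 - rss / sum((y - mean(y))^2)
  list(rss = rss,
       aic = n * log(rss / n) + n * log(2 * pi) + n + 2 * (k + 2),
       adj_r2 = 1 - (1 - r2) * (n - 1) / (n - k - 1))
}

# Brute-force per-species range/midpoint: explicit loops over records.
oracle_ranges <- function(records, sites, w = 100) {
  band_of <- setNames(sites$elevation_band_lower, sites$site_id)
  out <- NULL
  for (sp in sort(unique(records$taxon_id))) {
    bands <- c()
    for (i in seq_len(nrow(records))) {
      if (records$taxon_id[i] == sp) {
        bands <- c(bands, band_of[[records$site_id[i]]])
      }
    }
    out <- rbind(out, data.frame(
      species_id = sp,
      min_band = min(bands), max_band = max(bands),
      range_m = (max(bands) + w) - min(bands),
      midpoint_m = (min(bands) + max(bands) + w) / 2
    ))
  }
  out
}

# Effective-taxon rule by explicit enumeration.
oracle_effective_taxa <- function(records) {
  kept <- character(0)
  for (i in seq_len(nrow(records))) {
    if (records$rank[i] == "species") kept <- c(kept, records$taxon_id[i])
  }
  for (i in seq_len(nrow(records))) {
    if (records$rank[i] != "species") {
      g <- records$taxon_id[i]
      has_species <- FALSE
      for (j in seq_len(nrow(records))) {
        if (records$rank[j] == "species" && records$parent_taxon[j] == g) {
          has_species <- TRUE
        }
      }
      flagged <- any(records$distinct_flag[records$taxon_id == g &
                                             records$rank != "species"])
      if (!has_species || flagged) kept <- c(kept, g)
    }
  }
  sort(unique(kept))
}

# Random small occurrence sets for property tests.
random_records <- function(n_sites = 4, n_species = 6, n_genera = 3,
                           n_rows = 12) {
  genera <- paste0("g", seq_len(n_genera))
  species <- paste0("s", seq_len(n_species))
  parent <- sample(genera, n_species, replace = TRUE)
  rows <- lapply(seq_len(n_rows), function(i) {
    if (runif(1) < 0.7) {
      k <- sample(n_species, 1)
      occ(paste0("S", sample(n_sites, 1)), species[k], "species", parent[k],
          count = sample(3, 1))
    } else {
      occ(paste0("S", sample(n_sites, 1)), sample(genera, 1), "higher",
          count = sample(3, 1), flag = runif(1) < 0.2)
    }
  })
  do.call(rbind, rows)
}
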
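#' Scenario configuration for the synthetic community generator
#'
#' Bundles all parameters of the simulated survey.  Defaults mirror the scale
#' and structure of a montane sweep-net study: 28 transect sites in 100-m
#' elevational bands spanning 1100–2500 m a.s.l. across three main study
#' areas plus a low-elevation valley supplement, 3–8 net and 2–3 hand
#' surveys per site with net effort increasing with elevation, roughly 37
#' named species (plus genus-rank records) and on the order of 1600 captured
#' individuals, overdispersed counts, and vegetation cover/height declining
#' with elevation.
#'
#' @param bands band lower bounds surveyed (default 1100–2500 step 100 m).
#' @param site_layout data.frame with columns `study_area` and `band`, one
#'   row per site; default emulates the study design (28 sites).
#' @param n_species number of true species in the pool (default 37).
#' @param n_genera number of genera they are spread over (default 14).
#' @param prop_caelifera proportion of genera in the Caelifera (default 0.72).
#' @param range_model list `(type, coef, noise_sd)`; `type` one of
#'   `"hump_quadratic"` (default: breadth peaks mid-gradient),
#'   `"rapoport_linear"` (breadth grows with midpoint) or `"constant"`.
#'   See [breadth_fun()] for the coefficient meanings.
#' @param abundance log-normal abundance parameters `(meanlog, sdlog)`.
#' @param detection list: `net_rate`/`hand_rate` (expected captures per
#'   survey per unit abundance), negative-binomial `size` (overdispersion,
#'   smaller = more overdispersed), `suit_decay` (log-linear decline of
#'   expected counts per metre of elevation, makes realised richness fall
#'   with elevation), `site_effect_sd` (SD of a log-normal site-quality
#'   multiplier — between-site heterogeneity that makes site richness
#'   overdispersed relative to Poisson, as in real communities).
#' @param effort list: net survey count bounds (`net_min`, `net_max`),
#'   elevational gain `net_elev_gain` (extra surveys from bottom to top) and
#'   jitter `net_sd`; hand survey bounds `hand_min`, `hand_max`.
#' @param higher_taxon_fraction probability an individual is recorded at
#'   genus rank only (default 0.6, emulating the large nymph fraction).
#' @param singleton_target informative target for the number of singleton
#'   species the defaults should produce (used by calibration tests).
#' @param covariate_noise list of noise SDs for the site covariates.
#' @param vegetation list: `plot_noise_sd` (plot-to-plot SD around the
#'   latent site values; 0 gives deterministic plots), `cover_tol` split of
#'   non-vegetated cover.
#' @param soft_occupancy logical; if `TRUE`, presence in a band decays as a
#'   Gaussian of distance from the range rather than a hard interval
#'   (robustness checks only; ground-truth ranges are then ill-defined).
#' @param band_width band width in metres.
#' @return a list of class `scenario_config`.
#' @export
scenario_config <- function(
    bands = seq(1100, 2500, by = 100),
    site_layout = default_site_layout(),
    n_species = 37,
    n_genera = 14,
    prop_caelifera = 0.72,
    range_model = list(type = "hump_quadratic",
                       coef = c(peak = 900, at = 1850, curv = 750 / 750^2),
                       noise_sd = 300),
    abundance = list(meanlog = log(2.5), sdlog = 1.3),
    detection = list(net_rate = 0.45, hand_rate = 0.135, size = 0.5,
                     suit_decay = 4e-3, site_effect_sd = 0.8),
    effort = list(net_min = 3, net_max = 8, net_elev_gain = 4.5,
                  net_sd = 0.8, hand_min = 2, hand_max = 3),
    higher_taxon_fraction = 0.6,
    singleton_target = 7,
    covariate_noise = list(cover = 6, height = 8, density = 1.2, slope = 4),
    vegetation = list(plot_noise_sd = 5),
    soft_occupancy = FALSE,
    band_width = 100) {
  stopifnot(all(diff(bands) == band_width), n_species >= 1,
            n_genera >= 1, n_genera <= n_species,
            range_model$type %in% c("hump_quadratic", "rapoport_linear",
                                    "constant"),
            range_model$noise_sd >= 0,
            higher_taxon_fraction >= 0, higher_taxon_fraction <= 1,
            all(site_layout$band %in% bands))
  structure(as.list(environment()), class = "scenario_config")
}

#' Default site layout: 28 sites across four study areas
#'
#' Ten sites at TOR (1200–2300 m), eight at MOL (1800–2500 m), seven at TAV
#' (1500–2200 m) and three valley-bottom sites at VFE (1100–1200 m), one
#' site per area-band combination except the duplicated VFE 1200 band.
#'
#' @return data.frame with columns `study_area`, `band`.
#' @export
default_site_layout <- function() {
  rbind(
    data.frame(study_area = "VFE", band = c(1100, 1200, 1200)),
    data.frame(study_area = "TOR",
               band = setdiff(seq(1200, 2300, 100), c(2000, 2100))),
    data.frame(study_area = "MOL", band = seq(1800, 2500, 100)),
    data.frame(study_area = "TAV",
               band = setdiff(seq(1500, 2200, 100), 1600))
  )
}

#' True breadth of a species' elevational range as a function of midpoint
#'
#' * `hump_quadratic`: `peak - curv * (mu - at)^2` — breadth peaks at
#'   elevation `at` (m) with maximum `peak` (m) and falls off
#'   quadratically at `curv` m per m².
#' * `rapoport_linear`: `intercept + slope * mu` — breadth grows linearly
#'   with midpoint (a true Rapoport effect when `slope > 0`).
#' * `constant`: `value`.
#'
#' @param mu numeric vector of range midpoints (m a.s.l.).
#' @param range_model the `range_model` list of a [scenario_config()].
#' @return expected breadths in metres (no noise).
#' @export
breadth_fun <- function(mu, range_model) {
  cf <- range_model$coef
  switch(range_model$type,
    hump_quadratic = cf[["peak"]] - cf[["curv"]] * (mu - cf[["at"]])^2,
    rapoport_linear = cf[["intercept"]] + cf[["slope"]] * mu,
    constant = rep(cf[["value"]], length(mu)),
    stop("unknown range_model type: ", range_model$type, call. = FALSE)
  )
}

#' Simulate continuous (midpoint, range) points from a range model
#'
#' Draws species midpoints uniformly over the elevational window and
#' breadths from the range model plus Gaussian noise, resampling the noise
#' (up to 20 tries, then clamping) when a breadth falls below `min_breadth`.
#' This is the species-level core of [generate_community()], exposed
#' directly for model-recovery simulations of [fit_polynomials()].
#'
#' @param n_species number of species.
#' @param range_model as in [scenario_config()].
#' @param window elevational window `c(lo, hi)` in metres.
#' @param min_breadth smallest admissible breadth (default 10 m).
#' @param seed optional seed (RNG state restored afterwards).
#' @return data.frame with `midpoint_m`, `range_m` and the noiseless
#'   `true_mean_m`.
#' @export
simulate_species_ranges <- function(n_species, range_model,
                                    window = c(1100, 2600),
                                    min_breadth = 10, seed = NULL) {
  with_seed(seed, {
    mu <- runif(n_species, window[1], window[2])
    mean_b <- breadth_fun(mu, range_model)
    b <- mean_b + rnorm(n_species, 0, range_model$noise_sd)
    for (tries in seq_len(20)) {
      bad <- b < min_breadth
      if (!any(bad)) break
      b[bad] <- mean_b[bad] + rnorm(sum(bad), 0, range_model$noise_sd)
    }
    b[b < min_breadth] <- min_breadth
    data.frame(midpoint_m = mu, range_m = b, true_mean_m = mean_b)
  })
}

# Latent site covariates with elevational trends: cover and heights decline
# with elevation, slope is negatively tied to cover, aspect is uniform.
generate_sites <- function(config) {
  layout <- config$site_layout
  n <- nrow(layout)
  span <- max(config$bands) - min(config$bands)
  rel <- (layout$band - min(config$bands)) / span
  ns <- config$covariate_noise
  veg_cover <- pmin(100, pmax(5, 92 - 40 * rel + rnorm(n, 0, ns$cover)))
  veg_max_height <- pmax(3, 70 - 48 * rel + rnorm(n, 0, ns$height))
  veg_height75 <- pmax(2, 0.55 * veg_max_height + rnorm(n, 0, ns$height / 2))
  veg_density <- pmax(0.2, 9 - 6 * rel + rnorm(n, 0, ns$density))
  slope <- pmin(60, pmax(0, 4 + 0.30 * (100 - veg_cover) +
                           rnorm(n, 0, ns$slope)))
  aspect <- runif(n, 0, 360)
  ids <- paste0(layout$study_area, "_", layout$band,
                ave(seq_len(n), layout$study_area, layout$band,
                    FUN = function(i) {
                      if (length(i) > 1) letters[seq_along(i)] else ""
                    }))
  data.frame(
    site_id = ids, study_area = layout$study_area,
    elevation_band_lower = layout$band,
    veg_cover = round(veg_cover, 1),
    veg_max_height = round(veg_max_height, 1),
    veg_height75 = round(veg_height75, 1),
    veg_density = round(veg_density, 2),
    slope = round(slope, 1), aspect = round(aspect, 1),
    stringsAsFactors = FALSE
  )
}

#' Generate a synthetic occurrence dataset with known ground truth
#'
#' Simulates the whole survey: site covariates with elevational trends, a
#' species pool with midpoint-dependent range breadths, hard band occupancy,
#' an elevation-dependent survey log, and negative-binomial capture counts
#' per survey (so quasipoisson dispersion > 1 arises naturally).  A fraction
#' of individuals is recorded at genus rank only.  Identical `seed` and
#' `config` give identical output.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; the caller's RNG state is restored afterwards.
#' @param out_dir optional directory: writes `occurrences.csv`, `sites.csv`,
#'   `visits.csv` and `ground_truth.json` there.
#' @return a list with `occurrences`, `sites`, `visits` (data.frames) and
#'   `ground_truth` (list: per-species truth, per-site true species sets,
#'   the generating coefficients, seed).
#' @export
generate_community <- function(config = scenario_config(), seed = 1,
                               out_dir = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  res <- with_seed(seed, generate_community_impl(config))
  res$ground_truth$seed <- seed
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(res$occurrences, file.path(out_dir, "occurrences.csv"),
              row.names = FALSE)
    write.csv(res$sites, file.path(out_dir, "sites.csv"), row.names = FALSE)
    write.csv(res$visits, file.path(out_dir, "visits.csv"), row.names = FALSE)
    jsonlite::write_json(res$ground_truth,
                         file.path(out_dir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

generate_community_impl <- function(config) {
  sites <- generate_sites(config)
  bands <- config$bands
  w <- config$band_width
  window <- c(min(bands), max(bands) + w)
  n_sp <- config$n_species
  n_gen <- config$n_genera

  # species pool: ids, genera, suborders
  genus_of <- ((seq_len(n_sp) - 1) %% n_gen) + 1
  n_cael_gen <- max(1, round(config$prop_caelifera * n_gen))
  genus_sub <- ifelse(seq_len(n_gen) <= n_cael_gen, "Caelifera", "Ensifera")
  species <- data.frame(
    species_id = sprintf("sp%02d", seq_len(n_sp)),
    genus = sprintf("gen%02d", genus_of),
    suborder = genus_sub[genus_of],
    stringsAsFactors = FALSE
  )

  rng <- simulate_species_ranges(n_sp, config$range_model, window = window)
  species$midpoint_true <- rng$midpoint_m
  species$breadth_true <- rng$range_m
  lo <- species$midpoint_true - species$breadth_true / 2
  hi <- species$midpoint_true + species$breadth_true / 2
  occupied <- lapply(seq_len(n_sp), function(i) {
    bands[hi[i] > bands & lo[i] < bands + w]
  })
  species$min_band_true <- vapply(occupied, function(b) {
    if (length(b)) min(b) else NA_real_
  }, 0)
  species$max_band_true <- vapply(occupied, function(b) {
    if (length(b)) max(b) else NA_real_
  }, 0)
  species$abundance <- rlnorm(n_sp, config$abundance$meanlog,
                              config$abundance$sdlog)

  # survey log: effort grows with elevation
  ef <- config$effort
  span <- max(bands) - min(bands)
  visits <- NULL
  for (s in seq_len(nrow(sites))) {
    relev <- (sites$elevation_band_lower[s] - min(bands)) / span
    n_net <- round(ef$net_min + ef$net_elev_gain * relev +
                     rnorm(1, 0, ef$net_sd))
    n_net <- min(ef$net_max, max(ef$net_min, n_net))
    n_hand <- sample(ef$hand_min:ef$hand_max, 1)
    mk <- function(prefix, k, method) {
      data.frame(site_id = sites$site_id[s],
                 visit_id = paste0(prefix, seq_len(k)),
                 season = rep(c("summer", "autumn"), length.out = k),
                 method = method, stringsAsFactors = FALSE)
    }
    visits <- rbind(visits, mk("n", n_net, "net"), mk("h", n_hand, "hand"))
  }

  # capture counts: negative binomial per (survey, present species), with a
  # lognormal site-quality multiplier creating between-site overdispersion
  det <- config$detection
  hf <- config$higher_taxon_fraction
  site_band <- setNames(sites$elevation_band_lower, sites$site_id)
  site_quality <- setNames(rlnorm(nrow(sites), 0,
                                  det$site_effect_sd %||% 0),
                           sites$site_id)
  draw_visit <- function(v) {
    b <- site_band[[visits$site_id[v]]]
    if (config$soft_occupancy) {
      centre <- b + w / 2
      prox <- exp(-0.5 * ((centre - species$midpoint_true) /
                            pmax(species$breadth_true / 2, w / 2))^2)
      present <- which(prox > 0.05)
      suit_sp <- prox[present]
    } else {
      present <- which(vapply(occupied, function(ob) b %in% ob, TRUE))
      suit_sp <- rep(1, length(present))
    }
    if (!length(present)) return(NULL)
    rate <- if (visits$method[v] == "net") det$net_rate else det$hand_rate
    mu <- rate * species$abundance[present] * suit_sp *
      site_quality[[visits$site_id[v]]] *
      exp(-det$suit_decay * (b - min(bands)))
    cnt <- rnbinom(length(present), size = det$size, mu = mu)
    hit <- cnt > 0
    if (!any(hit)) return(NULL)
    idx <- present[hit]
    cnt <- cnt[hit]
    n_hi <- rbinom(length(idx), cnt, hf)
    n_sp_lvl <- cnt - n_hi
    stage <- function(k) c("nymph", "adult")[1 + rbinom(k, 1, 0.37)]
    rows <- list()
    keep <- n_sp_lvl > 0
    if (any(keep)) {
      rows$species <- data.frame(
        site_id = visits$site_id[v], visit_id = visits$visit_id[v],
        season = visits$season[v], method = visits$method[v],
        taxon_id = species$species_id[idx[keep]], rank = "species",
        parent_taxon = species$genus[idx[keep]],
        suborder = species$suborder[idx[keep]],
        life_stage = stage(sum(keep)), count = n_sp_lvl[keep],
        distinct_flag = FALSE, stringsAsFactors = FALSE
      )
    }
    keep <- n_hi > 0
    if (any(keep)) {
      rows$higher <- data.frame(
        site_id = visits$site_id[v], visit_id = visits$visit_id[v],
        season = visits$season[v], method = visits$method[v],
        taxon_id = species$genus[idx[keep]], rank = "higher",
        parent_taxon = "", suborder = species$suborder[idx[keep]],
        life_stage = "nymph", count = n_hi[keep],
        distinct_flag = FALSE, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, rows)
  }
  # Draw site by site; a site whose hand surveys caught specimens but whose
  # net surveys caught none has an undefined effort index, so its counts are
  # redrawn (up to 20 tries, then its hand captures are discarded).
  occ_sites <- lapply(sites$site_id, function(sid) {
    vs <- which(visits$site_id == sid)
    for (try in 1:20) {
      rows <- do.call(rbind, lapply(vs, draw_visit))
      if (is.null(rows)) return(NULL)
      net_any <- any(rows$method == "net")
      hand_any <- any(rows$method == "hand")
      if (net_any || !hand_any) return(rows)
    }
    rows[rows$method == "net", , drop = FALSE]
  })
  occurrences <- do.call(rbind, occ_sites)
  rownames(occurrences) <- NULL

  site_taxa <- lapply(seq_len(nrow(sites)), function(s) {
    b <- sites$elevation_band_lower[s]
    species$species_id[vapply(occupied, function(ob) b %in% ob, TRUE)]
  })
  names(site_taxa) <- sites$site_id

  list(
    occurrences = occurrences,
    sites = sites,
    visits = visits,
    ground_truth = list(
      species = species,
      site_taxa = site_taxa,
      site_quality = as.list(site_quality),
      range_model = config$range_model,
      window = window
    )
  )
}

#' Generate synthetic vegetation plot measurements
#'
#' Emulates the field protocol: three 1.2 x 1.2 m plots per site per season
#' (summer and autumn), each with a maximum height, a 75th-percentile
#' height, five vertical-rod touch counts and eye-estimated covers.  Values
#' are drawn around the site's latent covariates; with
#' `config$vegetation$plot_noise_sd = 0` the plots reproduce the latent
#' values deterministically (touch counts then average exactly to the latent
#' density rounded to the nearest 0.2).
#'
#' @param sites a site table carrying the latent covariates (as produced by
#'   [generate_community()]).
#' @param config a [scenario_config()].
#' @param seed integer seed.
#' @param out_dir optional directory to write `vegetation_plots.csv`.
#' @return a `data.frame` in the [read_vegetation_plots()] layout.
#' @export
generate_vegetation_plots <- function(sites, config = scenario_config(),
                                      seed = 1, out_dir = NULL) {
  sd0 <- config$vegetation$plot_noise_sd
  plots <- with_seed(seed, {
    grid <- expand.grid(site = seq_len(nrow(sites)),
                        visit_season = c("summer", "autumn"),
                        plot = 1:3, stringsAsFactors = FALSE)
    n <- nrow(grid)
    s <- sites[grid$site, ]
    noise <- function(sd) if (sd0 == 0) 0 else rnorm(n, 0, sd)
    max_height <- pmax(0, s$veg_max_height + noise(sd0))
    height75 <- pmax(0, s$veg_height75 + noise(sd0 * 0.6))
    touches <- t(vapply(seq_len(n), function(i) {
      if (sd0 == 0) {
        target <- round(s$veg_density[i] * 5) / 5
        base <- floor(target)
        k <- round((target - base) * 5)
        base + c(rep(1, k), rep(0, 5 - k))
      } else {
        rpois(5, s$veg_density[i])
      }
    }, numeric(5)))
    cover_veg <- pmin(100, pmax(0, s$veg_cover + noise(sd0)))
    rock_frac <- if (sd0 == 0) 0.6 else runif(n, 0.3, 0.8)
    cover_rock <- round((100 - cover_veg) * rock_frac)
    cover_bare <- round(100 - cover_veg - cover_rock)
    out <- data.frame(
      site_id = s$site_id, visit_season = grid$visit_season,
      max_height = round(max_height, 1), height75 = round(height75, 1),
      stringsAsFactors = FALSE
    )
    out[paste0("touch", 1:5)] <- as.data.frame(touches)
    out$cover_vegetation <- round(cover_veg, 1)
    out$cover_rock <- cover_rock
    out$cover_bare <- cover_bare
    out
  })
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write.csv(plots, file.path(out_dir, "vegetation_plots.csv"),
              row.names = FALSE)
  }
  plots
}
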
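#' Pipeline configuration
#'
#' Describes one end-to-end run: either a synthetic scenario or paths to
#' occurrence/site (and optionally visit registry / vegetation plot) CSVs,
#' plus the modelling choices.
#'
#' @param scenario a [scenario_config()] to simulate from, or `NULL` to read
#'   the CSV inputs instead.
#' @param occurrences,sites,visits,vegetation_plots input CSV paths (ignored
#'   when `scenario` is given; `visits` and `vegetation_plots` optional).
#' @param terms full-model covariates for the richness GLM.
#' @param alpha significance level for stepwise retention.
#' @param stepwise_criterion `"deviance_guarded"` or `"strict_alpha"`.
#' @param f_max scaled-deviance budget for the guarded criterion.
#' @param max_order highest polynomial order for the range-midpoint fit.
#' @param out_dir output directory for the artifact bundle.
#' @param seed integer seed (simulation only).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(scenario = NULL, occurrences = NULL,
                            sites = NULL, visits = NULL,
                            vegetation_plots = NULL,
                            terms = c("elevation_band_lower", "study_area",
                                      "se_value", "veg_cover",
                                      "veg_max_height", "veg_density",
                                      "slope", "aspect"),
                            alpha = 0.05,
                            stepwise_criterion = "deviance_guarded",
                            f_max = 2, max_order = 4,
                            out_dir = "elevgrad_out", seed = 1) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)",
                                      call. = FALSE)
  if (is.null(scenario)) {
    if (is.null(occurrences) || is.null(sites)) {
      stop("either a scenario or occurrence + site paths are required",
           call. = FALSE)
    }
    for (p in c(occurrences, sites, visits, vegetation_plots)) {
      if (!file.exists(p)) stop("input file not found: ", p, call. = FALSE)
    }
  } else {
    stopifnot(inherits(scenario, "scenario_config"))
  }
  structure(as.list(environment()), class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Stages: data (simulate or ingest) -> sampling effort -> richness table ->
#' correlation screen -> stepwise quasipoisson GLM -> species ranges ->
#' polynomial range-midpoint comparison.  Writes `effort.csv`,
#' `richness_model.json`, `rapoport.json` and a human-readable `report.md`
#' (assembled purely from the JSON artifacts, never recomputed) to
#' `config$out_dir`.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with the stage objects and artifact paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  provenance <- list(package = "elevgrad",
                     version = as.character(packageVersion("elevgrad")),
                     seed = config$seed)

  # ---- stage: data ----------------------------------------------------------
  if (!is.null(config$scenario)) {
    com <- generate_community(config$scenario, seed = config$seed)
    occurrences <- validate_occurrences(com$occurrences)
    sites <- validate_sites(com$sites)
    visits <- com$visits
  } else {
    occurrences <- read_occurrences(config$occurrences)
    sites <- read_sites(config$sites)
    visits <- if (!is.null(config$visits)) read_visits(config$visits)
    if (!is.null(config$vegetation_plots)) {
      veg <- aggregate_vegetation(read_vegetation_plots(config$vegetation_plots))
      keep <- setdiff(names(sites), setdiff(names(veg), "site_id"))
      sites <- merge(sites[keep], veg, by = "site_id", all.x = TRUE)
    }
  }

  # ---- stage: effort --------------------------------------------------------
  effort <- effort_from_records(occurrences, visits)
  effort_path <- file.path(config$out_dir, "effort.csv")
  write.csv(effort, effort_path, row.names = FALSE)

  # ---- stage: richness model ------------------------------------------------
  rt <- richness_per_site(occurrences, sites, effort)
  terms <- intersect(config$terms, names(rt))
  numeric_terms <- terms[vapply(rt[terms], is.numeric, TRUE)]
  screen <- correlation_screen(rt, numeric_terms)
  rich_elev <- spearman_correlation(rt$elevation_band_lower, rt$richness)
  rich_se <- spearman_correlation(rt$se_value, rt$richness)
  sw <- backwards_stepwise(rt, terms, alpha = config$alpha,
                           criterion = config$stepwise_criterion,
                           f_max = config$f_max)
  ftab <- term_f_table(sw$fit, type = "sequential")
  richness_json <- list(
    provenance = provenance,
    n_sites = sw$fit$n,
    terms_full = terms,
    terms_final = sw$fit$terms,
    coefficients = as.list(sw$fit$coefficients),
    std_errors = as.list(sw$fit$std_errors),
    dispersion = sw$fit$dispersion,
    null_deviance = sw$fit$null_deviance, df_null = sw$fit$df_null,
    residual_deviance = sw$fit$deviance, df_residual = sw$fit$df_residual,
    stepwise_trace = sw$trace,
    term_f_table = ftab,
    correlation_screen = screen,
    richness_vs_elevation = rich_elev,
    richness_vs_effort = rich_se
  )
  richness_path <- file.path(config$out_dir, "richness_model.json")
  jsonlite::write_json(richness_json, richness_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")

  # ---- stage: rapoport ------------------------------------------------------
  sp <- remove_singletons(filter_species_level(occurrences))
  ranges <- species_elevational_range(sp, sites)
  max_order <- config$max_order
  if (nrow(ranges) <= max_order + 1) {
    max_order <- max(1, nrow(ranges) - 2)
    warning("too few species for order ", config$max_order,
            "; lowering max_order to ", max_order, call. = FALSE)
  }
  fits <- fit_polynomials(ranges$midpoint_m, ranges$range_m, max_order)
  sel <- select_model(fits)
  rapoport_json <- list(
    provenance = provenance,
    n_species = nrow(ranges),
    n_individuals = sum(ranges$n_records),
    singletons_removed = attr(sp, "singletons"),
    window = attr(ranges, "window"),
    ranges = as.data.frame(ranges),
    fits = lapply(fits, function(f) {
      list(order = f$order, coefficients = as.list(f$coefficients),
           rss = f$rss, aic = f$aic, r2 = f$r2, adj_r2 = f$adj_r2,
           residual_df = f$residual_df)
    }),
    comparisons = sel$comparisons,
    best_order = sel$best$order,
    aic_adjr2_conflict = sel$conflict,
    stevens = stevens_estimate(ranges),
    pagel = tryCatch(pagel_estimate(ranges), error = function(e) NULL)
  )
  rapoport_path <- file.path(config$out_dir, "rapoport.json")
  jsonlite::write_json(rapoport_json, rapoport_path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")

  # ---- stage: report (read back from artifacts only) ------------------------
  report_path <- file.path(config$out_dir, "report.md")
  writeLines(render_report(richness_path, rapoport_path), report_path)

  invisible(list(
    paths = c(effort = effort_path, richness_model = richness_path,
              rapoport = rapoport_path, report = report_path),
    effort = effort, richness_table = rt, stepwise = sw,
    term_f_table = ftab, ranges = ranges, selection = sel
  ))
}

# Markdown report assembled from the stage artifacts (single source of
# truth: numbers are read back from JSON, never recomputed here).
render_report <- function(richness_path, rapoport_path) {
  rm_ <- jsonlite::read_json(richness_path, simplifyVector = TRUE)
  rp <- jsonlite::read_json(rapoport_path, simplifyVector = TRUE)
  fmt <- function(x, d = 3) formatC(x, digits = d, format = "g")
  lines <- c(
    "# Elevational gradient analysis report",
    "",
    sprintf("elevgrad %s, seed %s", rm_$provenance$version,
            rm_$provenance$seed),
    "",
    "## Species richness",
    "",
    sprintf("Sites analysed: %d.  Richness vs elevation: Spearman rho = %s (p = %s).",
            rm_$n_sites, fmt(rm_$richness_vs_elevation$rho),
            fmt(rm_$richness_vs_elevation$p_value)),
    sprintf("Richness vs sampling effort: rho = %s (p = %s).",
            fmt(rm_$richness_vs_effort$rho), fmt(rm_$richness_vs_effort$p_value)),
    "",
    sprintf("Final quasipoisson GLM (%s): null deviance %s (df %d), residual deviance %s (df %d), dispersion %s.",
            paste(rm_$terms_final, collapse = " + "),
            fmt(rm_$null_deviance, 4), rm_$df_null,
            fmt(rm_$residual_deviance, 4), rm_$df_residual,
            fmt(rm_$dispersion)),
    "",
    "| term | estimate | SE | F | df | p |",
    "|---|---|---|---|---|---|",
    apply(rm_$term_f_table, 1, function(r) {
      sprintf("| %s | %s | %s | %s | %s | %s |", r[["term"]],
              fmt(as.numeric(r[["estimate"]])),
              fmt(as.numeric(r[["std_error"]])),
              fmt(as.numeric(r[["f_value"]])), r[["df_num"]],
              fmt(as.numeric(r[["p_value"]])))
    }),
    "",
    "## Rapoport effect (range vs midpoint)",
    "",
    sprintf("%d species (%d individuals) after removing %d singleton(s); surveyed window %s-%s m.",
            rp$n_species, rp$n_individuals, length(rp$singletons_removed),
            rp$window[1], rp$window[2]),
    "",
    "| order | AIC | adj R2 | RSS |",
    "|---|---|---|---|",
    {
      f <- rp$fits
      if (!is.data.frame(f)) {
        f <- data.frame(order = sapply(f, `[[`, "order"),
                        aic = sapply(f, `[[`, "aic"),
                        adj_r2 = sapply(f, `[[`, "adj_r2"),
                        rss = sapply(f, `[[`, "rss"))
      }
      sprintf("| %d | %s | %s | %s |", f$order, fmt(f$aic, 4),
              fmt(f$adj_r2), fmt(f$rss, 5))
    },
    "",
    sprintf("Selected order: %d%s.", rp$best_order,
            if (isTRUE(rp$aic_adjr2_conflict)) " (AIC and adjusted R2 disagreed; AIC used)" else "")
  )
  unlist(lines)
}

#' Command-line interface
#'
#' Subcommands: `simulate`, `effort`, `richness`, `rapoport`, `run`.
#' Invoke via `Rscript -e 'elevgrad::elevgrad_cli()' <subcommand> [options]`
#' or the installed `exec/elevgrad` script.  `--config` accepts a YAML file
#' whose top-level keys match [pipeline_config()] arguments, with an
#' optional `scenario:` block of [scenario_config()] arguments.
#'
#' @param args character vector of command-line arguments.
#' @return exit status, invisibly (0 on success).
#' @export
elevgrad_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- "usage: elevgrad <simulate|effort|richness|rapoport|run> [options]"
  if (!length(args)) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1]
  rest <- args[-1]
  opt <- function(spec) optparse::parse_args(
    optparse::OptionParser(option_list = spec), args = rest
  )
  o <- optparse::make_option
  status <- 0L
  switch(sub,
    simulate = {
      po <- opt(list(
        o("--config", type = "character", default = NULL),
        o("--seed", type = "integer", default = 1L),
        o("--out-dir", type = "character", default = "data", dest = "out_dir")
      ))
      sc <- if (is.null(po$config)) scenario_config() else
        scenario_from_yaml(po$config)
      generate_community(sc, seed = po$seed, out_dir = po$out_dir)
      message("wrote occurrences.csv, sites.csv, visits.csv, ground_truth.json to ",
              po$out_dir)
    },
    effort = {
      po <- opt(list(
        o("--occurrences", type = "character"),
        o("--visits", type = "character", default = NULL),
        o("--out", type = "character", default = "effort.csv")
      ))
      recs <- read_occurrences(po$occurrences)
      vis <- if (!is.null(po$visits)) read_visits(po$visits)
      write.csv(effort_from_records(recs, vis), po$out, row.names = FALSE)
      message("wrote ", po$out)
    },
    richness = ,
    rapoport = ,
    run = {
      po <- opt(list(
        o("--config", type = "character", default = NULL),
        o("--occurrences", type = "character", default = NULL),
        o("--sites", type = "character", default = NULL),
        o("--visits", type = "character", default = NULL),
        o("--alpha", type = "double", default = 0.05),
        o("--max-order", type = "integer", default = 4L,
          dest = "max_order"),
        o("--seed", type = "integer", default = 1L),
        o("--out-dir", type = "character", default = "elevgrad_out",
          dest = "out_dir")
      ))
      cfg <- if (!is.null(po$config)) {
        pipeline_from_yaml(po$config)
      } else if (!is.null(po$occurrences)) {
        pipeline_config(occurrences = po$occurrences, sites = po$sites,
                        visits = po$visits, alpha = po$alpha,
                        max_order = po$max_order, out_dir = po$out_dir,
                        seed = po$seed)
      } else {
        pipeline_config(scenario = scenario_config(), alpha = po$alpha,
                        max_order = po$max_order, out_dir = po$out_dir,
                        seed = po$seed)
      }
      res <- run_pipeline(cfg)
      message("artifacts: ", paste(res$paths, collapse = ", "))
    },
    {
      message("unknown subcommand: ", sub, "\n", usage)
      status <- 1L
    }
  )
  invisible(status)
}

scenario_from_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$range_model$coef)) {
    lst$range_model$coef <- unlist(lst$range_model$coef)
  }
  do.call(scenario_config, lst)
}

pipeline_from_yaml <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$scenario)) {
    sc <- lst$scenario
    if (!is.null(sc$range_model$coef)) {
      sc$range_model$coef <- unlist(sc$range_model$coef)
    }
    lst$scenario <- do.call(scenario_config, sc)
  }
  do.call(pipeline_config, lst)
}
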
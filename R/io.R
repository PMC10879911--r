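#' Read and validate occurrence records
#'
#' Occurrence files are UTF-8 comma-delimited text with a header row and the
#' columns `site_id, visit_id, season, method, taxon_id, rank, parent_taxon,
#' suborder, life_stage, count, distinct_flag`.  One row is one capture event
#' (possibly several conspecific individuals, see `count`) at one site visit
#' with one survey method.
#'
#' `distinct_flag` is a curator's marker on higher-rank (genus or above)
#' records asserting that the specimens are clearly distinct from every
#' species-level taxon in the same group, so the record counts towards
#' richness even when congeneric species are present.
#'
#' @param path path to a CSV file.
#' @return validated `data.frame` of occurrence records.
#' @seealso [validate_occurrences()], [read_sites()]
#' @export
read_occurrences <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_occurrences(df)
}

#' @rdname read_occurrences
#' @param records a data.frame with the occurrence columns.
#' @export
validate_occurrences <- function(records) {
  required <- c("site_id", "visit_id", "season", "method", "taxon_id",
                "rank", "parent_taxon", "suborder", "life_stage", "count",
                "distinct_flag")
  missing <- setdiff(required, names(records))
  if (length(missing)) {
    stop("occurrence table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  records$count <- as.integer(records$count)
  records$distinct_flag <- as_flag(records$distinct_flag)
  records$parent_taxon[is.na(records$parent_taxon)] <- ""
  check_enum(records$season, c("summer", "autumn", "spring"), "season")
  check_enum(records$method, c("net", "hand"), "method")
  check_enum(records$rank, c("species", "higher"), "rank")
  check_enum(records$suborder, c("Caelifera", "Ensifera"), "suborder")
  check_enum(records$life_stage, c("adult", "nymph", "unknown"), "life_stage")
  if (any(is.na(records$count)) || any(records$count < 1)) {
    stop("every stored occurrence record must have count >= 1", call. = FALSE)
  }
  bad <- records$rank == "species" & !nzchar(records$parent_taxon)
  if (any(bad)) {
    stop("species-rank record(s) without parent_taxon: ",
         paste(unique(records$taxon_id[bad]), collapse = ", "), call. = FALSE)
  }
  records
}

#' Read and validate site profiles
#'
#' Site files are CSV with columns `site_id, study_area, elevation_band_lower,
#' veg_cover, veg_max_height, veg_height75, veg_density, slope, aspect`.
#' `elevation_band_lower` is the band key (a multiple of 100 m, see
#' [assign_band()]); vegetation covariates are site-level means over the
#' season plots (see [aggregate_vegetation()]); slope and aspect are
#' precomputed terrain covariates in degrees.
#'
#' @param path path to a CSV file.
#' @return validated `data.frame` of site profiles.
#' @export
read_sites <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_sites(df)
}

#' @rdname read_sites
#' @param sites a data.frame with the site columns.
#' @export
validate_sites <- function(sites) {
  required <- c("site_id", "study_area", "elevation_band_lower", "veg_cover",
                "veg_max_height", "veg_height75", "veg_density", "slope",
                "aspect")
  missing <- setdiff(required, names(sites))
  if (length(missing)) {
    stop("site table lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sites$site_id)) {
    stop("duplicated site_id in site table", call. = FALSE)
  }
  check_enum(sites$study_area, c("TOR", "MOL", "TAV", "VFE"), "study_area")
  if (any(sites$elevation_band_lower %% 100 != 0)) {
    stop("elevation_band_lower must be a multiple of 100 m", call. = FALSE)
  }
  cov_ok <- !is.na(sites$veg_cover) & sites$veg_cover >= 0 &
    sites$veg_cover <= 100
  if (!all(cov_ok | is.na(sites$veg_cover))) {
    stop("veg_cover must lie in [0, 100]", call. = FALSE)
  }
  sites
}

#' Read pre-aggregation vegetation plot measurements
#'
#' Plot files are CSV with columns `site_id, visit_season, max_height,
#' height75, touch1..touch5, cover_vegetation, cover_rock, cover_bare`.
#' Each row is one 1.2 x 1.2 m quadrat characterised in one season; heights
#' in cm, rod touches as five non-negative integer counts, covers as
#' eye-estimated percentages.
#'
#' @param path path to a CSV file.
#' @return validated `data.frame` of vegetation plots.
#' @seealso [aggregate_vegetation()]
#' @export
read_vegetation_plots <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_vegetation_plots(df)
}

#' @rdname read_vegetation_plots
#' @param plots a data.frame with the plot columns.
#' @export
validate_vegetation_plots <- function(plots) {
  touch_cols <- paste0("touch", 1:5)
  required <- c("site_id", "visit_season", "max_height", "height75",
                touch_cols, "cover_vegetation", "cover_rock", "cover_bare")
  missing <- setdiff(required, names(plots))
  if (length(missing)) {
    stop("vegetation plot table lacks column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  check_enum(plots$visit_season, c("summer", "autumn"), "visit_season")
  touches <- as.matrix(plots[touch_cols])
  if (any(is.na(touches)) || any(touches < 0)) {
    stop("each plot needs exactly five non-negative rod touch counts",
         call. = FALSE)
  }
  plots
}

#' Read a visit registry
#'
#' An optional survey log with one row per survey pass (`site_id, visit_id,
#' season, method`).  When supplied to [effort_from_records()], the number of
#' net surveys per site is taken from this registry, which makes zero-capture
#' surveys count towards effort; without it surveys are inferred from the
#' capture records and empty surveys are invisible.
#'
#' @param path path to a CSV file.
#' @return validated `data.frame` of survey passes.
#' @export
read_visits <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  required <- c("site_id", "visit_id", "season", "method")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("visit registry lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  check_enum(df$method, c("net", "hand"), "method")
  df
}

# ---- internal helpers -------------------------------------------------------

check_enum <- function(x, levels, what) {
  bad <- !is.na(x) & !(x %in% levels)
  if (any(bad)) {
    stop(sprintf("invalid %s value(s): %s (allowed: %s)", what,
                 paste(unique(x[bad]), collapse = ", "),
                 paste(levels, collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

as_flag <- function(x) {
  if (is.logical(x)) return(ifelse(is.na(x), FALSE, x))
  x <- tolower(trimws(as.character(x)))
  out <- x %in% c("true", "t", "1", "yes")
  out
}
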
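#' Effective taxa under the higher-taxon counting rule
#'
#' Richness counts every species-level taxon, and additionally counts a
#' higher-rank taxon (typically a genus) as one "species" when either (a) no
#' species belonging to that taxon was recorded in the same scope (site or
#' band), or (b) the record carries the curator's `distinct_flag`, asserting
#' the specimens are clearly distinct from all congeneric species recorded
#' there.  Taxa lists are pooled across all visits within the scope before
#' the rule is applied.
#'
#' @param records occurrence records (see [read_occurrences()]) already
#'   restricted to a single scope — one site, or all sites of one band.
#' @return character vector of effective taxon identifiers (sorted, unique).
#' @examples
#' recs <- data.frame(
#'   taxon_id = c("chorthippus_biguttulus", "chorthippus"),
#'   rank = c("species", "higher"),
#'   parent_taxon = c("chorthippus", ""),
#'   distinct_flag = c(FALSE, FALSE)
#' )
#' effective_taxa(recs)  # genus record absorbed by its species
#' @export
effective_taxa <- function(records) {
  if (NROW(records) == 0) return(character(0))
  sp <- records$rank == "species"
  species <- unique(records$taxon_id[sp])
  parents_present <- unique(records$parent_taxon[sp])
  hi <- records[!sp, , drop = FALSE]
  keep_higher <- character(0)
  if (nrow(hi)) {
    flagged <- tapply(hi$distinct_flag, hi$taxon_id, any)
    hi_taxa <- names(flagged)
    keep <- !(hi_taxa %in% parents_present) | as.logical(flagged)
    keep_higher <- hi_taxa[keep]
  }
  sort(unique(c(species, keep_higher)))
}

#' Per-site species richness table
#'
#' Builds the modelling table: one row per site with the effective-taxon
#' richness (see [effective_taxa()]), all site covariates, and — when an
#' effort table is supplied — the site's sampling-effort index `se_value`.
#' Sites without records get richness 0.
#'
#' @param records occurrence records.
#' @param sites site profiles (see [read_sites()]); every `site_id` in
#'   `records` must appear here.
#' @param effort optional per-site effort table from [effort_from_records()].
#' @param drop_incomplete drop rows with missing covariates (with a warning)
#'   rather than passing `NA` into models.  Default `TRUE`.
#' @return a `data.frame` with columns `site_id`, `richness`, the site
#'   covariates, and `se_value` if `effort` was given.
#' @export
richness_per_site <- function(records, sites, effort = NULL,
                              drop_incomplete = TRUE) {
  orphans <- setdiff(unique(records$site_id), sites$site_id)
  if (length(orphans)) {
    stop("occurrence record(s) reference unknown site_id: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  per_site <- split(records, factor(records$site_id, levels = sites$site_id))
  richness <- vapply(per_site, function(r) length(effective_taxa(r)), 0L)
  out <- data.frame(site_id = sites$site_id, richness = unname(richness),
                    stringsAsFactors = FALSE)
  out <- merge(out, sites, by = "site_id", sort = FALSE)
  if (!is.null(effort)) {
    out <- merge(out, effort[, c("site_id", "se_value")], by = "site_id",
                 all.x = TRUE, sort = FALSE)
  }
  if (drop_incomplete) {
    keep <- complete.cases(out)
    if (!all(keep)) {
      warning("dropping ", sum(!keep), " site(s) with missing covariates: ",
              paste(out$site_id[!keep], collapse = ", "), call. = FALSE)
      out <- out[keep, , drop = FALSE]
    }
  }
  rownames(out) <- NULL
  out
}

#' Per-band species richness
#'
#' Band richness is the effective-taxon count over the pooled records of all
#' sites in the band — the union of site lists, so shared taxa are counted
#' once and the higher-taxon rule is applied band-wide.
#'
#' @inheritParams richness_per_site
#' @return a `data.frame` with columns `band` (lower bound, m) and `richness`.
#' @export
richness_per_band <- function(records, sites) {
  orphans <- setdiff(unique(records$site_id), sites$site_id)
  if (length(orphans)) {
    stop("occurrence record(s) reference unknown site_id: ",
         paste(orphans, collapse = ", "), call. = FALSE)
  }
  band_of <- setNames(sites$elevation_band_lower, sites$site_id)
  bands <- sort(unique(sites$elevation_band_lower))
  rec_band <- band_of[records$site_id]
  richness <- vapply(bands, function(b) {
    length(effective_taxa(records[rec_band == b, , drop = FALSE]))
  }, 0L)
  data.frame(band = bands, richness = richness)
}

#' Aggregate vegetation plots to site covariates
#'
#' Each plot's density is the mean of its five rod-touch counts; every
#' vegetation parameter is then averaged arithmetically over all plots of all
#' seasons at the site, giving one value per parameter per site.  The
#' structural measures are deliberately kept separate (no product index).
#' Eye-estimated covers need not sum exactly to 100; sums outside
#' `100 +/- cover_tol` raise a warning (or the vegetated fraction is rescaled
#' if `renormalise = TRUE`).
#'
#' @param plots vegetation plot table (see [read_vegetation_plots()]).
#' @param cover_tol tolerance on the cover sum, percentage points (default 5).
#' @param renormalise rescale the three covers to sum to 100 before
#'   averaging.  Default `FALSE` (values kept as recorded in the field).
#' @return a `data.frame` with one row per site: `site_id`, `veg_cover`,
#'   `veg_max_height`, `veg_height75`, `veg_density`.
#' @export
aggregate_vegetation <- function(plots, cover_tol = 5, renormalise = FALSE) {
  plots <- validate_vegetation_plots(plots)
  touch_cols <- paste0("touch", 1:5)
  plots$density <- rowMeans(plots[touch_cols])
  cover_sum <- plots$cover_vegetation + plots$cover_rock + plots$cover_bare
  off <- abs(cover_sum - 100) > cover_tol
  if (any(off)) {
    warning(sum(off), " plot(s) with cover sum outside 100 +/- ", cover_tol,
            call. = FALSE)
  }
  if (renormalise) {
    plots$cover_vegetation <- 100 * plots$cover_vegetation / cover_sum
  }
  agg <- aggregate(
    plots[, c("cover_vegetation", "max_height", "height75", "density")],
    by = list(site_id = plots$site_id), FUN = mean
  )
  names(agg) <- c("site_id", "veg_cover", "veg_max_height", "veg_height75",
                  "veg_density")
  agg[order(agg$site_id), , drop = FALSE]
}
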
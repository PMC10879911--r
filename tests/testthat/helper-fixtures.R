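# Fixture builders shared across test files.  Everything is constructed in
# code; no data files.

occ <- function(site, taxon, rank = "species", parent = "gen01", count = 1,
                method = "net", visit = "v1", season = "summer",
                suborder = "Caelifera", stage = "adult", flag = FALSE) {
  data.frame(site_id = site, visit_id = visit, season = season,
             method = method, taxon_id = taxon, rank = rank,
             parent_taxon = if (rank == "species") parent else "",
             suborder = suborder, life_stage = stage, count = count,
             distinct_flag = flag, stringsAsFactors = FALSE)
}

occ_tbl <- function(...) do.call(rbind, list(...))

sites_tbl <- function(bands, ids = NULL, area = "TOR") {
  n <- length(bands)
  data.frame(
    site_id = ids %||% paste0("S", seq_len(n)),
    study_area = rep_len(area, n),
    elevation_band_lower = bands,
    veg_cover = rep_len(c(80, 60, 40), n),
    veg_max_height = rep_len(c(50, 35, 20), n),
    veg_height75 = rep_len(c(30, 20, 12), n),
    veg_density = rep_len(c(6, 4, 2), n),
    slope = rep_len(c(10, 20, 30), n),
    aspect = rep_len(c(90, 180, 270), n),
    stringsAsFactors = FALSE
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# A fast, small scenario for tests that need a full community but not the
# default study scale.
small_scenario <- function(...) {
  scenario_config(
    site_layout = data.frame(study_area = rep(c("TOR", "MOL"), each = 4),
                             band = c(1100, 1300, 1500, 1700,
                                      1800, 2000, 2200, 2400)),
    n_species = 12, n_genera = 5,
    ...
  )
}
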
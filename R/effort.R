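#' Sampling-effort index for mixed net and hand surveys
#'
#' Standardises uneven survey effort across sites where sweep-net transects
#' were supplemented by hand captures.  The index is
#' \deqn{SE = \mathrm{surveys}_{NET} + \frac{\mathrm{total\_obs}_{HAND}}
#'   {\mathrm{mean\_obs}_{NET}}}
#' i.e. the hand-caught specimens are converted into the equivalent number of
#' net surveys that would have caught them.  SE is dimensionless (units of
#' net surveys) and equals `surveys_net` exactly when no specimens were
#' caught by hand.
#'
#' @param surveys_net number of net transect surveys at the site (>= 1).
#' @param total_obs_hand total specimens caught in hand surveys (>= 0).
#' @param mean_obs_net mean specimens per net survey (>= 0).
#' @param site_id optional identifier(s) used in error messages.
#' @return numeric vector of SE values.
#' @examples
#' sampling_effort(3, 8, 4)  # 3 net surveys + 8 hand captures at 4/net = 5
#' @export
sampling_effort <- function(surveys_net, total_obs_hand, mean_obs_net,
                            site_id = NULL) {
  if (any(surveys_net < 1)) {
    stop("surveys_net must be >= 1 for every surveyed site", call. = FALSE)
  }
  if (any(total_obs_hand < 0) || any(mean_obs_net < 0)) {
    stop("hand totals and net means must be non-negative", call. = FALSE)
  }
  undef <- total_obs_hand > 0 & mean_obs_net == 0
  if (any(undef)) {
    who <- if (is.null(site_id)) which(undef) else site_id[undef]
    stop("sampling effort undefined (hand captures but zero net captures) ",
         "at site(s): ", paste(who, collapse = ", "), call. = FALSE)
  }
  ifelse(total_obs_hand == 0, as.numeric(surveys_net),
         surveys_net + total_obs_hand / mean_obs_net)
}

#' Per-site effort components from occurrence records
#'
#' Derives `surveys_net`, `mean_obs_net`, `total_obs_hand` and the SE index
#' per site.  A survey is one (site, visit, method) pass.  If a visit
#' registry is supplied (see [read_visits()]), survey counts come from it, so
#' net surveys that caught nothing still count towards effort; otherwise
#' surveys are inferred from the capture records and empty surveys are
#' invisible.
#'
#' @param records occurrence records.
#' @param visits optional visit registry (`site_id, visit_id, season,
#'   method`), one row per survey pass.
#' @return a `data.frame` with columns `site_id, surveys_net, total_obs_hand,
#'   mean_obs_net, se_value`.
#' @export
effort_from_records <- function(records, visits = NULL) {
  net <- records[records$method == "net", , drop = FALSE]
  hand <- records[records$method == "hand", , drop = FALSE]
  site_ids <- sort(unique(c(records$site_id, visits$site_id)))

  if (is.null(visits)) {
    keys <- unique(net[, c("site_id", "visit_id")])
    n_net <- table(factor(keys$site_id, levels = site_ids))
  } else {
    vnet <- visits[visits$method == "net", , drop = FALSE]
    n_net <- table(factor(vnet$site_id, levels = site_ids))
  }
  n_net <- as.integer(n_net)

  no_net <- site_ids[n_net == 0]
  if (length(no_net)) {
    stop("SE undefined for site(s) without net surveys: ",
         paste(no_net, collapse = ", "), call. = FALSE)
  }

  sum_by_site <- function(df) {
    s <- tapply(df$count, factor(df$site_id, levels = site_ids), sum)
    ifelse(is.na(s), 0, s)
  }
  net_total <- sum_by_site(net)
  hand_total <- sum_by_site(hand)
  mean_net <- net_total / n_net

  data.frame(
    site_id = site_ids,
    surveys_net = n_net,
    total_obs_hand = as.numeric(hand_total),
    mean_obs_net = as.numeric(mean_net),
    se_value = sampling_effort(n_net, hand_total, mean_net, site_ids),
    stringsAsFactors = FALSE
  )
}
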